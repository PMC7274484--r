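#' Discretized meridional curve of an axisymmetric shape
#'
#' A `shape_curve` stores the upper (Z >= 0) quarter-meridian of a closed,
#' rotationally symmetric and Z-reflection-symmetric surface, from the pole
#' on the symmetry axis (R = 0, the dimple centre for a biconcave cell) to
#' the equator (Z = 0, the maximum radius). The full surface is recovered by
#' revolution about the Z axis plus reflection in the Z = 0 plane. All
#' lengths are in micrometres.
#'
#' @param s Arclength at each node (non-decreasing, starts at 0).
#' @param R Radius at each node (>= 0, first node on the axis).
#' @param Z Height at each node.
#' @param provenance One of `"parametric"`, `"simulated"`, `"synthetic"`.
#' @return An object of class `shape_curve` with fields `s`, `R`, `Z`,
#'   `N` (node count) and `provenance`.
#' @examples
#' crv <- sample_parametric(parametric_rbc(), 200)
#' characteristic_lengths(crv)
#' @export
shape_curve <- function(s, R, Z,
                        provenance = c("parametric", "simulated", "synthetic")) {
  provenance <- match.arg(provenance)
  s <- as.numeric(s)
  R <- as.numeric(R)
  Z <- as.numeric(Z)
  n <- length(s)
  if (n < 2L || length(R) != n || length(Z) != n) {
    stop("'s', 'R' and 'Z' must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(s)) || any(!is.finite(R)) || any(!is.finite(Z))) {
    stop("shape_curve coordinates must be finite", call. = FALSE)
  }
  if (any(diff(s) <= 0)) {
    stop("'s' must be strictly increasing", call. = FALSE)
  }
  if (min(R) < -1e-8) {
    stop("'R' must be non-negative", call. = FALSE)
  }
  R[R < 0] <- 0
  if (abs(R[1]) > 1e-6 * max(R)) {
    stop("first node must lie on the symmetry axis (R[1] = 0)", call. = FALSE)
  }
  R[1] <- 0
  structure(
    list(s = s - s[1], R = R, Z = Z, N = n, provenance = provenance),
    class = "shape_curve"
  )
}

#' @export
print.shape_curve <- function(x, ...) {
  cl <- characteristic_lengths(x)
  cat(sprintf(
    "<shape_curve> %d nodes, provenance '%s'\n  h_min = %.4f, h_max = %.4f, L = %.4f um (arclength %.4f um)\n",
    x$N, x$provenance, cl$h_min, cl$h_max, cl$L, x$s[x$N]
  ))
  invisible(x)
}

#' @export
as.data.frame.shape_curve <- function(x, ...) {
  data.frame(s = x$s, R = x$R, Z = x$Z)
}

#' Resample a shape curve uniformly in normalized arclength
#'
#' Interpolates `R(s)` and `Z(s)` with cubic splines at `N` nodes spaced
#' uniformly in `s`. Used to put a simulated and a reference curve on a
#' matched node set before computing point-wise shape errors.
#'
#' @param curve A [shape_curve].
#' @param N Target node count (>= 2).
#' @return A [shape_curve] with `N` nodes and the same provenance.
#' @export
resample_curve <- function(curve, N) {
  stopifnot(inherits(curve, "shape_curve"))
  stop_if_not_scalar(N, "N", positive = TRUE)
  N <- as.integer(N)
  if (N < 2L) stop("'N' must be at least 2", call. = FALSE)
  s_new <- seq(0, curve$s[curve$N], length.out = N)
  R_new <- stats::spline(curve$s, curve$R, xout = s_new, method = "fmm")$y
  Z_new <- stats::spline(curve$s, curve$Z, xout = s_new, method = "fmm")$y
  R_new[1] <- 0
  R_new[R_new < 0] <- 0
  shape_curve(s_new, R_new, Z_new, provenance = curve$provenance)
}

# Tangent angle and curvature fields of a shape_curve, computed by finite
# differences along the meridian. Convention: psi = atan2(-dZ/ds, dR/ds),
# so a sphere traversed pole -> equator has psi in [0, pi/2], meridional
# curvature k_m = dpsi/ds = +1/a, and mean curvature H = +1/a with the
# outward normal. The dimple of a biconcave cell has k_m < 0.
curvature_fields <- function(curve) {
  s <- curve$s
  dR <- deriv_grid(s, curve$R)
  dZ <- deriv_grid(s, curve$Z)
  psi <- atan2(-dZ, dR)
  # unwrap any branch jumps (the meridian never turns by more than pi here)
  jumps <- diff(psi)
  wrap <- cumsum(c(0, round(jumps / (2 * pi)))) * 2 * pi
  psi <- psi - wrap
  k_m <- deriv_grid(s, psi)
  k_p <- numeric(curve$N)
  k_p[-1] <- sin(psi[-1]) / curve$R[-1]
  k_p[1] <- k_m[1] # axis limit: both principal curvatures coincide
  H <- (k_m + k_p) / 2
  K <- k_m * k_p
  list(psi = psi, k_m = k_m, k_p = k_p, H = H, K = K)
}

#' Surface area, volume, sphericity and reduced volume of a shape curve
#'
#' Area is `2 * integral(2 pi R ds)` over the quarter-meridian (the factor 2
#' accounts for the Z-reflection), and volume is the signed solid of
#' revolution `2 * |integral(pi R^2 dZ)|`, both by composite trapezoid on
#' the curve nodes. The sphericity index uses the standard definition
#' `SI = pi^(1/3) (6V)^(2/3) / A` and the reduced volume is taken relative
#' to the sphere of equal area, `v = 6 sqrt(pi) V / A^(3/2)` (so `v = SI^(3/2)`).
#'
#' @param curve A [shape_curve].
#' @return A list with `A` (um^2), `V` (um^3), `SI` and `v`.
#' @export
geometry_measures <- function(curve) {
  stopifnot(inherits(curve, "shape_curve"))
  if (max(curve$R) <= 0) {
    stop("degenerate curve: all nodes on the symmetry axis", call. = FALSE)
  }
  A <- 2 * 2 * pi * pracma::trapz(curve$s, curve$R)
  dZ <- diff(curve$Z)
  Rmid2 <- (curve$R[-curve$N]^2 + curve$R[-1]^2) / 2
  V <- 2 * abs(sum(pi * Rmid2 * dZ))
  SI <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  v <- 6 * sqrt(pi) * V / A^(3 / 2)
  list(A = A, V = V, SI = SI, v = v)
}

#' Characteristic lengths of an axisymmetric cell shape
#'
#' Returns the three lengths that summarize a biconcave profile: the
#' minimum height at the dimple `h_min = 2 Z(R = 0)`, the maximum height at
#' the rim `h_max = 2 max(Z)`, and the maximum diameter `L = 2 max(R)`.
#'
#' @param curve A [shape_curve].
#' @return A list with `h_min`, `h_max` and `L` in micrometres.
#' @export
characteristic_lengths <- function(curve) {
  stopifnot(inherits(curve, "shape_curve"))
  list(
    h_min = 2 * curve$Z[1],
    h_max = 2 * max(curve$Z),
    L = 2 * max(curve$R)
  )
}

#' Write / read a shape curve as CSV plus a JSON sidecar
#'
#' The CSV holds columns `s,R,Z` in micrometres at full double precision
#' (17 significant digits, so a write/read round trip reproduces the curve
#' bit-exactly). A JSON sidecar `<path>.json` records the provenance and
#' the geometry measures.
#'
#' @param curve A [shape_curve].
#' @param path Output CSV path.
#' @return `write_shape_curve` returns `path` invisibly; `read_shape_curve`
#'   returns a [shape_curve].
#' @export
write_shape_curve <- function(curve, path) {
  stopifnot(inherits(curve, "shape_curve"))
  df <- data.frame(
    s = format_full(curve$s),
    R = format_full(curve$R),
    Z = format_full(curve$Z)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(provenance = curve$provenance, N = curve$N),
            geometry_measures(curve))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_curve
#' @export
read_shape_curve <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  meta_path <- paste0(path, ".json")
  provenance <- "parametric"
  if (file.exists(meta_path)) {
    provenance <- jsonlite::read_json(meta_path)$provenance
  }
  shape_curve(as.numeric(df$s), as.numeric(df$R), as.numeric(df$Z),
              provenance = provenance)
}
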
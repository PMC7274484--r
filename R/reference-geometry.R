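#' Evans-Fung parametric red blood cell profile
#'
#' Coefficients of the classic light-microscopy fit to the RZ cross-section
#' of a healthy human red blood cell. The half-thickness of the cell at
#' radius R is
#' \deqn{Z(R) = 0.5 \sqrt{1 - u^2} (c_0 + c_1 u^2 + c_2 u^4), \quad u = 2R/L,}
#' with the upper (positive) branch taken; the full biconcave surface is the
#' revolution of `+Z` and `-Z` about the symmetry axis.
#'
#' @param c0,c1,c2 Dimensionless profile coefficients.
#' @param L Maximum cell diameter in micrometres.
#' @return An object of class `parametric_rbc`.
#' @examples
#' p <- parametric_rbc()
#' evans_fung_z(0, p) # half the dimple height, 0.405 um
#' @export
parametric_rbc <- function(c0 = 0.81, c1 = 7.83, c2 = -4.39, L = 7.82) {
  stop_if_not_scalar(c0, "c0")
  stop_if_not_scalar(c1, "c1")
  stop_if_not_scalar(c2, "c2")
  stop_if_not_scalar(L, "L", positive = TRUE)
  obj <- structure(list(c0 = c0, c1 = c1, c2 = c2, L = L),
                   class = "parametric_rbc")
  z_edge <- evans_fung_z(L / 2, obj)
  if (!is.finite(z_edge) || abs(z_edge) > 1e-12) {
    stop("invalid profile: Z(L/2) must vanish", call. = FALSE)
  }
  obj
}

#' @export
print.parametric_rbc <- function(x, ...) {
  cat(sprintf(
    "<parametric_rbc> Z(R) = 0.5 sqrt(1-u^2) (%.3g %+.3g u^2 %+.3g u^4), u = 2R/%.3g um\n",
    x$c0, x$c1, x$c2, x$L
  ))
  invisible(x)
}

#' Half-thickness of the parametric red blood cell profile
#'
#' Evaluates the upper branch of the biconcave profile at radius `R`.
#'
#' @param R Radius (or vector of radii) in micrometres, within `[0, L/2]`.
#' @param params A [parametric_rbc].
#' @return Signed half-thickness Z in micrometres (positive branch).
#' @export
evans_fung_z <- function(R, params = parametric_rbc()) {
  stopifnot(inherits(params, "parametric_rbc"))
  if (any(!is.finite(R)) || any(R < -1e-12) || any(R > params$L / 2 + 1e-12)) {
    stop("'R' must lie in [0, L/2]", call. = FALSE)
  }
  u2 <- pmin((2 * R / params$L)^2, 1)
  0.5 * sqrt(1 - u2) * (params$c0 + params$c1 * u2 + params$c2 * u2^2)
}

# Analytic derivatives of the profile via symbolic differentiation of the
# closed form; returns dZ/dR and d2Z/dR2 at the given radii. Kept separate
# from the finite-difference path so the two can cross-check each other.
evans_fung_deriv <- function(R, params = parametric_rbc()) {
  expr <- stats::deriv(
    ~ 0.5 * sqrt(1 - (2 * R / L)^2) *
      (c0 + c1 * (2 * R / L)^2 + c2 * (2 * R / L)^4),
    "R",
    function.arg = c("R", "c0", "c1", "c2", "L"),
    hessian = TRUE
  )
  out <- expr(R, params$c0, params$c1, params$c2, params$L)
  list(
    Z = as.numeric(out),
    dZ = as.numeric(attr(out, "gradient")),
    d2Z = as.numeric(attr(out, "hessian"))
  )
}

# Analytic curvatures of the revolved Evans-Fung surface at radii R
# (upper branch, outward normal pointing away from the cell interior).
# k_m is the meridional curvature (negative in the dimple), k_p the
# circumferential one; at the axis both tend to the same limit.
evans_fung_curvatures <- function(R, params = parametric_rbc()) {
  d <- evans_fung_deriv(R, params)
  k_m <- -d$d2Z / (1 + d$dZ^2)^(3 / 2)
  k_p <- ifelse(R > 0, -d$dZ / (R * sqrt(1 + d$dZ^2)), k_m)
  # at the axis dZ/R -> d2Z, so k_p -> k_m; patch any 0/0 at R = 0
  on_axis <- R == 0
  k_p[on_axis] <- k_m[on_axis]
  list(k_m = k_m, k_p = k_p, H = (k_m + k_p) / 2, K = k_m * k_p)
}

#' Sample the parametric reference shape as a discrete meridian
#'
#' Discretizes the quarter-meridian of the parametric profile (from the
#' dimple pole at R = 0 to the equator at Z = 0) into `N` nodes spaced
#' uniformly in arclength. The arclength is accumulated by composite
#' trapezoid quadrature of the speed along a dense regularized grid
#' `R = (L/2) sin(theta)` (which removes the square-root singularity of
#' `dZ/dR` at the equator), and node positions are found by monotone
#' interpolation of the arclength map.
#'
#' @param params A [parametric_rbc].
#' @param N Number of nodes (>= 16).
#' @param dense Size of the internal quadrature grid.
#' @return A [shape_curve] with provenance `"parametric"`.
#' @export
sample_parametric <- function(params = parametric_rbc(), N = 200L,
                              dense = 8192L) {
  stopifnot(inherits(params, "parametric_rbc"))
  stop_if_not_scalar(N, "N", positive = TRUE)
  if (N < 16L) stop("'N' must be at least 16", call. = FALSE)
  theta <- seq(0, pi / 2, length.out = dense)
  Rg <- params$L / 2 * sin(theta)
  d <- evans_fung_deriv(Rg, params)
  dRdt <- params$L / 2 * cos(theta)
  dZdt <- d$dZ * dRdt
  # at theta = pi/2 the product dZ/dR * dR/dtheta has a finite limit; the
  # grid endpoint evaluates to NaN * 0, replace by one-sided extrapolation
  bad <- !is.finite(dZdt)
  if (any(bad)) {
    dZdt[bad] <- stats::approx(theta[!bad], dZdt[!bad], xout = theta[bad],
                               rule = 2)$y
  }
  speed <- sqrt(dRdt^2 + dZdt^2)
  s_dense <- pracma::cumtrapz(theta, speed)[, 1]
  S <- s_dense[dense]
  s_nodes <- seq(0, S, length.out = N)
  th_of_s <- stats::splinefun(s_dense, theta, method = "monoH.FC")
  th_nodes <- pmin(pmax(th_of_s(s_nodes), 0), pi / 2)
  R_nodes <- params$L / 2 * sin(th_nodes)
  Z_nodes <- evans_fung_z(R_nodes, params)
  shape_curve(s_nodes, R_nodes, Z_nodes, provenance = "parametric")
}
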
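#' Perturb a reference shape with smooth correlated measurement noise
#'
#' Emulates the measurement uncertainty of the parametric reference
#' profile: the height is modulated by a smooth random field with
#' pointwise envelope `noise_frac * |Z|` (the reference uncertainty is
#' about 10% of the mean profile), leaving the radius untouched. The
#' noise is white Gaussian at the nodes, smoothed with a Gaussian kernel
#' whose width is a fixed fraction of the meridian, and rescaled so its
#' maximum modulus is exactly 1, which guarantees the envelope bound.
#' Deterministic for a given seed; the caller's RNG state is untouched.
#'
#' @param ref Reference [shape_curve].
#' @param noise_frac Relative noise envelope (default 0.10).
#' @param seed Integer seed.
#' @param corr_frac Smoothing kernel width as a fraction of the total
#'   arclength (default 0.1).
#' @return A [shape_curve] with provenance `"synthetic"` (or `ref`
#'   unchanged when `noise_frac = 0`).
#' @export
generate_noisy_shape <- function(ref, noise_frac = 0.10, seed,
                                 corr_frac = 0.1) {
  stopifnot(inherits(ref, "shape_curve"))
  if (!is.numeric(noise_frac) || noise_frac < 0) {
    stop("'noise_frac' must be non-negative", call. = FALSE)
  }
  if (noise_frac == 0) {
    return(ref)
  }
  n <- ref$N
  g <- with_seed(seed, {
    eta <- stats::rnorm(n)
    S <- ref$s[n]
    sigma <- corr_frac * S
    # Gaussian-kernel smoothing on the arclength grid
    W <- exp(-0.5 * (outer(ref$s, ref$s, "-") / sigma)^2)
    sm <- as.numeric(W %*% eta) / rowSums(W)
    sm / max(abs(sm))
  })
  shape_curve(ref$s, ref$R, ref$Z * (1 + noise_frac * g),
              provenance = "synthetic")
}

#' Generate a synthetic 3D myosin puncta point pattern inside a cell
#'
#' Draws homogeneous Poisson point patterns in the dimple and rim regions
#' of the closed biconcave volume, with the prescribed region intensities
#' (puncta per cubic micrometre). The dimple region is the part of the
#' cell inside the coaxial cylinder through the dimple/rim boundary
#' radius `R_d` (the meridional-curvature sign change); the rim is the
#' rest. Points are placed by rejection sampling against the interpolated
#' surface height, so they lie exactly inside the revolved surface.
#'
#' @param shape A biconcave [shape_curve] (e.g. [sample_parametric] or a
#'   solved shape).
#' @param density_dimple,density_rim Region intensities in um^-3
#'   (defaults 2.15 and 1.70, the measured dimple and rim puncta
#'   densities).
#' @param seed Integer seed.
#' @return An object of class `puncta_dataset`: a list with `points`
#'   (data.frame x, y, z, region), `R_d`, `partition`, the generating
#'   `densities`, `seed` and the `shape`.
#' @export
generate_puncta <- function(shape, density_dimple = 2.15,
                            density_rim = 1.70, seed) {
  stopifnot(inherits(shape, "shape_curve"))
  if (density_dimple < 0 || density_rim < 0) {
    stop("densities must be non-negative", call. = FALSE)
  }
  part <- dimple_rim_partition(shape)
  if (part$V_dimple <= 0 || part$V_rim <= 0) {
    stop("degenerate region volume", call. = FALSE)
  }
  # single-valued upper envelope Z(r) of the meridian
  ord <- order(shape$R)
  r_knots <- shape$R[ord]
  z_knots <- shape$Z[ord]
  z_of_r <- stats::approxfun(r_knots, z_knots, rule = 2)
  R_max <- max(shape$R)

  sample_region <- function(n_target, r_lo, r_hi) {
    if (n_target == 0) {
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
    }
    z_cap <- max(z_knots[r_knots >= r_lo - 1e-9 & r_knots <= r_hi + 1e-9],
                 0) # bounding slab height for this annulus
    out <- matrix(numeric(0), ncol = 3)
    while (nrow(out) < n_target) {
      m <- max(2L * (n_target - nrow(out)), 32L)
      # uniform in the bounding annulus x slab
      r <- sqrt(stats::runif(m, r_lo^2, r_hi^2))
      z <- stats::runif(m, -z_cap, z_cap)
      keep <- abs(z) <= z_of_r(r)
      if (any(keep)) {
        th <- stats::runif(sum(keep), 0, 2 * pi)
        out <- rbind(out, cbind(r[keep] * cos(th), r[keep] * sin(th),
                                z[keep]))
      }
    }
    out <- out[seq_len(n_target), , drop = FALSE]
    data.frame(x = out[, 1], y = out[, 2], z = out[, 3])
  }

  pts <- with_seed(seed, {
    n_dimple <- stats::rpois(1, density_dimple * part$V_dimple)
    n_rim <- stats::rpois(1, density_rim * part$V_rim)
    pd <- sample_region(n_dimple, 0, part$R_d)
    pr <- sample_region(n_rim, part$R_d, R_max)
    pd$region <- rep("dimple", nrow(pd))
    pr$region <- rep("rim", nrow(pr))
    rbind(pd, pr)
  })

  structure(
    list(points = pts, R_d = part$R_d, partition = part,
         densities = c(dimple = density_dimple, rim = density_rim),
         seed = seed, shape = shape),
    class = "puncta_dataset"
  )
}

#' @export
print.puncta_dataset <- function(x, ...) {
  cat(sprintf(
    "<puncta_dataset> %d puncta (%d dimple / %d rim), R_d = %.3f um, seed %s\n",
    nrow(x$points), sum(x$points$region == "dimple"),
    sum(x$points$region == "rim"), x$R_d, format(x$seed)
  ))
  invisible(x)
}

#' Quantify a puncta dataset the way 3D image stacks are analysed
#'
#' Splits the cell volume at the dimple cylinder, counts puncta per
#' region and reports densities and their dimple/rim ratio. Region
#' membership is recomputed from the coordinates (not taken from the
#' generator labels), mirroring an analysis pipeline that only sees
#' point coordinates and the segmented cell.
#'
#' @param data A [generate_puncta] dataset.
#' @return A list with `n_total`, `n_dimple`, `n_rim`,
#'   `pct_volume_dimple`, `pct_puncta_dimple`, `density_total`,
#'   `density_dimple`, `density_rim` and `ratio`
#'   (`density_dimple / density_rim`; `Inf` if the rim is empty).
#' @export
puncta_density_analysis <- function(data) {
  stopifnot(inherits(data, "puncta_dataset"))
  pts <- data$points
  if (nrow(pts) < 1) {
    stop("dataset contains no puncta", call. = FALSE)
  }
  part <- data$partition
  r <- sqrt(pts$x^2 + pts$y^2)
  in_dimple <- r <= data$R_d
  n_d <- sum(in_dimple)
  n_r <- sum(!in_dimple)
  d_d <- n_d / part$V_dimple
  d_r <- n_r / part$V_rim
  list(
    n_total = nrow(pts), n_dimple = n_d, n_rim = n_r,
    pct_volume_dimple = 100 * part$V_dimple / part$V,
    pct_puncta_dimple = 100 * n_d / nrow(pts),
    density_total = nrow(pts) / part$V,
    density_dimple = d_d,
    density_rim = d_r,
    ratio = if (n_r == 0) Inf else d_d / d_r
  )
}
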
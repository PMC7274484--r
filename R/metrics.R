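#' Shape-error report against the parametric reference
#'
#' Quantifies how far a simulated meridian deviates from a reference one.
#' Both curves are resampled to `N` nodes spaced uniformly in their own
#' normalized arclength (node i of one curve is mapped to node i of the
#' other), and the report contains the three characteristic-length errors
#' \deqn{\epsilon_{hmin} = |\Delta h_{min}|/L_{par}, \quad
#'       \epsilon_{hmax} = |\Delta h_{max}|/L_{par}, \quad
#'       \epsilon_L = |\Delta L|/L_{par},}
#' and the total point-wise error. Two conventions for the total error are
#' provided: `"printed"` follows the formula as typeset in the source
#' model, with the prefactor 1/N outside the square root,
#' \deqn{\epsilon_{total} = \frac{1}{N}\sqrt{\sum_i (\Delta Z_i)^2 + (\Delta R_i)^2} / L_{par},}
#' while `"rms"` (the default, and the quantity the printed percentages
#' are on the order of) uses the root mean square,
#' \deqn{\epsilon_{total} = \sqrt{\tfrac{1}{N}\sum_i (\Delta Z_i)^2 + (\Delta R_i)^2} / L_{par}.}
#' Measurement uncertainty of the reference is propagated by re-evaluating
#' the error against the reference with its height scaled by (1 +/- 10%),
#' giving the envelope `eps_total_lo`/`eps_total_hi`.
#'
#' @param sim Simulated [shape_curve].
#' @param ref Reference [shape_curve] (typically [sample_parametric]).
#' @param N Number of matched nodes (default 200).
#' @param convention `"rms"` or `"printed"` (see above).
#' @param z_error_frac Relative half-width of the reference uncertainty
#'   band (default 0.10).
#' @return An object of class `error_report`: a list with `eps_hmin`,
#'   `eps_hmax`, `eps_L`, `eps_total`, `eps_total_lo`, `eps_total_hi` (all
#'   fractions of `L_par`), plus `N` and `convention`.
#' @export
shape_errors <- function(sim, ref, N = 200L,
                         convention = c("rms", "printed"),
                         z_error_frac = 0.10) {
  stopifnot(inherits(sim, "shape_curve"), inherits(ref, "shape_curve"))
  convention <- match.arg(convention)
  N <- as.integer(N)
  if (N < 8L) stop("'N' must be at least 8", call. = FALSE)
  L_par <- characteristic_lengths(ref)$L
  sim_r <- resample_curve(sim, N)

  point_err <- function(ref_curve) {
    ref_r <- resample_curve(ref_curve, N)
    ss <- sum((sim_r$Z - ref_r$Z)^2 + (sim_r$R - ref_r$R)^2)
    if (convention == "rms") sqrt(ss / N) / L_par else sqrt(ss) / N / L_par
  }

  scale_ref <- function(fac) {
    shape_curve(ref$s, ref$R, ref$Z * fac, provenance = ref$provenance)
  }

  cl_sim <- characteristic_lengths(sim)
  cl_ref <- characteristic_lengths(ref)
  e0 <- point_err(ref)
  elo <- point_err(scale_ref(1 - z_error_frac))
  ehi <- point_err(scale_ref(1 + z_error_frac))
  structure(
    list(
      eps_hmin = abs(cl_ref$h_min - cl_sim$h_min) / L_par,
      eps_hmax = abs(cl_ref$h_max - cl_sim$h_max) / L_par,
      eps_L = abs(cl_ref$L - cl_sim$L) / L_par,
      eps_total = e0,
      eps_total_lo = min(e0, elo, ehi),
      eps_total_hi = max(e0, elo, ehi),
      N = N,
      convention = convention
    ),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> eps_total = %.3f%% [%.3f, %.3f] (%s, N = %d)\n  eps_hmin = %.3f%%, eps_hmax = %.3f%%, eps_L = %.3f%%\n",
    100 * x$eps_total, 100 * x$eps_total_lo, 100 * x$eps_total_hi,
    x$convention, x$N,
    100 * x$eps_hmin, 100 * x$eps_hmax, 100 * x$eps_L
  ))
  invisible(x)
}

#' Classify the regime of a solved shape
#'
#' A shape is `"spherical"` when rim and dimple heights coincide
#' (`h_max - h_min < tol * L`), `"kissing"` when the dimple has (nearly)
#' closed (`h_min < kiss_frac * L`), and `"biconcave"` otherwise.
#'
#' @param curve A [shape_curve].
#' @param tol Relative height-split tolerance for the spherical label.
#' @param kiss_frac Relative dimple-closure threshold.
#' @return Character label.
#' @export
classify_regime <- function(curve, tol = 0.01, kiss_frac = 0.01) {
  stopifnot(inherits(curve, "shape_curve"))
  cl <- characteristic_lengths(curve)
  if (cl$h_min < kiss_frac * cl$L) {
    "kissing"
  } else if (cl$h_max - cl$h_min < tol * cl$L) {
    "spherical"
  } else {
    "biconcave"
  }
}

#' Partition a biconcave shape into dimple and rim regions
#'
#' The dimple/rim boundary is the point where the meridional curvature
#' changes sign along the arclength (concave near the axis, convex at the
#' rim). Membrane area is split along the meridian at that point; the
#' enclosed volume is split by the coaxial cylinder of radius `R_d`
#' through the boundary, matching how dimple volumes are segmented in 3D
#' image stacks.
#'
#' @param curve A biconcave [shape_curve].
#' @return An object of class `region_partition` with `R_d`, `s_d`,
#'   `A_dimple`, `A_rim`, `V_dimple`, `V_rim`, `A`, `V`.
#' @export
dimple_rim_partition <- function(curve) {
  stopifnot(inherits(curve, "shape_curve"))
  cf <- curvature_fields(curve)
  k <- cf$k_m
  n <- curve$N
  # ignore the immediate pole/equator nodes where one-sided differences
  # are least accurate
  idx <- which(k[-n] * k[-1] < 0)
  idx <- idx[idx > 2 & idx < n - 2]
  if (k[3] >= 0 || length(idx) == 0) {
    stop("no meridional curvature sign change: shape is not biconcave",
         call. = FALSE)
  }
  i <- idx[1]
  frac <- k[i] / (k[i] - k[i + 1])
  s_d <- curve$s[i] + frac * (curve$s[i + 1] - curve$s[i])
  R_d <- curve$R[i] + frac * (curve$R[i + 1] - curve$R[i])
  Z_d <- curve$Z[i] + frac * (curve$Z[i + 1] - curve$Z[i])

  meas <- geometry_measures(curve)
  # area split along the meridian at s_d (factor 2: reflection)
  s_cut <- c(curve$s[seq_len(i)], s_d)
  R_cut <- c(curve$R[seq_len(i)], R_d)
  A_dimple <- 2 * 2 * pi * pracma::trapz(s_cut, R_cut)
  # volume inside the coaxial cylinder r <= R_d: V = 2 * int 2 pi r z dr
  Z_cut <- c(curve$Z[seq_len(i)], Z_d)
  V_dimple <- 2 * 2 * pi * pracma::trapz(R_cut, R_cut * Z_cut)
  structure(
    list(
      R_d = R_d, s_d = s_d,
      A_dimple = A_dimple, A_rim = meas$A - A_dimple,
      V_dimple = V_dimple, V_rim = meas$V - V_dimple,
      A = meas$A, V = meas$V
    ),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition> R_d = %.3f um; A_dimple = %.2f (%.1f%%), V_dimple = %.2f um^3 (%.1f%% of V)\n",
    x$R_d, x$A_dimple, 100 * x$A_dimple / x$A,
    x$V_dimple, 100 * x$V_dimple / x$V
  ))
  invisible(x)
}

#' Dimple-to-rim ratio of force per unit volume
#'
#' \deqn{F_{ratio} = \frac{F_{dimple}}{F_{rim}} \cdot
#'       \frac{A_{dimple} V_{rim}}{A_{rim} V_{dimple}}.}
#' The force densities act per unit membrane area, so `F * A / V` is the
#' force per unit enclosed volume of each region.
#'
#' @param profile A [force_profile].
#' @param part A [dimple_rim_partition] of the solved shape.
#' @return The dimensionless ratio (`Inf` when `F_rim` is zero).
#' @export
force_ratio <- function(profile, part) {
  stopifnot(inherits(profile, "force_profile"),
            inherits(part, "region_partition"))
  if (profile$F_rim == 0) {
    return(Inf)
  }
  (profile$F_dimple / profile$F_rim) *
    (part$A_dimple * part$V_rim) / (part$A_rim * part$V_dimple)
}

#' Myosin motor-domain counts implied by a force configuration
#'
#' Converts the continuum force densities into numbers of active myosin
#' motor domains, assuming each domain exerts `f_single` piconewtons. Two
#' readings of "force per region" are reported: `area` integrates the
#' force density over the region's membrane area (`|F| A / f_single`), and
#' `volume` first converts to force per unit region volume and weights by
#' volume (`(|F| A / V) * V / f_single`); the two coincide for an exact
#' partition and are kept separate as a bookkeeping cross-check.
#'
#' @param profile A [force_profile].
#' @param part A [dimple_rim_partition].
#' @param f_single Force per motor domain in pN (default 2).
#' @return A list with `n_dimple`, `n_rim`, `n_total` (rounded counts) and
#'   the unrounded per-area and per-volume variants.
#' @export
estimate_motor_counts <- function(profile, part, f_single = 2) {
  stopifnot(inherits(profile, "force_profile"),
            inherits(part, "region_partition"))
  stop_if_not_scalar(f_single, "f_single", positive = TRUE)
  raw_d <- abs(profile$F_dimple) * part$A_dimple / f_single
  raw_r <- abs(profile$F_rim) * part$A_rim / f_single
  vol_d <- (abs(profile$F_dimple) * part$A_dimple / part$V_dimple) *
    part$V_dimple / f_single
  vol_r <- (abs(profile$F_rim) * part$A_rim / part$V_rim) *
    part$V_rim / f_single
  list(
    n_dimple = round(raw_d), n_rim = round(raw_r),
    n_total = round(raw_d) + round(raw_r),
    area = c(dimple = raw_d, rim = raw_r),
    volume = c(dimple = vol_d, rim = vol_r)
  )
}
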
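#' Spatial profile of myosin-mimicking force densities along the meridian
#'
#' Describes the applied force density per unit membrane area as a function
#' of normalized arclength t in [0, 1] along the quarter-meridian (t = 0 at
#' the dimple pole, t = 1 at the equator). The magnitude interpolates
#' smoothly between a dimple plateau and a rim plateau through a hyperbolic
#' tangent,
#' \deqn{F(t) = F_{rim} + (F_{dimple} - F_{rim}) \tfrac12 [1 - \tanh((t - t^*)/w)],}
#' and the force vector makes an angle `phi` with the meridional tangent
#' direction. Positive plateau values mean pulling (force along the inward
#' normal, -n); negative values mean pushing (outward). The tangential
#' component, present for `phi < 90`, points from the pole toward the
#' equator (+a_s).
#'
#' @param F_dimple Signed force density in the dimple plateau (pN/um^2,
#'   positive = pulling).
#' @param F_rim Signed force density in the rim plateau (pN/um^2).
#' @param phi Orientation angle in degrees relative to the tangent
#'   (90 = purely normal, 0 = purely tangential).
#' @param t_star Transition location. The default 0.45 (fraction of the
#'   quarter-meridian) is calibrated so that the dimple-only force window
#'   reproduces the spherical/biconcave/kissing regime boundaries of the
#'   modeled landscape; `"auto"` instead places the transition where the
#'   meridional curvature of the reference shape changes sign (the
#'   geometric dimple/rim boundary, a noticeably smaller fraction).
#'   Interpreted in the units selected by `coord`: a fraction of the
#'   quarter-meridian for `"normalized"`, micrometres of arclength for
#'   `"arclength"`.
#' @param w Transition sharpness, in the same units as `t_star`
#'   (default 0.05 of the quarter-meridian).
#' @param coord Coordinate in which the tanh transition is expressed.
#'   `"normalized"` (default) ties the transition to the fraction of the
#'   deformed meridian; `"arclength"` pins it at a fixed physical distance
#'   from the pole along the meridian; `"radius"` pins it at a fixed
#'   cylindrical radius (micrometres), which makes the load a conservative
#'   spatial pressure field for normal forcing and is the form the energy
#'   oracle can check exactly.
#' @param reference A [parametric_rbc] used to resolve `t_star = "auto"`
#'   and the default `w`.
#' @return An object of class `force_profile`.
#' @examples
#' force_profile(3.73, 0)            # dimple-only pulling force
#' force_profile(1.83, 1.83)         # uniform pulling force
#' force_profile(5, 1, phi = 60)     # oblique forces
#' @export
force_profile <- function(F_dimple, F_rim, phi = 90, t_star = 0.45,
                          w = NULL,
                          coord = c("normalized", "arclength", "radius"),
                          reference = parametric_rbc()) {
  coord <- match.arg(coord)
  stop_if_not_scalar(F_dimple, "F_dimple")
  stop_if_not_scalar(F_rim, "F_rim")
  stop_if_not_scalar(phi, "phi")
  if (phi < 0 || phi > 90) stop("'phi' must lie in [0, 90]", call. = FALSE)
  S_ref <- reference_arclength(reference)
  if (identical(t_star, "auto")) {
    t_star <- dimple_boundary_fraction(reference)
    if (coord == "arclength") t_star <- t_star * S_ref
    if (coord == "radius") {
      crv <- sample_parametric(reference, N = 2001L)
      t_star <- stats::approx(crv$s / crv$s[2001], crv$R, xout = t_star)$y
    }
  }
  if (is.null(w)) {
    w <- if (coord == "normalized") 0.05 else 0.05 * S_ref
  }
  stop_if_not_scalar(t_star, "t_star")
  stop_if_not_scalar(w, "w", positive = TRUE)
  upper <- if (coord == "normalized") 1 else Inf
  if (t_star <= 0 || t_star >= upper) {
    stop("'t_star' must be positive (and < 1 in normalized coordinates)",
         call. = FALSE)
  }
  structure(
    list(F_dimple = F_dimple, F_rim = F_rim, phi = phi,
         t_star = t_star, w = w, coord = coord),
    class = "force_profile"
  )
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf(
    "<force_profile> F_dimple = %.4g, F_rim = %.4g pN/um^2, phi = %.1f deg, t* = %.4f, w = %.3f (%s)\n",
    x$F_dimple, x$F_rim, x$phi, x$t_star, x$w, x$coord
  ))
  invisible(x)
}

# Quarter-meridian arclength of a reference profile (cached).
reference_arclength <- local({
  cache <- new.env(parent = emptyenv())
  function(reference = parametric_rbc()) {
    key <- paste(reference$c0, reference$c1, reference$c2, reference$L)
    if (is.null(cache[[key]])) {
      crv <- sample_parametric(reference, N = 2001L)
      cache[[key]] <- crv$s[crv$N]
    }
    cache[[key]]
  }
})

# Arclength fraction of the dimple/rim boundary of a reference shape:
# the point where the meridional curvature changes sign. Cached per
# coefficient set since it is reused by every profile construction.
dimple_boundary_fraction <- local({
  cache <- new.env(parent = emptyenv())
  function(reference = parametric_rbc()) {
    key <- paste(reference$c0, reference$c1, reference$c2, reference$L)
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    crv <- sample_parametric(reference, N = 4001L)
    cf <- evans_fung_curvatures(crv$R, reference)
    k <- cf$k_m
    idx <- which(k[-1] * k[-length(k)] < 0)
    if (length(idx) == 0) {
      stop("reference shape has no meridional curvature sign change",
           call. = FALSE)
    }
    i <- idx[1]
    # linear interpolation of the zero crossing in arclength
    frac <- k[i] / (k[i] - k[i + 1])
    s_star <- crv$s[i] + frac * (crv$s[i + 1] - crv$s[i])
    val <- s_star / crv$s[crv$N]
    cache[[key]] <- val
    val
  }
})

#' Normal and tangential force-density components along the meridian
#'
#' Evaluates the tanh force profile at normalized arclength `t` and
#' projects it on the local surface frame. The returned `f_n` is the
#' component along the outward normal (negative for a pulling force) and
#' `f_t` the component along the pole-to-equator tangent.
#'
#' @param t Normalized arclength in `[0, 1]` (vectorized).
#' @param profile A [force_profile].
#' @param S Total quarter-meridian arclength in micrometres; required when
#'   the profile transition is expressed in physical arclength.
#' @param r Cylindrical radius at the evaluation points (micrometres);
#'   required when the transition is expressed in radius.
#' @return A list with `magnitude`, `f_n` and `f_t` (pN/um^2).
#' @export
force_density <- function(t, profile, S = NULL, r = NULL) {
  stopifnot(inherits(profile, "force_profile"))
  if (any(t < -1e-9) || any(t > 1 + 1e-9)) {
    stop("'t' must lie in [0, 1]", call. = FALSE)
  }
  pos <- switch(profile$coord,
    "normalized" = t,
    "arclength" = {
      if (is.null(S)) {
        stop("'S' is required for an arclength-coordinate profile",
             call. = FALSE)
      }
      t * S
    },
    "radius" = {
      if (is.null(r)) {
        stop("'r' is required for a radius-coordinate profile",
             call. = FALSE)
      }
      r
    }
  )
  Fmag <- profile$F_rim + (profile$F_dimple - profile$F_rim) *
    0.5 * (1 - tanh((pos - profile$t_star) / profile$w))
  phi_rad <- profile$phi * pi / 180
  # Sign convention: in the arclength frame used by the solver (psi
  # measured so that the sphere has H = +1/a with the outward normal), a
  # PULLING force density (positive plateau, directed along the inward
  # normal) enters the normal force balance with a positive sign; a
  # pushing force enters negatively. The tangential component points from
  # the pole toward the equator.
  list(
    magnitude = Fmag,
    f_n = Fmag * sin(phi_rad),
    f_t = Fmag * cos(phi_rad)
  )
}

# Scale the plateau magnitudes (used by force continuation).
scale_profile <- function(profile, tau) {
  profile$F_dimple <- profile$F_dimple * tau
  profile$F_rim <- profile$F_rim * tau
  profile
}
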
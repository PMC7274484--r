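#' Direct energy-minimization oracle for equilibrium shapes
#'
#' Independent cross-check of the boundary-value solver: instead of
#' solving the Euler-Lagrange (shape) equation, this routine minimizes
#' the discretized energy directly over nodal tangent angles. The curve
#' is parameterized by the tangent angle `psi(t)` at `n_nodes` points on
#' the quarter-meridian plus the total arclength `S`; positions follow by
#' quadrature, the bending energy by the trapezoid rule, the fixed-area
#' constraint by a stiff quadratic penalty, and the minimization runs
#' L-BFGS-B from the analytic sphere (no information from the BVP path
#' enters). Normal pulling forces are represented by their conservative
#' spatial-field potential `U = integral of p(radius) over the enclosed
#' volume`, with the tanh profile mapped onto cylindrical radius through
#' the reference geometry; purely tangential or oblique forcing has no
#' such potential (follower force) and is rejected.
#'
#' This variational problem fixes the total area and lets the tension
#' level arise as its Lagrange multiplier, so it cross-checks the
#' `"free-tension"` closure of [solve_shape].
#'
#' @param params A [membrane_params] (`lambda0` only shifts the energy by
#'   a constant at fixed area and is ignored).
#' @param profile A [force_profile] with `phi = 90`.
#' @param n_nodes Coarse mesh size (default 61, at most 101).
#' @param reference [parametric_rbc] used to map the transition location
#'   to a radius.
#' @param penalty Area-penalty weight relative to `kappa` (default 2e5).
#' @param init `"sphere"` (default) or `"reference"` starting curve.
#' @return A list with `curve` (a [shape_curve]), `energy`, `area`,
#'   `volume`, `convergence` (optim code, 0 = success) and `counts`.
#' @export
energy_minimization_oracle <- function(params, profile, n_nodes = 61L,
                                       reference = parametric_rbc(),
                                       penalty = 2e5,
                                       init = c("sphere", "reference")) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(profile, "force_profile"))
  init <- match.arg(init)
  if (profile$phi != 90) {
    stop("the energy oracle is defined for normal forcing (phi = 90) only",
         call. = FALSE)
  }
  M <- as.integer(n_nodes)
  if (M < 21L || M > 101L) {
    stop("'n_nodes' must be between 21 and 101 (coarse mesh)", call. = FALSE)
  }
  tg <- seq(0, 1, length.out = M)
  kappa <- params$kappa
  A_target <- params$A_total

  # transition expressed as a spatial field in cylindrical radius; for
  # meridian-coordinate profiles the mapping goes through the reference
  # geometry (approximate -- the exact dual of the BVP load is the
  # "radius" coordinate)
  if (profile$coord == "radius") {
    R_star <- profile$t_star
    w_R <- profile$w
  } else {
    ref_crv <- sample_parametric(reference, N = 1001L)
    S_ref <- ref_crv$s[1001]
    t_star_frac <- if (profile$coord == "arclength") {
      profile$t_star / S_ref
    } else {
      profile$t_star
    }
    w_frac <- if (profile$coord == "arclength") {
      profile$w / S_ref
    } else {
      profile$w
    }
    R_star <- stats::approx(ref_crv$s / S_ref, ref_crv$R,
                            xout = min(max(t_star_frac, 0), 1))$y
    w_R <- max(w_frac * S_ref, 1e-3)
  }
  p_field <- function(r) {
    profile$F_rim + (profile$F_dimple - profile$F_rim) *
      0.5 * (1 - tanh((r - R_star) / w_R))
  }

  cum_weights <- function(v) {
    # trapezoid cumulative integral on the uniform unit grid
    dt <- 1 / (M - 1)
    c(0, cumsum((v[-M] + v[-1]) / 2 * dt))
  }

  counts <- 0L
  objective <- function(theta) {
    counts <<- counts + 1L
    psi <- c(0, theta[seq_len(M - 2L)], pi / 2)
    S <- theta[M - 1L]
    r <- S * cum_weights(cos(psi))
    z_from_eq <- S * cum_weights(rev(sin(psi)))
    z <- rev(z_from_eq)
    k_m <- deriv_grid(tg, psi) / S
    k_p <- c(k_m[1], sin(psi[-1]) / pmax(r[-1], 1e-9))
    H <- (k_m + k_p) / 2
    ring <- 2 * pi * r
    dt <- 1 / (M - 1)
    E_b <- 2 * kappa * S * sum(((H^2 * ring)[-M] + (H^2 * ring)[-1]) / 2) * dt
    A <- 2 * S * sum((ring[-M] + ring[-1]) / 2) * dt
    # force potential: integral of p over the enclosed volume,
    # U = 2 * int p(r) 2 pi r z dr along the meridian
    integrand <- p_field(r) * 2 * pi * r * z
    U <- 2 * sum((integrand[-M] + integrand[-1]) / 2 * diff(r))
    pen <- penalty * kappa * ((A - A_target) / A_target)^2
    E_b + U + pen
  }

  a <- sqrt(A_target / (4 * pi))
  theta0 <- if (init == "sphere") {
    c(pi / 2 * tg[2:(M - 1L)], a * pi / 2)
  } else {
    crv0 <- sample_parametric(reference, N = M)
    beta <- sqrt(A_target / geometry_measures(crv0)$A)
    c(curvature_fields(crv0)$psi[2:(M - 1L)], crv0$s[M] * beta)
  }
  fit <- stats::optim(
    theta0, objective,
    method = "L-BFGS-B",
    lower = c(rep(-1.4, M - 2L), 1),
    upper = c(rep(2.6, M - 2L), 4 * a),
    control = list(maxit = 2000L, factr = 1e7)
  )

  psi <- c(0, fit$par[seq_len(M - 2L)], pi / 2)
  S <- fit$par[M - 1L]
  r <- S * cum_weights(cos(psi))
  z <- rev(S * cum_weights(rev(sin(psi))))
  curve <- shape_curve(tg * S, pmax(r, 0), pmax(z, 0),
                       provenance = "simulated")
  meas <- geometry_measures(curve)
  list(
    curve = curve, energy = fit$value, area = meas$A, volume = meas$V,
    convergence = fit$convergence, counts = counts
  )
}
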
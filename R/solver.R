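#' Options for the equilibrium shape solver
#'
#' The boundary-value problem is discretized by a midpoint (box) collocation
#' scheme on a uniform mesh in normalized arclength and solved by a damped
#' Newton iteration with a sparse finite-difference Jacobian. The target
#' force densities and tension are reached by pseudo-arclength-free
#' continuation: a single load factor tau is ramped from 0 (the analytic
#' sphere of the prescribed area) to 1, with step halving on failure.
#'
#' @param mesh_n Number of mesh nodes along the quarter-meridian.
#' @param tol Convergence tolerance on the maximum residual component.
#' @param max_iter Maximum Newton iterations per continuation step.
#' @param tau0 Initial continuation step in the load factor.
#' @param tau_grow Growth factor applied to the step after a success.
#' @param min_dtau Smallest allowed continuation step before giving up.
#' @param kiss_frac Contact ("kissing") threshold: the solve stops when
#'   `h_min < kiss_frac * L`.
#' @param mode Closure of the boundary conditions. Prescribing the
#'   membrane tension, fixing the total area and requiring a perfectly
#'   regular pole together over-determine the boundary-value problem by
#'   one condition (the tension level is the Lagrange multiplier conjugate
#'   to the area), so exactly one of three conditions must be released:
#'   `"anchored-pole"` (default) prescribes `lambda(equator) = lambda0`
#'   and the equatorial symmetry condition `l(equator) = 0`, releasing the
#'   pole regularity `l(pole) = 0` (the residual pole value is reported as
#'   a diagnostic; it corresponds to a point reaction at the dimple
#'   centre). `"anchored-equator"` keeps both pole conditions and releases
#'   `l(equator) = 0`. `"free-tension"` keeps both symmetry conditions and
#'   lets the tension level float as the area multiplier (`lambda0` is
#'   then ignored and the realized tension is an output).
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(mesh_n = 161L, tol = 1e-8, max_iter = 30L,
                           tau0 = 0.05, tau_grow = 1.5, min_dtau = 1e-3,
                           kiss_frac = 0.01, seed_reference = TRUE,
                           mode = c("anchored-equator", "free-tension",
                                    "anchored-pole", "free-area")) {
  mode <- match.arg(mode)
  stop_if_not_scalar(mesh_n, "mesh_n", positive = TRUE)
  stop_if_not_scalar(tol, "tol", positive = TRUE)
  stop_if_not_scalar(tau0, "tau0", positive = TRUE)
  stop_if_not_scalar(min_dtau, "min_dtau", positive = TRUE)
  stop_if_not_scalar(kiss_frac, "kiss_frac", positive = TRUE)
  structure(
    list(mesh_n = as.integer(mesh_n), tol = tol, max_iter = as.integer(max_iter),
         tau0 = tau0, tau_grow = tau_grow, min_dtau = min_dtau,
         kiss_frac = kiss_frac, seed_reference = isTRUE(seed_reference),
         mode = mode),
    class = "solver_options"
  )
}

# ---- discrete system -------------------------------------------------------

# Unknown vector layout: x = (y_1, ..., y_N, S) with y_i = (r, z, psi, h,
# l, lam) at node i and S the total quarter-meridian arclength. Residual
# layout: 6 (N-1) interior midpoint equations (interval-major), then six
# boundary rows, then the area-constraint row (normalized by the target).
bvp_residual <- function(x, tgrid, params, profile, mode) {
  N <- length(tgrid)
  Y <- matrix(x[seq_len(6 * N)], ncol = 6, byrow = TRUE)
  S <- x[6 * N + 1]
  dt <- tgrid[2] - tgrid[1]
  tm <- (tgrid[-N] + tgrid[-1]) / 2
  Ym <- (Y[-N, , drop = FALSE] + Y[-1, , drop = FALSE]) / 2
  Fm <- rhs_matrix(tm, Ym, params, profile, S)
  Gint <- Y[-1, , drop = FALSE] - Y[-N, , drop = FALSE] - dt * S * Fm
  if (mode == "free-area") {
    # both symmetry conditions and the tension anchor; area is an output
    return(c(
      as.vector(t(Gint)),
      Y[1, 1], Y[1, 3], Y[1, 5],
      Y[N, 2], Y[N, 3] - pi / 2, Y[N, 5],
      Y[N, 6] - params$lambda0
    ))
  }
  A_half <- params$A_total / 2
  trap_r <- dt * (sum(Y[, 1]) - (Y[1, 1] + Y[N, 1]) / 2)
  g_area <- (2 * pi * S * trap_r - A_half) / A_half
  bc56 <- switch(mode,
    "anchored-pole" = c(Y[N, 5], Y[N, 6] - params$lambda0),
    "anchored-equator" = c(Y[1, 5], Y[N, 6] - params$lambda0),
    "free-tension" = c(Y[1, 5], Y[N, 5])
  )
  c(
    as.vector(t(Gint)),
    Y[1, 1], Y[1, 3],
    Y[N, 2], Y[N, 3] - pi / 2,
    bc56,
    g_area
  )
}

# Sparse Jacobian by grouped finite differences. Interior midpoint rows
# couple only the two nodes of their interval, so perturbing every other
# node simultaneously (2 parities x 6 state components = 12 groups, plus
# one group for S) recovers all interior derivatives exactly as in a
# column-by-column difference. Boundary and area rows are analytic.
bvp_jacobian <- function(x, G0, tgrid, params, profile, mode) {
  N <- length(tgrid)
  nun <- 6 * N + 1
  nint <- 6 * (N - 1)
  dt <- tgrid[2] - tgrid[1]
  S <- x[nun]
  intervals <- seq_len(N - 1)
  rows_int <- seq_len(nint)

  trip_i <- vector("list", 16)
  trip_j <- vector("list", 16)
  trip_x <- vector("list", 16)
  g <- 0L

  for (p in 0:1) {
    nodes <- which(seq_len(N) %% 2L == p)
    jmap <- ifelse(intervals %% 2L == p, intervals, intervals + 1L)
    for (k in 1:6) {
      cols <- (nodes - 1L) * 6L + k
      eps <- 1e-7 * (1 + abs(x[cols]))
      xp <- x
      xp[cols] <- xp[cols] + eps
      Gp <- bvp_residual(xp, tgrid, params, profile, mode)
      dG <- (Gp - G0)[rows_int]
      colv <- (jmap - 1L) * 6L + k
      eps_by_interval <- eps[match(jmap, nodes)]
      g <- g + 1L
      trip_i[[g]] <- rows_int
      trip_j[[g]] <- rep(colv, each = 6L)
      trip_x[[g]] <- dG / rep(eps_by_interval, each = 6L)
    }
  }

  epsS <- 1e-7 * (1 + abs(S))
  xp <- x
  xp[nun] <- xp[nun] + epsS
  Gp <- bvp_residual(xp, tgrid, params, profile, mode)
  g <- g + 1L
  trip_i[[g]] <- rows_int
  trip_j[[g]] <- rep(nun, nint)
  trip_x[[g]] <- (Gp - G0)[rows_int] / epsS

  # boundary rows (unit entries)
  idx <- function(i, k) (i - 1L) * 6L + k
  if (mode == "free-area") {
    bc_cols <- c(idx(1L, 1L), idx(1L, 3L), idx(1L, 5L),
                 idx(N, 2L), idx(N, 3L), idx(N, 5L), idx(N, 6L))
    g <- g + 1L
    trip_i[[g]] <- nint + 1:7
    trip_j[[g]] <- bc_cols
    trip_x[[g]] <- rep(1, 7)
  } else {
    bc_cols <- c(idx(1L, 1L), idx(1L, 3L),
                 idx(N, 2L), idx(N, 3L),
                 switch(mode,
                   "anchored-pole" = c(idx(N, 5L), idx(N, 6L)),
                   "anchored-equator" = c(idx(1L, 5L), idx(N, 6L)),
                   "free-tension" = c(idx(1L, 5L), idx(N, 5L))
                 ))
    g <- g + 1L
    trip_i[[g]] <- nint + 1:6
    trip_j[[g]] <- bc_cols
    trip_x[[g]] <- rep(1, 6)

    # area row
    A_half <- params$A_total / 2
    w <- rep(dt, N)
    w[c(1, N)] <- dt / 2
    r_nodes <- x[idx(seq_len(N), 1L)]
    g <- g + 1L
    trip_i[[g]] <- rep(nun, N + 1L)
    trip_j[[g]] <- c(idx(seq_len(N), 1L), nun)
    trip_x[[g]] <- c(2 * pi * S * w, 2 * pi * sum(w * r_nodes)) / A_half
  }

  Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(nun, nun)
  )
}

newton_bvp <- function(x, tgrid, params, profile, mode, tol, max_iter) {
  G <- bvp_residual(x, tgrid, params, profile, mode)
  ng <- max(abs(G))
  if (!is.finite(ng)) {
    return(list(x = x, converged = FALSE, resid = Inf, iters = 0L))
  }
  iters <- 0L
  while (ng > tol && iters < max_iter) {
    J <- bvp_jacobian(x, G, tgrid, params, profile, mode)
    dx <- tryCatch(
      as.numeric(Matrix::solve(J, -G)),
      error = function(e) NULL
    )
    if (is.null(dx) || any(!is.finite(dx))) {
      return(list(x = x, converged = FALSE, resid = ng, iters = iters))
    }
    alpha <- 1
    improved <- FALSE
    for (ls in 1:9) {
      x1 <- x + alpha * dx
      G1 <- bvp_residual(x1, tgrid, params, profile, mode)
      ng1 <- max(abs(G1))
      if (is.finite(ng1) && ng1 < ng * (1 - 1e-4 * alpha)) {
        x <- x1
        G <- G1
        ng <- ng1
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      return(list(x = x, converged = FALSE, resid = ng, iters = iters))
    }
    iters <- iters + 1L
  }
  list(x = x, converged = ng <= tol, resid = ng, iters = iters)
}

# Discrete state built from the parametric biconcave reference (rescaled
# to the prescribed area). Used to seed Newton directly on the discocyte
# branch; continuation from the sphere cannot reach it for uniform loads
# because nothing breaks the oblate/prolate symmetry there.
reference_state_vector <- function(params, N, reference = parametric_rbc()) {
  crv <- sample_parametric(reference, N = N)
  beta <- sqrt(params$A_total / geometry_measures(crv)$A)
  cf <- curvature_fields(crv)
  s <- crv$s * beta
  h <- cf$H / beta
  l <- crv$R * beta * deriv_grid(s, h)
  Y <- cbind(crv$R * beta, crv$Z * beta, cf$psi, h, l,
             rep(params$lambda0, N))
  c(as.vector(t(Y)), s[N])
}

# Analytic sphere of the prescribed area as the continuation seed.
sphere_state_vector <- function(params, N) {
  a <- sqrt(params$A_total / (4 * pi))
  tg <- seq(0, 1, length.out = N)
  Y <- cbind(
    a * sin(pi * tg / 2),
    a * cos(pi * tg / 2),
    pi * tg / 2,
    rep(1 / a, N),
    rep(0, N),
    rep(params$lambda0, N)
  )
  c(as.vector(t(Y)), a * pi / 2)
}

#' Solve for the equilibrium membrane shape under a force profile
#'
#' Solves the axisymmetric shape equation with the tension equation as a
#' nonlinear two-point boundary-value problem on the quarter-meridian.
#' Boundary conditions: `r = 0`, `psi = 0`, `l = 0` at the pole; `z = 0`,
#' `psi = pi/2` at the equator; the tension anchored to `lambda0` at the
#' equator (or the symmetry condition `l = 0` in `"free"` mode); and the
#' total membrane area constrained to `A_total` through the unknown
#' quarter-meridian length `S`. The solve is fully deterministic.
#'
#' @param params A [membrane_params].
#' @param profile A [force_profile].
#' @param options A [solver_options].
#' @param init Optional previous [shape_solution] on the same mesh used as
#'   a warm start (the continuation is skipped if a direct Newton solve
#'   from it succeeds).
#' @return An object of class `shape_solution` with elements `curve` (a
#'   [shape_curve]), the nodal fields `psi`, `h`, `l`, `lam`, `K`, the
#'   quarter-arclength `S_total`, `measures` (see [geometry_measures]),
#'   flags `converged` and `kissing`, the load factor `tau_reached`, the
#'   residual `max_resid`, the equatorial symmetry diagnostic `sym_resid`
#'   (the free boundary value of `l`), and a continuation `trace`.
#' @examples
#' \donttest{
#' sol <- solve_shape(membrane_params(), force_profile(1.83, 1.83))
#' characteristic_lengths(sol$curve)
#' }
#' @export
solve_shape <- function(params = membrane_params(),
                        profile = force_profile(0, 0),
                        options = solver_options(),
                        init = NULL) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(profile, "force_profile"),
            inherits(options, "solver_options"))
  N <- options$mesh_n
  tgrid <- seq(0, 1, length.out = N)

  scaled <- function(tau) {
    list(
      params = membrane_params(
        kappa = params$kappa, kappa_G = params$kappa_G,
        lambda0 = params$lambda0 * tau, p = params$p * tau,
        A_total = params$A_total
      ),
      profile = scale_profile(profile, tau)
    )
  }

  trace <- list()
  push_trace <- function(tau, res) {
    trace[[length(trace) + 1L]] <<- data.frame(
      tau = tau, iters = res$iters, resid = res$resid,
      accepted = res$converged
    )
  }

  kissed <- function(x) {
    Y <- matrix(x[seq_len(6 * N)], ncol = 6, byrow = TRUE)
    h_min <- 2 * Y[1, 2]
    L <- 2 * max(Y[, 1])
    h_min < options$kiss_frac * L
  }

  V_sphere <- params$A_total^(3 / 2) / (6 * sqrt(pi))
  valid_x <- function(x) {
    if (any(!is.finite(x))) return(FALSE)
    Y <- matrix(x[seq_len(6 * N)], ncol = 6, byrow = TRUE)
    if (any(Y[-1, 1] <= 0)) return(FALSE)
    if (min(Y[2:(N - 1), 2]) < min(0, Y[1, 2]) - 0.2) return(FALSE)
    S <- x[6 * N + 1]
    if (!is.finite(S) || S <= 0) return(FALSE)
    # isoperimetric sanity: an embedded closed surface of this area cannot
    # enclose more than the sphere's volume
    crv <- shape_curve(tgrid * S, Y[, 1], pmax(Y[, 2], 0), "simulated")
    m <- geometry_measures(crv)
    m$V <= 1.02 * (m$A^(3 / 2) / (6 * sqrt(pi)))
  }

  x <- NULL
  tau <- 0
  kissing <- FALSE
  strategy <- "staged"

  direct_attempt <- function(x_init) {
    sc <- scaled(1)
    res <- newton_bvp(x_init, tgrid, sc$params, sc$profile, options$mode,
                      options$tol, options$max_iter)
    push_trace(1, res)
    res
  }

  if (!is.null(init)) {
    x_init <- if (inherits(init, "shape_solution")) init$x else init
    if (length(x_init) == 6 * N + 1) {
      res <- direct_attempt(x_init)
      if (res$converged && valid_x(res$x)) {
        x <- res$x
        tau <- 1
        kissing <- kissed(x)
        strategy <- "warm"
      }
    }
  }

  zero_load <- profile$F_dimple == 0 && profile$F_rim == 0 &&
    params$lambda0 == 0 && params$p == 0
  if (is.null(x) && zero_load) {
    res <- direct_attempt(sphere_state_vector(params, N))
    if (res$converged && valid_x(res$x)) {
      x <- res$x
      tau <- 1
      strategy <- "sphere"
    }
  }

  if (is.null(x) && isTRUE(options$seed_reference)) {
    res <- direct_attempt(reference_state_vector(params, N))
    if (res$converged && valid_x(res$x) && !kissed(res$x)) {
      x <- res$x
      tau <- 1
      strategy <- "reference"
    }
  }

  if (is.null(x)) {
    # Staged continuation.
    #
    # Stage 1a ramps a one-sided surrogate load (dimple pulling, or rim
    # pushing when the target is rim-dominated pushing) in the
    # free-tension closure, which follows the physically deflating
    # (discocyte) branch from the sphere because the area multiplier
    # absorbs the mean load. (Ramping directly in a prescribed-tension
    # closure falls onto a spurious prolate branch.)
    #
    # Stage 1b carries the solution into the target closure by walking
    # the equatorial tension anchor from the multiplier value realized in
    # stage 1a to the prescribed lambda0.
    #
    # Stage 2 then walks the force plateaus and the orientation angle
    # linearly from the surrogate to the target inside the target
    # closure, at the full tension anchor, with adaptive step halving.
    F_dev <- profile$F_dimple - profile$F_rim
    rim_push <- profile$F_rim < 0 && profile$F_dimple <= 0.5 * abs(profile$F_rim)
    F_start <- min(max(abs(F_dev), 0.15 * params$kappa / 0.9), 3.5)
    prof_start <- profile
    if (rim_push) {
      prof_start$F_dimple <- 0
      prof_start$F_rim <- -F_start
    } else {
      prof_start$F_dimple <- F_start
      prof_start$F_rim <- 0
    }
    prof_start$phi <- 90

    with_lambda0 <- function(lam) {
      pa <- params
      pa$lambda0 <- lam
      pa
    }

    # stage 1a: free-tension ladder on the surrogate load
    x_ft <- sphere_state_vector(with_lambda0(0), N)
    tau_ft <- 0
    dtau <- options$tau0
    while (tau_ft < 1) {
      tau_try <- min(1, tau_ft + dtau)
      pstep <- scale_profile(prof_start, tau_try)
      res <- newton_bvp(x_ft, tgrid, with_lambda0(0), pstep, "free-tension",
                        options$tol, options$max_iter)
      if (res$converged && valid_x(res$x)) {
        x_ft <- res$x
        tau_ft <- tau_try
        dtau <- dtau * options$tau_grow
      } else {
        dtau <- dtau / 2
        if (dtau < options$min_dtau) break
      }
    }

    # stage 1b: tension-anchor homotopy into the target closure
    x_t <- NULL
    prof_at <- scale_profile(prof_start, tau_ft)
    if (options$mode == "free-tension") {
      x_t <- x_ft
    } else if (tau_ft > 0) {
      lam_out <- x_ft[6 * (N - 1) + 6] # lam at the equator node
      sigma <- 0
      dsig <- 0.5
      x_sig <- x_ft
      while (sigma < 1) {
        sig_try <- min(1, sigma + dsig)
        lam_path <- lam_out + sig_try * (params$lambda0 - lam_out)
        res <- newton_bvp(x_sig, tgrid, with_lambda0(lam_path), prof_at,
                          options$mode, options$tol, options$max_iter)
        if (res$converged && valid_x(res$x)) {
          x_sig <- res$x
          sigma <- sig_try
          dsig <- dsig * options$tau_grow
        } else {
          dsig <- dsig / 2
          if (dsig < options$min_dtau) break
        }
      }
      if (sigma >= 1) x_t <- x_sig
    }

    if (!is.null(x_t)) {
      cfg <- function(eta) {
        pr <- profile
        pr$F_dimple <- prof_at$F_dimple +
          eta * (profile$F_dimple - prof_at$F_dimple)
        pr$F_rim <- prof_at$F_rim +
          eta * (profile$F_rim - prof_at$F_rim)
        pr$phi <- 90 + eta * (profile$phi - 90)
        list(params = with_lambda0(params$lambda0), profile = pr)
      }
      eta <- 0
      deta <- 0.2
      while (eta < 1 && !kissing) {
        eta_try <- min(1, eta + deta)
        cc <- cfg(eta_try)
        res <- newton_bvp(x_t, tgrid, cc$params, cc$profile, options$mode,
                          options$tol, options$max_iter)
        push_trace(eta_try, res)
        ok <- res$converged && valid_x(res$x)
        if (ok && !kissed(res$x)) {
          x_t <- res$x
          eta <- eta_try
          deta <- min(deta * options$tau_grow, 0.2)
        } else if (ok && deta <= 2 * options$min_dtau) {
          # contact persists at the finest step: genuine kissing boundary
          x_t <- res$x
          eta <- eta_try
          kissing <- TRUE
        } else {
          # failed, or jumped past the contact fold: refine
          deta <- deta / 2
          if (deta < options$min_dtau) break
        }
      }
      x <- x_t
      tau <- eta
    } else {
      x <- x_ft
      tau <- 0
      strategy <- "staged-incomplete"
    }
  }

  sc <- scaled(tau)
  G <- bvp_residual(x, tgrid, sc$params, sc$profile, options$mode)
  Y <- matrix(x[seq_len(6 * N)], ncol = 6, byrow = TRUE)
  S <- x[6 * N + 1]
  curve <- shape_curve(tgrid * S, Y[, 1], pmax(Y[, 2], 0),
                       provenance = "simulated")
  rs <- ifelse(Y[, 1] < 1e-10, 1, Y[, 1])
  k_p <- sin(Y[, 3]) / rs
  k_p[1] <- Y[1, 4]
  k_m <- 2 * Y[, 4] - k_p
  k_m[1] <- Y[1, 4]

  structure(
    list(
      curve = curve,
      psi = Y[, 3], h = Y[, 4], l = Y[, 5], lam = Y[, 6],
      K = k_m * k_p, k_m = k_m,
      S_total = S,
      measures = geometry_measures(curve),
      converged = (tau >= 1) && max(abs(G)) <= options$tol * 10,
      kissing = kissing,
      tau_reached = tau,
      strategy = strategy,
      max_resid = max(abs(G)),
      sym_resid = switch(options$mode,
        "free-area" = 0,
        "anchored-pole" = Y[1, 5],
        "anchored-equator" = Y[N, 5],
        "free-tension" = Y[N, 6]
      ),
      trace = do.call(rbind, trace),
      params = params, profile = profile, options = options,
      x = x
    ),
    class = "shape_solution"
  )
}

#' @export
print.shape_solution <- function(x, ...) {
  cl <- characteristic_lengths(x$curve)
  cat(sprintf(
    "<shape_solution> %s%s tau = %.3f, resid = %.2e\n  h_min = %.4f, h_max = %.4f, L = %.4f um; A = %.2f um^2, V = %.2f um^3\n",
    if (x$converged) "converged;" else "NOT converged;",
    if (x$kissing) " kissing;" else "",
    x$tau_reached, x$max_resid,
    cl$h_min, cl$h_max, cl$L, x$measures$A, x$measures$V
  ))
  invisible(x)
}
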
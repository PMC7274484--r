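#' Specification of a deterministic parameter sweep
#'
#' Defines a rectangular grid over one or more of the sweep parameters
#' `F_dimple`, `F_rim`, `F_uniform` (sets both plateaus), `phi` and
#' `lambda0`, holding everything else at the values in `params` /
#' `profile`. Grids are fully deterministic; rows are solved in grid order
#' with warm starts from the neighbouring solution, which mirrors the
#' quasi-static protocol of ramping a force slowly.
#'
#' @param axes Named list of numeric vectors, e.g.
#'   `list(F_dimple = seq(3.5, 14, length.out = 25), F_rim = seq(0, 3.5, length.out = 25))`.
#' @param params Base [membrane_params].
#' @param profile Template [force_profile] supplying the transition shape
#'   and any parameter not swept (its plateau values are overridden by the
#'   grid axes).
#' @param options [solver_options] used for every solve.
#' @param reference [parametric_rbc] reference shape for the error metrics.
#' @param error_n Node count for [shape_errors].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(axes, params = membrane_params(),
                       profile = force_profile(0, 0),
                       options = solver_options(),
                       reference = parametric_rbc(),
                       error_n = 200L) {
  allowed <- c("F_dimple", "F_rim", "F_uniform", "phi", "lambda0")
  if (!is.list(axes) || length(axes) == 0 || is.null(names(axes)) ||
      !all(nzchar(names(axes)))) {
    stop("'axes' must be a non-empty named list", call. = FALSE)
  }
  if (!all(names(axes) %in% allowed)) {
    stop("axis names must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(axes, length, 1L) < 1L) ||
      any(!vapply(axes, is.numeric, TRUE))) {
    stop("every axis needs at least one numeric value", call. = FALSE)
  }
  if ("F_uniform" %in% names(axes) &&
      any(c("F_dimple", "F_rim") %in% names(axes))) {
    stop("'F_uniform' cannot be combined with 'F_dimple'/'F_rim' axes",
         call. = FALSE)
  }
  structure(
    list(axes = axes, params = params, profile = profile,
         options = options, reference = reference,
         error_n = as.integer(error_n)),
    class = "sweep_spec"
  )
}

# Materialize the (params, profile) pair for one grid point.
sweep_point_config <- function(spec, point) {
  params <- spec$params
  profile <- spec$profile
  for (nm in names(point)) {
    val <- point[[nm]]
    switch(nm,
      F_dimple = profile$F_dimple <- val,
      F_rim = profile$F_rim <- val,
      F_uniform = {
        profile$F_dimple <- val
        profile$F_rim <- val
      },
      phi = profile$phi <- val,
      lambda0 = params$lambda0 <- val
    )
  }
  list(params = params, profile = profile)
}

#' Run a parameter sweep of equilibrium shape solves
#'
#' Solves the shape equation at every grid point of a [sweep_spec] and
#' tabulates geometry, regime and error metrics. Failed or kissing points
#' are flagged in place, never dropped, mirroring a protocol that stops a
#' force ramp when the dimple height reaches zero. The first grid axis
#' varies fastest; each solve is warm-started from its predecessor in the
#' row and falls back to the staged continuation otherwise.
#'
#' @param spec A [sweep_spec].
#' @param keep_solutions Keep the full [solve_shape] objects (memory-heavy
#'   for large grids; default `FALSE`).
#' @return A `data.frame` with one row per grid point: the axis values,
#'   `converged`, `kissing`, `regime`, `strategy`, `h_min`, `h_max`, `L`,
#'   `A`, `V`, `v`, `eps_hmin`, `eps_hmax`, `eps_L`, `eps_total` (+ bounds,
#'   all fractions), `F_ratio`, `R_d`, `V_dimple_frac`. The spec is
#'   attached as attribute `"spec"` (and solutions as `"solutions"` if
#'   kept).
#' @export
run_sweep <- function(spec, keep_solutions = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- do.call(expand.grid, c(spec$axes, KEEP.OUT.ATTRS = FALSE))
  n <- nrow(grid)
  ref_curve <- sample_parametric(spec$reference, N = 400L)
  first_axis <- names(spec$axes)[1]
  row_len <- length(spec$axes[[1]])

  rows <- vector("list", n)
  sols <- if (keep_solutions) vector("list", n) else NULL
  warm_prev <- NULL
  warm_rowstart <- NULL

  for (i in seq_len(n)) {
    at_row_start <- (i - 1L) %% row_len == 0L
    init <- if (!is.null(warm_prev) && !at_row_start) {
      warm_prev
    } else {
      warm_rowstart
    }
    cc <- sweep_point_config(spec, as.list(grid[i, , drop = FALSE]))
    sol <- solve_shape(cc$params, cc$profile, spec$options, init = init)
    if (keep_solutions) sols[[i]] <- sol

    ok <- sol$converged && !sol$kissing
    if (ok) {
      warm_prev <- sol
      if (at_row_start) warm_rowstart <- sol
    } else if (at_row_start) {
      warm_rowstart <- NULL
      warm_prev <- NULL
    }

    regime <- if (!sol$converged && !sol$kissing) {
      "failed"
    } else if (sol$kissing) {
      "kissing"
    } else {
      classify_regime(sol$curve)
    }
    er <- shape_errors(sol$curve, ref_curve, N = spec$error_n)
    part <- tryCatch(dimple_rim_partition(sol$curve),
                     error = function(e) NULL)
    fr <- if (!is.null(part) && cc$profile$F_rim != 0) {
      force_ratio(cc$profile, part)
    } else {
      NA_real_
    }
    rows[[i]] <- data.frame(
      grid[i, , drop = FALSE],
      converged = sol$converged, kissing = sol$kissing,
      regime = regime, strategy = sol$strategy,
      h_min = characteristic_lengths(sol$curve)$h_min,
      h_max = characteristic_lengths(sol$curve)$h_max,
      L = characteristic_lengths(sol$curve)$L,
      A = sol$measures$A, V = sol$measures$V, v = sol$measures$v,
      eps_hmin = er$eps_hmin, eps_hmax = er$eps_hmax, eps_L = er$eps_L,
      eps_total = er$eps_total,
      eps_total_lo = er$eps_total_lo, eps_total_hi = er$eps_total_hi,
      F_ratio = fr,
      R_d = if (!is.null(part)) part$R_d else NA_real_,
      V_dimple_frac = if (!is.null(part)) part$V_dimple / part$V else NA_real_,
      row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  if (keep_solutions) attr(out, "solutions") <- sols
  class(out) <- c("rbc_sweep", class(out))
  out
}

#' Locate the error-minimizing configuration of a sweep
#'
#' Returns the grid argmin of `eps_total` over converged, non-kissing
#' biconcave rows, optionally refined by a golden-section line search
#' along each swept axis (coordinate descent with warm-started solves).
#' The refined minimum can only improve on the grid minimum.
#'
#' @param table A sweep table from [run_sweep].
#' @param refine Refine the argmin by golden-section along each axis?
#' @param tol Axis localization tolerance for the refinement (same units
#'   as the axis, default 0.05).
#' @param regimes Regimes considered valid candidates.
#' @return A list with `argmin` (named parameter values), `eps_total`,
#'   `V`, `F_ratio`, `h_min`, the `row` index of the grid minimum and, if
#'   refined, the refined `solution` ([solve_shape] object).
#' @export
find_minimum <- function(table, refine = TRUE, tol = 0.05,
                         regimes = "biconcave") {
  stopifnot(inherits(table, "rbc_sweep"))
  spec <- attr(table, "spec")
  cand <- which(table$converged & !table$kissing &
                  table$regime %in% regimes)
  if (length(cand) == 0) {
    stop("no converged rows in the requested regimes", call. = FALSE)
  }
  ibest <- cand[which.min(table$eps_total[cand])]
  axes <- names(spec$axes)
  best <- list(
    argmin = stats::setNames(as.numeric(table[ibest, axes]), axes),
    eps_total = table$eps_total[ibest],
    V = table$V[ibest], F_ratio = table$F_ratio[ibest],
    h_min = table$h_min[ibest], row = ibest, solution = NULL
  )
  if (!refine) {
    return(best)
  }

  ref_curve <- sample_parametric(spec$reference, N = 400L)
  eval_at <- function(point, init) {
    cc <- sweep_point_config(spec, as.list(point))
    sol <- solve_shape(cc$params, cc$profile, spec$options, init = init)
    eps <- if (sol$converged && !sol$kissing) {
      shape_errors(sol$curve, ref_curve, N = spec$error_n)$eps_total
    } else {
      Inf
    }
    list(eps = eps, sol = sol, profile = cc$profile)
  }

  point <- as.list(best$argmin)
  cur <- eval_at(point, NULL)
  if (!is.finite(cur$eps)) {
    return(best)
  }
  gr <- (sqrt(5) - 1) / 2
  for (ax in axes) {
    vals <- sort(unique(table[[ax]]))
    if (length(vals) < 2) next
    i0 <- which.min(abs(vals - point[[ax]]))
    lo <- vals[max(1, i0 - 1)]
    hi <- vals[min(length(vals), i0 + 1)]
    if (hi - lo <= tol) next
    a <- lo
    b <- hi
    x1 <- b - gr * (b - a)
    x2 <- a + gr * (b - a)
    p1 <- point; p1[[ax]] <- x1
    p2 <- point; p2[[ax]] <- x2
    f1 <- eval_at(p1, cur$sol)
    f2 <- eval_at(p2, cur$sol)
    while (b - a > tol) {
      if (f1$eps <= f2$eps) {
        b <- x2
        x2 <- x1
        f2 <- f1
        x1 <- b - gr * (b - a)
        p1[[ax]] <- x1
        f1 <- eval_at(p1, f2$sol)
      } else {
        a <- x1
        x1 <- x2
        f1 <- f2
        x2 <- a + gr * (b - a)
        p2[[ax]] <- x2
        f2 <- eval_at(p2, f1$sol)
      }
    }
    fb <- if (f1$eps <= f2$eps) f1 else f2
    xb <- if (f1$eps <= f2$eps) x1 else x2
    if (fb$eps < cur$eps) {
      point[[ax]] <- xb
      cur <- fb
    }
  }

  if (cur$eps <= best$eps_total) {
    part <- tryCatch(dimple_rim_partition(cur$sol$curve),
                     error = function(e) NULL)
    best$argmin <- stats::setNames(as.numeric(point[axes]), axes)
    best$eps_total <- cur$eps
    best$V <- cur$sol$measures$V
    best$h_min <- characteristic_lengths(cur$sol$curve)$h_min
    best$F_ratio <- if (!is.null(part) && cur$profile$F_rim != 0) {
      force_ratio(cur$profile, part)
    } else {
      NA_real_
    }
    best$solution <- cur$sol
  }
  best
}

#' Minimum shape error as a function of force orientation and tension
#'
#' For each combination of membrane tension and orientation angle, runs an
#' inner grid search over the dimple/rim force plateaus and records the
#' smallest attainable shape error, classifying the outcome as
#' `"biconcave"` when the minimum error is below `biconcave_eps` (the
#' pink/grey split of the landscape) and `"pancake"` otherwise.
#'
#' @param tensions Numeric vector of equatorial tension anchors (pN/um).
#' @param phis Numeric vector of orientation angles in degrees.
#' @param F_dimple,F_rim Numeric vectors defining the inner force grid.
#' @param params,profile,options,reference Shared configuration (see
#'   [sweep_spec]).
#' @param biconcave_eps Classification threshold on `eps_total`
#'   (fraction; default 0.05).
#' @return A `data.frame` with one row per (tension, phi): the minimizing
#'   plateaus, `eps_total`, `V` and the regime `label`.
#' @export
run_angle_study <- function(tensions, phis,
                            F_dimple = seq(2, 6, by = 1),
                            F_rim = c(0, 0.5, 1, 2),
                            params = membrane_params(),
                            profile = force_profile(0, 0),
                            options = solver_options(),
                            reference = parametric_rbc(),
                            biconcave_eps = 0.05) {
  stopifnot(is.numeric(tensions), is.numeric(phis),
            all(phis >= 0 & phis <= 90))
  out <- vector("list", length(tensions) * length(phis))
  k <- 0L
  for (lam in tensions) {
    for (phi in phis) {
      prof <- profile
      prof$phi <- phi
      par <- params
      par$lambda0 <- lam
      spec <- sweep_spec(
        axes = list(F_dimple = F_dimple, F_rim = F_rim),
        params = par, profile = prof, options = options,
        reference = reference
      )
      tab <- run_sweep(spec)
      valid <- which(tab$converged & !tab$kissing)
      k <- k + 1L
      if (length(valid) == 0) {
        out[[k]] <- data.frame(
          lambda0 = lam, phi = phi, F_dimple = NA_real_, F_rim = NA_real_,
          eps_total = NA_real_, V = NA_real_, label = "failed"
        )
        next
      }
      ib <- valid[which.min(tab$eps_total[valid])]
      out[[k]] <- data.frame(
        lambda0 = lam, phi = phi,
        F_dimple = tab$F_dimple[ib], F_rim = tab$F_rim[ib],
        eps_total = tab$eps_total[ib], V = tab$V[ib],
        label = if (tab$eps_total[ib] < biconcave_eps) "biconcave" else "pancake"
      )
    }
  }
  do.call(rbind, out)
}
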
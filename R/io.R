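#' Read a model configuration from YAML or JSON
#'
#' A configuration file has up to three blocks: `membrane` (fields of
#' [membrane_params]), `force` (fields of [force_profile]: `F_dimple`,
#' `F_rim`, `phi`, `t_star` — a number or `"auto"` —, `w`, `coord`) and
#' `solver` (fields of [solver_options]). Missing fields fall back to the
#' package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params`, `profile`, `options`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params <- do.call(membrane_params, as.list(cfg$membrane))
  profile <- if (is.null(cfg$force)) {
    force_profile(0, 0)
  } else {
    do.call(force_profile, as.list(cfg$force))
  }
  options <- do.call(solver_options, as.list(cfg$solver))
  list(params = params, profile = profile, options = options)
}

#' Write a solved shape as CSV plus JSON metadata
#'
#' Writes the meridian through [write_shape_curve] and a metadata JSON
#' (`<path>.meta.json`) carrying the solve configuration, convergence
#' diagnostics, geometry measures and regime label.
#'
#' @param sol A [solve_shape] solution.
#' @param path Output CSV path for the curve.
#' @return `path`, invisibly.
#' @export
write_shape_solution <- function(sol, path) {
  stopifnot(inherits(sol, "shape_solution"))
  write_shape_curve(sol$curve, path)
  meta <- list(
    converged = sol$converged,
    kissing = sol$kissing,
    regime = classify_regime(sol$curve),
    strategy = sol$strategy,
    max_resid = sol$max_resid,
    sym_resid = sol$sym_resid,
    S_total = sol$S_total,
    measures = sol$measures,
    params = unclass(sol$params),
    profile = unclass(sol$profile),
    mode = sol$options$mode,
    mesh_n = sol$options$mesh_n
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a puncta dataset as CSV plus JSON metadata
#'
#' @param data A [generate_puncta] dataset.
#' @param path Output CSV path (columns x, y, z, region in micrometres).
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(data, path) {
  stopifnot(inherits(data, "puncta_dataset"))
  df <- data$points
  df$x <- format_full(df$x)
  df$y <- format_full(df$y)
  df$z <- format_full(df$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    n = nrow(data$points), R_d = data$R_d,
    densities = as.list(data$densities), seed = data$seed,
    V_dimple = data$partition$V_dimple, V_rim = data$partition$V_rim
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
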
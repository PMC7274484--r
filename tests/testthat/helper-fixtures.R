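# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- force(expr)
  }
  .fixtures[[key]]
}

ref_curve <- function(N = 400L) {
  cached(paste0("ref", N), sample_parametric(parametric_rbc(), N = N))
}

# quarter-circle meridian of a sphere of radius a (pole -> equator)
sphere_curve <- function(a = 1, N = 201L) {
  tg <- seq(0, pi / 2, length.out = N)
  shape_curve(a * tg, a * sin(tg), a * cos(tg), provenance = "synthetic")
}

# solved uniform-force shape at the error-minimizing force density
uniform_solution <- function() {
  cached("uniform183",
         solve_shape(membrane_params(), force_profile(1.83, 1.83)))
}

# solved dimple-only biconcave shape in the middle of the window
dimple_solution <- function() {
  cached("dimple30",
         solve_shape(membrane_params(), force_profile(3.0, 0)))
}
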
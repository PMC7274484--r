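test_that("identical curves give zero error", {
  ref <- ref_curve()
  er <- shape_errors(ref, ref)
  expect_equal(er$eps_hmin, 0)
  expect_equal(er$eps_hmax, 0)
  expect_equal(er$eps_L, 0)
  expect_equal(er$eps_total, 0, tolerance = 1e-12)
})

test_that("height-scaled reference reproduces the direct-summation oracle", {
  ref <- ref_curve()
  sim <- shape_curve(ref$s, ref$R, ref$Z * 1.10, provenance = "synthetic")
  er_rms <- shape_errors(sim, ref, N = 200, convention = "rms")
  er_pr <- shape_errors(sim, ref, N = 200, convention = "printed")
  cl <- characteristic_lengths(ref)

  expect_equal(er_rms$eps_hmin, 0.10 * cl$h_min / cl$L, tolerance = 1e-9)
  expect_equal(er_rms$eps_hmax, 0.10 * cl$h_max / cl$L, tolerance = 1e-9)
  expect_equal(er_rms$eps_L, 0)

  # brute-force node-sum oracle on matched resamplings
  a <- resample_curve(sim, 200)
  b <- resample_curve(ref, 200)
  ss <- 0
  for (i in 1:200) {
    ss <- ss + (a$Z[i] - b$Z[i])^2 + (a$R[i] - b$R[i])^2
  }
  expect_equal(er_rms$eps_total, sqrt(ss / 200) / cl$L, tolerance = 1e-12)
  expect_equal(er_pr$eps_total, sqrt(ss) / 200 / cl$L, tolerance = 1e-12)
  expect_equal(er_rms$eps_total, er_pr$eps_total * sqrt(200),
               tolerance = 1e-12)
})

test_that("total error is symmetric for same-scale curves", {
  ref <- ref_curve()
  noisy <- generate_noisy_shape(ref, 0.08, seed = 11)
  e1 <- shape_errors(noisy, ref)$eps_total
  e2 <- shape_errors(ref, noisy)$eps_total
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("error decreases monotonically along a homotopy to the reference", {
  ref <- ref_curve()
  sim <- shape_curve(ref$s, ref$R, ref$Z * 1.25, provenance = "synthetic")
  eps <- vapply(seq(0, 1, by = 0.2), function(a) {
    mid <- shape_curve(ref$s, ref$R, (1 - a) * sim$Z + a * ref$Z,
                       provenance = "synthetic")
    shape_errors(mid, ref)$eps_total
  }, numeric(1))
  expect_true(all(diff(eps) < 0))
})

test_that("uncertainty band brackets the point estimate", {
  ref <- ref_curve()
  for (sim in list(uniform_solution()$curve, dimple_solution()$curve)) {
    er <- shape_errors(sim, ref)
    expect_lte(er$eps_total_lo, er$eps_total)
    expect_gte(er$eps_total_hi, er$eps_total)
    expect_gt(er$eps_total_hi, er$eps_total_lo)
  }
})

test_that("regimes are classified from the characteristic heights", {
  expect_identical(classify_regime(sphere_curve(a = 2)), "spherical")
  expect_identical(classify_regime(ref_curve()), "biconcave")
  squashed <- shape_curve(ref_curve()$s, ref_curve()$R,
                          ref_curve()$Z - ref_curve()$Z[1] * 0.999,
                          provenance = "synthetic")
  expect_identical(classify_regime(squashed), "kissing")
})

test_that("dimple/rim partition splits area and volume consistently", {
  part <- dimple_rim_partition(ref_curve(800))
  expect_gt(part$R_d, 0)
  expect_lt(part$R_d, 7.82 / 2)
  expect_equal(part$A_dimple + part$A_rim, part$A, tolerance = 1e-9)
  expect_equal(part$V_dimple + part$V_rim, part$V, tolerance = 1e-9)
  # the dimple is a small fraction of the cell volume (measured ~7%)
  expect_gt(100 * part$V_dimple / part$V, 4)
  expect_lt(100 * part$V_dimple / part$V, 11)
  expect_error(dimple_rim_partition(sphere_curve()), "not biconcave")
})

test_that("partition is stable under mesh refinement", {
  p1 <- dimple_rim_partition(ref_curve(400))
  p2 <- dimple_rim_partition(ref_curve(800))
  expect_equal(p1$R_d, p2$R_d, tolerance = 5e-3)
  expect_equal(p1$V_dimple, p2$V_dimple, tolerance = 2e-2)
})

test_that("force ratio reduces to the force quotient for matched regions", {
  part <- structure(
    list(R_d = 1, A_dimple = 10, A_rim = 100, V_dimple = 5, V_rim = 50,
         A = 110, V = 55),
    class = "region_partition"
  )
  expect_equal(force_ratio(force_profile(3, 3), part), 1)
  expect_equal(force_ratio(force_profile(6, 3), part), 2)
  expect_identical(force_ratio(force_profile(3, 0), part), Inf)
})

test_that("motor counts scale inversely with the single-motor force", {
  part <- dimple_rim_partition(ref_curve())
  prof <- force_profile(4, 1)
  n2 <- estimate_motor_counts(prof, part, f_single = 2)
  n4 <- estimate_motor_counts(prof, part, f_single = 4)
  expect_equal(n2$area, 2 * n4$area)
  expect_equal(unname(n2$area), unname(n2$volume), tolerance = 1e-12)
  n0 <- estimate_motor_counts(force_profile(0, 0), part)
  expect_identical(n0$n_total, 0)
})
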
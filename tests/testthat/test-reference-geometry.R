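test_that("parametric profile endpoint identities hold exactly", {
  p <- parametric_rbc()
  expect_identical(evans_fung_z(0, p), 0.5 * 0.81)
  expect_equal(evans_fung_z(p$L / 2, p), 0)
  expect_error(evans_fung_z(-0.1, p), "must lie in")
  expect_error(evans_fung_z(p$L / 2 + 0.1, p), "must lie in")
})

test_that("rim crest location and height match a dense grid scan", {
  p <- parametric_rbc()
  # independent oracle: brute-force scan of the closed form on 1e5 points
  Rg <- seq(0, p$L / 2, length.out = 1e5)
  Zg <- evans_fung_z(Rg, p)
  Z_max_oracle <- max(Zg)
  R_at_max_oracle <- Rg[which.max(Zg)]

  crv <- ref_curve(400)
  cl <- characteristic_lengths(crv)
  expect_equal(cl$h_max, 2 * Z_max_oracle, tolerance = 1e-3)
  expect_equal(crv$R[which.max(crv$Z)], R_at_max_oracle, tolerance = 0.02)
  # the crest sits in the outer half of the cell
  expect_gt(R_at_max_oracle, p$L / 4)
})

test_that("characteristic lengths of reference and sphere are correct", {
  cl <- characteristic_lengths(ref_curve())
  expect_equal(cl$h_min, 0.81, tolerance = 1e-10)
  expect_equal(cl$L, 7.82, tolerance = 1e-6)
  cs <- characteristic_lengths(sphere_curve(a = 1.7))
  expect_equal(cs$h_min, 3.4, tolerance = 1e-9)
  expect_equal(cs$h_max, 3.4, tolerance = 1e-9)
  expect_equal(cs$L, 3.4, tolerance = 1e-9)
})

test_that("sphere closure: area and volume converge at second order", {
  errs <- vapply(c(101L, 201L, 401L), function(N) {
    m <- geometry_measures(sphere_curve(a = 1, N = N))
    abs(m$V - 4 * pi / 3) / (4 * pi / 3)
  }, numeric(1))
  m <- geometry_measures(sphere_curve(a = 1, N = 401L))
  expect_equal(m$A, 4 * pi, tolerance = 1e-4)
  expect_equal(m$V, 4 * pi / 3, tolerance = 1e-4)
  expect_equal(m$SI, 1, tolerance = 1e-4)
  expect_equal(m$v, 1, tolerance = 1e-4)
  # halving the mesh spacing divides the volume error by about four
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("reference measures agree with a Richardson-extrapolated oracle", {
  p <- parametric_rbc()
  # independent quadrature in theta (R = L/2 sin theta) at two resolutions
  measure_at <- function(n) {
    th <- seq(0, pi / 2, length.out = n)
    R <- p$L / 2 * sin(th)
    Z <- evans_fung_z(R, p)
    dR <- diff(R)
    dZ <- diff(Z)
    ds <- sqrt(dR^2 + dZ^2)
    Rm <- (R[-1] + R[-n]) / 2
    A <- 2 * sum(2 * pi * Rm * ds)
    V <- 2 * abs(sum(pi * Rm^2 * dZ))
    c(A = A, V = V)
  }
  m1 <- measure_at(10000L)
  m2 <- measure_at(20000L)
  oracle <- m2 + (m2 - m1) / 3
  m <- geometry_measures(ref_curve(400))
  expect_equal(m$A, unname(oracle["A"]), tolerance = 1e-4)
  expect_equal(m$V, unname(oracle["V"]), tolerance = 1e-4)
})

test_that("reference reduced volume lies in the biconcave band", {
  v <- geometry_measures(ref_curve())$v
  expect_gt(v, 0.62)
  expect_lt(v, 0.83)
})

test_that("geometry measures are stable under mesh refinement", {
  m200 <- geometry_measures(sample_parametric(N = 200))
  m400 <- geometry_measures(sample_parametric(N = 400))
  expect_equal(m200$A, m400$A, tolerance = 1e-3)
  expect_equal(m200$V, m400$V, tolerance = 1e-3)
})

test_that("degenerate and invalid curves are rejected", {
  expect_error(shape_curve(c(0, 1), c(0.5, 1), c(1, 0)), "symmetry axis")
  expect_error(shape_curve(c(0, 0), c(0, 1), c(1, 0)), "strictly increasing")
  flat <- shape_curve(c(0, 1, 2), c(0, 0, 0), c(1, 0.5, 0))
  expect_error(geometry_measures(flat), "degenerate")
})

test_that("curve CSV round-trips bit-exactly with its sidecar", {
  crv <- ref_curve(200)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_shape_curve(crv, path)
  back <- read_shape_curve(path)
  expect_identical(back$s, crv$s)
  expect_identical(back$R, crv$R)
  expect_identical(back$Z, crv$Z)
  expect_identical(back$provenance, crv$provenance)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$A, geometry_measures(crv)$A, tolerance = 1e-12)
})
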
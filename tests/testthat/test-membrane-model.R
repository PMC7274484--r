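test_that("sphere bending energy is 4 pi kappa, independent of radius", {
  # with the energy density W = kappa H^2 (H = mean curvature), the
  # closed sphere integrates to exactly 4 pi kappa at any radius -- the
  # scale invariance of curvature elasticity
  par <- membrane_params()
  for (a in c(1, 3.2776)) {
    crv <- sphere_curve(a = a, N = 401L)
    H <- rep(1 / a, crv$N)
    K <- rep(1 / a^2, crv$N)
    en <- helfrich_energy(crv, H, K, par)
    expect_equal(en$E_b, 4 * pi * par$kappa, tolerance = 1e-4)
  }
})

test_that("Gauss-Bonnet: total Gaussian curvature is 4 pi", {
  par <- membrane_params(kappa_G = 1, kappa = 1)
  for (crv in list(sphere_curve(a = 2, N = 801L), ref_curve(800))) {
    cf <- rbcshape:::curvature_fields(crv)
    en <- helfrich_energy(crv, cf$H, cf$K, par)
    expect_equal(en$E_gauss, 4 * pi, tolerance = 0.01)
  }
})

test_that("finite-difference curvatures match the symbolic profile derivatives", {
  crv <- ref_curve(800)
  cf_fd <- rbcshape:::curvature_fields(crv)
  cf_an <- rbcshape:::evans_fung_curvatures(crv$R[-crv$N], parametric_rbc())
  par <- membrane_params()
  e_fd <- helfrich_energy(crv, cf_fd$H, cf_fd$K, par)
  # symbolic curvatures are singular at the equator node; reuse the
  # finite-difference value there so both routes share one quadrature
  H_an <- c(cf_an$H, cf_fd$H[crv$N])
  K_an <- c(cf_an$K, cf_fd$K[crv$N])
  e_an <- helfrich_energy(crv, H_an, K_an, par)
  expect_equal(e_fd$E_b, e_an$E_b, tolerance = 0.02)
  # pointwise agreement away from the endpoints
  mid <- 10:(crv$N - 10)
  expect_lt(max(abs(cf_fd$H[mid] - H_an[mid]) / (abs(H_an[mid]) + 0.1)), 0.01)
})

test_that("the Gaussian modulus does not enter the force balance", {
  prof <- force_profile(2, 0.5)
  state <- c(r = 1.2, z = 0.8, psi = 0.6, h = 0.3, l = 0.05, lam = 0.1)
  rhs <- lapply(c(-0.9, 0, 0.9), function(kG) {
    shape_ode_rhs(0.4, state, membrane_params(kappa_G = kG), prof)
  })
  expect_identical(rhs[[1]], rhs[[2]])
  expect_identical(rhs[[2]], rhs[[3]])
})

test_that("pole limits of the shape equation are regular", {
  prof <- force_profile(2, 0.5)
  par <- membrane_params()
  d <- shape_ode_rhs(0, c(r = 0, z = 1, psi = 0, h = 0.3, l = 0, lam = 0),
                     par, prof)
  expect_true(all(is.finite(d)))
  expect_equal(unname(d["psi"]), 0.3) # psi' -> h at the axis
  expect_equal(unname(d["h"]), 0)
  expect_equal(unname(d["l"]), 0)
  expect_error(
    shape_ode_rhs(0.5, c(r = 0, z = 1, psi = 0.4, h = 0.3, l = 0, lam = 0),
                  par, prof),
    "away from the pole"
  )
})

test_that("a uniformly loaded sphere balances through Young-Laplace tension", {
  # with pulling force F on a sphere of radius a, equilibrium requires
  # 2 lam H + f_n = 0, i.e. lam = -F a / 2
  par <- membrane_params(kappa = 9)
  Fu <- 1.3
  a <- sqrt(par$A_total / (4 * pi))
  prof <- force_profile(Fu, Fu)
  tg <- seq(0.1, 0.9, by = 0.1)
  for (t in tg) {
    st <- c(r = a * sin(pi * t / 2), z = a * cos(pi * t / 2),
            psi = pi * t / 2, h = 1 / a, l = 0, lam = -Fu * a / 2)
    d <- shape_ode_rhs(t, st, par, prof)
    expect_equal(unname(d["l"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["h"]), 0)
    expect_equal(unname(d["lam"]), 0) # normal forcing leaves tension flat
  }
})

test_that("tangent-angle rate equals the meridional curvature identity", {
  # on an analytic state sampled from the reference surface the identity
  # psi' = 2H - sin(psi)/r must reproduce the symbolic k_m
  crv <- ref_curve(400)
  p <- parametric_rbc()
  cf <- rbcshape:::curvature_fields(crv)
  an <- rbcshape:::evans_fung_curvatures(crv$R[2:399], p)
  par <- membrane_params()
  prof <- force_profile(0, 0)
  for (i in c(50, 150, 300)) {
    st <- c(r = crv$R[i + 1], z = crv$Z[i + 1], psi = cf$psi[i + 1],
            h = an$H[i], l = 0, lam = 0)
    d <- shape_ode_rhs(crv$s[i + 1] / crv$s[400], st, par, prof)
    expect_equal(unname(d["psi"]), an$k_m[i], tolerance = 5e-3)
  }
})

test_that("mismatched curvature fields are rejected", {
  crv <- ref_curve(200)
  expect_error(
    helfrich_energy(crv, rep(0.1, 100), rep(0, 200), membrane_params()),
    "per curve node"
  )
})
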
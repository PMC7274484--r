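test_that("zero noise returns the reference unchanged", {
  ref <- ref_curve()
  expect_identical(generate_noisy_shape(ref, 0, seed = 1), ref)
})

test_that("noisy shapes respect the pointwise envelope and the error bound", {
  ref <- ref_curve()
  cl <- characteristic_lengths(ref)
  for (seed in c(3, 17, 92)) {
    noisy <- generate_noisy_shape(ref, 0.10, seed = seed)
    expect_true(all(abs(noisy$Z - ref$Z) <= 0.10 * abs(ref$Z) + 1e-12))
    expect_identical(noisy$R, ref$R)
    er <- shape_errors(noisy, ref)
    expect_lte(er$eps_total, 0.10 * max(abs(ref$Z)) / cl$L + 1e-12)
  }
})

test_that("noise generation is deterministic per seed and leaves the RNG alone", {
  ref <- ref_curve()
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  a <- generate_noisy_shape(ref, 0.1, seed = 42)
  after <- stats::runif(1)
  expect_identical(before, after)
  b <- generate_noisy_shape(ref, 0.1, seed = 42)
  d <- generate_noisy_shape(ref, 0.1, seed = 43)
  expect_identical(a$Z, b$Z)
  expect_false(identical(a$Z, d$Z))
})

test_that("mean noisy-shape error matches a larger Monte-Carlo estimate", {
  ref <- ref_curve(201)
  eps_of <- function(seed) {
    shape_errors(generate_noisy_shape(ref, 0.10, seed = seed), ref)$eps_total
  }
  small <- vapply(1:100, eps_of, numeric(1))
  big <- vapply(1001:2500, eps_of, numeric(1))
  se <- stats::sd(small) / sqrt(length(small))
  expect_lt(abs(mean(small) - mean(big)), 3 * se)
})

test_that("puncta land inside the surface with labels matching the cylinder", {
  shape <- ref_curve(800)
  data <- generate_puncta(shape, 2.15, 1.70, seed = 7)
  pts <- data$points
  expect_gt(nrow(pts), 50)
  r <- sqrt(pts$x^2 + pts$y^2)
  z_of_r <- stats::approxfun(shape$R, shape$Z, rule = 2)
  expect_true(all(abs(pts$z) <= z_of_r(r) + 1e-9))
  expect_identical(pts$region == "dimple", r <= data$R_d)
  # determinism
  data2 <- generate_puncta(shape, 2.15, 1.70, seed = 7)
  expect_identical(data$points, data2$points)
})

test_that("zero intensity yields an empty pattern", {
  data <- generate_puncta(ref_curve(800), 0, 0, seed = 5)
  expect_identical(nrow(data$points), 0L)
  expect_error(puncta_density_analysis(data), "no puncta")
})

test_that("density analysis conserves counts and recovers the generator truth", {
  shape <- ref_curve(800)
  data <- generate_puncta(shape, 2.15, 1.70, seed = 21)
  an <- puncta_density_analysis(data)
  expect_equal(an$n_dimple + an$n_rim, an$n_total)
  pct_rim <- 100 * an$n_rim / an$n_total
  expect_equal(an$pct_puncta_dimple + pct_rim, 100)
  # moderate-sample sanity: recovered densities near truth (Poisson noise)
  dens <- vapply(1:40, function(s) {
    a <- puncta_density_analysis(generate_puncta(shape, 2.15, 1.70, seed = s))
    c(a$density_dimple, a$density_rim)
  }, numeric(2))
  expect_equal(mean(dens[1, ]), 2.15, tolerance = 0.15)
  expect_equal(mean(dens[2, ]), 1.70, tolerance = 0.05)
})

test_that("puncta datasets round-trip through CSV", {
  data <- generate_puncta(ref_curve(800), 2.15, 1.70, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_puncta_csv(data, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(data$points))
  expect_identical(as.numeric(back$x), data$points$x)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$R_d, data$R_d, tolerance = 1e-12)
})
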
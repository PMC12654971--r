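test_that("reference study fixture matches the published table", {
  ds <- load_reference_dataset()
  expect_s3_class(ds, "mixture_dataset")
  expect_equal(nrow(ds$composition), 25)
  expect_equal(ncol(ds$composition), 5)
  expect_equal(ds$times, c(2, 8, 24))
  # spot values
  expect_equal(unname(ds$responses[3, "Y_24"]), 102.3)
  expect_equal(unname(ds$composition[16, "X2"]), 21.8)
  # formulation 1 sums to the constant total exactly
  expect_equal(sum(ds$composition[1, ]), 82.8, tolerance = 1e-12)
})

test_that("candidate table fixture matches the published table", {
  ct <- load_candidate_table()
  expect_equal(nrow(ct), 45)
  expect_equal(as.vector(table(ct$algorithm)[c("NSGA-III", "MOGWO", "NSWOA")]),
               c(15, 15, 15))
  expect_equal(unlist(ct[45, c("Y_2", "Y_8", "Y_24")], use.names = FALSE),
               c(22.747, 64.983, 100.227))
  expect_equal(ct$X2[ct$scheme == 16], 27.800)
})

test_that("constructor enforces the dataset invariants", {
  expect_error(mixture_dataset(rbind(c(3, 7)), rbind(c(1, 2)), c(2, 1)),
               "strictly increasing")
  expect_error(mixture_dataset(rbind(c(-1, 11)), rbind(c(1, 2)), c(1, 2),
                               total = 10), ">= 0")
  expect_error(mixture_dataset(rbind(c(3, 7)), rbind(c(-1, 2)), c(1, 2),
                               total = 10), ">= 0")
  expect_error(mixture_dataset(rbind(c(3, 8)), rbind(c(1, 2)), c(1, 2),
                               total = 10, sum_tol = 0.5), "constant sum")
})

test_that("constant-sum validation reports per-row deviations", {
  ds <- load_reference_dataset()
  rep <- validate_constant_sum(ds)
  expect_true(attr(rep, "pass"))
  expect_equal(nrow(rep), 25)
  # printed rounding leaves rows 8, 12 and 16 off the exact total
  expect_equal(rep$deviation[8], 0.1, tolerance = 1e-9)
  expect_equal(rep$deviation[12], 0.2, tolerance = 1e-9)
  expect_equal(rep$deviation[16], 0.1, tolerance = 1e-9)
  expect_equal(max(rep$deviation), 0.2, tolerance = 1e-9)

  # a corrupted row fails at its exact deviation
  ds2 <- ds
  ds2$composition[5, 1] <- ds2$composition[5, 1] + 1
  rep2 <- validate_constant_sum(ds2, tol = 0.25)
  expect_false(rep2$pass[5])
  expect_equal(rep2$deviation[5], 1.0, tolerance = 1e-9)
  expect_false(attr(rep2, "pass"))

  # generated data passes at machine tolerance
  sim <- simulate_simple(10)
  expect_true(attr(validate_constant_sum(sim$dataset, tol = 1e-9), "pass"))

  expect_error(validate_constant_sum(ds, tol = 0), "positive")
})

test_that("release correlations match the textbook formula and flag degenerate input", {
  ds <- toy_dataset()
  R <- release_correlations(ds)
  # direct covariance-ratio oracle
  y1 <- ds$responses[, 1]; y2 <- ds$responses[, 2]
  r12 <- sum((y1 - mean(y1)) * (y2 - mean(y2))) /
    sqrt(sum((y1 - mean(y1))^2) * sum((y2 - mean(y2))^2))
  expect_equal(R[1, 2], r12, tolerance = 1e-12)
  expect_equal(R, t(R))
  expect_equal(diag(R), setNames(c(1, 1), colnames(ds$responses)))

  # identical columns correlate perfectly
  ds2 <- ds
  ds2$responses[, 2] <- ds2$responses[, 1]
  expect_equal(release_correlations(ds2)[1, 2], 1.0)

  ds3 <- ds
  ds3$responses[, 1] <- 5
  expect_error(release_correlations(ds3), "constant")
})

test_that("correlation matrix is symmetric positive semidefinite", {
  for (seed in 1:5) {
    sim <- simulate_simple(12, noise_sd = 2, seed = seed)
    R <- release_correlations(sim$dataset)
    expect_equal(R, t(R))
    expect_true(all(eigen(R, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("synthetic generator honours the constant sum, bounds and seed", {
  sim <- simulate_simple(40, seed = 7)
  ds <- sim$dataset
  expect_true(all(abs(rowSums(ds$composition) - 82.8) < 1e-9))
  b <- default_bounds()
  for (j in 1:5) {
    expect_true(all(ds$composition[, j] >= b[j, 1] - 1e-12))
    expect_true(all(ds$composition[, j] <= b[j, 2] + 1e-12))
  }
  # identical seed, identical draw; different seed differs
  sim2 <- simulate_simple(40, seed = 7)
  expect_identical(ds$composition, sim2$dataset$composition)
  expect_identical(ds$responses, sim2$dataset$responses)
  sim3 <- simulate_simple(40, seed = 8)
  expect_false(identical(ds$composition, sim3$dataset$composition))
})

test_that("zero-noise responses equal the ground-truth polynomial exactly", {
  sim <- simulate_simple(15, noise_sd = 0, seed = 3)
  tr <- sim$truth
  basis <- term_basis(5)
  mod <- release_model(basis, tr$true_coefficients)
  mu <- predict_release(mod, sim$dataset$composition, sim$dataset$times)
  expect_equal(unname(sim$dataset$responses), unname(mu), tolerance = 1e-12)
})

test_that("generator residuals carry the configured AR(1) correlation", {
  cfg <- synthetic_config(n_formulations = 2000, noise_sd = 2, rho = 0.6,
                          seed = 11, true_coefficients = simple_truth())
  sim <- simulate_mixture_study(cfg)
  basis <- term_basis(5)
  mod <- release_model(basis, simple_truth())
  mu <- predict_release(mod, sim$dataset$composition, sim$dataset$times)
  eps <- unname(sim$dataset$responses) - unname(mu)
  lag1 <- cor(c(eps[, 1], eps[, 2]), c(eps[, 2], eps[, 3]))
  expect_lt(abs(lag1 - 0.6), 0.05)
  expect_lt(abs(sd(eps) - 2), 0.1)
})

test_that("infeasible bounds are rejected", {
  expect_error(synthetic_config(component_bounds = cbind(rep(0, 5), rep(10, 5))),
               "infeasible")
  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  # feasible config but almost no room on the slice: rejection budget trips
  tight <- synthetic_config(
    component_bounds = cbind(c(25, 10, 2, 15, 5), c(47.8, 27.8, 10, 22.8, 12.8)))
  expect_s3_class(tight, "synthetic_config")
})

test_that("CSV round trip preserves all numeric fields", {
  sim <- simulate_simple(8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mixture_csv(sim$dataset, path)
  back <- read_mixture_csv(path, sum_tol = 1e-6)
  expect_equal(back$composition, sim$dataset$composition, tolerance = 1e-12)
  expect_equal(back$responses, sim$dataset$responses, tolerance = 1e-12)
  expect_equal(back$times, sim$dataset$times)
})

test_that("synthetic config YAML round trip is faithful", {
  cfg <- synthetic_config(n_formulations = 12, noise_sd = 1.5, rho = 0.3,
                          seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$component_bounds, unname(cfg$component_bounds),
               ignore_attr = TRUE)
  expect_equal(back$true_coefficients, cfg$true_coefficients)
  expect_equal(back$rho, cfg$rho)
  expect_equal(back$seed, cfg$seed)
})
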
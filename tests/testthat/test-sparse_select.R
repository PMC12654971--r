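test_that("proximal operators match their closed forms", {
  # soft threshold
  expect_equal(prox_penalty(c(-3, -0.5, 0, 0.5, 3), 1, "lasso"),
               c(-2, 0, 0, 0, 2))
  # MCP: S(2,1)/(1 - 1/3) = 1.5; untouched beyond gamma*lambda
  expect_equal(prox_penalty(2, 1, "mcp", gamma = 3), 1.5)
  expect_equal(prox_penalty(5, 1, "mcp", gamma = 3), 5)
  # SCAD middle branch: ((a-1)z - a*lambda)/(a-2) = 4.4/1.7
  expect_equal(prox_penalty(3, 1, "scad", a = 3.7), 4.4 / 1.7)
  expect_equal(prox_penalty(1.5, 1, "scad", a = 3.7), 0.5)  # soft region
  expect_equal(prox_penalty(10, 1, "scad", a = 3.7), 10)    # identity region
  # no penalty, identity for every family
  z <- c(-2.2, 0.3, 4)
  for (p in c("lasso", "scad", "mcp"))
    expect_equal(prox_penalty(z, 0, p), z)
  # odd symmetry
  expect_equal(prox_penalty(-2, 1, "mcp", gamma = 3), -1.5)
  expect_error(prox_penalty(1, -1, "lasso"), "lambda")
  expect_error(prox_penalty(1, 1, "mcp", gamma = 1), "gamma")
  expect_error(prox_penalty(1, 1, "scad", a = 2), "a > 2")
})

test_that("lambda = 0 fit reproduces least squares; huge lambda shrinks to the mean", {
  set.seed(42)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  beta <- c(2, -1, 0.5, 0, 0, 3)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.3) + 4
  for (pen in c("lasso", "scad", "mcp")) {
    co <- penalized_fit(X, y, pen, lambda = 0)
    ols <- drop(solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y)))
    expect_equal(unname(co), unname(ols), tolerance = 1e-6)
    co_inf <- penalized_fit(X, y, pen, lambda = 1e6)
    expect_equal(unname(co_inf), c(mean(y), rep(0, p)), tolerance = 1e-10)
  }
})

test_that("orthogonal-design lasso equals soft-thresholded univariate solutions", {
  n <- 50; p <- 4
  X <- stats::poly(seq_len(n), p)  # orthogonal, mean-zero columns
  colnames(X) <- paste0("V", 1:p)
  set.seed(1)
  y <- drop(X %*% c(3, -2, 0.05, 0)) + rnorm(n, sd = 0.1)
  lambda <- 0.05
  co <- penalized_fit(X, y, "lasso", lambda = lambda)
  # closed form on the standardized scale, computed independently
  s <- sqrt(colSums(scale(X, scale = FALSE)^2) / n)
  Xs <- scale(X, scale = s * sqrt(n / (n)))  # mean 0, variance 1 (n denom)
  Xs <- sweep(scale(X, scale = FALSE), 2, s, "/")
  z <- drop(crossprod(Xs, y - mean(y))) / n
  soft <- sign(z) * pmax(abs(z) - lambda, 0)
  expect_equal(unname(co[-1]), unname(soft / s), tolerance = 1e-6)
  expect_equal(unname(co[1]), mean(y) - sum(co[-1] * colMeans(X)),
               tolerance = 1e-8)
})

test_that("lasso solutions agree with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 80; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- drop(X %*% c(1.5, -2, 0, 0, 0.8, rep(0, 5))) + rnorm(n, sd = 0.5)
  for (lambda in c(0.05, 0.2, 0.6)) {
    mine <- penalized_fit(X, y, "lasso", lambda = lambda, tol = 1e-10)
    gl <- glmnet::glmnet(X, y, lambda = lambda, standardize = TRUE,
                         thresh = 1e-14)
    ref <- as.numeric(coef(gl))
    expect_equal(unname(mine), ref, tolerance = 1e-4)
  }
})

test_that("MCP and SCAD converge to the lasso as their shape parameters grow", {
  set.seed(3)
  n <- 40; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  la <- penalized_fit(X, y, "lasso", lambda = 0.3, tol = 1e-10)
  mc <- penalized_fit(X, y, "mcp", lambda = 0.3, gamma = 1e6, tol = 1e-10)
  sc <- penalized_fit(X, y, "scad", lambda = 0.3, a = 1e6, tol = 1e-10)
  expect_equal(mc, la, tolerance = 1e-4)
  expect_equal(sc, la, tolerance = 1e-4)
})

test_that("non-finite inputs are rejected", {
  X <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(penalized_fit(X, c(1, 2), "lasso", lambda = 0.1), "non-finite")
  expect_error(penalized_fit(matrix(1:4, 2), c(1, Inf), "lasso", lambda = 0.1),
               "non-finite")
})

test_that("formulation folds never split a cluster and CV chooses a sparse model", {
  sim <- simulate_simple(30, noise_sd = 1, seed = 10)
  basis <- term_basis(5)
  sel <- suppressWarnings(cv_select(sim$dataset, basis, "lasso", nfolds = 5,
                                    nlambda = 40))
  # no-leakage property: every row of one formulation shares a fold
  split_folds <- tapply(sel$folds, sel$cluster, function(f) length(unique(f)))
  expect_true(all(split_folds == 1))
  expect_equal(sort(unique(sel$folds)), 1:5)
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$selected,
               names(sel$coefficients[-1])[sel$coefficients[-1] != 0])
  expect_true(all(is.finite(sel$path$cvm)))
  # row folds spread clusters across folds
  sel2 <- suppressWarnings(cv_select(sim$dataset, basis, "lasso", nfolds = 5,
                                     fold_by = "row", nlambda = 20))
  expect_gt(max(tapply(sel2$folds, sel2$cluster,
                       function(f) length(unique(f)))), 1)
})

test_that("selection recovers an identifiable sparse truth", {
  # note: on the constant-sum slice several term sets are exactly
  # equivalent (e.g. sum_i Xi*t is proportional to t), so recovery is
  # asserted for the identifiable interaction and for the time trend as an
  # equivalence class
  truth <- c(intercept = 5, X13 = 0.05, t = 2)
  sim <- simulate_mixture_study(synthetic_config(
    n_formulations = 80, noise_sd = 0.2, rho = 0.3, seed = 21,
    true_coefficients = truth))
  basis <- term_basis(5, max_order = 2)
  time_class <- c("t", "t2", paste0("X", 1:5, "t"))
  for (pen in c("lasso", "mcp")) {
    sel <- suppressWarnings(cv_select(sim$dataset, basis, pen, nfolds = 5,
                                      nlambda = 50))
    expect_true("X13" %in% sel$selected)
    expect_true(any(sel$selected %in% time_class))
  }
})

test_that("pure-noise responses yield few spurious selections", {
  hits <- 0L
  n_seeds <- 5L
  for (seed in seq_len(n_seeds)) {
    sim <- simulate_mixture_study(synthetic_config(
      n_formulations = 40, noise_sd = 1, rho = 0, seed = 100 + seed,
      true_coefficients = c(intercept = 50)))
    sel <- suppressWarnings(cv_select(sim$dataset, term_basis(5), "mcp",
                                      nfolds = 5, nlambda = 40))
    if (length(sel$selected) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("max_terms caps the admissible support and results serialize", {
  sim <- simulate_simple(20, seed = 33)
  sel <- suppressWarnings(cv_select(sim$dataset, term_basis(5), "lasso",
                                    nfolds = 4, nlambda = 30, max_terms = 3))
  expect_lte(length(sel$selected), 3)
  coef_path <- withr::local_tempfile(fileext = ".csv")
  path_path <- withr::local_tempfile(fileext = ".csv")
  write_selection_result(sel, coef_path, path_path)
  df <- read.csv(coef_path)
  expect_equal(df$label[df$selected], sel$selected)
  expect_equal(nrow(read.csv(path_path)), 30)
})
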
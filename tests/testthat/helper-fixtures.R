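# Shared fixtures and small utilities, built in code at test time.

# tiny 4-formulation, 2-component study with exact constant sum 10
toy_dataset <- function() {
  comp <- rbind(c(3, 7), c(5, 5), c(6, 4), c(2, 8))
  resp <- rbind(c(10, 20), c(12, 24), c(13, 25), c(9, 18))
  mixture_dataset(comp, resp, times = c(1, 4), total = 10, sum_tol = 1e-9)
}

# synthetic study under a simple 3-term ground truth
simple_truth <- function() c(intercept = 5, X1 = 0.8, t = 2)

simulate_simple <- function(n = 50, noise_sd = 1, rho = 0.5, seed = 1) {
  simulate_mixture_study(synthetic_config(
    n_formulations = n, noise_sd = noise_sd, rho = rho, seed = seed,
    true_coefficients = simple_truth()))
}

# a fake objectives object over a 2-variable box, for optimizer tests that
# do not need a fitted release model
toy_objectives <- function(centers = rbind(c(1, 1), c(3, 1), c(2, 3))) {
  Qfun <- function(X) {
    X <- as.matrix(X)
    out <- sapply(seq_len(nrow(centers)), function(k)
      rowSums(sweep(X, 2, centers[k, ])^2))
    matrix(out, nrow = nrow(X))
  }
  structure(list(Q = Qfun,
                 Y = function(X) Qfun(X),  # placeholder release surrogate
                 times = c(2, 8, 24), sigma = 0, total = NA, q = 2),
            class = "release_objectives")
}

toy_bounds <- function() cbind(lo = c(0, 0), hi = c(4, 4))

# brute-force O(n^2 M) Pareto front peeling, kept independent of the
# package implementation
brute_fronts <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  left <- seq_len(n)
  fronts <- list()
  while (length(left)) {
    nd <- logical(length(left))
    for (ii in seq_along(left)) {
      i <- left[ii]
      dominated <- FALSE
      for (j in left) {
        if (i == j) next
        if (all(P[j, ] <= P[i, ]) && any(P[j, ] < P[i, ])) {
          dominated <- TRUE; break
        }
      }
      nd[ii] <- !dominated
    }
    fronts[[length(fronts) + 1L]] <- left[nd]
    left <- left[!nd]
  }
  fronts
}

# memoized reference-data computations shared between slow tests
.cache <- new.env(parent = emptyenv())
reference_selection <- function() {
  if (is.null(.cache$sel)) {
    ds <- load_reference_dataset()
    basis <- term_basis(5)
    .cache$sel <- lapply(c("lasso", "scad", "mcp"), function(p)
      suppressWarnings(cv_select(ds, basis, penalty = p, max_terms = 11)))
    names(.cache$sel) <- c("lasso", "scad", "mcp")
  }
  .cache$sel
}

reference_pipeline <- function() {
  if (is.null(.cache$pipe))
    .cache$pipe <- suppressWarnings(run_pipeline(pipeline_config(),
                                                 verbose = FALSE))
  .cache$pipe
}
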
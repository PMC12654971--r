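test_that("non-dominated sorting matches the exhaustive pairwise oracle", {
  set.seed(19)
  for (rep in 1:4) {
    P <- matrix(runif(50 * 3), 50, 3)
    got <- nondominated_sort(P)
    want <- brute_fronts(P)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
  # degenerate cases
  expect_equal(nondominated_sort(matrix(c(1, 2), 1)), list(1L))
  dup <- rbind(c(1, 2), c(1, 2), c(0, 3))
  expect_equal(sort(nondominated_sort(dup)[[1]]), 1:3)  # duplicates share a front
  expect_error(nondominated_sort(rbind(c(1, Inf))), "finite")
})

test_that("crowding distance rewards boundary and isolated points", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  # three collinear equally spaced points: middle gets 1 per objective
  P <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(P), c(Inf, 2, Inf))
  # a constant objective contributes nothing
  P2 <- cbind(c(0, 1, 2), c(5, 5, 5))
  expect_equal(crowding_distance(P2), c(Inf, 1, Inf))
})

test_that("Das-Dennis directions tile the simplex", {
  W <- das_dennis(3, 13)
  expect_equal(nrow(W), choose(15, 2))  # 105
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_true(all(W >= 0))
  expect_false(any(duplicated(W)))
  expect_equal(das_dennis(2, 1), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
})

small_config <- function(...) {
  optimizer_config(pop_size = 30, generations = 40, runs = 2,
                   bounds = toy_bounds(), ...)
}

test_that("all three optimizers return in-bound, mutually non-dominated, reproducible archives", {
  obj <- toy_objectives()
  cfg <- small_config()
  for (runner in list(run_nsga3, run_mogwo, run_nswoa)) {
    a <- runner(obj, cfg, seed = 5)
    expect_s3_class(a, "pareto_archive")
    expect_true(all(a$x >= 0 & a$x <= 4))
    # mutual non-dominance
    expect_length(nondominated_sort(a$Q), 1)
    # determinism
    b <- runner(obj, cfg, seed = 5)
    expect_identical(a$x, b$x)
    expect_identical(a$history, b$history)
    c_ <- runner(obj, cfg, seed = 6)
    expect_false(identical(a$x, c_$x))
    # best-so-far curve never decreases
    expect_true(all(diff(a$history$best) >= -1e-12))
    expect_equal(nrow(a$history), cfg$generations)
  }
})

test_that("optimizers approximate a known tri-criterion front", {
  # minimize squared distance to three centers: the Pareto set is the
  # triangle spanned by the centers; check hypervolume against a dense
  # reference front by Monte-Carlo domination counts
  obj <- toy_objectives()
  cfg <- optimizer_config(pop_size = 60, generations = 80, runs = 1,
                          bounds = toy_bounds())
  set.seed(101)
  grid <- as.matrix(expand.grid(x = seq(0, 4, by = 0.05),
                                y = seq(0, 4, by = 0.05)))
  Qg <- obj$Q(grid)
  ref_front <- Qg[nondominated_sort(Qg)[[1]], ]
  refpoint <- c(12, 12, 12)
  samp <- matrix(runif(20000 * 3, 0, 12), ncol = 3)
  dominated_by <- function(front, S) {
    hit <- rep(FALSE, nrow(S))
    for (i in seq_len(nrow(front)))
      hit <- hit | (S[, 1] >= front[i, 1] & S[, 2] >= front[i, 2] &
                    S[, 3] >= front[i, 3])
    mean(hit)
  }
  hv_ref <- dominated_by(ref_front, samp)
  for (runner in list(run_nsga3, run_nswoa)) {
    a <- runner(obj, cfg, seed = 31)
    hv <- dominated_by(a$Q, samp)
    expect_gte(hv, 0.95 * hv_ref)
  }
})

test_that("MOGWO archive never exceeds its capacity and leaders come from sparse cells", {
  obj <- toy_objectives()
  cfg <- small_config(archive_size = 12)
  a <- run_mogwo(obj, cfg, seed = 3)
  expect_lte(nrow(a$x), 12)
  expect_length(nondominated_sort(a$Q), 1)

  # with a single grid cell (huge inflation, odd division count so the
  # grid center is a bin interior), leader selection is uniform over the
  # archive
  AQ <- matrix(runif(8 * 3), 8, 3)
  expect_equal(length(unique(releaseopt:::grid_cells(AQ, 9, 1e6))), 1)
  draws <- withr::with_seed(123,
    replicate(10000, releaseopt:::mogwo_leader_draw(AQ, 9, 1e6, 5)))
  counts <- tabulate(draws, 8)
  # each member expected 1250 times, sd ~ 33: all within 3 sigma
  expect_true(all(abs(counts - 1250) < 3 * sqrt(10000 * (1 / 8) * (7 / 8))))
})

test_that("initial populations are uniform within bounds", {
  b <- cbind(lo = c(2, 10), hi = c(4, 30))
  X <- withr::with_seed(9, releaseopt:::init_population(10000, b))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(X[, j], "punif", b[j, 1], b[j, 2]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("pooling picks one feasible representative per run", {
  mk_archive <- function(Y, alg) {
    n <- nrow(Y)
    structure(list(x = matrix(runif(n * 5, 10, 20), n,
                              dimnames = list(NULL, paste0("X", 1:5))),
                   Q = -Y, Y = Y,
                   history = data.frame(generation = 1, best = 0, mean = 0),
                   algorithm = alg, seed = 1),
              class = "pareto_archive")
  }
  Y_names <- c("Y_2", "Y_8", "Y_24")
  one <- matrix(c(20, 60, 95), 1, dimnames = list(NULL, Y_names))
  several <- matrix(c(20, 60, 95,
                      24, 64, 105,
                      30, 70, 120), 3, byrow = TRUE,
                    dimnames = list(NULL, Y_names))
  archives <- list(
    A = list(mk_archive(one, "A"), mk_archive(several, "A")),
    B = list(mk_archive(several, "B")))
  pooled <- pool_candidates(archives)
  expect_equal(nrow(pooled), 3)
  expect_equal(pooled$scheme, 1:3)
  # single feasible point is the representative
  expect_equal(unlist(pooled[1, Y_names], use.names = FALSE), c(20, 60, 95))
  # the infeasible row (30/70/120) is filtered; the dominant feasible row wins
  expect_equal(unlist(pooled[2, Y_names], use.names = FALSE), c(24, 64, 105))
  # every pooled row passes the filter
  expect_equal(nrow(pharmacopoeia_filter(pooled)), 3)

  none <- matrix(c(30, 70, 120), 1, dimnames = list(NULL, Y_names))
  expect_error(pool_candidates(list(A = list(mk_archive(none, "A")))),
               "no feasible")
})

test_that("optimizer configuration is validated", {
  expect_error(optimizer_config(pop_size = 0), "pop_size")
  expect_error(optimizer_config(pc = 1.5))
  expect_error(optimizer_config(bounds = cbind(c(1, 2), c(1, 1))), "lo < hi")
  obj <- toy_objectives()
  expect_error(run_nsga3(obj, optimizer_config(bounds = default_bounds()),
                         seed = 1), "components")
})
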
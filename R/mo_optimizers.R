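#' Default composition box bounds
#'
#' Per-component `[lo, hi]` percentages for the five-excipient design space,
#' taken as the observed ranges of the reference 25-formulation study
#' (config-overridable).
#'
#' @return A 5 x 2 matrix with rows `X1..X5`.
#' @export
default_bounds <- function() {
  b <- rbind(X1 = c(25, 47.8), X2 = c(10, 27.8), X3 = c(2, 10),
             X4 = c(15, 22.8), X5 = c(5, 12.8))
  colnames(b) <- c("lo", "hi")
  b
}

#' Optimizer configuration
#'
#' Shared settings of the three multi-objective metaheuristics. Defaults
#' follow the reference study where stated (population 100, 200
#' generations, 15 independent runs, crossover probability 0.8, mutation
#' probability 0.05, MOGWO grid inflation 0.1 with leader pressure 5 and
#' deletion pressure 2, NSWOA progress interval 10); reference-direction
#' divisions (13, giving 105 directions for 3 objectives) and the MOGWO
#' archive size (100, matching the population) are the standard sizing
#' choices.
#'
#' @param pop_size population size N.
#' @param generations number of generations.
#' @param runs independent runs per algorithm.
#' @param bounds q x 2 matrix of per-component `[lo, hi]`.
#' @param pc single-point crossover probability (NSGA-III).
#' @param pm per-gene uniform-reset mutation probability (NSGA-III).
#' @param divisions Das-Dennis reference-direction divisions (NSGA-III).
#' @param archive_size external archive cap (MOGWO).
#' @param grid_divisions hypercube grid divisions per objective (MOGWO).
#' @param grid_alpha grid inflation factor (MOGWO).
#' @param leader_beta leader selection pressure (MOGWO).
#' @param delete_gamma archive deletion pressure (MOGWO).
#' @param ishow progress-report interval in generations (NSWOA).
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 100, generations = 200, runs = 15,
                             bounds = default_bounds(), pc = 0.8, pm = 0.05,
                             divisions = 13, archive_size = 100,
                             grid_divisions = 10, grid_alpha = 0.1,
                             leader_beta = 5, delete_gamma = 2, ishow = 10) {
  stopifnot(pop_size > 0, generations > 0, runs > 0,
            pc >= 0, pc <= 1, pm >= 0, pm <= 1)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a q x 2 matrix with lo < hi")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 runs = as.integer(runs), bounds = bounds, pc = pc, pm = pm,
                 divisions = divisions, archive_size = archive_size,
                 grid_divisions = grid_divisions, grid_alpha = grid_alpha,
                 leader_beta = leader_beta, delete_gamma = delete_gamma,
                 ishow = ishow),
            class = "optimizer_config")
}

#' Fast non-dominated sorting
#'
#' Partitions objective vectors (smaller is better) into Pareto fronts:
#' front 1 is the non-dominated set, each later front is non-dominated once
#' earlier fronts are removed. Dominance is the standard relation: no worse
#' in every objective, strictly better in at least one.
#'
#' @param P n x M matrix of objective values.
#' @return A list of integer index vectors, one per front.
#' @export
nondominated_sort <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n == 0L) return(list())
  if (any(!is.finite(P))) stop("objective values must be finite")
  le <- matrix(TRUE, n, n); lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(P))) {
    le <- le & outer(P[, k], P[, k], "<=")
    lt <- lt | outer(P[, k], P[, k], "<")
  }
  D <- le & lt  # D[i, j]: i dominates j
  count <- colSums(D)
  assigned <- rep(FALSE, n)
  fronts <- list()
  while (!all(assigned)) {
    f <- which(!assigned & count == 0)
    fronts[[length(fronts) + 1L]] <- f
    assigned[f] <- TRUE
    count <- count - colSums(D[f, , drop = FALSE])
  }
  fronts
}

# rank vector (front number per point)
front_ranks <- function(P) {
  fronts <- nondominated_sort(P)
  r <- integer(nrow(as.matrix(P)))
  for (i in seq_along(fronts)) r[fronts[[i]]] <- i
  r
}

#' Crowding distance within a front
#'
#' Boundary points of each objective get infinite distance; interior points
#' accumulate the normalized gap between their neighbours; a zero-range
#' objective contributes nothing.
#'
#' @param P n x M matrix of objective values of one front.
#' @return Numeric vector of distances.
#' @export
crowding_distance <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n == 0L) return(numeric(0))
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(P))) {
    o <- order(P[, k])
    rng <- P[o[n], k] - P[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (P[o[3:n], k] - P[o[1:(n - 2)], k]) / rng
  }
  d
}

#' Das-Dennis reference directions
#'
#' All M-vectors with non-negative components that are multiples of `1/p`
#' and sum to one: `choose(p + M - 1, M - 1)` uniformly spaced points on the
#' unit simplex, used as NSGA-III reference directions.
#'
#' @param M number of objectives (>= 2).
#' @param p number of divisions (>= 1).
#' @return A matrix with M columns, one reference direction per row.
#' @export
das_dennis <- function(M, p) {
  stopifnot(M >= 2, p >= 1)
  rec <- function(left, dims) {
    if (dims == 1L) return(matrix(left, 1, 1))
    do.call(rbind, lapply(0:left, function(i) cbind(i, rec(left - i, dims - 1L))))
  }
  out <- rec(p, M) / p
  dimnames(out) <- NULL
  out
}

# ---- shared run machinery ---------------------------------------------------

new_archive <- function(x, Q, Y, history, algorithm, seed) {
  keep <- !duplicated(round(x, 10))
  structure(list(x = x[keep, , drop = FALSE], Q = Q[keep, , drop = FALSE],
                 Y = Y[keep, , drop = FALSE], history = history,
                 algorithm = algorithm, seed = seed),
            class = "pareto_archive")
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("<pareto_archive> %s: %d non-dominated solutions (seed %d)\n",
              x$algorithm, nrow(x$x), x$seed))
  invisible(x)
}

init_population <- function(n, bounds) {
  q <- nrow(bounds)
  matrix(stats::runif(n * q, rep(bounds[, 1], each = n),
                      rep(bounds[, 2], each = n)), n, q,
         dimnames = list(NULL, rownames(bounds)))
}

clip_bounds <- function(X, bounds) {
  for (j in seq_len(ncol(X)))
    X[, j] <- pmin(pmax(X[, j], bounds[j, 1]), bounds[j, 2])
  X
}

# scalarized fitness for the evolution curves (higher = better); a
# reporting convention for the 3-objective problem, not part of selection
scalar_fitness <- function(Q) -rowSums(Q)

# ---- NSGA-III ---------------------------------------------------------------

# reference-direction niching on the last front (ideal-point normalization)
niche_select <- function(Qsel, Qlast, k, refs) {
  comb <- rbind(Qsel, Qlast)
  zmin <- apply(comb, 2, min)
  span <- apply(comb, 2, max) - zmin
  span[span <= 0] <- 1e-12
  normed <- sweep(sweep(comb, 2, zmin), 2, span, "/")
  nw2 <- rowSums(refs^2)
  FW <- normed %*% t(refs)
  perp2 <- pmax(outer(rowSums(normed^2), rep(1, nrow(refs))) -
                sweep(FW^2, 2, nw2, "/"), 0)
  assoc <- max.col(-perp2, ties.method = "first")
  dist <- sqrt(perp2[cbind(seq_len(nrow(perp2)), assoc)])
  nsel <- nrow(Qsel)
  counts <- tabulate(assoc[seq_len(nsel)], nbins = nrow(refs))
  cand <- seq_len(nrow(Qlast))            # indices into Qlast
  cand_assoc <- assoc[nsel + cand]
  cand_dist <- dist[nsel + cand]
  picked <- integer(0)
  alive <- rep(TRUE, length(cand))
  while (length(picked) < k) {
    refs_avail <- unique(cand_assoc[alive])
    jmin <- refs_avail[which.min(counts[refs_avail])]
    members <- which(alive & cand_assoc == jmin)
    pick <- if (counts[jmin] == 0L) members[which.min(cand_dist[members])]
            else members[sample.int(length(members), 1L)]
    picked <- c(picked, pick)
    alive[pick] <- FALSE
    counts[jmin] <- counts[jmin] + 1L
  }
  picked
}

#' Run one multi-objective optimization
#'
#' `run_nsga3()`, `run_mogwo()` and `run_nswoa()` search the box-bounded
#' composition space for the Pareto front of the penalty-transformed release
#' objectives. All three are deterministic under a fixed seed, clip bound
#' violations, and record a per-generation history of the best-so-far and
#' population-mean scalarized fitness (`-(Q1+Q2+Q3)`, higher is better).
#'
#' `run_nsga3` evolves a real-coded population by binary tournament on front
#' rank, single-point tail-swap crossover, per-gene uniform-reset mutation,
#' and environmental selection by non-dominated sorting with ideal-point
#' normalization and Das-Dennis reference-direction niching.
#'
#' `run_mogwo` keeps an external archive of non-dominated solutions on an
#' adaptive hypercube grid; wolves move toward three leaders drawn by
#' roulette over inverse grid-cell density raised to the leader pressure,
#' and an over-full archive evicts members from crowded cells.
#'
#' `run_nswoa` applies the whale operators (shrinking encirclement,
#' logarithmic-spiral bubble-net with b = 1, random-leader exploration) with
#' elitist non-dominated sorting plus crowding-distance truncation.
#'
#' @param objectives a [build_objectives()] object.
#' @param config an [optimizer_config()].
#' @param seed integer seed for this run.
#' @param verbose print progress (NSWOA honours `ishow`).
#' @return A `pareto_archive`: `x` (solutions), `Q` (objective values), `Y`
#'   (predicted releases), `history` (data frame generation / best / mean),
#'   `algorithm`, `seed`.
#' @export
run_nsga3 <- function(objectives, config = optimizer_config(), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(objectives, "release_objectives"),
            inherits(config, "optimizer_config"))
  bounds <- config$bounds
  if (nrow(bounds) != objectives$q)
    stop("bounds do not match the number of components")
  N <- config$pop_size
  withr::with_seed(seed, {
    refs <- das_dennis(3L, config$divisions)
    X <- init_population(N, bounds)
    Q <- objectives$Q(X)
    ranks <- front_ranks(Q)
    best <- -Inf
    hist <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      # binary tournament on rank
      a <- sample.int(N, N, replace = TRUE)
      b <- sample.int(N, N, replace = TRUE)
      win <- ifelse(ranks[a] < ranks[b], a,
             ifelse(ranks[b] < ranks[a], b,
                    ifelse(stats::runif(N) < 0.5, a, b)))
      Xo <- X[win, , drop = FALSE]
      d <- ncol(Xo)
      for (i in seq(1, N - 1, by = 2)) {
        if (stats::runif(1) < config$pc) {
          cut <- sample.int(d - 1L, 1L)
          tail_ix <- (cut + 1L):d
          tmp <- Xo[i, tail_ix]
          Xo[i, tail_ix] <- Xo[i + 1L, tail_ix]
          Xo[i + 1L, tail_ix] <- tmp
        }
      }
      mut <- matrix(stats::runif(N * d) < config$pm, N, d)
      if (any(mut)) {
        repl <- init_population(N, bounds)
        Xo[mut] <- repl[mut]
      }
      Xo <- clip_bounds(Xo, bounds)
      Qo <- objectives$Q(Xo)
      Xc <- rbind(X, Xo); Qc <- rbind(Q, Qo)
      fronts <- nondominated_sort(Qc)
      sel <- integer(0); ranks_new <- integer(0)
      for (fi in seq_along(fronts)) {
        f <- fronts[[fi]]
        if (length(sel) + length(f) <= N) {
          sel <- c(sel, f); ranks_new <- c(ranks_new, rep(fi, length(f)))
        } else {
          k <- N - length(sel)
          if (k > 0) {
            pick <- niche_select(Qc[sel, , drop = FALSE],
                                 Qc[f, , drop = FALSE], k, refs)
            sel <- c(sel, f[pick]); ranks_new <- c(ranks_new, rep(fi, k))
          }
          break
        }
      }
      X <- Xc[sel, , drop = FALSE]; Q <- Qc[sel, , drop = FALSE]
      ranks <- ranks_new
      fit <- scalar_fitness(Q)
      best <- max(best, max(scalar_fitness(Qo)), max(fit))
      hist[[gen]] <- c(gen, best, mean(fit))
    }
    f1 <- which(ranks == 1L)
    history <- as.data.frame(do.call(rbind, hist))
    names(history) <- c("generation", "best", "mean")
    new_archive(X[f1, , drop = FALSE], Q[f1, , drop = FALSE],
                objectives$Y(X[f1, , drop = FALSE]), history,
                "NSGA-III", seed)
  })
}

# ---- MOGWO ------------------------------------------------------------------

# hypercube grid cell index per archive member
grid_cells <- function(Q, divisions, alpha) {
  n <- nrow(Q)
  cell <- matrix(1L, n, ncol(Q))
  for (k in seq_len(ncol(Q))) {
    lo <- min(Q[, k]); hi <- max(Q[, k])
    pad <- alpha * (hi - lo) / 2
    br <- seq(lo - pad, hi + pad, length.out = divisions + 1L)
    if (br[1] == br[divisions + 1L]) br <- br[1] + seq(-1, 1, length.out = divisions + 1L)
    cell[, k] <- pmin(pmax(findInterval(Q[, k], br, all.inside = TRUE), 1L),
                      divisions)
  }
  apply(cell, 1, paste, collapse = ":")
}

roulette <- function(w) sample.int(length(w), 1L, prob = w)

# draw one leader index from an archive by roulette over inverse grid-cell
# density raised to the selection pressure
mogwo_leader_draw <- function(AQ, divisions, alpha, beta) {
  cells <- grid_cells(AQ, divisions, alpha)
  tab <- table(cells)
  cl <- names(tab)[roulette(as.numeric(tab)^(-beta))]
  members <- which(cells == cl)
  members[sample.int(length(members), 1L)]
}

#' @rdname run_nsga3
#' @export
run_mogwo <- function(objectives, config = optimizer_config(), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(objectives, "release_objectives"),
            inherits(config, "optimizer_config"))
  bounds <- config$bounds
  if (nrow(bounds) != objectives$q)
    stop("bounds do not match the number of components")
  N <- config$pop_size
  withr::with_seed(seed, {
    X <- init_population(N, bounds)
    Q <- objectives$Q(X)
    f1 <- nondominated_sort(Q)[[1]]
    AX <- X[f1, , drop = FALSE]; AQ <- Q[f1, , drop = FALSE]
    best <- max(scalar_fitness(Q))
    hist <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      pick_leader <- function() mogwo_leader_draw(AQ, config$grid_divisions,
                                                  config$grid_alpha,
                                                  config$leader_beta)
      leaders <- AX[c(pick_leader(), pick_leader(), pick_leader()), ,
                    drop = FALSE]
      a <- 2 - 2 * gen / config$generations
      d <- ncol(X)
      Xn <- 0
      for (l in 1:3) {
        A <- 2 * a * matrix(stats::runif(N * d), N, d) - a
        Cc <- 2 * matrix(stats::runif(N * d), N, d)
        L <- matrix(leaders[l, ], N, d, byrow = TRUE)
        Xn <- Xn + (L - A * abs(Cc * L - X))
      }
      X <- clip_bounds(Xn / 3, bounds)
      Q <- objectives$Q(X)
      # archive update
      cX <- rbind(AX, X); cQ <- rbind(AQ, Q)
      keep <- !duplicated(round(cX, 10))
      cX <- cX[keep, , drop = FALSE]; cQ <- cQ[keep, , drop = FALSE]
      f1 <- nondominated_sort(cQ)[[1]]
      AX <- cX[f1, , drop = FALSE]; AQ <- cQ[f1, , drop = FALSE]
      while (nrow(AX) > config$archive_size) {
        cells <- grid_cells(AQ, config$grid_divisions, config$grid_alpha)
        tab <- table(cells)
        cl <- names(tab)[roulette(as.numeric(tab)^config$delete_gamma)]
        members <- which(cells == cl)
        drop_i <- members[sample.int(length(members), 1L)]
        AX <- AX[-drop_i, , drop = FALSE]; AQ <- AQ[-drop_i, , drop = FALSE]
      }
      fit <- scalar_fitness(Q)
      best <- max(best, max(fit))
      hist[[gen]] <- c(gen, best, mean(fit))
    }
    history <- as.data.frame(do.call(rbind, hist))
    names(history) <- c("generation", "best", "mean")
    new_archive(AX, AQ, objectives$Y(AX), history, "MOGWO", seed)
  })
}

# ---- NSWOA ------------------------------------------------------------------

#' @rdname run_nsga3
#' @export
run_nswoa <- function(objectives, config = optimizer_config(), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(objectives, "release_objectives"),
            inherits(config, "optimizer_config"))
  bounds <- config$bounds
  if (nrow(bounds) != objectives$q)
    stop("bounds do not match the number of components")
  N <- config$pop_size
  withr::with_seed(seed, {
    X <- init_population(N, bounds)
    Q <- objectives$Q(X)
    best <- -Inf
    hist <- vector("list", config$generations)
    d <- ncol(X)
    for (gen in seq_len(config$generations)) {
      fronts <- nondominated_sort(Q)
      lead_ix <- fronts[[1]]
      a <- 2 - 2 * gen / config$generations
      Xo <- X
      for (i in seq_len(N)) {
        L <- X[lead_ix[sample.int(length(lead_ix), 1L)], ]
        if (stats::runif(1) < 0.5) {
          A <- 2 * a * stats::runif(d) - a
          Cc <- 2 * stats::runif(d)
          A0 <- 2 * a * stats::runif(1) - a
          target <- if (abs(A0) < 1) L else X[sample.int(N, 1L), ]
          Xo[i, ] <- target - A * abs(Cc * target - X[i, ])
        } else {
          l <- stats::runif(1, -1, 1)
          D <- abs(L - X[i, ])
          Xo[i, ] <- D * exp(l) * cos(2 * pi * l) + L
        }
      }
      Xo <- clip_bounds(Xo, bounds)
      Qo <- objectives$Q(Xo)
      Xc <- rbind(X, Xo); Qc <- rbind(Q, Qo)
      cf <- nondominated_sort(Qc)
      sel <- integer(0)
      for (f in cf) {
        if (length(sel) + length(f) <= N) sel <- c(sel, f)
        else {
          k <- N - length(sel)
          if (k > 0) {
            cd <- crowding_distance(Qc[f, , drop = FALSE])
            sel <- c(sel, f[order(-cd)[seq_len(k)]])
          }
          break
        }
      }
      X <- Xc[sel, , drop = FALSE]; Q <- Qc[sel, , drop = FALSE]
      fit <- scalar_fitness(Q)
      best <- max(best, max(scalar_fitness(Qo)), max(fit))
      hist[[gen]] <- c(gen, best, mean(fit))
      if (verbose && gen %% config$ishow == 0)
        message(sprintf("NSWOA generation %d: best %.4f", gen, best))
    }
    f1 <- nondominated_sort(Q)[[1]]
    history <- as.data.frame(do.call(rbind, hist))
    names(history) <- c("generation", "best", "mean")
    new_archive(X[f1, , drop = FALSE], Q[f1, , drop = FALSE],
                objectives$Y(X[f1, , drop = FALSE]), history, "NSWOA", seed)
  })
}

#' Run the full multi-run optimizer suite
#'
#' Executes every algorithm for `config$runs` independent seeded runs. Run r
#' of algorithm k uses seed `seed + 1000 * k + r`, so any single run can be
#' reproduced in isolation.
#'
#' @inheritParams run_nsga3
#' @param algorithms subset of `c("nsga3", "mogwo", "nswoa")`.
#' @param seed master seed.
#' @return A named list (one element per algorithm) of lists of
#'   `pareto_archive` objects.
#' @export
run_optimizer_suite <- function(objectives, config = optimizer_config(),
                                algorithms = c("nsga3", "mogwo", "nswoa"),
                                seed = 1L, verbose = FALSE) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  runners <- list(nsga3 = run_nsga3, mogwo = run_mogwo, nswoa = run_nswoa)
  out <- list()
  for (k in seq_along(algorithms)) {
    alg <- algorithms[k]
    out[[alg]] <- lapply(seq_len(config$runs), function(r)
      runners[[alg]](objectives, config, seed = seed + 1000L * k + r,
                     verbose = verbose))
  }
  out
}

#' Pool per-run Pareto archives into a candidate table
#'
#' From each run's final archive, candidates violating the pharmacopoeia
#' release limits are removed, then one representative is chosen by
#' equal-weight TOPSIS on the raw release values (vector normalization,
#' zero negative ideal). The representatives are pooled across runs and
#' algorithms into a table shaped like the published 45-candidate set
#' (compositions and releases to 3 decimals).
#'
#' @param archives output of [run_optimizer_suite()]: a named list of lists
#'   of `pareto_archive` objects.
#' @param limits a [release_limits()].
#' @return A data frame with columns `algorithm`, `scheme`, the component
#'   columns, and the release columns.
#' @export
pool_candidates <- function(archives, limits = release_limits()) {
  rows <- list()
  for (alg in names(archives)) {
    for (r in seq_along(archives[[alg]])) {
      arc <- archives[[alg]][[r]]
      df <- data.frame(arc$x, arc$Y, check.names = FALSE)
      feas <- pharmacopoeia_filter(df, limits)
      if (nrow(feas) == 0L)
        stop(sprintf("run %d of %s has no feasible solution", r,
                     arc$algorithm))
      rep_row <- if (nrow(feas) == 1L) feas else {
        Y <- as.matrix(feas[, names(limits), drop = FALSE])
        ts <- topsis(Y, weights = rep(1 / ncol(Y), ncol(Y)),
                     preprocess = "none", zero_negative_ideal = TRUE)
        feas[which(ts$table$rank == 1L)[1L], , drop = FALSE]
      }
      rep_row$algorithm <- arc$algorithm
      rows[[length(rows) + 1L]] <- rep_row
    }
  }
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 3)
  data.frame(algorithm = out$algorithm,
             scheme = seq_len(nrow(out)),
             out[setdiff(names(out), "algorithm")],
             row.names = NULL, check.names = FALSE)
}

#' Write pooled candidates and fitness histories
#'
#' @param candidates a [pool_candidates()] table.
#' @param path output CSV path.
#' @export
write_candidate_table <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_candidate_table
#' @param archives a [run_optimizer_suite()] result.
#' @param dir output directory for per-run history CSVs.
#' @export
write_fitness_histories <- function(archives, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (alg in names(archives))
    for (r in seq_along(archives[[alg]])) {
      h <- archives[[alg]][[r]]$history
      utils::write.csv(h, file.path(dir, sprintf("history_%s_run%02d.csv",
                                                 alg, r)),
                       row.names = FALSE, quote = FALSE)
    }
  invisible(dir)
}
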
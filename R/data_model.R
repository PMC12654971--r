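#' Mixture dissolution study container
#'
#' Bundles a mixture-design dissolution study: one row per formulation holding
#' the q excipient percentages (constant-sum composition, percent w/w) and the
#' cumulative release percentages measured at an ordered set of time points.
#'
#' @param composition numeric matrix or data frame, n formulations x q
#'   components, percentages on the 0-100 scale. Columns are labelled
#'   `X1..Xq` if unnamed.
#' @param responses numeric matrix or data frame, n x m cumulative release
#'   percentages, one column per time point.
#' @param times strictly increasing numeric vector of m time points (hours).
#' @param id optional formulation labels (default `1:n`).
#' @param total the constant sum the compositions must honour (percent;
#'   default 82.8, the fixed excipient load of the reference study).
#' @param sum_tol tolerance for the per-row constant-sum check at
#'   construction. The default 0.25 absorbs worst-case rounding of five
#'   components printed to one decimal (5 x 0.05). Use a tiny tolerance for
#'   machine-generated data.
#'
#' @return An object of class `mixture_dataset`: a list with elements
#'   `id`, `composition` (n x q matrix), `times`, `responses` (n x m matrix,
#'   columns `Y_<t>`), and `total`.
#' @export
mixture_dataset <- function(composition, responses, times, id = NULL,
                            total = 82.8, sum_tol = 0.25) {
  composition <- as.matrix(composition)
  responses <- as.matrix(responses)
  storage.mode(composition) <- "double"
  storage.mode(responses) <- "double"
  n <- nrow(composition)
  if (n == 0L) stop("dataset must contain at least one formulation")
  if (nrow(responses) != n)
    stop("composition and responses must have the same number of rows")
  if (!is.numeric(times) || length(times) != ncol(responses))
    stop("length(times) must equal ncol(responses)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyNA(composition) || any(!is.finite(composition)))
    stop("composition entries must be finite")
  if (any(composition < 0)) stop("composition entries must be >= 0")
  if (anyNA(responses) || any(!is.finite(responses)))
    stop("responses must be finite")
  if (any(responses < 0)) stop("responses must be >= 0")
  dev <- abs(rowSums(composition) - total)
  if (any(dev > sum_tol))
    stop(sprintf("composition row(s) %s deviate from the constant sum %g by more than %g",
                 paste(which(dev > sum_tol), collapse = ", "), total, sum_tol))
  if (is.null(colnames(composition)) ||
      any(!nzchar(colnames(composition))))
    colnames(composition) <- paste0("X", seq_len(ncol(composition)))
  colnames(responses) <- paste0("Y_", format(times, trim = TRUE))
  if (is.null(id)) id <- seq_len(n)
  structure(
    list(id = id, composition = composition, times = as.numeric(times),
         responses = responses, total = total),
    class = "mixture_dataset")
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf("<mixture_dataset> %d formulations, %d components, release at t = {%s} h, constant sum %g%%\n",
              nrow(x$composition), ncol(x$composition),
              paste(x$times, collapse = ", "), x$total))
  invisible(x)
}

#' @export
as.data.frame.mixture_dataset <- function(x, ...) {
  data.frame(formulation = x$id, x$composition, x$responses,
             check.names = FALSE)
}

#' @export
dim.mixture_dataset <- function(x) {
  c(nrow(x$composition), ncol(x$composition), length(x$times))
}

path_to_extdata <- function(file) {
  system.file("extdata", file, package = "releaseopt", mustWork = TRUE)
}

#' Read / write wide-format mixture study tables
#'
#' The CSV dialect is a header row with component columns `X1..Xq` followed by
#' response columns `Y_<t>` (UTF-8, '.' decimal separator). An optional
#' leading `formulation` column carries row labels.
#'
#' @param path file path.
#' @param total,sum_tol passed to [mixture_dataset()].
#' @return [read_mixture_csv()] returns a `mixture_dataset`;
#'   [write_mixture_csv()] invisibly returns `path`.
#' @export
read_mixture_csv <- function(path, total = 82.8, sum_tol = 0.25) {
  df <- utils::read.csv(path, check.names = FALSE)
  xcols <- grep("^X[0-9]+$", names(df), value = TRUE)
  ycols <- grep("^Y_", names(df), value = TRUE)
  if (length(xcols) == 0 || length(ycols) == 0)
    stop("CSV must contain X<i> component and Y_<t> response columns")
  times <- as.numeric(sub("^Y_", "", ycols))
  ord <- order(times)
  id <- if ("formulation" %in% names(df)) df$formulation else NULL
  mixture_dataset(df[xcols], df[ycols[ord]], times[ord], id = id,
                  total = total, sum_tol = sum_tol)
}

#' @rdname read_mixture_csv
#' @param dataset a `mixture_dataset`.
#' @export
write_mixture_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Reference glipizide sustained-release study (25 formulations)
#'
#' The packaged D-optimal mixture-design study of glipizide pH-independent
#' sustained-release tablets: 25 formulations of five excipients
#' (HPMC K4M, HPMC K100LV, MgO, lactose, anhydrous CaHPO4; constant sum
#' 82.8% w/w) with cumulative release measured at 2, 8 and 24 h.
#'
#' @return A `mixture_dataset` with 25 rows, 5 components and 3 time points.
#' @examples
#' ds <- load_reference_dataset()
#' ds
#' release_correlations(ds, method = "spearman")
#' @export
load_reference_dataset <- function() {
  read_mixture_csv(path_to_extdata("table1_reference.csv"))
}

#' Reference pooled candidate table (45 optimized formulations)
#'
#' The 45 pooled Pareto-candidate formulations of the reference study
#' (15 per optimizer: NSGA-III, MOGWO, NSWOA), each with its five component
#' percentages and predicted cumulative release at 2, 8 and 24 h.
#'
#' @return A data frame with columns `algorithm`, `scheme`, `X1..X5`,
#'   `Y_2`, `Y_8`, `Y_24`.
#' @export
load_candidate_table <- function() {
  utils::read.csv(path_to_extdata("table5_candidates.csv"),
                  check.names = FALSE)
}

#' Reference TOPSIS ranking and baseline-comparison tables
#'
#' `load_topsis_table()` returns the published top-15 entropy-weight TOPSIS
#' ranking of the 45 candidates (distances to the ideal solutions, relative
#' closeness C, rank). `load_comparison_table()` returns the original
#' formulation and the top-ranked candidate used for the improvement report.
#'
#' @return A data frame.
#' @export
load_topsis_table <- function() {
  utils::read.csv(path_to_extdata("table6_topsis.csv"), check.names = FALSE)
}

#' @rdname load_topsis_table
#' @export
load_comparison_table <- function() {
  utils::read.csv(path_to_extdata("table7_comparison.csv"),
                  check.names = FALSE)
}

#' Validate the constant-sum mixture constraint
#'
#' Checks every formulation's component sum against the design total and
#' reports per-row deviations. Printed tables carry rounding error: five
#' components rounded to one decimal can be off by up to 0.25 in the sum,
#' hence the default tolerance.
#'
#' @param dataset a `mixture_dataset`.
#' @param total target sum (default the dataset's own).
#' @param tol maximum allowed absolute deviation (> 0).
#' @return A data frame with one row per formulation (`formulation`, `sum`,
#'   `deviation`, `pass`) carrying attribute `pass` (logical, dataset-level
#'   verdict).
#' @export
validate_constant_sum <- function(dataset, total = dataset$total, tol = 0.25) {
  stopifnot(inherits(dataset, "mixture_dataset"))
  if (nrow(dataset$composition) == 0L) stop("empty dataset")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  s <- rowSums(dataset$composition)
  dev <- abs(s - total)
  out <- data.frame(formulation = dataset$id, sum = s, deviation = dev,
                    pass = dev <= tol)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Correlation of release responses across time points
#'
#' Correlates the cumulative release columns over formulations, giving the
#' empirical between-time-point dependence that motivates a working
#' correlation structure in the repeated-measures fit. Rank (Spearman)
#' correlation is offered because release profiles are monotone in
#' composition effects and the reference study reports rank-based values.
#'
#' @param dataset a `mixture_dataset` with at least 3 formulations and 2 time
#'   points.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An m x m symmetric correlation matrix with unit diagonal.
#' @export
release_correlations <- function(dataset,
                                 method = c("pearson", "spearman")) {
  stopifnot(inherits(dataset, "mixture_dataset"))
  method <- match.arg(method)
  Y <- dataset$responses
  if (nrow(Y) < 3L) stop("need at least 3 formulations")
  if (ncol(Y) < 2L) stop("need at least 2 time points")
  if (any(apply(Y, 2, stats::sd) == 0))
    stop("a response column is constant; correlation is undefined")
  stats::cor(Y, method = method)
}

#' Configuration for the synthetic mixture-study generator
#'
#' Describes the simulated study: box bounds for each component on the
#' constant-sum slice, a sparse ground-truth mixture polynomial, and AR(1)
#' within-formulation residual correlation across time points. The defaults
#' emulate the reference glipizide study: 25 formulations, the observed
#' component ranges of the reference design, the published 11-term release
#' model as ground truth, residual standard deviation 2 release percentage
#' points and lag-one autocorrelation 0.5.
#'
#' @param n_formulations number of formulations to simulate.
#' @param component_bounds q x 2 matrix (or 2-column data frame) of
#'   `[lo, hi]` percentages per component.
#' @param total constant sum (percent).
#' @param times release measurement times (hours), strictly increasing.
#' @param true_coefficients named numeric vector of ground-truth term values;
#'   names are canonical term labels (see [term_basis()]).
#' @param noise_sd residual standard deviation (release percentage points).
#' @param rho AR(1) lag-one correlation of within-formulation residuals,
#'   `|rho| < 1`.
#' @param seed integer seed for the dedicated generator stream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_formulations = 25,
                             component_bounds = default_bounds(),
                             total = 82.8,
                             times = c(2, 8, 24),
                             true_coefficients = reference_coefficients(),
                             noise_sd = 2,
                             rho = 0.5,
                             seed = 1L) {
  b <- as.matrix(component_bounds)
  if (ncol(b) != 2L) stop("component_bounds must have two columns [lo, hi]")
  if (any(b[, 1] > b[, 2])) stop("lower bounds must not exceed upper bounds")
  if (sum(b[, 1]) > total || sum(b[, 2]) < total)
    stop("bounds and total are jointly infeasible")
  if (!is.numeric(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_formulations < 1) stop("n_formulations must be >= 1")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(names(true_coefficients)) || anyNA(true_coefficients))
    stop("true_coefficients must be a named, finite numeric vector")
  structure(
    list(n_formulations = as.integer(n_formulations),
         component_bounds = b, total = total, times = as.numeric(times),
         true_coefficients = true_coefficients,
         noise_sd = noise_sd, rho = rho, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Published release-model coefficients of the reference study
#'
#' The 11-term MCP-selected mixture-polynomial coefficients reported for the
#' glipizide study, used as the generator's default ground truth. Labels are
#' canonical term labels: `X24` is the X2*X4 product, `X3t` the X3-by-time
#' interaction, `t2` squared time.
#'
#' @return A named numeric vector of length 11.
#' @export
reference_coefficients <- function() {
  c(intercept = -4.27112, X24 = -0.01113, X25 = -0.00974, X35 = -0.61399,
    X134 = -0.00165, X135 = 0.01076, X12345 = 0.00005,
    X3t = 0.02473, X5t = -0.00049, t2 = -0.21985, t = 9.08641)
}

#' Simulate a constant-sum mixture dissolution study
#'
#' Samples compositions uniformly inside the box bounds, projects each draw
#' onto the constant-sum hyperplane (equal shift of all components), and
#' rejects draws the projection pushes outside the box. Responses are the
#' ground-truth mixture polynomial plus stationary AR(1) Gaussian noise
#' across the time points of each formulation.
#'
#' @param config a [synthetic_config()].
#' @param max_attempts rejection-sampling budget (total candidate draws).
#' @return A list with elements `dataset` (a `mixture_dataset` whose rows sum
#'   to the total exactly) and `truth` (class `ground_truth`: the generating
#'   coefficients, `rho` and `noise_sd`).
#' @export
simulate_mixture_study <- function(config, max_attempts = 100000L) {
  stopifnot(inherits(config, "synthetic_config"))
  b <- config$component_bounds
  q <- nrow(b)
  n <- config$n_formulations
  withr::with_seed(config$seed, {
    comp <- matrix(NA_real_, 0, q)
    attempts <- 0L
    while (nrow(comp) < n) {
      batch <- max(n, 64L)
      attempts <- attempts + batch
      if (attempts > max_attempts)
        stop("could not sample compositions: bounds leave too little room around the constant-sum slice")
      X <- matrix(stats::runif(batch * q, rep(b[, 1], each = batch),
                               rep(b[, 2], each = batch)), batch, q)
      X <- X + (config$total - rowSums(X)) / q
      ok <- rowSums(sweep(X, 2, b[, 1], ">=") &
                    sweep(X, 2, b[, 2], "<=")) == q
      comp <- rbind(comp, X[ok, , drop = FALSE])
    }
    comp <- comp[seq_len(n), , drop = FALSE]
    colnames(comp) <- paste0("X", seq_len(q))

    basis <- term_basis(q, max_order = q, time_terms = TRUE)
    labs <- names(config$true_coefficients)
    unknown <- setdiff(labs, basis$terms$label)
    if (length(unknown))
      stop("unknown term label(s) in true_coefficients: ",
           paste(unknown, collapse = ", "))
    m <- length(config$times)
    comp_long <- comp[rep(seq_len(n), each = m), , drop = FALSE]
    t_long <- rep(config$times, n)
    mu <- drop(eval_terms(basis, comp_long, t_long, labels = labs) %*%
               config$true_coefficients)

    rho <- config$rho
    sd <- config$noise_sd
    eps <- matrix(0, n, m)
    if (sd > 0) {
      z <- matrix(stats::rnorm(n * m), n, m)
      eps[, 1] <- sd * z[, 1]
      if (m > 1) for (j in 2:m)
        eps[, j] <- rho * eps[, j - 1] + sd * sqrt(1 - rho^2) * z[, j]
    }
    Y <- matrix(mu, n, m, byrow = TRUE) + eps
    ds <- mixture_dataset(comp, Y, config$times, total = config$total,
                          sum_tol = 1e-9)
    truth <- structure(
      list(true_coefficients = config$true_coefficients,
           rho = rho, noise_sd = sd),
      class = "ground_truth")
    list(dataset = ds, truth = truth)
  })
}

#' Round-trip a synthetic configuration through YAML
#'
#' @param config a `synthetic_config`.
#' @param path YAML file path.
#' @return `read_synthetic_config()` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$component_bounds <- list(lo = unname(x$component_bounds[, 1]),
                             hi = unname(x$component_bounds[, 2]))
  x$true_coefficients <- as.list(x$true_coefficients)
  write_yaml_full(x, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_config(
    n_formulations = x$n_formulations,
    component_bounds = cbind(unlist(x$component_bounds$lo),
                             unlist(x$component_bounds$hi)),
    total = x$total, times = unlist(x$times),
    true_coefficients = unlist(x$true_coefficients),
    noise_sd = x$noise_sd, rho = x$rho, seed = x$seed)
}
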
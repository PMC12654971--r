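#' Fitted release model as a prediction object
#'
#' Couples a term basis with a sparse coefficient vector so that predicted
#' cumulative release can be evaluated at any (composition, time) point.
#'
#' @param basis a [term_basis()] (carrying centering offsets if centered).
#' @param coefficients named numeric vector; every name must be a basis term
#'   label.
#' @param total the constant sum of the design space (percent).
#' @return An object of class `release_model`.
#' @export
release_model <- function(basis, coefficients, total = 82.8) {
  stopifnot(inherits(basis, "term_basis"))
  bad <- setdiff(names(coefficients), basis$terms$label)
  if (length(bad)) stop("coefficient label(s) not in basis: ",
                        paste(bad, collapse = ", "))
  structure(list(basis = basis, coefficients = coefficients, total = total),
            class = "release_model")
}

#' @rdname release_model
#' @param fit a [fit_qif()] result to convert.
#' @export
as_release_model <- function(fit, basis, total = 82.8) {
  stopifnot(inherits(fit, "qif_fit"))
  release_model(basis, fit$beta, total = total)
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf("<release_model> %d terms, constant sum %g%%\n",
              length(x$coefficients), x$total))
  invisible(x)
}

#' Predict cumulative release
#'
#' Evaluates the fitted mixture polynomial at compositions `x` and times
#' `t`.
#'
#' @param model a [release_model()].
#' @param x composition vector of length q, or an n x q matrix.
#' @param t time point(s) in hours (> 0).
#' @return If `t` is scalar, a numeric vector of length n; otherwise an
#'   n x length(t) matrix with one column per time point.
#' @examples
#' mod <- release_model(term_basis(5), reference_coefficients())
#' predict_release(mod, c(38.4, 13.5, 6.3, 17.1, 7.5), c(2, 8, 24))
#' @export
predict_release <- function(model, x, t) {
  stopifnot(inherits(model, "release_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$basis$q)
    stop(sprintf("composition has %d components, model expects %d",
                 ncol(x), model$basis$q))
  if (any(t <= 0)) stop("t must be positive")
  labs <- names(model$coefficients)
  out <- sapply(t, function(tt) {
    M <- eval_terms(model$basis, x, rep(tt, nrow(x)), labels = labs)
    drop(M %*% model$coefficients)
  })
  if (length(t) == 1L) as.numeric(out)
  else matrix(out, nrow = nrow(x), dimnames = list(NULL, paste0("Y_", t)))
}

#' Exterior penalty for the constant-sum constraint
#'
#' The quadratic exterior penalty `sigma * (sum(x) - total)^exponent`
#' converts the equality-constrained mixture problem into an unconstrained
#' one: the penalty is zero on the feasibility hyperplane and grows steeply
#' off it, so with the default `sigma = 1000` any release gain of plausible
#' magnitude is dominated once the sum drifts.
#'
#' @param x composition vector or n x q matrix.
#' @param sigma penalty factor (> 0; default 1000).
#' @param total target sum (percent).
#' @param exponent even integer >= 2 (default 2).
#' @return Numeric vector of penalties (one per row).
#' @export
penalty_term <- function(x, sigma = 1000, total = 82.8, exponent = 2) {
  if (sigma <= 0) stop("sigma must be positive")
  if (exponent < 2 || exponent %% 2 != 0)
    stop("exponent must be even and >= 2")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sigma * (rowSums(as.matrix(x)) - total)^exponent
}

#' Pharmacopoeia release acceptance limits
#'
#' Closed acceptance intervals for cumulative release at each time point;
#' the defaults are the glipizide requirements: 15-25% at 2 h, 55-65% at
#' 8 h, 80-110% at 24 h (110% caps complete dissolution).
#'
#' @param limits named list mapping `Y_<t>` to `c(lo, hi)`.
#' @return The validated list, class `release_limits`.
#' @export
release_limits <- function(limits = list(Y_2 = c(15, 25), Y_8 = c(55, 65),
                                         Y_24 = c(80, 110))) {
  for (l in limits) if (l[1] >= l[2]) stop("each limit needs lo < hi")
  structure(limits, class = "release_limits")
}

#' Penalty-transformed objective functions
#'
#' Builds the three scalar objectives minimized by the optimizers:
#' `Q_k(x) = -Yhat(x, t_k) + sigma * P(x)` for each release time, so that
#' minimizing Q maximizes predicted release subject to the exterior
#' constant-sum penalty. On the feasibility hyperplane `Q_k = -Yhat(t_k)`
#' exactly.
#'
#' @param model a [release_model()].
#' @param sigma exterior penalty factor.
#' @param times release times defining the sub-objectives (default 2, 8,
#'   24 h).
#' @param exponent penalty exponent.
#' @param limits optional [release_limits()]: when supplied, the quadratic
#'   exterior penalty additionally charges `sigma` times the squared
#'   distance of each predicted release outside its acceptance interval, so
#'   the search is steered inside the pharmacopoeia window rather than
#'   relying solely on post-hoc filtering. With concordant release
#'   objectives the unconstrained optimum typically overshoots the upper
#'   caps, so in-search limits are what keep final archives feasible.
#' @return An object of class `release_objectives`: list with `Q(X)`
#'   (n x length(times) matrix of objective values, smaller is better),
#'   `Y(X)` (predicted releases), plus `times`, `sigma`, `total` and the
#'   number of decision variables `q`.
#' @export
build_objectives <- function(model, sigma = 1000, times = c(2, 8, 24),
                             exponent = 2, limits = NULL) {
  stopifnot(inherits(model, "release_model"))
  if (!is.null(limits)) {
    stopifnot(inherits(limits, "release_limits"))
    missing <- setdiff(paste0("Y_", times), names(limits))
    if (length(missing)) stop("limits lack interval(s): ",
                              paste(missing, collapse = ", "))
  }
  force(sigma); force(times); force(exponent)
  Yfun <- function(X) {
    Y <- predict_release(model, X, times)
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = length(times),
                                     dimnames = list(NULL, paste0("Y_", times)))
    Y
  }
  Qfun <- function(X) {
    pen <- penalty_term(X, sigma = sigma, total = model$total,
                        exponent = exponent)
    Y <- Yfun(X)
    if (!is.null(limits)) {
      for (k in seq_along(times)) {
        l <- limits[[paste0("Y_", times[k])]]
        viol <- pmax(0, l[1] - Y[, k]) + pmax(0, Y[, k] - l[2])
        pen <- pen + sigma * viol^2
      }
    }
    Q <- -Y + pen
    colnames(Q) <- paste0("Q", seq_along(times))
    Q
  }
  structure(list(Q = Qfun, Y = Yfun, times = times, sigma = sigma,
                 total = model$total, q = model$basis$q),
            class = "release_objectives")
}

#' Filter candidates against pharmacopoeia release limits
#'
#' Keeps the rows whose predicted releases fall inside every acceptance
#' interval (closed bounds).
#'
#' @param candidates a data frame containing the release columns named in
#'   `limits` (e.g. `Y_2`, `Y_8`, `Y_24`).
#' @param limits a [release_limits()].
#' @return The feasible subset of `candidates` (possibly empty).
#' @export
pharmacopoeia_filter <- function(candidates, limits = release_limits()) {
  stopifnot(inherits(limits, "release_limits"))
  if (nrow(candidates) == 0L) return(candidates)
  missing <- setdiff(names(limits), names(candidates))
  if (length(missing)) stop("candidates lack release column(s): ",
                            paste(missing, collapse = ", "))
  ok <- rep(TRUE, nrow(candidates))
  for (nm in names(limits)) {
    l <- limits[[nm]]
    ok <- ok & candidates[[nm]] >= l[1] & candidates[[nm]] <= l[2]
  }
  candidates[ok, , drop = FALSE]
}

#' Serialize a release model to YAML
#'
#' @param model a `release_model`.
#' @param path YAML file path.
#' @return `read_release_model()` returns a `release_model`.
#' @export
write_release_model <- function(model, path) {
  stopifnot(inherits(model, "release_model"))
  write_yaml_full(list(q = model$basis$q, centered = model$basis$centered,
                        offsets = if (is.null(model$basis$offsets)) NULL
                                  else as.numeric(model$basis$offsets),
                        total = model$total,
                        coefficients = as.list(model$coefficients)),
                   path)
  invisible(path)
}

#' @rdname write_release_model
#' @export
read_release_model <- function(path) {
  x <- yaml::read_yaml(path)
  b <- term_basis(x$q, centered = isTRUE(x$centered))
  if (!is.null(x$offsets)) b$offsets <- as.numeric(unlist(x$offsets))
  release_model(b, unlist(x$coefficients), total = x$total)
}
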
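#' Univariate penalized solutions (proximal operators)
#'
#' Closed-form solutions of the one-dimensional penalized least-squares
#' problem for a standardized coordinate: the building block of the
#' coordinate-descent solver. `lasso` is soft-thresholding
#' S(z, lambda) = sign(z) max(|z| - lambda, 0); `scad` and `mcp` relax the
#' shrinkage of large coefficients and leave |z| beyond `a*lambda`
#' (respectively `gamma*lambda`) untouched.
#'
#' @param z numeric vector of unpenalized univariate solutions.
#' @param lambda penalty strength (>= 0).
#' @param penalty one of `"lasso"`, `"scad"`, `"mcp"`.
#' @param gamma MCP concavity (> 1); default 3, the literature standard.
#' @param a SCAD shape (> 2); default 3.7, the literature standard.
#' @return Numeric vector of the same length as `z`.
#' @examples
#' prox_penalty(c(-2, 0.5, 2), 1, "lasso")
#' prox_penalty(2, 1, "mcp", gamma = 3)   # 1.5: relaxed shrinkage
#' prox_penalty(5, 1, "mcp", gamma = 3)   # 5: beyond gamma * lambda, untouched
#' @export
prox_penalty <- function(z, lambda, penalty = c("lasso", "scad", "mcp"),
                         gamma = 3, a = 3.7) {
  penalty <- match.arg(penalty)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single value >= 0")
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  switch(penalty,
    lasso = soft(z, lambda),
    scad = {
      if (a <= 2) stop("SCAD requires a > 2")
      az <- abs(z)
      ifelse(az <= 2 * lambda, soft(z, lambda),
      ifelse(az <= a * lambda,
             ((a - 1) * z - sign(z) * a * lambda) / (a - 2),
             z))
    },
    mcp = {
      if (gamma <= 1) stop("MCP requires gamma > 1")
      ifelse(abs(z) <= gamma * lambda,
             soft(z, lambda) / (1 - 1 / gamma), z)
    })
}

# standardize columns to mean 0 / variance 1 (n denominator); flags
# zero-variance columns so they are dropped from the descent.
standardize_cols <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colSums(Xc^2) / n)
  keep <- s > 1e-12
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, s[keep], "/")
  list(Xs = Xs, mu = mu, s = s, keep = keep)
}

#' Penalized least squares by cyclic coordinate descent
#'
#' Fits `y ~ X` under a LASSO, SCAD or MCP penalty. Columns are standardized
#' internally to mean 0 / unit variance (n denominator); the intercept is
#' unpenalized and recovered on the original scale; returned coefficients
#' are de-standardized. Constant columns (including an explicit intercept
#' column) are absorbed into the intercept.
#'
#' @param X design matrix (n x p); column names label the coefficients.
#' @param y response vector of length n.
#' @inheritParams prox_penalty
#' @param tol convergence threshold on the maximum coefficient change
#'   between sweeps (standardized scale).
#' @param max_iter maximum number of full sweeps; non-convergence warns,
#'   never fails.
#' @param init optional warm-start coefficient vector on the standardized
#'   scale (length = number of penalized columns).
#' @return Named numeric vector `c(intercept, beta)` on the original scale.
#' @export
penalized_fit <- function(X, y, penalty = c("lasso", "scad", "mcp"),
                          lambda, gamma = 3, a = 3.7,
                          tol = 1e-7, max_iter = 10000L, init = NULL) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("X must have at least one column")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  std <- standardize_cols(X)
  Xs <- std$Xs
  n <- nrow(Xs); p <- ncol(Xs)
  ybar <- mean(y)
  ys <- y - ybar
  if (penalty == "scad" && a <= 2) stop("SCAD requires a > 2")
  if (penalty == "mcp" && gamma <= 1) stop("MCP requires gamma > 1")
  b <- if (!is.null(init)) init else numeric(p)
  if (p > 0L) {
    pen_code <- match(penalty, c("lasso", "scad", "mcp")) - 1L
    sol <- cd_fit(Xs, ys, pen_code, lambda, gamma, a, tol,
                  as.integer(max_iter), b)
    b <- sol$b
    if (!sol$converged)
      warning(sprintf("coordinate descent did not converge in %d sweeps", max_iter))
  }
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  beta[std$keep] <- b / std$s[std$keep]
  intercept <- ybar - sum(beta * std$mu)
  c(intercept = intercept, beta)
}

# smallest lambda that zeroes every penalized coefficient, on the
# standardized scale used by the descent
lambda_max <- function(X, y) {
  std <- standardize_cols(as.matrix(X))
  if (ncol(std$Xs) == 0L) return(1)
  max(abs(crossprod(std$Xs, y - mean(y)) / nrow(std$Xs)))
}

#' Penalized variable selection with cluster-wise cross-validation
#'
#' Screens candidate mixture-polynomial terms on the pooled long-format data
#' (all formulation x time rows) by LASSO, SCAD or MCP along a 100-point
#' log-spaced lambda path, choosing lambda by k-fold cross-validation.
#' Ties in CV error resolve toward the sparser model (larger lambda).
#'
#' @param dataset a `mixture_dataset`.
#' @param basis a [term_basis()] describing the candidate terms.
#' @inheritParams prox_penalty
#' @param fold_by `"formulation"` (default) keeps all time points of a
#'   formulation in one fold, so repeated measures never leak between
#'   training and validation; `"row"` assigns individual long-format rows,
#'   the convention of standard penalized-regression CV on pooled data
#'   (within-formulation correlation is then ignored at the screening stage
#'   and handled afterwards by the QIF fit). Leakage-free folds are markedly
#'   more conservative on small designs.
#' @param nfolds number of folds (>= 2, at most the number of formulations).
#' @param seed fold-shuffling seed; fixed default so the shipped pipeline is
#'   deterministic.
#' @param nlambda path length; the grid spans `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @param max_terms optional cap on the selected support size: lambda is
#'   chosen as the CV minimizer among path points whose full-data support
#'   has at most this many terms. The downstream quadratic-inference fit
#'   with K basis matrices is identifiable only when `K * (p + 1)` moment
#'   conditions do not exceed the number of formulations, so pipelines pass
#'   `floor(n/K) - 1` here. NULL (default) leaves the support unconstrained.
#' @return An object of class `selection_result`: `penalty`, `coefficients`
#'   (full named vector incl. intercept), `selected` (labels of nonzero
#'   penalized terms), `lambda`, `path` (data frame lambda / cvm / cvsd /
#'   nonzero), `nfolds`, `seed`.
#' @export
cv_select <- function(dataset, basis, penalty = c("lasso", "scad", "mcp"),
                      fold_by = c("formulation", "row"),
                      nfolds = 10, seed = 20251101, gamma = 3, a = 3.7,
                      nlambda = 100, lambda_min_ratio = 0.001,
                      max_terms = NULL) {
  penalty <- match.arg(penalty)
  fold_by <- match.arg(fold_by)
  stopifnot(inherits(dataset, "mixture_dataset"))
  n_form <- nrow(dataset$composition)
  if (nfolds < 2) stop("nfolds must be >= 2")
  if (n_form < nfolds) stop("more folds than formulations")
  dm <- design_matrix(basis, dataset)
  pen_cols <- setdiff(colnames(dm$X), "intercept")
  X <- dm$X[, pen_cols, drop = FALSE]
  y <- dm$y
  lmax <- lambda_max(X, y)
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = nlambda))
  fold_of_row <- withr::with_seed(seed,
    if (fold_by == "formulation") {
      folds <- sample(rep_len(seq_len(nfolds), n_form))
      folds[dm$cluster]
    } else {
      sample(rep_len(seq_len(nfolds), length(y)))
    })
  cv_err <- matrix(NA_real_, nfolds, nlambda)
  for (f in seq_len(nfolds)) {
    tr <- fold_of_row != f
    if (!any(tr) || all(tr)) stop("empty cross-validation fold")
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    std <- standardize_cols(Xtr)
    init <- NULL
    for (l in seq_len(nlambda)) {
      co <- penalized_fit(Xtr, ytr, penalty, lambdas[l],
                          gamma = gamma, a = a, init = init)
      init <- (co[-1][std$keep]) * std$s[std$keep]
      pred <- co[1] + drop(Xte %*% co[-1])
      cv_err[f, l] <- mean((yte - pred)^2)
    }
  }
  cvm <- colMeans(cv_err)
  cvsd <- apply(cv_err, 2, stats::sd) / sqrt(nfolds)
  std <- standardize_cols(X)
  full_path_init <- NULL
  nonzero <- integer(nlambda)
  path_coefs <- matrix(NA_real_, ncol(X) + 1L, nlambda)
  for (l in seq_len(nlambda)) {
    co <- penalized_fit(X, y, penalty, lambdas[l], gamma = gamma, a = a,
                        init = full_path_init)
    full_path_init <- (co[-1][std$keep]) * std$s[std$keep]
    nonzero[l] <- sum(co[-1] != 0)
    path_coefs[, l] <- co
  }
  admissible <- if (is.null(max_terms)) seq_len(nlambda)
                else which(nonzero <= max_terms)
  if (length(admissible) == 0L) stop("no path point satisfies max_terms")
  # grid descends, so the first minimum is the largest (sparsest) lambda
  best <- admissible[which.min(cvm[admissible])]
  coefs <- path_coefs[, best]
  names(coefs) <- c("intercept", colnames(X))
  structure(
    list(penalty = penalty, coefficients = coefs,
         selected = names(coefs[-1])[coefs[-1] != 0],
         lambda = lambdas[best],
         path = data.frame(lambda = lambdas, cvm = cvm, cvsd = cvsd,
                           nonzero = nonzero),
         nfolds = nfolds, fold_by = fold_by, folds = fold_of_row,
         cluster = dm$cluster, seed = seed, gamma = gamma, a = a),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d of %d terms selected at lambda = %.5g (%d-fold CV)\n",
              toupper(x$penalty), length(x$selected),
              length(x$coefficients) - 1L, x$lambda, x$nfolds))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a selection result
#'
#' Writes the coefficient table (label, coefficient, selected flag) and the
#' lambda path as CSV files.
#'
#' @param result a `selection_result`.
#' @param coef_path,path_path output CSV paths (either may be NULL).
#' @export
write_selection_result <- function(result, coef_path = NULL,
                                   path_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  if (!is.null(coef_path)) {
    df <- data.frame(label = names(result$coefficients),
                     coefficient = unname(result$coefficients))
    df$selected <- df$label %in% result$selected
    utils::write.csv(df, coef_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_path))
    utils::write.csv(result$path, path_path, row.names = FALSE, quote = FALSE)
  invisible(result)
}
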
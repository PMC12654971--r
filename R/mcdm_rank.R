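#' Entropy weights for benefit criteria
#'
#' Objective criterion weights from information entropy of the decision
#' matrix: criteria whose values vary more across alternatives carry more
#' information and receive larger weights. With the default `"minmax"`
#' preprocessing each column is first rescaled to `[0, 1]`
#' (`(x - min)/(max - min)`), the dialect that reproduces the reference
#' study's published ranking; `"none"` forms probabilities directly from
#' the raw (strictly positive) values. Either way,
#' `P_ij = x_ij / sum_i x_ij`, `e_j = -(1/ln n) sum_i P_ij ln P_ij` (with
#' `0 ln 0 := 0`), and `w_j = (1 - e_j) / sum_k (1 - e_k)`. A constant
#' column carries no information (`e_j = 1`, weight 0).
#'
#' @param X n x m matrix of benefit criteria, n >= 2 alternatives.
#' @param preprocess `"minmax"` (default) or `"none"` (requires strictly
#'   positive entries).
#' @return An object of class `entropy_weights`: `entropy` (e_j), `weights`
#'   (w_j, summing to 1), `preprocess`.
#' @export
entropy_weights <- function(X, preprocess = c("minmax", "none")) {
  preprocess <- match.arg(preprocess)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 alternatives")
  if (anyNA(X) || any(!is.finite(X))) stop("criteria must be finite")
  M <- preprocess_criteria(X, preprocess)
  e <- apply(M, 2, function(col) {
    s <- sum(col)
    if (s <= 0) return(1)  # constant (degenerate) criterion
    p <- col / s
    -sum(ifelse(p > 0, p * log(p), 0)) / log(n)
  })
  if (all(1 - e <= .Machine$double.eps))
    stop("every criterion is constant; weights are undefined")
  w <- (1 - e) / sum(1 - e)
  structure(list(entropy = e, weights = w, preprocess = preprocess),
            class = "entropy_weights")
}

preprocess_criteria <- function(X, preprocess) {
  if (preprocess == "none") {
    if (any(X <= 0))
      stop("raw-dialect entropy weights require strictly positive entries")
    return(X)
  }
  apply(X, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("<entropy_weights>\n")
  print(data.frame(entropy = x$entropy, weight = x$weights))
  invisible(x)
}

#' TOPSIS ranking of alternatives
#'
#' Ranks alternatives by relative closeness to the ideal solution:
#' criteria are preprocessed (min-max by default, matching
#' [entropy_weights()]), vector-normalized
#' (`r_ij = x_ij / sqrt(sum_i x_ij^2)`), weighted, and each alternative is
#' scored `C = D- / (D+ + D-)` from its Euclidean distances to the positive
#' ideal (column-wise maximum of the weighted matrix) and the negative
#' ideal. For all-benefit criteria the negative ideal is the zero vector
#' (with min-max preprocessing the column minima are zero, so this is also
#' the column-wise minimum); set `zero_negative_ideal = FALSE` to use the
#' column-wise minimum explicitly.
#'
#' @param X n x m matrix of benefit criteria (non-negative).
#' @param weights an [entropy_weights()] object or a numeric vector summing
#'   to 1. When an `entropy_weights` object is supplied its preprocessing
#'   dialect is reused.
#' @param preprocess `"minmax"` or `"none"` (ignored when `weights` carries
#'   a dialect).
#' @param zero_negative_ideal use the zero vector as negative ideal
#'   (default TRUE, the all-benefit convention)?
#' @return An object of class `topsis_result` whose `table` element is a
#'   data frame with columns `D_plus`, `D_minus`, `C`, `rank` (descending
#'   C; ties keep input order). `weights` stores the weights used.
#' @export
topsis <- function(X, weights, preprocess = c("minmax", "none"),
                   zero_negative_ideal = TRUE) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("criteria must be non-negative")
  if (inherits(weights, "entropy_weights")) {
    preprocess <- weights$preprocess
    w <- weights$weights
  } else {
    preprocess <- match.arg(preprocess)
    w <- as.numeric(weights)
  }
  if (length(w) != ncol(X)) stop("weights length must match criteria count")
  M <- preprocess_criteria(X, preprocess)
  norms <- sqrt(colSums(M^2))
  if (any(norms == 0)) stop("zero-norm criterion column")
  v <- sweep(sweep(M, 2, norms, "/"), 2, w, "*")
  pos <- apply(v, 2, max)
  neg <- if (zero_negative_ideal) rep(0, ncol(v)) else apply(v, 2, min)
  D_plus <- sqrt(rowSums(sweep(v, 2, pos)^2))
  D_minus <- sqrt(rowSums(sweep(v, 2, neg)^2))
  C <- D_minus / (D_plus + D_minus)
  rank <- integer(length(C))
  rank[order(-C)] <- seq_along(C)  # order() is stable: ties keep input order
  structure(list(table = data.frame(D_plus = D_plus, D_minus = D_minus,
                                    C = C, rank = rank),
                 weights = w, preprocess = preprocess,
                 zero_negative_ideal = zero_negative_ideal),
            class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, ...) {
  cat(sprintf("<topsis_result> %d alternatives; weights: %s\n",
              nrow(x$table), paste(round(x$weights, 4), collapse = " ")))
  print(utils::head(x$table[order(x$table$rank), ], 5))
  invisible(x)
}

#' Ordered ranking report
#'
#' Joins a TOPSIS result onto its candidate table and sorts by rank, with
#' distances and closeness rounded to three decimals as in the published
#' table.
#'
#' @param result a [topsis()] result.
#' @param candidates the candidate table the decision matrix came from
#'   (same row order).
#' @param digits rounding for the report columns.
#' @return A data frame sorted by rank: the candidate columns followed by
#'   `D_plus`, `D_minus`, `C`, `rank`.
#' @export
rank_report <- function(result, candidates, digits = 3) {
  stopifnot(inherits(result, "topsis_result"))
  if (nrow(candidates) != nrow(result$table))
    stop("candidates and result must have the same number of rows")
  out <- cbind(candidates,
               round(result$table[c("D_plus", "D_minus", "C")], digits),
               rank = result$table$rank)
  out[order(out$rank), , drop = FALSE]
}

#' Entropy-weight TOPSIS ranking of a candidate table
#'
#' Convenience wrapper for the final evaluation stage: extracts the release
#' columns from a pooled candidate table, computes entropy weights, runs
#' TOPSIS, and returns the ordered report.
#'
#' @param candidates a candidate table with release columns `Y_<t>`.
#' @param preprocess entropy/TOPSIS dialect (see [entropy_weights()]).
#' @return A list: `weights` (`entropy_weights`), `result`
#'   (`topsis_result`), `report` (ordered data frame).
#' @examples
#' rk <- rank_candidates(load_candidate_table())
#' round(rk$weights$weights, 3)
#' head(rk$report[c("scheme", "C", "rank")], 3)
#' @export
rank_candidates <- function(candidates, preprocess = "minmax") {
  ycols <- grep("^Y_", names(candidates), value = TRUE)
  if (length(ycols) < 2L) stop("candidate table needs at least two Y_<t> columns")
  Y <- as.matrix(candidates[ycols])
  w <- entropy_weights(Y, preprocess = preprocess)
  ts <- topsis(Y, w)
  list(weights = w, result = ts, report = rank_report(ts, candidates))
}

#' Serialize entropy weights to YAML
#'
#' @param weights an `entropy_weights` object.
#' @param path YAML file path.
#' @export
write_entropy_weights <- function(weights, path) {
  stopifnot(inherits(weights, "entropy_weights"))
  write_yaml_full(list(entropy = as.numeric(weights$entropy),
                        weights = as.numeric(weights$weights),
                        preprocess = weights$preprocess),
                   path)
  invisible(path)
}
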
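#' Candidate term basis for a q-component mixture polynomial
#'
#' Enumerates the candidate terms of a q-component centered-polynomial
#' release model: the q main effects, all product interactions of orders
#' 2..`max_order`, optionally each component-by-time interaction plus linear
#' and quadratic time, and an intercept. Term labels are canonical
#' concatenations of ascending component indices: `"X24"` is the X2*X4
#' product, `"X12345"` the full five-way product, `"X3t"` the X3-by-time
#' interaction, `"t"`/`"t2"` the time terms.
#'
#' Centering is optional: classical Scheffé-type models use raw products
#' (the default), centered variants shift each component column by a stored
#' offset before products are formed. Offsets are captured from the training
#' data by [design_matrix()] and reused at prediction time.
#'
#' @param q number of mixture components (2..9).
#' @param max_order highest interaction order to include (2..q).
#' @param time_terms include `Xi*t`, `t` and `t^2` terms?
#' @param centered form products on mean-shifted component columns?
#' @param intercept include an intercept term (last)?
#' @return An object of class `term_basis`: list with `q`, `terms` (data
#'   frame `label`, `order`, `time_power`, list-column `indices`),
#'   `centered`, `offsets` (NULL until captured).
#' @export
term_basis <- function(q, max_order = q, time_terms = TRUE,
                       centered = FALSE, intercept = TRUE) {
  if (q < 2) stop("q must be >= 2")
  if (q > 9) stop("q > 9 is not supported (ambiguous term labels)")
  if (max_order < 2 || max_order > q)
    stop("max_order must be in 2..q")
  lab <- character(0); idx <- list(); tp <- integer(0); ord <- integer(0)
  add <- function(indices, time_power) {
    l <- if (length(indices))
      paste0("X", paste(indices, collapse = ""),
             if (time_power == 1L) "t" else "")
    else if (time_power == 1L) "t" else if (time_power == 2L) "t2"
    else "intercept"
    lab <<- c(lab, l); idx <<- c(idx, list(as.integer(indices)))
    tp <<- c(tp, as.integer(time_power)); ord <<- c(ord, length(indices))
  }
  for (i in seq_len(q)) add(i, 0L)
  for (k in 2:max_order)
    apply(utils::combn(q, k), 2, function(ix) add(ix, 0L))
  if (time_terms) {
    for (i in seq_len(q)) add(i, 1L)
    add(integer(0), 1L)
    add(integer(0), 2L)
  }
  if (intercept) add(integer(0), 0L)
  terms <- data.frame(label = lab, order = ord, time_power = tp,
                      stringsAsFactors = FALSE)
  terms$indices <- idx
  structure(list(q = as.integer(q), terms = terms,
                 centered = isTRUE(centered), offsets = NULL),
            class = "term_basis")
}

#' @export
print.term_basis <- function(x, ...) {
  cat(sprintf("<term_basis> q = %d, %d terms%s%s\n", x$q, nrow(x$terms),
              if (x$centered) ", centered" else "",
              if (!is.null(x$offsets)) " (offsets captured)" else ""))
  invisible(x)
}

# Core evaluator: comp is N x q (raw percentages), tvec length N.
# Centering offsets are applied to component columns before products.
eval_terms <- function(basis, comp, tvec, labels = NULL) {
  comp <- as.matrix(comp)
  if (ncol(comp) != basis$q)
    stop(sprintf("composition has %d components, basis expects %d",
                 ncol(comp), basis$q))
  if (length(tvec) != nrow(comp))
    stop("tvec length must match composition rows")
  terms <- basis$terms
  if (!is.null(labels)) {
    pos <- match(labels, terms$label)
    if (anyNA(pos)) stop("unknown term label(s): ",
                         paste(labels[is.na(pos)], collapse = ", "))
    terms <- terms[pos, , drop = FALSE]
  }
  C <- comp
  if (basis$centered) {
    if (is.null(basis$offsets))
      stop("centered basis has no offsets; evaluate a design matrix first")
    C <- sweep(comp, 2, basis$offsets)
  }
  out <- matrix(NA_real_, nrow(comp), nrow(terms),
                dimnames = list(NULL, terms$label))
  for (j in seq_len(nrow(terms))) {
    ix <- terms$indices[[j]]
    v <- if (length(ix)) Reduce(`*`, lapply(ix, function(i) C[, i]))
         else rep(1, nrow(comp))
    if (terms$time_power[j] == 1L) v <- v * tvec
    if (terms$time_power[j] == 2L) v <- v * tvec^2
    out[, j] <- v
  }
  out
}

#' Long-format design matrix for a mixture dissolution study
#'
#' Expands a study to one row per formulation x time point (time-major
#' within formulation, the repeated-measures layout the QIF fit expects) and
#' evaluates every basis term. For a centered basis, offsets are the
#' training-data component means, captured on first evaluation and stored in
#' the returned basis for prediction-time reuse.
#'
#' @param basis a [term_basis()] with `q` equal to the dataset's component
#'   count.
#' @param dataset a `mixture_dataset`.
#' @return A list: `X` (design matrix, columns named by term label), `y`
#'   (stacked response vector), `cluster` (formulation index per row),
#'   `time` (time per row), and `basis` (the basis, with offsets filled in
#'   when centering is on).
#' @export
design_matrix <- function(basis, dataset) {
  stopifnot(inherits(basis, "term_basis"), inherits(dataset, "mixture_dataset"))
  n <- nrow(dataset$composition)
  m <- length(dataset$times)
  if (basis$centered && is.null(basis$offsets))
    basis$offsets <- colMeans(dataset$composition)
  comp_long <- dataset$composition[rep(seq_len(n), each = m), , drop = FALSE]
  t_long <- rep(dataset$times, n)
  X <- eval_terms(basis, comp_long, t_long)
  list(X = X, y = as.vector(t(dataset$responses)),
       cluster = rep(seq_len(n), each = m), time = t_long, basis = basis)
}

#' Round-trip a term basis through YAML
#'
#' Serializes term labels, centering flag and offsets so a fitted model is
#' portable across sessions.
#'
#' @param basis a `term_basis`.
#' @param path YAML file path.
#' @export
write_term_basis <- function(basis, path) {
  stopifnot(inherits(basis, "term_basis"))
  write_yaml_full(list(q = basis$q, labels = basis$terms$label,
                        centered = basis$centered,
                        offsets = if (is.null(basis$offsets)) NULL
                                  else as.numeric(basis$offsets)),
                   path)
  invisible(path)
}

#' @rdname write_term_basis
#' @export
read_term_basis <- function(path) {
  x <- yaml::read_yaml(path)
  b <- term_basis(x$q, time_terms = any(unlist(x$labels) %in% c("t", "t2")),
                  centered = isTRUE(x$centered))
  keep <- match(unlist(x$labels), b$terms$label)
  if (anyNA(keep)) stop("stored basis contains unknown labels")
  b$terms <- b$terms[keep, , drop = FALSE]
  if (!is.null(x$offsets)) b$offsets <- as.numeric(unlist(x$offsets))
  b
}
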
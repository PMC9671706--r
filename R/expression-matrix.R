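#' Expression matrix with an explicit scale
#'
#' A light container for a genes-by-samples numeric matrix together with a
#' flag recording whether the values are linear-scale intensities or log2
#' intensities. All preprocessing and statistical functions in the package
#' act on this object, and several of them are only defined on one of the
#' two scales (for example the intensity filter works on linear signals,
#' the IQR filter on log2 values), so the flag is checked rather than
#' guessed from the data.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty rownames (gene symbols) and colnames (sample IDs).
#' @param scale Either `"linear"` or `"log2"`. Linear values must be
#'   strictly positive; values on both scales must be finite.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `scale`.
#' @export
#'
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m, scale = "linear")
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) || anyNA(rn) || any(rn == "")) {
    abort("`values` must have non-empty rownames (gene symbols).")
  }
  if (is.null(cn) || anyNA(cn) || any(cn == "")) {
    abort("`values` must have non-empty colnames (sample IDs).")
  }
  dup <- unique(rn[duplicated(rn)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene identifiers: ", toString(head(dup, 5))))
  }
  dup <- unique(cn[duplicated(cn)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample identifiers: ", toString(head(dup, 5))))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite expression value at gene '%s', sample '%s'.",
                  rn[bad[1]], cn[bad[2]]))
  }
  if (scale == "linear" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Linear-scale expression must be strictly positive; gene '%s', sample '%s' is %g.",
      rn[bad[1]], cn[bad[2]], values[bad[1], bad[2]]))
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @return Character vector of gene symbols (`gene_ids()`) or sample IDs
#'   (`sample_ids()`).
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  rownames(x$values)
}

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  colnames(x$values)
}

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `value`, `scale`.
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    gene   = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value  = as.vector(x$values),
    scale  = x$scale
  )
}

assert_scale <- function(x, scale, what) {
  if (!inherits(x, "expr_matrix")) {
    abort(paste0(what, " expects an `expr_matrix`; see expression_matrix()."))
  }
  if (x$scale != scale) {
    abort(sprintf("%s requires a %s-scale matrix but got %s scale.",
                  what, scale, x$scale))
  }
  invisible(x)
}

replace_values <- function(x, values) {
  x$values <- values
  x
}
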
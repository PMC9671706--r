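new_filter_report <- function(step, n_input, kept, removed_ids, ...) {
  structure(list(step = step, n_input = n_input, n_kept = length(kept),
                 removed_ids = removed_ids, ...),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report:%s> %d -> %d genes (%d removed)\n",
              x$step, x$n_input, x$n_kept, length(x$removed_ids)))
  invisible(x)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one intensity distribution: each
#' column's sorted values are replaced by the per-rank means of the
#' column-sorted input, and tied values within a column receive the mean
#' of the reference values at their tied ranks. Gene order and the scale
#' flag are preserved. After normalization all column-sorted vectors are
#' identical, so in particular the per-sample medians coincide.
#'
#' @param x An [expression_matrix()] with at least two samples.
#' @return The normalized [expression_matrix()].
#' @export
#'
#' @examples
#' m <- expression_matrix(matrix(c(1, 2, 3, 4), 2,
#'        dimnames = list(c("A", "B"), c("s1", "s2"))), "linear")
#' quantile_normalize(m)$values
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) {
    abort("quantile_normalize() needs at least 2 samples.")
  }
  out <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(out) <- dimnames(x$values)
  replace_values(x, out)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param x A linear-scale [expression_matrix()] (all values > 0).
#' @return The matrix on the log2 scale.
#' @export
log2_transform <- function(x) {
  assert_scale(x, "linear", "log2_transform()")
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Filter genes by minimum linear-scale signal
#'
#' Keeps a gene when the fraction of samples with signal strictly above
#' `min_signal` is at least `min_fraction` (strict `>` on the signal,
#' `>=` on the fraction). The threshold is defined on linear intensities,
#' so log2-scale input is rejected.
#'
#' @param x A linear-scale [expression_matrix()].
#' @param min_signal Linear intensity a sample must exceed (default 100).
#' @param min_fraction Minimum fraction of samples exceeding it
#'   (default 0.25).
#' @return A list with the filtered `expr` and a `report`
#'   (`filter_report` with input/kept counts and removed symbols).
#' @export
intensity_filter <- function(x, min_signal = 100, min_fraction = 0.25) {
  assert_scale(x, "linear", "intensity_filter()")
  frac <- rowMeans(x$values > min_signal)
  keep <- frac >= min_fraction
  report <- new_filter_report("intensity", nrow(x$values), which(keep),
                              removed_ids = rownames(x$values)[!keep],
                              min_signal = min_signal,
                              min_fraction = min_fraction)
  list(expr = replace_values(x, x$values[keep, , drop = FALSE]),
       report = report)
}

#' Filter genes by interquartile range
#'
#' Computes each gene's IQR across samples on the log2 scale (quartiles by
#' the linear-interpolation convention, `stats::quantile` type 7, recorded
#' in the report) and keeps genes whose IQR strictly exceeds the median of
#' all gene IQRs. By construction at most half of the genes survive; if
#' all genes have identical IQR, none do.
#'
#' @param x A log2-scale [expression_matrix()] with at least 4 samples.
#' @return A list with the filtered `expr` and a `report` that also
#'   records `median_iqr` and the quartile convention.
#' @export
iqr_filter <- function(x) {
  assert_scale(x, "log2", "iqr_filter()")
  if (ncol(x$values) < 4) {
    abort("iqr_filter() needs at least 4 samples to estimate quartiles.")
  }
  q <- apply(x$values, 1, quantile, probs = c(0.25, 0.75), type = 7,
             names = FALSE)
  iqrs <- q[2, ] - q[1, ]
  med <- median(iqrs)
  keep <- iqrs > med
  report <- new_filter_report("iqr", nrow(x$values), which(keep),
                              removed_ids = rownames(x$values)[!keep],
                              median_iqr = med, quartile_type = 7L)
  list(expr = replace_values(x, x$values[keep, , drop = FALSE]),
       report = report)
}

build_covariate_matrix <- function(meta, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(meta)) {
      abort(sprintf("Covariate '%s' is not a metadata column.", cv))
    }
    v <- meta[[cv]]
    if (is.numeric(v)) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)   # mean-impute missing values
      m <- matrix(v - mean(v), ncol = 1)
      colnames(m) <- cv
      m
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "missing"               # missing category = own level
      f <- factor(v)
      if (nlevels(f) < 2) {
        matrix(numeric(nrow(meta)), nrow = nrow(meta), ncol = 0)
      } else {
        m <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(cv, levels(f)[-1])
        scale(m, center = TRUE, scale = FALSE)
      }
    }
  })
  do.call(cbind, cols)
}

#' Remove covariate effects while protecting the group contrast
#'
#' For each gene, fits least squares on an intercept, the case/control
#' indicator and the (centered) covariates, then subtracts only the fitted
#' covariate contributions. The intercept and group effect are retained,
#' so planted or biological group differences survive adjustment; the
#' operation is idempotent. Missing numeric covariates are mean-imputed and
#' a missing categorical value becomes its own level, so no sample is
#' dropped.
#'
#' @param x A log2-scale [expression_matrix()].
#' @param meta Sample metadata with a `group` column and one column per
#'   covariate; rows are matched to `sample_ids(x)`.
#' @param covariates Character vector of metadata columns to remove
#'   (default `c("age", "gender")`). Empty vector returns `x` unchanged.
#' @return The adjusted [expression_matrix()].
#' @export
adjust_covariates <- function(x, meta, covariates = c("age", "gender")) {
  assert_scale(x, "log2", "adjust_covariates()")
  if (length(covariates) == 0) return(x)
  if (!all(sample_ids(x) %in% meta$sample_id)) {
    abort("Metadata is missing rows for some expression samples.")
  }
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  cmat <- build_covariate_matrix(meta, covariates)
  if (is.null(cmat) || ncol(cmat) == 0) return(x)
  design <- model.matrix(~group, data = meta)
  full <- cbind(design, cmat)
  if (qr(full)$rank < ncol(full)) {
    abort(paste("Rank-deficient design: a covariate is confounded with the",
                "group indicator or with another covariate."))
  }
  adj <- limma::removeBatchEffect(x$values, covariates = cmat, design = design)
  dimnames(adj) <- dimnames(x$values)
  replace_values(x, adj)
}

#' Run the full preprocessing chain
#'
#' Quantile normalization on the linear scale, then the intensity filter,
#' log2 transform, IQR filter, and covariate adjustment, in that order.
#'
#' @param x A linear-scale [expression_matrix()].
#' @param meta Sample metadata (needed when `covariates` is non-empty).
#' @param min_signal,min_fraction Passed to [intensity_filter()].
#' @param covariates Passed to [adjust_covariates()].
#' @return A list with the final log2-scale `expr` and `reports`, a list
#'   of the two `filter_report`s.
#' @export
preprocess_expression <- function(x, meta = NULL, min_signal = 100,
                                  min_fraction = 0.25,
                                  covariates = c("age", "gender")) {
  assert_scale(x, "linear", "preprocess_expression()")
  x <- quantile_normalize(x)
  step1 <- intensity_filter(x, min_signal, min_fraction)
  x <- log2_transform(step1$expr)
  step2 <- iqr_filter(x)
  x <- step2$expr
  if (length(covariates) > 0) {
    if (is.null(meta)) abort("`meta` is required when covariates are adjusted.")
    x <- adjust_covariates(x, meta, covariates)
  }
  list(expr = x, reports = list(intensity = step1$report, iqr = step2$report))
}
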
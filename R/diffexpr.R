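## Invert the trigamma function: find x > 0 with trigamma(x) = y.
## trigamma is strictly decreasing on (0, Inf) with range (0, Inf), so a
## bracketing search is robust; tolerances are far below anything the
## moderation fit can resolve.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))      # trigamma(x) ~ 1/x^2 as x -> 0
  lo <- 1e-8
  hi <- 1e8
  stats::uniroot(function(x) trigamma(x) - y, lower = lo, upper = hi,
                 tol = 1e-12)$root
}

#' Fit empirical-Bayes variance-moderation hyperparameters
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of a scaled-inverse-chi-squared prior on gene variances by the method
#' of moments on log variances. With residual degrees of freedom `d` and
#' per-gene sample variances `s_g^2`, define
#' `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`; then
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` is solved for `d0`, and
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the right-hand
#' side is non-positive the log-variances show no excess dispersion, so
#' `d0 = Inf` and `s0_sq = exp(mean(e))`.
#'
#' @param variances Per-gene sample variances (at least 10 positive finite
#'   values; zero or negative variances are dropped with a warning).
#' @param residual_df Residual degrees of freedom of each variance,
#'   `n1 + n2 - 2` for a two-group comparison.
#' @return A `moderation_fit` object with elements `d0`, `s0_sq`,
#'   `residual_df`, `n_genes`.
#' @export
#'
#' @examples
#' set.seed(1)
#' v <- 0.04 * 4 / rchisq(2000, 4) * rchisq(2000, 10) / 10
#' fit_moderation(v, residual_df = 10)
fit_moderation <- function(variances, residual_df) {
  if (length(residual_df) != 1 || !is.finite(residual_df) || residual_df < 1) {
    abort("`residual_df` must be a single value >= 1.")
  }
  v <- variances[is.finite(variances)]
  bad <- sum(v <= 0)
  if (bad > 0) {
    warn(sprintf("%d zero or negative variance(s) excluded from the moderation fit.", bad))
    v <- v[v > 0]
  }
  if (length(v) < 10) {
    abort("fit_moderation() needs at least 10 positive finite variances.")
  }
  d <- residual_df
  e <- log(v) - digamma(d / 2) + log(d / 2)
  rhs <- var(e) - trigamma(d / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, residual_df = d,
                 n_genes = length(v)),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("<moderation_fit> d0 = %s, s0_sq = %.4g (residual df %g, %d genes)\n",
              format(x$d0, digits = 4), x$s0_sq, x$residual_df, x$n_genes))
  invisible(x)
}

#' Tidy a moderation fit
#'
#' @param x A `moderation_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per hyperparameter (`term`,
#'   `estimate`); `glance()`: a one-row tibble with `d0`, `s0_sq`,
#'   `residual_df`, `n_genes`.
#' @method tidy moderation_fit
#' @export
tidy.moderation_fit <- function(x, ...) {
  tibble(term = c("d0", "s0_sq"), estimate = c(x$d0, x$s0_sq))
}

#' @rdname tidy.moderation_fit
#' @method glance moderation_fit
#' @export
glance.moderation_fit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, residual_df = x$residual_df,
         n_genes = x$n_genes)
}

#' Moderated two-group t-test per gene
#'
#' For each gene computes the case/control means, the log2 fold change
#' (case minus control), the pooled variance `s^2`, the posterior variance
#' `s~^2 = (d0 * s0_sq + d * s^2) / (d0 + d)` under the moderation fit,
#' the moderated t statistic `log2fc / (s~ * sqrt(1/n1 + 1/n2))` and its
#' two-sided p-value on `d0 + d` degrees of freedom (normal tail when
#' `d0 = Inf`). With `ordinary = TRUE` (or a fit with `d0 = 0`) this is
#' exactly the classical pooled-variance Student t-test. Genes with zero
#' posterior variance cannot be tested and receive `t = 0`, `p = 1` with
#' a warning.
#'
#' @param x A log2-scale [expression_matrix()].
#' @param meta Sample metadata with `sample_id` and `group`
#'   (`"schizophrenic"` = case, `"control"` = control); both groups need
#'   at least 2 samples.
#' @param fit Optional `moderation_fit`; estimated from the pooled
#'   variances when `NULL`.
#' @param ordinary If `TRUE`, disable moderation (`d0 = 0`).
#' @return A tibble with columns `symbol`, `mean_case`, `mean_control`,
#'   `log2fc`, `t_stat`, `p_value`, `adj_p` (Benjamini-Hochberg), carrying
#'   the moderation fit in attribute `"moderation_fit"`.
#' @export
moderated_t_test <- function(x, meta, fit = NULL, ordinary = FALSE) {
  assert_scale(x, "log2", "moderated_t_test()")
  if (!all(sample_ids(x) %in% meta$sample_id)) {
    abort("Metadata is missing rows for some expression samples.")
  }
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  case <- meta$group == "schizophrenic"
  ctrl <- meta$group == "control"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2 || n2 < 2) {
    abort("Both groups need at least 2 samples for a two-sample test.")
  }
  vals <- x$values
  m1 <- rowMeans(vals[, case, drop = FALSE])
  m2 <- rowMeans(vals[, ctrl, drop = FALSE])
  v1 <- apply(vals[, case, drop = FALSE], 1, var)
  v2 <- apply(vals[, ctrl, drop = FALSE], 1, var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  if (ordinary) {
    fit <- structure(list(d0 = 0, s0_sq = 0, residual_df = d,
                          n_genes = length(s2)), class = "moderation_fit")
  } else if (is.null(fit)) {
    fit <- fit_moderation(s2, d)
  } else if (!inherits(fit, "moderation_fit")) {
    abort("`fit` must be a moderation_fit (see fit_moderation()).")
  }

  if (is.infinite(fit$d0)) {
    post_var <- rep(fit$s0_sq, length(s2))
  } else {
    post_var <- (fit$d0 * fit$s0_sq + d * s2) / (fit$d0 + d)
  }
  lfc <- m1 - m2
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  tt <- lfc / se
  zero_var <- !is.finite(tt) | se == 0
  if (any(zero_var)) {
    warn(sprintf("%d gene(s) with zero posterior variance set to t = 0, p = 1.",
                 sum(zero_var)))
    tt[zero_var] <- 0
  }
  df_total <- fit$d0 + d
  p <- 2 * pt(-abs(tt), df = df_total)
  p[zero_var] <- 1

  out <- tibble(
    symbol = rownames(vals),
    mean_case = unname(m1), mean_control = unname(m2),
    log2fc = unname(lfc), t_stat = unname(tt), p_value = unname(p),
    adj_p = unname(benjamini_hochberg(p))
  )
  attr(out, "moderation_fit") <- fit
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns adjusted p-values `adj_(i) = min_{j: rank(j) >= rank(i)}
#' (m * p_(j) / j)` capped at 1; the result is invariant to permutations
#' of the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#'
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || !is.numeric(p) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric, non-missing, and in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Assigns status `"up"` when `log2fc >= lfc_cut` (or `> lfc_cut` with
#' `strict_lfc = TRUE`) and `adj_p < fdr_cut` (strict), `"down"`
#' symmetrically, otherwise `"not_de"`.
#'
#' @param table A DE tibble from [moderated_t_test()].
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_cut Adjusted-p threshold (default 0.001, strict `<`).
#' @param strict_lfc Use strict `>` for the fold-change comparison.
#' @return The tibble with a `status` column added.
#' @export
call_degs <- function(table, lfc_cut = 0.5, fdr_cut = 0.001,
                      strict_lfc = FALSE) {
  if (!all(c("log2fc", "adj_p") %in% names(table))) {
    abort("`table` must contain `log2fc` and `adj_p` (see moderated_t_test()).")
  }
  pass_lfc <- if (strict_lfc) abs(table$log2fc) > lfc_cut else
    abs(table$log2fc) >= lfc_cut
  sig <- pass_lfc & table$adj_p < fdr_cut
  table |>
    mutate(status = dplyr::case_when(
      sig & .data$log2fc > 0 ~ "up",
      sig & .data$log2fc < 0 ~ "down",
      TRUE ~ "not_de"
    ))
}

#' Partition DE genes into lncRNAs and mRNAs
#'
#' Splits the differentially expressed genes by exact, case-sensitive
#' membership of their symbol in a caller-supplied lncRNA list; DE genes
#' not in the list are treated as mRNAs.
#'
#' @param table A DE tibble with `status` assigned (see [call_degs()]).
#' @param lnc_symbols Character vector of lncRNA symbols.
#' @return A list with tibbles `delncrna` and `demrna` (DE rows only,
#'   each with a `biotype` column).
#' @export
partition_lnc_mrna <- function(table, lnc_symbols) {
  if (!"status" %in% names(table)) {
    abort("`table` must have DE status; run call_degs() first.")
  }
  de <- table |>
    filter(.data$status != "not_de") |>
    mutate(biotype = ifelse(.data$symbol %in% lnc_symbols, "lncRNA", "mRNA"))
  list(delncrna = de |> filter(.data$biotype == "lncRNA"),
       demrna = de |> filter(.data$biotype == "mRNA"))
}
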
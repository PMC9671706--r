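#' Filter interaction edges by species and evidence class
#'
#' Applies the curation rules used when querying interaction databases:
#' lncRNA--miRNA edges are kept only for Homo sapiens at high miRNA
#' confidence; miRNA--mRNA edges are kept only with strong experimental
#' evidence. Comparisons are case-insensitive after trimming; surviving
#' edges are deduplicated.
#'
#' @param edges Interaction tibble of one kind (see
#'   [read_interaction_table()]).
#' @param kind `"lncrna_mirna"` or `"mirna_mrna"`.
#' @return The filtered edge tibble, reduced to its identifier columns.
#' @export
filter_interactions <- function(edges, kind = c("lncrna_mirna", "mirna_mrna")) {
  kind <- match.arg(kind)
  lowtrim <- function(x) tolower(trimws(x))
  if (kind == "lncrna_mirna") {
    edges |>
      filter(lowtrim(.data$species) == "homo sapiens",
             lowtrim(.data$confidence) == "high") |>
      distinct(.data$lncrna, .data$mirna)
  } else {
    edges |>
      filter(lowtrim(.data$evidence) == "strong") |>
      distinct(.data$mirna, .data$mrna)
  }
}

#' Enumerate candidate lncRNA--miRNA--mRNA triples
#'
#' Builds every triple (L, m, G) such that L is a DE lncRNA, G a DE mRNA,
#' and both edges (L, m) and (m, G) exist in the filtered interaction
#' tables. The result is deduplicated and sorted lexicographically by
#' lncRNA, miRNA, mRNA, so the output is deterministic.
#'
#' @param delnc Character vector of DE lncRNA symbols.
#' @param demrna Character vector of DE mRNA symbols.
#' @param lnc_mir Filtered lncRNA--miRNA edges (`lncrna`, `mirna`).
#' @param mir_mrna Filtered miRNA--mRNA edges (`mirna`, `mrna`).
#' @return A tibble with columns `lncrna`, `mirna`, `mrna`.
#' @export
#'
#' @examples
#' build_candidate_triples(
#'   "L1", "G1",
#'   tibble::tibble(lncrna = "L1", mirna = "m1"),
#'   tibble::tibble(mirna = "m1", mrna = "G1"))
build_candidate_triples <- function(delnc, demrna, lnc_mir, mir_mrna) {
  lnc_mir |>
    filter(.data$lncrna %in% delnc) |>
    inner_join(mir_mrna, by = "mirna", relationship = "many-to-many") |>
    filter(.data$mrna %in% demrna) |>
    distinct(.data$lncrna, .data$mirna, .data$mrna) |>
    arrange(.data$lncrna, .data$mirna, .data$mrna)
}

#' Pearson correlation of lncRNA--mRNA pairs with FDR control
#'
#' For each unique (lncRNA, mRNA) pair, computes the sample Pearson
#' coefficient over all samples (cases and controls pooled), the
#' two-sided p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom, and the Benjamini-Hochberg FDR across the
#' unique pair list. Pairs involving a zero-variance gene have no defined
#' correlation and are dropped with a warning.
#'
#' @param x A log2-scale [expression_matrix()] with at least 4 samples.
#' @param pairs Tibble with columns `lncrna` and `mrna`; all symbols must
#'   be rows of `x`.
#' @return A tibble with columns `lncrna`, `mrna`, `r`, `p_value`,
#'   `corr_fdr`, `n`.
#' @export
correlate_pairs <- function(x, pairs) {
  assert_scale(x, "log2", "correlate_pairs()")
  n <- ncol(x$values)
  if (n < 4) abort("correlate_pairs() needs at least 4 samples.")
  pairs <- pairs |> distinct(.data$lncrna, .data$mrna)
  missing <- setdiff(unique(c(pairs$lncrna, pairs$mrna)), gene_ids(x))
  if (length(missing) > 0) {
    abort(sprintf("Symbol(s) absent from the expression matrix: %s",
                  toString(head(missing, 5))))
  }
  sds <- apply(x$values[unique(c(pairs$lncrna, pairs$mrna)), , drop = FALSE],
               1, stats::sd)
  degenerate <- names(sds)[sds == 0]
  if (length(degenerate) > 0) {
    drop <- pairs$lncrna %in% degenerate | pairs$mrna %in% degenerate
    warn(sprintf("%d pair(s) dropped: zero-variance gene(s) %s have undefined correlation.",
                 sum(drop), toString(head(degenerate, 5))))
    pairs <- pairs[!drop, ]
  }
  if (nrow(pairs) == 0) {
    return(tibble(lncrna = character(), mrna = character(), r = numeric(),
                  p_value = numeric(), corr_fdr = numeric(), n = integer()))
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(x$values[pairs$lncrna[i], ], x$values[pairs$mrna[i], ])
  }, numeric(1))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(is.finite(tt), 2 * pt(-abs(tt), df = n - 2), 0)
  pairs |>
    mutate(r = r, p_value = p, corr_fdr = benjamini_hochberg(p),
           n = as.integer(n))
}

#' Assemble ceRNA axes from candidate triples
#'
#' Keeps a candidate triple when its lncRNA--mRNA co-expression passes
#' `r > r_min` (strict) and `corr_fdr < fdr_max` (strict) and the DE
#' directions of the lncRNA and mRNA agree — triples with opposing
#' expression patterns are omitted, per the ceRNA hypothesis of a shared
#' sponged miRNA inducing positive co-expression. Output is sorted
#' deterministically.
#'
#' @param triples Candidate triples from [build_candidate_triples()].
#' @param de DE tibble with `status` assigned ([call_degs()]).
#' @param correlations Output of [correlate_pairs()] covering every
#'   triple's (lncRNA, mRNA) pair; a missing record is a consistency
#'   error.
#' @param r_min Minimum Pearson coefficient (default 0.5, strict `>`).
#' @param fdr_max Maximum correlation FDR (default 0.001, strict `<`).
#' @return A tibble with columns `lncrna`, `mirna`, `mrna`, `direction`,
#'   `r`, `corr_fdr`, `log2fc_lncrna`, `log2fc_mrna`.
#' @export
assemble_axes <- function(triples, de, correlations, r_min = 0.5,
                          fdr_max = 0.001) {
  if (nrow(triples) == 0) {
    return(tibble(lncrna = character(), mirna = character(),
                  mrna = character(), direction = character(), r = numeric(),
                  corr_fdr = numeric(), log2fc_lncrna = numeric(),
                  log2fc_mrna = numeric()))
  }
  joined <- triples |>
    left_join(correlations |> select("lncrna", "mrna", "r", "corr_fdr"),
              by = c("lncrna", "mrna"))
  if (anyNA(joined$r)) {
    miss <- joined |> filter(is.na(.data$r))
    abort(sprintf("No correlation record for pair(s): %s",
                  toString(head(paste0(miss$lncrna, "~", miss$mrna), 5))))
  }
  de_status <- de |> select("symbol", "status", "log2fc")
  joined |>
    left_join(de_status, by = c(lncrna = "symbol")) |>
    rename(status_lnc = "status", log2fc_lncrna = "log2fc") |>
    left_join(de_status, by = c(mrna = "symbol")) |>
    rename(status_mrna = "status", log2fc_mrna = "log2fc") |>
    filter(.data$r > r_min, .data$corr_fdr < fdr_max,
           .data$status_lnc %in% c("up", "down"),
           .data$status_lnc == .data$status_mrna) |>
    transmute(.data$lncrna, .data$mirna, .data$mrna,
              direction = .data$status_lnc, .data$r, .data$corr_fdr,
              .data$log2fc_lncrna, .data$log2fc_mrna) |>
    arrange(.data$lncrna, .data$mirna, .data$mrna)
}

#' Summarize axis membership
#'
#' @param axes Axis tibble from [assemble_axes()].
#' @return A one-row tibble with the number of axes and of distinct
#'   lncRNAs, miRNAs and mRNAs.
#' @export
axis_summary <- function(axes) {
  tibble(
    n_axes = nrow(axes),
    n_lncrna = dplyr::n_distinct(axes$lncrna),
    n_mirna = dplyr::n_distinct(axes$mirna),
    n_mrna = dplyr::n_distinct(axes$mrna)
  )
}

#' Overlay protein-protein interactions on axis mRNAs
#'
#' Retains PPI edges with combined score at or above `min_score`
#' (inclusive, the medium-confidence convention) connecting two distinct
#' mRNAs that both appear in the assembled axes. Edges are undirected and
#' deduplicated.
#'
#' @param axes Axis tibble from [assemble_axes()].
#' @param ppi PPI tibble (`protein_a`, `protein_b`, `combined_score` on
#'   `[0, 1]`).
#' @param min_score Minimum combined score (default 0.4).
#' @return The filtered PPI tibble.
#' @export
overlay_ppi <- function(axes, ppi, min_score = 0.4) {
  if (any(ppi$combined_score < 0 | ppi$combined_score > 1)) {
    abort("PPI combined scores must lie in [0, 1]; see read_ppi_table(string_scale=).")
  }
  nodes <- unique(axes$mrna)
  ppi |>
    filter(.data$combined_score >= min_score,
           .data$protein_a != .data$protein_b,
           .data$protein_a %in% nodes, .data$protein_b %in% nodes) |>
    mutate(a = pmin(.data$protein_a, .data$protein_b),
           b = pmax(.data$protein_a, .data$protein_b)) |>
    distinct(.data$a, .data$b, .keep_all = TRUE) |>
    select("protein_a", "protein_b", "combined_score") |>
    arrange(.data$protein_a, .data$protein_b)
}
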
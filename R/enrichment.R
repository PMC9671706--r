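#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query genes against
#' a finite universe with the one-sided hypergeometric tail
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`, where `N` is
#' the universe size, `K` the set size within the universe, `n` the query
#' size and `k` the overlap. P-values are Benjamini-Hochberg adjusted
#' across all tested sets, and rows are sorted by p ascending with a
#' lexicographic tie-break on the set name.
#'
#' Set members outside the universe are ignored (the universe is the
#' population actually sampled from — here, genes surviving the
#' preprocessing filters); query genes outside the universe are dropped
#' with a warning.
#'
#' @param query Character vector of gene symbols to test (non-empty).
#' @param sets Gene-set tibble with `set_name`, `description` and a
#'   `genes` list column (see [read_gmt()]).
#' @param universe Character vector of background gene symbols.
#' @return A tibble with columns `set_name`, `overlap_k`, `set_size_K`,
#'   `query_n`, `universe_N`, `p_value`, `adj_p` and a list column
#'   `overlap_genes`.
#' @export
#'
#' @examples
#' sets <- tibble::tibble(set_name = "S", description = "d",
#'                        genes = list(paste0("G", 1:5)))
#' enrich(paste0("G", 1:5), sets, paste0("G", 1:20))
enrich <- function(query, sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) abort("`query` must contain at least one gene.")
  if (is.null(sets) || nrow(sets) == 0) {
    abort("`sets` must contain at least one gene set.")
  }
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped: %s",
                 length(outside), toString(head(outside, 5))))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    abort("No query genes remain inside the universe.")
  }
  n <- length(query)
  N <- length(universe)
  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    members <- intersect(sets$genes[[i]], universe)
    K <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = sets$set_name[i], overlap_k = k, set_size_K = K,
           query_n = n, universe_N = N, p_value = p,
           overlap_genes = list(sort(ov)))
  })
  bind_rows(rows) |>
    mutate(adj_p = benjamini_hochberg(.data$p_value), .before = "overlap_genes") |>
    arrange(.data$p_value, .data$set_name)
}
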
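#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- as.data.frame(x$values)
  df <- cbind(symbol = rownames(x$values), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Write sample metadata with demographic-sheet column names
#'
#' Writes the columns under the same headers the demographic table prints
#' (`Sample`, `Source name`, `Age`, `Gender`, `Ph`,
#' `Post-mortem delay (h)`), with missing values as the literal `NA`,
#' so that [read_sample_metadata()] round-trips the table.
#'
#' @param meta Metadata tibble as returned by [read_sample_metadata()] or
#'   [generate_cohort_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- tibble(
    "Sample" = meta$sample_id,
    "Source name" = meta$source_name,
    "Age" = meta$age,
    "Gender" = ifelse(is.na(meta$gender), "NA",
                      paste0(toupper(substr(meta$gender, 1, 1)),
                             substr(meta$gender, 2, nchar(meta$gender)))),
    "Ph" = ifelse(is.na(meta$ph), "NA", format(meta$ph)),
    "Post-mortem delay (h)" = ifelse(is.na(meta$pmd_hours), "NA",
                                     format(meta$pmd_hours))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write interaction, PPI and gene-set tables
#'
#' @param edges Interaction tibble (see [read_interaction_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_interaction_table
#' @param ppi PPI tibble (see [read_ppi_table()]).
#' @export
write_ppi_table <- function(ppi, path) {
  readr::write_tsv(ppi, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_interaction_table
#' @param sets Gene-set tibble with `set_name`, `description`, `genes`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Export a ceRNA network as SIF plus node attributes
#'
#' Writes `<out_prefix>.sif` with one edge per line (`lncrna sponges
#' mirna`, `mirna targets mrna`, `mrna ppi mrna`) and
#' `<out_prefix>.nodes.tsv` listing each node exactly once with its type
#' (lncRNA / miRNA / mRNA), DE direction and log2 fold change (`NA` for
#' miRNAs, which are not measured). Both files load into standard network
#' tools.
#'
#' @param axes Axis tibble from [assemble_axes()].
#' @param ppi PPI edge tibble (already gated, e.g. via [overlay_ppi()]).
#' @param out_prefix Path prefix for the two output files.
#' @param de Optional DE tibble (from [call_degs()]) used to annotate
#'   node log2FC and direction.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_network <- function(axes, ppi = NULL, out_prefix, de = NULL) {
  sponge <- axes |> distinct(.data$lncrna, .data$mirna) |>
    transmute(source = .data$lncrna, relation = "sponges", target = .data$mirna)
  target <- axes |> distinct(.data$mirna, .data$mrna) |>
    transmute(source = .data$mirna, relation = "targets", target = .data$mrna)
  edges <- bind_rows(sponge, target)
  if (!is.null(ppi) && nrow(ppi) > 0) {
    edges <- bind_rows(edges, ppi |>
      transmute(source = .data$protein_a, relation = "ppi",
                target = .data$protein_b))
  }
  sif_path <- paste0(out_prefix, ".sif")
  readr::write_lines(
    sprintf("%s\t%s\t%s", edges$source, edges$relation, edges$target),
    sif_path)

  nodes <- bind_rows(
    tibble(node = unique(axes$lncrna), type = "lncRNA"),
    tibble(node = unique(axes$mirna), type = "miRNA"),
    tibble(node = unique(axes$mrna), type = "mRNA")
  )
  if (!is.null(de)) {
    nodes <- nodes |>
      left_join(de |> select("symbol", "status", "log2fc"),
                by = c(node = "symbol")) |>
      rename(direction = "status")
  } else {
    nodes$direction <- NA_character_
    nodes$log2fc <- NA_real_
  }
  node_path <- paste0(out_prefix, ".nodes.tsv")
  readr::write_tsv(nodes, node_path, progress = FALSE)
  invisible(c(sif_path, node_path))
}

#' Write every artifact of a synthetic study to a directory
#'
#' Emits the expression TSV, demographic-style metadata TSV, both
#' interaction TSVs, the PPI TSV, the GMT collection, the lncRNA symbol
#' list and a ground-truth JSON, all reproducible byte-for-byte under a
#' fixed configuration.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(sim$expr, p("expression.tsv"))
  write_sample_metadata(sim$metadata, p("metadata.tsv"))
  write_interaction_table(sim$truth$lnc_mir, p("lncrna_mirna.tsv"))
  write_interaction_table(sim$truth$mir_mrna, p("mirna_mrna.tsv"))
  write_ppi_table(sim$truth$ppi, p("ppi.tsv"))
  write_gmt(sim$truth$gene_sets, p("gene_sets.gmt"))
  lnc <- sim$truth$annotation |> filter(.data$biotype == "lncRNA")
  readr::write_tsv(tibble("Approved symbol" = lnc$symbol), p("lncrna_list.tsv"),
                   progress = FALSE)
  gt <- list(
    planted_de = sim$truth$planted_de,
    planted_axes = sim$truth$planted_axes,
    covariate_genes = sim$truth$covariate_genes
  )
  jsonlite::write_json(gt, p("ground_truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
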
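norm_colname <- function(x) gsub("[^a-z0-9]", "", tolower(x))

require_columns <- function(df, wanted, path) {
  ## `wanted`: named list, name = internal column, value = vector of
  ## acceptable normalized header spellings
  nm <- norm_colname(names(df))
  idx <- vapply(wanted, function(alts) {
    hit <- which(nm %in% alts)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  missing <- names(wanted)[is.na(idx)]
  if (length(missing) > 0) {
    abort(sprintf("File '%s' is missing required column(s): %s",
                  path, toString(missing)))
  }
  out <- df[, idx]
  names(out) <- names(wanted)
  out
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers with gene symbols in the
#' first column. Duplicated gene symbols, non-numeric cells and (for
#' linear-scale files) non-positive values are format errors that name the
#' offending row and column; symbols are never silently collapsed.
#'
#' @param path Path to a tab-separated file.
#' @param scale Scale of the stored values, `"linear"` or `"log2"`.
#'
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(sprintf("File '%s' does not look like an expression matrix (need >= 1 gene and >= 1 sample).", path))
  }
  genes <- trimws(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene symbol(s) in '%s': %s",
                  path, toString(head(dup, 5))))
  }
  samples <- names(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric expression value '%s' at gene '%s', sample '%s' in '%s'.",
                    col[bad[1]], genes[bad[1]], samples[j], path))
    }
    vals[, j] <- num
  }
  if (scale == "linear" && any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Linear-scale file '%s' contains a non-positive value (%g) at gene '%s', sample '%s'; log2 would be undefined.",
                  path, vals[bad[1], bad[2]], genes[bad[1]], samples[bad[2]]))
  }
  expression_matrix(vals, scale = scale)
}

#' Read a demographic sample-metadata table
#'
#' Parses a table with the columns of a GEO-style demographic sheet
#' (sample, source name, age, gender, pH, post-mortem delay). The literal
#' string `"NA"` denotes a missing value. The diagnosis group is derived
#' from the source name: it must contain "schizophrenic" or "control"
#' (case-insensitive); anything else is a format error naming the sample.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `sample_id`, `source_name`, `group`,
#'   `age`, `gender` (`"male"`, `"female"` or `NA`), `ph`, `pmd_hours`.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE)
  df <- require_columns(df, list(
    sample_id   = c("sample", "sampleid", "gsm"),
    source_name = c("sourcename", "source"),
    age         = "age",
    gender      = c("gender", "sex"),
    ph          = "ph",
    pmd_hours   = c("postmortemdelayh", "postmortemdelay", "pmdhours", "pmd")
  ), path)

  miss <- function(x) ifelse(trimws(x) == "NA", NA_character_, trimws(x))
  df <- df |> mutate(across(everything(), miss))

  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate sample identifier(s) in '%s': %s",
                  path, toString(dup)))
  }

  src <- tolower(df$source_name)
  group <- dplyr::case_when(
    stringr::str_detect(src, "schizophrenic") ~ "schizophrenic",
    stringr::str_detect(src, "control") ~ "control",
    TRUE ~ NA_character_
  )
  if (anyNA(group)) {
    bad <- df$sample_id[which(is.na(group))[1]]
    abort(sprintf("Source name of sample '%s' in '%s' matches neither 'schizophrenic' nor 'control'.",
                  bad, path))
  }

  num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric %s value '%s' for sample '%s' in '%s'.",
                    what, x[bad[1]], df$sample_id[bad[1]], path))
    }
    out
  }
  age <- num(df$age, "age")
  if (any(!is.na(age) & age <= 0)) {
    bad <- df$sample_id[which(!is.na(age) & age <= 0)[1]]
    abort(sprintf("Non-positive age for sample '%s' in '%s'.", bad, path))
  }
  gender <- tolower(df$gender)
  bad_g <- which(!is.na(gender) & !gender %in% c("male", "female"))
  if (length(bad_g) > 0) {
    abort(sprintf("Unrecognized gender '%s' for sample '%s' in '%s'.",
                  df$gender[bad_g[1]], df$sample_id[bad_g[1]], path))
  }

  tibble(
    sample_id = df$sample_id,
    source_name = df$source_name,
    group = group,
    age = age,
    gender = gender,
    ph = num(df$ph, "pH"),
    pmd_hours = num(df$pmd_hours, "post-mortem delay")
  )
}

#' Read a list of lncRNA symbols
#'
#' Accepts either a headered TSV containing a column whose name mentions
#' "symbol" (an HGNC-style export) or a plain one-symbol-per-line file.
#' Symbols are whitespace-trimmed, deduplicated, and case is preserved.
#'
#' @param path Path to the symbol list.
#' @return A character vector of unique lncRNA symbols.
#' @export
read_lncrna_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) abort(sprintf("lncRNA list '%s' is empty.", path))
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sym_col <- which(grepl("symbol", first, ignore.case = TRUE))
  if (length(sym_col) > 0) {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    syms <- df[[sym_col[1]]]
  } else {
    syms <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  }
  syms <- unique(trimws(syms))
  syms <- syms[!is.na(syms) & syms != ""]
  if (length(syms) == 0) abort(sprintf("lncRNA list '%s' contains no symbols.", path))
  syms
}

#' Read an RNA interaction table
#'
#' Reads curated interaction exports of the two kinds the axis builder
#' consumes: lncRNA--miRNA pairs with a species and a confidence level
#' (DIANA-LncBase style), or miRNA--mRNA pairs with an evidence class
#' (miRTarBase style). Self-edges are format errors.
#'
#' @param path Path to a tab-separated file.
#' @param kind `"lncrna_mirna"` or `"mirna_mrna"`.
#' @return A tibble: for `"lncrna_mirna"` columns `lncrna`, `mirna`,
#'   `species`, `confidence`; for `"mirna_mrna"` columns `mirna`, `mrna`,
#'   `evidence`.
#' @export
read_interaction_table <- function(path, kind = c("lncrna_mirna", "mirna_mrna")) {
  if (length(kind) != 1 || !kind %in% c("lncrna_mirna", "mirna_mrna")) {
    kind <- tryCatch(match.arg(kind),
                     error = function(e) abort(
                       sprintf("Unknown interaction kind '%s'.", toString(kind))))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (kind == "lncrna_mirna") {
    out <- require_columns(df, list(
      lncrna = c("lncrna", "genename", "lncrnasymbol"),
      mirna = c("mirna", "mirnaname"),
      species = "species",
      confidence = c("confidence", "mirnaconfidencelevels", "confidencelevel")
    ), path)
    bad <- which(out$lncrna == out$mirna)
  } else {
    out <- require_columns(df, list(
      mirna = c("mirna", "mirnaname"),
      mrna = c("mrna", "target", "targetgene", "genesymbol"),
      evidence = c("evidence", "supporttype", "experimentalevidence")
    ), path)
    bad <- which(out$mirna == out$mrna)
  }
  if (length(bad) > 0) {
    abort(sprintf("Self-edge at row %d of '%s'.", bad[1], path))
  }
  out |> mutate(across(everything(), trimws)) |> distinct()
}

#' Read a protein-protein interaction table
#'
#' @param path Path to a TSV with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @param string_scale If `TRUE`, scores are STRING-dialect integers on
#'   0--999 and are divided by 1000; otherwise they must already lie in
#'   `[0, 1]`.
#' @return A tibble with columns `protein_a`, `protein_b`,
#'   `combined_score` (always on `[0, 1]`).
#' @export
read_ppi_table <- function(path, string_scale = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  out <- require_columns(df, list(
    protein_a = c("proteina", "protein1", "node1"),
    protein_b = c("proteinb", "protein2", "node2"),
    combined_score = c("combinedscore", "score")
  ), path)
  score <- suppressWarnings(as.numeric(out$combined_score))
  bad <- which(is.na(score))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric combined score '%s' at row %d of '%s'.",
                  out$combined_score[bad[1]], bad[1], path))
  }
  if (string_scale) score <- score / 1000
  if (any(score < 0 | score > 1)) {
    bad <- which(score < 0 | score > 1)[1]
    abort(sprintf("Combined score %g at row %d of '%s' is outside [0, 1].",
                  score[bad], bad, path))
  }
  self <- which(out$protein_a == out$protein_b)
  if (length(self) > 0) {
    abort(sprintf("Self-edge at row %d of '%s'.", self[1], path))
  }
  tibble(protein_a = trimws(out$protein_a),
         protein_b = trimws(out$protein_b),
         combined_score = score) |> distinct()
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene symbols. Lines with fewer than three
#' fields, duplicate set names and empty collections are format errors.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set_name`, `description`, and a list
#'   column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) abort(sprintf("GMT file '%s' is empty.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("Malformed GMT line %d in '%s' (fewer than 3 fields).",
                  short[1], path))
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene-set name(s) in '%s': %s", path, toString(dup)))
  }
  tibble(
    set_name = nm,
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  )
}
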
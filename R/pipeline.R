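#' Default pipeline configuration
#'
#' Returns the full configuration list used by [run_pipeline()], with
#' every threshold at its standard value: intensity filter `> 100` in at
#' least 25% of arrays, DE cut-offs `|log2FC| >= 0.5` and adjusted
#' p `< 0.001`, correlation gates `r > 0.5` and FDR `< 0.001`, PPI
#' combined score `>= 0.4`, and age/gender covariate adjustment. In
#' synthetic mode (`simulate = TRUE`, the default) the `sim` element is
#' passed to [simulation_config()].
#'
#' @return A named list of configuration values.
#' @export
cerna_default_config <- function() {
  list(
    simulate = TRUE,
    sim = list(),          # overrides for simulation_config()
    hard_decoys = FALSE,
    inputs = list(expr = NULL, expr_scale = "linear", meta = NULL,
                  lnc_list = NULL, lnc_mir = NULL, mir_mrna = NULL,
                  ppi = NULL, string_scale = FALSE, gmt = NULL),
    min_signal = 100, min_fraction = 0.25,
    covariates = c("age", "gender"),
    lfc_cut = 0.5, fdr_cut = 0.001, strict_lfc = FALSE, ordinary = FALSE,
    r_min = 0.5, corr_fdr_max = 0.001,
    ppi_min_score = 0.4,
    out = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stage <- function(name, timings, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  timings[[name]] <- proc.time()[["elapsed"]] - t0
  list(value = res, timings = timings)
}

#' Run the full ceRNA-axis discovery pipeline
#'
#' Orchestrates data acquisition (synthetic simulation or reading user
#' files), preprocessing (quantile normalization, intensity filter, log2,
#' IQR filter, covariate adjustment), moderated differential expression
#' with BH control, lncRNA/mRNA partitioning, interaction filtering,
#' candidate-triple construction, Pearson co-expression gating, PPI
#' overlay and pathway over-representation, and returns a run report. In
#' synthetic mode the report also scores recovery of the planted axes
#' (sensitivity and decoy count).
#'
#' @param config A configuration list (see [cerna_default_config()]; only
#'   overrides need to be supplied) or the path to a YAML file with the
#'   same structure.
#' @return A `cerna_run` object: a list with the resolved `config`,
#'   per-stage `counts`, filter reports, the DE table, candidate triples,
#'   correlations, axes, PPI overlay, enrichment table, ground truth and
#'   `recovery` scores (synthetic mode), per-stage `timings` and the
#'   package `version`. Has [tidy()] and [glance()] methods.
#' @export
#'
#' @examples
#' cfg <- list(sim = list(n_case = 8, n_control = 8, n_genes = 150,
#'                        n_lncrna = 10, n_mirna = 6, n_axes = 2, seed = 7))
#' run <- run_pipeline(cfg)
#' glance(run)
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("Configuration file '%s' does not exist.", config))
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(cerna_default_config(), config)
  timings <- list()

  ## ---- acquire ----
  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(simulation_config, cfg$sim)
    st <- stage("simulate", timings, simulate_study(sim_cfg, hard_decoys = isTRUE(cfg$hard_decoys)))
    timings <- st$timings
    sim <- st$value
    expr <- sim$expr; meta <- sim$metadata; truth <- sim$truth
    lnc_symbols <- truth$annotation$symbol[truth$annotation$biotype == "lncRNA"]
    lnc_mir_raw <- truth$lnc_mir; mir_mrna_raw <- truth$mir_mrna
    ppi_raw <- truth$ppi; gene_sets <- truth$gene_sets
  } else {
    inp <- cfg$inputs
    needed <- c("expr", "meta", "lnc_list", "lnc_mir", "mir_mrna", "ppi", "gmt")
    paths <- unlist(inp[needed])
    if (length(paths) < length(needed) || any(!nzchar(paths))) {
      abort("Real-data mode requires paths for: expr, meta, lnc_list, lnc_mir, mir_mrna, ppi, gmt.")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(sprintf("Input file(s) not found: %s", toString(missing)))
    }
    st <- stage("read", timings, {
      list(expr = read_expression_matrix(inp$expr, scale = inp$expr_scale),
           meta = read_sample_metadata(inp$meta),
           lnc = read_lncrna_list(inp$lnc_list),
           lnc_mir = read_interaction_table(inp$lnc_mir, "lncrna_mirna"),
           mir_mrna = read_interaction_table(inp$mir_mrna, "mirna_mrna"),
           ppi = read_ppi_table(inp$ppi, string_scale = isTRUE(inp$string_scale)),
           gmt = read_gmt(inp$gmt))
    })
    timings <- st$timings
    expr <- st$value$expr; meta <- st$value$meta
    lnc_symbols <- st$value$lnc
    lnc_mir_raw <- st$value$lnc_mir; mir_mrna_raw <- st$value$mir_mrna
    ppi_raw <- st$value$ppi; gene_sets <- st$value$gmt
    truth <- NULL
  }
  if (!all(sample_ids(expr) %in% meta$sample_id)) {
    abort("Expression samples and metadata sample IDs are inconsistent.")
  }

  ## ---- preprocess ----
  st <- stage("preprocess", timings,
              preprocess_expression(expr, meta,
                                    min_signal = cfg$min_signal,
                                    min_fraction = cfg$min_fraction,
                                    covariates = cfg$covariates))
  timings <- st$timings
  prep <- st$value

  ## ---- differential expression ----
  st <- stage("diffexpr", timings, {
    de <- moderated_t_test(prep$expr, meta, ordinary = isTRUE(cfg$ordinary))
    de <- call_degs(de, lfc_cut = cfg$lfc_cut, fdr_cut = cfg$fdr_cut,
                    strict_lfc = isTRUE(cfg$strict_lfc))
    parts <- partition_lnc_mrna(de, lnc_symbols)
    list(de = de, parts = parts)
  })
  timings <- st$timings
  de <- st$value$de
  delncrna <- st$value$parts$delncrna
  demrna <- st$value$parts$demrna

  ## ---- axis construction ----
  st <- stage("axes", timings, {
    lnc_mir <- filter_interactions(lnc_mir_raw, "lncrna_mirna")
    mir_mrna <- filter_interactions(mir_mrna_raw, "mirna_mrna")
    triples <- build_candidate_triples(delncrna$symbol, demrna$symbol,
                                       lnc_mir, mir_mrna)
    correlations <- if (nrow(triples) > 0) {
      correlate_pairs(prep$expr, triples |> distinct(.data$lncrna, .data$mrna))
    } else {
      tibble(lncrna = character(), mrna = character(), r = numeric(),
             p_value = numeric(), corr_fdr = numeric(), n = integer())
    }
    axes <- assemble_axes(triples, de, correlations,
                          r_min = cfg$r_min, fdr_max = cfg$corr_fdr_max)
    ppi_edges <- overlay_ppi(axes, ppi_raw, min_score = cfg$ppi_min_score)
    list(triples = triples, correlations = correlations, axes = axes,
         ppi_edges = ppi_edges)
  })
  timings <- st$timings
  ax <- st$value

  ## ---- enrichment ----
  st <- stage("enrichment", timings, {
    query <- unique(ax$axes$mrna)
    if (length(query) == 0) {
      tibble(set_name = character(), overlap_k = integer(),
             set_size_K = integer(), query_n = integer(),
             universe_N = integer(), p_value = numeric(), adj_p = numeric(),
             overlap_genes = list())
    } else {
      enrich(query, gene_sets, universe = gene_ids(prep$expr))
    }
  })
  timings <- st$timings
  enrichment <- st$value

  recovery <- NULL
  if (!is.null(truth)) {
    planted <- truth$planted_axes |> select("lncrna", "mirna", "mrna")
    emitted <- ax$axes |> select("lncrna", "mirna", "mrna")
    recovered <- dplyr::semi_join(planted, emitted,
                                  by = c("lncrna", "mirna", "mrna"))
    decoys <- dplyr::anti_join(emitted, planted,
                               by = c("lncrna", "mirna", "mrna"))
    recovery <- list(
      sensitivity = if (nrow(planted) > 0) nrow(recovered) / nrow(planted) else NA_real_,
      n_recovered = nrow(recovered),
      n_planted = nrow(planted),
      n_decoy = nrow(decoys),
      decoys = decoys
    )
  }

  counts <- list(
    n_samples = ncol(expr$values),
    n_genes_input = prep$reports$intensity$n_input,
    n_after_intensity = prep$reports$intensity$n_kept,
    n_after_iqr = prep$reports$iqr$n_kept,
    median_iqr = prep$reports$iqr$median_iqr,
    n_de = sum(de$status != "not_de"),
    n_delncrna = nrow(delncrna),
    n_demrna = nrow(demrna),
    n_triples = nrow(ax$triples),
    n_axes = nrow(ax$axes),
    n_axis_lncrna = dplyr::n_distinct(ax$axes$lncrna),
    n_axis_mirna = dplyr::n_distinct(ax$axes$mirna),
    n_axis_mrna = dplyr::n_distinct(ax$axes$mrna),
    n_ppi_edges = nrow(ax$ppi_edges),
    n_enriched_sets = sum(enrichment$adj_p < 0.05)
  )

  run <- structure(list(
    config = cfg, counts = counts, filter_reports = prep$reports,
    moderation = glance(attr(de, "moderation_fit")),
    expr = prep$expr, de = de, delncrna = delncrna, demrna = demrna,
    triples = ax$triples, correlations = ax$correlations, axes = ax$axes,
    ppi_edges = ax$ppi_edges, enrichment = enrichment,
    truth = truth, recovery = recovery,
    timings = timings,
    version = as.character(utils::packageVersion("cernaxes"))
  ), class = "cerna_run")

  if (!is.null(cfg$out)) write_run(run, cfg$out)
  run
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(run$expr, p("expression_preprocessed.tsv"))
  readr::write_tsv(run$de, p("de_table.tsv"), progress = FALSE)
  readr::write_tsv(run$axes, p("axes.tsv"), progress = FALSE)
  readr::write_tsv(run$correlations, p("correlations.tsv"), progress = FALSE)
  readr::write_tsv(run$enrichment |> mutate(
    overlap_genes = vapply(.data$overlap_genes, paste, character(1),
                           collapse = ";")),
    p("enrichment.tsv"), progress = FALSE)
  write_network(run$axes, run$ppi_edges, p("network"), de = run$de)
  report <- list(config = run$config[setdiff(names(run$config), "out")],
                 counts = run$counts,
                 moderation = run$moderation,
                 recovery = run$recovery[c("sensitivity", "n_recovered",
                                           "n_planted", "n_decoy")],
                 version = run$version,
                 wall_time = run$timings)
  jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.cerna_run <- function(x, ...) {
  c0 <- x$counts
  cat("<cerna_run>\n")
  cat(sprintf("  samples: %d | genes: %d -> %d (intensity) -> %d (IQR)\n",
              c0$n_samples, c0$n_genes_input, c0$n_after_intensity,
              c0$n_after_iqr))
  cat(sprintf("  DE genes: %d (%d lncRNA, %d mRNA)\n",
              c0$n_de, c0$n_delncrna, c0$n_demrna))
  cat(sprintf("  candidate triples: %d | ceRNA axes: %d (%d lncRNA / %d miRNA / %d mRNA)\n",
              c0$n_triples, c0$n_axes, c0$n_axis_lncrna, c0$n_axis_mirna,
              c0$n_axis_mrna))
  cat(sprintf("  PPI overlay edges: %d | enriched sets (adj p < 0.05): %d\n",
              c0$n_ppi_edges, c0$n_enriched_sets))
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-axis recovery: %d/%d (sensitivity %s), decoys: %d\n",
                x$recovery$n_recovered, x$recovery$n_planted,
                format(x$recovery$sensitivity, digits = 3),
                x$recovery$n_decoy))
  }
  invisible(x)
}

#' Tidy and glance methods for pipeline runs
#'
#' @param x A `cerna_run` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: a tibble of per-stage counts (`stat`, `value`);
#'   `glance()`: a one-row tibble with the headline counts and, in
#'   synthetic mode, planted-axis `sensitivity` and `n_decoy`.
#' @method tidy cerna_run
#' @export
tidy.cerna_run <- function(x, ...) {
  tibble(stat = names(x$counts), value = as.numeric(unlist(x$counts)))
}

#' @rdname tidy.cerna_run
#' @method glance cerna_run
#' @export
glance.cerna_run <- function(x, ...) {
  out <- tibble(
    n_samples = x$counts$n_samples,
    n_genes_tested = x$counts$n_after_iqr,
    n_delncrna = x$counts$n_delncrna,
    n_demrna = x$counts$n_demrna,
    n_triples = x$counts$n_triples,
    n_axes = x$counts$n_axes,
    n_ppi_edges = x$counts$n_ppi_edges
  )
  if (!is.null(x$recovery)) {
    out$sensitivity <- x$recovery$sensitivity
    out$n_decoy <- x$recovery$n_decoy
  }
  out
}
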
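#' Configuration for a synthetic ceRNA study
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' describe a two-group post-mortem brain cohort of 25 cases and 25
#' controls profiled over 2000 background mRNAs and 60 lncRNAs, with ten
#' planted lncRNA--miRNA--mRNA axes whose lncRNA and mRNA share a latent
#' per-sample factor (inducing positive Pearson co-expression) and are both
#' differentially expressed with effect `de_log2fc` in the same direction.
#'
#' @param n_case,n_control Number of case (schizophrenic) and control
#'   samples; both at least 2.
#' @param n_genes Number of protein-coding (mRNA) genes.
#' @param n_lncrna Number of lncRNA genes.
#' @param n_mirna Number of miRNA identifiers available for axes; miRNAs
#'   are not measured on the array, they only appear in interaction tables.
#' @param n_axes Number of planted lncRNA--miRNA--mRNA axes; must not
#'   exceed `min(n_lncrna, n_mirna, n_genes)`.
#' @param de_log2fc Planted group effect: the expected case-minus-control
#'   difference in log2 units for every planted DE gene.
#' @param axis_latent_sd Standard deviation (log2 units) of the per-sample
#'   latent factor shared by each axis's lncRNA and mRNA; 0 disables the
#'   shared factor.
#' @param noise_sd Residual Gaussian noise standard deviation (log2 units);
#'   must be positive.
#' @param baseline_log2_mean Mean baseline log2 intensity of background
#'   genes.
#' @param age_effect Slope in log2 units per year of (centered) age for
#'   covariate-affected genes.
#' @param gender_effect Additive log2 offset between genders for
#'   covariate-affected genes (applied to a centered male indicator).
#' @param frac_covariate_genes Fraction of genes (in `[0, 1]`) that carry
#'   the age and gender effects.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   every generated object exactly.
#'
#' @return A `simulation_config` object (a validated named list).
#' @export
#'
#' @examples
#' cfg <- simulation_config(n_case = 5, n_control = 5, n_genes = 50,
#'                          n_lncrna = 6, n_mirna = 4, n_axes = 2, seed = 1)
#' cfg$n_axes
simulation_config <- function(n_case = 25, n_control = 25,
                              n_genes = 2000, n_lncrna = 60, n_mirna = 30,
                              n_axes = 10,
                              de_log2fc = 1.0, axis_latent_sd = 1.0,
                              noise_sd = 0.3, baseline_log2_mean = 8,
                              age_effect = 0.02, gender_effect = 0.5,
                              frac_covariate_genes = 0.1,
                              seed = 1L) {
  counts <- c(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_lncrna = n_lncrna, n_mirna = n_mirna)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (length(v) != 1 || !is.finite(v) || v <= 0 || v != round(v)) {
      abort(sprintf("`%s` must be a positive integer (got %s).", nm, format(v)))
    }
  }
  if (length(n_axes) != 1 || !is.finite(n_axes) || n_axes < 0 ||
      n_axes != round(n_axes)) {
    abort("`n_axes` must be a non-negative integer.")
  }
  if (n_axes > min(n_lncrna, n_mirna, n_genes)) {
    abort("`n_axes` may not exceed min(n_lncrna, n_mirna, n_genes).")
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (!is.finite(axis_latent_sd) || axis_latent_sd < 0) {
    abort("`axis_latent_sd` must be >= 0.")
  }
  if (!is.finite(frac_covariate_genes) || frac_covariate_genes < 0 ||
      frac_covariate_genes > 1) {
    abort("`frac_covariate_genes` must lie in [0, 1].")
  }
  if (!is.finite(seed) || seed != round(seed)) abort("`seed` must be an integer.")
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_genes = as.integer(n_genes), n_lncrna = as.integer(n_lncrna),
    n_mirna = as.integer(n_mirna), n_axes = as.integer(n_axes),
    de_log2fc = de_log2fc, axis_latent_sd = axis_latent_sd,
    noise_sd = noise_sd, baseline_log2_mean = baseline_log2_mean,
    age_effect = age_effect, gender_effect = gender_effect,
    frac_covariate_genes = frac_covariate_genes, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate cohort sample metadata
#'
#' Draws a demographic table shaped like a post-mortem brain study: one row
#' per sample with source name (which encodes the diagnosis), age in years
#' uniform over 25--97, gender with equal probability, tissue pH and
#' post-mortem delay from plausible uniform ranges.
#'
#' @param n_case,n_control Group sizes, each at least 2.
#' @param seed Integer seed; identical arguments reproduce the table.
#'
#' @return A tibble with columns `sample_id`, `source_name`, `group`
#'   (`"schizophrenic"` or `"control"`), `age`, `gender`, `ph`,
#'   `pmd_hours`.
#' @export
#'
#' @examples
#' generate_cohort_metadata(3, 2, seed = 1)
generate_cohort_metadata <- function(n_case, n_control, seed = 1L) {
  for (nm in c("n_case", "n_control")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 2 || v != round(v)) {
      abort(sprintf("`%s` must be an integer >= 2.", nm))
    }
  }
  n <- n_case + n_control
  set.seed(seed)
  group <- c(rep("schizophrenic", n_case), rep("control", n_control))
  tibble(
    sample_id   = sprintf("SAMP%03d", seq_len(n)),
    source_name = paste("Synthetic brain post-mortem", group),
    group       = group,
    age         = round(runif(n, 25, 97)),
    gender      = ifelse(rbinom(n, 1, 0.5) == 1, "male", "female"),
    ph          = round(runif(n, 5.7, 6.9), 1),
    pmd_hours   = round(runif(n, 3, 30), 1)
  )
}

#' Generate planted ground truth and matching annotation tables
#'
#' Plants `n_axes` lncRNA--miRNA--mRNA axes with alternating up/down
#' directions and emits everything downstream stages consume: a gene
#' annotation (symbol, biotype), lncRNA--miRNA and miRNA--mRNA interaction
#' tables containing every planted edge plus decoy edges, a PPI table
#' linking planted-axis mRNAs above the medium-confidence score plus random
#' decoy edges, and a gene-set collection in which exactly one set is
#' stacked with the planted-axis mRNAs.
#'
#' Decoy interaction edges touch only non-planted (hence non-DE) genes, so
#' the planted axes are the unique expected pipeline output; with
#' `hard_decoys = TRUE` additional cross-axis edges pair DE genes that do
#' not share a latent factor, exercising the correlation gate.
#'
#' @param config A [simulation_config()].
#' @param hard_decoys Also plant decoy triples over DE genes from
#'   different axes (default `FALSE`).
#'
#' @return A `cerna_ground_truth` object: list with `planted_de`,
#'   `planted_axes`, `covariate_genes`, `annotation`, `lnc_mir`,
#'   `mir_mrna`, `ppi`, `gene_sets`.
#' @export
generate_ground_truth <- function(config, hard_decoys = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  mrna <- sprintf("GENE%04d", seq_len(config$n_genes))
  lnc  <- sprintf("LNC%03d", seq_len(config$n_lncrna))
  mir  <- sprintf("sim-miR-%d-5p", seq_len(config$n_mirna))
  annotation <- bind_rows(
    tibble(symbol = mrna, biotype = "mRNA"),
    tibble(symbol = lnc, biotype = "lncRNA")
  )

  k <- config$n_axes
  if (k > 0) {
    planted_axes <- tibble(
      lncrna = lnc[seq_len(k)],
      mirna  = mir[seq_len(k)],
      mrna   = mrna[seq_len(k)],
      direction = rep(c("up", "down"), length.out = k)
    )
    planted_de <- bind_rows(
      tibble(symbol = planted_axes$lncrna, direction = planted_axes$direction),
      tibble(symbol = planted_axes$mrna, direction = planted_axes$direction)
    ) |> distinct()
  } else {
    planted_axes <- tibble(lncrna = character(), mirna = character(),
                           mrna = character(), direction = character())
    planted_de <- tibble(symbol = character(), direction = character())
  }

  background_mrna <- setdiff(mrna, planted_de$symbol)
  background_lnc <- setdiff(lnc, planted_de$symbol)
  n_cov <- floor(config$frac_covariate_genes * (config$n_genes + config$n_lncrna))
  cov_pool <- c(background_mrna, background_lnc)
  covariate_genes <- sort(sample(cov_pool, min(n_cov, length(cov_pool))))

  ## interaction tables: planted edges + decoys among non-DE genes, plus
  ## low-confidence / non-human rows that the evidence filters must drop
  n_decoy <- min(30L, length(background_lnc), length(background_mrna))
  decoy_lnc <- sample(background_lnc, n_decoy, replace = TRUE)
  decoy_mir <- sample(mir, n_decoy, replace = TRUE)
  decoy_mrna <- sample(background_mrna, n_decoy, replace = TRUE)

  lnc_mir <- bind_rows(
    tibble(lncrna = planted_axes$lncrna, mirna = planted_axes$mirna,
           species = "Homo sapiens", confidence = "high"),
    tibble(lncrna = decoy_lnc, mirna = decoy_mir,
           species = "Homo sapiens", confidence = "high"),
    tibble(lncrna = sample(lnc, 5, replace = TRUE),
           mirna = sample(mir, 5, replace = TRUE),
           species = "Homo sapiens", confidence = "low"),
    tibble(lncrna = sample(lnc, 5, replace = TRUE),
           mirna = sample(mir, 5, replace = TRUE),
           species = "Mus musculus", confidence = "high")
  ) |> distinct()

  mir_mrna <- bind_rows(
    tibble(mirna = planted_axes$mirna, mrna = planted_axes$mrna,
           evidence = "strong"),
    tibble(mirna = decoy_mir, mrna = decoy_mrna, evidence = "strong"),
    tibble(mirna = sample(mir, 5, replace = TRUE),
           mrna = sample(background_mrna, 5, replace = TRUE),
           evidence = "weak")
  ) |> distinct()

  if (hard_decoys && k >= 2) {
    ## cross-axis triples: DE lncRNA of axis i paired (via a fresh edge)
    ## with the DE mRNA of axis j != i; no shared latent factor, so these
    ## must fall to the correlation gate, not the DE gate
    shift <- c(seq_len(k)[-1], 1L)
    lnc_mir <- bind_rows(lnc_mir, tibble(
      lncrna = planted_axes$lncrna, mirna = planted_axes$mirna[shift],
      species = "Homo sapiens", confidence = "high")) |> distinct()
    mir_mrna <- bind_rows(mir_mrna, tibble(
      mirna = planted_axes$mirna[shift], mrna = planted_axes$mrna[shift],
      evidence = "strong")) |> distinct()
  }

  ## PPI: ring over axis mRNAs at high confidence + random decoys
  if (k >= 2) {
    nxt <- c(seq_len(k)[-1], 1L)
    ppi_axis <- tibble(
      protein_a = planted_axes$mrna,
      protein_b = planted_axes$mrna[nxt],
      combined_score = round(runif(k, 0.5, 0.95), 3)
    ) |> filter(.data$protein_a != .data$protein_b)
  } else {
    ppi_axis <- tibble(protein_a = character(), protein_b = character(),
                       combined_score = numeric())
  }
  n_ppi_decoy <- min(40L, length(background_mrna) %/% 2L)
  ppi_decoy <- tibble(
    protein_a = sample(background_mrna, n_ppi_decoy),
    protein_b = sample(background_mrna, n_ppi_decoy),
    combined_score = round(runif(n_ppi_decoy, 0.05, 0.95), 3)
  ) |> filter(.data$protein_a != .data$protein_b)
  ppi <- bind_rows(ppi_axis, ppi_decoy) |> distinct()

  ## gene sets: one stacked with the planted-axis mRNAs, the rest background
  n_decoy_sets <- 9L
  decoy_sets <- purrr::map(seq_len(n_decoy_sets), function(i) {
    sort(sample(background_mrna, min(15L, length(background_mrna))))
  })
  planted_members <- sort(unique(c(
    planted_axes$mrna,
    sample(background_mrna, min(5L, length(background_mrna)))
  )))
  gene_sets <- tibble(
    set_name = c("Planted axis signaling pathway",
                 sprintf("Background pathway %02d", seq_len(n_decoy_sets))),
    description = c("set stacked with planted-axis mRNAs",
                    rep("random background set", n_decoy_sets)),
    genes = c(list(planted_members), decoy_sets)
  )

  structure(list(
    planted_de = planted_de,
    planted_axes = planted_axes,
    covariate_genes = covariate_genes,
    annotation = annotation,
    lnc_mir = lnc_mir,
    mir_mrna = mir_mrna,
    ppi = ppi,
    gene_sets = gene_sets
  ), class = "cerna_ground_truth")
}

#' @export
print.cerna_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<cerna_ground_truth> %d planted axes, %d planted DE genes, ",
                     "%d annotated genes, %d covariate genes\n"),
              nrow(x$planted_axes), nrow(x$planted_de),
              nrow(x$annotation), length(x$covariate_genes)))
  invisible(x)
}

#' Generate a linear-scale expression matrix from planted ground truth
#'
#' The log2-scale signal of gene g in sample s is the sum of a gene
#' baseline, a group effect of `+/- de_log2fc` for planted DE genes (sign
#' by planted direction, applied to case samples), a per-axis latent factor
#' shared by that axis's lncRNA and mRNA (per-sample draws with sd
#' `axis_latent_sd`), centered age and gender effects for covariate genes,
#' and Gaussian noise with sd `noise_sd`. The returned matrix is
#' `2^signal`, i.e. strictly positive linear-scale intensities.
#'
#' Background gene baselines are drawn from N(`baseline_log2_mean`, 1.5) so
#' that the intensity filter has genuine work to do; planted genes are
#' drawn from N(`baseline_log2_mean` + 1, 0.5), i.e. they are
#' well-expressed transcripts.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param metadata A [generate_cohort_metadata()] result consistent with
#'   `config` (`n_case + n_control` rows).
#' @param config The [simulation_config()] used to build `truth`.
#'
#' @return A linear-scale [expression_matrix()] over all annotated genes.
#' @export
generate_expression <- function(truth, metadata, config) {
  stopifnot(inherits(truth, "cerna_ground_truth"),
            inherits(config, "simulation_config"))
  if (nrow(metadata) != config$n_case + config$n_control) {
    abort("`metadata` row count does not match `config` group sizes.")
  }
  if (!all(truth$planted_de$symbol %in% truth$annotation$symbol)) {
    abort("Ground truth references symbols missing from its annotation.")
  }
  set.seed(config$seed + 2L)
  genes <- truth$annotation$symbol
  n_g <- length(genes)
  n_s <- nrow(metadata)

  planted <- truth$planted_de$symbol
  is_planted <- genes %in% planted
  baseline <- rnorm(n_g, config$baseline_log2_mean, 1.5)
  baseline[is_planted] <- rnorm(sum(is_planted), config$baseline_log2_mean + 1, 0.5)

  signal <- matrix(baseline, n_g, n_s,
                   dimnames = list(genes, metadata$sample_id))

  case <- as.numeric(metadata$group == "schizophrenic")
  if (nrow(truth$planted_de) > 0) {
    sgn <- ifelse(truth$planted_de$direction == "up", 1, -1)
    idx <- match(truth$planted_de$symbol, genes)
    signal[idx, ] <- signal[idx, ] +
      (sgn * config$de_log2fc) %o% case
  }

  if (nrow(truth$planted_axes) > 0 && config$axis_latent_sd > 0) {
    for (a in seq_len(nrow(truth$planted_axes))) {
      z <- rnorm(n_s, 0, config$axis_latent_sd)
      rows <- match(c(truth$planted_axes$lncrna[a], truth$planted_axes$mrna[a]),
                    genes)
      signal[rows, ] <- sweep(signal[rows, , drop = FALSE], 2, z, `+`)
    }
  }

  if (length(truth$covariate_genes) > 0) {
    age_c <- metadata$age - mean(metadata$age)
    male_c <- as.numeric(metadata$gender == "male")
    male_c <- male_c - mean(male_c)
    cov_effect <- config$age_effect * age_c + config$gender_effect * male_c
    rows <- match(truth$covariate_genes, genes)
    signal[rows, ] <- sweep(signal[rows, , drop = FALSE], 2, cov_effect, `+`)
  }

  signal <- signal + matrix(rnorm(n_g * n_s, 0, config$noise_sd), n_g, n_s)
  expression_matrix(2^signal, scale = "linear")
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_cohort_metadata()],
#' [generate_ground_truth()] and [generate_expression()] with one
#' configuration.
#'
#' @inheritParams generate_ground_truth
#' @return A list with `metadata`, `truth`, `expr` (linear-scale
#'   [expression_matrix()]), and the `config`.
#' @export
#'
#' @examples
#' cfg <- simulation_config(n_case = 4, n_control = 4, n_genes = 40,
#'                          n_lncrna = 6, n_mirna = 4, n_axes = 2, seed = 3)
#' sim <- simulate_study(cfg)
#' dim(sim$expr)
simulate_study <- function(config, hard_decoys = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  metadata <- generate_cohort_metadata(config$n_case, config$n_control,
                                       seed = config$seed)
  truth <- generate_ground_truth(config, hard_decoys = hard_decoys)
  expr <- generate_expression(truth, metadata, config)
  list(metadata = metadata, truth = truth, expr = expr, config = config)
}
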
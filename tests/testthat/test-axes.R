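test_that("interaction filtering enforces species and evidence rules", {
  lm <- tibble::tibble(
    lncrna = c("L1", "L1", "L2", "L3"),
    mirna = c("m1", "m1", "m2", "m3"),
    species = c("Homo sapiens", "Homo sapiens", "Mus musculus", "Homo sapiens"),
    confidence = c("high", "low", "high", "high")
  )
  out <- filter_interactions(lm, "lncrna_mirna")
  expect_equal(nrow(out), 2)                      # L1-m1 deduped, mouse dropped
  expect_setequal(paste(out$lncrna, out$mirna), c("L1 m1", "L3 m3"))

  mm <- tibble::tibble(
    mirna = c("m1", "m1", "m2"),
    mrna = c("G1", "G2", "G3"),
    evidence = c("strong", "weak", "strong")
  )
  out2 <- filter_interactions(mm, "mirna_mrna")
  expect_setequal(paste(out2$mirna, out2$mrna), c("m1 G1", "m2 G3"))
})

test_that("candidate triples match exhaustive enumeration", {
  lnc_mir <- tibble::tibble(lncrna = "L1", mirna = "m1")
  mir_mrna <- tibble::tibble(mirna = "m1", mrna = "G1")
  expect_equal(build_candidate_triples("L1", "G1", lnc_mir, mir_mrna),
               tibble::tibble(lncrna = "L1", mirna = "m1", mrna = "G1"))
  expect_equal(nrow(build_candidate_triples("L1", character(), lnc_mir,
                                            mir_mrna)), 0)

  lnc_mir2 <- tibble::tibble(lncrna = c("L1", "L1"), mirna = c("m1", "m2"))
  mir_mrna2 <- tibble::tibble(mirna = c("m1", "m1", "m2"),
                              mrna = c("G1", "G2", "G1"))
  out <- build_candidate_triples("L1", c("G1", "G2"), lnc_mir2, mir_mrna2)
  expect_equal(nrow(out), 3)

  ## brute-force oracle over random small instances
  set.seed(77)
  for (rep in 1:20) {
    lncs <- sprintf("L%d", 1:4); mirs <- sprintf("m%d", 1:4)
    mrnas <- sprintf("G%d", 1:6)
    lm <- tibble::tibble(
      lncrna = sample(lncs, 6, replace = TRUE),
      mirna = sample(mirs, 6, replace = TRUE)) |> dplyr::distinct()
    mm <- tibble::tibble(
      mirna = sample(mirs, 8, replace = TRUE),
      mrna = sample(mrnas, 8, replace = TRUE)) |> dplyr::distinct()
    delnc <- sample(lncs, 2); demrna <- sample(mrnas, 3)
    got <- build_candidate_triples(delnc, demrna, lm, mm)
    all_combos <- expand.grid(lncrna = lncs, mirna = mirs, mrna = mrnas,
                              stringsAsFactors = FALSE)
    want <- all_combos[
      all_combos$lncrna %in% delnc & all_combos$mrna %in% demrna &
        paste(all_combos$lncrna, all_combos$mirna) %in% paste(lm$lncrna, lm$mirna) &
        paste(all_combos$mirna, all_combos$mrna) %in% paste(mm$mirna, mm$mrna), ]
    expect_setequal(paste(got$lncrna, got$mirna, got$mrna),
                    paste(want$lncrna, want$mirna, want$mrna))
  }
})

test_that("pair correlation reproduces closed-form references", {
  n <- 51
  v <- vectors_with_cor(0.5, n, seed = 2)
  vals <- rbind(L1 = v$x, G1 = v$y, G2 = -v$x, G3 = v$x)
  colnames(vals) <- sprintf("s%02d", 1:n)
  x <- expression_matrix(vals, "log2")
  pairs <- tibble::tibble(lncrna = c("L1", "L1", "L1"),
                          mrna = c("G1", "G2", "G3"))
  out <- correlate_pairs(x, pairs)
  expect_equal(out$r[out$mrna == "G1"], 0.5, tolerance = 1e-10)
  ## two-sided p for r = 0.5 at n = 51: t = 0.5 * 7 / sqrt(0.75) on 49 df
  p_ref <- 2 * pt(-0.5 * sqrt(49) / sqrt(0.75), 49)
  expect_equal(out$p_value[out$mrna == "G1"], p_ref, tolerance = 1e-12)
  expect_equal(p_ref, 1.8e-4, tolerance = 0.05)
  expect_equal(out$r[out$mrna == "G2"], -1, tolerance = 1e-10)
  expect_equal(out$r[out$mrna == "G3"], 1, tolerance = 1e-10)
  expect_equal(out$p_value[out$mrna == "G3"], 0)

  ## zero-variance gene: pair dropped with a warning
  vals2 <- rbind(vals, FLAT = rep(1, n))
  x2 <- expression_matrix(vals2, "log2")
  expect_warning(
    out2 <- correlate_pairs(x2, tibble::tibble(lncrna = c("L1", "L1"),
                                               mrna = c("G1", "FLAT"))),
    "zero-variance")
  expect_equal(nrow(out2), 1)

  expect_error(correlate_pairs(x, tibble::tibble(lncrna = "L1", mrna = "NOPE")),
               "NOPE")
})

test_that("axis assembly applies all three gates", {
  triples <- tibble::tibble(
    lncrna = c("L1", "L2", "L3", "L4"),
    mirna = c("m1", "m2", "m3", "m4"),
    mrna = c("G1", "G2", "G3", "G4")
  )
  de <- tibble::tibble(
    symbol = c("L1", "L2", "L3", "L4", "G1", "G2", "G3", "G4"),
    log2fc = c(1, 1, 1, 1, 1, 1, -1, 1),
    adj_p = rep(1e-6, 8),
    status = c("up", "up", "up", "up", "up", "up", "down", "up")
  )
  correlations <- tibble::tibble(
    lncrna = c("L1", "L2", "L3", "L4"),
    mrna = c("G1", "G2", "G3", "G4"),
    r = c(0.9, 0.6, -0.8, 0.6),
    p_value = c(1e-8, 1e-3, 1e-7, 1e-8),
    corr_fdr = c(1e-5, 0.01, 1e-5, 1e-5),
    n = 50L
  )
  axes <- assemble_axes(triples, de, correlations)
  ## L2 fails the FDR gate, L3 has an opposing pattern (and negative r)
  expect_equal(axes$lncrna, c("L1", "L4"))
  expect_equal(axes$direction, c("up", "up"))

  expect_error(assemble_axes(triples, de, correlations[-1, ]),
               "No correlation record")

  summ <- axis_summary(axes)
  expect_equal(summ$n_axes, 2)
  expect_equal(summ$n_lncrna, 2)
})

test_that("boundary values of the correlation gates are exclusive", {
  triples <- tibble::tibble(lncrna = c("L1", "L2"), mirna = c("m1", "m2"),
                            mrna = c("G1", "G2"))
  de <- tibble::tibble(symbol = c("L1", "L2", "G1", "G2"),
                       log2fc = 1, adj_p = 1e-6, status = "up")
  correlations <- tibble::tibble(
    lncrna = c("L1", "L2"), mrna = c("G1", "G2"),
    r = c(0.5, 0.51), p_value = c(1e-6, 1e-6),
    corr_fdr = c(1e-6, 0.001), n = 50L)
  ## r = 0.5 exactly fails r > 0.5; corr_fdr = 0.001 exactly fails < 0.001
  expect_equal(nrow(assemble_axes(triples, de, correlations)), 0)
})

test_that("PPI overlay keeps medium-confidence edges between axis mRNAs", {
  axes <- tibble::tibble(lncrna = "L1", mirna = "m1",
                         mrna = c("EGR1", "TGFB2", "DUSP6"),
                         direction = "up", r = 0.9, corr_fdr = 1e-6,
                         log2fc_lncrna = 1, log2fc_mrna = 1)
  ppi <- tibble::tibble(
    protein_a = c("EGR1", "EGR1", "EGR1", "TGFB2", "DUSP6"),
    protein_b = c("TGFB2", "DUSP6", "CD93", "EGR1", "DUSP6"),
    combined_score = c(0.45, 0.39, 0.9, 0.45, 0.8)
  )
  ## self-edge DUSP6-DUSP6 dropped, 0.39 below threshold, CD93 not in axes,
  ## TGFB2-EGR1 is the duplicate of EGR1-TGFB2
  out <- overlay_ppi(axes, ppi, min_score = 0.4)
  expect_equal(nrow(out), 1)
  expect_setequal(c(out$protein_a, out$protein_b), c("EGR1", "TGFB2"))
  expect_equal(out$combined_score, 0.45)

  out2 <- overlay_ppi(axes, ppi, min_score = 0.46)
  expect_equal(nrow(out2), 0)
})

test_that("emitted axes re-validate against raw inputs end to end", {
  ## latent factor disabled so planted genes are detectable at these sizes;
  ## the group effect itself induces the positive co-expression
  run <- run_pipeline(list(sim = list(n_case = 25, n_control = 25,
                                      n_genes = 300, n_lncrna = 20,
                                      n_mirna = 10, n_axes = 5,
                                      axis_latent_sd = 0, seed = 19)))
  expect_gt(nrow(run$axes), 0)
  lv <- run$expr$values
  for (i in seq_len(nrow(run$axes))) {
    ax <- run$axes[i, ]
    r_raw <- cor(lv[ax$lncrna, ], lv[ax$mrna, ])
    expect_gt(r_raw, 0.5)
    de_l <- run$de[run$de$symbol == ax$lncrna, ]
    de_g <- run$de[run$de$symbol == ax$mrna, ]
    expect_true(de_l$status == de_g$status)
    expect_true(abs(de_l$log2fc) >= 0.5 && de_l$adj_p < 0.001)
    expect_true(abs(de_g$log2fc) >= 0.5 && de_g$adj_p < 0.001)
    expect_equal(ax$corr_fdr < 0.001, TRUE)
  }
})
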
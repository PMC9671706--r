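test_that("moderation fit recovers known hyperparameters and limits", {
  ## parameter recovery: gene variances from a scaled-inverse-chi-square
  ## prior (d0 = 4, s0^2 = 0.04) observed through chi-square sampling noise
  ests <- sapply(1:3, function(s) {
    set.seed(s)
    sigma2 <- 0.04 * 4 / rchisq(5000, 4)
    v <- sigma2 * rchisq(5000, 48) / 48
    f <- fit_moderation(v, 48)
    c(f$d0, f$s0_sq)
  })
  d0_hat <- mean(ests[1, ]); s0_hat <- mean(ests[2, ])
  expect_gt(d0_hat, 2.5)
  expect_lt(d0_hat, 6.5)
  expect_lt(abs(s0_hat - 0.04) / 0.04, 0.25)

  ## identical variances carry no dispersion: d0 = Inf, and the prior
  ## variance is exp(mean(e)), i.e. the common variance with the
  ## chi-square log-bias correction exp(log(d/2) - digamma(d/2))
  f <- fit_moderation(rep(0.25, 50), 10)
  expect_true(is.infinite(f$d0))
  expect_equal(f$s0_sq, 0.25 * exp(log(5) - digamma(5)), tolerance = 1e-12)

  expect_error(fit_moderation(runif(5), 10), "at least 10")
  expect_warning(fit_moderation(c(rep(0.2, 12), 0), 10), "excluded")

  g <- glance(f)
  expect_equal(g$d0, Inf)
  expect_equal(tidy(f)$term, c("d0", "s0_sq"))
})

test_that("moderation fit agrees with an independent empirical-Bayes oracle", {
  set.seed(8)
  sigma2 <- 0.05 * 6 / rchisq(3000, 6)
  v <- sigma2 * rchisq(3000, 30) / 30
  mine <- fit_moderation(v, 30)
  sq <- limma::squeezeVar(v, df = 30)
  expect_equal(mine$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mine$s0_sq, sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t reduces to the classical Student t when d0 = 0", {
  set.seed(13)
  meta <- plain_meta(6, 5)
  vals <- matrix(rnorm(40 * 11, 8, 1), 40, 11,
                 dimnames = list(sprintf("G%02d", 1:40), meta$sample_id))
  x <- expression_matrix(vals, "log2")
  de <- moderated_t_test(x, meta, ordinary = TRUE)
  grp <- meta$group == "schizophrenic"
  for (i in c(1, 7, 25, 40)) {
    tt <- t.test(vals[i, grp], vals[i, !grp], var.equal = TRUE)
    expect_equal(de$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("d0 = Inf gives constant posterior variance and |log2fc| ordering", {
  set.seed(14)
  meta <- plain_meta(5, 5)
  vals <- matrix(rnorm(30 * 10, 8, 0.5), 30, 10,
                 dimnames = list(sprintf("G%02d", 1:30), meta$sample_id))
  x <- expression_matrix(vals, "log2")
  fit <- structure(list(d0 = Inf, s0_sq = 0.25, residual_df = 8, n_genes = 30),
                   class = "moderation_fit")
  de <- moderated_t_test(x, meta, fit = fit)
  ## constant posterior variance: t is a fixed multiple of log2fc
  expect_equal(de$t_stat, de$log2fc / sqrt(0.25 * (1 / 5 + 1 / 5)),
               tolerance = 1e-12)
  expect_equal(order(abs(de$t_stat)), order(abs(de$log2fc)))
})

test_that("moderated t matches limma's eBayes given the same hyperparameters", {
  set.seed(15)
  meta <- plain_meta(8, 7)
  ## heteroscedastic genes so the estimated prior df is finite and both
  ## routes use the same total degrees of freedom
  gene_sd <- sqrt(0.05 * 3 / rchisq(200, 3))
  vals <- matrix(rnorm(200 * 15, 8, rep(gene_sd, 15)), 200, 15,
                 dimnames = list(sprintf("G%03d", 1:200), meta$sample_id))
  vals[1:10, meta$group == "schizophrenic"] <-
    vals[1:10, meta$group == "schizophrenic"] + 1
  design <- model.matrix(~factor(meta$group, c("control", "schizophrenic")))
  efit <- limma::eBayes(limma::lmFit(vals, design))
  expect_true(is.finite(efit$df.prior))
  fit <- structure(list(d0 = efit$df.prior, s0_sq = efit$s2.prior,
                        residual_df = 13, n_genes = 200),
                   class = "moderation_fit")
  x <- expression_matrix(vals, "log2")
  de <- moderated_t_test(x, meta, fit = fit)
  expect_equal(de$log2fc, unname(efit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$t_stat, unname(efit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(efit$p.value[, 2]), tolerance = 1e-8)
})

test_that("degenerate genes are flagged instead of failing the run", {
  meta <- plain_meta(3, 3)
  vals <- rbind(flat = rep(5, 6),
                equal_means = c(1, 2, 3, 3, 2, 1))
  colnames(vals) <- meta$sample_id
  x <- expression_matrix(vals, "log2")
  expect_warning(de <- moderated_t_test(x, meta, ordinary = TRUE),
                 "zero posterior variance")
  expect_equal(de$t_stat[de$symbol == "flat"], 0)
  expect_equal(de$p_value[de$symbol == "flat"], 1)
  expect_equal(de$log2fc[de$symbol == "equal_means"], 0)
  expect_equal(de$t_stat[de$symbol == "equal_means"], 0)
  expect_equal(de$p_value[de$symbol == "equal_means"], 1)

  meta1 <- plain_meta(1, 5)
  vals1 <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, meta1$sample_id))
  rownames(vals1) <- sprintf("G%02d", 1:12)
  expect_error(moderated_t_test(expression_matrix(vals1, "log2"), meta1),
               "at least 2 samples")
})

test_that("Benjamini-Hochberg equals the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  grid <- seq(0, 1, by = 0.05)
  set.seed(42)
  for (n in 1:8) {
    for (rep in 1:40) {
      p <- sample(grid, n, replace = TRUE)
      expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
  ## permutation invariance
  p <- c(0.001, 0.02, 0.02, 0.4, 0.4, 0.4, 0.99, 0)
  perm <- sample(length(p))
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
})

test_that("null data yields a calibrated discovery fraction", {
  frac <- vapply(1:100, function(s) {
    sim <- simulate_study(tiny_config(n_case = 6, n_control = 6, n_genes = 80,
                                      n_lncrna = 6, n_mirna = 4, n_axes = 0,
                                      frac_covariate_genes = 0, seed = s))
    de <- moderated_t_test(log2_transform(sim$expr), sim$metadata)
    mean(de$adj_p < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("planted effects without latent variance are detected reliably", {
  called <- vapply(1:5, function(s) {
    sim <- simulate_study(tiny_config(n_case = 25, n_control = 25,
                                      n_genes = 300, n_lncrna = 20,
                                      n_mirna = 10, n_axes = 10,
                                      axis_latent_sd = 0, seed = s))
    de <- moderated_t_test(log2_transform(sim$expr), sim$metadata)
    de <- call_degs(de)
    called <- de$symbol[de$status != "not_de"]
    mean(sim$truth$planted_de$symbol %in% called)
  }, numeric(1))
  expect_gte(mean(called), 0.99)
})

test_that("DE calling honours the threshold conventions", {
  tbl <- tibble::tibble(
    symbol = c("a", "b", "c", "d"),
    log2fc = c(0.6, 0.5, -2, 0.4),
    adj_p = c(1e-4, 1e-4, 0.001, 1e-9)
  )
  out <- call_degs(tbl)
  expect_equal(out$status, c("up", "up", "not_de", "not_de"))
  strict <- call_degs(tbl, strict_lfc = TRUE)
  expect_equal(strict$status[2], "not_de")   # 0.5 is not > 0.5
  expect_equal(out$status[3], "not_de")      # adj_p 0.001 is not < 0.001
})

test_that("partitioning splits DE genes by exact symbol membership", {
  tbl <- tibble::tibble(
    symbol = c("PEG3-AS1", "EGR1", "XIST"),
    log2fc = c(1, -1, 0.1),
    adj_p = c(1e-5, 1e-5, 0.9)
  ) |> call_degs()
  parts <- partition_lnc_mrna(tbl, c("PEG3-AS1", "XIST"))
  expect_equal(parts$delncrna$symbol, "PEG3-AS1")
  expect_equal(parts$demrna$symbol, "EGR1")

  none <- partition_lnc_mrna(tbl, character())
  expect_equal(nrow(none$delncrna), 0)
  expect_setequal(none$demrna$symbol, c("PEG3-AS1", "EGR1"))

  disjoint <- partition_lnc_mrna(tbl, "NEAT1")
  expect_equal(nrow(disjoint$delncrna), 0)
})
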
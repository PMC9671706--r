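# tiny study configurations and hand-built matrices shared across tests

tiny_config <- function(...) {
  defaults <- list(n_case = 8, n_control = 8, n_genes = 60, n_lncrna = 8,
                   n_mirna = 5, n_axes = 2, seed = 11)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# expression matrix from a plain matrix, labelling rows/cols when absent
em <- function(values, scale = "linear") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, scale = scale)
}

# a row of 5 samples whose type-7 IQR is exactly `q`
row_with_iqr <- function(q, center = 8) center + c(-q, -q / 2, 0, q / 2, q)

# metadata for a plain two-group design without covariates of interest
plain_meta <- function(n1, n2) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n1 + n2)),
    source_name = rep(c("post-mortem schizophrenic", "post-mortem control"),
                      c(n1, n2)),
    group = rep(c("schizophrenic", "control"), c(n1, n2)),
    age = rep(60, n1 + n2),
    gender = rep("male", n1 + n2),
    ph = rep(6.5, n1 + n2),
    pmd_hours = rep(10, n1 + n2)
  )
}

# independent step-up oracle for Benjamini-Hochberg, straight from the
# definition: adj_(i) = min_{j : rank j >= rank i} m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# independent combinatorial oracle for the hypergeometric upper tail
hyper_tail_oracle <- function(k, K, N, n) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / choose(N, n)
}

# two vectors whose sample Pearson correlation is exactly `r`
vectors_with_cor <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(stats::lm(z ~ x))
  x <- as.vector(scale(x))
  z <- as.vector(scale(z))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
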
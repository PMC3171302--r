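# Shared fixture builders. Everything is generated in code; seeds are fixed
# so the suite is deterministic.

FIXTURE_SEED <- 424242L

# Transcription model with both delays removed: an immigration-death process
# with birth rate k_t and per-molecule death rate k_d.
zero_delay_params <- function(k_t = 0.05, k_d = 1 / 600) {
  transcription_params(k_t = k_t, tau1 = 0, tau2_mean = 0, tau2_sd = 0, k_d = k_d)
}

# Near-independent steady-state samples of one species: many sparse samples
# (spaced several mean lifetimes apart) from a few long runs.
sparse_steady_samples <- function(system, n_samples, spacing, burn_in,
                                  n_runs = 50, species = "RNA", seed = FIXTURE_SEED) {
  per_run <- ceiling(n_samples / n_runs)
  times <- burn_in + (seq_len(per_run) - 1) * spacing
  out <- integer(0)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, paste0("sparse-run-", r)))
    tr <- run_dssa(system, t_end = max(times), record = FALSE, sample_times = times)
    out <- c(out, tr$samples[, species])
  }
  out[seq_len(n_samples)]
}

# Two-sample chi-square comparison of count distributions, pooling sparse
# bins so expected cell counts stay reasonable.
counts_chisq_p <- function(x, y, min_expected = 10) {
  k <- max(x, y)
  tab <- rbind(tabulate(x + 1L, nbins = k + 1), tabulate(y + 1L, nbins = k + 1))
  tot <- colSums(tab)
  # merge adjacent sparse bins left to right
  groups <- integer(ncol(tab)); g <- 1L; acc <- 0
  for (i in seq_len(ncol(tab))) {
    groups[i] <- g
    acc <- acc + tot[i]
    if (acc >= 2 * min_expected && i < ncol(tab)) { g <- g + 1L; acc <- 0 }
  }
  m <- t(rowsum(t(tab), groups))
  suppressWarnings(stats::chisq.test(m)$p.value)
}
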
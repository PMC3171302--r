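#' Configuration of a full simulate-and-infer experiment
#'
#' One experiment simulates `n_cells` independent RNA time series at the
#' true parameters, optionally corrupts them with measurement noise, and
#' runs the full delay inference. All randomness flows from `seed` through
#' named substreams (data cells, per-candidate chains, noise).
#'
#' @param n_cells Number of simulated cells (the study used 10, 100, 1000).
#' @param noisy Add Gaussian measurement noise before inference?
#' @param noise_sd Noise standard deviation (default 0.5).
#' @param params True [transcription_params()] generating the data.
#' @param protocol [sampling_protocol()] shared by data and chains.
#' @param tau_max Candidate range upper bound, seconds; the default 60 is
#'   the model's lifetime-to-mean-level ratio. `NULL` switches to the
#'   plug-in bound from the observed mean.
#' @param grid_n,n_pairs,kernel Inference settings, see [infer_config()].
#' @param seed Master seed.
#' @param out_dir Optional output directory; when set, [run_experiment()]
#'   writes the series CSV, per-candidate chain JSONs, a result JSON and a
#'   posterior plot there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_cells, noisy = FALSE, noise_sd = 0.5,
                              params = transcription_params(),
                              protocol = sampling_protocol(),
                              tau_max = 60, grid_n = 13, n_pairs = 2e5,
                              kernel = smear_kernel(), seed, out_dir = NULL) {
  stopifnot(n_cells >= 1)
  structure(list(n_cells = n_cells, noisy = noisy, noise_sd = noise_sd,
                 params = params, protocol = protocol, tau_max = tau_max,
                 grid_n = grid_n, n_pairs = n_pairs, kernel = kernel,
                 seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

config_hash <- function(config) {
  # FNV-1a over the canonical JSON form; provenance fingerprint only
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.function(x)) deparse(x)
    else as.vector(x)
  }
  cfg <- unclass(config)
  cfg$out_dir <- NULL # fingerprint the scientific configuration only
  s <- jsonlite::toJSON(strip(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run one simulate-and-infer experiment
#'
#' Pipeline: [simulate_cells()] at the true parameters, then (if configured)
#' [add_measurement_noise()] + [discretize_observations()], then
#' [infer_tau()]. Rerunning with the same config reproduces the result
#' exactly.
#'
#' @param config An [experiment_config()].
#' @param chains Optional precomputed per-candidate chains (list of
#'   [estimate_chain()] results matching the config's grid), reused instead
#'   of re-simulating them.
#' @return An object of class `experiment_result`: list with `summary`
#'   (a [posterior_summary()]), `series` (the data used for inference),
#'   `burnin` diagnostic, and `provenance` (config, hash, seeds).
#' @export
run_experiment <- function(config, chains = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  data_seed <- derive_seed(config$seed, "data")
  noise_seed <- derive_seed(config$seed, "noise")
  chain_seed <- derive_seed(config$seed, "chains")

  clean <- simulate_cells(config$n_cells, config$params, config$protocol, data_seed)
  series <- clean
  if (config$noisy) {
    series <- discretize_observations(
      add_measurement_noise(clean, config$noise_sd, seed = noise_seed))
  }
  icfg <- infer_config(k_t = config$params$k_t, k_d = config$params$k_d,
                       tau2_sd = config$params$tau2_sd,
                       tau2_offset = config$params$tau2_mean - config$params$tau1,
                       tau_max = config$tau_max, grid_n = config$grid_n,
                       n_pairs = config$n_pairs, kernel = config$kernel,
                       protocol = config$protocol)
  summary <- if (is.null(chains)) {
    infer_tau(series, icfg, chain_seed)
  } else {
    grid <- seq(0, config$tau_max, length.out = config$grid_n)
    scan <- scan_tau(grid, series, icfg, chain_seed, chains = chains)
    fit <- fit_quadratic(scan$grid, scan$logliks)
    out <- posterior_summary(fit, config$tau_max, scan$grid, scan$logliks)
    attr(out, "chains") <- scan$chains
    out
  }
  result <- structure(
    list(summary = summary, series = series,
         true_tau1 = config$params$tau1,
         burnin = burnin_diagnostic(series),
         provenance = list(config = config, hash = config_hash(config),
                           seeds = list(master = config$seed, data = data_seed,
                                        noise = if (config$noisy) noise_seed else NULL,
                                        chains = chain_seed),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d cells, %s data (true delay %g s)\n",
              x$provenance$config$n_cells,
              if (x$provenance$config$noisy) "noisy" else "noiseless",
              x$true_tau1))
  print(x$summary)
  invisible(x)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE)) # no partial outputs
  cfg <- result$provenance$config
  write_series_csv(result$series, file.path(out_dir, "series.csv"),
                   params = cfg$params, seed = result$provenance$seeds$data)
  chains <- attr(result$summary, "chains")
  if (!is.null(chains)) {
    cdir <- file.path(out_dir, "chains")
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_along(chains))
      chain_to_json(chains[[i]], file.path(cdir, sprintf("chain_tau_%02d.json", i)),
                    meta = list(tau = result$summary$grid[i]))
  }
  s <- result$summary
  jsonlite::write_json(
    list(true_value = result$true_tau1,
         ml_estimate = s$ml_estimate, expected_value = s$expected_value,
         tau_max = s$tau_max, grid = s$grid, logliks = s$logliks,
         fit = list(a = s$fit$a, b = s$fit$b, c = s$fit$c, concave = s$fit$concave),
         burnin = as.list(result$burnin),
         config_hash = result$provenance$hash,
         seeds = result$provenance$seeds),
    file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  grDevices::png(file.path(out_dir, "posterior.png"), width = 720, height = 480)
  plot(result)
  grDevices::dev.off()
  ok <- TRUE
  invisible(out_dir)
}

#' @export
plot.experiment_result <- function(x, ...) {
  s <- x$summary
  if (is.null(s$density)) {
    plot(s$grid, s$logliks, xlab = "candidate delay (s)", ylab = "log-likelihood",
         main = "Non-concave fit: grid log-likelihoods", pch = 19)
    return(invisible(x))
  }
  plot(s$density$tau, s$density$density, type = "l", lwd = 2,
       xlab = "promoter open-complex delay (s)", ylab = "posterior density",
       main = sprintf("%d cells, %s data", x$provenance$config$n_cells,
                      if (x$provenance$config$noisy) "noisy" else "noiseless"), ...)
  graphics::abline(v = x$true_tau1, lty = 2)
  graphics::abline(v = s$ml_estimate, col = "red3")
  graphics::abline(v = s$expected_value, col = "blue3")
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("true = %g", x$true_tau1),
                              sprintf("ML = %.1f", s$ml_estimate),
                              sprintf("expected = %.1f", s$expected_value)),
                   col = c("black", "red3", "blue3"), lty = c(2, 1, 1))
  invisible(x)
}

#' Reproduce one of the study's figures
#'
#' Figure 1: RNA level traces from six independent simulations. Figures
#' 2-4: posterior of the open-complex delay from 10 / 100 / 1000 noiseless
#' series. Figures 5-7: the same with Gaussian(0, 0.5) measurement noise.
#'
#' @param figure_id Integer 1..7.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param n_pairs Chain budget per candidate for figures 2-7.
#' @return Invisibly, the list of files written.
#' @export
reproduce_figure <- function(figure_id, seed, out_dir, n_pairs = 2e5) {
  if (!figure_id %in% 1:7)
    stop("unknown figure id ", figure_id, " (valid: 1..7)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (figure_id == 1) {
    series <- simulate_cells(6, seed = derive_seed(seed, "fig1"))
    csv <- file.path(out_dir, "figure1_series.csv")
    write_series_csv(series, csv, params = transcription_params(), seed = seed)
    png <- file.path(out_dir, "figure1.png")
    grDevices::png(png, width = 720, height = 480)
    tt <- as.numeric(sub("^t", "", colnames(series)))
    graphics::matplot(tt, t(series), type = "s", lty = 1,
                      xlab = "time (s)", ylab = "RNA molecules",
                      main = "RNA levels from six independent simulations")
    grDevices::dev.off()
    return(invisible(c(csv, png)))
  }
  design <- list(`2` = c(10, FALSE), `3` = c(100, FALSE), `4` = c(1000, FALSE),
                 `5` = c(10, TRUE), `6` = c(100, TRUE), `7` = c(1000, TRUE))
  d <- design[[as.character(figure_id)]]
  fdir <- file.path(out_dir, sprintf("figure%d", figure_id))
  cfg <- experiment_config(n_cells = d[1], noisy = as.logical(d[2]),
                           n_pairs = n_pairs, seed = seed, out_dir = fdir)
  run_experiment(cfg)
  invisible(list.files(fdir, full.names = TRUE))
}
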
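#' Parameters of the delayed stochastic transcription model
#'
#' The model describes single-gene transcription in a prokaryote with two
#' reactions. Reaction 1, initiation: the promoter `Pro` fires at stochastic
#' rate `k_t`; firing consumes the promoter, which is returned after a
#' constant delay `tau1` (the promoter open complex formation, during which
#' the promoter is occupied and unavailable), while the completed `RNA`
#' molecule appears after a Gaussian delay with mean `tau2_mean` and
#' standard deviation `tau2_sd` (open complex formation plus elongation plus
#' termination, hence `tau2_mean >= tau1`). Reaction 2, degradation: each RNA
#' decays at rate `k_d`. RNA polymerase is not represented explicitly, which
#' is adequate while its abundance is roughly constant.
#'
#' Defaults correspond to a lac-promoter-like gene in E. coli: `tau1 = 40` s,
#' completion delay Gaussian(102, 14) s (40 s open complex + ~60 s
#' elongation + termination), degradation `k_d = 1/600` per second (10 min
#' mean RNA lifetime), and initiation `k_t = 0.05` per second, which makes
#' the effective initiation cycle `1/k_t + tau1 = 60` s and the stationary
#' mean RNA level 10.
#'
#' @param k_t Transcription initiation stochastic rate constant, per second.
#' @param tau1 Promoter open-complex delay, seconds.
#' @param tau2_mean,tau2_sd Mean and sd of the Gaussian RNA completion delay,
#'   seconds.
#' @param k_d RNA degradation rate constant, per second.
#' @return An object of class `transcription_params`.
#' @export
transcription_params <- function(k_t = 0.05, tau1 = 40, tau2_mean = 102,
                                 tau2_sd = 14, k_d = 1 / 600) {
  vals <- c(k_t = k_t, tau1 = tau1, tau2_mean = tau2_mean,
            tau2_sd = tau2_sd, k_d = k_d)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all transcription parameters must be finite and nonnegative")
  if (tau2_mean < tau1)
    stop("tau2_mean must be >= tau1 (completion includes open complex formation)")
  structure(as.list(vals), class = "transcription_params")
}

#' @export
print.transcription_params <- function(x, ...) {
  cat(sprintf(paste0("Transcription parameters: k_t = %g /s, tau1 = %g s, ",
                     "tau2 ~ N(%g, %g) s, k_d = %g /s\n"),
              x$k_t, x$tau1, x$tau2_mean, x$tau2_sd, x$k_d))
  invisible(x)
}

#' Build the two-reaction delayed transcription system
#'
#' @param params A [transcription_params()] object.
#' @return A [reaction_system()] with species `Pro` (initial count 1) and
#'   `RNA` (initial count 0).
#' @examples
#' build_transcription_model(transcription_params())
#' @export
build_transcription_model <- function(params = transcription_params()) {
  stopifnot(inherits(params, "transcription_params"))
  init <- reaction(
    reactants = c(Pro = 1),
    delayed = list(
      list(species = "Pro", count = 1L, delay = delay_spec(params$tau1)),
      list(species = "RNA", count = 1L,
           delay = delay_spec(params$tau2_mean, params$tau2_sd,
                              if (params$tau2_sd > 0) "gaussian" else "constant"))),
    rate = params$k_t, name = "initiation")
  deg <- reaction(c(RNA = 1), rate = params$k_d, name = "degradation")
  reaction_system(list(init, deg), c(Pro = 1L, RNA = 0L))
}

#' Analytic stationary mean RNA level
#'
#' Each initiation cycle consists of an exponential wait of mean `1/k_t`
#' followed by the constant occupied period `tau1`, so completed RNA are
#' produced at long-run rate `1/(1/k_t + tau1)`; each survives `1/k_d` on
#' average. By renewal-reward the stationary mean RNA level is
#' `(1/k_d) / (1/k_t + tau1)`. Used as an independent oracle for the
#' simulator.
#'
#' @param params A [transcription_params()] object.
#' @return The stationary mean RNA count (0 when `k_t = 0`).
#' @examples
#' analytic_stationary_mean(transcription_params()) # 10
#' @export
analytic_stationary_mean <- function(params) {
  stopifnot(inherits(params, "transcription_params"))
  if (params$k_t == 0) return(0)
  if (params$k_d == 0) stop("k_d must be positive")
  (1 / params$k_d) / (1 / params$k_t + params$tau1)
}

#' Steady-state sampling protocol
#'
#' Each simulated cell runs for `t_end` seconds and its RNA count is read at
#' `n_points` instants `window_start, window_start + interval, ...` within
#' the steady-state window. Defaults: 30 s interval (the shortest currently
#' feasible in single-molecule RNA measurements), 6000 s runs, samples at
#' 3000, 3030, ..., 5970 s — 100 points spanning 2970 s.
#'
#' @param interval Sampling interval, seconds.
#' @param t_end Run length, seconds.
#' @param window_start Start of the steady-state window, seconds.
#' @param n_points Number of samples per cell.
#' @return An object of class `sampling_protocol`.
#' @export
sampling_protocol <- function(interval = 30, t_end = 6000,
                              window_start = 3000, n_points = 100) {
  if (interval <= 0 || t_end <= 0 || window_start < 0 || n_points < 1)
    stop("invalid sampling protocol")
  if (window_start + (n_points - 1) * interval > t_end)
    stop("sampling grid extends beyond t_end")
  structure(list(interval = interval, t_end = t_end,
                 window_start = window_start, n_points = n_points),
            class = "sampling_protocol")
}

sample_times_of <- function(protocol) {
  protocol$window_start + (seq_len(protocol$n_points) - 1) * protocol$interval
}

#' Sample a trajectory at the protocol's steady-state grid
#'
#' The value reported at a sample time `s` is the RNA count after all events
#' with event time at or before `s`.
#'
#' @param trajectory A recorded [run_dssa()] trajectory covering
#'   `[0, t_end]`, or one run with matching `sample_times`.
#' @param protocol A [sampling_protocol()].
#' @param species Species to read, default `"RNA"`.
#' @return Integer vector of length `n_points` (class `sampled_series`).
#' @export
sample_at_interval <- function(trajectory, protocol = sampling_protocol(),
                               species = "RNA") {
  stopifnot(inherits(trajectory, "dssa_trajectory"),
            inherits(protocol, "sampling_protocol"))
  times <- sample_times_of(protocol)
  if (trajectory$t_end < max(times))
    stop("trajectory does not cover the sampling window")
  if (!is.null(trajectory$samples) &&
      isTRUE(all.equal(trajectory$sample_times, times))) {
    v <- trajectory$samples[, species]
  } else {
    v <- counts_at(trajectory, times, species)[, 1]
  }
  structure(as.integer(v), class = "sampled_series", times = times)
}

#' Simulate independent cells and sample their RNA time series
#'
#' Runs `n_cells` independent delayed-SSA simulations of the transcription
#' model, each seeded from its own substream of `seed`, and samples each at
#' the protocol grid.
#'
#' @param n_cells Number of cells (independent runs).
#' @param params A [transcription_params()] object.
#' @param protocol A [sampling_protocol()] object.
#' @param seed Master seed for this batch.
#' @return Integer matrix with `n_cells` rows and `n_points` columns
#'   (class `series_set`); column names give the sample times.
#' @examples
#' s <- simulate_cells(3, seed = 1,
#'                     protocol = sampling_protocol(t_end = 3200, n_points = 5))
#' dim(s)
#' @export
simulate_cells <- function(n_cells, params = transcription_params(),
                           protocol = sampling_protocol(), seed) {
  stopifnot(n_cells >= 1)
  system <- build_transcription_model(params)
  times <- sample_times_of(protocol)
  out <- matrix(NA_integer_, nrow = n_cells, ncol = protocol$n_points,
                dimnames = list(NULL, paste0("t", times)))
  for (i in seq_len(n_cells)) {
    set.seed(derive_seed(seed, paste0("cell-", i)))
    tr <- run_dssa(system, protocol$t_end, record = FALSE, sample_times = times)
    out[i, ] <- tr$samples[, "RNA"]
  }
  structure(out, class = c("series_set", "matrix", "array"),
            protocol = protocol, seed = seed)
}

#' Write / read a set of sampled series as CSV
#'
#' One row per cell; columns `cell` then one column per sample time
#' (`t3000`, `t3030`, ...). `write_series_csv()` also writes a JSON metadata
#' sidecar (`<path>.meta.json`) with the parameters, protocol and seed when
#' these are available.
#'
#' @param series A matrix as returned by [simulate_cells()] (integer counts)
#'   or its noisy real-valued counterpart.
#' @param path CSV file path.
#' @param params,seed Optional metadata recorded in the sidecar.
#' @return `read_series_csv()` returns the series matrix.
#' @export
write_series_csv <- function(series, path, params = NULL, seed = attr(series, "seed")) {
  df <- data.frame(cell = seq_len(nrow(series)), unclass(series)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(n_cells = nrow(series), n_points = ncol(series),
               columns = colnames(series))
  if (!is.null(params)) meta$params <- unclass(params)
  if (!is.null(seed)) meta$seed <- seed
  pr <- attr(series, "protocol")
  if (!is.null(pr)) meta$protocol <- unclass(pr)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "cell"), drop = FALSE])
  rownames(m) <- NULL
  m
}

# Burn-in diagnostic: compares first- and second-half means of the sampling
# window per batch; logged by run_experiment, never enforced.
burnin_diagnostic <- function(series) {
  half <- ncol(series) %/% 2
  c(first_half_mean = mean(series[, seq_len(half)]),
    second_half_mean = mean(series[, (half + 1):ncol(series)]))
}
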
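#' Markov-chain log-likelihood of observed RNA series
#'
#' For each series x_1..x_T the log-likelihood under an empirical chain is
#' `log pi(x_1) + sum_t log P(x_{t-1} -> x_t)`; independent series add.
#'
#' @param series A single integer vector, a matrix (one row per cell), or a
#'   list of integer vectors.
#' @param chain An [estimate_chain()] (or analytic) chain.
#' @param clip If `TRUE` (default), observed states above the chain's `K`
#'   are clipped to `K` (the state space is data-driven); the number of
#'   clipped points is attached as attribute `"n_clipped"`. If `FALSE`,
#'   out-of-range states are an error.
#' @return The summed log-likelihood (a single number).
#' @examples
#' ch <- structure(list(K = 1, pi = c(0.5, 0.5),
#'                      P = rbind(c(0.9, 0.1), c(0.2, 0.8))),
#'                 class = "empirical_chain")
#' log_likelihood(c(0, 0, 1), ch) # log 0.5 + log 0.9 + log 0.1
#' @export
log_likelihood <- function(series, chain, clip = TRUE) {
  rows <- if (is.matrix(series)) lapply(seq_len(nrow(series)), function(i) series[i, ])
          else if (is.list(series)) series else list(series)
  n_clipped <- 0L
  ll <- 0
  for (x in rows) {
    x <- as.integer(x)
    if (any(x < 0)) stop("negative observed state")
    over <- x > chain$K
    if (any(over)) {
      if (!clip) stop("observed state above chain's maximum state K")
      n_clipped <- n_clipped + sum(over)
      x[over] <- chain$K
    }
    ll <- ll + log(chain$pi[x[1] + 1L])
    if (length(x) > 1)
      ll <- ll + sum(log(chain$P[cbind(x[-length(x)] + 1L, x[-1] + 1L)]))
  }
  structure(ll, n_clipped = n_clipped)
}

#' Upper bound of the candidate delay range
#'
#' The open-complex delay cannot exceed the mean RNA lifetime divided by the
#' mean RNA level (for the default model this ratio is 60). With known true
#' parameters the mean level is [analytic_stationary_mean()]; when only data
#' are available, pass the observed mean as `mean_level` (plug-in form).
#'
#' @param params A [transcription_params()] object (used when `mean_level`
#'   is not supplied).
#' @param mean_level Optional plug-in mean RNA level estimated from data.
#' @return Upper bound for the delay, seconds.
#' @examples
#' tau_upper_bound(transcription_params()) # 60
#' @export
tau_upper_bound <- function(params = transcription_params(), mean_level = NULL) {
  m <- if (is.null(mean_level)) analytic_stationary_mean(params) else mean_level
  if (!is.finite(m) || m <= 0) stop("mean RNA level must be positive")
  (1 / params$k_d) / m
}

#' Inference configuration
#'
#' Bundles everything [infer_tau()] needs besides the data: the assumed
#' known model parameters (`k_t`, `k_d`), the completion-delay handling, the
#' candidate grid, and the chain-estimation budget.
#'
#' Each candidate delay tau is simulated with `tau1 = tau` and, when
#' `vary_tau2 = TRUE` (default), `tau2_mean = tau + tau2_offset` so the
#' completion delay keeps its open-complex component; with
#' `vary_tau2 = FALSE` the completion delay is held at `tau2_fixed`. At
#' steady state the two choices give the same sampled law (a pure time shift
#' of production events).
#'
#' @param k_t,k_d Assumed known initiation and degradation rates, per second.
#' @param tau2_offset Elongation-plus-termination mean, seconds (102 - 40).
#' @param tau2_sd Completion-delay sd, seconds.
#' @param tau2_fixed Completion-delay mean when `vary_tau2 = FALSE`.
#' @param vary_tau2 See above.
#' @param tau_max Upper end of the candidate range, seconds; `NULL` uses the
#'   plug-in bound [tau_upper_bound()] with the observed data mean.
#' @param grid_n Number of equally spaced candidate delays on `[0, tau_max]`.
#' @param n_pairs Chain-estimation budget: minimum sample pairs per
#'   candidate.
#' @param kernel A [smear_kernel()].
#' @param floor_prob Passed to [estimate_chain()].
#' @param protocol A [sampling_protocol()] for the chain-building
#'   simulations.
#' @return An object of class `infer_config`.
#' @export
infer_config <- function(k_t = 0.05, k_d = 1 / 600, tau2_offset = 62,
                         tau2_sd = 14, tau2_fixed = 102, vary_tau2 = TRUE,
                         tau_max = NULL, grid_n = 13, n_pairs = 2e5,
                         kernel = smear_kernel(), floor_prob = NULL,
                         protocol = sampling_protocol()) {
  if (grid_n < 5) stop("grid needs at least 5 points (quadratic fit slack)")
  structure(list(k_t = k_t, k_d = k_d, tau2_offset = tau2_offset,
                 tau2_sd = tau2_sd, tau2_fixed = tau2_fixed,
                 vary_tau2 = vary_tau2, tau_max = tau_max, grid_n = grid_n,
                 n_pairs = n_pairs, kernel = kernel, floor_prob = floor_prob,
                 protocol = protocol),
            class = "infer_config")
}

params_for_tau <- function(tau, config) {
  t2 <- if (config$vary_tau2) tau + config$tau2_offset else config$tau2_fixed
  transcription_params(k_t = config$k_t, tau1 = tau,
                       tau2_mean = max(t2, tau), tau2_sd = config$tau2_sd,
                       k_d = config$k_d)
}

#' Estimate the empirical chain for one candidate delay
#'
#' @param tau Candidate open-complex delay, seconds.
#' @param config An [infer_config()].
#' @param seed Seed for this candidate's simulations.
#' @return An [estimate_chain()] result.
#' @export
chain_for_tau <- function(tau, config = infer_config(), seed) {
  pairs <- collect_sample_pairs(params_for_tau(tau, config), config$protocol,
                                config$n_pairs, seed)
  estimate_chain(pairs, config$kernel, config$floor_prob)
}

#' Evaluate the chain log-likelihood over a grid of candidate delays
#'
#' For each candidate, an empirical chain is built (budget `n_pairs`, seed
#' derived from `seed` and the candidate's grid position, disjoint across
#' candidates) and the log-likelihood of the observed series is evaluated.
#'
#' @param grid Increasing numeric vector of candidate delays, seconds.
#' @param data Observed integer series (matrix, one row per cell).
#' @param config An [infer_config()].
#' @param seed Master seed of the scan's chain substreams.
#' @param chains Optional precomputed list of chains, one per grid point
#'   (reused instead of simulating; useful when scanning several data sets
#'   against the same candidates).
#' @return List with `grid`, `logliks`, `chains`, `n_clipped`.
#' @export
scan_tau <- function(grid, data, config = infer_config(), seed, chains = NULL) {
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0))
    stop("grid must be strictly increasing and nonnegative")
  if (is.null(chains)) {
    chains <- lapply(seq_along(grid), function(i)
      chain_for_tau(grid[i], config, derive_seed(seed, paste0("chain-tau-", i))))
  }
  evals <- lapply(chains, function(ch) log_likelihood(data, ch))
  list(grid = grid,
       logliks = vapply(evals, as.numeric, numeric(1)),
       chains = chains,
       n_clipped = vapply(evals, attr, integer(1), "n_clipped"))
}

#' Quadratic fit to grid log-likelihoods
#'
#' The sampled log-likelihood is nonsmooth in the candidate delay, so a
#' quadratic `a tau^2 + b tau + c` is least-squares fitted to the grid
#' points; a concave fit (`a < 0`) corresponds to a Gaussian likelihood
#' profile.
#'
#' @param grid Candidate delays (>= 3 points).
#' @param logliks Log-likelihood at each grid point.
#' @return An object of class `quadratic_fit`: list with `a`, `b`, `c`,
#'   `concave`, `fitted`, `residuals`.
#' @export
fit_quadratic <- function(grid, logliks) {
  if (length(grid) < 3) stop("quadratic fit needs at least 3 points")
  if (length(grid) != length(logliks)) stop("grid and logliks lengths differ")
  if (stats::sd(logliks) < 1e-10 * (1 + max(abs(logliks)))) {
    # constant response: report the exactly degenerate fit
    a <- 0; b <- 0; cc <- mean(logliks)
    return(structure(list(a = a, b = b, c = cc, concave = FALSE,
                          fitted = rep(cc, length(grid)),
                          residuals = logliks - cc),
                     class = "quadratic_fit"))
  }
  fit <- stats::lm(logliks ~ grid + I(grid^2))
  co <- stats::coef(fit)
  a <- unname(co[3]); b <- unname(co[2]); cc <- unname(co[1])
  structure(list(a = a, b = b, c = cc, concave = is.finite(a) && a < 0,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::resid(fit))),
            class = "quadratic_fit")
}

#' Posterior over the candidate delay from a quadratic likelihood fit
#'
#' Exponentiating the concave quadratic gives a likelihood proportional to a
#' truncated normal on `[0, tau_max]`; with a flat prior this is normalized
#' to unit probability. The maximum-likelihood estimate is the parabola
#' vertex `-b / (2a)` clipped into the range; the expected value is the mean
#' of the truncated density, computed by numerical integration at 1e-3 s
#' resolution. For a non-concave fit the summaries fall back to the grid
#' argmax, with a warning.
#'
#' @param fit A [fit_quadratic()] result.
#' @param tau_max Upper end of the admissible range, seconds.
#' @param grid,logliks The scanned points (kept for audit and used for the
#'   non-concave fallback).
#' @return An object of class `posterior_summary`: list with `grid`,
#'   `logliks`, `fit`, `tau_max`, `ml_estimate`, `expected_value`, `density`
#'   (data frame `tau`, `density` at 0.01 s resolution).
#' @export
posterior_summary <- function(fit, tau_max, grid = NULL, logliks = NULL) {
  stopifnot(inherits(fit, "quadratic_fit"), tau_max > 0)
  if (!fit$concave) {
    warning("non-concave quadratic fit; summaries fall back to the grid argmax")
    ml <- if (!is.null(grid)) grid[which.max(logliks)] else NA_real_
    ev <- ml
    dens <- NULL
  } else {
    n_steps <- 2L * ceiling(tau_max / 2e-3) # even count for Simpson's rule
    tau <- seq(0, tau_max, length.out = n_steps + 1L)
    logd <- fit$a * tau^2 + fit$b * tau # drop c: cancels in normalization
    logd <- logd - max(logd)
    d <- exp(logd)
    z <- simpson(tau, d)
    d <- d / z
    ml <- min(max(-fit$b / (2 * fit$a), 0), tau_max)
    ev <- simpson(tau, tau * d)
    keep <- unique(c(seq(1, length(tau), by = 10), length(tau)))
    dens <- data.frame(tau = tau[keep], density = d[keep])
  }
  structure(list(grid = grid, logliks = logliks, fit = fit, tau_max = tau_max,
                 ml_estimate = ml, expected_value = ev, density = dens),
            class = "posterior_summary")
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

# composite Simpson's rule on an equally spaced grid with an even number of
# intervals; fourth-order accuracy matters for boundary-peaked posteriors
simpson <- function(x, y) {
  n <- length(x) - 1L
  h <- (x[n + 1L] - x[1L]) / n
  w <- rep(c(4, 2), length.out = n - 1L)
  h / 3 * (y[1L] + y[n + 1L] + sum(w * y[2:n]))
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior over the open-complex delay on [0, %.3g] s\n", x$tau_max))
  cat(sprintf("  maximum likelihood: %.1f s\n", x$ml_estimate))
  cat(sprintf("  expected value:     %.1f s\n", x$expected_value))
  if (!is.null(x$fit) && !x$fit$concave) cat("  (non-concave fit: grid-argmax fallback)\n")
  invisible(x)
}

#' Infer the promoter open-complex delay from RNA count series
#'
#' End-to-end inference: determines the admissible range (plug-in
#' [tau_upper_bound()] from the observed mean unless `tau_max` is fixed in
#' the config), scans the chain log-likelihood over an equally spaced
#' candidate grid, fits a quadratic, and summarizes the normalized truncated
#' posterior.
#'
#' @param data Observed integer series, matrix with one row per cell (as
#'   from [simulate_cells()], possibly noised and re-discretized).
#' @param config An [infer_config()].
#' @param seed Master seed; chain substreams are derived from it and should
#'   be disjoint from the seeds that generated `data`.
#' @return A [posterior_summary()] with the scan's `chains` attached as
#'   attribute `"chains"` and the config as attribute `"config"`.
#' @export
infer_tau <- function(data, config = infer_config(), seed) {
  data <- as.matrix(data)
  if (length(data) == 0) stop("data must be nonempty")
  tau_max <- config$tau_max
  if (is.null(tau_max))
    tau_max <- tau_upper_bound(transcription_params(k_t = config$k_t, k_d = config$k_d),
                               mean_level = mean(data))
  grid <- seq(0, tau_max, length.out = config$grid_n)
  scan <- scan_tau(grid, data, config, seed)
  fit <- fit_quadratic(scan$grid, scan$logliks)
  out <- posterior_summary(fit, tau_max, scan$grid, scan$logliks)
  attr(out, "chains") <- scan$chains
  attr(out, "n_clipped") <- scan$n_clipped
  attr(out, "config") <- config
  out
}
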
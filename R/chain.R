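#' Smearing kernel over adjacent RNA-count states
#'
#' Empirical state and transition counts are "smeared out" over neighbouring
#' states before normalization, compensating for finite-sample gaps: a count
#' at state s is redistributed as `w_minus` to s-1, `w_zero` to s and
#' `w_plus` to s+1.
#'
#' The default is the light symmetric kernel (0.02, 0.96, 0.02). Smearing
#' trades variance for bias: convolving the transition rows with the kernel
#' over-disperses them, which systematically favours longer candidate
#' delays (whose rows are narrower), so heavy kernels shift the likelihood
#' argmax upward. At the package's default sampling budget a 2% spill per
#' side bridges single-state sampling gaps while leaving the argmax
#' unbiased within the grid resolution; see the methods vignette.
#'
#' @param w_minus,w_zero,w_plus Nonnegative weights summing to 1; `w_zero`
#'   must be positive.
#' @return An object of class `smear_kernel` (numeric length-3 vector).
#' @export
smear_kernel <- function(w_minus = 0.02, w_zero = 0.96, w_plus = 0.02) {
  w <- c(w_minus, w_zero, w_plus)
  if (any(w < 0) || w_zero <= 0 || abs(sum(w) - 1) > 1e-12)
    stop("kernel weights must be nonnegative, sum to 1, with w_zero > 0")
  structure(w, names = c("w_minus", "w_zero", "w_plus"), class = "smear_kernel")
}

#' Identity kernel (no smearing)
#' @rdname smear_kernel
#' @export
identity_kernel <- function() smear_kernel(0, 1, 0)

#' Smear a count vector over adjacent states
#'
#' States are 0-based: element i of the input is the count of state i - 1.
#' Mass pushed below state 0 stays at state 0 (boundary clamp); at the top
#' the vector grows by one state so no mass is lost. Total mass is conserved
#' exactly.
#'
#' @param counts Nonnegative numeric vector; element i is the count of
#'   state i - 1.
#' @param kernel A [smear_kernel()].
#' @return Smeared numeric vector, trimmed to the last positive state but
#'   never shorter than the input.
#' @examples
#' smear_counts(c(0, 0, 0, 0, 0, 10), smear_kernel()) # 10 at state 5
#' @export
smear_counts <- function(counts, kernel = smear_kernel()) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- length(counts)
  out <- numeric(n + 1)
  out[seq_len(n)] <- kernel[["w_zero"]] * counts
  out[seq_len(n) + 1L] <- out[seq_len(n) + 1L] + kernel[["w_plus"]] * counts
  out[1L] <- out[1L] + kernel[["w_minus"]] * counts[1L] # clamp at state 0
  if (n > 1)
    out[seq_len(n - 1)] <- out[seq_len(n - 1)] + kernel[["w_minus"]] * counts[-1L]
  last <- max(which(out > 0), n)
  out[seq_len(last)]
}

#' Collect consecutive steady-state sample pairs from simulated cells
#'
#' Simulates as many independent cells as needed for at least `n_samples`
#' consecutive 30-s-apart sample pairs from the steady-state window (each
#' cell with `n_points` samples yields `n_points - 1` pairs; pairs never
#' span two cells).
#'
#' @param params A [transcription_params()] object.
#' @param protocol A [sampling_protocol()] object.
#' @param n_samples Minimum number of (state, next state) pairs.
#' @param seed Master seed for the batch of cells.
#' @return A data frame with columns `cell`, `from`, `to` (class
#'   `sample_pairs`); the simulated series matrix is attached as attribute
#'   `"series"`.
#' @export
collect_sample_pairs <- function(params = transcription_params(),
                                 protocol = sampling_protocol(),
                                 n_samples, seed) {
  stopifnot(n_samples >= 1, protocol$n_points >= 2)
  n_cells <- ceiling(n_samples / (protocol$n_points - 1))
  series <- simulate_cells(n_cells, params, protocol, seed)
  pr <- pairs_from_series(series)
  attr(pr, "series") <- series
  pr
}

#' Consecutive pairs of an existing series set
#'
#' @param series Integer matrix, one row per cell.
#' @return Same form as [collect_sample_pairs()].
#' @export
pairs_from_series <- function(series) {
  series <- as.matrix(series)
  tt <- ncol(series)
  if (tt < 2) stop("series need at least two time points to form pairs")
  pr <- data.frame(cell = rep(seq_len(nrow(series)), each = tt - 1),
                   from = as.vector(t(series[, -tt, drop = FALSE])),
                   to = as.vector(t(series[, -1, drop = FALSE])))
  class(pr) <- c("sample_pairs", "data.frame")
  pr
}

# The marginal sample multiset underlying a pair set: each cell's samples
# counted once (all `from` values plus that cell's final `to`).
marginal_samples <- function(pairs) {
  last <- !duplicated(pairs$cell, fromLast = TRUE)
  c(pairs$from, pairs$to[last])
}

#' Estimate the empirical Markov chain of the sampled RNA process
#'
#' Approximates the sampled (30-s-spaced) RNA-count process for one
#' parameter setting as a time-homogeneous Markov chain on states `0..K`:
#' the stationary distribution `pi` comes from the smeared marginal counts
#' of all samples, and row x of the transition matrix `P` from the smeared
#' counts of the next states observed after x. `K` is the maximum observed
#' state plus a margin of 1 so smeared mass at the top is retained.
#'
#' Rows for states never observed fall back to `pi`. After smearing, all
#' probabilities are floored at `floor_prob` and renormalized, keeping the
#' log-likelihood of any observable series finite.
#'
#' @param pairs A pair set from [collect_sample_pairs()] /
#'   [pairs_from_series()], or a 2-column matrix of (from, to) pairs from a
#'   single chain.
#' @param kernel A [smear_kernel()]; use [identity_kernel()] for raw counts.
#' @param floor_prob Probability floor; `NULL` (default) uses
#'   `1 / (n_samples + K + 1)`, and `0` disables flooring.
#' @return An object of class `empirical_chain`: list with `K`, `pi`
#'   (length K + 1), `P` ((K+1) x (K+1), rows sum to 1), `n_samples`,
#'   `kernel`, `floor_prob`.
#' @export
estimate_chain <- function(pairs, kernel = smear_kernel(), floor_prob = NULL) {
  if (is.matrix(pairs)) {
    if (ncol(pairs) != 2) stop("pair matrix must have two columns")
    if (nrow(pairs) < 1) stop("at least one sample pair is required")
    pairs <- data.frame(cell = 1L, from = pairs[, 1], to = pairs[, 2])
  }
  if (nrow(pairs) < 1) stop("at least one sample pair is required")
  if (any(pairs$from < 0) || any(pairs$to < 0)) stop("states must be nonnegative")

  K <- max(pairs$from, pairs$to) + 1L # +1 margin for smear spill at the top
  n_states <- K + 1L
  samples <- marginal_samples(pairs)
  n_samples <- length(samples)
  if (is.null(floor_prob)) floor_prob <- 1 / (n_samples + K + 1)

  marg <- tabulate(samples + 1L, nbins = n_states)
  pi_s <- smear_counts(marg, kernel)
  length(pi_s) <- n_states
  pi_s[is.na(pi_s)] <- 0
  pi_v <- floor_and_normalize(pi_s, floor_prob)

  trans <- matrix(0, n_states, n_states)
  tab <- table(factor(pairs$from, levels = 0:K), factor(pairs$to, levels = 0:K))
  trans[] <- as.numeric(tab)
  P <- matrix(0, n_states, n_states)
  for (x in seq_len(n_states)) {
    row <- trans[x, ]
    if (sum(row) == 0) {
      P[x, ] <- pi_v # unobserved state: fall back to the stationary law
    } else {
      sm <- smear_counts(row, kernel)
      length(sm) <- n_states
      sm[is.na(sm)] <- 0
      P[x, ] <- floor_and_normalize(sm, floor_prob)
    }
  }
  structure(list(K = K, pi = pi_v, P = P, n_samples = n_samples,
                 kernel = kernel, floor_prob = floor_prob),
            class = "empirical_chain")
}

# Floor then renormalize the remaining mass, so floored entries sit at
# exactly floor_prob and the vector still sums to 1. Terminates because the
# floored set only grows and floor_prob < 1/length(w) by construction.
floor_and_normalize <- function(w, floor_prob) {
  p <- w / sum(w)
  if (floor_prob <= 0) return(p)
  fixed <- rep(FALSE, length(p))
  repeat {
    low <- !fixed & p < floor_prob
    if (!any(low)) break
    fixed <- fixed | low
    p[fixed] <- floor_prob
    p[!fixed] <- p[!fixed] * (1 - sum(fixed) * floor_prob) / sum(p[!fixed])
  }
  p
}

#' @export
print.empirical_chain <- function(x, ...) {
  cat(sprintf("<empirical_chain: states 0..%d, %d samples, floor %.3g>\n",
              x$K, x$n_samples, x$floor_prob))
  invisible(x)
}

#' Exact 30-s transition law of the zero-delay (immigration-death) model
#'
#' With both delays zero the transcription model is an immigration-death
#' (birth-death) process: RNA appear at rate `birth_rate` and each decays at
#' rate `k_d`. Over an interval `delta` each of the current x molecules
#' survives independently with probability `exp(-k_d * delta)` and a
#' Poisson((birth_rate / k_d) (1 - exp(-k_d delta))) number of newcomers
#' arrives, so the transition row is the convolution of a binomial and a
#' Poisson. The stationary law is Poisson(birth_rate / k_d). Serves as the
#' independent oracle for [estimate_chain()].
#'
#' @param birth_rate RNA production rate, per second.
#' @param k_d Degradation rate, per second.
#' @param delta Sampling interval, seconds.
#' @param K Truncation state; rows and `pi` are truncated to `0..K` and
#'   renormalized.
#' @return An `empirical_chain`-shaped object (identity kernel, no floor).
#' @export
analytic_chain_no_delay <- function(birth_rate, k_d, delta, K) {
  stopifnot(birth_rate > 0, k_d > 0, delta > 0, K >= 1)
  q <- exp(-k_d * delta)
  m <- (birth_rate / k_d) * (1 - q)
  states <- 0:K
  P <- matrix(0, K + 1, K + 1)
  pois <- stats::dpois(states, m)
  for (x in states) {
    surv <- stats::dbinom(0:x, x, q)
    row <- numeric(K + 1)
    for (s in 0:x) {
      upto <- K - s
      row[s + 1 + 0:upto] <- row[s + 1 + 0:upto] + surv[s + 1] * pois[1:(upto + 1)]
    }
    P[x + 1, ] <- row / sum(row)
  }
  pi_v <- stats::dpois(states, birth_rate / k_d)
  pi_v <- pi_v / sum(pi_v)
  structure(list(K = K, pi = pi_v, P = P, n_samples = Inf,
                 kernel = identity_kernel(), floor_prob = 0),
            class = "empirical_chain")
}

#' Total variation distance between two probability vectors
#'
#' Vectors are zero-padded to a common length.
#'
#' @param p,q Probability vectors.
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  length(p) <- n; length(q) <- n
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  0.5 * sum(abs(p - q))
}

#' Serialize / deserialize an empirical chain as JSON
#'
#' @param chain An [estimate_chain()] result.
#' @param path JSON file path.
#' @param meta Optional named list of provenance metadata stored alongside.
#' @return `chain_from_json()` returns the `empirical_chain`.
#' @export
chain_to_json <- function(chain, path, meta = NULL) {
  obj <- list(K = chain$K, pi = chain$pi, P = apply(chain$P, 1, identity, simplify = FALSE),
              n_samples = chain$n_samples,
              kernel = as.numeric(chain$kernel), floor_prob = chain$floor_prob,
              meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname chain_to_json
#' @export
chain_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- if (is.list(obj$P)) do.call(rbind, obj$P) else obj$P
  structure(list(K = obj$K, pi = obj$pi, P = P, n_samples = obj$n_samples,
                 kernel = smear_kernel(obj$kernel[1], obj$kernel[2], obj$kernel[3]),
                 floor_prob = obj$floor_prob),
            class = "empirical_chain")
}
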
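toy_chain <- function() {
  structure(list(K = 1, pi = c(0.5, 0.5),
                 P = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                 n_samples = Inf, kernel = identity_kernel(), floor_prob = 0),
            class = "empirical_chain")
}

test_that("the chain log-likelihood sums the initial-state and transition terms", {
  ch <- toy_chain()
  ll <- log_likelihood(c(0, 0, 1), ch)
  expect_identical(as.numeric(ll), log(0.5) + log(0.9) + log(0.1))

  # independent series are additive
  two <- rbind(c(0, 0, 1), c(0, 0, 1))
  expect_identical(as.numeric(log_likelihood(two, ch)), 2 * as.numeric(ll))

  # a length-1 series contributes only its stationary term
  expect_identical(as.numeric(log_likelihood(1L, ch)), log(0.5))

  # out-of-range states: clipped by default (and counted), error when asked
  high <- c(0, 5, 1)
  expect_equal(attr(log_likelihood(high, ch), "n_clipped"), 1L)
  expect_error(log_likelihood(high, ch, clip = FALSE), "above")
  expect_error(log_likelihood(c(-1, 0), ch), "negative")
})

test_that("the delay range bound is lifetime over mean level", {
  expect_equal(tau_upper_bound(transcription_params()), 60)
  # mean level equal to the lifetime gives a bound of 1
  expect_equal(tau_upper_bound(transcription_params(), mean_level = 600), 1)
  # plug-in form with an observed mean
  expect_equal(tau_upper_bound(transcription_params(), mean_level = 12), 50)
  expect_error(tau_upper_bound(transcription_params(k_t = 0)), "positive")
})

test_that("quadratic fits recover exact and least-squares coefficients", {
  tau <- seq(0, 60, by = 5)
  fit <- fit_quadratic(tau, -(tau - 40)^2)
  expect_equal(c(fit$a, fit$b, fit$c), c(-1, 80, -1600), tolerance = 1e-8)
  expect_true(fit$concave)

  flat <- fit_quadratic(tau, rep(7, length(tau)))
  expect_equal(c(flat$a, flat$b, flat$c), c(0, 0, 7), tolerance = 1e-8)
  expect_false(flat$concave)

  # OLS solution agrees with the normal equations on noisy points
  set.seed(4)
  y <- -(tau - 35)^2 / 3 + stats::rnorm(length(tau), 0, 5)
  f <- fit_quadratic(tau, y)
  X <- cbind(1, tau, tau^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f$c, f$b, f$a), as.numeric(beta), tolerance = 1e-8)

  expect_error(fit_quadratic(c(0, 1), c(0, 1)), "at least 3")
})

test_that("the truncated-normal posterior matches the closed form", {
  tn_mean <- function(a, b, lo, hi) {
    mu <- -b / (2 * a); sigma <- sqrt(-1 / (2 * a))
    al <- (lo - mu) / sigma; be <- (hi - mu) / sigma
    mu + sigma * (stats::dnorm(al) - stats::dnorm(be)) /
      (stats::pnorm(be) - stats::pnorm(al))
  }
  cases <- list(c(a = -0.02, b = 1.4), # vertex 35, sigma 5
                c(a = -0.002, b = 0.2), # vertex 50, sigma ~15.8
                c(a = -0.5, b = 70)) # vertex 70, beyond the range
  for (cs in cases) {
    fit <- structure(list(a = cs[["a"]], b = cs[["b"]], c = 0, concave = TRUE),
                     class = "quadratic_fit")
    ps <- posterior_summary(fit, tau_max = 60)
    expect_lt(abs(ps$expected_value - tn_mean(cs[["a"]], cs[["b"]], 0, 60)), 1e-6)
    dens <- ps$density
    expect_equal(sum(diff(dens$tau) * (dens$density[-1] + dens$density[-nrow(dens)])) / 2,
                 1, tolerance = 1e-3)
  }
  # interior vertex is the ML estimate; an exterior vertex clips to the boundary
  f1 <- structure(list(a = -0.5, b = 40, c = 0, concave = TRUE), class = "quadratic_fit")
  expect_equal(posterior_summary(f1, 60)$ml_estimate, 40)
  f2 <- structure(list(a = -0.5, b = 70, c = 0, concave = TRUE), class = "quadratic_fit")
  expect_equal(posterior_summary(f2, 60)$ml_estimate, 60)
  # non-concave fits fall back to the grid argmax with a warning
  f3 <- structure(list(a = 0.1, b = 0, c = 0, concave = FALSE), class = "quadratic_fit")
  expect_warning(ps3 <- posterior_summary(f3, 60, grid = c(0, 30, 60),
                                          logliks = c(-5, -1, -4)), "non-concave")
  expect_equal(ps3$ml_estimate, 30)
})

test_that("scans are deterministic and favour the true delay on sizeable data", {
  data <- simulate_cells(150, seed = derive_seed(77, "data"))
  cfg <- infer_config(tau_max = 60, n_pairs = 2e4)
  s1 <- scan_tau(c(0, 40, 60), data, cfg, seed = derive_seed(77, "scan"))
  s2 <- scan_tau(c(0, 40, 60), data, cfg, seed = derive_seed(77, "scan"))
  expect_identical(s1$logliks, s2$logliks)
  expect_true(all(is.finite(s1$logliks)))
  expect_gt(s1$logliks[2], s1$logliks[1])
  expect_gt(s1$logliks[2], s1$logliks[3])
})

test_that("end-to-end inference recovers a short delay as short", {
  # data generated without any open-complex delay; the plug-in bound caps
  # the grid near lifetime/mean = 20 s and the estimate stays low
  data <- simulate_cells(60, transcription_params(tau1 = 0, tau2_mean = 62),
                         seed = derive_seed(88, "data"))
  post <- infer_tau(data, infer_config(tau_max = NULL, n_pairs = 2e4, grid_n = 7),
                    seed = derive_seed(88, "chains"))
  expect_lt(post$tau_max, 25)
  expect_lt(post$expected_value, 20)
  expect_error(infer_tau(matrix(numeric(0), 0, 0), infer_config(), seed = 1),
               "nonempty")
})
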
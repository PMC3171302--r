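test_that("propensities follow the combinatorial rate law", {
  pro <- reaction(c(Pro = 1), rate = 0.05)
  deg <- reaction(c(RNA = 1), rate = 1 / 600)
  dim_rx <- reaction(c(A = 2), rate = 0.5)
  birth <- reaction(rate = 3) # constitutive: no reactants

  st <- sim_state(c(Pro = 1, RNA = 0, A = 4))
  a <- compute_propensities(st, list(pro, deg, dim_rx, birth))
  expect_equal(a, c(0.05, 0, 0.5 * 4 * 3, 3))

  st2 <- sim_state(c(Pro = 0, RNA = 7, A = 1))
  expect_equal(compute_propensities(st2, list(pro, deg, dim_rx)),
               c(0, 7 / 600, 0))

  st_bad <- sim_state(c(RNA = 1))
  st_bad$counts[["RNA"]] <- -1L
  expect_error(compute_propensities(st_bad, list(deg)), "negative")
})

test_that("next-event draws have exponential waiting times and propensity-weighted channels", {
  set.seed(101)
  expect_null(draw_next_event(c(0, 0)))

  # single open channel is always chosen
  js <- replicate(50, draw_next_event(c(0, 2.0))$j)
  expect_true(all(js == 2L))

  n <- 1e5
  draws <- replicate(n, draw_next_event(c(1.0, 3.0)))
  frac_j2 <- mean(vapply(draws[2, ], identity, numeric(1)) == 2)
  expect_lt(abs(frac_j2 - 0.75), 0.01)

  dts <- replicate(n, draw_next_event(c(2.0))$dt)
  expect_lt(abs(mean(dts) - 0.5), 0.01)
})

test_that("single steps race the drawn reaction against the earliest release", {
  deg <- reaction(c(RNA = 1), rate = 0.1)

  # waitlist empty, only degradation open
  set.seed(7)
  st <- step_dssa(sim_state(c(RNA = 5)), list(deg))
  expect_equal(attr(st, "event"), "reaction")
  expect_equal(st$counts[["RNA"]], 4L)

  # pending release beats a reaction drawn to occur later; the draw is discarded
  st <- sim_state(c(RNA = 1))
  st$waitlist <- data.frame(release_time = 5, species = "RNA", count = 1L)
  slow <- reaction(c(RNA = 1), rate = 1e-9) # next reaction ~1e9 s away
  set.seed(1)
  st2 <- step_dssa(st, list(slow))
  expect_equal(attr(st2, "event"), "release")
  expect_equal(st2$t, 5)
  expect_equal(st2$counts[["RNA"]], 2L)
  expect_equal(nrow(st2$waitlist), 0L)

  # initiation consumes the promoter and parks two delayed products
  sys <- build_transcription_model(transcription_params())
  set.seed(2)
  st3 <- step_dssa(sim_state(c(Pro = 1, RNA = 0)), sys$reactions)
  expect_equal(attr(st3, "event"), "reaction")
  expect_equal(st3$counts[["Pro"]], 0L)
  expect_equal(st3$counts[["RNA"]], 0L)
  expect_equal(nrow(st3$waitlist), 2L)
  expect_setequal(st3$waitlist$species, c("Pro", "RNA"))
})

test_that("pure degradation absorbs at zero with exactly the initial number of events", {
  sys <- reaction_system(list(reaction(c(RNA = 1), rate = 0.1)), c(RNA = 5))
  set.seed(11)
  tr <- run_dssa(sys, t_end = 1e6)
  expect_equal(length(tr$time), 5L)
  expect_equal(unname(tr$final_counts[["RNA"]]), 0L)
  expect_true(all(diff(tr$time) > 0))
})

test_that("compiled runs reproduce the R reference stepper event for event", {
  sys <- build_transcription_model(transcription_params())
  t_end <- 2000

  set.seed(31)
  tr <- run_dssa(sys, t_end)

  set.seed(31)
  st <- sim_state(sys$initial_counts)
  times <- numeric(0); snap <- NULL
  repeat {
    st2 <- step_dssa(st, sys$reactions)
    if (attr(st2, "event") == "halt" || st2$t > t_end) break
    st <- st2
    times <- c(times, st$t)
    snap <- rbind(snap, st$counts[sys$species])
  }
  expect_equal(tr$time, times, tolerance = 1e-12)
  expect_equal(unname(tr$counts), unname(snap))
})

test_that("counts stay nonnegative and sampled values replay from the event log", {
  set.seed(21)
  pr <- sampling_protocol()
  tr <- run_dssa(build_transcription_model(transcription_params()), pr$t_end,
                 record = TRUE, sample_times = sample_times_of(pr))
  expect_true(all(tr$counts >= 0))
  expect_true(all(diff(tr$time) >= 0))
  replayed <- counts_at(tr, sample_times_of(pr), "RNA")[, 1]
  expect_equal(unname(tr$samples[, "RNA"]), replayed)
})

test_that("simultaneous releases come off the waitlist in insertion order", {
  both <- reaction(c(A = 1),
                   delayed = list(list(species = "B", count = 1L, delay = delay_spec(10)),
                                  list(species = "C", count = 1L, delay = delay_spec(10))),
                   rate = 100)
  sys <- reaction_system(list(both), c(A = 1, B = 0, C = 0))
  set.seed(5)
  tr <- run_dssa(sys, t_end = 100)
  rel <- which(tr$event == 0)
  expect_equal(length(rel), 2L)
  expect_equal(tr$time[rel[1]], tr$time[rel[2]])
  # B was pushed first, so it is released first
  expect_equal(unname(tr$counts[rel[1], c("B", "C")]), c(1L, 0L))
  expect_equal(unname(tr$counts[rel[2], c("B", "C")]), c(1L, 1L))
})

test_that("a saturated promoter cycles at the constant open-complex delay", {
  # k_t large: the exponential wait vanishes and initiations are ~40 s apart
  p <- transcription_params(k_t = 1000, tau1 = 40, tau2_mean = 102, tau2_sd = 14,
                            k_d = 0)
  sys <- build_transcription_model(p)
  set.seed(17)
  tr <- run_dssa(sys, t_end = 4010)
  gaps <- diff(tr$time[tr$event == 1])
  expect_equal(length(gaps) + 1, 100, tolerance = 0.05)
  expect_lt(abs(mean(gaps) - 40), 0.1)
})

test_that("steady-state production events occur at rate 1/(1/k_t + tau1)", {
  p <- transcription_params()
  sys <- build_transcription_model(p)
  set.seed(23)
  t_end <- 1.2e5
  tr <- run_dssa(sys, t_end)
  init_times <- tr$time[tr$event == 1]
  window <- init_times[init_times > 2e4]
  rate <- length(window) / (t_end - 2e4)
  expect_lt(abs(rate - 1 / 60), 5 * sqrt(length(window)) / (t_end - 2e4))
})

test_that("with delays removed the stationary law is Poisson (birth-death equivalence)", {
  sys <- reaction_system(list(reaction(products = c(X = 1), rate = 0.02),
                              reaction(c(X = 1), rate = 0.01)),
                         c(X = 0))
  x <- sparse_steady_samples(sys, n_samples = 2e4, spacing = 500, burn_in = 1000,
                             n_runs = 20, species = "X")
  emp <- tabulate(x + 1L, nbins = max(x) + 1) / length(x)
  expect_lt(tv_distance(emp, stats::dpois(0:max(x), 2)), 0.03)
})

test_that("gaussian delay draws are nonnegative and respect their moments", {
  set.seed(3)
  sd_big <- delay_spec(5, 10, "gaussian") # heavy truncation exercises the redraw
  draws <- replicate(4000, delaygene:::draw_one_delay(sd_big))
  expect_true(all(draws >= 0))
  # rejection sampling from N(5,10) restricted to [0, Inf): mean via closed form
  alpha <- -0.5
  m <- 5 + 10 * stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
  expect_lt(abs(mean(draws) - m), 0.5)
})
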
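test_that("the transcription system has the documented structure", {
  sys <- build_transcription_model(transcription_params())
  expect_s3_class(sys, "reaction_system")
  expect_length(sys$reactions, 2L)
  expect_setequal(sys$species, c("Pro", "RNA"))
  expect_equal(unname(sys$initial_counts[c("Pro", "RNA")]), c(1L, 0L))

  init <- sys$reactions[[1]]
  expect_equal(init$reactants, c(Pro = 1L))
  expect_length(init$delayed, 2L)
  expect_equal(init$delayed[[1]]$delay$kind, "constant")
  expect_equal(init$delayed[[2]]$delay$kind, "gaussian")

  expect_error(transcription_params(tau1 = 50, tau2_mean = 40), "tau2_mean")
})

test_that("the analytic stationary mean matches the renewal argument", {
  expect_equal(analytic_stationary_mean(transcription_params()), 10)
  # no promoter delay: plain birth-death mean
  expect_equal(analytic_stationary_mean(zero_delay_params(k_t = 0.02, k_d = 0.01)), 2)
  # saturated initiation: the cycle collapses to tau1
  expect_equal(analytic_stationary_mean(
    transcription_params(k_t = 1e9, tau1 = 40, tau2_mean = 102)), 15,
    tolerance = 1e-6)
  expect_equal(analytic_stationary_mean(transcription_params(k_t = 0)), 0)
})

test_that("series are read off the trajectory as a right-continuous step function", {
  pr <- sampling_protocol()
  # no events at all: all zero
  sys0 <- build_transcription_model(transcription_params(k_t = 0))
  set.seed(1)
  tr0 <- run_dssa(sys0, pr$t_end)
  expect_equal(unclass(sample_at_interval(tr0, pr)), rep(0L, 100),
               ignore_attr = TRUE)

  # a single production inside the window: zero before, one from then on
  fake <- structure(list(initial_counts = c(Pro = 1L, RNA = 0L),
                         species = c("Pro", "RNA"), t_end = 6000,
                         time = 3010, event = 0L,
                         counts = matrix(c(1L, 1L), 1, 2,
                                         dimnames = list(NULL, c("Pro", "RNA")))),
                    class = "dssa_trajectory")
  v <- sample_at_interval(fake, pr)
  expect_equal(unclass(v), c(0L, rep(1L, 99)), ignore_attr = TRUE)
  expect_length(v, 100L)
})

test_that("simulated cells are reproducible and match the analytic mean", {
  s1 <- simulate_cells(6, seed = 99)
  s2 <- simulate_cells(6, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(6L, 100L))

  s <- simulate_cells(400, seed = 17)
  se <- stats::sd(rowMeans(s)) / sqrt(nrow(s))
  expect_lt(abs(mean(s) - analytic_stationary_mean(transcription_params())), 4 * se)
})

test_that("shifting the completion-delay mean leaves the stationary law unchanged", {
  pr1 <- sampling_protocol(t_end = 3100, window_start = 3050, n_points = 1)
  a <- as.vector(simulate_cells(1200, transcription_params(), pr1, seed = 301))
  b <- as.vector(simulate_cells(1200, transcription_params(tau2_mean = 162), pr1,
                                seed = 302))
  expect_gt(counts_chisq_p(a, b), 1e-3)
  pooled_se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 4 * pooled_se)
})

test_that("the promoter delay lowers the stationary mean relative to the no-delay model", {
  pr1 <- sampling_protocol(t_end = 3100, window_start = 3050, n_points = 1)
  with_delay <- simulate_cells(300, transcription_params(), pr1, seed = 41)
  no_delay <- simulate_cells(300, transcription_params(tau1 = 0, tau2_mean = 62),
                             pr1, seed = 42)
  expect_lt(mean(with_delay), mean(no_delay) - 10) # 10 vs 30 expected
})

test_that("series survive a CSV round trip with metadata sidecar", {
  s <- simulate_cells(4, seed = 7)
  path <- file.path(withr::local_tempdir(), "series.csv")
  write_series_csv(s, path, params = transcription_params())
  back <- read_series_csv(path)
  expect_equal(unname(back), unname(unclass(s)), ignore_attr = TRUE)
  expect_equal(colnames(back), colnames(s))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  expect_equal(meta$n_cells, 4L)
  expect_equal(meta$params$tau1, 40)
})

test_that("model definitions load from YAML", {
  sys <- read_model_yaml(system.file("extdata", "transcription_model.yaml",
                                     package = "delaygene"))
  expect_length(sys$reactions, 2L)
  expect_equal(unname(sys$initial_counts["Pro"]), 1L)
  expect_equal(sys$reactions[[1]]$delayed[[2]]$delay$sd, 14)
  set.seed(1)
  tr <- run_dssa(sys, 500)
  expect_true(all(tr$counts >= 0))
})
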
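test_that("cohort simulation is deterministic under a fixed seed", {
  a <- quick_cohort(n_per_group = 3L, seed = 42L)
  b <- quick_cohort(n_per_group = 3L, seed = 42L)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$annotations, b$annotations)
  c2 <- quick_cohort(n_per_group = 3L, seed = 43L)
  expect_false(identical(a$recordings$sbp, c2$recordings$sbp))
})

test_that("simulated pressures are physiological and groups separated", {
  sim <- quick_cohort(n_per_group = 4L, seed = 13L)
  expect_true(all(sim$recordings$sbp > sim$recordings$dbp))
  parts <- sim$participants
  h <- parts[parts$group == "H-bBP", ]
  n <- parts[parts$group == "N-bBP", ]
  expect_gt(mean(h$baseline_mu_sbp), mean(n$baseline_mu_sbp))
  expect_gt(mean(h$baseline_mu_dbp), mean(n$baseline_mu_dbp))
})

test_that("a zero-noise zero-reactivity cohort is flat at the baseline mean", {
  cat30 <- scaled_catalog()
  cfg <- silent_config()
  sim <- simulate_cohort(cfg, cat30, make_playlists(cat30, 3, seed = 5))
  for (pid in unique(sim$recordings$participant_id)) {
    rec <- sim$recordings[sim$recordings$participant_id == pid, ]
    expect_equal(diff(range(rec$sbp)), 0)
    expect_equal(diff(range(rec$dbp)), 0)
  }
  summ <- summarize_cohort(sim)
  expect_true(all(abs(as.matrix(summ[bp_variables()])) < 1e-10))
})

test_that("configured reactivity is recovered from a large cohort", {
  cat30 <- scaled_catalog(10)
  cfg <- cohort_config(n_per_group = 200L, baseline_duration = 40,
                       gap_duration = 2, seed = 99L)
  pl <- make_playlists(cat30, 200, seed = 99)
  summ <- summarize_cohort(simulate_cohort(cfg, cat30, pl))
  for (g in c("H", "N")) {
    glab <- paste0(g, "-bBP")
    x <- summ$sys_mean[summ$group == glab]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$reactivity_mean_sbp[g]), 3 * se + 0.2)
    y <- summ$dia_mean[summ$group == glab]
    se_y <- stats::sd(y) / sqrt(length(y))
    expect_lt(abs(mean(y) - cfg$reactivity_mean_dbp[g]), 3 * se_y + 0.2)
  }
})

test_that("tempo coupling suppresses within-listen variability on fast tracks", {
  sim <- quick_cohort(n_per_group = 8L, seed = 31L,
                      tempo_variability_coupling = 0.4)
  summ <- summarize_cohort(sim)
  fast <- summ$version %in% c("V3", "V4")
  expect_lt(mean(summ$sys_sd[fast]), mean(summ$sys_sd[!fast]))
  expect_lt(mean(summ$sys_range[fast]), mean(summ$sys_range[!fast]))
  expect_lt(mean(summ$dia_sd[fast]), mean(summ$dia_sd[!fast]))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = 1), "at least 2")
  expect_error(cohort_config(tempo_variability_coupling = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(beat_noise_sd = -1), ">= 0")
  expect_error(cohort_config(baseline_mean_sbp = 80, baseline_mean_dbp = 90),
               "impossible")
})

test_that("cohort configs round-trip through YAML", {
  cfg <- cohort_config(n_per_group = 5L, loudness_effect = 2, seed = 77L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, f)
  back <- read_cohort_config(f)
  expect_equal(back$reactivity_mean_sbp, cfg$reactivity_mean_sbp)
  expect_equal(back$loudness_effect, 2)
  expect_equal(back$seed, 77L)
})

test_that("pressure waveforms peak at systole and trough at diastole", {
  beats <- data.frame(sbp = 120, dbp = 80, period = 1)
  wav <- generate_pressure_waveform(beats, sample_rate = 100)
  expect_equal(max(wav), 120, tolerance = 0.01)
  expect_equal(min(wav), 80, tolerance = 1e-6)
  expect_equal(length(wav), 100L)

  one <- generate_pressure_waveform(data.frame(sbp = 110, dbp = 70, period = 0.8),
                                    sample_rate = 50)
  expect_equal(length(one), 40L) # a single full cycle is emitted

  expect_error(generate_pressure_waveform(data.frame(sbp = 80, dbp = 90, period = 1)),
               "exceed")
  expect_error(generate_pressure_waveform(beats, sample_rate = 10), "20")
})

test_that("waveform delineation recovers the generating beats within 0.5 mmHg", {
  const <- generate_pressure_waveform(
    data.frame(sbp = rep(120, 5), dbp = rep(80, 5), period = rep(1, 5)), 100)
  det <- delineate_beats(const)
  expect_gte(nrow(det), 4L)
  expect_true(all(abs(det$sbp - 120) < 0.5))
  expect_true(all(abs(det$dbp - 80) < 0.5))

  set.seed(6)
  for (k in 1:3) {
    n <- sample(5:15, 1)
    beats <- data.frame(
      sbp = runif(n, 100, 160), dbp = runif(n, 60, 90),
      period = runif(n, 0.6, 1.2)
    )
    wav <- generate_pressure_waveform(beats, sample_rate = 200)
    det <- delineate_beats(wav)
    expect_equal(nrow(det), n)
    expect_true(all(abs(det$sbp - beats$sbp) < 0.5))
    expect_true(all(abs(det$dbp - beats$dbp) < 0.5))
  }

  expect_error(delineate_beats(rep(100, 500), sample_rate = 100), "no beats")
})
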
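# Shared fixtures: all data is generated in code at test time.

# Catalogue with durations scaled down for fast simulations.
scaled_catalog <- function(factor = 6) {
  cat30 <- track_catalog()
  cat30$duration_s <- pmax(10, cat30$duration_s / factor)
  cat30
}

# A small, fast cohort: short pieces, short baseline.
quick_cohort <- function(n_per_group = 4L, seed = 11L, ...) {
  cat30 <- scaled_catalog()
  cfg <- cohort_config(n_per_group = n_per_group, baseline_duration = 60,
                       gap_duration = 5, seed = seed, ...)
  pl <- make_playlists(cat30, n_playlists = n_per_group, seed = seed)
  simulate_cohort(cfg, cat30, pl)
}

# A noiseless, effect-free configuration: every music beat equals the
# participant baseline mean exactly.
silent_config <- function(n_per_group = 3L, seed = 5L) {
  cohort_config(
    n_per_group = n_per_group,
    baseline_between_subject_sd_sbp = 0, baseline_between_subject_sd_dbp = 0,
    reactivity_mean_sbp = 0, reactivity_mean_dbp = 0,
    reactivity_between_listen_sd_sbp = 0, reactivity_between_listen_sd_dbp = 0,
    beat_noise_sd = 0, drift_amplitude = 0,
    tempo_variability_coupling = 0, loudness_effect = 0,
    baseline_duration = 60, gap_duration = 5, seed = seed
  )
}

# Exact two-sided Mann-Whitney p by enumeration of all C(N, n1) labelings.
enum_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  N <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (N - n1) / 2
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(N, n1), 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Tie-corrected Kruskal-Wallis H computed from first principles.
direct_kw_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  rs <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) * sum(vapply(rs, sum, 1)^2 / lengths(groups)) - 3 * (N + 1)
  tie_tab <- table(values)
  h / (1 - sum(tie_tab^3 - tie_tab) / (N^3 - N))
}
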
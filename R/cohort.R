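#' Configuration for the synthetic listening cohort
#'
#' Defines the statistical structure of the simulated study: two groups of
#' `n_per_group` participants ("H-bBP" with baseline blood pressure above
#' 140/90 mmHg, "N-bBP" below), a silent baseline followed by a 9-track
#' playlist, group-specific BP elevation (reactivity) during music, and a
#' tempo-coupled suppression of within-listen BP variability.
#'
#' Defaults are calibrated to the published cohort statistics:
#' \itemize{
#'   \item baseline means 148.25/94.5 mmHg (H-bBP) and 123.0/78.35 (N-bBP);
#'     between-subject SDs derived from the 95\% CIs as
#'     half-width x sqrt(20) / t(0.975, 19);
#'   \item reactivity means 3.61/3.95 (H-bBP) and 10.12/9.38 (N-bBP) mmHg;
#'     between-listen SDs derived from the listen-level 95\% CIs (n = 180) as
#'     half-width x sqrt(180) / 1.96;
#'   \item beat noise and slow drift amplitudes chosen so within-listen SD
#'     and range match the reported magnitudes (about 5 and 21 mmHg systolic,
#'     3.8 and 16 diastolic); the slow drift dominates the white beat noise,
#'     as beat-to-beat BP is strongly autocorrelated;
#'   \item `tempo_variability_coupling` 0.18, matching the reported fast/slow
#'     within-listen SD ratio of about 0.82; `loudness_effect` 0 (the
#'     loudness null result).
#' }
#'
#' Per-group and per-channel fields accept a scalar (recycled), a length-2
#' vector (sbp, dbp) or, for group-wise fields, a 2x2 structure.
#'
#' @param n_per_group Participants per group (default 20).
#' @param baseline_mean_sbp,baseline_mean_dbp Named (`H`, `N`) baseline means, mmHg.
#' @param baseline_between_subject_sd_sbp,baseline_between_subject_sd_dbp
#'   Named (`H`, `N`) between-subject baseline SDs, mmHg.
#' @param reactivity_mean_sbp,reactivity_mean_dbp Named (`H`, `N`) mean BP
#'   elevation during music, mmHg.
#' @param reactivity_between_listen_sd_sbp,reactivity_between_listen_sd_dbp
#'   Named (`H`, `N`) SD of per-listen reactivity deviations, mmHg.
#' @param beat_noise_sd Beat-to-beat white-noise SD, mmHg; length-2 (sbp, dbp)
#'   or scalar.
#' @param drift_amplitude Amplitude of the slow physiological drift, mmHg;
#'   length-2 (sbp, dbp) or scalar.
#' @param tempo_variability_coupling In [0, 1]: drift amplitude and beat-noise
#'   SD are multiplied by (1 - coupling) during tempo-altered (fast) tracks.
#' @param loudness_effect Additive BP shift (mmHg) during loud versions
#'   (V2/V4); default 0.
#' @param heart_rate Beats per minute of the simulated pulse (default 70).
#' @param baseline_duration Silent baseline length, seconds (default 300).
#' @param gap_duration Unlabelled inter-piece question period, seconds.
#' @param seed Integer master seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 20L,
                          baseline_mean_sbp = c(H = 148.25, N = 123.0),
                          baseline_mean_dbp = c(H = 94.5, N = 78.35),
                          baseline_between_subject_sd_sbp = c(H = 14.23, N = 8.87),
                          baseline_between_subject_sd_dbp = c(H = 6.65, N = 6.71),
                          reactivity_mean_sbp = c(H = 3.61, N = 10.12),
                          reactivity_mean_dbp = c(H = 3.95, N = 9.38),
                          reactivity_between_listen_sd_sbp = c(H = 15.33, N = 16.53),
                          reactivity_between_listen_sd_dbp = c(H = 12.22, N = 12.36),
                          beat_noise_sd = c(sbp = 2.0, dbp = 1.5),
                          drift_amplitude = c(sbp = 12, dbp = 9),
                          tempo_variability_coupling = 0.18,
                          loudness_effect = 0,
                          heart_rate = 70,
                          baseline_duration = 300,
                          gap_duration = 20,
                          seed = 20251L) {
  pair <- function(x, what) {
    x <- unlist(x)
    if (length(x) == 1L) x <- c(H = unname(x), N = unname(x))
    if (length(x) != 2L) stopf("%s must have 1 or 2 values", what)
    if (is.null(names(x)) || !all(c("H", "N") %in% names(x))) names(x) <- c("H", "N")
    x[c("H", "N")]
  }
  chan <- function(x, what) {
    x <- unlist(x)
    if (length(x) == 1L) x <- c(sbp = unname(x), dbp = unname(x))
    if (length(x) != 2L) stopf("%s must have 1 or 2 values", what)
    if (is.null(names(x)) || !all(c("sbp", "dbp") %in% names(x))) names(x) <- c("sbp", "dbp")
    x[c("sbp", "dbp")]
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    baseline_mean_sbp = pair(baseline_mean_sbp, "baseline_mean_sbp"),
    baseline_mean_dbp = pair(baseline_mean_dbp, "baseline_mean_dbp"),
    baseline_between_subject_sd_sbp = pair(baseline_between_subject_sd_sbp, "baseline_between_subject_sd_sbp"),
    baseline_between_subject_sd_dbp = pair(baseline_between_subject_sd_dbp, "baseline_between_subject_sd_dbp"),
    reactivity_mean_sbp = pair(reactivity_mean_sbp, "reactivity_mean_sbp"),
    reactivity_mean_dbp = pair(reactivity_mean_dbp, "reactivity_mean_dbp"),
    reactivity_between_listen_sd_sbp = pair(reactivity_between_listen_sd_sbp, "reactivity_between_listen_sd_sbp"),
    reactivity_between_listen_sd_dbp = pair(reactivity_between_listen_sd_dbp, "reactivity_between_listen_sd_dbp"),
    beat_noise_sd = chan(beat_noise_sd, "beat_noise_sd"),
    drift_amplitude = chan(drift_amplitude, "drift_amplitude"),
    tempo_variability_coupling = tempo_variability_coupling,
    loudness_effect = loudness_effect,
    heart_rate = heart_rate,
    baseline_duration = baseline_duration,
    gap_duration = gap_duration,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_per_group < 2L) stopf("n_per_group must be at least 2")
  sds <- c(cfg$baseline_between_subject_sd_sbp, cfg$baseline_between_subject_sd_dbp,
           cfg$reactivity_between_listen_sd_sbp, cfg$reactivity_between_listen_sd_dbp,
           cfg$beat_noise_sd, cfg$drift_amplitude)
  if (any(sds < 0)) stopf("all SDs and amplitudes must be >= 0")
  if (cfg$tempo_variability_coupling < 0 || cfg$tempo_variability_coupling > 1) {
    stopf("tempo_variability_coupling must lie in [0, 1]")
  }
  if (any(cfg$baseline_mean_dbp >= cfg$baseline_mean_sbp)) {
    stopf("impossible config: diastolic baseline mean >= systolic baseline mean")
  }
  if (cfg$heart_rate <= 0 || cfg$baseline_duration <= 0 || cfg$gap_duration < 0) {
    stopf("heart_rate and baseline_duration must be positive, gap_duration >= 0")
  }
  invisible(cfg)
}

#' Read / write a cohort configuration as YAML
#'
#' @param path YAML file.
#' @return For the reader, a `cohort_config`; the writer returns `path`
#'   invisibly.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

# slow smooth drift: fixed period mix, random phases per participant/channel
drift_wave <- function(t, amplitude, phases) {
  amplitude * (0.5 * sin(2 * pi * t / 150 + phases[1L]) +
               0.3 * sin(2 * pi * t / 75 + phases[2L]) +
               0.2 * sin(2 * pi * t / 40 + phases[3L]))
}

#' Simulate beat-to-beat BP recordings for a two-group listening cohort
#'
#' Generates, for each participant, a continuous beat-resolved systolic and
#' diastolic BP recording covering a silent baseline, nine music listens with
#' unlabelled question gaps in between. Beat values are
#' participant baseline mean + slow drift + white beat noise, plus (during
#' music) the group reactivity and a per-listen deviation; during
#' tempo-altered (fast) tracks, drift and beat noise are damped by
#' (1 - coupling), and fast tracks are shorter because their catalogue
#' duration is the source duration divided by the tempo factor. Loud versions
#' (V2/V4) additionally receive `loudness_effect` (0 by default).
#'
#' Both groups hear the same playlists: participant i of each group is paired
#' with playlist i.
#'
#' @param config A [cohort_config()].
#' @param catalog Catalogue tibble from [track_catalog()] (metadata columns
#'   suffice; durations drive listen lengths).
#' @param playlists Playlist tibble from [make_playlists()], at least
#'   `n_per_group` playlists.
#' @return List of class `bp_cohort` with elements `recordings` (tibble
#'   `participant_id`, `group`, `time_s`, `sbp`, `dbp`), `annotations`
#'   (tibble `participant_id`, `segment`, `piece_id`, `version`, `start_s`,
#'   `end_s`; the baseline segment is labelled `"baseline"`), `participants`
#'   (with true per-participant baseline means) and `config`.
#' @export
simulate_cohort <- function(config, catalog = track_catalog(),
                            playlists = NULL) {
  validate_cohort_config(config)
  if (is.null(playlists)) {
    playlists <- make_playlists(catalog, n_playlists = config$n_per_group,
                                seed = derive_seed(config$seed, 777L))
  }
  n_pl <- length(unique(playlists$playlist_id))
  if (n_pl < config$n_per_group) {
    stopf("need at least %d playlists, got %d", config$n_per_group, n_pl)
  }
  key <- paste(playlists$piece_id, playlists$version)
  bad <- setdiff(key, paste(catalog$piece_id, catalog$version))
  if (length(bad)) stopf("playlist track(s) not in catalog: %s", paste(unique(bad), collapse = ", "))

  cat_key <- paste(catalog$piece_id, catalog$version)
  ibi <- 60 / config$heart_rate
  cpl <- config$tempo_variability_coupling

  recs <- vector("list", 2L * config$n_per_group)
  anns <- vector("list", 2L * config$n_per_group)
  parts <- vector("list", 2L * config$n_per_group)
  idx <- 0L
  for (grp in c("H", "N")) {
    group_label <- if (grp == "H") "H-bBP" else "N-bBP"
    for (i in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      pid <- sprintf("%s_%02d", grp, i)
      with_seed(derive_seed(config$seed, idx), {
        mu_s <- stats::rnorm(1, config$baseline_mean_sbp[grp],
                             config$baseline_between_subject_sd_sbp[grp])
        mu_d <- stats::rnorm(1, config$baseline_mean_dbp[grp],
                             config$baseline_between_subject_sd_dbp[grp])
        mu_d <- min(mu_d, mu_s - 20) # keep the participant physiological
        ph_s <- stats::runif(3, 0, 2 * pi)
        ph_d <- stats::runif(3, 0, 2 * pi)

        pl <- playlists[playlists$playlist_id == sort(unique(playlists$playlist_id))[i], ]
        pl <- pl[order(pl$position), ]
        tr <- match(paste(pl$piece_id, pl$version), cat_key)
        durs <- catalog$duration_s[tr]
        starts <- config$baseline_duration +
          cumsum(c(config$gap_duration, utils::head(durs + config$gap_duration, -1L)))
        ends <- starts + durs
        ann <- tibble::tibble(
          participant_id = pid,
          segment = c("baseline", paste0(pl$piece_id, ":", pl$version, ":", pl$position)),
          piece_id = c(NA_character_, pl$piece_id),
          version = c(NA_character_, pl$version),
          position = c(NA_integer_, pl$position),
          start_s = c(0, starts),
          end_s = c(config$baseline_duration, ends)
        )

        total <- max(ends)
        t <- seq(0, total, by = ibi)
        n <- length(t)

        seg_idx <- findInterval(t, starts) # 0 before first piece
        in_piece <- seg_idx >= 1L & seg_idx <= length(durs) & t < ends[pmax(seg_idx, 1L)]
        fast <- in_piece & catalog$tempo_altered[tr][pmax(seg_idx, 1L)]
        loud <- in_piece & pl$version[pmax(seg_idx, 1L)] %in% c("V2", "V4")
        damp <- ifelse(fast, 1 - cpl, 1)

        dev_s <- stats::rnorm(length(durs), 0, config$reactivity_between_listen_sd_sbp[grp])
        dev_d <- stats::rnorm(length(durs), 0, config$reactivity_between_listen_sd_dbp[grp])

        react_s <- ifelse(in_piece,
                          config$reactivity_mean_sbp[grp] + dev_s[pmax(seg_idx, 1L)], 0)
        react_d <- ifelse(in_piece,
                          config$reactivity_mean_dbp[grp] + dev_d[pmax(seg_idx, 1L)], 0)
        loud_add <- ifelse(loud, config$loudness_effect, 0)

        sbp <- mu_s + react_s + loud_add +
          damp * (drift_wave(t, config$drift_amplitude["sbp"], ph_s) +
                    stats::rnorm(n, 0, config$beat_noise_sd["sbp"]))
        dbp <- mu_d + react_d + loud_add +
          damp * (drift_wave(t, config$drift_amplitude["dbp"], ph_d) +
                    stats::rnorm(n, 0, config$beat_noise_sd["dbp"]))
        dbp <- pmin(dbp, sbp - 1) # invariant: systolic above diastolic

        recs[[idx]] <- tibble::tibble(
          participant_id = pid, group = group_label, time_s = t,
          sbp = sbp, dbp = dbp
        )
        anns[[idx]] <- dplyr::mutate(ann, group = group_label)
        parts[[idx]] <- tibble::tibble(
          participant_id = pid, group = group_label,
          playlist_id = pl$playlist_id[1L],
          baseline_mu_sbp = mu_s, baseline_mu_dbp = mu_d
        )
      })
    }
  }
  structure(
    list(
      recordings = dplyr::bind_rows(recs),
      annotations = dplyr::bind_rows(anns),
      participants = dplyr::bind_rows(parts),
      config = config
    ),
    class = "bp_cohort"
  )
}

#' Render a beat sequence as a continuous arterial pressure waveform
#'
#' Stand-in for a continuous noninvasive arterial pressure (CNAP) channel:
#' each cardiac cycle is a raised-cosine pulse rising from the diastolic
#' trough to the systolic peak and back, so the waveform maximum per cycle is
#' the systolic value and the minimum the diastolic value (within one
#' sample's interpolation error; the pulse has zero slope at trough and peak,
#' which keeps that error quadratic in the sampling interval).
#'
#' @param beats Data frame with columns `sbp`, `dbp` (mmHg) and `period`
#'   (seconds per cycle), one row per beat.
#' @param sample_rate Sampling rate in Hz, at least 20.
#' @return Numeric waveform vector with attribute `rate`.
#' @export
generate_pressure_waveform <- function(beats, sample_rate = 100) {
  if (!all(c("sbp", "dbp", "period") %in% names(beats))) {
    stopf("beats need columns sbp, dbp, period")
  }
  if (nrow(beats) == 0L) stopf("no beats supplied")
  if (any(beats$sbp <= beats$dbp)) stopf("sbp must exceed dbp for every beat")
  if (any(beats$period <= 0)) stopf("periods must be positive")
  if (sample_rate < 20) stopf("sample_rate must be at least 20 Hz")
  t0 <- c(0, cumsum(beats$period))
  total <- t0[length(t0)]
  t <- seq(0, total - 1 / sample_rate, by = 1 / sample_rate)
  cyc <- findInterval(t, t0, rightmost.closed = TRUE)
  x <- (t - t0[cyc]) / beats$period[cyc]
  # raised-cosine pulse: min 0 at x in {0,1}, max 1 at mid-cycle
  shape <- sin(pi * pmin(pmax(x, 0), 1))^2
  wav <- beats$dbp[cyc] + (beats$sbp[cyc] - beats$dbp[cyc]) * shape
  attr(wav, "rate") <- sample_rate
  wav
}

#' Delineate a pressure waveform into per-cycle systolic/diastolic values
#'
#' Segments the waveform trough-to-trough (local minima, including the
#' endpoints when they are troughs) and reports each cycle's maximum as the
#' systolic and minimum as the diastolic value.
#'
#' @param waveform Numeric waveform (e.g. from
#'   [generate_pressure_waveform()]).
#' @param sample_rate Sampling rate in Hz; defaults to the waveform's `rate`
#'   attribute.
#' @return Tibble with `sbp`, `dbp` per detected cycle and the onset time
#'   `t_s`; the number of cycles is `nrow()`.
#' @export
delineate_beats <- function(waveform, sample_rate = attr(waveform, "rate")) {
  v <- as.numeric(waveform)
  if (is.null(sample_rate)) stopf("sample_rate must be supplied")
  if (length(v) < 3L) stopf("waveform shorter than one cycle")
  if (max(v) - min(v) < 1e-9) stopf("no beats detected: flat-line signal")
  n <- length(v)
  interior <- which(v[2:(n - 1)] <= v[1:(n - 2)] & v[2:(n - 1)] < v[3:n]) + 1L
  troughs <- interior
  if (v[1L] < v[2L]) troughs <- c(1L, troughs)
  if (v[n] <= v[n - 1L]) troughs <- c(troughs, n)
  troughs <- sort(unique(troughs))
  # drop spurious minima closer than 3 samples
  if (length(troughs) > 1L) troughs <- troughs[c(TRUE, diff(troughs) >= 3L)]
  if (length(troughs) < 2L) stopf("no beats detected")
  cycles <- lapply(seq_len(length(troughs) - 1L), function(k) {
    span <- troughs[k]:troughs[k + 1L]
    # boundary trough samples can sit a fraction of a sample inside the
    # neighbouring cycle; the interior minimum is this cycle's diastole
    interior <- (troughs[k] + 1L):(troughs[k + 1L] - 1L)
    tibble::tibble(
      t_s = (troughs[k] - 1L) / sample_rate,
      sbp = max(v[span]),
      dbp = min(v[interior])
    )
  })
  dplyr::bind_rows(cycles)
}

#' Write a simulated cohort to per-participant CSV files
#'
#' One CSV per participant with columns
#' `time_s,segment,piece,version,sbp_mmHg,dbp_mmHg` (segment is `baseline`,
#' the piece id, or empty for unlabelled question gaps), plus a JSON manifest
#' recording the seed and playlist assignments.
#'
#' @param cohort A `bp_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (pid in unique(cohort$recordings$participant_id)) {
    rec <- cohort$recordings[cohort$recordings$participant_id == pid, ]
    ann <- cohort$annotations[cohort$annotations$participant_id == pid, ]
    seg_i <- findInterval(rec$time_s, ann$start_s)
    inside <- seg_i >= 1L & rec$time_s < ann$end_s[pmax(seg_i, 1L)]
    seg <- ifelse(inside, ifelse(is.na(ann$piece_id[pmax(seg_i, 1L)]), "baseline",
                                 ann$piece_id[pmax(seg_i, 1L)]), "")
    ver <- ifelse(inside, ann$version[pmax(seg_i, 1L)], NA_character_)
    f <- file.path(dir, paste0(pid, ".csv"))
    utils::write.csv(
      data.frame(time_s = rec$time_s, segment = seg,
                 piece = ifelse(seg %in% c("baseline", ""), "", seg),
                 version = ifelse(is.na(ver), "", ver),
                 sbp_mmHg = rec$sbp, dbp_mmHg = rec$dbp),
      f, row.names = FALSE, quote = FALSE
    )
    files <- c(files, f)
  }
  manifest <- list(
    seed = cohort$config$seed,
    n_per_group = cohort$config$n_per_group,
    participants = cohort$participants[, c("participant_id", "group", "playlist_id")]
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(files, mf))
}
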
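#' Tempo feature summary from beat annotations
#'
#' Instantaneous tempo is 60 / inter-beat interval (bpm) for each consecutive
#' beat pair; the summary reports its mean, sample standard deviation (n-1)
#' and maximum.
#'
#' @param beat_times Strictly increasing numeric vector of beat times
#'   (seconds), at least 3 beats.
#' @return Tibble row with `mean`, `sd`, `maximum` (bpm) and `n_samples`.
#' @export
#' @examples
#' tempo_summary(c(0, 1, 1.5, 2.5)) # instantaneous 60, 120, 60 bpm
tempo_summary <- function(beat_times) {
  if (length(beat_times) < 3L) stopf("need at least 3 beat times, got %d", length(beat_times))
  ibi <- diff(beat_times)
  if (any(ibi <= 0)) stopf("beat times must be strictly increasing")
  inst <- 60 / ibi
  tibble::tibble(
    mean = mean(inst),
    sd = stats::sd(inst),
    maximum = max(inst),
    n_samples = length(inst)
  )
}

#' Loudness feature summary from a continuous sone series
#'
#' @param series Non-empty numeric vector of non-negative loudness values in
#'   sones (uniformly sampled).
#' @return Tibble row with `mean`, `sd`, `maximum` (sones) and `n_samples`.
#' @export
loudness_summary <- function(series) {
  if (length(series) == 0L) stopf("loudness series is empty")
  if (any(series < 0)) stopf("loudness values must be non-negative")
  tibble::tibble(
    mean = mean(series),
    sd = if (length(series) > 1L) stats::sd(series) else 0,
    maximum = max(series),
    n_samples = length(series)
  )
}

#' Convert loudness in sones to A-weighted decibels
#'
#' Uses the psychoacoustic mapping dBA = 33.2 * log10(sones) + 28, a strictly
#' increasing function of loudness.
#'
#' @param s Numeric vector of loudness values in sones, all > 0.
#' @return Numeric vector of dBA values.
#' @export
#' @examples
#' sones_to_dba(c(1, 10, 100)) # 28, 61.2, 94.4
sones_to_dba <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0)) stopf("sones must be positive")
  33.2 * log10(s) + 28
}

#' Define a tertile scheme for a track feature summary
#'
#' @param feature `"tempo"` or `"loudness"`.
#' @param statistic `"mean"`, `"sd"` or `"max"` (maxima serve as the "range"
#'   index for track features).
#' @param mode `"fixed_thresholds"` (cut at two supplied feature values) or
#'   `"equal_split"` (10/10/10-style split of a count divisible by 3).
#' @param thresholds Length-2 strictly increasing numeric cut points, required
#'   for `fixed_thresholds`.
#' @return A `tertile_scheme` list.
#' @export
tertile_scheme <- function(feature = c("tempo", "loudness"),
                           statistic = c("mean", "sd", "max"),
                           mode = c("fixed_thresholds", "equal_split"),
                           thresholds = NULL) {
  feature <- match.arg(feature)
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (mode == "fixed_thresholds") {
    if (is.null(thresholds) || length(thresholds) != 2L || diff(thresholds) <= 0) {
      stopf("fixed_thresholds mode needs 2 strictly increasing thresholds")
    }
  }
  structure(
    list(feature = feature, statistic = statistic, mode = mode,
         thresholds = thresholds),
    class = "tertile_scheme"
  )
}

#' Assign tracks to low/mid/high tertiles
#'
#' With fixed thresholds t1 < t2: low is value < t1, high is value > t2, mid
#' otherwise (boundary values fall in the middle group). With `equal_split`,
#' tracks are stably sorted by (value, track id) and cut at positions n/3 and
#' 2n/3; ties straddling a cut are broken by track id with a warning.
#'
#' @param values Named numeric vector (names are track ids) or a tibble with
#'   columns `track_id` and `value`.
#' @param scheme A [tertile_scheme()].
#' @return Tibble with `track_id`, `value`, `tertile` (factor low/mid/high);
#'   group sizes in attribute `sizes`.
#' @export
assign_tertiles <- function(values, scheme) {
  if (!inherits(scheme, "tertile_scheme")) stopf("scheme must be a tertile_scheme")
  if (is.numeric(values)) {
    values <- tibble::tibble(track_id = names(values), value = unname(values))
  }
  if (is.null(values$track_id)) stopf("values need track ids")
  n <- nrow(values)
  if (scheme$mode == "equal_split") {
    if (n %% 3L != 0L) stopf("equal_split needs a track count divisible by 3, got %d", n)
    ord <- order(values$value, values$track_id)
    cut1 <- n %/% 3L
    cut2 <- 2L * n %/% 3L
    sorted <- values$value[ord]
    if (sorted[cut1] == sorted[cut1 + 1L] || sorted[cut2] == sorted[cut2 + 1L]) {
      warning("ties straddle an equal-split cut; broken by track id", call. = FALSE)
    }
    tert <- character(n)
    tert[ord[seq_len(cut1)]] <- "low"
    tert[ord[(cut1 + 1L):cut2]] <- "mid"
    tert[ord[(cut2 + 1L):n]] <- "high"
  } else {
    t1 <- scheme$thresholds[1L]
    t2 <- scheme$thresholds[2L]
    tert <- ifelse(values$value < t1, "low", ifelse(values$value > t2, "high", "mid"))
  }
  out <- tibble::tibble(
    track_id = values$track_id,
    value = values$value,
    tertile = factor(tert, levels = c("low", "mid", "high"))
  )
  attr(out, "sizes") <- table(out$tertile)
  out
}

#' Default tertile schemes for the six feature indices
#'
#' Mean indices use the study's fixed cut points (tempo 60/120 bpm; loudness
#' 12.72/16.48 sones). SD and maximum indices default to equal 10/10/10
#' splits of the catalogue; the corresponding published cut points (tempo sd
#' 11/27.7, tempo max 87/210 bpm; loudness sd 4.72/6, loudness max 37.5/47
#' sones) are kept in the scheme table for use with `mode = "fixed_thresholds"`.
#'
#' @param mode_sd_max Mode used for the sd/max schemes, `"equal_split"`
#'   (default) or `"fixed_thresholds"`.
#' @return Tibble with columns `scheme_id`, `feature`, `statistic`, and a
#'   list-column `scheme`.
#' @export
default_tertile_schemes <- function(mode_sd_max = c("equal_split", "fixed_thresholds")) {
  mode_sd_max <- match.arg(mode_sd_max)
  defs <- tibble::tribble(
    ~scheme_id,      ~feature,   ~statistic, ~t1,    ~t2,
    "tempo_mean",    "tempo",    "mean",     60,     120,
    "tempo_sd",      "tempo",    "sd",       11,     27.7,
    "tempo_max",     "tempo",    "max",      87,     210,
    "loudness_mean", "loudness", "mean",     12.72,  16.48,
    "loudness_sd",   "loudness", "sd",       4.72,   6,
    "loudness_max",  "loudness", "max",      37.5,   47
  )
  defs$scheme <- lapply(seq_len(nrow(defs)), function(i) {
    mode <- if (defs$statistic[i] == "mean") "fixed_thresholds" else mode_sd_max
    tertile_scheme(defs$feature[i], defs$statistic[i], mode,
                   thresholds = c(defs$t1[i], defs$t2[i]))
  })
  defs[, c("scheme_id", "feature", "statistic", "scheme")]
}

#' Compute the per-track feature table for a stimulus set
#'
#' For each track version: tempo summaries from the beat grid and loudness
#' summaries from the sone series (see [build_stimulus_set()]). Synthetic
#' performances are normalised so the mean statistics equal the catalogue's
#' printed mean bpm / mean sones.
#'
#' @param stimuli Catalogue with `beat_times` and `loudness_series`
#'   list-columns, from [build_stimulus_set()].
#' @return Long tibble `piece_id`, `version`, `track_id`, `feature`,
#'   `statistic`, `value`.
#' @export
feature_table <- function(stimuli) {
  if (is.null(stimuli$beat_times) || is.null(stimuli$loudness_series)) {
    stopf("stimuli must carry beat_times and loudness_series (see build_stimulus_set)")
  }
  rows <- lapply(seq_len(nrow(stimuli)), function(i) {
    tem <- tempo_summary(stimuli$beat_times[[i]])
    lou <- loudness_summary(stimuli$loudness_series[[i]])
    tibble::tibble(
      piece_id = stimuli$piece_id[i],
      version = stimuli$version[i],
      track_id = paste(stimuli$piece_id[i], stimuli$version[i], sep = ":"),
      feature = rep(c("tempo", "loudness"), each = 3L),
      statistic = rep(c("mean", "sd", "max"), 2L),
      value = c(tem$mean, tem$sd, tem$maximum, lou$mean, lou$sd, lou$maximum)
    )
  })
  dplyr::bind_rows(rows)
}

#' Assign every track to a tertile under each scheme
#'
#' @param features Feature table from [feature_table()].
#' @param schemes Scheme table from [default_tertile_schemes()].
#' @return Tibble `scheme_id`, `feature`, `statistic`, `piece_id`, `version`,
#'   `track_id`, `value`, `tertile`.
#' @export
track_tertiles <- function(features, schemes = default_tertile_schemes()) {
  rows <- lapply(seq_len(nrow(schemes)), function(i) {
    sub <- features[features$feature == schemes$feature[i] &
                      features$statistic == schemes$statistic[i], ]
    asg <- assign_tertiles(
      tibble::tibble(track_id = sub$track_id, value = sub$value),
      schemes$scheme[[i]]
    )
    dplyr::mutate(
      dplyr::left_join(asg, sub[, c("track_id", "piece_id", "version")],
                       by = "track_id"),
      scheme_id = schemes$scheme_id[i],
      feature = schemes$feature[i],
      statistic = schemes$statistic[i]
    )
  })
  dplyr::bind_rows(rows)
}
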
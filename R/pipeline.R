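#' Segment a beat-level recording by annotated intervals
#'
#' Assigns each beat to the half-open interval `[start_s, end_s)` containing
#' its time; beats outside every interval (question gaps, run-in/out) are
#' dropped and counted. A beat exactly on a boundary belongs to the segment
#' that starts there.
#'
#' @param recording Tibble with at least `time_s`, `sbp`, `dbp` for one
#'   participant.
#' @param annotations Tibble with `segment`, `start_s`, `end_s` (non-
#'   overlapping, within the recording span) and optional `piece_id`,
#'   `version`, `position` columns carried through.
#' @return The recording restricted to annotated beats, with the annotation
#'   columns bound; attribute `n_dropped` counts discarded beats and empty
#'   segments are listed in attribute `empty_segments`.
#' @export
segment_by_piece <- function(recording, annotations) {
  ann <- annotations[order(annotations$start_s), , drop = FALSE]
  if (any(ann$end_s <= ann$start_s)) stopf("annotation intervals must have end > start")
  if (nrow(ann) > 1L && any(ann$start_s[-1L] < ann$end_s[-nrow(ann)])) {
    stopf("annotation intervals overlap")
  }
  i <- findInterval(recording$time_s, ann$start_s)
  inside <- i >= 1L & recording$time_s < ann$end_s[pmax(i, 1L)]
  out <- recording[inside, , drop = FALSE]
  ai <- i[inside]
  out$segment <- ann$segment[ai]
  for (col in intersect(c("piece_id", "version", "position"), names(ann))) {
    out[[col]] <- ann[[col]][ai]
  }
  empty <- setdiff(ann$segment, out$segment)
  attr(out, "n_dropped") <- sum(!inside)
  attr(out, "empty_segments") <- empty
  out
}

#' Baseline-normalise BP values
#'
#' Subtracts the mean of the baseline values from every segment value. A pure
#' shift: the SD and range of the segment are unchanged.
#'
#' @param segment_values Numeric vector, mmHg.
#' @param baseline_values Non-empty numeric vector of baseline beats, mmHg.
#' @return Numeric deltas from the baseline mean, mmHg.
#' @export
baseline_normalize <- function(segment_values, baseline_values) {
  if (length(baseline_values) == 0L) stopf("baseline is empty")
  segment_values - mean(baseline_values)
}

#' Summarise one listen into the six analysis variables
#'
#' Mean, sample standard deviation and range (max - min) of the
#' baseline-normalised systolic and diastolic beat series.
#'
#' @param sys Normalised systolic deltas, mmHg (>= 2 beats).
#' @param dia Normalised diastolic deltas, mmHg (same length).
#' @return Tibble row `sys_mean`, `dia_mean`, `sys_sd`, `dia_sd`,
#'   `sys_range`, `dia_range`, `n_beats`.
#' @export
summarize_listen <- function(sys, dia) {
  if (length(sys) < 2L || length(dia) < 2L) {
    stopf("need at least 2 beats per channel to summarise a listen")
  }
  if (length(sys) != length(dia)) stopf("systolic and diastolic series differ in length")
  tibble::tibble(
    sys_mean = mean(sys), dia_mean = mean(dia),
    sys_sd = stats::sd(sys), dia_sd = stats::sd(dia),
    sys_range = value_range(sys), dia_range = value_range(dia),
    n_beats = length(sys)
  )
}

#' Six analysis variable names
#' @return Character vector of the per-listen variable names.
#' @export
bp_variables <- function() {
  c("sys_mean", "dia_mean", "sys_sd", "dia_sd", "sys_range", "dia_range")
}

#' Segment, normalise and summarise a whole simulated cohort
#'
#' For every participant: segments the recording by the annotation intervals,
#' computes the baseline means from the `"baseline"` segment, subtracts them
#' from every music beat, and emits one [summarize_listen()] row per listen.
#'
#' @param cohort A `bp_cohort` from [simulate_cohort()], or a list with
#'   compatible `recordings` and `annotations`.
#' @param min_beats Minimum beats for a listen to be summarised (default 2);
#'   shorter segments are flagged and skipped.
#' @return Tibble with the listen key (`participant_id`, `group`, `piece_id`,
#'   `version`, `position`), the six variables, `n_beats`, and baseline beat
#'   counts. Participant baseline means are kept in attribute `baselines`.
#' @export
summarize_cohort <- function(cohort, min_beats = 2L) {
  recs <- cohort$recordings
  anns <- cohort$annotations
  out <- list()
  bases <- list()
  for (pid in unique(recs$participant_id)) {
    rec <- recs[recs$participant_id == pid, ]
    ann <- anns[anns$participant_id == pid, ]
    seg <- segment_by_piece(rec, ann)
    base <- seg[seg$segment == "baseline", ]
    if (nrow(base) == 0L) stopf("participant %s has no baseline segment", pid)
    mu_s <- mean(base$sbp)
    mu_d <- mean(base$dbp)
    bases[[pid]] <- tibble::tibble(
      participant_id = pid, group = rec$group[1L],
      baseline_sys_mean = mu_s, baseline_dia_mean = mu_d,
      n_baseline_beats = nrow(base)
    )
    music <- seg[seg$segment != "baseline", ]
    for (sg in unique(music$segment)) {
      m <- music[music$segment == sg, ]
      if (nrow(m) < min_beats) next
      s <- summarize_listen(
        baseline_normalize(m$sbp, base$sbp),
        baseline_normalize(m$dbp, base$dbp)
      )
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          participant_id = pid, group = rec$group[1L],
          piece_id = m$piece_id[1L], version = m$version[1L],
          position = m$position[1L]
        ), s
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "baselines") <- dplyr::bind_rows(bases)
  res
}

#' Build the comparison datasets for the statistical battery
#'
#' Expands per-listen summaries into every grouping the analysis design
#' tests, for all six variables:
#' \itemize{
#'   \item between-group (H-bBP vs N-bBP): overall; per version V1-V4
#'     (excluding tracks flagged `excluded_from_version_comparison`); the
#'     slow (V1+V2) vs fast (V3+V4) and quiet (V1+V3) vs loud (V2+V4)
#'     aggregates; and each tertile subgroup of each scheme;
#'   \item within-group: Kruskal-Wallis sets over versions (same exclusions)
#'     and over each scheme's tertiles; two-level Mann-Whitney contrasts
#'     slow vs fast and quiet vs loud.
#' }
#'
#' @param summaries Listen summaries from [summarize_cohort()].
#' @param catalog Catalogue tibble (for exclusion flags).
#' @param tertiles Track tertile assignments from [track_tertiles()], or
#'   `NULL` to skip tertile datasets.
#' @return Tibble with one row per (comparison, scope, variable): `comparison`
#'   label, `scope` (`"between-group"` or the participant group), `test`
#'   (`"mwu"` or `"kw"`), `variable`, and `data`, a list-column of named
#'   value-vector lists (one vector per level).
#' @export
build_comparison_datasets <- function(summaries, catalog = track_catalog(),
                                      tertiles = NULL) {
  key <- paste(summaries$piece_id, summaries$version)
  cat_key <- paste(catalog$piece_id, catalog$version)
  unknown <- setdiff(key, cat_key)
  if (length(unknown)) stopf("unknown track(s) in summaries: %s", paste(unique(unknown), collapse = ", "))
  excl <- catalog$excluded_from_version_comparison[match(key, cat_key)]
  slowfast <- ifelse(summaries$version %in% c("V1", "V2"), "slow", "fast")
  quietloud <- ifelse(summaries$version %in% c("V1", "V3"), "quiet", "loud")
  groups <- c("H-bBP", "N-bBP")

  long <- tidyr::pivot_longer(
    dplyr::mutate(summaries, .excluded = excl, .slowfast = slowfast,
                  .quietloud = quietloud, .row = dplyr::row_number()),
    cols = dplyr::all_of(bp_variables()),
    names_to = "variable", values_to = "value"
  )

  datasets <- list()
  add <- function(comparison, scope, test, sub, level_col) {
    for (v in bp_variables()) {
      dat <- sub[sub$variable == v, ]
      vecs <- split(dat$value, dat[[level_col]], drop = TRUE)
      datasets[[length(datasets) + 1L]] <<- tibble::tibble(
        comparison = comparison, scope = scope, test = test, variable = v,
        data = list(vecs)
      )
    }
  }

  # between-group
  add("music overall", "between-group", "mwu", long, "group")
  for (vv in c("V1", "V2", "V3", "V4")) {
    sub <- long[long$version == vv & !long$.excluded, ]
    if (nrow(sub)) add(paste("version", vv), "between-group", "mwu", sub, "group")
  }
  for (lv in c("slow", "fast")) {
    add(paste0(lv, " (", if (lv == "slow") "V1+V2" else "V3+V4", ")"),
        "between-group", "mwu", long[long$.slowfast == lv, ], "group")
  }
  for (lv in c("quiet", "loud")) {
    add(paste0(lv, " (", if (lv == "quiet") "V1+V3" else "V2+V4", ")"),
        "between-group", "mwu", long[long$.quietloud == lv, ], "group")
  }

  # within-group two-level alteration contrasts and version KW
  for (g in groups) {
    gl <- long[long$group == g, ]
    add("tempo alteration (slow vs fast)", g, "mwu", gl, ".slowfast")
    add("loudness alteration (quiet vs loud)", g, "mwu", gl, ".quietloud")
    add("versions", g, "kw", gl[!gl$.excluded, ], "version")
  }

  # tertile groupings
  if (!is.null(tertiles)) {
    for (sid in unique(tertiles$scheme_id)) {
      tt <- tertiles[tertiles$scheme_id == sid, ]
      tmap <- as.character(tt$tertile)
      names(tmap) <- paste(tt$piece_id, tt$version)
      lt <- dplyr::mutate(long, .tertile = factor(tmap[paste(long$piece_id, long$version)],
                                                  levels = c("low", "mid", "high")))
      if (anyNA(lt$.tertile)) stopf("track(s) missing from tertile scheme %s", sid)
      for (lv in c("low", "mid", "high")) {
        add(paste0(sid, " tertile: ", lv), "between-group", "mwu",
            lt[lt$.tertile == lv, ], "group")
      }
      for (g in groups) {
        add(paste0(sid, " tertiles"), g, "kw", lt[lt$group == g, ], ".tertile")
      }
    }
  }
  dplyr::bind_rows(datasets)
}

#' Serialise comparison datasets to long-format CSV
#'
#' @param datasets Output of [build_comparison_datasets()].
#' @param path Output CSV (`comparison,scope,variable,group,value`).
#' @return `path`, invisibly.
#' @export
write_comparison_datasets <- function(datasets, path) {
  rows <- lapply(seq_len(nrow(datasets)), function(i) {
    vecs <- datasets$data[[i]]
    tibble::tibble(
      comparison = datasets$comparison[i], scope = datasets$scope[i],
      variable = datasets$variable[i],
      group = rep(names(vecs), lengths(vecs)),
      value = unlist(vecs, use.names = FALSE)
    )
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}
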
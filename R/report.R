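#' Mean and confidence interval of a value vector
#'
#' @param x Numeric vector.
#' @param level Confidence level (default 0.95).
#' @param quantile `"t"` (Student) or `"normal"`.
#' @return Tibble `mean`, `lower`, `upper`, `n`.
#' @export
mean_ci <- function(x, level = 0.95, quantile = c("normal", "t")) {
  quantile <- match.arg(quantile)
  n <- length(x)
  m <- mean(x)
  se <- stats::sd(x) / sqrt(n)
  q <- if (quantile == "t") stats::qt(1 - (1 - level) / 2, df = n - 1) else
    stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(mean = m, lower = m - q * se, upper = m + q * se, n = n)
}

format_ci <- function(x, digits = 2) {
  ci <- mean_ci(x)
  sprintf("%.*f (%.*f-%.*f)", digits, ci$mean, digits, ci$lower, digits, ci$upper)
}

variable_labels <- function() {
  c(sys_mean = "Systolic BP (mean)", dia_mean = "Diastolic BP (mean)",
    sys_sd = "Systolic standard deviation", dia_sd = "Diastolic standard deviation",
    sys_range = "Systolic range", dia_range = "Diastolic range")
}

#' Render one comparison as a summary table
#'
#' Produces the grouped analysis table layout: one row per analysis variable,
#' one `mean (95% CI)` cell per level, the test p-value and a significance
#' marker. Purely a renderer: every number comes from the supplied datasets
#' and results.
#'
#' @param datasets Comparison datasets (see [build_comparison_datasets()]).
#' @param results Battery results (see [run_full_battery()]).
#' @param comparison Comparison label to render.
#' @param scope Scope of the comparison (`"between-group"` or a group).
#' @return Tibble, one row per variable, with formatted cells.
#' @export
render_results_table <- function(datasets, results, comparison,
                                 scope = "between-group") {
  sel_d <- datasets[datasets$comparison == comparison & datasets$scope == scope, ]
  sel_r <- results[results$comparison == comparison & results$scope == scope, ]
  if (nrow(sel_d) == 0L) stopf("no dataset for comparison '%s' (%s)", comparison, scope)
  labs <- variable_labels()
  rows <- lapply(bp_variables(), function(v) {
    d <- sel_d[sel_d$variable == v, ]
    r <- sel_r[sel_r$variable == v, ]
    vecs <- d$data[[1L]]
    cells <- vapply(vecs, format_ci, "")
    names(cells) <- paste0(names(vecs), " (n = ", lengths(vecs), ")")
    out <- tibble::as_tibble(as.list(cells))
    out$variable <- unname(labs[v])
    out$p <- sprintf("P = %.2g%s", r$p_value,
                     if (isTRUE(r$significant)) " **" else "")
    if (isTRUE(r$overridden)) out$p <- paste(out$p, "(overridden)")
    dplyr::relocate(out, "variable")
  })
  dplyr::bind_rows(rows)
}

#' Render a results table as Markdown
#'
#' @param table Tibble from [render_results_table()].
#' @return Character vector of Markdown lines.
#' @export
markdown_table <- function(table) {
  header <- paste0("| ", paste(names(table), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(table)), collapse = "|"), "|")
  body <- apply(table, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Orchestrate the full pipeline from the command surface
#'
#' The four sub-commands mirror the analysis stages:
#' \describe{
#'   \item{simulate}{draw playlists, simulate the cohort, write per-
#'     participant CSVs and a manifest;}
#'   \item{features}{build the synthetic stimulus set and write the feature /
#'     tertile table;}
#'   \item{analyze}{segment, normalise, summarise and run the statistical
#'     battery, writing summaries and results CSVs;}
#'   \item{report}{render Markdown tables of the headline comparisons from
#'     the results of `analyze`.}
#' }
#' Later stages recompute earlier stages deterministically from the same
#' config and seed when their inputs are not already in `out_dir`.
#'
#' @param command One of `"simulate"`, `"features"`, `"analyze"`, `"report"`.
#' @param config A [cohort_config()], a YAML path, or `NULL` for defaults.
#' @param seed Master seed overriding the config seed (optional).
#' @param out_dir Output directory.
#' @param alpha Significance threshold for `analyze` (default
#'   [bonferroni_alpha()]).
#' @param n_surrogates Surrogate iterations per test for `analyze`.
#' @return Invisible list of the artefacts produced.
#' @export
run_pipeline <- function(command = c("simulate", "features", "analyze", "report"),
                         config = NULL, seed = NULL, out_dir = "musicbp_out",
                         alpha = bonferroni_alpha(), n_surrogates = 1000L) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_cohort_config(config)
  if (is.null(config)) config <- cohort_config()
  if (!is.null(seed)) {
    cfg_vals <- unclass(config)
    cfg_vals$seed <- as.integer(seed)
    config <- do.call(cohort_config, cfg_vals)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- track_catalog()

  log_msg <- function(module, fmt, ...) {
    message(sprintf("[%s] %s", module, sprintf(fmt, ...)))
  }

  if (command == "simulate") {
    playlists <- make_playlists(catalog, config$n_per_group,
                                seed = derive_seed(config$seed, 777L))
    cohort <- simulate_cohort(config, catalog, playlists)
    files <- write_cohort_csv(cohort, file.path(out_dir, "cohort"))
    utils::write.csv(playlists, file.path(out_dir, "playlists.csv"), row.names = FALSE)
    write_cohort_config(config, file.path(out_dir, "config.yaml"))
    log_msg("simulate", "wrote %d participant recordings to %s",
            2L * config$n_per_group, file.path(out_dir, "cohort"))
    return(invisible(list(cohort = cohort, playlists = playlists, files = files)))
  }

  if (command == "features") {
    stimuli <- build_stimulus_set(catalog, seed = derive_seed(config$seed, 555L))
    features <- feature_table(stimuli)
    tertiles <- track_tertiles(features)
    ft <- dplyr::mutate(features,
                        scheme_id = paste(features$feature, features$statistic, sep = "_"))
    ft <- dplyr::left_join(ft, tertiles[, c("track_id", "scheme_id", "tertile")],
                           by = c("track_id", "scheme_id"))
    path <- file.path(out_dir, "features.csv")
    utils::write.csv(
      ft[, c("piece_id", "version", "feature", "statistic", "value", "tertile")],
      path, row.names = FALSE
    )
    log_msg("features", "wrote feature/tertile table for %d tracks", nrow(catalog))
    return(invisible(list(features = features, tertiles = tertiles, path = path)))
  }

  # analyze and report both need the analysis products
  playlists <- make_playlists(catalog, config$n_per_group,
                              seed = derive_seed(config$seed, 777L))
  cohort <- simulate_cohort(config, catalog, playlists)
  summaries <- summarize_cohort(cohort)
  stimuli <- build_stimulus_set(catalog, seed = derive_seed(config$seed, 555L))
  tertiles <- track_tertiles(feature_table(stimuli))
  datasets <- build_comparison_datasets(summaries, catalog, tertiles)
  results <- run_full_battery(datasets, alpha = alpha,
                              n_surrogates = n_surrogates,
                              seed = derive_seed(config$seed, 999L))

  if (command == "analyze") {
    utils::write.csv(summaries, file.path(out_dir, "listen_summaries.csv"),
                     row.names = FALSE)
    write_battery_results(results, file.path(out_dir, "results.csv"))
    write_comparison_datasets(datasets, file.path(out_dir, "datasets.csv"))
    log_msg("analyze", "%d listens, %d comparisons, alpha = %.4f",
            nrow(summaries), nrow(results), alpha)
    return(invisible(list(summaries = summaries, datasets = datasets,
                          results = results)))
  }

  # report
  lines <- character(0)
  headline <- unique(datasets$comparison[datasets$scope == "between-group"])
  for (cmp in headline[1:min(3L, length(headline))]) {
    tab <- render_results_table(datasets, results, cmp)
    lines <- c(lines, paste0("## ", cmp), "", markdown_table(tab), "")
  }
  for (g in c("H-bBP", "N-bBP")) {
    tab <- render_results_table(datasets, results, "tempo alteration (slow vs fast)", g)
    lines <- c(lines, paste0("## tempo alteration (slow vs fast), ", g), "",
               markdown_table(tab), "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  log_msg("report", "wrote %s", path)
  invisible(list(path = path, results = results))
}
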
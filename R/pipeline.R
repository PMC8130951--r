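analysis_parameters <- c("n_correct", "seq_index", "n_near", "n_null",
                         "n_ins")

#' Run the full scoring and statistical analysis
#'
#' Scores every sheet, then for each of the five analyzed parameters
#' (correct count, Sequence Index, near-miss, NULL and insertion counts)
#' equalizes group sizes by random exclusion (re-drawn independently per
#' parameter), runs the within-group Friedman test across timepoints with
#' Kendall's W and Nemenyi post-hoc comparisons, and computes the
#' improvement-to-perfect-recall ratio per group using the first
#' post-training timepoint. Removal (REM) errors are reported as raw counts
#' only; they are too infrequent for repeated-measures analysis.
#'
#' @param responses Response tibble (see [read_responses()]).
#' @param targets A [word_list()].
#' @param lex A [lexicon()].
#' @param scoring A [scoring_config()].
#' @param alpha Significance level recorded in the report (default 0.05).
#' @param equalization_seed Base seed for the per-parameter random
#'   exclusions.
#' @param improvement_threshold Score counting as perfect recall (default:
#'   the word-list length).
#' @return An object of class `recall_report`: list with `scored`,
#'   `summary_long`, `friedman` (tibble), `pairwise` (tibble),
#'   `improvement` (tibble), `rem_total`, `provenance`.
#' @export
run_analysis <- function(responses, targets, lex,
                         scoring = scoring_config(), alpha = 0.05,
                         equalization_seed = 1L,
                         improvement_threshold = NULL) {
  scored <- score_study(responses, targets, lex, scoring)
  if (is.null(improvement_threshold)) {
    improvement_threshold <- length(targets)
  }
  tp <- levels(scored$timepoint)
  groups <- sort(unique(scored$group))
  ids_by_group <- lapply(stats::setNames(groups, groups), function(g) {
    sort(unique(scored$participant_id[scored$group == g]))
  })
  target_n <- min(lengths(ids_by_group))

  fr_rows <- list(); pw_rows <- list(); excl <- list()
  for (pi in seq_along(analysis_parameters)) {
    param <- analysis_parameters[pi]
    eq <- equalize_group_sizes(ids_by_group, target_n,
                               seed = equalization_seed + pi)
    excl[[param]] <- eq$excluded
    for (g in groups) {
      keep <- eq$kept[[g]]
      sub <- scored[scored$participant_id %in% keep, , drop = FALSE]
      wide <- tidyr::pivot_wider(
        sub[, c("participant_id", "timepoint", param)],
        names_from = "timepoint", values_from = dplyr::all_of(param))
      m <- as.matrix(wide[, tp, drop = FALSE])
      res <- tryCatch(friedman_rm(m), error = function(e) NULL)
      if (is.null(res)) next
      fr_rows[[length(fr_rows) + 1L]] <- tibble::tibble(
        parameter = param, group = g, N = res$N, Q = res$Q, df = res$df,
        p = res$p, KW = res$KW, label = res$label,
        n_dropped = res$n_dropped)
      pw <- suppressMessages(
        nemenyi_posthoc(m[stats::complete.cases(m), , drop = FALSE]))
      pw$parameter <- param; pw$group <- g
      pw_rows[[length(pw_rows) + 1L]] <- pw
    }
  }

  base <- scored[scored$timepoint == tp[1L], , drop = FALSE]
  post <- scored[scored$timepoint == tp[2L], , drop = FALSE]
  baseline_perfect_ids <- base$participant_id[
    base$n_correct >= improvement_threshold]
  baseline_perfect_total <- length(baseline_perfect_ids)
  cohort_total <- length(unique(scored$participant_id))
  imp_rows <- list()
  for (g in groups) {
    gids <- ids_by_group[[g]]
    eligible <- setdiff(gids, baseline_perfect_ids)
    improved <- intersect(eligible, post$participant_id[
      post$n_correct >= improvement_threshold])
    ir <- improvement_ratio(length(improved), length(eligible),
                            baseline_perfect_total, cohort_total)
    imp_rows[[length(imp_rows) + 1L]] <- tibble::tibble(
      group = g, n_baseline_perfect_group = sum(gids %in%
                                                  baseline_perfect_ids),
      n_eligible = ir$n_eligible, n_improved = ir$n_improved,
      baseline_perfect_total = baseline_perfect_total,
      cohort_total = cohort_total, ratio = ir$ratio,
      ci_low = ir$ci_low, ci_high = ir$ci_high, method = ir$method)
  }

  summary_long <- scored |>
    tidyr::pivot_longer(dplyr::all_of(analysis_parameters),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$group, .data$timepoint, .data$parameter) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = unname(stats::quantile(.data$value, 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(.data$value, 0.75, na.rm = TRUE)),
      .groups = "drop")

  provenance <- list(
    package_version = as.character(utils::packageVersion("recallkit")),
    equalization_seed = equalization_seed,
    alpha = alpha,
    improvement_threshold = improvement_threshold,
    target_n = target_n,
    excluded = excl,
    scoring_config = unclass(scoring),
    config_hash = rlang::hash(list(scoring = unclass(scoring),
                                   alpha = alpha,
                                   equalization_seed = equalization_seed,
                                   improvement_threshold =
                                     improvement_threshold)))

  structure(list(scored = scored,
                 summary_long = summary_long,
                 friedman = dplyr::bind_rows(fr_rows),
                 pairwise = dplyr::bind_rows(pw_rows),
                 improvement = dplyr::bind_rows(imp_rows),
                 rem_total = sum(scored$n_rem),
                 provenance = provenance),
            class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  cat("<recall_report>\n")
  cat(" Friedman results:\n")
  print(x$friedman, n = Inf)
  cat(" Improvement to perfect recall:\n")
  print(x$improvement)
  cat(" Total REM errors:", x$rem_total, "\n")
  invisible(x)
}

#' Write a recall report to disk
#'
#' Emits `scored.csv`, `summary_long.csv` (violin-ready long format),
#' `report.json` (Friedman, pairwise and improvement results) and
#' `provenance.json` into `out_dir`.
#'
#' @param report A `recall_report` from [run_analysis()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scored <- report$scored
  scored$timepoint <- as.character(scored$timepoint)
  utils::write.csv(scored, file.path(out_dir, "scored.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary_long,
                   file.path(out_dir, "summary_long.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(friedman = report$friedman, pairwise = report$pairwise,
         improvement = report$improvement, rem_total = report$rem_total),
    file.path(out_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
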
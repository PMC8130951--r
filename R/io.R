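#' Read participant response sheets from CSV
#'
#' Expects columns `participant_id, group, timepoint, entry_order,
#' entry_text` (header required), one row per written entry, ordered within
#' participant x timepoint by `entry_order`. A participant with no entries
#' at a timepoint appears as a single row with empty `entry_text`.
#' Validation failures report the offending rows.
#'
#' @param path CSV file path.
#' @return Tibble of responses ordered by participant, timepoint,
#'   entry_order.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "group", "timepoint", "entry_order",
            "entry_text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("response CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$entry_order <- suppressWarnings(as.integer(df$entry_order))
  if (anyNA(df$entry_order)) {
    stop("non-integer entry_order at row(s): ",
         paste(which(is.na(df$entry_order)), collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df <- validate_responses(df)
  dplyr::arrange(df, .data$participant_id, .data$timepoint,
                 .data$entry_order)
}

#' Write response sheets to CSV
#'
#' Inverse of [read_responses()]: round-trips to an identical dataset.
#'
#' @param responses Response tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  out <- responses
  out$timepoint <- as.character(out$timepoint)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write ground-truth category labels to CSV
#'
#' @param truth Truth tibble from [simulate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `paths` (wordlist, lexicon_words,
#' lexicon_morphemes, responses, out_dir), `scoring` (arguments to
#' [scoring_config()]), `simulation` (arguments to [simulation_config()];
#' matrices given as 3x3 row lists), `analysis` (`alpha`,
#' `equalization_seed`, `improvement_threshold`). Missing keys fall back
#' to package defaults.
#'
#' @param path YAML file path.
#' @return List of class `run_config` with `paths`, `scoring`,
#'   `simulation`, `analysis`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build_run_config(raw)
}

build_run_config <- function(raw = list()) {
  paths <- raw$paths %||% list()
  sc <- do.call(scoring_config, raw$scoring %||% list())
  sim_args <- raw$simulation %||% list()
  for (m in c("group_effects", "sequence_jitter")) {
    if (!is.null(sim_args[[m]])) {
      sim_args[[m]] <- matrix(unlist(sim_args[[m]]), nrow = 3L,
                              byrow = TRUE,
                              dimnames = list(group_labels,
                                              timepoint_levels))
    }
  }
  sim <- do.call(simulation_config, sim_args)
  an <- raw$analysis %||% list()
  analysis <- list(alpha = an$alpha %||% 0.05,
                   equalization_seed = an$equalization_seed %||% 1L,
                   improvement_threshold = an$improvement_threshold)
  structure(list(paths = paths, scoring = sc, simulation = sim,
                 analysis = analysis),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
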
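#' Normalize a free-text recall entry
#'
#' Lowercases, strips outer whitespace, and removes internal whitespace and
#' hyphens so that "Angle-wing", "angle wing" and "anglewing" all compare
#' equal. An all-whitespace entry yields `NA_character_` (blank marker).
#'
#' @param raw A single raw string.
#' @return Canonical token, or `NA_character_` for blank input.
#' @examples
#' normalize_entry(" Metalmark ")
#' normalize_entry("angle-wing")
#' @export
normalize_entry <- function(raw) {
  if (length(raw) != 1L) stop("normalize_entry takes a single string",
                              call. = FALSE)
  if (is.na(raw)) return(NA_character_)
  x <- tolower(trimws(raw))
  x <- gsub("[[:space:]-]+", "", x)
  if (!nzchar(x)) NA_character_ else x
}

#' Levenshtein edit distance between two tokens
#'
#' Unit-cost insertions, deletions and substitutions. Used to operationalize
#' the "small error" criterion separating near misses and spelling slips
#' from outright insertions.
#'
#' @param a,b Normalized tokens.
#' @return Non-negative integer distance.
#' @examples
#' edit_distance("metalmark", "metalmask")
#' @export
edit_distance <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L, !is.na(a), !is.na(b))
  as.integer(utils::adist(a, b)[1, 1])
}

#' Scoring configuration
#'
#' Captures the judgment calls a human scorer would make implicitly.
#'
#' @param max_spelling_distance Maximum edit distance still counted as a
#'   "small error" (near miss or spelling slip). Default 2: covers one-letter
#'   substitutions and adjacent transpositions.
#' @param assignment_min_similarity Similarity floor in \[0, 1\] below which
#'   an entry is left unassigned to any target. Default 0.5.
#' @param sequence_mode `"rank_based"` (displacement among recalled items;
#'   default) or `"literal_position"` (absolute sheet position vs list
#'   position).
#' @param near_miss_counts_toward_correct_responses Should near misses enter
#'   the Sequence Index denominator and the sequence-scorable set? Default
#'   `FALSE` (a near miss is an error).
#' @param removal_precedence `"null_first"` (default: an absent item is a
#'   NULL error) or `"removal_first"` (an item correct at the previous
#'   timepoint and absent now is a removal, REM).
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(max_spelling_distance = 2L,
                           assignment_min_similarity = 0.5,
                           sequence_mode = c("rank_based", "literal_position"),
                           near_miss_counts_toward_correct_responses = FALSE,
                           removal_precedence = c("null_first",
                                                  "removal_first")) {
  sequence_mode <- match.arg(sequence_mode)
  removal_precedence <- match.arg(removal_precedence)
  if (max_spelling_distance < 1L) {
    stop("max_spelling_distance must be >= 1", call. = FALSE)
  }
  if (assignment_min_similarity < 0 || assignment_min_similarity > 1) {
    stop("assignment_min_similarity must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(max_spelling_distance = as.integer(max_spelling_distance),
         assignment_min_similarity = assignment_min_similarity,
         sequence_mode = sequence_mode,
         near_miss_counts_toward_correct_responses =
           isTRUE(near_miss_counts_toward_correct_responses),
         removal_precedence = removal_precedence),
    class = "scoring_config")
}

# Similarity used for entry <-> target assignment: character similarity
# 1 - d / max(lengths), boosted when the two tokens share a compound
# morpheme under the lexicon (so "metalspot" still pairs with "metalmark").
pair_similarity <- function(entry, target, lex) {
  d <- edit_distance(entry, target)
  base <- 1 - d / max(nchar(entry), nchar(target))
  se <- split_morphemes(entry, lex)
  st <- split_morphemes(target, lex)
  if (!is.null(se) && !is.null(st) && length(intersect(se, st)) > 0L) {
    base <- max(base, 0.5 + base / 2)
  }
  base
}

#' Assign written entries to target items
#'
#' Greedy one-to-one maximum-similarity matching: candidate pairs at or above
#' the similarity floor are taken in decreasing similarity order, ties broken
#' by lower target position then lower entry position, so the assignment is
#' fully deterministic. Every unmatched target becomes a NULL record; every
#' unmatched entry becomes a target-less insertion record.
#'
#' @param entries Character vector of normalized tokens (blanks already
#'   dropped), in written order.
#' @param targets A [word_list()].
#' @param lex A [lexicon()] (used for morpheme credit in similarity).
#' @param cfg A [scoring_config()].
#' @return A tibble of match records with columns `entry_index`,
#'   `target_index`, `entry`, `target`, `similarity`, `distance`, `category`
#'   (category is `NULL_` for unmatched targets and `NA` otherwise; final
#'   categories are filled by [classify_match()] via [score_sheet()]).
#' @export
assign_entries <- function(entries, targets, lex, cfg = scoring_config()) {
  stopifnot(inherits(targets, "word_list"))
  if (length(targets$canonical) == 0L) {
    stop("empty target list", call. = FALSE)
  }
  n_e <- length(entries)
  n_t <- length(targets$canonical)

  taken_e <- logical(n_e)
  taken_t <- logical(n_t)
  pairs <- NULL
  if (n_e > 0L) {
    sim <- matrix(0, n_e, n_t)
    for (i in seq_len(n_e)) {
      for (j in seq_len(n_t)) {
        sim[i, j] <- pair_similarity(entries[i], targets$canonical[j], lex)
      }
    }
    cand <- which(sim >= cfg$assignment_min_similarity - 1e-12,
                  arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      s <- sim[cand]
      ord <- order(-s, cand[, 2L], cand[, 1L])
      picks <- integer(0)
      for (k in ord) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!taken_e[i] && !taken_t[j]) {
          taken_e[i] <- TRUE
          taken_t[j] <- TRUE
          picks <- c(picks, k)
        }
      }
      if (length(picks) > 0L) {
        pairs <- tibble::tibble(
          entry_index = as.integer(cand[picks, 1L]),
          target_index = as.integer(cand[picks, 2L]),
          similarity = sim[cand[picks, , drop = FALSE]])
      }
    }
  }
  rows <- list()
  if (!is.null(pairs)) {
    rows[[1]] <- tibble::tibble(
      entry_index = pairs$entry_index,
      target_index = pairs$target_index,
      entry = entries[pairs$entry_index],
      target = targets$canonical[pairs$target_index],
      similarity = pairs$similarity,
      distance = mapply(edit_distance, entries[pairs$entry_index],
                        targets$canonical[pairs$target_index]),
      category = NA_character_)
  }
  if (any(!taken_t)) {
    jj <- which(!taken_t)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      entry_index = NA_integer_, target_index = jj,
      entry = NA_character_, target = targets$canonical[jj],
      similarity = NA_real_, distance = NA_integer_,
      category = "NULL_")
  }
  if (any(!taken_e)) {
    ii <- which(!taken_e)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      entry_index = ii, target_index = NA_integer_,
      entry = entries[ii], target = NA_character_,
      similarity = NA_real_, distance = NA_integer_,
      category = "INS")
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, !is.na(.data$target_index), .data$target_index,
                 .data$entry_index)
}

#' Classify an assigned entry against its target
#'
#' The four-way taxonomy applied to an entry that has been paired with a
#' target:
#' * `CORRECT` — entry equals the target, or differs by at most
#'   `max_spelling_distance` edits while NOT being a semantically meaningful
#'   word (a pure spelling slip, e.g. "meselmark" for metalmark);
#' * `NEAR_MISS` — within `max_spelling_distance` edits AND lexicon-
#'   meaningful AND different from the target (e.g. "metalmask");
#' * `INS` — anything else written in the target's place (a completely
#'   different word, e.g. "metalspot").
#'
#' @param entry,target Normalized tokens (entry assigned to target).
#' @param lex A [lexicon()].
#' @param cfg A [scoring_config()].
#' @return One of `"CORRECT"`, `"NEAR_MISS"`, `"INS"`.
#' @examples
#' lex <- lexicon(morphemes = c("metal", "mark", "mask", "spot"))
#' classify_match("metalmask", "metalmark", lex)  # NEAR_MISS
#' classify_match("meselmark", "metalmark", lex)  # CORRECT (spelling slip)
#' classify_match("metalspot", "metalmark", lex)  # INS
#' @export
classify_match <- function(entry, target, lex, cfg = scoring_config()) {
  if (identical(entry, target)) return("CORRECT")
  d <- edit_distance(entry, target)
  if (d <= cfg$max_spelling_distance) {
    if (is_meaningful(entry, lex)) "NEAR_MISS" else "CORRECT"
  } else {
    "INS"
  }
}

#' Positional distances of recalled items
#'
#' For each sequence-scorable match (CORRECT, plus NEAR_MISS when configured)
#' computes how far out of sequence the item fell. In `rank_based` mode the
#' distance is the absolute difference between the item's rank among the
#' scorable written entries and its target's rank among the recalled targets,
#' so omissions do not penalize the items around them. In `literal_position`
#' mode it is the absolute difference between the written position and the
#' list position (the "4th item written in 6th place counts 2" reading).
#' The two modes coincide on complete recalls.
#'
#' @param matches Match-record tibble from [assign_entries()] with final
#'   categories filled in.
#' @param cfg A [scoring_config()].
#' @return A list with `distances` (tibble: `target_index`, `entry_index`,
#'   `distance`) and `position_sum` (sum of distances).
#' @export
position_errors <- function(matches, cfg = scoring_config()) {
  ok_cat <- "CORRECT"
  if (cfg$near_miss_counts_toward_correct_responses) {
    ok_cat <- c(ok_cat, "NEAR_MISS")
  }
  m <- matches[!is.na(matches$entry_index) & !is.na(matches$target_index) &
                 matches$category %in% ok_cat, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(list(distances = tibble::tibble(target_index = integer(),
                                           entry_index = integer(),
                                           distance = integer()),
                position_sum = 0L))
  }
  if (cfg$sequence_mode == "rank_based") {
    entry_rank <- rank(m$entry_index, ties.method = "first")
    target_rank <- rank(m$target_index, ties.method = "first")
    d <- abs(entry_rank - target_rank)
  } else {
    d <- abs(m$entry_index - m$target_index)
  }
  list(distances = tibble::tibble(target_index = m$target_index,
                                  entry_index = m$entry_index,
                                  distance = as.integer(d)),
       position_sum = as.integer(sum(d)))
}

#' Sequence Index
#'
#' Order-accuracy statistic for one response sheet:
#' `SeqI = (position_sum / 2) / n_correct`. The halving corrects for the
#' fact that a single out-of-order item necessarily produces two observed
#' position errors (at its written place and at its vacated place);
#' normalizing by the number of correct responses makes sheets with
#' different recall totals comparable. Undefined (NA) when `n_correct` is 0.
#'
#' @param position_sum Sum of positional distances (non-negative integer).
#' @param n_correct Number of correct responses.
#' @return SeqI value, or `NA_real_` when `n_correct == 0`.
#' @examples
#' sequence_index(2, 5)   # the 1,3,2,4,5 worked example -> 0.2
#' @export
sequence_index <- function(position_sum, n_correct) {
  stopifnot(position_sum >= 0, n_correct >= 0)
  if (n_correct == 0) return(NA_real_)
  (position_sum / 2) / n_correct
}

#' Count removal (REM) errors between consecutive timepoints
#'
#' A removal is a target answered correctly at the previous timepoint but
#' absent at the current one with no replacement falling into another error
#' category (i.e. its slot is a bare NULL). Under the default `null_first`
#' precedence such absences stay NULL errors (matching the near-zero REM
#' incidence in practice); under `removal_first` they are reclassified REM
#' and deducted from the NULL count.
#'
#' @param prev_matches,curr_matches Match tibbles (categories filled) for
#'   the same participant at consecutive timepoints.
#' @param cfg A [scoring_config()].
#' @return A list with `n_rem` and `rem_target_indices`.
#' @export
count_removals <- function(prev_matches, curr_matches,
                           cfg = scoring_config()) {
  prev_correct <- prev_matches$target_index[
    !is.na(prev_matches$target_index) & prev_matches$category == "CORRECT"]
  curr_null <- curr_matches$target_index[
    !is.na(curr_matches$target_index) & curr_matches$category == "NULL_"]
  candidates <- intersect(prev_correct, curr_null)
  if (cfg$removal_precedence == "removal_first") {
    list(n_rem = length(candidates),
         rem_target_indices = as.integer(candidates))
  } else {
    list(n_rem = 0L, rem_target_indices = integer())
  }
}

#' Score one response sheet against the target list
#'
#' Composes normalization, assignment, classification, positional-distance
#' counting, the Sequence Index, and (when the participant's previous
#' timepoint is supplied) removal detection.
#'
#' @param entries Character vector of raw written entries in written order
#'   (blanks dropped after normalization).
#' @param targets A [word_list()].
#' @param lex A [lexicon()].
#' @param cfg A [scoring_config()].
#' @param prev Optional result of a previous [score_sheet()] call for the
#'   same participant's preceding timepoint (enables REM counting).
#' @return An object of class `scored_sheet`: a list with `counts` (tibble
#'   with `n_correct`, `n_near`, `n_ins`, `n_null`, `n_rem`, `position_sum`,
#'   `seq_index`) and `matches` (the classified match records).
#' @export
score_sheet <- function(entries, targets, lex, cfg = scoring_config(),
                        prev = NULL) {
  stopifnot(inherits(targets, "word_list"), inherits(lex, "lexicon"))
  norm <- vapply(as.character(entries), normalize_entry, character(1),
                 USE.NAMES = FALSE)
  norm <- norm[!is.na(norm)]
  m <- assign_entries(norm, targets, lex, cfg)
  assigned <- !is.na(m$entry_index) & !is.na(m$target_index)
  if (any(assigned)) {
    m$category[assigned] <- mapply(classify_match, m$entry[assigned],
                                   m$target[assigned],
                                   MoreArgs = list(lex = lex, cfg = cfg))
  }
  n_rem <- 0L
  if (!is.null(prev)) {
    stopifnot(inherits(prev, "scored_sheet"))
    rem <- count_removals(prev$matches, m, cfg)
    n_rem <- rem$n_rem
    if (n_rem > 0L) {
      m$category[m$target_index %in% rem$rem_target_indices &
                   m$category == "NULL_"] <- "REM"
    }
  }
  pe <- position_errors(m, cfg)
  n_correct <- sum(m$category == "CORRECT", na.rm = TRUE)
  counts <- tibble::tibble(
    n_correct = n_correct,
    n_near = sum(m$category == "NEAR_MISS", na.rm = TRUE),
    n_ins = sum(m$category == "INS", na.rm = TRUE),
    n_null = sum(m$category == "NULL_", na.rm = TRUE),
    n_rem = n_rem,
    position_sum = pe$position_sum,
    seq_index = sequence_index(pe$position_sum, n_correct))
  structure(list(counts = counts, matches = m, distances = pe$distances),
            class = "scored_sheet")
}

#' @export
print.scored_sheet <- function(x, ...) {
  cat("<scored_sheet>\n")
  print(x$counts)
  invisible(x)
}

#' Score a whole study dataset
#'
#' Applies [score_sheet()] to every participant x timepoint sheet in a
#' long-format response table, threading each participant's previous
#' timepoint through for removal detection.
#'
#' @param responses Tibble with columns `participant_id`, `group`,
#'   `timepoint`, `entry_order`, `entry_text` (one row per written entry;
#'   a participant with no entries at a timepoint appears as one row with
#'   empty `entry_text`). `timepoint` must be an ordered factor or use the
#'   standard labels `baseline`, `post_training`, `delayed`.
#' @param targets A [word_list()].
#' @param lex A [lexicon()].
#' @param cfg A [scoring_config()].
#' @return A tibble, one row per participant x timepoint, with identifier
#'   columns plus all scored-sheet count columns.
#' @export
score_study <- function(responses, targets, lex, cfg = scoring_config()) {
  responses <- validate_responses(responses)
  keys <- dplyr::distinct(responses, .data$participant_id, .data$group)
  out <- vector("list", nrow(keys))
  tp_levels <- levels(responses$timepoint)
  for (i in seq_len(nrow(keys))) {
    pid <- keys$participant_id[i]
    rows <- responses[responses$participant_id == pid, , drop = FALSE]
    prev <- NULL
    acc <- vector("list", length(tp_levels))
    for (t in seq_along(tp_levels)) {
      tp <- tp_levels[t]
      sheet_rows <- rows[as.character(rows$timepoint) == tp, , drop = FALSE]
      if (nrow(sheet_rows) == 0L) next
      sheet_rows <- sheet_rows[order(sheet_rows$entry_order), , drop = FALSE]
      sc <- score_sheet(sheet_rows$entry_text, targets, lex, cfg, prev = prev)
      prev <- sc
      acc[[t]] <- dplyr::bind_cols(
        tibble::tibble(participant_id = pid, group = keys$group[i],
                       timepoint = tp),
        sc$counts)
    }
    out[[i]] <- dplyr::bind_rows(acc)
  }
  res <- dplyr::bind_rows(out)
  res$timepoint <- factor(res$timepoint, levels = tp_levels, ordered = TRUE)
  res
}

timepoint_levels <- c("baseline", "post_training", "delayed")

validate_responses <- function(responses) {
  need <- c("participant_id", "group", "timepoint", "entry_order",
            "entry_text")
  missing_cols <- setdiff(need, names(responses))
  if (length(missing_cols) > 0L) {
    stop("response table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.ordered(responses$timepoint)) {
    bad <- setdiff(unique(as.character(responses$timepoint)),
                   timepoint_levels)
    if (length(bad) > 0L) {
      stop("unknown timepoint labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    responses$timepoint <- factor(responses$timepoint,
                                  levels = timepoint_levels, ordered = TRUE)
  }
  key <- paste(responses$participant_id, responses$timepoint,
               responses$entry_order, sep = "\r")
  filled <- !is.na(responses$entry_text) & nzchar(responses$entry_text)
  dup <- duplicated(key) & filled
  if (any(dup)) {
    stop("duplicate (participant_id, timepoint, entry_order) at row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  responses
}
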
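#' Default morpheme pools for compound-word list generation
#'
#' Modifier and head pools used to build butterfly-style compound item
#' names (modifier + head, e.g. "metalmark", "anglewing"). Pools are sized
#' so a 20-item list leaves spare heads for generating insertion errors
#' that collide with no target.
#'
#' @return Named list with `modifiers` and `heads` character vectors.
#' @export
default_morpheme_pools <- function() {
  list(
    modifiers = c("metal", "angle", "silver", "copper", "orange", "painted",
                  "checker", "cloud", "shadow", "marble", "pearl", "amber",
                  "crimson", "golden", "hazel", "indigo", "ivory", "russet",
                  "sable", "scarlet", "velvet", "walnut", "willow", "ember"),
    heads = c("mark", "wing", "spot", "tail", "cap", "tip", "streak",
              "crest", "patch", "band", "fold", "edge", "vein", "lace",
              "fan", "dot", "ring", "moth", "crown", "leaf", "flame",
              "brush", "cloak", "gem", "plume", "thorn"))
}

#' Generate a compound word list with a matching lexicon
#'
#' Builds `n_items` unique modifier+head compounds, plus the lexicon needed
#' to score them: all pool morphemes, all valid modifier+head compounds, and
#' one designated near variant per item (the item with a single letter of
#' its head substituted, declared a meaningful word -- the "metalmask for
#' metalmark" pattern). Modifiers and heads are drawn without replacement so
#' every item has a unique modifier and a unique head; insertion variants
#' use heads left unused by the list, so simulated errors are attributable
#' to exactly one target.
#'
#' @param n_items Number of list items (default 20).
#' @param pools Morpheme pools as from [default_morpheme_pools()].
#' @param seed Integer seed.
#' @return A list of class `wordlist_bundle`: `wordlist` ([word_list()]),
#'   `lexicon` ([lexicon()]), `near_variants` and `ins_variants` (character
#'   vectors parallel to the items).
#' @export
generate_wordlist <- function(n_items = 20L,
                              pools = default_morpheme_pools(),
                              seed = NULL) {
  if (n_items > length(pools$modifiers) ||
      n_items >= length(pools$heads)) {
    stop("morpheme pools too small for ", n_items, " unique compounds",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mods <- sample(pools$modifiers, n_items)
  heads <- sample(pools$heads, n_items)
  items <- paste0(mods, heads)
  spare_heads <- setdiff(pools$heads, heads)

  all_compounds <- as.vector(outer(pools$modifiers, pools$heads, paste0))

  near_variants <- character(n_items)
  letters_pool <- letters
  for (i in seq_len(n_items)) {
    h <- heads[i]
    v <- NA_character_
    for (pos in seq_len(nchar(h))) {
      for (ch in sample(letters_pool)) {
        cand_h <- h
        substr(cand_h, pos, pos) <- ch
        cand <- paste0(mods[i], cand_h)
        if (cand_h != h && !(cand %in% items)) {
          v <- cand
          break
        }
      }
      if (!is.na(v)) break
    }
    near_variants[i] <- v
  }

  ins_variants <- character(n_items)
  for (i in seq_len(n_items)) {
    ok <- spare_heads[vapply(spare_heads, function(h) {
      edit_distance(h, heads[i]) > 2L
    }, logical(1))]
    if (length(ok) == 0L) ok <- spare_heads
    ins_variants[i] <- paste0(mods[i], sample(ok, 1L))
  }

  lex <- lexicon(words = c(all_compounds, near_variants),
                 morphemes = c(pools$modifiers, pools$heads))
  structure(list(wordlist = word_list(items), lexicon = lex,
                 near_variants = near_variants,
                 ins_variants = ins_variants),
            class = "wordlist_bundle")
}

#' Simulation configuration for a three-arm recall study
#'
#' Defaults emulate a cohort of high-achieving students with a strong
#' ceiling effect (median baseline recall of at least 17/20), positive
#' post-training effects on recall counts for the two trained arms, and a
#' large training effect on sequence accuracy in the narrative-technique
#' arm. Timepoints are baseline, post_training, delayed.
#'
#' @param n_per_group Participants per group (default 25).
#' @param list_length Items on the study list (default 20).
#' @param ability_shape1,ability_shape2 Beta parameters for latent recall
#'   ability (default Beta(16, 2): mean about 0.89, putting the median
#'   baseline count at the observed ceiling).
#' @param group_effects 3x3 numeric matrix of logit offsets added to each
#'   participant's latent ability, rows = groups (memory_palace,
#'   aboriginal_method, untrained), columns = timepoints.
#' @param sequence_jitter 3x3 matrix of rank-noise SDs (same layout):
#'   written order is targets sorted by rank + Gaussian noise of this SD.
#' @param error_mix Probabilities (p_null, p_near, p_ins) for the fate of
#'   an unrecalled item; must sum to 1.
#' @param p_spell Probability a recalled item is written with a small
#'   non-meaningful spelling slip.
#' @param decay Optional multiplier (< 1) applied on the logit scale at a
#'   six-week follow-up; unused by the core three-timepoint design.
#' @param seed Integer seed for the whole study simulation.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 25L,
                              list_length = 20L,
                              ability_shape1 = 16,
                              ability_shape2 = 2,
                              group_effects = default_group_effects(),
                              sequence_jitter = default_sequence_jitter(),
                              error_mix = c(p_null = 0.6, p_near = 0.25,
                                            p_ins = 0.15),
                              p_spell = 0.02,
                              decay = NULL,
                              seed = 1L) {
  stopifnot(n_per_group >= 1L, list_length >= 1L,
            all(dim(group_effects) == c(3L, 3L)),
            all(dim(sequence_jitter) == c(3L, 3L)),
            length(error_mix) == 3L, all(error_mix >= 0),
            abs(sum(error_mix) - 1) < 1e-8,
            p_spell >= 0, p_spell <= 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 list_length = as.integer(list_length),
                 ability_shape1 = ability_shape1,
                 ability_shape2 = ability_shape2,
                 group_effects = group_effects,
                 sequence_jitter = sequence_jitter,
                 error_mix = error_mix, p_spell = p_spell,
                 decay = decay, seed = as.integer(seed)),
            class = "simulation_config")
}

group_labels <- c("memory_palace", "aboriginal_method", "untrained")

#' @rdname simulation_config
#' @export
default_group_effects <- function() {
  m <- rbind(memory_palace = c(0, 1.2, 1.2),
             aboriginal_method = c(0, 1.4, 1.4),
             untrained = c(0, 0.4, 0.4))
  colnames(m) <- timepoint_levels
  m
}

#' @rdname simulation_config
#' @export
default_sequence_jitter <- function() {
  m <- rbind(memory_palace = c(1.2, 0.8, 0.8),
             aboriginal_method = c(1.2, 0.3, 0.3),
             untrained = c(1.2, 1.2, 1.2))
  colnames(m) <- timepoint_levels
  m
}

#' Zero-effect (null) variant of a simulation configuration
#'
#' All group-by-timepoint effects and jitter differences removed; used for
#' type-I-error calibration of the downstream tests.
#'
#' @param cfg A [simulation_config()].
#' @return A [simulation_config()] with zero effects and constant jitter.
#' @export
null_config <- function(cfg = simulation_config()) {
  ge <- cfg$group_effects; ge[] <- 0
  sj <- cfg$sequence_jitter; sj[] <- cfg$sequence_jitter[1, 1]
  cfg$group_effects <- ge
  cfg$sequence_jitter <- sj
  cfg
}

#' Card-deck block randomization to three groups
#'
#' Emulates drawing from two shuffled decks with the club suit removed:
#' a pool of 26 hearts (group 1, memory_palace), 26 diamonds (group 2,
#' aboriginal_method) and 26 spades (group 3, untrained), drawn without
#' replacement, one card per participant.
#'
#' @param n_participants Number of participants (at most 78).
#' @param seed Optional integer seed.
#' @return Character vector of group labels, length `n_participants`.
#' @export
block_randomize <- function(n_participants, seed = NULL) {
  if (n_participants > 78L) {
    stop("card pool exhausted: at most 78 participants", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rep(group_labels, each = 26L)
  sample(pool)[seq_len(n_participants)]
}

# Perturb one character of a recalled token into a spelling slip that is
# not lexicon-meaningful and collides with no target.
spelling_slip <- function(token, lex, targets) {
  for (attempt in seq_len(25L)) {
    pos <- sample.int(nchar(token), 1L)
    ch <- sample(c("x", "z", "q", "j", "k", "w"), 1L)
    cand <- token
    substr(cand, pos, pos) <- ch
    if (cand != token && !is_meaningful(cand, lex) &&
        !(cand %in% targets)) {
      return(cand)
    }
  }
  token
}

#' Simulate one participant's response sheets across timepoints
#'
#' Each target is recalled independently with probability
#' `plogis(qlogis(ability) + effect)`. An unrecalled target becomes a NULL,
#' a near miss (the item's designated lexicon-meaningful variant) or an
#' insertion (a spare-head compound sharing the item's modifier) according
#' to the error mixture. Recalled items receive a non-meaningful spelling
#' slip with probability `p_spell`. Written order is the targets with
#' entries, sorted by target rank plus Gaussian jitter.
#'
#' @param ability Latent recall probability in (0, 1).
#' @param group Group label (row of the effect matrices).
#' @param bundle A `wordlist_bundle` from [generate_wordlist()].
#' @param cfg A [simulation_config()].
#' @param participant_id Identifier carried into the output rows.
#' @return List with `responses` (tibble: participant_id, group, timepoint,
#'   entry_order, entry_text) and `truth` (tibble: participant_id,
#'   timepoint, target_index, true_category).
#' @export
simulate_participant <- function(ability, group, bundle, cfg,
                                 participant_id = "P1") {
  L <- cfg$list_length
  stopifnot(L <= length(bundle$wordlist))
  targets <- bundle$wordlist$canonical[seq_len(L)]
  resp <- list(); truth <- list()
  for (t in seq_along(timepoint_levels)) {
    tp <- timepoint_levels[t]
    eff <- cfg$group_effects[group, t]
    p_recall <- stats::plogis(stats::qlogis(ability) + eff)
    recalled <- stats::runif(L) < p_recall
    cat_true <- ifelse(recalled, "CORRECT", NA)
    tokens <- ifelse(recalled, targets, NA_character_)
    for (i in which(!recalled)) {
      fate <- sample(c("NULL_", "NEAR_MISS", "INS"), 1L,
                     prob = cfg$error_mix)
      cat_true[i] <- fate
      tokens[i] <- switch(fate,
                          NULL_ = NA_character_,
                          NEAR_MISS = bundle$near_variants[i],
                          INS = bundle$ins_variants[i])
    }
    if (cfg$p_spell > 0) {
      for (i in which(recalled)) {
        if (stats::runif(1) < cfg$p_spell) {
          tokens[i] <- spelling_slip(tokens[i], bundle$lexicon, targets)
        }
      }
    }
    written <- which(!is.na(tokens))
    jit <- cfg$sequence_jitter[group, t]
    ord <- written[order(seq_along(written) +
                           stats::rnorm(length(written), 0, jit))]
    if (length(ord) > 0L) {
      resp[[t]] <- tibble::tibble(
        participant_id = participant_id, group = group, timepoint = tp,
        entry_order = seq_along(ord), entry_text = tokens[ord])
    } else {
      resp[[t]] <- tibble::tibble(
        participant_id = participant_id, group = group, timepoint = tp,
        entry_order = 1L, entry_text = "")
    }
    truth[[t]] <- tibble::tibble(
      participant_id = participant_id, timepoint = tp,
      target_index = seq_len(L), true_category = cat_true)
  }
  list(responses = dplyr::bind_rows(resp), truth = dplyr::bind_rows(truth))
}

#' Simulate a full three-arm recall study
#'
#' Block-randomizes `3 * n_per_group` participants to the three arms via
#' the card-deck scheme, draws per-participant latent abilities from the
#' configured Beta distribution, and emits response sheets for the three
#' timepoints together with the generating ground truth.
#'
#' @param cfg A [simulation_config()].
#' @param bundle Optional `wordlist_bundle`; generated from `cfg$seed` when
#'   omitted.
#' @return List of class `study_dataset`: `responses`, `truth`, `bundle`,
#'   `profiles` (tibble of participant abilities and groups), `config`.
#' @export
simulate_study <- function(cfg = simulation_config(), bundle = NULL) {
  set.seed(cfg$seed)
  if (is.null(bundle)) {
    bundle <- generate_wordlist(cfg$list_length, seed = NULL)
  }
  n_total <- 3L * cfg$n_per_group
  # pure card draw: arm sizes vary slightly around n_per_group, as in a
  # real suit-draw allocation; downstream analysis equalizes sizes
  groups <- block_randomize(n_total, seed = NULL)
  ids <- sprintf("S%03d", seq_len(n_total))
  abilities <- stats::rbeta(n_total, cfg$ability_shape1, cfg$ability_shape2)
  abilities <- pmin(pmax(abilities, 1e-4), 1 - 1e-4)
  resp <- list(); truth <- list()
  for (i in seq_len(n_total)) {
    sim <- simulate_participant(abilities[i], groups[i], bundle, cfg,
                                participant_id = ids[i])
    resp[[i]] <- sim$responses
    truth[[i]] <- sim$truth
  }
  structure(list(responses = dplyr::bind_rows(resp),
                 truth = dplyr::bind_rows(truth),
                 bundle = bundle,
                 profiles = tibble::tibble(participant_id = ids,
                                           group = groups,
                                           ability = abilities),
                 config = cfg),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", nrow(x$profiles), " participants, ",
      length(unique(x$responses$timepoint)), " timepoints, list of ",
      x$config$list_length, "\n", sep = "")
  invisible(x)
}

#' Simulate correct-recall counts only (fast path)
#'
#' Draws the per-participant, per-timepoint correct counts implied by the
#' recall model (Beta ability, logit offsets, Binomial recall) without
#' materializing written sheets. The count marginal is identical to scoring
#' the full simulated sheets; used for calibration studies that need
#' thousands of replicates.
#'
#' @param cfg A [simulation_config()].
#' @param group Group label whose effect row to use.
#' @param n Number of participants.
#' @return Integer matrix `n x 3` of correct counts (columns = timepoints).
#' @export
simulate_recall_counts <- function(cfg, group = "untrained",
                                   n = cfg$n_per_group) {
  ability <- stats::rbeta(n, cfg$ability_shape1, cfg$ability_shape2)
  ability <- pmin(pmax(ability, 1e-4), 1 - 1e-4)
  k <- length(timepoint_levels)
  out <- matrix(0L, n, k, dimnames = list(NULL, timepoint_levels))
  for (t in seq_len(k)) {
    p <- stats::plogis(stats::qlogis(ability) + cfg$group_effects[group, t])
    out[, t] <- stats::rbinom(n, cfg$list_length, p)
  }
  out
}
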
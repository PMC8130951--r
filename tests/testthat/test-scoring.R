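test_that("normalize_entry canonicalizes case, whitespace and hyphens", {
  expect_equal(normalize_entry(" Metalmark "), "metalmark")
  expect_equal(normalize_entry("angle-wing"), "anglewing")
  expect_equal(normalize_entry("Angle  Wing"), "anglewing")
  expect_true(is.na(normalize_entry("   ")))
  expect_true(is.na(normalize_entry(NA_character_)))
})

test_that("edit_distance matches an exhaustive DP oracle", {
  expect_equal(edit_distance("metalmark", "metalmark"), 0L)
  expect_equal(edit_distance("metalmark", "metalmask"), 1L)
  expect_equal(edit_distance("metalmark", "metalspot"), 4L)

  # exhaustive over short tokens on a 3-letter alphabet
  alph <- c("a", "b", "c")
  toks <- unlist(lapply(1:3, function(n) {
    apply(as.matrix(expand.grid(rep(list(alph), n))), 1L, paste,
          collapse = "")
  }))
  for (a in toks) {
    for (b in toks) {
      expect_equal(edit_distance(a, b), dp_edit_distance(a, b))
    }
  }
  # random longer pairs up to length 6
  set.seed(11)
  for (i in 1:200) {
    a <- paste(sample(alph, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alph, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(edit_distance(a, b), dp_edit_distance(a, b))
  }
})

test_that("lexicon meaningfulness uses words, morphemes and compounds", {
  lex <- toy_lexicon()
  expect_true(is_meaningful("metalmask", lex))   # listed word
  expect_true(is_meaningful("metalspot", lex))   # metal + spot decomposes
  expect_true(is_meaningful("angelwing", lex))
  expect_false(is_meaningful("meselmark", lex))  # "mesel" is nothing
  expect_equal(split_morphemes("metalspot", lex), c("metal", "spot"))
  expect_null(split_morphemes("meselmark", lex))
})

test_that("classify_match reproduces the printed taxonomy examples", {
  lex <- toy_lexicon()
  expect_equal(classify_match("metalmark", "metalmark", lex), "CORRECT")
  expect_equal(classify_match("metalmask", "metalmark", lex), "NEAR_MISS")
  expect_equal(classify_match("angelwing", "anglewing", lex), "NEAR_MISS")
  expect_equal(classify_match("meselmark", "metalmark", lex), "CORRECT")
  expect_equal(classify_match("metalspot", "metalmark", lex), "INS")
})

test_that("assign_entries is a deterministic one-to-one matching", {
  lex <- toy_lexicon()
  wl <- word_list(c("metalmark", "anglewing", "silvertail"))

  m <- assign_entries(c("metalmark", "anglewing", "silvertail"), wl, lex)
  assigned <- m[!is.na(m$entry_index) & !is.na(m$target_index), ]
  expect_equal(assigned$target_index, assigned$entry_index)
  expect_false(any(m$category %in% "NULL_"))

  m2 <- assign_entries(c("metalmask"), wl, lex)
  hit <- m2[!is.na(m2$entry_index) & !is.na(m2$target_index), ]
  expect_equal(hit$target, "metalmark")

  m3 <- assign_entries(c("zzzz"), wl, lex)
  expect_true(any(is.na(m3$target_index) & m3$category == "INS"))
  expect_equal(sum(m3$category == "NULL_", na.rm = TRUE), 3L)

  # no duplicated entries or targets among assignments
  expect_false(anyDuplicated(stats::na.omit(m3$target_index)) > 0)
  expect_error(assign_entries("x", word_list(character()), lex))
})

test_that("position errors reproduce the single-swap worked example", {
  lex <- toy_lexicon()
  wl <- toy_wordlist(5L)
  sc <- score_sheet(wl$items[c(1, 3, 2, 4, 5)], wl, lex)
  expect_equal(sc$counts$position_sum, 2L)
  expect_equal(sum(sc$distances$distance > 0), 2L)
  expect_equal(sc$counts$seq_index, 0.2)

  ident <- score_sheet(wl$items, wl, lex)
  expect_equal(ident$counts$position_sum, 0L)
  expect_equal(ident$counts$seq_index, 0)

  rev5 <- score_sheet(rev(wl$items), wl, lex)
  expect_equal(rev5$counts$position_sum, 12L)  # 4 + 2 + 0 + 2 + 4
  expect_equal(rev5$counts$seq_index, 1.2)
})

test_that("rank-based and literal modes agree on complete recalls and
           differ under omission", {
  lex <- toy_lexicon()
  wl <- toy_wordlist(5L)
  lit <- scoring_config(sequence_mode = "literal_position")
  perm <- wl$items[c(2, 1, 4, 3, 5)]
  expect_equal(score_sheet(perm, wl, lex)$counts$position_sum,
               score_sheet(perm, wl, lex, lit)$counts$position_sum)

  # omit item 1: ranks stay aligned, literal positions all shift
  omitted <- wl$items[2:5]
  expect_equal(score_sheet(omitted, wl, lex)$counts$position_sum, 0L)
  expect_equal(score_sheet(omitted, wl, lex, lit)$counts$position_sum, 4L)
})

test_that("rank-based position_sum is always even", {
  set.seed(42)
  for (i in 1:10000) {
    n <- sample(2:20, 1L)
    sigma <- sample(n)
    expect_true(sum(abs(sigma - seq_len(n))) %% 2L == 0L)
  }
  # and through the scorer itself on a handful of permutations
  lex <- toy_lexicon()
  wl <- toy_wordlist(6L)
  set.seed(43)
  for (i in 1:25) {
    sc <- score_sheet(sample(wl$items), wl, lex)
    expect_true(sc$counts$position_sum %% 2L == 0L)
  }
})

test_that("sequence_index follows its formula and is NA at zero correct", {
  expect_equal(sequence_index(2, 5), 0.2)
  expect_equal(sequence_index(0, 20), 0)
  expect_equal(sequence_index(12, 5), 1.2)
  expect_true(is.na(sequence_index(0, 0)))
})

test_that("scored sheets satisfy the category partition invariant", {
  lex <- toy_lexicon()
  bundle <- generate_wordlist(12L, seed = 5)
  cfg <- simulation_config(n_per_group = 2L, list_length = 12L, seed = 5)
  set.seed(5)
  for (i in 1:6) {
    sim <- simulate_participant(runif(1, 0.4, 0.95), "untrained", bundle,
                                cfg, participant_id = paste0("P", i))
    for (tp in unique(sim$responses$timepoint)) {
      rows <- sim$responses[sim$responses$timepoint == tp, ]
      sc <- score_sheet(rows$entry_text, bundle$wordlist, bundle$lexicon)
      n_ins_assigned <- sum(sc$matches$category == "INS" &
                              !is.na(sc$matches$target_index))
      with(sc$counts, expect_equal(
        n_correct + n_near + n_null + n_ins_assigned + n_rem, 12L))
    }
  }
})

test_that("removal counting honours the precedence configuration", {
  lex <- toy_lexicon()
  wl <- toy_wordlist(5L)
  prev <- score_sheet(wl$items, wl, lex)

  # identical sheet: nothing removed
  curr_same <- score_sheet(wl$items, wl, lex, prev = prev)
  expect_equal(curr_same$counts$n_rem, 0L)

  # default (null-first): the absent item stays a NULL error
  curr <- score_sheet(wl$items[-3], wl, lex, prev = prev)
  expect_equal(curr$counts$n_rem, 0L)
  expect_equal(curr$counts$n_null, 1L)

  # removal-first precedence reclassifies it as REM
  cfg_rem <- scoring_config(removal_precedence = "removal_first")
  prev_rem <- score_sheet(wl$items, wl, lex, cfg_rem)
  curr_rem <- score_sheet(wl$items[-3], wl, lex, cfg_rem, prev = prev_rem)
  expect_equal(curr_rem$counts$n_rem, 1L)
  expect_equal(curr_rem$counts$n_null, 0L)
})

test_that("score_sheet handles perfect and near-miss sheets", {
  lex <- toy_lexicon()
  wl <- word_list(c("metalmark", "anglewing", "silvertail"))
  perfect <- score_sheet(wl$items, wl, lex)
  expect_equal(perfect$counts$n_correct, 3L)
  expect_equal(perfect$counts$seq_index, 0)
  expect_equal(perfect$counts$n_near + perfect$counts$n_ins +
                 perfect$counts$n_null, 0L)

  near <- score_sheet(c("metalmask", "anglewing", "silvertail"), wl, lex)
  expect_equal(near$counts$n_correct, 2L)
  expect_equal(near$counts$n_near, 1L)
})
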
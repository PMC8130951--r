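test_that("block_randomize respects the card pool", {
  g78 <- block_randomize(78, seed = 1)
  expect_equal(as.integer(table(g78)), rep(26L, 3L))

  g76 <- block_randomize(76, seed = 2)
  tab <- table(factor(g76, levels = c("memory_palace",
                                      "aboriginal_method", "untrained")))
  expect_true(all(tab <= 26L))
  expect_equal(sum(tab), 76L)

  expect_identical(block_randomize(50, seed = 3),
                   block_randomize(50, seed = 3))
  expect_error(block_randomize(79), "78")
})

test_that("block_randomize group sizes follow the hypergeometric draw", {
  # drawing 76 cards from 26/26/26: E[size] = 76 * 26 / 78, and the size
  # of one group is multivariate-hypergeometric with known variance
  set.seed(4)
  sizes <- replicate(2000, sum(block_randomize(76) == "untrained"))
  n <- 76; K <- 26; M <- 78
  mu <- n * K / M
  v <- n * (K / M) * (1 - K / M) * (M - n) / (M - 1)
  expect_lt(abs(mean(sizes) - mu), 4 * sqrt(v / 2000))
  expect_true(all(sizes <= 26 & sizes >= 76 - 52))
})

test_that("generate_wordlist builds unique lexicon-covered compounds", {
  b <- generate_wordlist(20L, seed = 10)
  expect_length(b$wordlist$items, 20L)
  expect_false(anyDuplicated(b$wordlist$canonical) > 0)
  for (i in seq_len(20L)) {
    expect_true(is_meaningful(b$wordlist$canonical[i], b$lexicon))
    # designated near variant: meaningful, within spelling distance, distinct
    expect_true(is_meaningful(b$near_variants[i], b$lexicon))
    expect_lte(edit_distance(b$near_variants[i], b$wordlist$canonical[i]),
               2L)
    expect_false(b$near_variants[i] %in% b$wordlist$canonical)
    # insertion variant: meaningful but far from its target
    expect_gt(edit_distance(b$ins_variants[i], b$wordlist$canonical[i]), 2L)
    expect_false(b$ins_variants[i] %in% b$wordlist$canonical)
  }
  b2 <- generate_wordlist(20L, seed = 10)
  expect_identical(b$wordlist$items, b2$wordlist$items)
  expect_error(generate_wordlist(100L), "pools too small")
})

test_that("noise-free simulation yields perfect ordered sheets", {
  b <- generate_wordlist(10L, seed = 11)
  cfg <- simulation_config(list_length = 10L, p_spell = 0,
                           sequence_jitter = matrix(0, 3, 3,
                             dimnames = list(c("memory_palace",
                                               "aboriginal_method",
                                               "untrained"), NULL)),
                           seed = 11)
  set.seed(11)
  sim <- simulate_participant(1 - 1e-9, "untrained", b, cfg)
  for (tp in unique(sim$responses$timepoint)) {
    rows <- sim$responses[sim$responses$timepoint == tp, ]
    expect_equal(rows$entry_text, b$wordlist$canonical[1:10])
    sc <- score_sheet(rows$entry_text, b$wordlist, b$lexicon)
    expect_equal(sc$counts$n_correct, 10L)
    expect_equal(sc$counts$position_sum, 0L)
  }
})

test_that("zero jitter preserves relative order despite omissions", {
  b <- generate_wordlist(12L, seed = 12)
  cfg <- simulation_config(list_length = 12L, p_spell = 0,
                           sequence_jitter = matrix(0, 3, 3,
                             dimnames = list(c("memory_palace",
                                               "aboriginal_method",
                                               "untrained"), NULL)),
                           seed = 12)
  set.seed(12)
  for (i in 1:5) {
    sim <- simulate_participant(0.6, "untrained", b, cfg)
    for (tp in unique(sim$responses$timepoint)) {
      rows <- sim$responses[sim$responses$timepoint == tp, ]
      sc <- score_sheet(rows$entry_text, b$wordlist, b$lexicon)
      expect_equal(sc$counts$position_sum, 0L)
    }
  }
})

test_that("mean correct count follows the binomial expectation", {
  ability <- 0.75
  b <- generate_wordlist(20L, seed = 13)
  set.seed(14)
  m <- replicate(120, {
    sim <- simulate_participant(ability, "untrained", b,
                                null_config(simulation_config()))
    rows <- sim$responses[sim$responses$timepoint == "baseline", ]
    score_sheet(rows$entry_text, b$wordlist, b$lexicon)$counts$n_correct
  })
  se <- sqrt(20 * ability * (1 - ability) / 120)
  expect_lt(abs(mean(m) - 20 * ability), 4 * se)
})

test_that("scoring recovers generator ground truth exactly", {
  cfg <- simulation_config(n_per_group = 4L, seed = 15)
  st <- simulate_study(cfg)
  scored <- score_study(st$responses, st$bundle$wordlist, st$bundle$lexicon)
  truth_counts <- dplyr::summarise(
    dplyr::group_by(st$truth, .data$participant_id, .data$timepoint),
    t_cor = sum(.data$true_category == "CORRECT"),
    t_near = sum(.data$true_category == "NEAR_MISS"),
    t_ins = sum(.data$true_category == "INS"),
    t_null = sum(.data$true_category == "NULL_"), .groups = "drop")
  m <- merge(scored, truth_counts, by = c("participant_id", "timepoint"))
  expect_equal(nrow(m), nrow(scored))
  expect_equal(m$n_correct, m$t_cor)
  expect_equal(m$n_near, m$t_near)
  expect_equal(m$n_ins, m$t_ins)
  expect_equal(m$n_null, m$t_null)
})

test_that("error-mixture frequencies are recovered from 50 participants", {
  mix <- c(p_null = 0.5, p_near = 0.3, p_ins = 0.2)
  cfg <- simulation_config(error_mix = mix, seed = 16,
                           ability_shape1 = 4, ability_shape2 = 4)
  b <- generate_wordlist(20L, seed = 16)
  set.seed(16)
  cats <- character(0)
  for (i in 1:50) {
    sim <- simulate_participant(stats::rbeta(1, 4, 4), "untrained", b, cfg)
    cats <- c(cats, sim$truth$true_category[
      sim$truth$true_category != "CORRECT"])
  }
  n_err <- length(cats)
  freq <- c(p_null = mean(cats == "NULL_"),
            p_near = mean(cats == "NEAR_MISS"),
            p_ins = mean(cats == "INS"))
  for (nm in names(mix)) {
    se <- sqrt(mix[nm] * (1 - mix[nm]) / n_err)
    expect_lt(abs(freq[nm] - mix[nm]), 4 * se)
  }
})

test_that("mean SeqI increases with sequence jitter", {
  b <- generate_wordlist(15L, seed = 17)
  grid <- c(0, 0.5, 1.5, 4)
  means <- numeric(length(grid))
  set.seed(17)
  for (gi in seq_along(grid)) {
    cfg <- simulation_config(list_length = 15L, p_spell = 0,
                             sequence_jitter = matrix(grid[gi], 3, 3,
                               dimnames = list(c("memory_palace",
                                                 "aboriginal_method",
                                                 "untrained"), NULL)),
                             seed = 17)
    s <- replicate(60, {
      sim <- simulate_participant(0.9, "untrained", b, cfg)
      rows <- sim$responses[sim$responses$timepoint == "baseline", ]
      score_sheet(rows$entry_text, b$wordlist, b$lexicon)$counts$seq_index
    })
    means[gi] <- mean(s, na.rm = TRUE)
  }
  expect_true(all(diff(means) > 0))
})

test_that("simulate_study is deterministic and ceiling-calibrated", {
  cfg <- simulation_config(n_per_group = 25L, seed = 18)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$profiles), 75L)

  # ceiling effect: median baseline ground-truth correct count >= 17/20
  base <- s1$truth[s1$truth$timepoint == "baseline", ]
  counts <- tapply(base$true_category == "CORRECT", base$participant_id,
                   sum)
  expect_gte(stats::median(counts), 17)
})
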
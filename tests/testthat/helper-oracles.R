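# Independent oracles and small fixtures used across the suite.

# Plain dynamic-programming Levenshtein, written separately from the
# implementation path (which delegates to utils::adist).
dp_edit_distance <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[n + 1L, m + 1L]
}

# Definitional Friedman statistic from within-row ranks (no ties assumed).
friedman_q_oracle <- function(y) {
  y <- as.matrix(y)
  N <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1L, rank))
  Rj <- colSums(r)
  12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
}

# Exact permutation p-value by enumerating every within-row ranking.
friedman_p_exact <- function(y) {
  y <- as.matrix(y)
  N <- nrow(y); k <- ncol(y)
  q_obs <- friedman_q_oracle(y)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), N)))
  qs <- apply(idx, 1L, function(ix) {
    r <- perms[ix, , drop = FALSE]
    Rj <- colSums(r)
    12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  })
  mean(qs >= q_obs - 1e-9)
}

# A tiny lexicon around the metalmark / anglewing examples.
toy_lexicon <- function() {
  lexicon(words = c("metalmask", "angelwing"),
          morphemes = c("metal", "mark", "mask", "spot", "angle", "angel",
                        "wing", "silver", "tail"))
}

toy_wordlist <- function(n = 5L) {
  pools <- default_morpheme_pools()
  word_list(paste0(pools$modifiers[seq_len(n)], pools$heads[seq_len(n)]))
}
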
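#' Friedman repeated-measures test with effect size
#'
#' Rank-based test for k related conditions measured on the same subjects,
#' using within-subject midranks and the standard tie correction (as
#' implemented by [stats::friedman.test()]). Kendall's W is attached as an
#' effect size computed from the Friedman statistic, together with the
#' conventional weak/moderate/strong label.
#'
#' @param values Numeric matrix, subjects in rows, conditions (e.g.
#'   timepoints) in columns. Rows with any missing cell are dropped
#'   (listwise deletion) with a message.
#' @return An object of class `friedman_rm`: list with `Q`, `df`, `p`,
#'   `KW`, `label`, `N`, `k`, `n_dropped`.
#' @export
friedman_rm <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need k >= 2 conditions", call. = FALSE)
  complete <- stats::complete.cases(values)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("friedman_rm: dropping ", n_dropped,
            " subject(s) with missing cells (listwise)")
    values <- values[complete, , drop = FALSE]
  }
  if (nrow(values) < 2L) stop("need N >= 2 subjects", call. = FALSE)
  ft <- suppressWarnings(stats::friedman.test(values))
  Q <- unname(ft$statistic)
  if (is.nan(Q)) Q <- 0  # all rows fully tied: no evidence of ordering
  df <- ncol(values) - 1L
  p <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  KW <- kendalls_w_from_q(Q, N = nrow(values), k = ncol(values))
  structure(list(Q = Q, df = df, p = p, KW = KW,
                 label = interpret_effect_size(KW),
                 N = nrow(values), k = ncol(values), n_dropped = n_dropped),
            class = "friedman_rm")
}

#' @export
print.friedman_rm <- function(x, ...) {
  cat(sprintf(
    "Friedman Q = %.3g, df = %d, p = %.3g, Kendall's W = %.2f (%s), N = %d\n",
    x$Q, x$df, x$p, x$KW, x$label, x$N))
  invisible(x)
}

#' Kendall's W from a Friedman statistic
#'
#' Concordance effect size for a Friedman repeated-measures comparison:
#' `W = Q / (N * (k - 1))`, clipped to \[0, 1\].
#'
#' @param Q Friedman chi-square statistic.
#' @param N Number of subjects.
#' @param k Number of conditions.
#' @return Kendall's W in \[0, 1\].
#' @examples
#' kendalls_w_from_q(18.5, N = 25, k = 3)  # 0.37
#' @export
kendalls_w_from_q <- function(Q, N, k) {
  stopifnot(Q >= 0, N >= 1, k >= 2)
  min(1, max(0, Q / (N * (k - 1))))
}

#' Interpret a Kendall's W effect size
#'
#' Conventional bins: weak below ~0.2, moderate up to ~0.4, strong above.
#' The published bin edges leave small gaps (0.19-0.20 and 0.39-0.40);
#' these are closed at their midpoints (0.195, 0.395).
#'
#' @param KW Kendall's W in \[0, 1\].
#' @return `"weak"`, `"moderate"` or `"strong"`.
#' @export
interpret_effect_size <- function(KW) {
  stopifnot(KW >= 0, KW <= 1)
  if (KW < 0.195) "weak" else if (KW < 0.395) "moderate" else "strong"
}

#' Nemenyi post-hoc pairwise comparisons after a Friedman test
#'
#' Compares mean within-subject ranks between every pair of conditions
#' against the studentized range distribution with infinite degrees of
#' freedom: for conditions i, j the statistic is
#' `q = |Rbar_i - Rbar_j| / sqrt(k (k + 1) / (6 N)) ` and the p-value is
#' `P(Q_{k,Inf} > q * sqrt(2))` -- equivalently mean-rank differences are
#' tested against the usual critical difference
#' `CD = (q_alpha / sqrt(2)) * sqrt(k (k + 1) / (6 N))`.
#'
#' @param values Numeric matrix, subjects x conditions; column names label
#'   the conditions. Rows with missing cells are dropped listwise.
#' @return Tibble with columns `cond_a`, `cond_b`, `mean_rank_diff`,
#'   `statistic`, `p`.
#' @export
nemenyi_posthoc <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2L) stop("need k >= 2 conditions", call. = FALSE)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  N <- nrow(values)
  if (N < 2L) stop("need N >= 2 subjects", call. = FALSE)
  labs <- colnames(values)
  if (is.null(labs)) labs <- paste0("cond", seq_len(k))
  r <- t(apply(values, 1L, rank))
  mean_ranks <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * N))
  pairs <- utils::combn(k, 2L)
  diff <- mean_ranks[pairs[1L, ]] - mean_ranks[pairs[2L, ]]
  q <- abs(diff) / se
  p <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  tibble::tibble(cond_a = labs[pairs[1L, ]], cond_b = labs[pairs[2L, ]],
                 mean_rank_diff = unname(diff), statistic = unname(q),
                 p = unname(p))
}

#' Improvement-to-perfect-recall ratio
#'
#' Compares, within one training group, the proportion of eligible
#' participants (those not already perfect at baseline) who improved to a
#' perfect score post-training against the proportion of the whole cohort
#' that was perfect at baseline. The default `proportion_ratio` method is
#' the ratio of those two proportions; `odds_ratio` gives the cross-product
#' odds ratio of the same 2x2 counts. Both carry Katz-type log-scale Wald
#' 95% confidence intervals; zero cells trigger a 0.5 continuity correction
#' (flagged in the result).
#'
#' @param n_improved Eligible participants in the group who reached a
#'   perfect score post-training.
#' @param n_eligible Group size after excluding baseline-perfect
#'   participants.
#' @param baseline_perfect_total Cohort-wide count of baseline-perfect
#'   participants.
#' @param cohort_total Total cohort size.
#' @param method `"proportion_ratio"` (default) or `"odds_ratio"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `improvement_result`: list with the input
#'   counts, `ratio`, `ci_low`, `ci_high`, `method`,
#'   `continuity_corrected`.
#' @examples
#' improvement_ratio(12, 19, 17, 76)  # ratio 2.82
#' @export
improvement_ratio <- function(n_improved, n_eligible,
                              baseline_perfect_total, cohort_total,
                              method = c("proportion_ratio", "odds_ratio"),
                              conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n_improved >= 0, n_eligible >= n_improved,
            baseline_perfect_total >= 0,
            cohort_total >= baseline_perfect_total, n_eligible >= 1,
            cohort_total >= 1)
  a <- n_improved; n1 <- n_eligible
  b <- baseline_perfect_total; n2 <- cohort_total
  cc <- FALSE
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "proportion_ratio") {
    ratio <- (a / n1) / (b / n2)
    if (a == 0L || b == 0L) {
      cc <- TRUE
      a2 <- a + 0.5; b2 <- b + 0.5; n1c <- n1 + 0.5; n2c <- n2 + 0.5
    } else {
      a2 <- a; b2 <- b; n1c <- n1; n2c <- n2
    }
    est <- (a2 / n1c) / (b2 / n2c)
    se <- sqrt(1 / a2 - 1 / n1c + 1 / b2 - 1 / n2c)
    ci <- est * exp(c(-1, 1) * z * se)
  } else {
    c_ <- n1 - a; d_ <- n2 - b
    if (any(c(a, b, c_, d_) == 0)) {
      cc <- TRUE
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d_ <- d_ + 0.5
    }
    ratio <- (a * d_) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
    ci <- ratio * exp(c(-1, 1) * z * se)
  }
  structure(list(n_improved = n_improved, n_eligible = n_eligible,
                 baseline_perfect_total = baseline_perfect_total,
                 cohort_total = cohort_total,
                 ratio = ratio, ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, method = method,
                 continuity_corrected = cc),
            class = "improvement_result")
}

#' @export
print.improvement_result <- function(x, ...) {
  cat(sprintf("%s = %.2f (%d%% CI %.2f-%.2f), %d/%d improved vs %d/%d at baseline%s\n",
              if (x$method == "odds_ratio") "OR" else "ratio",
              x$ratio, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_improved, x$n_eligible, x$baseline_perfect_total,
              x$cohort_total,
              if (x$continuity_corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Randomly equalize group sizes
#'
#' Repeated-measures comparisons across groups require equal N; oversized
#' groups are trimmed by uniformly random exclusion of subjects, re-drawn
#' independently for each analyzed parameter so no single participant's
#' exclusion drives every comparison.
#'
#' @param ids_by_group Named list: group label -> character vector of
#'   subject ids.
#' @param target_n Target size per group (default: size of the smallest
#'   group).
#' @param seed Integer seed making the exclusion reproducible.
#' @return List with `kept` (named list of retained ids) and `excluded`
#'   (named list of excluded ids).
#' @export
equalize_group_sizes <- function(ids_by_group,
                                 target_n = min(lengths(ids_by_group)),
                                 seed = NULL) {
  sizes <- lengths(ids_by_group)
  if (any(target_n > sizes)) {
    stop("target_n exceeds a group size", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  kept <- excluded <- stats::setNames(vector("list", length(ids_by_group)),
                                      names(ids_by_group))
  for (g in names(ids_by_group)) {
    ids <- ids_by_group[[g]]
    n_drop <- length(ids) - target_n
    if (n_drop > 0L) {
      drop_ids <- sample(ids, n_drop)
      excluded[[g]] <- drop_ids
      kept[[g]] <- setdiff(ids, drop_ids)
    } else {
      excluded[[g]] <- character()
      kept[[g]] <- ids
    }
  }
  list(kept = kept, excluded = excluded)
}
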
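# recallkit

Scoring and nonparametric analysis of free-recall memory experiments.

Memory-training trials — for example comparing the classical memory-palace
technique with Australian Aboriginal narrative (songline-style) methods —
typically ask participants to study an ordered list of items and write down
as many as they can recall at several timepoints. Scoring those handwritten
sheets is a surprisingly judgment-laden task: is "metalmask" a creative
near miss for *metalmark*, a spelling slip, or a different word entirely?
And how should order accuracy be measured when a single misplaced item
produces two observed position errors? `recallkit` turns those judgments
into a deterministic, configurable, fully tested pipeline for
experimentalists analysing serial-recall data.

## What it computes

**Scoring.** Each written entry is normalized and fuzzily matched to the
target list with a one-to-one maximum-similarity assignment (Levenshtein
similarity plus compound-morpheme credit, deterministic tie-breaking).
Matched entries are classified into a four-category error taxonomy:

* `CORRECT` — exact match, or a small misspelling (edit distance ≤ 2) that
  is *not* a meaningful word ("meselmark");
* `NEAR_MISS` — a small edit that *is* a semantically meaningful word under
  a user-supplied lexicon ("metalmask");
* `INS` — a completely different word written in a target's place
  ("metalspot");
* `NULL` — no entry for a target; `REM` tracks removals of previously
  correct answers across timepoints.

Order accuracy is summarised by the **Sequence Index**

> SeqI = (Σ positional distances ÷ 2) ÷ (# correct responses),

where the halving corrects for the fact that one out-of-order item
necessarily creates two observed position errors: recalling 1,2,3,4,5 as
1,3,2,4,5 gives two position errors of distance 1 and SeqI = (2/2)/5 = 0.2.

**Statistics.** Within-group repeated-measures comparisons across
timepoints use the Friedman test (midranks, tie-corrected) with Nemenyi
post-hoc pairwise comparisons (studentized range, infinite df), and
Kendall's W effect sizes computed from the Friedman statistic as
W = Q / (N(k−1)), labelled weak/moderate/strong. A ceiling-robust
**improvement analysis** compares each group's proportion of eligible
(non-perfect-baseline) participants who improved to a perfect score
post-training against the cohort's baseline-perfect proportion, with
Katz-type log-scale Wald confidence intervals (a true cross-product odds
ratio is available alongside the default proportion ratio).

**Simulation.** A synthetic cohort generator reproduces the structure the
analysis assumes — card-deck block randomization into three arms,
compound-word target lists with a matching lexicon, a Beta-ability /
logistic-effect Bernoulli recall model with a strong ceiling effect, a
configurable error mixture and rank-jitter sequence noise — with full
ground-truth bookkeeping, so every stage of the pipeline can be tested
end to end without any external data.

## Worked example

```r
library(recallkit)

lex <- lexicon(words = "metalmask",
               morphemes = c("metal", "mark", "mask", "spot",
                             "angle", "wing", "silver", "tail"))
wl <- word_list(c("metalmark", "anglewing", "silvertail"))
score_sheet(c("Metal-mask", "anglewing", "silvertail"), wl, lex)
#> <scored_sheet>
#> # A tibble: 1 × 7
#>   n_correct n_near n_ins n_null n_rem position_sum seq_index
#>       <int>  <int> <int>  <int> <int>        <int>     <dbl>
#> 1         2      1     0      0     0            0         0
```

"Metal-mask" normalizes to `metalmask`, one edit from `metalmark` and a
meaningful word, so it scores a near miss; the other two items are correct
and in order, so the Sequence Index is 0.

A full synthetic study, scored and analysed:

```r
study <- simulate_study(simulation_config(n_per_group = 25, seed = 7))
rep <- run_analysis(study$responses, study$bundle$wordlist,
                    study$bundle$lexicon, equalization_seed = 7)
rep$friedman[rep$friedman$parameter == "seq_index", ]
#>   parameter group                 N      Q    df        p      KW label
#> 1 seq_index aboriginal_method    24 43.3       2 3.96e-10 0.902   strong
#> 2 seq_index memory_palace        24 21.9       2 1.74e- 5 0.457   strong
#> 3 seq_index untrained            24  0.154     2 9.26e- 1 0.00321 weak
rep$improvement[, c("group", "n_improved", "n_eligible", "ratio")]
#>   group             n_improved n_eligible ratio
#> 1 aboriginal_method          8         17  1.86
#> 2 memory_palace              8         19  1.66
#> 3 untrained                  7         20  1.38
```

The simulated narrative-method arm shows the largest sequencing effect
(Kendall's W = 0.90, strong) while the untrained arm shows none, and its
improvement-to-perfect-recall ratio is the highest of the three arms —
the qualitative pattern the generator is calibrated to produce.

The same pipeline runs from a shell via the thin wrapper installed at
`inst/bin/recallkit`:

```sh
Rscript inst/bin/recallkit run-all --seed 7 --out results/run7
```

which writes `responses.csv`, `truth.csv`, `scored.csv`,
`summary_long.csv` (violin-ready long format), `report.json` and
`provenance.json`.

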
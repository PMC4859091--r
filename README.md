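# stylemark

Markov style capture, constrained melody generation, and style-attribution
experiments in R.

## What problem this package addresses

Statistical style-imitation systems learn a performer's habits from a few
minutes of free improvisation and generate "more of the same". The
scientific question is whether the imitation works *for its own user*:
presented with short excerpts and asked "Does this sound like your
music?", do people attribute machine-generated pieces built from their own
material to themselves as accurately as they recognise their own plain
recordings? `stylemark` is for researchers in music cognition and
computational psychology who want to run, simulate, or reanalyse that
experiment end to end.

## The models at the core

**Style model.** A performance is a sequence of events (notes or chords =
pitch sets). A participant's style is a first-order Markov chain over
these states, `P(t | s) = n(s→t) / Σ_u n(s→u)`, fitted per participant
with no transitions across melody boundaries, plus the sets of start
states and end states (first/last events of the training melodies).

**Constrained generation.** A generated piece is 16 events in 4 chunks —
statement, continuation, continuation, conclusion — with unary positional
constraints: position 1 ∈ start states, position 4 free, positions 8 and
12 ∈ end states, position 16 = position 1, all other positions in neither
boundary set. A backward feasibility pass keeps, at each position, only
the states from which the remaining constraints are satisfiable; forward
sampling renormalises the transition probabilities over those sets, so
generation preserves local statistics and provably never dead-ends.

**Experiment + analysis.** A simulated cohort (equal-variance
signal-detection responders over styled training sets) produces the trial
table; the analysis computes per-condition accuracies, the equivalence
margin δ = 0.2 × reference accuracy, the Hodges–Lehmann estimate and
rank-based 90% CI of the paired accuracy difference (with the TOST
restatement), Woolf homogeneity and the Mantel–Haenszel pooled odds ratio
over group strata, and the nonparametric indices A′ (discriminability) and
B″d (response bias) with paired condition comparisons.

## Worked example

```r
library(stylemark)

# a 56-participant cohort in 14 groups of 4, then the 896-trial experiment
cohort <- generate_cohort(cohort_config(), seed = 11)
trials <- run_experiment(cohort, seed = 22)
report <- analyze_trials(trials)
report
#> Style-attribution analysis
#>   896 trials; mean accuracy: human 0.737, machine 0.717
#>   equivalence margin +/- 0.147
#> Rank-based equivalence test (n = 56)
#>   HL estimate 0.0000, 90% CI (-0.0625, 0.0625)
#>   margin +/- 0.1473 -> EQUIVALENT
#>   TOST p = 0.0001 (lower), 0.0000 (upper)
#>   Woolf X-squared = 7.43, df = 13, p = 0.88
#>   MH pooled OR = 0.90 [0.67-1.21]
#>   A':   0.764 vs 0.736, p = 0.423
#>   B''d: -0.009 vs 0.444, p = 0.000
#>   split-half bias (machine): 0.240 vs 0.305, p = 0.403 (n = 54)
```

Reading the output: the two conditions' mean accuracies sit well above the
0.5 chance level; the 90% interval for the machine-minus-human accuracy
difference lies inside (−0.147, 0.147), so practical equivalence is
declared; the Woolf test finds no heterogeneity of the per-group odds
ratios, licensing the pooled Mantel–Haenszel OR; discriminability (A′)
does not differ detectably between conditions while response bias (B″d)
is markedly more conservative for machine-generated pieces.

Generating music from a style:

```r
p <- cohort$participants[["p01"]]
piece <- sample_piece(p$model, seed = 5)   # 16 events, 4 constrained chunks
write_midi(piece, "piece.mid")
validate_piece(piece, p$model)             # TRUE
```

The statistical layer also runs from a shell:

```sh
Rscript scripts/analyze.R --trials trials.csv --json report.json
```

## Package layout

- `R/` — MIDI I/O and event preparation, style model, constrained
  generation, synthetic cohort, experiment assembly, statistics.
- `vignettes/style-attribution.Rmd` — the methods vignette: model
  assumptions, parameter defaults and their derivations, numerical
  choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
- `scripts/` — `acceptance.R` and the `analyze.R` command-line entry.
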
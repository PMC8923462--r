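---
title: "Scoring drug-gene interactions from pinned colony arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-gene interactions from pinned colony arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinscreen)
```

## The measurement and its problems

A chemogenomic screen pins a genome-wide mutant library onto agar plates in
a fixed grid (384 or 1536 colonies per plate), with and without a drug, and
uses colony area as a proxy for fitness. The quantity of interest per
library strain is the log2 ratio of its drug-treated to untreated fitness: a
negative value means drug sensitivity, a positive value resistance — or, in
a drug-hypersensitive query background, suppression of that
hypersensitivity.

Raw colony areas are not comparable across plates or positions. Plates
differ in pinning density, inoculum and incubation; within a plate, colony
size drifts along rows and columns, follows smooth spatial fields
(incubator gradients, agar thickness), is inflated at plate edges where
nutrients are unshared, and is inflated next to dead or missing neighbors
(nutrient windfall). On top of that, spontaneous suppressor mutations
produce rare "jackpot" colonies — very large in one replicate, normal in
the others — that mimic resistance if left in.

`pinscreen` implements the full path from quantified colony-size tables to
ranked, FDR-controlled interaction calls, plus a seeded generator of
synthetic screens with planted ground truth so that every stage can be
validated without any external data.

## Normalization cascade

Each plate passes through the following steps, in order; all parameters
live in `normalization_config()` and every applied step is recorded on the
returned plate.

1. **Intra-plate 70th-percentile scaling** (`percentile_normalize()`).
   Every size is divided by the plate's 0.70-quantile, computed with linear
   interpolation between order statistics over library positions only
   (`BORDER`/`EMPTY` positions are still rescaled but do not set the
   anchor, since control and border colonies differ systematically from
   library colonies). The 70th percentile rather than the median makes the
   anchor robust when a substantial fraction of the library is drug
   sensitive — the bulk above the 70th percentile is dominated by
   unaffected strains — while a handful of resistant outliers cannot move
   it either.
2. **Row/column correction** (`row_col_normalize()`). Each colony is
   divided by its row median relative to the plate median, then (on the
   row-corrected plate) by its column median relative to the plate median.
   On separable gradients this leaves every row and column median equal to
   the plate median.
3. **Neighborhood correction** (`neighborhood_normalize()`). Each colony
   is divided by the median of its square window (default half-width 2, a
   5×5 window clipped at plate edges) relative to the plate median. The
   focal colony is excluded from its own window so that a lone outlier —
   which is exactly the signal we are after — cannot flatten itself.
4. **Competition correction** (`competition_normalize()`). With
   `d = max(0, 1 − median(4-neighbors)/plate median)`, each colony is
   divided by `1 + γ·d` (default γ = 0.5). A colony whose neighbors are
   dead (`d = 1`) is shrunk by 1.5-fold, compensating the nutrient
   windfall; colonies with normal neighbors are untouched.
5. **Final rescale.** The positional corrections are ratios of medians and
   preserve the overall scale only approximately, so the plate is rescaled
   once more to put the library 70th percentile exactly at 1. This makes
   "size 1.0" mean "typical library colony" everywhere downstream.

The cascade is exactly invariant under global rescaling of the raw sizes,
and applying the percentile step twice equals applying it once.

**Dead colonies.** Sizes at or below `min_size` (default 0, i.e. exactly
dead) are excluded from every quantile and median above — a patch of dead
colonies must not drag its row median down — but their values are retained:
a dead colony is biological signal, and the log transform later maps it to
a strongly negative fitness via the `log2_floor` pseudo-size (default 0.01,
log2 = −6.64).

**Jackpot filter** (`jackpot_filter()`). Jackpots are defined by replicate
discordance on a reference condition (in the motivating screens,
hydroxyurea in the DNA-damage-checkpoint mutant background, where
spontaneous suppressors are strongly selected): a (strain, replicate) is
flagged when its normalized size exceeds `m` times the strain's own
cross-replicate median while at least one replicate stays within the
bound. A strain that is large in *every* replicate is genuine resistance
and is never flagged. Flagged pairs are removed from **all** conditions of
that background, since the underlying colony carries an unknown secondary
mutation. The threshold is anchored on the strain's own median rather than
an absolute size precisely because the phenomenon is discordance, not
largeness. The default `m = 1.5` separates cleanly between replicate noise
(SD ≈ 0.2 on log2, so sizes within ~15% of each other) and jackpots
(typically ≥ 4-fold); with fewer than two reference replicates the filter
disables itself with a warning.

## Interaction score and calls

Per strain, background and condition, surviving replicate sizes are
log2-transformed (`log2(max(size, log2_floor))`) and summarized by their
mean and sample SD (`strain_stats()`; the SD is undefined below two
replicates, which makes the strain uncallable but still reported). Then,
with ΔMEAN = mean(treated) − mean(untreated) and ΣSD = SD(treated) +
SD(untreated):

$$S \;=\; \frac{\Delta MEAN}{1 + k\,\Sigma SD / |\Delta MEAN|}, \qquad k = 2$$

`sd_corrected_score()` shrinks noisy effects toward zero: S equals ΔMEAN
when ΣSD = 0, is zero when ΔMEAN = 0, preserves the sign, satisfies
|S| ≤ |ΔMEAN| everywhere, and strictly decreases in magnitude as ΣSD
grows. Working on the log2 scale throughout (log-then-average, and ΣSD
computed on log2 values) keeps the score in interpretable log2-fitness
units and is the scale on which multiplicative colony-size effects are
additive; averaging raw ratios before the log would bias the means.

A strain is **called** (`call_interaction()`) when both

* |ΔMEAN| > k·ΣSD — the separation of the two condition means exceeds
  twice the summed SDs, and
* |S| ≥ `effect_floor` — a minimum-effect filter that discards
  statistically clean but biologically negligible shifts. The defaults are
  0.05 for sensitivity/resistance screens and 0.5 for suppressor screens,
  where only strong rescue is of interest.

Negative significant effects are `sensitive`, positive `resistant`.
Independently, each strain gets a two-sided unpaired Student t-test on the
replicate log2 values (`two_sample_t_test()`; Welch's correction is an
option flag, off by default) and Benjamini-Hochberg adjusted q-values
(`bh_adjust()`) computed over **all callable strains of the background**,
not only the candidates — a smaller family would be anti-conservative.
Suppressor calling (`call_suppressors()`) then requires all three:
resistant-direction two-SD significance, S ≥ 0.5, and q < 0.10.

The minimum-effect floor is applied to S, the SD-corrected quantity, not to
raw ΔMEAN; where the two readings could diverge the shrunken score is the
more conservative choice and matches the floor's purpose of filtering weak
effects after noise correction.

`run_screen()` composes the whole path (normalize → jackpot → stats →
score → call → t-test/BH) and sorts the result from most sensitive to most
resistant, the rank axis of the classic screen plot. `cross_tabulate()`
builds per-suppressor profiles across a counter-drug screen and a second
sensitized background, with the relative suppressor strength defined as
the ratio of SD-corrected scores (secondary/primary) and strains missing
from a secondary screen marked not-determined.

## The synthetic screen generator

`generate_screen()` simulates every plate of a design as

```
size(r, c) = baseline(strain) · 2^(effect + ε) · rowfac(r) · colfac(c)
             · smoothfield(r, c) · edgefac(r, c) · competitionfac(neighbors)
```

with ε ~ Normal(0, `noise_sd`) independently per colony (log-normal noise:
areas are positive and effects multiplicative). The defaults define the
simulated study conditions and are not tuned per run:

| parameter | default | what it emulates |
|---|---|---|
| grid | 32 × 48 (1536) | standard high-density pinning |
| replicates | 4 (2 for the lighter screen design) | replicate structure of query-based library screens |
| `noise_sd` | 0.2 log2 units | replicate scatter of pinned colony areas |
| `row_slope`, `col_slope` | 0.1 | ±10% linear row/column trends |
| `smooth_amplitude` | 0.3 | Gaussian spatial field (incubator/agar gradients) |
| `edge_factor`, `edge_width` | 1.3, 2 | nutrient excess in the outer two rings |
| `competition_coef` | 0.5 | windfall next to missing neighbors |
| `missing_prob` | 0.01 | failed pinnings |
| `jackpot_prob`, `jackpot_factor` | 0.01, 4 | spontaneous suppressors on the reference condition, never in all replicates of a strain |
| baseline | log-normal around 500 px (25% CV) | strain-to-strain size differences |

One global seed drives a deterministic per-plate substream, so any subset
of plates is reproducible independently, and the same seed gives
bit-identical output. The planted truth (`synthetic_truth()`) is echoed
back with the realized jackpot assignments, and `truth_confusion()` scores
pipeline calls against it.

What the generator does **not** emulate: colony-shape/segmentation errors
of the upstream quantifier, growth kinetics (a single endpoint size is
drawn), batch effects between plates beyond the global scale (which the
percentile step removes by construction), spatially correlated replicate
noise, and linkage between neighboring library strains. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated noise model, not robustness to every failure mode of real plates.

## Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics (the common
  type-7 convention); medians are the standard sample median over
  non-missing, non-dead entries.
* A row, column or window with no live colony contributes a correction
  factor of 1 (with a warning) rather than dropping the positions.
* A plate with no live colony at all is a hard error naming the plate.
* Zero-variance t-tests resolve by their limit (p = 1 for equal means,
  p = 0 otherwise).
* Ties in rank tables break lexicographically by strain ID, so output
  order is fully deterministic; plate input order never changes results.
* Score tables are written with 17 significant digits and round-trip
  exactly.

## Design choices where the design was open

* **Order of corrections.** Percentile scaling first, then row/column,
  neighborhood, competition — from the global artifact to the most local
  one; each later step works on the residuals of the earlier ones. The
  final rescale restores the percentile anchor that the median-ratio steps
  perturb by a few percent.
* **Self-influence at low density.** On 384-position plates a strong hit
  can shift its own 16-entry column median noticeably (medians over few,
  widely scattered values have coarse steps); at 1536 density this bias is
  well under 0.1 log2 units. The positional toggles in
  `normalization_config()` allow switching the row/column step off for
  very small custom arrays.
* **Edge steps.** The sharp two-ring edge boost is only partially removed
  by median-window corrections (the window straddles the discontinuity);
  in real screens the outer rings are `BORDER` positions excluded from
  scoring anyway, and the generator keeps the artifact to keep the
  simulation honest rather than flattering.
* **Jackpot threshold.** `m = 1.5` is a package default chosen from the
  discordance argument above, not an externally fixed constant; it is
  config-exposed and logged.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
single plates at 8×12 to 32×48 for unit properties, and full screens at
1536 strains × 4 replicates (10–20 simulations) for hit-recovery and
false-discovery measurements, with 30 planted effects of |log2| ≥ 1.5
against noise SD 0.2 — effect sizes and noise chosen to mirror the screen
regime the scoring rule targets: clear hits a two-SD rule should recover
essentially completely, with the BH filter holding false discoveries near
the nominal 10%.

## Limitations

* The positional corrections are median-ratio heuristics, not a 2-D
  surface model; pathological artifacts (checkerboards, half-plate steps)
  are out of scope.
* Strains present in fewer than two surviving replicates per condition are
  reported but uncallable; the pipeline does not borrow strength across
  strains (no moderated variance estimation).
* The jackpot filter needs a reference condition with at least two
  replicates and selective pressure that makes spontaneous suppressors
  visible; without one, discordant outliers remain in the data.
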
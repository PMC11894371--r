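---
title: "Methods: repeatability metrics for replicated stress-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability metrics for replicated stress-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressrep)
```

## The problem

A stress-response curve is a short hormone time course measured on one
animal during a standardized stressor — typically plasma corticosterone at
baseline (0 min) and after 15–30 min of restraint. When the same individual
is sampled on many occasions, the *curve* is the repeated unit. stressrep
asks, per individual: how repeatable are these replicate curves? This is
discrete-individual repeatability, distinct from population-level
repeatability estimated with linear mixed models (which is out of scope
here).

The package operates on a `curve_matrix` per individual (an `R x T` matrix
of replicate curves on a shared time grid, replicates in collection order)
and on a `stress_curve_dataset` of individuals sharing one design. Only
individuals with the same replicate count and time grid are ranked and
correlated against each other.

## The three metrics and their assumptions

### Profile repeatability (PR)

PR summarizes how tightly the replicate curves cluster and how often they
cross:

$$v_t = \frac{\widehat{\mathrm{Var}}_r(X_{\cdot t})}{G^2}, \qquad
S = \left(\overline{v} + \max_t v_t\right)
    \left(1 + \frac{C}{C_{\max}}\right)
    \left(1 + \frac{m}{RT}\right), \qquad
PR = \frac{1}{1+S}$$

where $G$ is the grand mean of all (filled) values, $C$ the number of
(replicate pair, adjacent interval) events with a strict sign change of the
pairwise difference, $C_{\max} = (T-1)R(R-1)/2$, and $m$ the number of
interpolated cells. Design notes:

* **Functional form.** The ingredients (per-timepoint variances, maximum
  variance, crossings, replicate count) are fixed by the metric's
  definition, but the exact published coefficients live in an external
  package we deliberately do not copy. The form above uses exactly those
  ingredients, is bounded on $[0,1]$ with most discrimination in the middle
  of its range, and is isolated behind `ProfileRepeatabilityDetail`-style
  output (`profile_repeatability()$detail`) so it can be swapped without
  touching ranking or combination code. All reference-value checks in the
  test suite use published *ranks*, which are insensitive to these
  constants.
* **Normalization.** Variances are divided by $G^2$, making PR invariant to
  the measurement scale (ng/mL vs nmol/L). $G = 0$ is an error.
* **Sample variance** (denominator $R-1$) is used because replicate counts
  are small (2–28 in practice).
* **Crossings.** A zero difference at an interval endpoint (touching) is
  *not* a crossing; requiring a strict sign reversal avoids double-counting
  a curve that meets another and retreats.
* **Missing data.** PR is the only metric that accepts missing cells. A
  missing cell is filled by linear interpolation *in replicate-index space*
  at its own timepoint (between the last and next present replicate), never
  along the time axis. When the first or last replicate is missing the
  index space is treated cyclically — for a single missing boundary
  replicate the fill is the mean of the last and next present values. Each
  timepoint must retain at least two present values. Because interpolation
  artificially smooths the panel and inflates apparent repeatability, the
  $(1 + m/RT)$ factor pushes the score back down.

### Generalized KL divergence

For successive ordered replicate pairs $p = X_{r\cdot}, q = X_{r+1,\cdot}$:

$$D(p\,\|\,q) = \sum_t \left[p_t \ln\frac{p_t}{q_t} - p_t + q_t\right],
\qquad \text{score} = \frac{1}{R-1}\sum_{r=1}^{R-1} D_r$$

The curves are used as-is, not converted to probability distributions. The
plain $\sum p\ln(p/q)$ can be negative on unnormalized data, so we use the
generalized (Bregman/I-) divergence with the $-p+q$ correction, which is
nonnegative and zero exactly when the successive curves are identical —
matching the required orientation (0 = most repeatable, no lower-
repeatability bound). Aggregation over *successive ordered pairs* (rather
than, say, all unordered pairs) is this package's documented choice: it
preserves the metric's stated order sensitivity and parallels the RMSSD.
The metric refuses missing cells and any value $\le 0$ (the natural log is
used throughout); the error names the offending replicate and timepoint.

### HPA flexibility (RMSSD)

Each replicate curve is collapsed to its unweighted mean over timepoints
(a time-weighted integral would be an alternative; unweighted is the
conventional reading and our choice), and the score is the root mean square
of successive differences of those means, denominator $R-1$. Low RMSSD =
low flexibility = high repeatability. Collapsing a curve to its mean
discards shape information — two curves with opposite slopes and equal
means are indistinguishable — which is precisely why comparing this metric
against PR is informative.

## Ranking and correlation

Scores on incomparable scales are compared through rankings.
`rank_scores()` uses competition ("min") ranking — $k$ individuals tied at
the best unassigned position $p$ all get rank $p$, the next distinct score
gets $p+k$ — because that is the tie pattern observed in published score
tables (a three-way tie at 5 followed by 8; dense or average ranking cannot
reproduce it). Ties are exact equalities at full precision by default;
`tie_decimals` optionally rounds first, since printed tables sometimes show
rounded ties that are distinct underneath.

`correlate_ranks()` computes plain Pearson correlations on the integer rank
vectors (which, on tie-free data, equals Spearman on the raw scores), with
two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df and star
codes `***` (< 0.001), `**` (< 0.01), `*` (< 0.05), `.` (< 0.10). No
multiple-testing correction is applied, matching the conventional
presentation of such matrices; an all-tied (zero-variance) rank column
yields `NA` with a warning rather than an error. Human visual rankings
("majority"/"minority") are merged as externally supplied columns via
`add_external_ranks()`; the package never models the visual-scoring
process.

## Combination analysis

`combination_analysis()` scores, for each individual and each subset size
$k$ from 2 to $R$, every $k$-subset of replicate curves — or, when
$\binom{R}{k} > 100$, a uniform sample of exactly 100 *distinct* subsets
(the cap). Whether the original analysis sampled with or without duplicate
designs is unstated; distinct subsets were chosen so the empirical
distribution is over unique designs. Subsets keep their indices sorted, so
the original collection order is preserved within each subset (this matters
for KL and RMSSD). One RNG stream per (individual, $k$) is derived from the
master seed, so adding individuals to a dataset does not perturb other
individuals' draws. The $k = R$ row is the consensus score and is included
in the tidy output table; by construction it equals `score_dataset()`
exactly.

## The synthetic generator: what it emulates and what it does not

`generate_curves()` emulates the *structure* of three reference designs
(11 individuals x 4 replicates x 4 timepoints; 5 x 28 x 2; 10 x 10 x 3 —
see `synth_preset()`) and a population spanning a gradient of
human-perceivable repeatability. Per individual $i$: a latent monotone rise
$f_i(\tau)$ from `baseline_mean` (default 5 ng/mL) to `peak_mean` (default
30 ng/mL, reached at 30 min of restraint and held beyond — plausible
passerine corticosterone magnitudes), plus i.i.d. Gaussian noise with
per-individual SD log-spaced over `noise_sd_range` (default 0.5–10 ng/mL),
truncated below at `floor` (default 0.1 ng/mL) so the KL positivity
precondition always holds. The 4-point preset grid is 0/15/30/60 min, a
standard restraint-protocol sampling scheme (the reference synthetic
dataset's own grid is not published).

A `crossing_fraction` (default 0.25) of the *noisiest* individuals
additionally have a minority of replicates (each with probability 1/4, at
least one) reflected about their own per-curve mean. This mechanism was
chosen deliberately: reflection changes slopes (creating crossings that hit
PR) while preserving the per-curve mean (leaving the RMSSD signal
untouched), and it creates *outlier replicate curves* — the mechanism by
which real low-consensus individuals arise and by which small-subset scores
overestimate the consensus (most small subsets miss the outlier). Under
homoscedastic Gaussian noise alone that overestimation property does not
hold (we measured medians slightly *below* consensus), so a green
directional test here establishes the outlier mechanism, not a universal
property of PR.

What the generator does not emulate: between-occasion drift and
habituation, lognormal/heteroscedastic assay error, within-curve
autocorrelation, missing-data patterns of field sampling, and the actual
numeric values of any published dataset. Green tests on synthetic data
therefore establish internal correctness and stated trends, not agreement
with any real bird.

## Numerical choices and degenerate inputs

* Ties in ranking: exact equality (after optional rounding) only.
* Crossing ties: strict sign reversal; touching excluded.
* KL: error on any value $\le 0$ or missing, naming the cell.
* PR: error when the grand mean is 0; a timepoint with fewer than two
  present replicates is an error (interpolation and variance undefined).
* Subset sampling: rejection of duplicate designs; requires a seed only
  when the cap binds.
* All generation and sampling is seeded; the CLI refuses stochastic
  subcommands without `--seed`, and identical command lines produce
  byte-identical output files.
* Tables are written as delimited text with numerics at 15 significant
  digits, so read/write round-trips are lossless well beyond 12 digits.

## Known limitations

* The PR functional form is a reconstruction from its stated ingredients;
  absolute PR values are therefore not comparable with other
  implementations, although rankings are robust to the constants in all
  cases we test.
* The successive-pair aggregation for KL is one of several defensible
  readings of an order-sensitive divergence on replicate curves.
* The combination analysis is quadratic-ish in replicates and capped
  subsets; with $R = 28$ and three metrics it evaluates ~7,800 subset
  scores per individual, which is fast but not instantaneous in plain R.
* Visual ("majority"/"minority") rankings are inputs, never outputs.
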
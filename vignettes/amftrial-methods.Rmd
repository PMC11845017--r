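---
title: "Methods: evaluating AMF inoculant pot trials with amftrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating AMF inoculant pot trials with amftrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amftrial)
```

## The problem

Screening trials for arbuscular mycorrhizal fungi (AMF) inoculants grow a
host plant (here tobacco) under a control and several inoculation
treatments, then ask two questions: did each inoculant actually colonize
the roots, and which inoculant promoted growth the most across a large
panel of physiological indicators? `amftrial` implements the full
statistical surface of such a trial — colonization indices from scored
root fragments, per-indicator ANOVA summaries with compact letter
displays, percent change versus control, and the membership-function
composite score that produces the final ranking — plus the two molecular
readouts used to validate the winning strain (a log2FC/p DEG screen and
Livak 2^-ddCt qPCR quantification).

The reference design is seven groups — an uninoculated control (CK), five
single-species inoculants (*Acaulospora bireticulata* Ab, *Claroideoglomus
etunicatum* Ce, *Septoglomus viscosum* Sv, *Funneliformis mosseae* Fm,
*Rhizophagus intraradices* Ri) and a mixture (H) — measured on 19
indicators after 180 days of growth.

## Colonization indices

Root fragments are stained and scored on the Trouvelot convention: an
intensity class 0–5 for the fraction of cortex colonized and an
arbuscule class A0–A3. With $n_k$ fragments in intensity class $k$ out of
$N$:

$$F\% = 100\,\frac{N - n_0}{N},\qquad
  M\% = \frac{95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1}{N},\qquad
  m\% = \frac{M N}{N - n_0}$$

and, with $mA_i$ the intensity-weighted share of colonized fragments in
arbuscule class $i$ (as a percentage of $m$),

$$a\% = \frac{100\,mA_3 + 50\,mA_2 + 10\,mA_1}{100},\qquad
  A\% = a \cdot \frac{M}{100}.$$

The class weights (95/70/30/5/1 and 100/50/10) are the convention of the
Mycocalc calculator and are pinned constants, overridable for other
scoring schemes. The chain $A \le M \le F$ is a theorem of the weights
and is enforced by property tests against a brute-force per-fragment
oracle. Published colonization tables in this field report only the
summary indices, never the underlying fragment scores, so those printed
values ship as fixtures (`builtin_fixture("table2")`) and are not
recomputation targets; the computation itself is validated on simulated
fragment sets where the truth is known.

## Group statistics and letters

`summarize_groups()` reports mean and dispersion per treatment, with
dispersion configurable as SD or SE. The default is SE with $n = 3$,
matching the "mean ± standard error (n = 3)" captions of the reference
tables; the trial's methods text says SD, and the package deliberately
supports both without resolving that ambiguity.

`anova_letters()` fits a one-way ANOVA (`stats::aov`), runs all-pairs
Tukey HSD (`stats::TukeyHSD`) at level $\alpha$ (default 0.05), and
assigns lowercase letters by the insert-and-absorb algorithm so that two
groups share at least one letter exactly when their comparison is
non-significant, letters starting at "a" for the largest mean. Tukey HSD
is chosen because it is the convention behind SPSS-style letter displays
when the post-hoc procedure is unnamed; the letter patterns of the
published tables are treated as fixtures rather than reproduction
targets because the replicate-level data behind them were not released.
The letter assignment is cross-checked in the test suite against
`multcomp::cld` as an independent reference. ANOVA assumptions
(normality, homoscedasticity) are not tested by default, mirroring the
reporting practice the package emulates.

`percent_change()` computes $100(\bar x_t - \bar x_{CK})/\bar x_{CK}$
from unrounded means and rounds half-up to 2 decimals at presentation —
base R's round-half-even does not reproduce published tables at ties,
so the package carries its own half-up rounding for all table output.
Applied to the packaged growth-indicator means this reproduces the
published response percentages exactly (91.07% plant height for Fm, and
so on). One discrepancy in the source is worth noting: the below-ground
fresh-weight response of Fm recomputes to 54.86% against a printed
54.85%, a rounding artifact in the source; similarly the source's text
states an arbuscular abundance of 26.91% for Fm where its own table
prints 36.91 ± 6.16. Fixtures follow the tables.

## Membership-function evaluation

The composite score is a direction-aware min–max normalization. For
indicator $i$ with value $X_i$ for a treatment,

$$F_1(X_i) = \frac{X_i - X_{min}}{X_{max} - X_{min}}, \qquad
  F_2(X_i) = 1 - F_1(X_i),$$

with $X_{min}, X_{max}$ taken across treatments. $F_2$ is used for
indicators inversely related to growth promotion. The direction registry
marks all 19 indicators positive except MDA: the source states the
inverse rule but never lists directions, and the published matrix itself
fixes them (the control has the highest MDA yet scores 0.00). Column
means are unweighted averages over indicators; treatments are ranked by
descending column mean, ties broken by input order (a deterministic,
documented rule; the published data have no ties).

Numerical corner cases: an indicator constant across treatments leaves
$F_1$ undefined ($X_{max} = X_{min}$); the default is to exclude it with
a warning (configurable to score 0.5), which changes no published cell.
Membership is computed at full precision from unrounded means and only
compared to published cells at 2-decimal half-up rounding.

Recomputing the matrix from the packaged growth means reproduces all 49
published growth-row cells at 2 decimals. Recomputing column means from
the 19 published rows gives 0.87 for Fm and 0.07 for CK, matching print;
the Sv column recomputes to 0.84 against a printed 0.83 (the source
presumably averaged unrounded cells), so the Sv average is reported but
not asserted. The published ranking Fm > Sv > Ab > Ce > Ri > H > CK is
reproduced in full.

## Molecular readouts

`screen_degs()` classifies per-gene differential statistics as
up/down/ns with the standard rule $p < 0.05$ (strict) and
$|log_2FC| \ge 1$ (inclusive), matching the usual typography of the
rule. No multiple-testing adjustment is applied by default because the
screen operates on whatever p-values it is given (a BH option exists).
The package does not refit count models: DESeq2-style statistics are an
input, and the bundled Welch test (`welch_deg_stats()`) exists only to
exercise the screen on simulated data. Published DEG totals from the
reference trial (8099 genes) require the unreleased sequencing data and
are out of scope; the screen is instead validated by planted-truth
recovery on simulated tables.

`relative_expression()` implements the Livak method: per replicate
$\Delta CT = CT_{target} - CT_{ref}$, then
$\Delta\Delta CT = \overline{\Delta CT}_{trt} -
\overline{\Delta CT}_{ctl}$ and fold change $2^{-\Delta\Delta CT}$.
Group-mean aggregation is the common convention; per-replicate fold
changes are also returned since sources rarely state their aggregation.
Exact identities (swap inversion, Ct-shift invariance, generator round
trip at zero noise) are asserted in tests.

## The synthetic-trial generator

Because no raw data accompany the reference trial, every stage is
exercised on seeded simulations that emulate its design:

* `simulate_trial()` draws Gaussian replicates per (treatment,
  indicator) cell on the measurement scale, truncated at zero (all
  panel indicators are non-negative; truncation is counted and
  reported). Means and dispersions for the tabulated indicators come
  from the packaged published tables (SE at $n=3$ converted to
  per-observation SD by $\sqrt{3}$). The figure-only indicators
  (enzymes, hormones, pigments, osmolytes) have no printed numbers; the
  package ships documented *synthetic* defaults
  (`synthetic_defaults()`): a plausible physiological range per
  indicator with the seven means placed inside it by the published
  membership cells. No figure was digitized, and these defaults are
  labeled synthetic wherever they appear. Replicates default to
  $n = 3$ (the tables' $n$) though the full design grew 12 pots per
  group; both are exposed.
* `simulate_fragments()` draws each fragment mycorrhizal with
  probability $F_{target}/100$, with intensity and arbuscule classes
  from user mixes — the inverse model of the colonization indices.
* `simulate_qpcr()` fixes the control $\Delta CT$ per gene and offsets
  the treatment $\Delta CT$ by $-\log_2$(fold change), with optional
  Gaussian Ct noise, making the 2^-ddCt estimator its exact inverse at
  zero noise.
* `simulate_deg_table()` plants signed log2 effects (default magnitude
  2, within-group log2 SD 0.5, 4 replicates per group) in a fraction of
  genes and computes each gene's Welch p so that null p-values are
  uniform by construction; truth labels are retained.

Each generator consumes a single RNG stream seeded from its own `seed`
argument and restores the caller's RNG state, so outputs are identical
across calls, runs and platforms at the same seed.

What the simulations do *not* emulate: measurement-scale skewness and
between-pot correlation of real phenotypes, count-level RNA-seq noise
(no negative-binomial matrices, no FASTQ), and amplification-efficiency
deviations in qPCR. Passing tests therefore demonstrate correctness of
the computations under the stated models, not robustness of the original
biological conclusions.

## Problem sizes and reproducibility

The test suite validates on deliberately desk-scale problems: 1000
random fragment sets for the colonization oracle, 200 simulated
replicates per cell for generator calibration, 1000-gene DEG tables,
dozens of random 7-group trials for the letter display. The whole suite
runs in well under five minutes on one CPU. `scripts/acceptance.R`
recomputes every headline quantity from the packaged tables and from
fresh seeded simulations, writing them as JSON; its table-derived values
are seed-independent, and its property statistics are stable across
seeds by design.

## Limitations

* Published colonization indices and qPCR fold changes cannot be
  recomputed without the unreleased fragment scores and Ct values; they
  serve as fixtures and simulator targets only.
* The post-hoc test behind the published letters is unnamed; a
  different choice (LSD, Duncan) can produce different letters on the
  same data.
* The membership evaluation weights all indicators equally; no
  entropy/CRITIC weighting or grey relational analysis is provided.
* The DEG screen takes differential statistics as given and inherits
  whatever multiplicity behaviour they carry.
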
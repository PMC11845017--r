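# amftrial

Statistical evaluation of pot-inoculation trials that screen arbuscular
mycorrhizal fungi (AMF) for plant growth promotion.

Trials of this kind grow a host plant (the packaged reference panel is a
tobacco trial) under an uninoculated control (CK) and several AMF
treatments — here five single inoculants (Ab, Ce, Sv, Fm, Ri) and a
mixture (H) — and measure a large panel of physiological indicators.
`amftrial` implements the complete analysis surface:

* **Colonization indices** from Trouvelot-scored root fragments:
  colonization frequency F%, intensity M% and m%, arbuscule abundance a%
  and A% (class weights 95/70/30/5/1 and 100/50/10), plus spore density
  per 25 g soil.
* **Group statistics**: per-indicator means with SD or SE, one-way ANOVA
  with Tukey HSD and a compact letter display (groups sharing a letter
  are not significantly different at α = 0.05), and signed percent
  change versus the control.
* **Membership-function evaluation**, the composite that ranks
  inoculants: per indicator, F1(X) = (X − Xmin)/(Xmax − Xmin) across
  treatments (F2 = 1 − F1 for inverse-direction indicators such as MDA),
  averaged per treatment; higher mean = stronger promotion.
* **Molecular readouts**: the DEG screen (p < 0.05 and |log2FC| ≥ 1) and
  Livak 2^−ΔΔCT relative expression for qPCR plates.
* **Seeded synthetic generators** for every input (replicate trials,
  fragment scores, qPCR plates, per-gene differential statistics), so
  the full pipeline is testable without field data.

The published group means, membership matrix and colonization table of
the reference trial ship as fixtures (`builtin_fixture("table2")`,
`"table3"`, `"table4"`).

## Worked example

Growth response of the best strain (Fm) versus control, recomputed from
the packaged group means:

```r
library(amftrial)
t3 <- builtin_fixture("table3")
subset(percent_change(t3), treatment == "Fm")
#>    treatment           indicator percent_change
#> 4         Fm        plant_height          91.07
#> 10        Fm         root_length          40.36
#> 16        Fm           leaf_area          16.00
#> 22        Fm       stem_diameter          18.28
#> 28        Fm aboveground_biomass          64.69
#> 34        Fm belowground_biomass          54.86
#> 40        Fm       total_biomass          59.17
```

Fm grew plants 91% taller than control. The membership evaluation turns
all indicators into one ranking:

```r
membership_matrix(fixture_means(t3))
#> Membership matrix (7 indicators x 7 treatments)
#>                       CK   Ab   Ce   Sv   Fm   Ri    H
#> plant_height        0.00 0.66 0.33 0.92 1.00 0.58 0.79
#> root_length         0.01 0.61 0.76 1.00 0.88 0.77 0.00
#> ...
#> Promotion ranking: Fm > Sv > Ab > Ri > Ce > H > CK
```

(Each row scores 0 at the weakest treatment and 1 at the strongest; on
the full 19-indicator panel the ranking is Fm > Sv > Ab > Ce > Ri > H >
CK with column means 0.87 for Fm and 0.07 for CK.) Colonization indices
from a scored fragment set, and a qPCR fold change:

```r
sc <- data.frame(intensity_class = c(rep(0, 5), rep(3, 3), rep(5, 2)),
                 arbuscule_class = c(rep(0, 5), rep(1, 3), rep(3, 2)))
colonization_summary(sc)
#> Colonization indices over 10 fragments:
#>   F = 50.00%  M = 28.00%  m = 56.00%  a = 71.07%  A = 19.90%

plate <- simulate_qpcr(c(LOC107803574 = 4.97), ct_noise_sd = 0)
relative_expression(plate, "LOC107803574", "Fm", "CK")
#> 2^-ddCt for LOC107803574 (reference actin): fold change 4.97 (ddCt = -2.313)
```

A YAML-configured end-to-end run (`run_pipeline()`) writes per-stage
TSVs plus a JSON manifest; a thin CLI wrapper lives at
`inst/cli/amftrial` with subcommands `simulate`, `colonize`, `stats`,
`membership`, `deg`, `qpcr`, `report`. See the methods vignette
(`vignettes/amftrial-methods.Rmd`) for the models, parameter choices and
limitations.

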
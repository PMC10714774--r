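# oralhsct

Longitudinal multi-site oral-microbiota dynamics and clinical outcomes in
allogeneic hematopoietic stem-cell transplantation (allo-HSCT).

Allo-HSCT recipients undergo conditioning chemo/radiotherapy, an aplastic
phase under broad antibiotic cover, donor-cell engraftment, and slow immune
reconstitution. Their oral microbiota — sampled here at gingival crevicular
fluid (GCF), oral mucosa (OM), and supragingival biofilm (SB) across five
timepoints (preconditioning P, aplasia A, engraftment E, E+30 d, E+75 d) —
is injured and then recovers, or fails to. `oralhsct` is an R package for
analysts of such cohorts: it quantifies the injury, detects blooms of
opportunistic taxa, relates them to antibiotic exposure, classifies
compositional recovery, and tests whether recovery predicts survival. A
seeded synthetic-cohort generator reproduces the statistical structure of
the design so the whole pipeline is testable without patient data.

## What it computes

* **Depth filter and SRS normalization.** Samples under 3,000 reads are
  excluded; diversity is computed at a common depth `C_min` via scaling with
  ranked subsampling — counts scaled by `C_min/N`, integer parts kept,
  remaining units assigned by descending fractional part with a documented,
  seeded tie-break. Every normalized sample sums to `C_min` exactly.
* **Diversity dynamics.** Gini–Simpson index `1 − Σ p_i²` per sample, and
  per patient–site: resistance `D_E/D_P`, resilience
  `(D_E30 − D_E)/(day_E30 − day_E)`, stability `D_E30/D_P`.
* **Weighted UniFrac kernel.** `Σ_b l_b |P_b − Q_b|` over tree branches,
  normalized by `Σ_leaf d_leaf (p_leaf + q_leaf)` to the bounded [0, 1]
  scale; plus PCoA, one-factor PERMANOVA
  (`F = (SS_B/(k−1))/(SS_W/(n−k))`, seeded add-one permutation p),
  Gower distance-to-centroid, dispersion, between-site minima,
  day-adjusted shift rates, and compositional stability `1 − d(P, E30)`.
* **Blooms.** A taxon rising from <1% at P to ≥30% at a later timepoint of
  the same site; a maximal run of dominant timepoints is one event with
  onset at its first timepoint.
* **Antibiotic exposure.** LOT (distinct days under any agent) and DOT
  (agent-days) in the P→E30 window, prophylaxis excluded; classes used by
  ≥20% of patients enter Fisher exact association tests (conditional-MLE
  odds ratio, Bonferroni-adjusted).
* **Recovery and outcomes.** Recovery ⇔ weighted UniFrac `d(P, E30) < 0.5`;
  landmark Cox (Efron ties) and Fine–Gray competing-risks fits of recovery
  against survival, with univariate-screened multivariate adjustment, and
  Kaplan–Meier / Aalen–Johansen curves.

## A worked example

```r
library(oralhsct)
library(dplyr)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> Synthetic allo-HSCT cohort: 31 patients, 448 samples, 60 taxa, 67 injected blooms

div <- sample_diversity(cohort$counts, cohort$meta)
div |>
  group_by(site, timepoint) |>
  summarise(median = median(diversity), .groups = "drop") |>
  tidyr::pivot_wider(names_from = timepoint, values_from = median)
#>   site      P     A     E   E30   E75
#> 1 GCF   0.946 0.864 0.600 0.931 0.939
#> 2 OM    0.945 0.837 0.595 0.927 0.939
#> 3 SB    0.943 0.856 0.656 0.918 0.934
```

Diversity dips to its nadir at engraftment and is largely restored by E30 —
the injury-and-recovery pattern the indices summarize per patient. Recovery
of *composition* is classified from the P→E30 UniFrac distance and carried
into a landmark survival model:

```r
d <- unifrac_matrix(cohort$counts, cohort$tree)
calls <- classify_recovery(d, cohort$meta)
calls |> filter(evaluable) |> group_by(site) |> summarise(pct = 100 * mean(recovered))
#>   site    pct
#> 1 GCF    73.3
#> 2 OM     65.5
#> 3 SB     66.7

calls |>
  filter(site == "OM", evaluable) |>
  select(patient_id, recovered) |>
  inner_join(cohort$outcomes, by = "patient_id") |>
  cox_univariate("recovered")
#> Cox fit for 'recovered': HR = 0.103 (95% CI 0.0254-0.418), p = 0.00148 (n = 24, events = 23)
```

Here two-thirds to three-quarters of patients recover their baseline
composition per site, and OM recovery is strongly protective (hazard ratio
≈ 0.1) — by construction: the generator gives true non-recoverers a
five-fold event hazard, so this is the signal the pipeline should find.
`tidy()` and `glance()` return the fit as tibbles; `autoplot()` draws PCoA
ordinations and survival/incidence curves.

See `vignette("oral-microbiota-dynamics")` for the models, the generator's
design, and every numerical convention.

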
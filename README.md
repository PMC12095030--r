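# lobiclean

Decontamination toolkit for low-biomass 16S rRNA amplicon count data.

In low-biomass specimens (plasma, skin, other low-microbial-DNA material),
reagent contamination and well-to-well cross-contamination can rival or
exceed the true biological signal in a 16S count table. `lobiclean`
provides two complementary decontamination pipelines, chosen by the
downstream research goal, plus the machinery to quantify and benchmark the
removal:

- **Biomarker pipeline** (`run_biomarker()`, goal `"biomarker"`) — stringent
  whole-feature removal ahead of biomarker discovery. Four independent
  flagging steps produce a per-feature evidence matrix: (1) a
  bias-corrected log-linear test for batch-dependent abundance (with a
  structural-zero rule), (2) a one-sided prevalence test of features in
  negative controls versus samples (continuity-corrected chi-squared with
  exact-test fallback), (3) detection concordance between technical
  replicates sequenced in different batches (with per-pair Cohen's kappa as
  QC), and (4) taxon blocklist matching at a chosen rank (default genus).
  Features flagged by at least a consensus threshold of steps (default 1)
  are removed outright. Requires two or more batches.
- **Composition pipeline** (`run_composition()`, goal `"orig-composition"`)
  — partial read removal that aims to restore each sample's original
  composition. Per batch, a two-level multinomial mixture is fitted by EM:
  sample `i` draws counts from `(1 - p_i) r_i + p_i g` (intrinsic profile
  `r_i`, shared contaminant profile `g`, contamination fraction `p_i`);
  negative control `c` draws from `(1 - a_c) g + a_c s_c`, where `a_c` is
  the control's well-to-well leakage and `s_c` the composition of the
  neighbouring sample wells on the 96-well plate (pseudo-wells are assigned
  automatically when locations are unknown). Each count is then reduced by
  its posterior probability of contaminant origin. Leakage above 0.10 in
  any control triggers an advisory to obtain real well locations. Requires
  a negative control in every batch.

Both pipelines report the **filtering loss**

```
FL = 1 - ||Y'Y||_F^2 / ||X'X||_F^2
```

where `X` is the pre-filter and `Y` the post-filter count matrix: the share
of the total feature covariance carried by the removed reads. Values near 0
mean little signal was lost; values near 1 warn of over-filtering
(`feature_contributions()` breaks this down per feature).

The package also contains a fully seeded **multi-batch contamination
simulator** (`simulate_multibatch()`: two batches, technical replicate
pairs spanning them, group-scaled differential genera, batch-specific
contaminants, sample-control leakage coupling, zero-inflation) with
ground-truth labels, and a **read-level benchmark**
(`benchmark_decontamination()`: per-sample accuracy, precision, recall, F1
with a positive case indicating a contaminant read).

## Worked example

```r
library(lobiclean)

sim <- simulate_multibatch(sim_config(seed = 1))   # 14 x 110 benchmark dataset
ds  <- align_dataset(sim$counts, sim$sheet)

bio <- run_biomarker(ds, taxonomy = sim$taxonomy,
                     blocklist = read_blocklist(default_blocklist_path()))
bio
#> <biomarker_result> removed 101 of 110 features (consensus threshold 1)
#>   filtering loss: 0.1826
```

101 of the 110 features are removed by at least one step; the removed
features carried about 18% of the pre-filter covariance. Nine of the ten
true genera survive — the one loss is a differentially abundant genus whose
group signal is confounded with batch. The composition pipeline on the same
data is far more conservative:

```r
glance(run_composition(ds))
#> # A tibble: 1 × 5
#>   n_samples n_batches       fl leakage_warning max_leakage
#>       <int>     <int>    <dbl> <lgl>                 <dbl>
#> 1        10         2 0.000119 FALSE            0.00000587
```

All ten true genera retain reads and the filtering loss is ~1e-4: almost no
covariance is sacrificed. Scoring the stringent run against the simulation
truth at read level:

```r
benchmark_decontamination(ds$counts[!ds$sheet$is_control, ], bio$filtered, sim$truth)
#> ...
#> average      0.984     0.972      1 0.985   # accuracy precision recall f1
```

`tidy()`, `glance()` and `autoplot()` methods summarize every result type;
`run_pipeline(..., out_dir = "run1/")` writes the filtered table, the step
matrix, `result.json` (filtering loss, parameters, checksums) and a run
log. A command-line wrapper with verbs `run`, `simulate`, `benchmark` and
`fl` lives in `inst/scripts/lobiclean.R`.

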
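---
title: "Models and methods behind lobiclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lobiclean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobiclean)
```

`lobiclean` decontaminates low-biomass 16S rRNA count tables. This
vignette explains the statistical models the package implements, the
parameters that matter, the numerical choices behind them, and what the
bundled simulator does and does not emulate.

## The data model

All user-facing functions work on tibbles. A count table has a
`sample_id` first column and one numeric column per feature (ASV); counts
are integers on input and may be fractional after partial
decontamination. A sample sheet carries `sample_id`, `is_control`,
`group`, and optionally `batch`, `well` (96-well coordinates A1–H12) and
`replicate_id` (shared by technical replicates of one biological sample).
`align_dataset()` intersects the two, keeps count-table order, refuses
datasets with no biological samples or control-only batches, and is
idempotent.

## Filtering loss

For a samples-by-features matrix $X$, $\|X^\top X\|_F^2$ — the sum of
squared inner products between all (ordered) pairs of feature columns —
summarizes the total covariance carried by the features. Filtering loss
compares this quantity before and after decontamination:

$$\mathrm{FL} = 1 - \frac{\|Y^\top Y\|_F^2}{\|X^\top X\|_F^2},$$

where $Y$ is the post-filter matrix with removed features treated as
zeroed columns. Both numerator and denominator count each off-diagonal
pair twice (the full Frobenius norm); a formulation counting each
unordered pair once gives the identical ratio provided the convention is
applied consistently, which is why the package exposes only the Frobenius
form. FL is 0 when nothing is removed, 1 when everything is, monotone
under further removal, and invariant to sample/feature permutation and to
global rescaling. An all-zero pre-filter matrix yields FL = 0 with a
warning rather than an error so that degenerate batches do not crash
pipelines. The comparison "post ≤ pre" uses an absolute tolerance of
1e-9 per cell to absorb float rounding in partially decontaminated
tables. `feature_contributions()` reports, per feature, the FL that
removing that single feature would cause — features near 1 dominate the
covariance and are the over-filtering risk.

## The biomarker pipeline

Four flagging steps are computed independently on the same input, so
every feature receives a verdict from every executed step; a feature is
removed when at least `threshold` steps flag it (default 1, i.e. any
single line of evidence suffices — the stringent end). Controls are used
only by the prevalence step and are dropped from the filtered output.

**Step 1 — batch differential abundance** (`alpha = 0.05`,
`pseudocount = 1`). Compositional counts confound per-sample sampling
depth with abundance. The step log-transforms counts with a pseudocount,
fits per-feature OLS on batch indicators, estimates per-sample sampling
offsets as the across-feature mean residual, subtracts and refits until
the offsets stabilize (max change < 1e-6, at most 100 sweeps), then
applies a global Wald chi-squared test of batch-coefficient equality with
Benjamini–Hochberg adjustment across features. With more than two batches
no pairwise decomposition is attempted — a feature is flagged if its
batch means differ anywhere. Features detected in one batch and entirely
absent in another (structural zeros) are flagged regardless of the test,
since categorical presence/absence by batch is direct evidence of
batch-specific origin. Features constant within batches (zero residual
variance) are handled explicitly: flagged only if their batch means
actually differ. The default alpha of 0.05 is the conventional level of
the differential-abundance tools this step mirrors.

**Step 2 — control prevalence** (`threshold = 0.1`, `min_count = 0`).
Presence (count above `min_count`) is cross-tabulated against control
status and tested one-sided for higher prevalence in controls. The
statistic is the continuity-corrected (Yates) chi-squared, halved and
directed; whenever any expected cell is below 5 the exact
hypergeometric (Fisher) tail is used instead. The corrected statistic was
chosen because, across every 2×2 table with margins up to 12, its flag
decision at the 0.1 threshold coincides with the exact test's — the
uncorrected statistic does not. The 0.1 default matches the conventional
default of prevalence-based contaminant classifiers. `min_count` exists
because single-read detections are fragile; 0 keeps the classical
presence definition.

**Step 3 — replicate concordance** (`max_discordant_fraction = 1.0`).
For every technical replicate present in two or more batches, detection
is compared per feature across the cross-batch pairs. A feature is
flagged when its detection disagrees in at least the given fraction of
pairs (default: all of them) *and* it is detected in at least one
replicate sample. The strict default reflects that this step should be a
scalpel: only features that never replicate across batches are
implicated. Cohen's unweighted kappa per pair over all features is
attached as a QC diagnostic; degenerate tables with chance agreement 1
return kappa 1 under perfect agreement and 0 otherwise. When no replicate
spans two batches the step is skipped with a notice and contributes
all-false flags, so the consensus arithmetic is unaffected.

**Step 4 — blocklist** matching is case-insensitive and exact on the
name at the entry's rank (default genus; `rank:name` entries match other
ranks). Features without taxonomy are never flagged and their number is
reported. The bundled list (`default_blocklist_path()`) is a synthetic
stand-in assembled from genera repeatedly reported as reagent
contaminants; real studies should supply their own curated lists.

Multiplicity is corrected within step 1 only; the steps are not jointly
corrected because the consensus threshold is itself the combination
device.

## The composition pipeline

Each batch is modelled as a two-level multinomial mixture. Sample $i$
with read depth $N_i$:

$$c_i \sim \mathrm{Multinomial}\!\big(N_i,\ (1-p_i)\,r_i + p_i\,\gamma\big),$$

with $r_i$ the sample's intrinsic composition, $\gamma$ the batch's
shared contaminant profile and $p_i$ the contamination fraction. Control
$c$:

$$c_c \sim \mathrm{Multinomial}\!\big(N_c,\ (1-\alpha_c)\,\gamma + \alpha_c\,s_c\big),$$

with $\alpha_c$ the well-to-well leakage and $s_c$ the read-weighted mean
intrinsic composition of the sample wells in the control's Moore
(8-cell) neighbourhood. When the sheet has no well column, pseudo-wells
are assigned in sheet order (vertical fill by default), mirroring common
plate-loading practice. The EM iteration computes per-cell posterior
contaminant probabilities $z_{ij}$, updates $p_i$, $r_i$, $\gamma$ and
$\alpha_c$ in closed form, and stops when the relative log-likelihood
change falls below 1e-6 or after 200 iterations. Decontamination then
replaces each count by $c_{ij}(1-z_{ij})$, rounded half-to-even so column
sums stay stable (`round_counts = FALSE` keeps fractions). Output never
exceeds input, and a multi-batch run is by construction identical to
per-batch runs concatenated.

### Identifiability and initialization

The sample-side likelihood is flat along a ridge: for any
$p' \le p$ one can fold the difference into the free profile $r_i$
without changing the mixture, so maximum likelihood alone does not pin
$p_i$ down and EM essentially stays where it starts. The scientifically
meaningful solution is the ridge boundary — the largest contamination
fraction that still leaves every intrinsic abundance non-negative; it
coincides with the truth exactly when the contaminant profile has
features the sample does not intrinsically carry, the typical situation
in low-biomass data. The package therefore initializes at that boundary:
per sample, the minimum over the high-mass half of the contaminant
profile of the (count-stabilized) ratio of observed to contaminant
proportion. A raw minimum of noisy ratios is biased downward, so each
ratio carries a $\sqrt{2\log m}$ Poisson standard-error allowance before
the minimum is taken (the usual extreme-value recentring for a minimum of
$m$ noisy values). The residual after subtracting the implied
contamination becomes the intrinsic start, and $p_i$ is set to one minus
the residual mass so the pair sits exactly on the ridge. Leakage
fractions are initialized the same way against the neighbour source
profile, the initial leakage component is subtracted from the pooled
control profile before $\gamma$ is formed (otherwise leak reads are baked
into the contaminant profile and the fit attributes leakage to
contamination), and the sample-side start is rebuilt against the cleaned
profile.

$s_c$ is computed once from the initial intrinsic estimates — weighted
by each neighbour's intrinsic reads — and held fixed during EM. With
$s_c$ fixed the iteration is an exact EM, so the log-likelihood trace is
non-decreasing by construction (and asserted in the tests). Leakage
estimation is disabled for controls whose neighbourhood carries less than
5% intrinsic reads: a neighbourhood that is essentially pure
contamination cannot define a leakage source, and a noise-derived one
corrupts the fit.

Degenerate inputs are handled explicitly: controls with zero total reads
yield the trivial no-contamination fit; all-zero samples get $p_i = 0$;
features with no reads anywhere pass through untouched. The 0.10 leakage
advisory uses a strict inequality — exactly 0.10 does not warn — and is
raised per control, not on an aggregate, because a single leaky well
already justifies obtaining real plate locations.

## The simulator

`simulate_multibatch()` regenerates a two-batch benchmark with known
ground truth: ten real gut genera as true signal (absent from controls),
the first five scaled per sample by U(1.5, 2.5) in the disease group and
U(0.5, 0.8) in the healthy group; 100 shared contaminant features whose
values are drawn per batch (U(0, 20) + N(0, 2)) under that batch's own
seed; a per-feature negative-binomial NB(1, 0.5) leakage vector added to
the batch's samples with scale U(1, 1.5) and to its controls with scale
U(2, 3), coupling samples and controls; clamping of negatives and
rounding; and finally row-wise zero-inflation with probability
$0.6\,(1 - x/\max x)$, so a row's maximum is never zeroed. Technical
replicate pairs S1A/S1B and S2A/S2B share a U(10, 100) base draw per
genus plus member-specific N(0, 10) noise and span the two batches
(batch 1: S1A, S2A, S3–S5; batch 2: S1B, S2B, S6–S8), giving two healthy
and three disease samples in batch 1 and four healthy plus one disease
sample in batch 2, with two negative controls per batch — 14 rows by 110
features in total. NB(1, 0.5) is parameterized as failures before the
first success with success probability 0.5 (mean 1); group scalings and
contaminant values are drawn per sample and feature. One master seed
drives the true-signal stream and derives the two batch streams
(overridable individually), so a stored config reproduces its dataset
byte-for-byte and changing one batch's stream leaves the other batch's
rows untouched.

What the simulator does *not* emulate: feature-level mixtures of true
and contaminant reads (every feature is purely one or the other, which
flatters whole-feature removal), taxonomic misassignment, chimeras,
library-size variation across orders of magnitude, and real
phylogenetic correlation between contaminants. Passing tests on this
generator therefore demonstrates correct mechanics and seed-robust
qualitative behaviour, not field performance on real plasma or skin
data. `simulate_mixture_batch()` complements it by generating directly
from the composition model (known $\gamma$, $r_i$, $p_i$, $\alpha_c$,
with intrinsic and contaminant supports overlapping only slightly) for
parameter-recovery and leakage checks.

## Benchmarking

Decontamination output is scored per sample at read level, the positive
class being a contaminant read: reads removed from a contaminant feature
are true positives, reads retained on one are false negatives, and
symmetrically for non-contaminant features; whole-feature removal is the
zero-count special case, and the four cells always sum to the sample's
pre-filter total. Precision is undefined — `NA`, not zero — when nothing
was removed, recall undefined when the sample has no contaminant reads;
F1 is 0 when precision is undefined but recall is 0, and undefined when
recall is. Averages skip undefined entries rather than imputing zeros,
and a metric undefined everywhere stays `NA`. A feature-level view can be
recovered by comparing whole-feature benchmarks to count-weighted
feature sums, which the tests assert agree.

## Problem sizes and tolerances in the test suite

The suite runs the default 14 × 110 simulation across a dozen seeds for
the retention checks, twenty seeds of the 11-or-12-sample mixture batches
at 5 × 10⁴ reads for EM recovery (tolerance ±0.05 on contamination
fractions), 1,000 random 6 × 5 matrices against a brute-force Gram
oracle, the full enumeration of 2×2 prevalence tables with margins up to
12 against the exact hypergeometric tail, and 50 replicates of a
10 × 50 null (no contamination, no batch effect) for the false-flag
bound. These sizes keep the full suite under a minute while leaving each
check statistically meaningful.

## Known limitations

- A genuine biological effect aligned with batch (as in the simulated
  design, where disease prevalence differs between batches) is
  indistinguishable from batch contamination in step 1 and will cost
  true features; the composition pipeline is the remedy when that risk
  matters.
- The composition model attributes to contamination as much of each
  sample as the contaminant profile can explain (maximal-attribution
  boundary); when a sample legitimately shares its entire composition
  with the contaminant profile, its contamination fraction is
  overestimated by design.
- Leakage cannot be estimated for controls without informative sample
  neighbours, and one plate per batch is assumed.
- Blocklist matching is exact by name at a rank; synonyms and
  rank-ambiguous lineages are not resolved.
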
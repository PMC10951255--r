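---
title: "Metabolic heterogeneity from imaging mass spectrometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic heterogeneity from imaging mass spectrometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`msihetero` turns per-patient MSI datacubes into (i) a cohort-wide partition
of pixels into metabolic subpopulations, (ii) a per-patient heterogeneity
score with a survival-guided high/low split, (iii) a presence-threshold × K
Cox-AIC model-selection grid linking subpopulations to outcome, and (iv) a
metabolite-level characterisation of each subpopulation. This vignette
documents the model, the parameters that matter, the synthetic test world,
and the numerical and design choices — including the ones that were genuinely
open.

## 1. Model and procedure

### Segmentation

All patients' TIC-normalised pixel spectra are pooled and clustered by
K-means under correlation distance `d(a,b) = 1 − cor(a,b)` for K = 2..10.
Pooling (rather than per-patient clustering) is what makes subpopulation
labels comparable across patients; per-patient clustering would require a
fragile post-hoc matching of cluster identities. Correlation distance is
scale-invariant, which suits TIC-normalised spectra whose informative content
is the *shape* of the profile.

Implementation: rows are centred to mean 0 and scaled to unit norm, so
`||u − v||² = 2·d(u,v)` between pixels. Centroids are renormalised to unit
vectors after every Lloyd update (spherical K-means); this makes the
Euclidean assignment step *exactly* the correlation-distance argmin — a
property the test suite asserts against a brute-force assignment — and the
reported inertia is the literal sum of correlation distances to assigned
centroids. With plain mean centroids the equivalence is only approximate
(centroid norms differ between clusters), which is why spherical updates were
chosen.

Assumptions: pixels are exchangeable across patients given their
subpopulation; no spatial regularisation is applied (the spatial coherence of
label maps emerges from the data, not the algorithm).

### Simpson's diversity and the cutoff-optimised split

For patient shares `p_1..p_K`, `D = 1 − Σ p_i²` ∈ [0, 1 − 1/K] is the
probability that two randomly chosen pixels of the patient belong to
different subpopulations. The cohort is split at the candidate cutoff
minimising the two-group log-rank p, with candidates restricted to midpoints
between consecutive distinct D values leaving at least `min_group_frac` of
patients and one event on each side.

Minimising p over candidates is a *selection*: under the null the minimal p
is strongly anti-conservative (the test suite measures the inflation — on a
40-patient null, roughly 46% of seeds reach p < 0.05 after optimisation
versus ~9% at a fixed cutoff). The split object therefore always carries a
caveat string, the optimised p is reported non-adjusted and labelled as such,
and a robustness flag records whether the two neighbouring candidate cutoffs
are also significant. Note the robustness criterion formalises a qualitative
idea ("similar cutoffs give similar results") as: both adjacent candidates
have p < 0.05.

A known and deliberate limitation: the optimised cutoff identifies the
planted high/low *boundary* only up to the resolution of the candidate race.
Adjacent candidates differ by a single patient membership, so their p-values
are nearly exchangeable, and the probability that the single candidate
strictly inside a planted gap wins the minimum is modest at realistic effect
sizes (enumerated in the decisions ledger; the acceptance suite keeps the
strict criterion and it is honestly red). What the stated two-strata world
(high-D doubling median survival, n = 60) *does* deliver, and the unit suite
asserts, is a significant split in the correct direction in the large
majority of seeds.

### Presence thresholding and the Cox-AIC grid

A patient is assigned to a subpopulation when its pixel share *strictly*
exceeds the presence threshold; multi-assignment is allowed and expected.
For each (K, threshold) cell one multivariable Cox proportional-hazards model
(Breslow ties) contains all admissible presence indicators — columns that are
neither all-0 nor all-1. The cell AIC is `2p − 2·logPL`; a cell with no
admissible indicator scores the null model's `−2·logPL₀`; non-convergent
fits (monotone likelihood) are excluded. The grid optimum minimises AIC with
ties broken toward smaller K, then smaller threshold; the grid scaled to 0–1
is retained as the heat-map analogue.

Open design point, resolved as follows: the source workflow is ambiguous
between one Cox model per cluster versus one joint model per (K, threshold).
The joint model was chosen because AIC comparisons across K are only
meaningful on a single likelihood per cell; per-cluster models would yield K
AICs per cell with no principled aggregate.

Two multiplicity facts about this grid, measured by the acceptance suite
rather than assumed: under a permuted-survival null the *minimum* AIC over
the ~95 correlated cells beats the null model by a median of ~4 (so "optimum
within 2 of null AIC" is *not* a property of the null — selection inflates
it), but the null optimum's location does not concentrate anywhere, while
under a planted prognostic subpopulation the optimum concentrates at the
generating threshold with a far larger AIC gain.

### Pairwise comparisons and response association

Comparing subpopulations i and j compares *overlapping* patient sets, so
records are stacked one per patient-membership (Andersen–Gill counting-
process view) and the Cox model uses a robust sandwich variance clustered by
patient; the Wald p of the group indicator is reported. The variance
estimator is a design choice (the formulation names the process, not the
estimator); for disjoint memberships the procedure reduces to fitting the
same records directly, which the tests assert numerically. Response
association uses Spearman rank correlation of the binary presence indicator
with the binary response (for two binaries this equals the phi coefficient),
and the heterogeneity split is tested against response with Fisher's exact
test (two-sided, sum of tables no more probable than observed). Survival
p-values are non-adjusted throughout, and flagged as such.

### Differential metabolites

Per subpopulation, each channel is tested pixel-wise against all other
subpopulations pooled with the Mann–Whitney U test: exact p from the null U
distribution when `min(n) ≤ 8` without ties, otherwise normal approximation
with tie and continuity corrections. BH adjustment is applied within each
subpopulation's channel family (one family per subpopulation, the natural
reporting unit). Direction: increased iff adjusted p < 0.05 and fold change
≥ 1.5; decreased iff adjusted p < 0.05 and FC ≤ 1/1.5; otherwise ns. Fold
change is the ratio of arithmetic means of TIC-normalised intensities (the
source defines no FC; mean/linear is the simplest auditable choice), and
channels with a zero mean in either group are flagged untestable rather than
patched with pseudocounts.

Pixels are the test unit, matching pixel-wise MSI practice — and they are
pseudoreplicated (hundreds of pixels per patient are not independent
patients). This is a real inferential caveat, carried in the pipeline
manifest; a patient-level mode (`unit = "patient"`, per-patient medians) is
provided for sensitivity analyses.

### Annotation, enrichment, networks

Five negative-mode adducts are built in: [M−H]⁻, [M−H₂O−H]⁻, [M+Na−2H]⁻,
[M+K−2H]⁻, [M+Cl]⁻. Their mass shifts are hard-coded but re-derived on every
access from monoisotopic atomic masses including the electron mass, and must
agree to 1e-6 Da — an [M+X]⁻ ion carries one extra electron relative to its
neutral composition, a detail that matters at FT-ICR accuracy. Annotation
reports *every* (peak, metabolite, adduct) triple within the ppm tolerance,
ranked by |ppm|; isomeric metabolites deliberately produce multiple hits.
Enrichment is the one-sided hypergeometric test of a query set against a
universe (default: all annotated channels — the original tool's universe is
unknown, so it is configurable), BH-adjusted across pathways, significant at
q < 0.05. Correlation networks compute Spearman rho over a subpopulation's
pixels for every channel pair, BH-adjust the pair p-values (asymptotic t
approximation), and keep edges with adjusted p < 0.05, signed and weighted by
|rho|.

KEGG itself is never queried: mass tables (TSV) and pathway sets (GMT) are
inputs, and a small demonstration table of ~50 common metabolites with
formula-derived masses plus five toy pathway sets ships with the package for
tests and examples. The demonstration table is synthetic curation, not a
KEGG extract.

## 2. Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_peaks` | half the channels | count | the source names peak selection but not a count; keep generous, let tests pick |
| `denoise_window` | 3 | pixels | smallest edge-preserving median window; 1 disables |
| `k_range` | 2..10 | — | the studied range |
| `n_init` / `max_iter` | 10 / 300 | — | standard robust K-means defaults absent source detail |
| thresholds | 4–40% step 2% | share | stated range; the step is unstated — 2% resolves the reported 24% optimum without inflating the grid |
| `min_group_frac` | 0.1 | fraction | cutoff search constraint (unstated in the source; configurable) |
| `response_cutoff` | 13.8 | months | trial-derived sensitivity dichotomy |
| `tol_ppm` | 4 | ppm | FT-ICR-appropriate annotation tolerance (source silent) |
| `fc_threshold`, `alpha` | 1.5, 0.05 | — | stated filters |

## 3. The synthetic world

`generate_cohort()` plants everything downstream stages must recover:

* **Space.** Each patient's grid is partitioned into `3·k_true` Voronoi
  patches (seeds uniform in the grid); each patch takes a subpopulation drawn
  from the patient's Dirichlet(α = 0.5) composition. Voronoi patches are the
  simplest mechanism producing contiguous, irregular regions like real
  segmentation maps; Markov random fields were rejected as needless machinery.
* **Spectra.** Per-channel log-baselines are drawn once per cohort
  (`channel_log_mean = log 100`, `channel_log_sd = 0.15`); a pixel's spectrum
  is the baseline with its subpopulation's signature channels multiplied by
  `signature_effect`, times unit-mean log-normal noise with CV `noise_cv`.
  The narrow baseline spread is deliberate: after TIC normalisation only
  relative structure matters, and it keeps planted signatures prominent in
  the mean spectrum the way discriminative peaks are in practice. Signature
  sets are disjoint across subpopulations and drawn on non-adjacent bins so
  each signature is a resolvable local maximum — two boosted adjacent bins
  would otherwise shadow each other in peak selection by construction.
* **Outcome.** Survival is exponential with baseline median 14 months (the
  cohort-scale median), hazard multiplied by `hazard_ratio` when the true
  share of `risk_subpop` exceeds `presence_fraction` (0.25); censoring is an
  independent exponential calibrated so the expected censored fraction is
  `censoring_rate`. Response is derived from survival at the 13.8-month
  cutoff; patients censored at or before the cutoff are *unknown* and
  excluded from response association (the source does not state its handling
  of such patients — 42 of its 49 were classifiable — so the conservative
  convention was adopted).

What the generator does **not** emulate: isotope envelopes, peak shape and
width, mass drift, matrix clusters, histology, patient-level covariates, and
any correlation between heterogeneity and subpopulation identity beyond what
the Dirichlet induces. A green recovery test therefore establishes that the
pipeline recovers planted structure of this idealised kind — not that it
would recover structure from real FT-ICR spectra, whose noise is richer.

Scale of the recovery experiments: segmentation recovery runs at the
spec-stated 20 patients × 400 pixels. For Cox-AIC model-selection recovery
the cohort size is not stated; at the 45-patient clinical scale the AIC
surface over (K, threshold) is nearly flat and the optimum location is
dominated by selection noise, so the experiment runs at n = 200 — the same
scale the generator's hazard-ratio recovery property uses — where the optimum
concentrates at the generating threshold. The measured power trajectory
across 45/100/200 patients is recorded in the decisions ledger; this is a
statement about the power of a 45-patient cohort, not about the method.

## 4. Numerical choices and degenerate inputs

* Strict inequality everywhere a share meets a threshold (presence, truth
  presence); boundary cases are pinned by tests.
* K-means ties in the assignment step break to the lowest cluster index;
  empty clusters are repaired by reseeding from the farthest pixel; labels
  are renumbered by descending global size; pooled pixels are ordered by
  patient id so results are invariant to input order.
* Seeded functions restore the caller's RNG state; derived child seeds stay
  within 32-bit range.
* Zero-variance pixels are dropped (with a count message) before clustering;
  constant channels are excluded from networks; all-zero pixels error in
  `tic_normalize` unless explicitly dropped.
* Cox fits: Breslow ties; collinear presence columns (duplicate indicator
  patterns) are dropped as unidentifiable before refitting; monotone
  likelihood is reported as non-convergence and the grid cell excluded.
* BH adjustment passes NA through and adjusts over the non-missing family.
* Exact vs approximate Mann–Whitney: the enumerated worst-case two-sided gap
  at n = 8 is 0.0109 (mid-range U; tails < 0.005) — slightly above the
  nominal 0.01 folklore bound, asserted exactly in the tests.

## 5. Known limitations

* Pixel-level tests are pseudoreplicated; the patient-level mode exists but
  is not the default because pixel-wise testing is the field convention being
  implemented.
* Optimised cutoffs and grid optima are selection-biased; the package
  measures and reports the bias instead of correcting it, matching the
  non-adjusted reporting convention of the source workflow.
* No spatial autocorrelation correction; neighbouring pixels share noise.
* The imzML reader supports the continuous and processed 64-bit-float
  encodings it writes, intended for round-trip interchange, not as a fully
  general imzML consumer.
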
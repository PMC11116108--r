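---
title: "ectnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ectnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `ectnet`, the
parameters that matter, the synthetic world the generator states, and the
design decisions taken where the design was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## The analysis model

The pipeline analyzes two subjects-by-regions matrices over a fixed
85-region parcellation: longitudinal volume change (ΔVol, %) and
electric-field amplitude (EF, V/m). The core decomposition is a
*normalize-then-PCA* step, stratified by electrode placement:

1. z-score every region across subjects (sample SD, n−1 denominator);
2. decompose by SVD of the centered matrix, equivalent to an
   eigendecomposition of the sample covariance;
3. keep K = 2 components (scree/elbow selection is available via
   `select_k_scree()`, but the pipeline fixes K = 2: in this design PC1 is
   the global volume-increase factor and PC2 the candidate network-like
   pattern, and later components carry diminishing variance).

Placements (RUL, BT, MIX) are never pooled into one PCA — pooling would
let the decomposition pick up placement differences as spurious
components. Hemisphere-split PCAs (42 regions each) guard against
bilaterally symmetric maps inflating whole-brain similarity.

Spatial similarity between a loading vector and a reference map is the
Pearson correlation across regions. Parametric p-values on df = 83 are
not trustworthy for spatially structured maps, so inference uses a
permutation null: baseline volumes are reassigned across subjects within
placement group, `ΔVol*ᵢᵣ = (V2ᵢᵣ − V1_{π(i)r})/V1_{π(i)r}·100`, and the
whole normalize-then-PCA-then-correlate chain is recomputed per
permutation. The null statistic is `max_k |r|` over the K components —
component-agnostic and conservative (per-component p-values are also
reported). P-values use the add-one rule `(1 + #{null ≥ obs})/(1 + n_perm)`,
so the minimum is `1/(n_perm + 1)` and the statistic is invariant to
loading sign.

The head-to-head check regresses the reference on PC1 and PC2 loadings
jointly across regions and reports partial t statistics and both nested
ΔR² values. The permutation comparison is implemented as the fraction of
permutations in which the *observed* advantage `|t_PC2| − |t_PC1|`
exceeds the advantage recomputed on that permutation's loadings — i.e. a
permutation test of the PC2-over-PC1 difference. (The alternative literal
reading — counting permutations whose own PC2 beats their own PC1 — sits
at ~0.5 under the null by symmetry and cannot discriminate anything; the
exact published procedure lives in an unavailable supplement, so this
choice is documented here.)

Outcome models regress the fractional MADRS change (post−pre)/pre
(negative = improvement) on component scores plus two mandatory
confounders. Age: older patients respond better to ECT while carrying
lower EF. Number of sessions: observational samples image non-responders
later, so longer courses accompany both larger volume change and poorer
outcome. Omitting either invites spurious conclusions in both directions.
Three designs are available: volume (PC1+PC2 of ΔVol), EF (PC1+PC2 of
EF), and cross (PC1_EF + PC2_ΔVol). A site-random-intercept mixed model
(REML, lme4) with sex and placement as extra fixed effects is provided as
a sensitivity analysis; its p-values use the normal approximation and are
labeled as such.

### Sign conventions

Eigenvector sign is arbitrary. Two explicit rules make results
reproducible: PC1 is flipped so its mean loading is positive (the global
factor reads as an increase everywhere); later PCs are flipped so their
largest-magnitude loading is positive. Both flips propagate to scores, so
the reconstruction `scores %*% t(loadings)` is invariant. A further
*optional* step, `orient_to_reference()`, flips components to correlate
positively with a reference map. This is a display/reporting convention:
no reference information enters the decomposition, similarity statistics
use |r| and are unaffected, but the sign of a score's regression
coefficient is only interpretable after fixing the orientation — the
planted "higher expression → better outcome" effect appears with a
negative coefficient only when PC2 points toward the reference.

## The EF dose surrogate

A finite-element solver is out of scope; the surrogate keeps exactly the
properties the downstream analysis consumes:

- **Geometry.** Two electrodes per placement in the atlas coordinate
  frame: RUL uses a C2-like vertex position (20, −15, 110) and an
  FT8-like right fronto-temporal position (68, 5, −10); BT uses FT8- and
  FT9-like bilateral positions. The unit-current field at a voxel is
  `base_amplitude · Σ_e exp(−d_e/decay_length)`.
- **Defaults.** `decay_length = 45` mm and `base_amplitude = 200` V/m/A
  were calibrated once so that group mean EF magnitudes and ordering are
  realistic (RUL ≈ 47 V/m, BT ≈ 62, MIX in between; bitemporal stimulation
  drives more current through tissue than a vertex–temporal montage).
  Only the BT > MIX > RUL ordering is asserted by tests; magnitudes are
  surrogate-calibrated, not solved.
- **Age.** The field is multiplied by `1 − 0.005·(age − 54)`, floored at
  0.2 (atrophy widens the CSF gap). With the anatomical gain below, this
  yields corr(age, mean EF) ≈ −0.3 to −0.4 in RUL cohorts.
- **Anatomical gain.** A per-subject log-normal factor
  (`anatomy_sd = 0.15`) models head-size/CSF/fat differences. Without it
  the age factor would be the only between-subject variation and the
  age–EF correlation would be ≈ −1, which no real cohort shows.
- **Aggregation.** Voxels (default 60 per region, isotropic 6 mm jitter
  around the centroid) are averaged after removing `ceil(0.01·n)` values
  from each tail — a count-based trim rule chosen because it is
  unambiguous for any n (the interpolated-percentile alternative is not);
  it errors when trimming would consume everything.
- **Device scaling and mixing.** Rows scale by device current (0.9 /
  0.8 A); switched courses combine placements by session-count weights,
  e.g. 6 RUL + 18 BT → 0.25·EF_RUL + 0.75·EF_BT. Mixing uses recorded
  session counts exactly; per-session field variation is not modeled.

Region centroids are fixed synthetic MNI-like coordinates shipped in
code; they exist only to drive this surrogate and are not measurements.

## The synthetic world

The generator states one world and the tests measure it; none of its
constants are tuned per-test.

**Cohort.** Age ~ Normal(54, 12) clipped to [18, 90]; 60% female;
baseline MADRS ~ Normal(25.5, 6) floored at 10, integer; placements drawn
at fractions 246/79/61 out of 386; session counts per placement
Normal(10.9, 4.4) / (14.3, 6.2) / (16.4, 5.3), rounded, floored at 2;
MIX subjects put 20–60% of sessions into the initial RUL phase (≥ 1 per
phase). Devices are assigned per site (a site runs one machine).

**Volume change.** `ΔVolᵢᵣ = aᵢ·L1ᵣ + s_b·bᵢ·L2ᵣ + κ·EFᵢᵣ + εᵢᵣ` with
`aᵢ = 0.08·nECTᵢ + ξᵢ` (ξ SD 0.6), strictly positive loadings
`L1 ~ 1 ± 0.2`, unit-norm L2 proportional to the reference map,
`bᵢ ~ N(0,1)` scaled by `s_b = 2.9`, `κ = 0.02` %/(V/m), and noise SD
0.8%. The linear-Gaussian form is the simplest structure a PCA can be
expected to recover. Constants were calibrated once, by simulation,
before being frozen, to land PC1 variance-explained near 40% and PC2 near
6–11% at n = 250 — the variance partition the pipeline is designed to
detect. (A literal `bᵢ·L2ᵣ` term with unit-norm L2 contributes ~1% of
variance and cannot reach that partition; the scale `s_b` is equivalent
to b ~ N(0, s_b²).)

**Outcome.** `(post−pre)/pre = −0.59 − 0.004·(age−54) + 0.012·(nECT−12.5)
− 0.05·bᵢ + η`, η SD 0.15; the post score is rounded and floored at 0 and
the fraction recomputed from integer scores (MADRS is an integer scale).
The negative b coefficient plants "more network-like change → better
outcome"; the positive nECT coefficient plants the observational
confound. The outcome noise scale and site-effect magnitude (default 0;
`site_sd` exercises the mixed model) are documented choices — no
published estimates exist for them.

**Baseline volumes.** Region-typical magnitudes by tissue class (cortical
8 000, subcortical 3 500, cerebellum 60 000, brainstem 20 000 mm³) with
log-normal region (SD 0.3), subject (SD 0.12) and cell (SD 0.08)
variation; `V2 = V1·(1 + ΔVol/100)`. Under baseline reshuffling the
subject-gain ratio survives as a global rank-1 null component and the
cell noise drowns region-specific structure — which is exactly why the
null kills reference similarity while the observed data keep it.

**What a green test does and does not establish.** The generator shares
the real data's *structure* (two factors, EF coupling, confounding,
placement asymmetry) but none of its *biology*: no spatial
autocorrelation between neighboring regions beyond left–right symmetry,
no heavy-tailed measurement error, no site-specific scanners, no
selection effects. Passing tests establish that the pipeline recovers
what was planted at realistic sizes and that its permutation inference is
calibrated — not that the published effect is true, nor that effect sizes
transfer to real cohorts.

## Numerical choices

- z-scoring uses the sample SD (n−1): conventional for cohort statistics;
  the column (1,2,3) maps exactly to (−1, 0, 1). Zero-variance regions
  are an error naming the region.
- PCA via LAPACK SVD of the centered matrix; the test oracle is an
  independent `eigen()` of the covariance (agreement to 1e−8 relative on
  eigenvalues, |loading correlation| = 1). Tied eigenvalues keep LAPACK's
  deterministic order; ties break by input column order.
- The scree elbow is the argmax of the second difference of the variance
  fractions, floored at 2; a curve whose maximal second difference is
  below 1e−3 has no elbow and returns the floor with a warning.
- Add-one permutation p-values never reach 0; `n_perm = 199` gives a
  minimum of 0.005. The identity permutation can be forced for
  diagnostics (`force_identity`), making null = observed and p = 1.
- OLS by QR; rank deficiency errors name the dependent columns. REML via
  lme4 defaults; singular fits are tolerated (the site_sd = 0 case is a
  legitimate boundary).
- BH-FDR wraps `stats::p.adjust(method = "BH")` across exactly the 85
  regional tests.

## Open design decisions

- **Cortical label set.** The 33-per-hemisphere count matches the
  Desikan–Killiany scheme minus one label; the exact published list is
  unavailable, so `frontalpole` (the smallest, least reliable parcel) was
  dropped from the 34. This affects region naming only, not any
  statistic.
- **Recovery benchmarks** run on the RUL group's PCA — the largest group
  and the primary cohort in this literature.
- **Permutation scope.** Baselines reshuffle within placement group:
  PCAs are placement-stratified, and cross-group swaps would break the
  design's exchangeability.
- **Null statistic.** `max|r|` over K = 2 components, because which
  component should resemble the reference is not knowable a priori under
  the null; per-component p-values are reported alongside.

## Known limitations

- The EF surrogate is not a field solver: no tissue conductivities, no
  head mesh, no shunting; only ordering/sign properties are meaningful.
- Synthetic maps lack spatial autocorrelation, so permutation nulls here
  are, if anything, easier than on real, smooth maps; spin-test style
  nulls are out of scope.
- The atlas ships synthetic centroids; do not reuse them as anatomy.
- `delta_madrs` is a ratio of integer scores: at low baseline MADRS the
  rounding granularity is visible (baselines are floored at 10 to keep it
  mild).
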
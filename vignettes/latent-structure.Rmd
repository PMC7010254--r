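---
title: "Latent structure of cognition: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent structure of cognition: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogstruct)
```

# The analysis this package implements

`cogstruct` asks, from the bottom up, whether a battery of cognitive tasks
decomposes into a small number of latent abilities, and whether the brain
activity evoked by those tasks decomposes the same way. Three stages:

1. **Behavioral factor structure.** Exploratory factor analysis (EFA) of
   the subject-by-task score matrix: maximum-likelihood extraction on the
   task correlation matrix, geomin (oblique) rotation, and a
   structural-equation fit suite (chi-square, CFI, TLI, RMSEA, SRMR) for
   3-, 4- and 5-factor candidates.
2. **Neural factor structure.** Each task's group-level z-map is
   thresholded at z > 2.3; for every pair of tasks the z-values are
   correlated over the intersection of the two positive activation masks.
   With 12 tasks this gives 66 pair correlations which, with the 12 unit
   self-correlations, fill the 78 distinct cells of a symmetric 12 x 12
   similarity matrix. The same EFA engine is then applied to that matrix.
3. **Brain-behavior coupling.** For each latent domain, subjects' beta
   estimates are averaged over the domain's conjunction mask (the
   voxelwise AND of its three task masks) and across its three tasks, and
   correlated with the subject's composite behavioral performance in that
   domain.

No subject-level fMRI preprocessing or GLM time-series modeling is
performed here: the pipeline starts from z/beta maps on a common grid.

# The common-factor model

For `p` standardized indicators and `m` factors,

    Sigma = Lambda Phi Lambda' + Psi

with loadings `Lambda` (p x m), factor correlations `Phi` (unit diagonal,
positive definite) and diagonal uniquenesses `Psi`. ML extraction
minimizes the discrepancy

    F(Psi) = log|Sigma| + tr(R Sigma^-1) - log|R| - p

profiling `Lambda` out via the eigendecomposition of
`Psi^(-1/2) R Psi^(-1/2)` (the classic Lawley-Maxwell reduction), with
uniquenesses box-constrained to `[1e-3, 1]` and ten random restarts.
A solution on the lower bound is a Heywood case and is flagged, not
silently accepted. `stats::factanal` optimizes the same profile
likelihood with different code and serves as an independent oracle in the
test suite; agreement on random positive-definite inputs is at the 1e-6
level (typically 1e-9).

Geomin rotation minimizes the row-wise geometric mean of squared loadings
(plus `eps = 0.01`, the common default; the value is configurable because
published analyses rarely state it) over oblique rotations by gradient
projection, from the identity start plus 29 random orthonormal starts.
The projected-gradient convergence tolerance is 1e-6 -- reference
gradient-projection implementations use 1e-5, and tighter tolerances are
unattainable on the flat landscapes produced by near-degenerate extra
factors. Rotation never changes the implied matrix; the package asserts
`Lambda Phi Lambda' + Psi` invariance to 1e-8.

Test statistics use `chi2 = (n_effective - 1) * F_min` (the `n * F`
convention is available via `chi2_scale`). The baseline model is
independence (`Sigma_b = I`, so `F_b = -log|R|` with `df_b = p(p-1)/2`).
RMSEA is 0 and CFI is 1 whenever `chi2 <= df`. SRMR averages squared
residuals over the `p(p+1)/2` lower moments including the diagonal. For
raw behavioral input the free-parameter count includes the `p` indicator
means (`p(m+1) - m(m-1)/2 + p`); a correlation-only input (the neural
matrix) omits them.

## Effective sample size

Behavioral: with pairwise-complete correlations, `n_effective` defaults
to the median pairwise count (72 complete cases of 114 in the emulated
design give a median near 100); listwise deletion is available. Full-
information ML from raw incomplete data is out of scope. Neural: there is
no principled subject-count equivalent for a spatial-similarity matrix;
the default is the voxel count of the union of all positive masks, which
reproduces the magnitude (thousands) of published imaging chi-squares,
and the parameter is exposed because any choice is a convention. Neural
chi-square p-values should not be read inferentially.

# What the synthetic generator emulates

The generator is the ground truth against which every stage is tested.

**Behavior.** Twelve tasks in four oblique domains (episodic memory
retrieval, reasoning, processing speed, vocabulary; three tasks each).
Primary loadings are fixed at the published 4-factor magnitudes
(memory .884/.628/.416, reasoning .844/.852/.617, speed .826/.815/.805,
vocabulary .903/.677/.798), cross-loadings zero, inter-factor
correlation 0.30 uniform, N = 114. The 0.30 value is a design choice
where the source is silent: it is a moderate obliqueness under which the
merged 3-factor model has population RMSEA 0.11, i.e. the planted
4-factor structure is identifiable at the design sample size. Latent
scores are Gaussian; accuracies are a logistic squash
`plogis(qlogis(0.75) + 0.35 y)` (mean ~0.75, range ~0.55-0.90) and
reaction times a *decreasing* `1.8 exp(-0.25 y)` seconds (CV ~25%), so
speed indicators oppose accuracy indicators in sign exactly as in real
batteries. Because EFA consumes correlations, any strictly monotone
transform preserves the planted structure up to small rank-preserving
distortion (empirically ~1-2% attenuation). Missingness can follow the
two-session study design (72 completers of 114, whole-session and
partial-session dropouts) rather than MCAR.

**Imaging.** Maps live on a 24^3 voxel grid by default (the smallest
grid where masks hold hundreds of voxels; the geometry is specified in
relative coordinates so smaller grids remain proportional). Templates
are graded quadratic-cap blobs: two shared blobs every task activates
(emulating the domain-general posterior visual and inferior/cerebellar
activations) and one blob per domain that partially overlaps the shared
regions and its neighbours. The overlap is essential: with disjoint flat
templates, cross-domain intersection masks would contain only voxels
where the two maps are identical, and within- and between-domain
similarities would coincide. With the default geometry the within-domain
pair correlation is ~0.87 and between-domain ~0.52, matching the
published magnitudes. Noise-free template peaks sit at z = 12
(`effect_scale`; group maps of ~100 subjects peak well above 10), and
smoothed Gaussian noise (FWHM 2 voxels, sd 1) is added per realization.

**Betas.** Subject beta maps share the behavioral draw's factor scores:
the in-network amplitude of subject i on a task of domain d is
`coupling_d * f_id` plus a per-subject-per-task scalar (sd 1) and
smoothed voxel noise. `calibrate_coupling()` inverts, in closed form, the
attenuation chain from a target brain-behavior correlation to the
required coupling: the behavioral composite reliability
(`cor(composite, f_d)` = 0.83 for the memory domain) and the neural
noise terms, including the exact variance of the mask-mean of smoothed
voxel noise (the smoothing operator is self-adjoint, so that variance
has a closed form). Replicate studies use the deterministic group-level
conjunction mask (noise-free template thresholded at 2.3), mirroring a
study's single fixed group mask; recovery of a planted r = 0.31 at
N = 114 is then accurate at any grid (verified at 24^3 and 12^3).

**What the generator does not emulate** -- and what green tests therefore
do not show about real data: no hemodynamics or trial-level variability,
no registration error or subject-specific anatomy, Gaussian and
homoscedastic noise, exact zero cross-loadings, and an exactly correct
factor model in the population. Real batteries violate all of these.

# Numerical and procedural choices

* **Strict threshold** (`value > z`): a voxel exactly at 2.3 is excluded.
  Fixtures avoid exact-boundary values.
* **Minimum pair-mask size** `n_min = 10` voxels: a Pearson r over fewer
  voxels is too unstable to report; smaller intersections are errors
  listing the failing pairs.
* **Cluster inference is out of scope**: thresholding is voxelwise. A
  26-neighbour minimum-cluster-size filter is available (default off)
  for contiguity pruning only.
* **PD repair**: pairwise masks differ per pair, so the assembled
  similarity matrix need not be positive semidefinite. Repair clips
  eigenvalues at a floor and rescales to unit diagonal, iterated to
  convergence; whether repair ran is recorded (`repaired` flag), since a
  published analysis may or may not have needed it. The standalone
  repair floors at 1e-6; the neural EFA entry point repairs to 0.005
  (the conventional uniqueness lower bound) because an eigenvalue below
  what the factor model can represent would dominate the voxel-scale
  chi-square with unfittable structure.
* **Selection rule**: smallest m with RMSEA <= 0.06 and SRMR <= 0.08,
  else the smallest-RMSEA model; the rationale string always lists every
  candidate so the report does not hide alternatives.
* **Membership**: `max_loading` (argmax of |loading|, ties to the lower
  factor index with a warning) is the default; an `a_priori` rule is
  provided because published bolding sometimes follows prior domain
  assignments where they disagree with the maximum -- both rules should
  be reported when they differ.
* **Outliers**: subjects beyond 4 group-SDs on the mask-mean beta
  (conservative relative to the ~5 SD case such rules are meant to
  catch); statistics with and without them are always reported.
* **Domain mask for beta extraction**: the conjunction mask of the
  domain's three thresholded task maps. "The group-level mask" is
  ambiguous in published descriptions; the conjunction is the choice
  here and is recorded in outputs.
* **Degenerate inputs**: non-PD correlation inputs error with an
  instruction to repair; `n_effective <= p` disables test statistics but
  returns loadings; one-factor models skip rotation; zero-variance or
  undersized masks propagate as undefined-correlation errors.

# Problem sizes used by the test suite

Chosen to keep the full suite within a normal desktop run: Monte-Carlo
convergence at N = 100,000 (one draw); within/between similarity
ordering over 200 noise realizations on a 12^3 grid; parameter recovery
at N = 10,000; model-selection study with 100 replicates at N = 114;
brain-behavior recovery with 500 replicates at N = 114 on a 12^3 grid
(the coupling calibration is grid-exact, so the smaller grid changes
runtime, not the planted effect). The oracle comparisons run 20 random
12 x 12 inputs against `stats::factanal` and a 500-start geomin
reference run.

# Known limitations

* No confirmatory SEM, no standard errors on loadings, no modification
  indices, no FIML for missing data.
* Neural chi-square scale rests on a conventional `n_effective`.
* The clip-and-rescale PD repair is a projection heuristic, not the
  Frobenius-optimal correlation projection (it agrees with an
  independent implementation of the same scheme to 1e-8 and stays close
  to the optimal projection in practice).
* Geomin with small `eps` on near-degenerate solutions can have multiple
  local minima; 30 starts with a fixed seed make results reproducible
  but global optimality is only probable, not guaranteed.
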
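---
title: "Methods: gray-matter-volume / gene-expression spatial association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gray-matter-volume / gene-expression spatial association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmvexpr)
```

# The question and the pipeline

Imaging-transcriptomics studies ask whether the spatial layout of a brain
phenotype — here, regional differences in gray matter volume (GMV) between
children with persistent stuttering and fluent controls — co-varies with
the spatial layout of gene expression measured in independent adult donor
brains. `gmvexpr` implements that analysis as composable stages: a
longitudinal group-difference GLM with cluster-robust variance, regional
t summaries, regionization of donor microarray samples onto an atlas,
gene-wise Spearman correlation with FDR control and percentile
thresholds, Fisher's-exact gene-set enrichment of the extreme tail, and
the study's sensitivity variants. A synthetic-data module provides all
inputs with known ground truth.

# The longitudinal marginal model

Each region (or voxel) is fit by ordinary least squares over all scans,

$$ y_{ij} = \beta_0 + \beta_g g_i + \beta_a a_{ij} + \beta_{a^2} a_{ij}^2
   + \beta_{ga} g_i a_{ij} + x_{ij}^\top\gamma + \varepsilon_{ij}, $$

where $g_i$ indicates the case group, $a_{ij}$ is age centered at the
grand mean over all retained scans (centered before squaring and before
forming the interaction), and $x_{ij}$ collects sex, IQ, brain size and
socioeconomic status, each demeaned over all scans. Stuttering severity
is a covariate that only exists for the stuttering group: it is coded 0
on control rows and group-mean-centered on case rows, so it absorbs
severity-related variance without shifting the group contrast. A linear
age term accompanies $a^2$ and $g\,a$ — without it the interaction is
not interpretable. The full design has 10 columns; single-sex subsets
drop the (then constant) sex column.

Repeated scans of a subject are correlated; instead of modeling that
covariance, inference uses the subject-clustered sandwich

$$ V = (X^\top X)^{-1}\Big(\sum_s X_s^\top \tilde e_s \tilde e_s^\top
   X_s\Big)(X^\top X)^{-1}, $$

with contrast t statistics referred to a Student t on
$G - \mathrm{rank}(X)$ degrees of freedom ($G$ = number of subjects), a
deliberately conservative cluster-count rule.

**Small-sample adjustment.** The raw cluster sandwich is biased downward
at realistic cohort sizes: in our null simulations at 70 subjects the
group-contrast test rejected at ~0.075 instead of 0.05. The default is
therefore the Bell–McCaffrey CR2 adjustment, which premultiplies each
subject's residual block by $(I - H_{ss})^{-1/2}$ (pseudo-inverse square
root of the within-cluster annihilator); measured type-I error is then
0.051–0.059 across simulation seeds, inside the binomial 99% band, and
95% CI coverage of a planted effect is 0.93–0.97. `adjust = "none"`
recovers the raw estimator — with one scan per subject it is exactly the
HC0 heteroskedasticity-robust covariance (CR2 collapses to HC2) — and
`"CR1"` applies the scalar $\frac{G}{G-1}\frac{N-1}{N-p}$ factor.
Degenerate inputs: a region with zero response variance has no defined t
and is flagged and excluded from the t-map rather than failing the fit;
constant covariates raise an error naming the column; designs with fewer
rows than columns are flagged rank-deficient.

# Cluster-extent thresholding

`cluster_threshold()` estimates the minimum cluster size $k_{\min}$ such
that a null field thresholded voxel-wise at height $p$ produces a
suprathreshold cluster of at least $k_{\min}$ voxels with probability at
most $\alpha$. Null fields are white Gaussian noise smoothed by FFT
convolution under periodic boundaries (periodicity keeps the field
stationary on small grids, avoiding edge-variance bias) and standardized
to unit variance. `fwhm` parameterizes the **field's autocorrelation**:
the ACF of the simulated field is $\exp(-4\ln 2\, d^2/\mathrm{fwhm}^2)$,
which requires the smoothing kernel's sigma to be the target sigma
divided by $\sqrt 2$, because convolving white noise doubles the ACF
variance. A Gaussian ACF is a simplification of the mixed-exponential
autocorrelation some packages fit to residual images; the fitted
parameters of any particular study are rarely reported, so the Gaussian
model is the identifiable default and the mixed model an extension
point. Thresholding is two-sided by default ($|z| > z_{1-p/2}$, one
pooled mask for both signs, since group differences of both signs are of
interest); connectivity is faces-only by default (edges/corners
configurable). Connected components are found on the voxel adjacency
graph via `igraph`; a brute-force flood fill serves as the test oracle.
At alpha below the $1/n_\mathrm{iter}$ simulation resolution the
returned $k_{\min}$ is the simulation ceiling, with a warning.

The reference threshold in the motivating study (k > 316 voxels at
p < 0.005 on the study's own residual smoothness) is not recomputable
without those residual images; what the package guarantees — and tests —
is the defining property: applying $(p, k_{\min})$ to fresh null fields
gives a family-wise false-positive rate ≤ α.

# Expression regionization

The donor bundle (probe table, sample table with MNI coordinates,
probe × sample log-intensity matrix) is reduced to a gene × region
matrix in four steps, mirroring the standard treatment of the donor
microarray resource:

- **Symbol whitelist.** Probes whose gene symbol is not in the supplied
  whitelist (emulating nomenclature-database filtering) are removed; the
  surviving unique symbols are the gene universe, and the surviving
  count is reported in the run log.
- **Probe averaging.** Probes of a gene are averaged per sample
  (arithmetic mean).
- **Sample assignment.** With a label volume, a sample maps to the voxel
  containing its MNI coordinate (0-based voxel indices via the inverse
  affine); background coordinates fall back to the nearest labeled voxel
  within `max_dist_mm` (default 2 mm), else the sample is unassigned and
  logged. With a precomputed table, assignments pass through.
- **Analysis regions and medians.** The analysis keeps the 45
  left-hemisphere supratentorial regions plus the right cerebellum
  merged to a single region (46 in total); right-hemisphere coverage in
  the emulated resource is too sparse, and the right cerebellum
  connects anatomically to the left cerebral hemisphere. Each region is
  the **median** of its assigned samples — robust to outlying samples,
  which the tests verify directly. The primary mode pools all donors'
  samples into one median; per-donor regionization supports the
  donor-variability analysis. `min_samples` defaults to 1 (no minimum);
  regions below it are dropped with a warning.

# Gene-wise association

Spearman's ρ is the Pearson correlation of midranks (average ranks on
ties), two-sided p from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$
degrees of freedom. The t approximation is the practical choice at 46
regions and ~19k genes; an exact permutation option exists for n ≤ 8 and
is used as a test oracle. The regional difference map is the mean |t|
per region (magnitude of the group difference, the primary mode) or the
mean signed t (the directional post hoc variant); by construction the
absolute map dominates the |signed| map elementwise. FDR control is
Benjamini–Hochberg across all tested genes (`stats::p.adjust`; the tests
hold it to the exhaustive step-up definition). Percentile thresholds on
the ρ distribution use linear interpolation between order statistics
(`stats::quantile` type 7, the common software default — the convention
matters for reproducibility and is therefore fixed and documented).
Genes with constant regional expression have no defined ρ and are
excluded and logged.

Sensitivity variants rerun the affected stages from the raw inputs:
region exclusion (recorrelate on the remaining regions), male-only
subset (refit without the sex column), an alternative case group
(e.g. recovered vs control, refit on those scans only, severity coded by
the same rule), and per-donor (one regionization and correlation per
donor, emitting a donor × gene ρ table).

# Enrichment

The selection is the top `floor(0.025 · n_genes)` genes by ρ (most
positive, or most negative for the exploratory negative tail) — the
floor rule reproduces the worked-example count 479 of 19,174. Boundary
ties are broken by gene-id lexicographic order, deterministically, and
logged. Each catalog category is first intersected with the background
(all tested genes); categories below `min_category` (default 3) in the
background are skipped. The one-sided over-representation p is the
hypergeometric upper tail (`stats::phyper`; exhaustive enumeration is
the oracle at N ≤ 30), the enrichment factor is $(k/n)/(K/N)$, and BH
FDR runs across tested categories. Exact discrete tests are
conservative: null p-values are sub-uniform rather than uniform, which
is what the calibration tests assert.

# The synthetic-data generator

`gen_cohort()` draws, per subject, a group, a random intercept
$u_i \sim N(0, \texttt{subject\_sd}^2)$, a first-visit age uniform on
`age_range` with fixed 1-year inter-visit spacing, and covariates at
printed-plausible population values (IQ ~ N(110, 13), brain size ~
N(1100, 100) cm³, SES ~ N(50, 10), sex Bernoulli(0.5), severity
~ N(20, 6) truncated at 0 for the stuttering groups only, `NA` for
controls). Regional GMV adds the region baseline, the planted group
effect, the group-by-age slope, optional covariate effects and
i.i.d. Gaussian noise. Defaults mirror the motivating cohort: 44
controls and 26 persistent-group subjects, 1–5 scans each. The
within-subject variance components are not reported in the motivating
study; `noise_sd = subject_sd = 0.5` GMV units are stated defaults, not
fitted values.

`gen_expression()` plants `n_causal` causal genes whose regional signal
is affine in the **rank** of the absolute planted effect:
$s_r = c\, z(\mathrm{rank}|\delta_r|) + \sqrt{1-c^2}\,\eta_r$. Spearman
is rank-based, so a rank-space link makes the target correlation
directly controllable by the coupling $c \in [0,1]$: $c = 1$ with no
measurement noise gives ρ = 1 exactly; $c = 0$ is spatially null; the
expected causal ρ is monotone in $c$ (all three verified in tests).
Probes of a gene share the gene signal plus a probe offset; samples add
N(0, `expr_noise_sd`) measurement noise. `samples_per_region` is drawn
**per donor** (so the pooled region has `n_donors ×` that many samples,
and per-donor reruns stay well defined); the default scale is 500
genes × 2 probes × 3 samples/region/donor × 6 donors over 46 regions —
a desk-scale stand-in for the real resource's 29k genes / 58k probes /
3.7k samples. The reference study conditions
(`write_synthetic_inputs()`) plant a graded effect map — magnitudes
spanning 0–0.8 GMV units with alternating signs across regions — the
way a real group-difference map varies smoothly in magnitude, which is
what makes rank coupling to |effect| informative; coupling defaults
to 1 (a cleanly planted truth).

What the generator does **not** emulate: registration and segmentation
artifacts, spatial autocorrelation between neighboring regions,
inter-donor normalization artifacts, and realistic microarray noise
structure. Passing tests therefore demonstrate that the statistical
machinery recovers planted truth under the stated model — not that the
original study's specific coefficients would replicate on real scans.
In particular, the subject random intercept is shared across regions,
so a single cohort's signed effect estimates all shift together with
the luck of the group draw; magnitude summaries at the reference cohort
size recover the planted ranking, but individual small-cohort runs can
be noisy, which is why calibration claims are tested across many
regions or seeds.

`gen_catalog()` plants `causal_enriched_categories` categories drawing
at least 80% of members from the causal genes (sizes capped so that is
feasible) among otherwise random categories.

# Problem sizes and numerical choices

The test suite and the acceptance script run at fixed, stated scales
chosen as reasonable Monte-Carlo sizes for the properties being
estimated: type-I error at 1,000 independent-noise regions (subject
intercepts switched off there so the binomial reference applies), CI
coverage at 500 regions × 200 subjects, end-to-end recovery over 8
seeds at the reference scale with 1 causal gene among 499 nulls,
cluster-extent calibration on a 32³ grid at 200–300 iterations, the
full-scale ranking at 19,174 genes. All randomness flows from one root
seed through named substreams; fixed seed means bit-identical outputs,
which the tests assert, including byte-identical pipeline TSVs.

Known limitations: no working covariance other than identity in the
GLM (the plain OLS + sandwich marginal model); Gaussian-ACF-only noise
model for cluster simulation; no spatial-autocorrelation-preserving
("spin") null for the gene correlations — the percentile thresholds
describe the empirical ρ distribution, they are not a spatial null;
GO-graph structure and category redundancy are out of scope for the
enrichment stage.
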
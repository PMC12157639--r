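---
title: "Cryptic-exon burden analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic-exon burden analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceburden)
```

## Scientific background

TDP-43 normally represses the splicing of non-conserved intronic sequence.
When nuclear TDP-43 is depleted — as in limbic-predominant age-related
TDP-43 encephalopathy (LATE) and a large fraction of Alzheimer's disease —
**cryptic exons (CEs)** appear in transcripts such as *STMN2*, *UNC13A*,
*ELAVL3*, *KALRN*, *ARHGAP32*, *CAMK2B*, *PFKP* and *SYT7*. CE abundance is
a quantitative molecular readout of TDP-43 loss of function, and many
CE-containing transcripts lose protein expression (nonsense-mediated decay
or truncated products), so the proteome carries a matching signature.
`ceburden` takes a cohort from raw qPCR cycle thresholds through molecular
subtyping, proteome normalization, co-expression network analysis, and
cross-modal comparison against a TDP-43-knockdown neuronal proteome.

## CE quantification (ΔΔCt)

For subject $i$ and CE assay $c$,

$$\Delta Ct_{ic} = Ct_{ic} - \mathrm{geomean}(Ct_{i,\mathrm{HK}}), \qquad
\Delta\Delta Ct_{ic} = \Delta Ct_{ic} - \overline{\Delta Ct}_{c,\mathrm{controls}},$$

and the reported value is $-\Delta\Delta Ct$ (log2 relative expression), so
larger numbers mean more CE. Design choices:

* The geometric mean is taken over the raw housekeeping **Ct values**
  (RPLP0, GAPDH, CYC1), not over linearized expression values.
* Control-group centering makes control column means exactly 0; the
  control set is an explicit argument, never inferred.
* Undetermined wells propagate as missing and are excluded pairwise
  downstream; no Ct ceiling is substituted by default (a cap is available
  via the generator/reader if a study uses one). Amplification-efficiency
  correction and standard curves are out of scope.

## Burden Score and molecular subtyping

Each CE column is ranked 1 (lowest) to $n$ (highest) with average ranks on
ties, and the eight ranks are summed per subject. The score is invariant
under any strictly monotone transform of a CE column, lives in
$[8, 8n]$, and (without ties) sums to $8\,n(n{+}1)/2$ across subjects.
Missing CE values rank lowest by default (absence of a cryptic exon means
no detectable template), configurable to an error.

Subtypes come from hierarchical clustering of subjects on the CE matrix —
Euclidean distance on the log2 values, Ward (`ward.D2`) linkage, no column
standardization since all CEs share the ΔΔCt scale (a `scale` switch exists
for heatmap parity). The tree is cut at $k = 3$ and the bins are named
*low* / *intermediate* / *high* by ascending mean Burden Score. Because
manual binning of such dendrograms in practice also inspects the expression
pattern, the deterministic stand-in implemented here refines the cut by
iterated nearest-centroid reassignment (hclust-initialized k-means) until a
fixed point; this places bin boundaries along the burden continuum much
more accurately than the raw tree cut and is exactly reproducible. Set
`refine = FALSE` for the pure tree cut. PCA (`pca_check`) provides the
validation view: PC1 orders the subtypes, and the mean silhouette width on
the first two PCs quantifies separation.

## Proteome preprocessing

**TAMPOR-style normalization** alternates two median polishes on the log2
scale: per feature and batch, subtract the median over that batch's GIS
reference channels (ratio-to-standard); per sample, subtract the median
over features. Iteration stops when the largest adjustment drops below
`tol = 1e-8` (cap 250 sweeps; non-convergence is a warning, never an
error). The procedure is idempotent at convergence. The exact iteration
schedule is this package's declared scheme.

**Missingness filter**: features absent in $\ge 50\%$ of cases are removed
(45 of 90 missing is removed; 44 is kept). Tissue values are never imputed
— only the pTDP-43 trait (floor 0.1, about half the lowest detected level)
and the knockdown matrix are.

**Outlier removal**: the criterion adopted is the standard network
connectivity z-score — a sample whose mean inter-sample correlation falls
more than 3 SDs below the cohort mean is removed, and the procedure
iterates (default up to 5 rounds) until clean.

**Covariate regression**: per feature, OLS of abundance on
diagnosis + age + sex + PMI + batch over `n_boot` bootstrap resamples
(default 1000, seed mandatory); nuisance coefficients are the medians over
resamples, and the column-centered nuisance design times those
coefficients is subtracted, so the diagnosis contribution and the grand
mean survive untouched. Pipeline order is outliers → TAMPOR → filter →
regression, each stage independently callable.

## Robust statistics

`bicor` is the Tukey biweight midcorrelation: with
$u_i = (x_i - \mathrm{med}\,x) / (9\,\mathrm{MAD}\,x)$ (unscaled MAD) and
weights $w_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1]$, the coefficient is the
normalized weighted cross-product of median-centered vectors. Pairs with a
missing entry are dropped before medians are computed (pairwise-complete);
a zero-MAD vector triggers a tagged Pearson fallback for that pair.
p-values use $t = r\sqrt{(n-2)/(1-r^2)}$ on the pairwise-complete $n$.
A single 100-SD outlier moves bicor by < 0.05 where Pearson moves by > 0.3
(property-tested). A C++ kernel computes pairwise-complete matrices; on
complete data an exactly equivalent transform-once-and-crossprod fast path
is used.

ANOVA, Welch contrasts and Spearman-vs-burden correlations are vectorized
over features; every analysis call is its own BH family. Volcano fold
change is the difference of group means of log2 abundance. The
CE-transcript bias test counts, among proteins from a supplied CE gene
list significant at BH q < 0.05, negatives versus positives in the burden
correlation, and applies a two-sided exact binomial test against 0.5.

## Signed co-expression network

Adjacency $a_{ij} = ((1+\mathrm{bicor}_{ij})/2)^{\beta}$ with $\beta = 24.5$
(fractional powers are fine on the nonnegative base), topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}},$$

and average-linkage clustering of $1-\mathrm{TOM}$. Features more than 25%
missing are excluded from the network with a warning; pairwise-complete
bicor handles the rest exactly, so the ceiling is a practical guard rather
than a statistical necessity.

Tree cutting is adaptive. At $\beta = 24.5$ the TOM dissimilarities
compress into the top fraction of the height range and the informative cut
moves with the data, so a fixed static cut is brittle; the implementation
scans a ladder of cuts (0.95–1.00 of the merge-height range) and keeps the
one producing the most clusters of at least `min_module_size = 15`
(ties: the most features covered). Each branch is then recursively split
where the merge-height gap is large relative to the tree (`deep_split`
0–4 lowers the required gap; default 2), and a PAM-style stage iterates
three refinements: reassign members to the nearest module by mean
dissimilarity, release members whose dissimilarity to their own module
approaches the background median (branch cuts sweep in loose hangers-on),
and attach unassigned features lying within a module's own radius.
Modules are numbered M1, M2, … by decreasing size; 0 is unassigned.

Eigenproteins are the first principal component of each module's
standardized abundance (unit norm, sign aligned with the module mean
profile); kME is each feature's bicor with each eigenprotein. Modules
whose eigenproteins correlate above 0.93 (dissimilarity < `cut_height
= 0.07`) are merged iteratively to a fixed point, and members whose own
kME falls below 0.3 — the conventional stay-in-module floor — are released
to unassigned. Module–trait association uses bicor over all samples for
continuous traits and, for disease types, bicor against a 0/1 indicator on
the control-plus-one-disease subset (each combination separately).

## Enrichment and cross-modal integration

Gene-set enrichment is the one-tailed (enrichment-only) Fisher's exact
test, computed as the hypergeometric upper tail, with BH across each
module × set grid. The default background is every feature in the analyzed
matrix — enrichment should condition on detectability in the proteome, not
on the genome. Symbols are case-folded; GMT files are validated line by
line.

The knockdown arm averages technical replicates (available-case mean),
imputes missing values per sample from
$\mathcal N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$ — the conventional
downshifted-normal parameters, recorded in the output — and runs Welch
t-tests per protein. Concordance: a protein significant at BH q < 0.1 in
**both** the tissue Spearman-vs-burden analysis and the knockdown contrast
is *concordant down* (both negative), *concordant up* (both positive) or
*discordant*; anything else is *ns*. The q-based reading of "nominally
significant in both datasets at FDR 0.1" is the default; a flag switches
to nominal p. Tissue-side significance is the burden correlation, not the
subtype ANOVA. Concordant sets are then tested for module overlap by FET
over the shared-feature background.

## The synthetic-data generator

The generator exists so that every stage can be validated against planted
truth; its defaults define the simulated study conditions.

* **Cohort** (default n = 90; Control : LATE : AD : AD+LATE in 21 : 10 :
  24 : 35 proportions): latent burden is a 3-component Gaussian mixture,
  adjacent component means `separation = 2` within-component SDs apart
  (subtype recovery checks use 4). Mixture weights depend on group —
  Control (0.85, 0.15, 0), AD (0.70, 0.25, 0.05), LATE (0.25, 0.40, 0.35),
  AD+LATE (0.10, 0.40, 0.50) — so high burden concentrates in AD+LATE and
  LATE while Control and AD stay mostly low. The **planted subtype** is the
  deterministic banding of each subject's realized burden at the midpoints
  between component means: a draw landing across a boundary is genuinely of
  the band it landed in, which is what a clustering method can and should
  recover. The drawn component is recorded separately. pTDP-43 is lognormal
  with correlation 0.6 to burden (the two are related but not
  co-dependent; the correlation is a parameter, not a constant), censored
  below 0.2 to exercise floor imputation; pTau ratio and Aβ42 are elevated
  in AD-containing groups independent of burden; MMSE declines linearly
  with burden plus noise.
* **qPCR**: each subject has an RNA-input offset shared by all assays;
  housekeeping Cts are baseline + input; CE Cts subtract
  `loading × burden` (defaults 0.8–1.2 cycles per burden SD, per-well
  noise 0.3 cycles). With zero noise and unit loading, `ce_quantify`
  returns the control-centered burden exactly — an algebraic round trip
  used as a test oracle.
* **Proteome** (1,500 features): six modules of 100–30 features with
  intra-module factor loading 0.6 and per-module burden association
  (0.8, −0.8, 0.5, −0.7, 0, 0.3) — two strong, two moderate, one null,
  one weak; a 10-feature runt block below the minimum module size that
  detection must leave unassigned; 35 CE-gene features with direct burden
  loadings ±0.5, 30 negative and 5 positive (the expected NMD-driven
  bias); small random per-feature age/sex/PMI/batch coefficients plus
  optional planted fixed effects for recovery tests; per-sample loading
  offsets and per-feature batch shifts shared with the GIS channels (what
  TAMPOR removes); 5% MCAR plus ~5% intensity-dependent MNAR missingness.
  Features with planted |burden correlation| ≥ 0.3 are recorded as the
  concordant set.
* **Knockdown** (4 vs 4): concordant features receive log2FC ±2 of the
  recorded sign (strong knockdown effects, in line with the near-complete
  loss of CE-gene products after TDP-43 depletion); noise SD 0.3;
  missingness is purely intensity-dependent with a steep (~0.7 log2 unit)
  detection transition, emulating label-free detection limits — a diffuse
  missing-at-random component would make global downshifted imputation
  destroy genuine effects at n = 4, which real DIA missingness does not.

What the generator does **not** emulate: peptide-level roll-up, reporter
ion interference, correlated biological confounding between burden and
covariates, heavy-tailed abundance noise, or qPCR efficiency differences.
Passing recovery tests therefore demonstrates correctness of the
algorithms under the declared generative model, not performance guarantees
on any real cohort.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at n = 90 subjects and 1,500
features (the study-scale condition) once, and uses 12×8 to 2,000-feature
problems for oracle-equivalence and null-calibration checks; these sizes
were chosen so that planted-effect recovery is statistically comfortable
at the default effect sizes. Tolerances: exact rank/arithmetic identities
at 1e-12, bicor/TOM oracle equivalence at 1e-10/1e-12, TAMPOR convergence
at 1e-8. Ties in ranks use average ranks; module numbering ties break by
first appearance; eigenprotein sign ties (exactly zero correlation with
the mean profile) keep the SVD orientation.

## Known limitations

* Module detection is a from-first-principles implementation of the
  dynamic-tree-cut idea (adaptive static cut + gap splitting + PAM-style
  refinement); on borderline data its module boundaries will not exactly
  match other implementations of the same idea.
* The bootstrap-median regression coefficients converge to, but are not
  identical to, single-fit OLS coefficients; for skewed resampling
  distributions the median can differ by a few percent.
* With only one reference channel per batch the TAMPOR ratio denominator
  is a single observation; two or more GIS channels per batch (the
  simulated default) stabilize it.
* Concordance classification inherits both arms' multiplicity choices; at
  n = 4 per group the knockdown arm has limited power for effects below
  about 1.5 log2 units regardless of FDR threshold.
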
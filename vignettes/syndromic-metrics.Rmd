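---
title: "Deriving and validating syndromic outcome metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating syndromic outcome metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`syndromix` builds composite outcome metrics from a multivariate preclinical
battery and — the part that carries the scientific weight — tests whether
those metrics are reliable and valid. This vignette explains the model, the
choices behind every tunable parameter, the synthetic generator that
provides ground truth, and the numerical conventions, so that a user can
judge what a passing validation does and does not establish.

## The measurement model

Each subject contributes a row to an $n \times p$ analysis matrix: one
time-collapsed value per outcome. Behavioural scales are averaged over their
assessment days (a single value capturing the temporal course), histological
areas and counts are expressed as percentages of the contralateral,
uninjured side, device-native impact displacements are converted to a common
micron unit, and body weight enters as terminal change. Missingness is kept
explicit; it is never coded as zero.

The syndromic metrics are principal components of the Pearson
cross-correlation matrix $R$: with eigenpairs $(\lambda_k, e_k)$, the
loading of variable $j$ on component $k$ is
$\ell_{jk} = e_{jk}\sqrt{\lambda_k}$, which equals the correlation between
variable $j$ and the standardized component score. Working on the
correlation (not covariance) matrix is forced by the battery's mixed scales
— ordinal behavioural scores, percentages, grams. Component scores are
standardized to mean 0, SD 1 within the dataset they were extracted from,
so scores are comparable *within* an extraction but their units are
internal to it.

PCA assumes linear associations and treats ordinal scales numerically; both
are conventional for these batteries but are assumptions, not facts. The
default extraction is unrotated. Varimax (`rotate_varimax()`) and promax
(`rotate_promax()`, power `kappa = 4`) are available; promax also reports
factor intercorrelations, which is the natural check on whether orthogonal
components are an artefact — correlations near zero say the unrotated
solution was already simple.

### Missing data

Sparse missingness is handled by multiple imputation: `m = 5` chains of
iterative conditional regression (each missing column regressed on all
others, missing entries replaced by prediction plus a stochastic normal
residual draw, up to 10 sweeps with early stop when column means move less
than `1e-4`), and the correlation matrix pooled as the mean over the $m$
completed datasets. Five imputations and ten sweeps are the standard
small-$m$ MI regime; the pooled matrix is symmetrized and its diagonal
restored exactly. A column with $\ge 50\%$ missing cells is refused — no
regression on the observed half of a column that sparse deserves trust.
Imputation is deterministic given its seed, and with no missing cells the
"imputation" is exact (completions identical to the input).

One honest caveat measured during development: with 10% cells missing at
random in a 159 × 24 battery, the *mean* absolute deviation of pooled
correlations from the complete-data values is ~0.02, but the *maximum* over
the 276 entries — an extreme order statistic — is typically 0.07–0.11. Tests
assert those oracle-computed bounds.

## Component retention

Three rules are computed and combined by consensus (the largest $k$ such
that components $1..k$ satisfy all three):

- **Kaiser**: eigenvalues strictly greater than 1 — a retained component
  must explain more than one variable's worth of variance. Liberal on
  batteries this size.
- **Scree**: the visual elbow formalized as maximum acceleration — the
  interior index maximizing the second difference
  $\lambda_{i-1} - 2\lambda_i + \lambda_{i+1}$ is the elbow; everything
  before it is retained. Ties break to the smallest index (fewest
  components), and the rule needs $p \ge 4$. Automating the elbow trades
  the judgment of a visual scree for reproducibility; at small $n$ the
  automated rule is noticeably stricter than a human reader, which is why
  case-split extractions default to the pooled run's consensus count (see
  below).
- **Over-determination**: a component is interpretable only if at least 3
  variables load saliently on it (strictly $|\ell| > 0.4$).

Interpretability of the resulting names is reported (via
`name_component()`) but never enforced — it is a judgment, not a rule.
The salience cutoff 0.4 is the field's conservative convention; note that
$0.4^2 = 16\%$ shared variance, so "salient" is a pattern claim, not a
large-effect claim.

## Pattern matching: does a component replicate?

Two extractions never agree in component order or sign, so matching begins
with alignment: exact one-to-one assignment maximizing total $|CC|$
(exhaustive search over permutations — batteries retain few components, so
exactness is cheap; ties break to the smaller index), then sign flips where
congruence is negative. Surplus components on either side are reported as
unmatched rather than forced into pairs.

Per matched pair, four statistics with different sensitivities:

- **RMS** difference: magnitude-sensitive; 0 means identical loadings.
- **CC** (congruence, cosine): scale-invariant shape-and-sign agreement.
- **Pearson $r$** over the $p$ loading entries, with the usual $t$-based
  two-sided p-value on $p-2$ df.
- **$s$**, the salient variable similarity index: classify each variable as
  salient-positive, hyperplane, or salient-negative; cross-tabulate; then
  $s = (f_{++} + f_{--} - f_{+-} - f_{-+}) / (f_{++} + f_{--} + f_{+-} +
  f_{-+} + \tfrac12 f_{\text{salient,hyperplane}})$, the
  hyperplane–hyperplane cell ignored. $s$ asks only *which* variables carry
  the pattern and with what sign.

Consensus replication requires all four: $RMS \le 0.20$ and $CC \ge 0.90$
(descriptive thresholds — the literature offers no significance cutoffs for
either; both configurable), and $p < .05$ for $r$ and $s$.

### The permutation null for $s$

Classical tables for $s$ are replaced by a Monte-Carlo null: one pattern's
variable labels are permuted, preserving each pattern's marginal salience
counts — under the null, *how many* variables are salient (and their signs)
is a property of the extraction, *which* ones is chance. The p-value uses
the add-one estimator $(1 + \#\{s_{null} \ge s_{obs}\})/(1 + N)$.

The null is discrete, which has two consequences worth internalizing:

- The reported critical value is the smallest *attainable* $s$ whose
  permutation p-value is $\le .05$, not an interpolated 95th percentile
  (which falls between support points and understates the usable
  threshold). For the classical calibration regime of two 24-variable
  patterns with 8 salient variables each (predominantly positive — roughly
  one-third salient over a two-thirds hyperplane, typical of consensus
  syndromic patterns), this threshold is 0.625, in line with the published
  $s > 0.63$ benchmark for 24-variable batteries. `scripts/acceptance.R`
  recomputes it from scratch.
- For small batteries the test loses meaning: comparing 6-variable
  histology patterns in which *every* variable is salient leaves the null
  only $\binom{6}{1}$-coarse — the attainable p-value floor is $1/6$, and no
  match, however perfect, reaches $p < .05$. The report then shows $s = 1$
  with its floor p-value; judge such comparisons on RMS/CC/$r$.

## Cross-validation machinery

- **Variable subsets** (`subset_variable_pca()`): re-extract from one class
  of variables and match against the full extraction restricted to the
  shared variables. Each subset applies the retention rules to itself — a
  pure-histology battery may legitimately support a single component. Order
  swaps (the subset's PC1 matching the full PC2) are part of the expected
  physics: removing a dominant block reorders explained variance, and the
  alignment reports it explicitly.
- **Case splits** (`split_case_pca()`): independent extractions per subject
  subset (by device, by default), matched pairwise, plus a consensus matrix
  keeping only loadings salient in *both* halves with agreeing sign,
  averaged. Sign-discordant salient pairs are flagged, never averaged —
  averaging opposite signs would fabricate a pattern. Halves default to the
  pooled run's consensus component count (`k = "parent"`): the question a
  split answers is "do the pooled components replicate?", and the automated
  elbow at half-sample sizes is too conservative to decide $k$ per half
  (per-half consensus remains available).
- **Equalized-n subsampling** (`subsample_equalized()`): pooled designs are
  unbalanced; drawing the same number per group (default 9, 10 iterations)
  checks that patterns do not hinge on the large groups. Alignment is
  performed per iteration, then statistics are averaged. A group smaller
  than the quota is an error by default; `undersized = "drop"` excludes it,
  which the default population needs (its smallest sham group has 6).

## Sparse PCA

`pmd_rank1()` solves the rank-1 penalized matrix decomposition: maximize
$u^\top X v$ subject to $\|u\|_2 = \|v\|_2 = 1$ and $\|v\|_1 \le c$, by
alternating updates ($u \propto Xv$; $v$ = soft-thresholded $X^\top u$,
the threshold found by bisection to tolerance 1e-8 as the smallest value
enforcing the L1 bound), warm-started from the unpenalized leading singular
vector. $c = \sqrt p$ recovers ordinary PCA's leading component; $c = 1$
forces a single nonzero weight. $K$ components come from deflation, ordered
by explained $d^2$ — penalization can *reorder* components relative to the
unpenalized extraction, so comparisons go through the alignment machinery.
The penalty is selected by entry-wise holdout cross-validation (5 folds ×
10% of cells, held-out cells mean-filled during the fit, squared
reconstruction error accumulated on them; defaults: 8 candidate penalties
linearly spaced in $[1, \sqrt p]$). Exact zeros in the loadings are the
point: they are variable subselection, and the profile of held-out error
against $c$ shows how much structure survives shrinkage.

## Group-effect validity

`anova_scores()` is a fixed-effects one-way ANOVA of a component score on
injury group with Tukey HSD posthocs (all pairs, $\alpha = .05$).
`ancova_scores()` fits `score ~ covariate + group` with sequential sums of
squares — covariate first, so the group test is displacement-adjusted.
Subjects without a defined displacement (shams, hemisections) are dropped by
default, and the function warns when group covariate ranges do not overlap,
since an adjusted comparison then rests on extrapolation.

## The synthetic generator

`syn_generate()` emulates the kind of pooled two-site cervical SCI battery
the pipeline targets: 159 subjects in 7 groups (NYU/MASCIS weight-drop sham
/ 6.25 mm / 12.5 mm: 10/10/32; Infinite Horizons sham / 75 kdyn / 100 kdyn:
6/58/34; hemisection: 9), 24 outcomes (17 behavioural, 6 histological,
weight change), and a 3-factor latent structure:
$X = F\Lambda^\top + E$, with factor scores = group shift + standard
normal, residuals independent normal with per-variable SD
$\sqrt{1 - \sum_k \Lambda_{jk}^2}$, an affine map to native scales, and
MCAR masking (default 10%).

Design choices that matter, all fixed at design time by simulation against
the structure the pipeline must detect:

- **Template** (`syn_loading_template()`): factor 1 ties the histology
  block (|0.82|, lesion size negative — these near-redundant epicenter
  measures are highly intercorrelated in real data) to gross behavioural
  recovery and weight; factor 2 is fine motor control (print areas 0.88,
  forelimb strides, BBB subscore); factor 3 links weight gain to hindlimb
  stride (with hindlimb step-deviation negative). Stride measures are split
  between factors 2 and 3 by limb pair rather than cross-loading every
  stride on both: population principal components only coincide with the
  generating factors when cross-loadings are modest, and a generator whose
  truth is unrecoverable *in principle* cannot validate anything. Weight is
  the one deliberate cross-salient variable (factors 1 and 3).
- **Group shifts**: a severity gradient on factor 1, a hemisection-specific
  displacement on factor 2, a device contrast on factor 3. The shift matrix
  is weighted-orthogonalized across factors (group sizes as weights) so the
  unbalanced design does not induce correlation between latent factors, then
  scaled to between-group SDs 0.35/0.40/0.45. When a subpopulation has
  fewer groups than factors, the contrast space runs out of dimensions; the
  residual-zero shift column is dropped rather than renormalized into
  numerical noise.
- **Device-split scenario** (`syn_device_split()`): both halves share the
  template; each half's severity separation on factor 1 uses a larger
  between-group SD (2.0 — sham versus severe spans roughly four
  within-group SDs, which is what single-device datasets actually show on
  primary recovery measures). That separation anchors the leading component
  in each half; with the pooled default shifts, half-sample extractions are
  dominated by eigenvector sampling noise and cross-device RMS sits near
  its sampling floor $\sqrt{2\lambda_1(1-CC)/p} \approx 0.2$.
- **Displacement**: device-native units (mm for NYU, micron for IH),
  group-specific means, and a within-group correlation of $-0.6$ with the
  subject's factor-1 deviation — deeper displacement, worse outcome — so
  the ANCOVA has a real covariate to find.
- **Scales**: ordinal behavioural scales are emulated as affine-transformed
  continuous values (no discretization), matching how the pipeline treats
  them numerically; the long-format output repeats each behavioural value
  over its assessment days, so time-averaging recovers it exactly.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: longitudinal trajectory shapes (values
are time-constant), discreteness and floor/ceiling effects of ordinal
scales, non-MCAR missingness (real dropout is anything but random),
inter-site batch structure, and non-linear dose-response. Parameter
recovery here shows the machinery is correct, not that three factors
underlie any particular rat.

## Numerical conventions

- $R$ is symmetrized as $(R + R^\top)/2$ before decomposition; eigenvalues
  below 1e-10 are clamped to zero; non-symmetric input beyond 1e-8 is an
  error, as are constant columns (no correlation information).
- Component signs are arbitrary; every extraction orients each component so
  its largest-|loading| entry is positive, making repeated runs bitwise
  identical. The matching machinery handles flips regardless.
- All randomness (imputation, permutation nulls, subsampling, holdout
  masks, generation) funnels through explicit seeds; pipeline stages derive
  per-stage seeds from one master seed and record them in every artifact.
- Degenerate inputs fail loudly with classed conditions: duplicate
  measurement keys, non-positive contralateral references, unknown devices,
  all-hyperplane salience patterns, constant covariates.

## Problem sizes in the tests

The test suite validates statistical behaviour at deliberately moderate
sizes: parameter recovery over 10 generator seeds at $n = 159$; permutation
p-value calibration over 1000 replicates of a 1000-permutation test; ANOVA
type-I calibration over 1000 simulated null batteries; the $s$ critical
value from 10,000–20,000 Monte-Carlo draws. These sizes put Monte-Carlo
error well below the tolerances asserted while keeping the full suite fast.

## Known limitations

- The automated scree elbow is a single global criterion; spectra with two
  comparable bends can flip it at small $n$. The consensus rule inherits
  that sensitivity, which is precisely why the retention decision reports
  all three counts rather than just their minimum.
- RMS between independently extracted loading patterns has a sampling floor
  driven by $\lambda_1$ and the sample sizes; at a few dozen subjects per
  split, an RMS threshold of 0.2 is close to that floor, and CC/$r$/$s$
  are the more discriminating statistics.
- The $s$ permutation test is uninformative for small, mostly salient
  batteries (p-value floor; see above).
- Imputation assumes linear conditional means and MCAR/MAR-style
  missingness; with $\ge 50\%$ missing in a column it refuses rather than
  extrapolates.
- Sparse PCA is pure L1 on the variable side (no elastic-net mixing, no
  two-sided sparsity); component order under penalization is not comparable
  to the unpenalized order except through alignment.
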
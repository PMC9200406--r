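---
title: "Methods: differential metabolite abundance in cave and surface fish"
author: "cavemet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential metabolite abundance in cave and surface fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavemet)
```

# The analysis problem

*Astyanax mexicanus* exists as river-dwelling surface populations and as
independently derived, cave-adapted populations (Pachón, Tinaja) that
survive months of food scarcity. Untargeted metabolomics of liver, muscle
and brain across three feeding states (refed, 4-day fasted, 30-day
fasted) asks, per metabolite or lipid: which features differ between
populations within a feeding state, which respond to feeding state within
a population, and which show the *same* fasting response in both cave
populations relative to surface — the signature of parallel adaptation.

`cavemet` implements that statistical pipeline on processed peak-height
tables (features x samples), with a synthetic metabolome generator so
every stage can be exercised and scored against planted ground truth.

# Pipeline stages

## mTIC normalization

Instrument peak heights are only comparable within a sample after
correcting for total signal load. The mTIC of sample $j$ is the sum of
its *identified* peak heights — unidentified peaks (possible column
bleed, contaminants) are excluded from the denominator but still scaled.
Each sample is rescaled to its group's average mTIC:

$$y_{ij} = \frac{x_{ij}}{\mathrm{mTIC}_j} \cdot \overline{\mathrm{mTIC}}.$$

The reference $\overline{\mathrm{mTIC}}$ is computed per
population-by-tissue group by default (each Tinaja brain replicate is
scaled to the mean mTIC of all Tinaja brain replicates, regardless of
feeding state); `grouping = "global"` uses a single reference. The
population-by-tissue default follows the described laboratory procedure;
the global option exists because the normalization formula is sometimes
glossed with a global average. After normalization the identified-peak
sum of every sample equals its group reference exactly (enforced to
1e-9 relative tolerance in the validity checks and test suite). Note
that rescaling a whole sample column by $c > 0$ leaves the normalized
data unchanged only up to the group reference, which itself absorbs the
factor — the per-sample *profile* is invariant, the group scale is not.

## Log z-scoring within comparisons

All modeling operates on $\log_{10}$ intensities z-scored per feature
*within* the samples of one binary comparison (or within one population
for the parallel contrast). Zeros — the encoding for absent
metabolites — are replaced by half the smallest positive intensity of
that feature within the scoring group (deterministic half-minimum
imputation, standard in metabolomics); features with no positive value
in the group are dropped with a warning, and features constant within
the group are set to all-zero and flagged rather than producing 0/0.
z-scores use the sample standard deviation ($n-1$), so oracle
implementations agree to machine precision.

Features are grouped into five broad categories for category-wise
modeling (carbohydrates and central carbon metabolism, amino acids,
fatty acids, nucleotides, miscellaneous/secondary), mapped from
HMDB-style subclass terms with superclass fallback; unmapped terms fall
into miscellaneous with a warning. The shipped default mapping is a
plain YAML file that can be replaced wholesale.

## O-PLS orthogonal signal correction

Before classification, structured variation orthogonal to the class
labels (population baselines, latent batch-like factors) is removed by
single-response O-PLS (NIPALS form). Per component: predictive weight
$w \propto X^\top y$ (unit norm), scores $t = Xw$, loadings
$p = X^\top t / t^\top t$, orthogonal weight $w_o = p - (w^\top p)w$
normalized, orthogonal scores $t_o = X w_o$, loadings
$p_o = X^\top t_o / t_o^\top t_o$, then $X \leftarrow X - t_o p_o^\top$.

Two exact identities follow from the algebra and are asserted in tests:
the removed components reconstruct the input
($X' + \sum t_o p_o^\top = X$), and every $t_o$ is exactly orthogonal to
$y$ (because $w^\top w_o = 0$). The orthogonal *weight* $w_o$ is
orthogonal to $w$ by construction; the orthogonal *loading* $p_o$ is
generally not, and that overlap is precisely what lets the recursion
detect nuisance structure that contaminates predictive features. A
nuisance component whose loading is exactly orthogonal to the predictive
loading is invisible to the single-$y$ recursion (then $w_o = 0$ and the
input is returned unchanged, with `nOrthEffective = 0`).

Defaults: one orthogonal component (`nOrth = 1`, matching a single
removed noise component), class coding $\pm 1$, no re-centering between
components (inputs are z-scored upstream), degeneracy threshold
$\|w_o\| < 10^{-12}\,\|p\|$. The filter is fit per comparison, matching
the per-comparison z-scoring.

## PLS classification scored by Q2 and DQ2

A one-component PLS1 classifier is trained on the filtered matrix:
$w \propto X^\top y$, $t = Xw$, then least-squares regression of $y$ on
$t$. Predictive ability is scored by cross-validated

$$Q^2 = 1 - \frac{\sum_k (y_k - \hat y_k)^2}{\sum_k (y_k - \bar y)^2},$$

and by the discriminant variant DQ2, which clamps each prediction to
$[-1, 1]$ before computing residuals so that a correct prediction
overshooting its class label is not penalized. Hence
$DQ2 \ge Q2$ always and both are at most 1; $Q2 = 0$ is the
mean-predictor baseline. (The truncation is applied to the *prediction*:
applied to the $\pm1$ labels it would be a no-op.)

Cross-validation is leave-one-out: with $n = 12$ samples per comparison,
k-fold splits are unstable, and LOO keeps every fold two-class. The
O-PLS filter and the classifier are *refit inside every fold*, and the
held-out sample is pushed through the training fold's orthogonal
weights/loadings, so no information from the held-out label leaks into
the filter.

Significance: class labels are shuffled `nPerm` times (default 1000 in
the API, 200 in the orchestrated pipeline; at least 100 enforced), the
full LOO pipeline is recomputed per shuffle, a normal distribution is
fitted to the permuted DQ2 values by sample mean and SD, and
$p = 2\,\Phi(-|z|)$ with $z = (DQ2_{obs} - \mu_{perm})/\sigma_{perm}$,
clamped to $[0, 1]$. A degenerate null (SD = 0) reports $p = 1$ with a
warning. Results are bit-reproducible given `(seed, nPerm)`, and
negating the labels changes nothing.

## Per-feature Bayesian logistic regression

Marginal evidence per feature comes from single-covariate logistic
regressions of group membership on the feature's filtered z-scores. With
6 vs 6 samples, complete separation is common and makes maximum
likelihood diverge; the model therefore uses independent Cauchy priors —
scale 2.5 on the slope of the covariate standardized to SD 0.5, scale 10
on the intercept. This is the classical weakly-informative default under
which no typical change in input should move the response probability
from 0.01 to 0.50 or from 0.50 to 0.99.

The posterior mode is found by EM-augmented IRLS: the Cauchy (t with one
degree of freedom) prior is treated as a scale mixture of normals, the
E-step updates the per-coefficient precision $2/(s^2 + \beta^2)$, and
the M-step is one penalized weighted-least-squares solve. The fixed
point satisfies the exact MAP stationarity condition; tests verify the
mode against an iteratively refined two-dimensional grid search of the
exact log-posterior to better than $10^{-3}$, including separated
datasets. Convergence: relative change of the penalized objective
below 1e-8, or 100 iterations. Standard errors come from the curvature
of the penalized objective at the mode using the EM normal approximation
of the prior (which stays positive definite where the exact Cauchy
curvature need not); p-values are two-sided Wald tests, matching the
reporting convention of weakly-informative GLM summaries rather than
posterior tail areas, and are floored at the smallest representable
double. Separation is flagged when an unpenalized IRLS fit diverges past
|slope| 10 on the standardized scale.

No multiple-testing correction is applied by default — the conservative
prior is the design's guard against overclaiming — but
Benjamini-Hochberg is available behind `bhFdr = TRUE`. Class-level tests
aggregate member features by their mean filtered z-score per sample
(sum and first-PC aggregation available as sensitivity options), skip
classes with fewer than two members, and free fatty acid saturation
classes map from double-bond counts (0 = SFA, 1 = MUFA, >=2 = PUFA).

## The parallel-adaptation contrast

For one tissue and one feeding-state pair, each population's samples are
z-scored within that population (across its typically 12 samples), and
per feature the pseudo-samples

$$x_k = \frac{P_k + T_k}{2} - S_k$$

are formed, where replicate $k$ of Pachón is paired with replicate $k$
of Tinaja and Surface by sorted replicate id within each state. Fish are
not biologically paired, so the pairing is an arbitrary but exchangeable
bookkeeping device; `pairing = "permute"` re-draws it as a stability
diagnostic (tests confirm top-ranked features are pairing-stable). The
pseudo-sample matrix is O-PLS filtered against the feeding-state labels
(filter applied *after* forming the combination; the z-scores entering
the combination are the population-wise ones) and each feature's $x$
vector is tested with the same Bayesian logistic machinery.
`direction = "up"` means increased in both cave populations in the
more-fasted state relative to surface. Unequal replicate counts across
populations are an error — no imputation. All three state pairs are
generated, and per tissue the 20 most significant features (ties broken
by |slope| then feature id, deterministically) form the report tables.

The construction is symmetric in Pachón and Tinaja, and paired-seed
simulations in the test suite confirm its design property: an effect
shared by both cave populations is detected more often than an effect of
the same magnitude in one cave population only.

# The synthetic metabolome generator

The generator emulates the study design: 6 replicates per
population x tissue x feeding-state cell (3 x 3 x 3 x 6 = 162 samples),
174 identified primary metabolites, 483 identified lipids and 50
unidentified peaks by default. On the $\log_{10}$ scale a feature's
intensity is

baseline (per feature, N(5, 0.8) — peak heights around $10^5$)
+ tissue offset (per feature x tissue, SD 0.3)
+ planted effects
+ nuisance loading x per-sample nuisance score (SDs 0.3 and 1)
+ measurement noise (SD 0.25),

exponentiated to intensities, with 5% of (feature, population x tissue)
cells zeroed to mimic absent metabolites and a per-sample multiplicative
mTIC jitter (log10 SD 0.1) so normalization is actually exercised.
Planted effects are specified by feature set, scope (shared cave /
single population / surface), axis (feeding-state response or population
baseline) and magnitude in z-units of the measurement noise: a
magnitude-$m$ effect shifts $\log_{10}$ intensity by $m \times$ 0.25.
Because the nuisance factor adds variance on top of the noise, the
realized within-comparison z-shift is somewhat smaller than $m$;
magnitudes around 2 are comfortably detectable at $n = 6$ and 0.5 is
marginal. The nuisance scores are drawn independently of all design
labels, so the factor is orthogonal to class structure in expectation —
the situation O-PLS is designed for — but any finite draw has nonzero
sample correlation with the labels, which matters below.

What the generator does **not** emulate: retention-time drift, batch
boundaries, isotope/adduct redundancy, heteroscedastic noise floors,
missingness that depends on abundance, and biological covariance
structure between related metabolites. Passing tests demonstrate the
statistics behave as designed under the generative model, not that the
pipeline is robust to every artifact of real LC/GC-MS data.

Everything is deterministic given `(config, seed)`; the generator saves
and restores the caller's RNG state.

# Calibration findings and limitations

The test suite checks the pipeline's operating characteristics on
simulated data, and two findings deserve emphasis.

**The DQ2 permutation test is calibrated.** On null comparisons (no
planted effects, nuisance factor present) the permutation p-value
rejects at close to the nominal 5% rate, because each permutation
recomputes the *entire* pipeline — filter, classifier,
cross-validation — under the shuffled labels.

**Per-feature tests after in-sample filtering are not nominally
calibrated.** The O-PLS filter is estimated jointly from all features of
a comparison. When a nuisance factor is present, its in-sample removal
is imperfect (the removed scores must stay exactly orthogonal to the
labels even though the realized factor is not), leaving a shared
residual aligned with the labels. Per-feature false positives are then
correlated across features: on all-null data the flagged fraction at
$\alpha = 0.05$ is inflated on average and strongly overdispersed
across datasets relative to a binomial reference, while without the
filter the Cauchy-prior Wald tests are conservative. This behavior is
inherent to filter-then-test designs, and it is the reason the
uncorrected per-feature p-values should be read as a ranking with an
honest-but-approximate scale — the calibrated significance instrument
for a comparison is the permutation test. The corresponding
null-calibration check in the acceptance suite documents this by
failing against the binomial band, and the same quantity is reported by
the acceptance script.

Other numerical choices worth knowing: condition-factor percent changes
divide by the *final* mass and K values (kept as the source convention,
switchable to the textbook initial-value denominators); the normality
router screens pooled within-group residuals with four tests
(D'Agostino-Pearson, Shapiro-Wilk, Lilliefors/KS, Anderson-Darling) at
$\alpha = 0.05$ and requires at least three passes for the parametric
route; Dunn's post-hoc z-tests use the standard tie correction with
Bonferroni adjustment.

# Problem sizes used by the test and acceptance runs

The suite exercises: 500 random 12 x 50 matrices for the O-PLS
contract; 10,000 random label/prediction pairs for the DQ2 bounds; 200
null replicates at 6 vs 6 with 20 features and 200 permutations for
permutation calibration; 20 fixed toys (5 separated) against the
grid-search posterior oracle; one 500-feature all-null comparison for
the type-I check; 200 paired-seed replicates at magnitude 1.5 for the
contrast power ordering; and a full 3 x 3 x 3 x 6 factorial end-to-end
run with 100 features, 100 permutations per classification and top-20
tables, executed twice to confirm byte-identical outputs. These sizes
give stable statistical checks at desk scale; power estimates at these
sizes are noisier than a production simulation study would use.

```{r example, eval = FALSE}
## a compact end-to-end run
cfg <- list(sim = simConfig(nPrimary = 40, nLipid = 10, nUnknown = 5),
            seed = 1, outDir = "run", nPerm = 200)
run <- runPipeline(cfg)
run$summary$n_comparisons   # 54 on the full factorial design
head(run$topTables[["Refed-Fasted30"]])
```
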
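---
title: "A molecular injury model for kidney transplant biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A molecular injury model for kidney transplant biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Kidney parenchyma responds to injury — ischemia at donation and implantation,
rejection, drug toxicity — with stereotyped transcriptional programs. In
bulk microarray data from indication biopsies these programs do not separate
into discrete disease entities; they form continuous gradients. `txinjury`
implements a model of that injury continuum: per-biopsy gene-set scores
referenced to normal-kidney controls, four cross-validated molecular
classifiers of clinical phenotypes, a correlation PCA of the ten resulting
injury inputs, an archetypal-analysis decomposition of the same inputs into
five interpretable injury states (normal, AKI1, AKI2, mild CKD, CKDAKI), and
survival analyses anchoring death-censored graft outcome at the biopsy.
Failed-repair gene sets derived from single-nucleus studies of native-kidney
AKI — four biological states (oxidative stress, hypoxia, interferon
response, EMT) per nephron segment — are carried as *supplementary*
variables: scored and projected, never allowed to influence the fit.

Because the cohorts such models are built on are not reproducible at desk
scale, the package ships a synthetic cohort generator whose statistical
structure mirrors the assumed data-generating process, with the planted
truth exposed. Every claim the test suite makes about recovery (latent axes,
archetype groups, hazard coefficients) is a claim about that generator.

## Scoring

A transcript-set score is the mean log2 fold-change of the set versus the
control group: for biopsy $s$ and set $G$,
$$\mathrm{score}_s = \frac{1}{|G|}\sum_{g \in G}\left(x_{gs} - \bar
x_{g,\mathrm{ctl}}\right),$$
computed entirely in log2 space, so $2^{\mathrm{score}}$ is a geometric-mean
fold-change. "Mean fold-change" is ambiguous between arithmetic and
geometric; the geometric form is used because the matrix stores log2
intensities and log-space averaging is the robust convention in microarray
pipelines. Set members absent from the matrix are dropped with a count, not
imputed; a set reduced below two members warns (the thin-limb substitution
for the one-probe TAL oxidative-stress set is the motivating example). The
model's six input sets are acute-injury sets (IRRAT30, IRITD3, IRITD5,
DAMP) and chronicity sets (MCAT, IGT).

Scores are standardized (z-scored, sd with the $n-1$ denominator) before
any model fitting, and the training mean/sd are stored so new biopsies are
projected with training parameters rather than re-standardized.

## Classifiers

The four phenotype classifiers (eGFR ≤ 30 mL/min/1.73m², proteinuria
positivity, ci > 1, ct > 1) are trained only on biopsies with the phenotype
recorded; the rest are projected through the final model. The pipeline is
deliberately simple and fully documented: stratified 10-fold CV; inside
each training fold a univariate two-sample $t$ filter keeps the top 30
probe sets; a ridge-penalized logistic model (fixed $\lambda = 0.05$) is
fit on those features; held-out folds give out-of-fold probabilities. The
reported AUC (Mann–Whitney, ties one half) always uses out-of-fold
probabilities — projections of training biopsies correlate with them but
never replace them. Feature selection inside the fold is what the
permuted-label test checks: with 30 of hundreds of features selected, the
null AUC must stay at 0.5. The published classifier ensembles this stands
in for live in prior work; the model family here is pluggable behind
`classifier_spec()` and the probability-score contract is what downstream
code relies on.

## The injury space

**PCA.** The ten standardized inputs (six set scores + four classifier
probabilities) enter a correlation PCA; all components are retained and the
first three are interpreted. Eigenvector signs being arbitrary, components
are oriented deterministically: PC1 so the mean of all ten inputs
correlates positively (global injury); PC2 so the CKD-minus-AKI contrast
(mean of MCAT, IGT, ci>1, ct>1 probabilities minus mean of the four acute
sets) is positive; PC3 so the low-GFR probability loads positively. An
exactly-zero orientation statistic keeps the sign and warns. The rules are
involutive: re-orienting an oriented model is a no-op.

**Archetypal analysis.** Each biopsy is represented as a convex combination
of $k = 5$ archetypes, themselves convex combinations of biopsies
(Cutler–Breiman). The fit alternates two steps:

* *Sample weights.* For each biopsy, the simplex-constrained least-squares
  problem against the fixed archetypes is solved **exactly** by support
  enumeration: for each of the $2^k - 1$ supports the sum-to-one
  equality-constrained solution has a closed form, and the feasible
  solution with minimal RSS is the global optimum by KKT. This is
  vectorized over biopsies and practical for the $k \le 12$ regime the
  model lives in (a penalized NNLS fallback covers larger $k$).
* *Archetypes.* Exact cyclic block-coordinate descent: with weights fixed,
  the unconstrained optimum for archetype $j$ is the weight-weighted
  residual mean excluding $j$; constraining it to the data hull reduces to
  a simplex regression of that target onto the biopsies, solved by
  Lawson–Hanson NNLS with a sum-to-one penalty row and renormalization.
  The NNLS gradient tolerance is *relative* to the initial gradient scale
  (an absolute tolerance under a large penalty row stalls the active-set
  loop). If a full update would increase the RSS, a backtracking line
  search over convex combinations of the old and new composition weights
  is used — convex combinations of row-stochastic matrices are
  row-stochastic, so every damped step is feasible — and if no damped step
  improves, the fit stops. The RSS trace is therefore non-increasing **by
  construction**, and both weight matrices satisfy the simplex constraints
  to 1e-8 after every iteration (tracked and asserted in tests).

Defaults: 10 restarts (the first seeded by a furthest-point traversal,
which starts archetypes at mutually distant extreme biopsies; the rest
random), `max_iter` 500, relative RSS tolerance 1e-6, all seed-controlled.
AA is fitted on the standardized 10-score matrix rather than on PC scores,
so its quality does not depend on how many components are retained;
fitting in PC space is supported by passing PC scores instead.

**Labeling and assignment.** Groups are the argmax of the archetype
weights, ties broken by lowest archetype index (exact ties have measure
zero but the rule must be deterministic). Archetype labels come from
deterministic rules on the centroids: *normal* has the lowest mean input
score; of the rest, the two with the highest acute-minus-chronic contrast
are the AKI pair, *AKI2* being the one with the higher PC1 centroid; of
the remaining two, *CKDAKI* has the higher acute-set mean. These rules
encode the published semantics (AKI1 carries less acute induction but more
remodeling than AKI2; CKDAKI is the chronic state with superimposed acute
injury).

**Supplementary projection.** A variable's factor-map coordinate on PC $j$
is its Pearson correlation with the PC-$j$ scores. For a model input this
equals $\mathrm{loading}_j \sqrt{\lambda_j}$ (the correlation-PCA
identity), which the tests verify to 1e-8; for archetype scores and the
twelve failed-repair set means it is a pure read-out that cannot perturb
the fit.

**Embedding.** `embed_2d()` is a seed-deterministic neighbor-graph layout
(symmetrized kNN graph, Fruchterman–Reingold from a PCA initialization).
It is visualization-only and never feeds inference.

## Outcomes

The survival frame takes one random biopsy per kidney (uniform among
biopsies with follow-up, seed-controlled), anchors time zero at the biopsy,
censors administratively at 3 years, and treats death with a functioning
graft as non-informative censoring. Kidneys with zero follow-up beyond the
biopsy day are excluded with a logged count.

* Kaplan–Meier curves per archetype group use the product-limit estimator.
* The Cox model includes, per injury component, a main effect and an
  interaction with $g(\mathrm{TxBx})$; $g$ is the natural log of days
  centered at one year by default (a linear transform is selectable), so
  the component's log-hazard effect is $\beta(t) = \beta_0 + \beta_1
  \log(t/365)$ with delta-method confidence bands. TxBx enters as a
  baseline covariate — biopsy timing — not as follow-up time.
* Random survival forests use permutation importance and out-of-bag error
  defined as $1 - C$ (Harrell). Splits are random with one candidate per
  variable, mirroring the reference configuration; the default 5000 trees
  is a runtime choice and tests use 500. Predictor columns are sorted
  internally so importance cannot depend on column order; missing
  predictor values are median-imputed.
* Restricted cubic splines use three knots at the 0.10/0.50/0.90 quantiles
  with the standard restricted basis (one nonlinear term, linear tails),
  fit by least squares.

## The synthetic cohort

The generator emulates an indication-biopsy population with three latent
axes: acute injury + inflammation ($z_1$), chronicity coupled to time
posttransplant ($z_2$), and epithelial remodeling ($z_3$). Five states sit
at fixed latent positions (normal at the origin; AKI1 low-acute/high-
remodeling; AKI2 high-acute; mild CKD chronic; CKDAKI chronic + acute +
remodeling), with state mixture probabilities drifting from AKI-dominant
early to CKD-dominant late. Biopsy times are log-uniform over 3 days to 15
years, reproducing a heavy early/late mix. Expression is per-gene baseline
plus loadings times latents plus Gaussian noise (log2 scale): acute sets
load on $z_1$ with a negative $z_2$ component, chronic sets on $z_2$ with
a shared $z_1$ component (so a global injury factor dominates the
correlation structure), EMT-like sets on $z_1$ and $z_3$, oxidative-stress
sets negatively on $z_1$. Donor age couples to standardized $z_3$ at
Pearson 0.2; eGFR decreases in $z_1$ and $z_3$; proteinuria and ci/ct
arise from logistic/ordinal links; the graft-failure hazard is exponential
with an acute-axis coefficient increasing linearly in log TxBx and a
constant remodeling-axis coefficient, death with function being an
independent competing censoring event drawn by inverse transform.

Default sizes are 4,000 biopsies, 4 controls and 2,000 probe sets (30 per
input set, 15 per failed-repair set) — large enough for stable recovery
statistics, small enough that the full pipeline runs in about a minute.
The five states are linearly separable in latent space for within-state
noise below roughly 0.3 (documented threshold; the default within-state sd
of 0.45 trades some separability for realism and still yields archetype
recovery with ARI ≈ 0.8).

What the generator deliberately does **not** emulate: probe-level
microarray artifacts (batch, scanner), realistic probe annotation,
rejection-driven expression, and center-to-center heterogeneity in the
proteinuria definition (a single logistic link stands in for what is, in
real cohorts, several standard-of-care definitions — one reason a real
proteinuria classifier performs worst of the four). The three-axis latent
dimensionality is itself a modeling choice: the real data's interpreted
components stop at three, but nothing rules out further structure. The
five state centers cannot make all three axes exactly independent — a
state that is simultaneously high-acute and high-remodeling induces a mild
positive $z_1$–$z_3$ correlation (about 0.2 under the defaults) — which
slightly rotates PC3 and attenuates the donor-age correlation read off PC3
relative to the planted coupling. Passing tests therefore demonstrate
correct mechanics and faithful recovery under these assumptions, not
performance on real microarray cohorts.

## Numerical choices

* Cortex inclusion is strict `> 10%`.
* Standardization stores mean and sd (n−1); zero-variance columns are an
  error, not a silent constant.
* Simplex feasibility tolerance 1e-8; weights are clipped at zero and
  renormalized after the exact solve, so row sums are exactly one.
* Argmax ties take the lowest archetype index; `which.max` supplies this.
* All stochastic steps (generator, fold assignment, per-kidney biopsy
  draw, AA restarts, forests, embedding) take explicit seeds, and library
  code saves and restores the caller's RNG state.
* Missing metadata are real `NA`s (empty strings on disk); no sentinel
  numerics anywhere.

## Limitations

The archetypal-analysis objective is non-convex; restarts plus the
furthest-point initialization make recovery reliable in the regimes tested
but give no global guarantee. The classifier stage is a single documented
pipeline, not the published ensemble, so its absolute AUCs are not
comparable to published values — only its contracts (out-of-fold
probabilities, no leakage, calibration under the null) are. Survival
analyses assume non-informative censoring, including death with function;
competing-risks modeling is out of scope.
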
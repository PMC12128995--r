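# txinjury

Molecular injury archetypes and outcomes in kidney transplant biopsies.

Kidney transplants experience parenchymal injury from donation,
implantation, rejection and drug toxicity, and indication biopsies with
genome-wide expression data make that injury measurable. `txinjury`
implements a complete molecular injury model for such biopsies and a
synthetic cohort generator that makes every stage testable against planted
truth:

- **Gene-set (PBT) scores** — mean log2 fold-change of a transcript set
  versus nephrectomy controls: `score_s = mean_g (x_gs − mean_ctl x_gc)`,
  with `2^score` the geometric-mean fold-change.
- **Four molecular classifiers** (low eGFR ≤ 30, proteinuria, fibrosis
  ci > 1, atrophy ct > 1) — stratified 10-fold CV, in-fold univariate
  feature selection + ridge logistic regression, out-of-fold probabilities
  and Mann–Whitney AUC.
- **The injury space** — correlation PCA of the 10 standardized inputs
  (6 set scores + 4 classifier probabilities) with deterministic component
  orientation, and archetypal analysis (alternating constrained least
  squares, Cutler–Breiman) with k = 5 archetypes labeled normal, AKI1,
  AKI2, mildCKD, CKDAKI; biopsies are assigned by highest archetype score.
  Twelve failed-repair gene sets (oxidative stress, hypoxia, interferon
  response, EMT per nephron segment) are projected as supplementary
  variables onto the factor map.
- **Outcomes** — biopsy-anchored 3-year death-censored survival with one
  random biopsy per kidney: Kaplan–Meier per archetype group, Cox models
  with time-varying component effects `β(t) = β0 + β1·log(t/365)`, random
  survival forest permutation importance (OOB error = 1 − Harrell's C),
  restricted cubic splines and Spearman associations (donor age, eGFR).

## Worked example

```r
library(txinjury)

cfg <- cohort_config(seed = 1)              # 4,000 biopsies, 4 controls
co  <- generate_cohort(cfg)
fit <- run_injury_pipeline(co$expr, co$meta, co$sets, seed = 1)
fit
#> injury_model
#> injury_pca: 10 inputs, 3880 biopsies; PC1/2/3 variance 69/25.8/3.3%
#> archetype_model: k=5, RSS=1298, 135 iterations (restart 2); labels: CKDAKI, AKI2, AKI1, mildCKD, normal
#> groups:
#>    AKI1    AKI2  CKDAKI mildCKD  normal
#>     538     642     513     912    1275
```

PC1 is the global injury dimension (all ten inputs load positively), PC2
separates chronic from acute scores and tracks time posttransplant, PC3 is
the epithelial-remodeling dimension. Against the generator's planted
latent axes this fit recovers Pearson correlations of 0.985 (PC1 vs acute
axis), 0.922 (PC2 vs chronic axis) and 0.841 (PC3 vs remodeling axis), and
the argmax archetype groups match the five planted states with adjusted
Rand index 0.79. Classifier out-of-fold AUCs: lowGFR 0.910, proteinuria
0.737, ci>1 0.845, ct>1 0.833.

Survival after the biopsy separates the groups sharply:

```r
meta <- fit$meta; rownames(meta) <- meta$sample_id
frame <- build_survival_frame(meta, as.data.frame(fit$pca$scores[, 1:3]), seed = 1)
km <- km_curve(frame, fit$groups[frame$sample_id])
km$survival_at("normal", 1095)   #> 0.831
km$survival_at("CKDAKI", 1095)   #> 0.385

cox <- cox_time_interaction(frame, pcs = c("PC1", "PC3"))
cox$effects$PC1$interaction      #> 0.137  (acute-axis hazard grows with log TxBx)
cox$effects$PC3$main             #> 0.698  (remodeling-axis hazard, time-constant)
```

Three-year death-censored graft survival is 83% after a molecularly normal
biopsy and 39% after a CKDAKI biopsy; the Cox interaction term shows the
acute axis's hazard increasing with time posttransplant while the
remodeling axis acts throughout.

See `vignettes/injury-model.Rmd` for the model's assumptions, the
archetypal-analysis algorithm, the generator's design and its limits.

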
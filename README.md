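# spinr

Sex-specific, pathway-masked neural networks for sexual-dimorphism analysis
of gene expression, in R.

Most expression studies either pool the sexes (gaining samples but
canceling effects whose direction differs between males and females — the
*net canceling* effect) or analyze them separately (halving the sample size
and missing shared signal). `spinr` implements a single joint model for
both: a feed-forward network whose first learned layer is **routed by
sex**, while everything downstream is shared. It is aimed at computational
biologists studying gene-by-sex interaction in transcriptomic cohorts with
survival or case/control outcomes.

## The model

For expression $G \in \mathbb{R}^{n \times q}$, a binary gene–pathway mask
$M_G \in \{0,1\}^{q \times r}$ (from a GMT file) sparsifies the first
layer, and each sample passes through its sex's weights:

$$P = \phi\big(G\,(W_G^{M/F} \odot M_G) + b_G^{M/F}\big), \qquad
  H = \phi\big(P\,(W_P \odot M_P) + b_P\big),$$

with ReLU $\phi$ and a hidden mask $M_P$ learned by validation-selected
magnitude pruning. The head is either a Cox prognostic index $Z = H W_H$
(no bias; trained by the average negative log partial likelihood, Breslow
ties) or a sigmoid risk score $Z = \sigma(H W_H + b_H)$ (binary
cross-entropy). Interpretation is global — per-sex importance scores with
rank tests and Benjamini–Hochberg FDR, classifying each gene/pathway as
shared, male-specific, female-specific or neither — and local — Shapley
attributions of a single prediction over the pathway nodes, including the
cross-sex counterfactual ("what would this sample's mechanism look like
routed through the other sex's pathway layer?").

The methods vignette (`vignettes/spinr-methods.Rmd`) documents the model,
training procedure, interpretation statistics and the synthetic generator
in full.

## Worked example

Simulate a cohort at the package's reference scale (600 samples, 500
standard-normal genes, 30 pathways of 15 genes) with one male-only and one
shared planted pathway effect, run the full pipeline (stratified 80/20/80/20
split, train-statistic normalization, training with restarts and pruning),
and interpret the fit:

```r
library(spinr)

sim <- simulate_spin_data(sim_config(seed = 7, effects = list(
  effect_spec(3, "male_only"), effect_spec(12, "shared"))))
res <- spin_pipeline(sim$dataset, sim$mask, spin_config("risk", seed = 7))
res$report
#> spin_report: 240 epochs, best epoch 120, final val loss 0.6235, sparsity [0.4]
res$metrics$auc
#> [1] 0.7336111
```

The held-out AUC of 0.73 says the model ranks unseen cases above controls
about three times out of four. Global interpretation recovers exactly the
planted structure — the male-only pathway PW03 is significant in males
only, the shared pathway PW12 in both sexes, and the 28 null pathways in
neither:

```r
full <- align_dataset(apply_normalizer(res$normalizer, sim$dataset), res$model$mask)
imp <- global_importance(res$model, full, level = "pathway")
imp[imp$class != "none", c("feature", "q_male", "q_female", "class")]
#>    feature       q_male     q_female         class
#> 3     PW03 5.500000e-09 6.682125e-01 male_specific
#> 12    PW12 5.548018e-13 3.219194e-10        shared
```

A local explanation decomposes one test sample's risk score into additive
pathway contributions (base value + attributions = prediction):

```r
te <- res$splits$test
bg <- shap_background(res$model, res$splits$train, te$sex[1])
shap_explain(res$model, te$expression[1, , drop = FALSE], te$sex[1], bg,
             sample_id = te$sample_ids[1])
#> spin_explanation [sampling]: sample S0002 routed as female; f(x)=0.6054, base=0.4567
#>   PW12                     phi=+0.17818 (up)
#>   PW14                     phi=-0.02441 (up)
#>   PW13                     phi=+0.01828 (up)
#>   PW02                     phi=-0.01198 (up)
#>   PW16                     phi=-0.01088 (up)
```

The shared risk pathway PW12 is enriched in this sample and contributes
+0.18 of the +0.15 gap between the base value and the predicted risk; the
remaining pathways make small corrections. Passing `route_as = "male"`
re-explains the same expression profile under the male mechanism for
counterfactual comparison (`cohort_contrast()` pairs and flags
sign-flipping pathways).

A command-line interface wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "spin.R", package = "spinr"))') \
  train --expression expr.tsv --clinical clin.tsv --gmt sets.gmt \
  --outdir run1 --seed 1
```

Each run writes a `manifest.json` sufficient to reproduce it.

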
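---
title: "Sex-routed pathway-masked networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-routed pathway-masked networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinr)
```

## The problem

Many diseases differ between males and females in prevalence, severity and
genetic architecture. Pooled (sex-combined) analyses gain sample size but
cancel effects whose direction differs between the sexes — the *net
canceling* phenomenon: if a pathway raises risk in males and lowers it in
females, its pooled association with the outcome is near zero. Conversely,
fully separate per-sex analyses halve the sample size and cannot borrow
strength for effects the sexes share. `spinr` implements a single joint
model that keeps both kinds of signal: expression profiles of both sexes are
trained together, but the first learned layer is *routed by sex*.

## Model

The architecture has four stages, for $n$ samples, $q$ genes and $r$
pathways:

1. **Gene layer.** The standardized expression matrix
   $G \in \mathbb{R}^{n \times q}$.
2. **Sex-specific pathway layers.** A binary gene–pathway bi-adjacency mask
   $M_G \in \{0,1\}^{q \times r}$ (built from a GMT file) constrains the
   connections. Each sex has its own weights and biases, sharing the mask:
   $$P_i = \phi\big(G_i\,(W_G^{(s_i)} \odot M_G) + b_G^{(s_i)}\big),
     \qquad s_i \in \{\text{male}, \text{female}\},$$
   with $\phi$ the ReLU. A sample is routed through its sex's branch; the
   `route_as` argument forces the other branch instead, which is the
   cross-sex counterfactual used in local interpretation. The routing never
   modifies stored parameters.
3. **Hidden layers.** Shared across sexes,
   $H = \phi(P\,(W_P \odot M_P) + b_P)$ (and onward for deeper stacks).
   $M_P$ starts dense and is sparsified during training (below). Sharing the
   tail is what lets the model pool both sexes' samples when estimating how
   pathway activations combine into risk.
4. **Output head.** For survival, a linear prognostic index $Z = H W_H$
   *without* a bias, matching the proportional-hazards convention that the
   linear predictor is only identified up to a constant; higher $Z$ means
   higher risk (shorter expected survival) throughout the package. For
   binary risk, $Z = \mathrm{sigmoid}(H W_H + b_H) \in (0,1)$.

Bias vectors have one entry per *target node* ($b_G$ of length $r$, $b_P$
of length $s$), and $M_P$ is $r \times s$ — the only shapes under which the
layer products compose.

## Losses

*Survival* uses the average negative log Cox partial likelihood
$$\mathcal{L} = -\frac{1}{d}\sum_{i:\,\delta_i = 1}
  \Big[z_i - \log\!\!\sum_{j:\,t_j \ge t_i}\!\! e^{z_j}\Big],$$
with $d$ the number of events and Breslow handling of tied event times (all
samples with $t_j \ge t_i$, ties included, form the risk set). The risk-set
sums are computed by a reverse cumulative sum after max-shifting for
numerical stability; the analytic gradient is implemented alongside and
verified against central finite differences. *Risk* uses mean binary
cross-entropy; predictions at exactly 0 or 1 are clamped at $10^{-12}$ with
a warning before logs are taken.

## Experimental protocol

`stratified_split()` assigns 80% of each stratum to development and 20% to
test, then splits development 80/20 into training and validation. Survival
datasets stratify on sex; binary datasets stratify on sex × disease status
jointly. Per-stratum counts are rounded, so realized sizes differ from the
exact fractions by at most one. `fit_normalizer()` estimates per-gene means
and population standard deviations *on training rows only*; validation and
test sets are transformed with those training statistics. Constant genes
are dropped with a warning, and re-standardizing an already standardized
matrix is an error rather than a silent double transform.

## Training

Training is full-batch Adam (default step size 0.003) with an L2 penalty of
0.05 on weight matrices (biases are not penalized), early stopping on
validation loss (patience 60, cap 500 epochs) and the best-validation
parameters retained. Because the loss surface of the masked first layer is
rough, `spin_train()` runs 3 independent restarts by default and keeps the
one with the lowest validation loss. Everything is deterministic given the
configuration seed: restarts derive their seeds from it, and full-batch
training uses no other randomness.

**Initialization.** Each pathway node starts as the *scaled mean of its
member genes*: weight $1/\sqrt{m_j}$ per member (so the node's initial value
has roughly unit variance for standardized inputs), jittered by ±10%, with
a unit bias so the ReLU sits in its linear range at the start. Hidden
layers use uniform initialization scaled by the masked fan-in. This
domain-informed start matters: the nodes are *meant* to represent pathway
enrichment, and starting them there reduces the first layer's search over
its (typically hundreds of) masked weights to fine-tuning. With generic
fan-in initialization the same optimizer frequently collapses into dead-ReLU
constant predictions or overfits before any structure emerges.

**Sparse hidden connectivity.** After convergence the hidden-layer masks
are sparsified by validation-selected magnitude pruning
(`sparse_code_masks()`): for each candidate fraction $\rho$ in the grid
(default $\{0, 0.2, 0.4, 0.6, 0.8\}$), the $\lfloor \rho \cdot \#\text{entries}
\rfloor$ smallest-magnitude effective weights $|W \odot M|$ of the layer are
zeroed, the fraction minimizing validation loss is kept (ties resolve toward
the sparser model), and the model is briefly fine-tuned (60 epochs),
retaining the pruned model only if fine-tuning did not hurt validation loss.
Ties between equal magnitudes break by (row, column) index, so pruning is
reproducible and the zeroed set grows monotonically with $\rho$. The
gene–pathway mask $M_G$ is fixed by annotation and never pruned; hidden
masks remain shared across both sex branches. Layers are pruned one at a
time in order — the interleaved schedule used by some sparse-network
methods is out of scope here.

## Global interpretation

For each feature (gene or pathway) and each sex, the importance score is
the mean over that sex's samples of $|\partial f / \partial v \cdot v|$,
the absolute gradient-times-value contribution of the feature's node under
the sample's own routing. The score ranks features and defines a guard: a
feature whose score is zero in a sex (for example a pathway disconnected by
pruning) cannot contribute to prediction there and is never called
significant in that sex.

Significance within each sex comes from a two-sample Wilcoxon rank-sum test
between outcome groups (binary: cases versus controls; survival: top versus
bottom prognostic-index tertiles), with Benjamini–Hochberg correction
within each (level, sex) family and a default adjusted-p threshold of
$10^{-5}$. The *values* tested are label-independent summaries: expression
itself at gene level, and the annotation-defined enrichment score (the
mask-normalized mean of member genes) at pathway level. An earlier design
tested the trained node values instead, and simulation showed it to be
anti-conservative: trained first-layer weights partially fit label noise in
the development cohort, so null pathways' nodes acquire spurious in-sample
associations that do not replicate on held-out data. The enrichment score
is independent of the outcome under the null, so the rank test's false
discovery rate stays at its nominal level, while power for truly associated
pathways is retained because all samples can be used. Rank tests are used
rather than permutation because thresholds like $10^{-5}$ after FDR cannot
be certified at feasible permutation counts.

A feature significant in both sexes is classified `shared`; in exactly one,
`male_specific` or `female_specific`; otherwise `none`.

Two caveats. For survival outcomes the tertile grouping is derived from the
model's prognostic index, so the survival-task test should be read as
exploratory. And when pathways share genes, a neighbor of a truly
associated pathway carries part of its signal through the shared members; a
significant call on such a neighbor is a property of the overlapping
annotation, not a false positive of the test.

## Local interpretation

`shap_explain()` attributes a single prediction to the $r$ pathway nodes of
the pathway→output sub-network using Shapley values: the coalition value of
a pathway subset $S$ is the mean prediction when pathways in $S$ take the
explained sample's activations and the rest take background activations
(reference samples routed through the same branch, capped at 200 rows by
seeded subsampling). The base value is the mean background prediction, so
$f(x) = E[f] + \sum_i \phi_i$. With $r \le 15$ the $2^r$ coalition values
are enumerated exactly (batched through the sub-network, so additivity and
the null-feature property hold to machine precision). Above that, an
antithetic permutation-sampling estimate is used (default 32 permutations
plus their reversals) and the small residual is redistributed
proportionally to $|\phi_i|$, making additivity exact by construction.

`waterfall_data()` orders pathways by $|\phi|$ and aggregates everything
beyond the top $k$ into one remainder term; each pathway carries an
enrichment direction (node value above or below the background mean).
`summary_data()` lays out per-sample $(\phi, \text{node value})$ pairs by
subgroup for beeswarm-style rendering. `cohort_contrast()` pairs each
sample's attributions under its own sex's routing with the counterfactual
routing and flags sign flips — pathways whose contribution direction
reverses between the male and female mechanisms.

## Evaluation

Harrell's concordance index over admissible pairs ($t_i < t_j$, $\delta_i =
1$; prediction ties count 0.5), the Mann–Whitney AUC with midrank ties, and
five-group risk stratification: samples sorted by predicted risk descending,
$n = 5k + m$ split so the first $m$ groups get $k + 1$ samples, observed
disease ratios compared against the *ideal* ratios obtained by filling the
risk-ordered groups with all cases first. The mean squared prediction error
between observed and ideal ratios summarizes stratification quality, and
`compare_repeats()` applies a two-sided Wilcoxon rank-sum test to
repeat-level metric values of two models.

## Synthetic data

The generator (`simulate_spin_data()`) emulates the statistical structure
the model assumes, not any particular cohort: i.i.d. standard-normal
expression per gene; pathways of 15 genes tiled over the gene list with 10%
overlap between adjacent pathways (so masks are not orthogonal); a pathway
*score* defined as the mean of member genes; and a per-sample linear
predictor summing planted sex-dependent effects $\beta_{\text{sex}} \cdot
\text{score}$. Binary labels are Bernoulli with probability
$\mathrm{sigmoid}(\eta)$; survival times are exponential with rate
proportional to $e^{\eta}$ under independent uniform censoring whose upper
bound is tuned numerically to the target censoring rate (default 30%).
Everything is deterministic given the seed.

Reference scenario sizes are desk-scale by design: $n = 600$, $q = 500$,
$r = 30$. The default planted effect size is $\beta = 4$ on the score
scale. Because a 15-gene score has standard deviation $1/\sqrt{15} \approx
0.26$, this corresponds to an odds ratio of about 2.8 per score standard
deviation — a strongly dysregulated pathway. The value was fixed by a
design-stage power analysis: with 300 samples per sex, a rank-sum test must
clear FDR-corrected thresholds near $10^{-5}$, which needs effects of at
least this size even before ReLU clipping at the node; weaker defaults
would make every downstream recovery experiment a coin flip. The
net-canceling scenario (`opposite_effect_scenario()`) instead plants a
single pathway at $\beta = \pm 1$ (positive in males, negative in females)
next to a matched twin with a shared $+1$ effect, built on common random
numbers so the two datasets differ only in how female outcomes are drawn.
At that effect size the within-sex oracle AUC is about 0.58, so results on
this scenario sit close to the information limit by construction.

What the generator does *not* emulate: count-based expression
distributions, library-size or batch effects, gene–gene correlation beyond
pathway overlap, real annotation topology, and non-proportional hazards.
Passing recovery tests on this generator therefore demonstrates that the
machinery works under its stated assumptions, not that it will perform
identically on cohort data.

## Numerical choices and degenerate inputs

Breslow tie handling in the partial likelihood; max-shifted log-sum-exp for
risk sets; cross-entropy clamped at $10^{-12}$; pruning tie-break by (row,
column); constant genes dropped at fit time with a warning; a stratum too
small to appear in all three partitions is an error; a pathway set that
empties under the size filter ([10, 500] by default) is an error; unknown
sex labels are errors everywhere. Checkpoints are a single JSON archive
with a format version string; pathway-activation exports print 17
significant digits so a round-trip read is bit-identical.

## Problem sizes used by the test suite

Unit tests run on fixtures of 20–240 samples with 2–8 pathways, where
exhaustive oracles (pair enumeration, $2^r$ coalitions, explicit risk
sets) are affordable. The heavier simulation checks use the reference
scenario: the net-canceling comparison trains sex-routed and sex-combined
models on 10 seed pairs at $n = 600$, and interpretation recovery runs 20
seeds with three planted pathways among 27 nulls (overlap set to 0 there so
the nulls are exactly null). `scripts/acceptance.R` reruns the same
computations at 3–5 seeds.

## Known limitations

Training quality is the binding constraint at weak signal: near the
information limit of the net-canceling scenario the advantage of sex
routing over a sex-combined ablation is real but smaller than the
estimation noise of a 450-parameter-per-sex first layer at $n = 600$.
The optimizer is plain full-batch Adam — no minibatching, schedules or
GPU path. Gene identifiers are matched by exact string identity (no alias
resolution), one pathway collection at a time, and the multi-class softmax
head is not implemented.
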
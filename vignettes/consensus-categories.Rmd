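---
title: "Deriving consensus category systems from similarity judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving consensus category systems from similarity judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(circaclust)
```

## The problem

Psychophysical experiments on categorization — free sorting of stimuli into
self-defined groups, or same–different judgements on stimulus pairs — produce
*pairwise* evidence about which stimuli belong together. Different
participants disagree, judgements are noisy, and (for pairwise tasks) most
pairs are never judged at all. circaclust derives a single *hard* consensus
category system from this soft, incomplete evidence, chooses how many
categories the data support, names the categories from participants'
free-text labels, and compares the result against baseline methods.

## The model

Each participant's sort of $n$ items is equivalent to a binary co-membership
matrix (1 if a pair shares a group). Averaging over participants — or
averaging same/different responses per judged pair — gives a soft similarity
matrix $S$ with entries $s_{ij} \in [0,1]$. The agreement between a candidate
hard clustering $c = (c_1,\dots,c_n)$ and $S$ is the **affinity**

$$\alpha(c, S) \;=\; \frac{1}{P}\sum_{j>i}\big[\,[c_i{=}c_j]\,s_{ij} +
[c_i{\neq}c_j]\,(1-s_{ij})\,\big],$$

where the sum runs over observed pairs and $P$ is their number. For a fully
observed binary $S$ the affinity *is* the Rand index; for soft $S$ it is the
mean per-pair agreement, so $\alpha \in [0,1]$ and $\alpha = 1$ means the
clustering reproduces every judgement. Normalizing by the observed-pair
count (rather than $n(n-1)/2$) is our choice for sparse data: it keeps
$\alpha$ a mean agreement per *judged* pair, so dense and sparse datasets
are scored on the same scale.

`circa_fit()` maximizes $\alpha$ by coordinate ascent: starting from a
uniform-random assignment into at most $k$ clusters, it proposes moving a
random item to a random other cluster and accepts proposals that *strictly*
increase $\alpha$ (ties are rejected, so the search cannot cycle). Each
proposal is evaluated incrementally in $O(n)$. With $n$ items and $k$
clusters there are at most $n(k-1)$ distinct single-item moves; after that
many consecutive rejections the random phase has probably stalled, and an
exhaustive sweep over all single-item moves either resumes the ascent or
certifies a local maximum. The sweep is a deliberate strengthening over
stopping heuristically: termination means *no* single-item move improves
$\alpha$, a property the test suite re-verifies by independent enumeration.
Because local maxima exist, the ascent is restarted from many random
initializations (1,000–10,000 in serious use; tests use 20–200) and the
best $\alpha$ wins. A strict-increase tolerance of $10^{-9}$ on the
unnormalized objective guards against floating-point cycling; terminal
$\alpha$ is recomputed from scratch before reporting.

For small instances `brute_force_best()` enumerates all partitions into at
most $k$ blocks (restricted-growth strings, guarded at $k^n \le 10^7$) and
serves as the exact oracle: restarted ascent matches its optimum on every
random instance the suite draws.

## Choosing the number of categories

$\alpha$ always improves with more clusters on training data, so $k$ is
chosen by cross-validation:

* **Leave-one-participant-out** (`select_k_loocv_participants()`): for each
  fold, fit the consensus on the remaining participants' averaged matrix and
  score the hard adjusted Rand index (ARI) against the left-out
  participant's partition. We score the *best-$\alpha$* training clustering
  against the left-out sort; selecting among restarts by validation ARI
  would leak the validation data into the fit.
* **k-fold over trials** (`select_k_kfold_trials()`): judgements are split
  into near-equal folds; the fit on the training folds is scored against the
  left-out fold's sparse matrix with the **soft-clustering ARI**
  $(RI_m - RI_r)/(1 - RI_r)$, where $RI_m$ is the affinity of the fitted
  clustering and $RI_r$ the Monte-Carlo mean affinity of random clusterings
  with the same number of non-empty clusters (uniform independent
  assignment by default; an equal-size null is available — the choice is
  not settled by theory, and uniform is the simpler null). The chance term
  is seeded and its sample size reported.

Ties in the argmax go to the smallest $k$ (parsimony). This matters in a
way worth spelling out: at zero noise the cross-validated curve *plateaus*
at 1 for every $k \ge k_{\text{true}}$, because surplus clusters simply
remain empty; the smallest-$k$ tie-break is what recovers
$k_{\text{true}}$ exactly. For trial-based selection the ARI-vs-$k$ curve
is kernel-smoothed (`smooth_ari_curve()`: Nadaraya–Watson, Gaussian kernel,
bandwidth minimizing leave-one-out squared error on a log-spaced grid from a
quarter of the smallest grid spacing to twice the grid range) before taking
the argmax, mirroring how noisy curves from sparse data are best read;
participant-LOOCV uses raw means. Smoothing is *not* appropriate on
plateaued noiseless curves — it drags the argmax into the plateau's
interior — which is why it is optional and off for the participant route.

## Naming categories

`score_and_assign_labels()` scores every participant category against every
consensus category with a **partial ARI**: both partitions are binarized
(target cluster vs. everything else merged) and compared with the hard ARI.
Each participant category's labels are case-folded, stemmed (a light
built-in suffix-stripper for plurals and -ing/-ed forms; multi-word labels
are stemmed per token), and credited with the partial ARI; credits are
summed across participants and repeated uses, and the top stem names the
category. A secondary label is added when a stem scores at least 0.65 after
min–max normalization within the category *and* has embedding cosine below
0.50 to the primary — i.e., it is both strongly associated and semantically
novel. The normalization is applied to the post-sum scores (the wording
admits either reading; the post-sum reading makes the threshold a statement
about the aggregate evidence). Embeddings enter through a pluggable
provider (`embedding_provider()`); tests use small deterministic fixtures,
and any real word-vector table can be supplied the same way.

One caveat the test fixtures exercise deliberately: with only two
categories, a cluster and its complement binarize to the *same* two-block
partition, so label credit leaks symmetrically. With three or more
categories (the regime the method is designed for, and the sorting bounds
enforce at least three) cross-category partial ARIs of disjoint equal
categories are exactly zero.

For same–different data with free-text names, `centroid_label()` names each
category by the vocabulary word whose unit vector is closest (cosine) to
the mean of the category's label vectors, and `f_ratio()` summarizes how
well a category system separates label meanings:
$F = (D_{between}/(k-1)) / (D_{within}/(N-k))$ over unit word vectors.
$D_{between}$ terms are weighted by category size by default so that the
decomposition matches the one-way ANOVA between-group sum of squares
coordinate-wise (the unweighted variant is a flag); the suite checks the
weighted form against `stats::aov` exactly.

## Association analyses

For designs where every item is classified on several dimensions,
`phi_matrix()` gives the Pearson correlation of binary category
memberships (undefined correlations from constant indicators are reported
as missing, never zero), and `bayes_classify()` predicts one dimension's
modal category from others by MAP under a naive (per-predictor posteriors
multiplied), joint (full predictor combination), or prior-only rule, with
leave-one-out cross-validation over items or participants. All probability
tables use add-one smoothing by default — the handling of unseen cells is
not dictated by the design, and Laplace smoothing is the conventional
choice; the constant is configurable. MAP ties break toward the higher
prior, then lexicographically, so runs are reproducible.
`typicality_subsets()` extracts per-category typical / atypical / random
item sets by interparticipant agreement.

## Baselines and benchmarking

`greene_refine()` implements the remove/merge refinement baseline:
categories with within-category "same" proportion below 0.75 are removed
first, then surviving pairs with between-category proportion above 0.5 are
merged. Removal precedes merging (the rule's natural reading), and merging
is by connected components on the original between-similarities, so chains
merge transitively; an iterative variant re-pools similarities
(trial-count-weighted) after each merge and can keep chain ends apart. Both
are provided because the original description does not say whether
similarities are recomputed during merging.

`run_benchmark()` sweeps response-noise levels, replicates, and clustering
methods (coordinate ascent, k-medoids via `cluster::pam` on $1-s$,
spectral clustering via `kernlab::specc` with $S$ as the kernel; unobserved
pairs imputed at 0.5 for the adapters) and scores each fit's ARI against
the planted truth. Failures are recorded as missing rather than aborting
the sweep, and everything is seeded.

## The synthetic generator

`generator_config()` fixes the study conditions: 80 items, 20 participants,
3–10 categories per sort with at least 2 items each — the free-sorting
design the package targets — with equal-size planted categories by default.
Participant **disagreement** is modelled as item reassignment: each
simulated participant moves a fraction $d$ of items (chosen uniformly) to a
uniformly chosen *different* category. We chose reassignment rather than
pair-flipping because participants produce partitions, and a set of flipped
pairs is not in general realizable as a partition. One consequence: at
$d = 1$ with $k = 2$ every item switches to the only other category,
producing the complement — i.e., the *same* partition up to labels — so
"total disagreement" is only meaningful for $k \ge 3$. Response **noise**
for same–different trials is a per-judgement flip with probability
$p_{flip}$; at $p_{flip} = 0.5$ the judgements carry no signal for any
method by construction, so robustness comparisons are run just below that
ceiling. Pair sampling is uniform at a configurable density, or hub-biased
(weights $\propto i^{-1/2}$) to emulate crowd-sourced sparsity. Label pools
are disjoint word lists per planted category plus optional shared
"confusable" words that exercise the secondary-label rule.

What the generator does *not* emulate: item-specific difficulty,
participant-specific bias or lapse rates, correlated errors within a
participant, and the semantic structure of real labels. Passing tests on
synthetic data therefore demonstrate the estimator's correctness and
robustness under controlled violations, not performance guarantees on any
particular human dataset.

## Problem sizes and numerical choices

The test suite and the reproduction script run at reduced scale chosen to
exercise every code path while keeping simulation studies quick to repeat:
48-item / 5-category robustness sweeps with 10 participants and 50 restarts
per fit, 24–60-item cross-validation problems, brute-force oracles at
$n = 8$, $k = 3$. The robustness sweep in `scripts/acceptance.R` scans
disagreement rates 5%–35% in 5% steps with 5 replicates per rate and
reports the largest rate whose modal selected $k$ equals the planted 5 —
the reduced-scale analogue of the claim that the method tolerates about
25% interparticipant disagreement.

Degenerate inputs are handled explicitly: a similarity matrix with no
observed pairs is an error; $k = 1$ fits return the single clustering and
its affinity; a constant ARI curve returns a flat smooth, an `NA`
bandwidth, and the smallest $k$; a chance term $RI_r = 1$ in the soft ARI
is signalled as degenerate rather than silently dividing by zero; undefined
phi coefficients are missing, not zero.

## A worked example

```{r example}
cfg <- generator_config(n_items = 48, k_true = 4, n_participants = 12,
                        disagreement = 0.10, seed = 101)
truth <- sample_truth(cfg)
sorts <- simulate_sorts(truth, cfg)

S <- average_sorts(sorts$sorts)
ks <- select_k_loocv_participants(sorts$sorts, k_grid = 2:7,
                                  n_restarts = 50, seed = 1)
ks$chosen_k

fit <- circa_fit(S, k = ks$chosen_k, n_restarts = 200, seed = 2)
glance(fit)
adjusted_rand_index(fit$best, truth)
```

```{r plot, fig.width = 5, fig.height = 3}
autoplot(ks)
```

## Interfaces

Everything above is a plain R function taking data frames (or the package's
light S3 containers) and returning tibbles or objects with `tidy()` /
`glance()` / `autoplot()` methods. A thin command-line wrapper
(`inst/cli/circa.R`) exposes the file-based workflow — `simulate`, `fit`,
`select-k`, and the `greene` baseline — writing a JSON run manifest (seeds,
config, input digests) next to each output so runs can be reproduced; the
association and labeling analyses take several tables at once and are meant
to be driven from R directly.

## Known limitations

* Coordinate ascent certifies only *single-move* local optimality; restarts
  make global misses rare (and the oracle tests never observed one at test
  scale) but cannot exclude them.
* The soft-ARI chance term is Monte-Carlo, so soft and hard ARIs on the same
  binary data agree only up to the chance term's sampling error.
* The built-in stemmer handles regular English inflections only.
* The benchmark adapters impute unobserved similarities at 0.5, which is
  neutral for the affinity but not necessarily for k-medoids or spectral
  clustering under extreme sparsity.
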
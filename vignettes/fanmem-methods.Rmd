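---
title: "Fan effects, skip-gram embeddings, and spreading activation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fan effects, skip-gram embeddings, and spreading activation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanmem)
```

## The scientific question

In fan experiments, participants memorize simple facts of the form "The
person is in the location" ("De *persoon* is in de/het *locatie*" in the
Dutch materials this package emulates). The *fan* of a concept is the number
of studied facts it participates in. Recognition of a fact slows down and
becomes less accurate as the fan of its concepts grows — the fan effect —
classically explained by spreading activation: a retrieval cue linked to many
memory traces spreads its activation thinly across them.

The rational analysis of memory makes this quantitative. The spreading
activation a cue $j$ sends to a memory chunk $i$ is

$$S_{ji} = \log \frac{P(i \mid j)}{P(i)},$$

which is exactly the pointwise mutual information (pmi) of $i$ and $j$.
Skip-gram models with negative sampling (SGNS) are trained so that the dot
product of a target and a context vector approximates the same quantity up to
a constant: $t \cdot c \approx \mathrm{pmi}(t, c) - \log k$, with $k$ the
number of negative samples. This formal link means an SGNS model trained on
the study sentences of a fan experiment should *predict* fan effects, and a
model fine-tuned from pretrained lexical embeddings should predict fan
effects driven by semantic similarity alone. `fanmem` implements the full
simulation pipeline behind that argument, together with the synthetic data
generators needed to test every stage without external downloads.

## Stimulus designs

`build_classic_design()` and `build_semantic_design()` encode the standard
24-sentence pattern as a fixed template: the varied category contributes four
fan-2 groups of 2 sentences and four fan-4 groups of 4 sentences (8 + 16 =
24), and the fixed category twelve groups of 2 sentences. In classic mode a
group is a single repeated word; in semantic mode a group is a set of 2-4
semantically similar words and every one of the 48 content words occurs in
exactly one target sentence. Group order and within-group item order are
shuffled under the caller's seed before assignment to the template, which is
how unique per-participant lists arise.

Foils (`make_foils()`) permute the person words across the location slots so
that no foil pair reproduces a target pair and no foil is duplicated; because
the permutation preserves each word's number of occurrences, the foil fan
distribution mirrors the targets'. A seeded rejection sampler (budget 1000)
runs first, then a deterministic backtracking search, and an error is raised
only when no valid re-pairing exists. A foil's condition label is the fan of
its varied-category word's group — the varied category carries the
manipulation, and the analysis codes a fan value for foils too.

Location determiners ("de"/"het") are part of the lexicon; designs are
re-drawn until the counts of the two determiners among target locations
differ by at most 2 (configurable), mirroring the balancing of the original
materials. Person words always take "de".

## Training pairs and the skip-gram model

Only the words that can differ between items enter the model. Each target
sentence contributes one pair: the varied-category word is the *target*
token, and the other-category word plus the article preceding the target are
its two cue (context) tokens — for "De kapitein is in de toren" with the
location fan varied, the target is *toren* and the cues are *kapitein* and
*de*. The 24 pairs expand to 48 (cue, target) edges, the training corpus.

`sgns_train()` optimizes the standard SGNS objective per edge,

$$\ell = -\log \sigma(t \cdot c) - \sum_{n=1}^{k} \log \sigma(-t_n \cdot c),$$

with $k = 5$ negative samples drawn *for the target slot*: the model scores
how well the cue predicts the studied target against noise targets drawn
from the target unigram distribution raised to $3/4$. This direction matters
and was chosen deliberately. At the optimum the shifted dot product
$t \cdot c + \log k$ equals $\log(P(t \mid c) / q(t))$ with $q$ the smoothed
noise distribution; because a fan-4 target occurs twice as often in the
corpus as a fan-2 target, the fan enters through $q$ and the predicted fan
gap is $0.75 \log 2 \approx 0.52$ — the compressed gap actually observed in
the simulation this package reproduces (means near 1.7 and 1.15 nats), which
the alternative direction (noise over cue words, gap $\log 2$, stationary
values near 1.59/0.90) cannot produce. Negative draws are taken with
replacement and may collide with the observed target; excluding collisions
roughly halves the negative pressure in this tiny corpus and shifts both
stationary means up by about 0.5 nats, away from the reproduced values.

Optimization is Adam (lr = 0.003, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) with one step per edge, edges shuffled per epoch, a
single global step counter for bias correction, and updates applied only to
the rows with nonzero gradient. Vectors are initialized uniform$(-1, 1)$,
dimension 100. Classic designs train for 24 epochs and semantic ones for 65
(the epoch counts at which recall of the studied pairs reaches 1% errors or
less under these dynamics — verified by the test suite); criterion-based
stopping is available via `recall_stop_threshold`. With pretrained target
vectors (the semantic experiment), target rows are copied exactly and frozen;
only cue vectors learn.

Three training seeds are fitted by default and *dot products*, not vectors,
are averaged across seeds: vectors from independent runs live in unrelated
coordinate systems, while per-pair dot products are the reported quantity.

`recall_error()` ranks, for each target, all content cue words by dot product
and counts an observed cue outside the target's top-$f$ (its fan) as one
mistake, normalized by the 24 content edges. Articles are excluded from the
ranking because "de" co-occurs with half the targets and would dominate it.

## From activation to behavior

`build_activation_table()` emits one row per target sentence's content-word
pair with the seed-averaged dot and the pmi estimate `dot + log(k)`; article
pairs are excluded because reported pair activations are over person-location
pairs. The ACT-R linking functions map activation $A$ to behavior:
retrieval latency $F e^{-A}$ and retrieval probability
$1 / (1 + e^{-(A - T)/s})$ (`retrieval_time()`, `retrieval_prob()`).

`generate_trials()` is the synthetic behavioral generator. RTs are shifted
log-normal around the latency prediction:
$\mathrm{rt} = \mathrm{shift} + \exp(\log F e^{-A} + u_p + w_i +
\varepsilon)$, with participant effects $u_p$, item effects $w_i$, and
residual $\varepsilon$ on the log scale; correctness is Bernoulli with
probability $\sigma((A - T)/s + u'_p + w'_i)$ on the logit scale, with
independent effect draws. Defaults were fixed once to produce realistic fan
data: $F = 2000$ ms and shift $= 1300$ ms put target means near 1650-1950 ms;
$T = 0.7$ and $s = 0.45$ put accuracies near 0.75-0.9 for activations around
1-2 nats; $\sigma_{\log} = 0.25$, participant sd 0.12, item sd 0.05 give
trial-to-trial and person-to-person spread of the magnitude seen in published
tables; 100 participants and 3 testing rounds over 48 sentences (24 targets,
24 foils) match the experimental session. Foils have no generative account in
the underlying theory; as an artifact convention they receive the mean of
their constituent words' trained pair activations, which reproduces the
directional foil-fan effects seen in data (higher foil fan, slower and less
accurate rejection) without further assumptions.

What the generator deliberately does *not* emulate: response-key effects,
practice/fatigue across rounds, correlations between a participant's speed
and accuracy, and lexical covariates (frequency, length). Passing tests
therefore validate the pipeline's statistical machinery, not those aspects of
real data.

## Cleaning, coding, summaries

`exclude_participants()` drops participants with mean accuracy strictly below
threshold (0.6 classic, 0.65 semantic), before any RT cleaning — the order
used in the original analyses. `clean_rts()` removes RTs outside 200 ms -
90 s, then RTs more than 3 sd from the mean of the survivors; the mean and sd
are computed once, globally, because the source analyses say only "from the
mean" (a per-participant option exists but is off by default). A zero sd
removes nothing. `code_contrasts()` applies the sum coding used in the
original models (`fan_target`, `fan_foil` in $\{-1, 0, +1\}$,
`stimulus_type` in $\{-1, +1\}$). `summarize_conditions()` reproduces the
descriptive-table layout (person / location / combined by fan 2 / fan 4); the
fan-2 row is identical across labels by design, since fan 2 means both
concepts at fan 2. Standard errors are over trials, matching the printed
granularity of such tables; a by-participant aggregation can be obtained by
summarizing participant means instead.

`split_by_dot_product()` implements the median-split check that smaller
item-level dot products align with longer RTs; items exactly at the split
value go to the upper group, and the applied rule is attached to the output.

## Fan-effect recovery and its bootstrap

`recover_fan_effect()` estimates the by-participant mean log-RT difference
(fan 4 minus fan 2, targets only). Items are *crossed* with participants:
every participant sees the same 24 targets, so item effects shift all
participants alike and survive averaging over participants. A bootstrap that
resamples only participants treats that shared item noise as signal and
undercovers badly (in calibration runs, a nominal 95% interval covered a true
zero effect in roughly half the runs). Each replicate therefore resamples
both participants and items within fan condition from the participant-by-item
matrix of mean log RTs. Calibration at the package defaults: with a zero
activation contrast the 95% interval covers zero in well over 90% of seeded
runs, and with a realistic positive contrast at 100 participants it excludes
zero in over 95% — both checked by the test suite.

## Synthetic embedding spaces

`synth_clustered_space()` emulates the pretrained-embedding neighborhoods
used to build semantic materials: group centroids drawn isotropically with
unit expected norm, members centroid-plus-noise with relative spread
`within_spread` (default 0.15, giving in-group cosines near 0.98 against
between-group cosines scattered around 0), regenerated until every group
satisfies the in-group > out-group cosine constraint that the real materials
were screened for. Vectors are not normalized — pretrained word2vec vectors
are not either. Synthetic location tokens carry alternating "de"/"het"
determiners so designs built on them balance. These clusters are tighter than
real fastText/word2vec neighbor sets (cosines 0.5-0.7), so semantic-mode
effects here are upper bounds on separability-driven effects in real
embeddings; all semantic-mode claims in the tests are therefore directional
(fan 2 above fan 4), not numeric.

One structural property matters for the pre-training null check: group
similarity is independent of fan assignment by construction, so before any
training the mean pair dot products of fan-2 and fan-4 items differ only by
sampling noise (the tests bound the difference by three standard errors over
50 seeds).

## The binarized-cue comparison model

`binarize_store()` maps every embedding dimension to a discrete cue via the
sign function (strictly positive becomes $+1$, anything else $-1$ — zeros
take the "otherwise" branch). `actr_fan_activation()` then applies the
classical cue-based formula: for each of the probe's $d$ cues, the cue's fan
is the number of study chunks whose same-category word carries the same sign
in that dimension, and the activation is $\sum_j W_j (S - \log
\mathrm{fan}_j)$ with uniform cue weights $W_j = W/d$. $S$, the log memory
size, is a free parameter in the theory; the default $\log(\text{number of
chunks})$ is the reading under which every chunk is equally likely to be
needed, and `total_weight` defaults to 100 so magnitudes are comparable to
published cue-model activations. Any choice of $S$ and $W$ only shifts and
rescales activations without reordering conditions, which is why the package
asserts only the fan-2 > fan-4 ordering for this model: published absolute
values depend on an unstated $S$ and cue-weighting scheme and are not
reproducible from first principles.

## Numerical and degenerate-input choices

Cosine similarity errors on zero vectors rather than returning NaN; neighbor
ranking breaks ties lexicographically so results are reproducible across
platforms. The word2vec text reader keeps the first of duplicate tokens with
a warning and reports the line number of any malformed row; the writer uses
9 significant digits, preserving cosines to better than $10^{-6}$ on a round
trip. Training aborts with a learning-rate hint if the loss becomes
non-finite. All randomness — design shuffling, initialization, edge order,
negative draws, behavioral noise, bootstrap — flows through explicit integer
seeds, and every seeded function restores the caller's RNG state.

## Problem sizes used in the checks

The test suite trains full-scale models (d = 100, 24-65 epochs) where the
scientific claim requires it: one 3-seed classic fit for the reproduction of
the reported activation means, 20 single-seed classic runs for the fan
ordering, 50 semantic runs for the fine-tuning contrast and its pre-training
null, 20 seeds for the binarized-cue ordering, and 100 seeded
generate-clean-estimate cycles at 100 participants for recovery calibration.
Unit tests use smaller dimensions and epoch counts where convergence is not
the property under test.

## Known limitations

The package reproduces the *simulation* side of the research line it
implements: hierarchical Bayesian fitting of behavioral data (shifted
log-normal brms models, Bayes factors) is intentionally out of scope, as are
experiment delivery, lexicon curation against frequency norms, and training
embeddings on natural corpora. Pretrained vectors are an input — real ones
via `read_word2vec()`, synthetic ones via `synth_clustered_space()`. The
exact optimizer micro-dynamics of the original simulation (batching, update
density) are not published; the implemented dynamics were chosen because
their stationary behavior matches the reported pair-activation means and
recall trajectory, and the methods above document every such choice.
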
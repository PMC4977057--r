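---
title: "Scoring, similarity, and clustering of HTS data for metabolic-disruptor screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, similarity, and clustering of HTS data for metabolic-disruptor screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxpiscreen)
```

## The problem and the data model

High-throughput screening (HTS) programs test large chemical libraries
against hundreds of in vitro assay endpoints. For each chemical-assay pair
the upstream processing yields a hit call, and for active pairs an AC50 (the
concentration of half-maximal activity, in micromolar) and a z-score: the
distance of the hit's potency from that chemical's cytotoxicity
distribution. A large z means the activity occurs well below cytotoxic
concentrations and is therefore likely target-specific; a small z flags the
"cytotoxic signal burst", the nonspecific assay activation that accompanies
cell stress. This package consumes those three quantities as given — curve
fitting and hit calling are upstream and out of scope — in a sparse
long-format table where an absent (chemical, assay) key means the pair was
never tested.

The scientific question is prioritization: which chemicals in the library
deserve targeted follow-up for diabetes- and obesity-related biology? Six
expert-curated "biological process models" map that question onto assay
endpoints: adipocyte differentiation (5 slices), feeding behavior in rodents
(9), feeding behavior in *C. elegans* (12), insulin sensitivity in
peripheral tissue (11), islet cell function (11), and beta cell function
(14) — 62 slices in all, each slice pooling the endpoints for one
gene/receptor family. The bundled definitions use `<GENE>_<k>` placeholder
endpoint ids; an analysis of a real release supplies its own model JSON with
the release's endpoint names.

## The ToxPi score

For each pair the input value is

\[
v = \begin{cases}
\max\{0,\; -\log_{10}(\mathrm{AC50}\cdot 10^{-6}) + z\} & \text{active, } z > 2\\
0 & \text{otherwise,}
\end{cases}
\]

so an active pair at 1 uM with z = 5.4 scores 6 + 5.4 = 11.4, and anything
inactive, untested, or within the burst zone (z <= 2, boundary excluded)
scores 0. Untested pairs scoring 0 is a policy, not a fact: missing data is
treated as no evidence, which means sparsely tested actives can be missed —
the approach finds candidate positives, it does not certify negatives. The
max(0, ...) floor only matters for potencies weaker than 1 M and exists
because input values represent evidence of activity on an implicitly
nonnegative scale.

Per model, input values are summed over each slice's assays, each slice's
sums are range-normalized across chemicals to [0, 1] (subtract the minimum,
divide by the range), multiplied by the slice weight (equal weights,
1/n_slices, by default), and summed to the overall ToxPi score in [0, 1]. A
score of 1 means "most potent chemical in every slice". A degenerate slice,
where every chemical ties, is assigned 0 for everyone: a constant slice
carries no ranking information and its normalization is undefined. Scores
are population-relative — at least two chemicals are required, and a score
only means something relative to the library scored with it.

Ranks are competition ("min") ranks over chemicals with positive scores;
score-0 chemicals are `not_active` and never banded. Percentile bands (top
~5/10/15%) divide rank by a denominator that is configurable: `active_only`
(the default) or `full_library`. The published band tables this scheme
echoes cannot be reconciled with a single denominator (a rank of 23 out of
1,860 marked top ~10% implies an active-only denominator of a few hundred;
other rows suggest otherwise), so both policies are exposed and neither is
asserted as canonical. The prioritization criterion — flag a chemical in the
top ~10% of at least one model — uses whichever banding the caller chose.

The retinoic acid receptor (RAR) companion model is a separate single-slice
model scored with identical machinery and reported next to the adipocyte
differentiation results, because RAR agonism can block adipogenic signaling
downstream and therefore qualifies a high adipocyte score.

## Similarity profiling

Independently of the process models, chemicals are compared across the full
assay panel through binned z-score fingerprints: untested = NA, tested
inactive = 0, then active pairs in four categories of increasing specificity
(z <= 3 -> 1, 3 < z <= 6 -> 2, 6 < z <= 9 -> 3, z > 9 -> 4). Note the
deliberate asymmetry with the ToxPi transform: weakly specific actives that
the burst filter zeroes (2 < z <= 3 and below) still appear as category 1
here — the two stages handle specificity differently by design, and the
package keeps both rules as stated rather than harmonizing them.

Pearson's r is computed on pairwise-complete observations: each pair of
fingerprints is restricted to the assays tested in both. Two choices are
ours, because the procedure this mirrors leaves them unstated: a minimum
overlap (default 10 jointly tested assays, configurable down to 2) below
which r is reported as undefined, since correlations on a handful of points
are noise; and constant-on-overlap vectors also yield undefined rather than
0, since Pearson's r does not exist there. The analysis is restricted to a
densely tested subset first (coverage filter, default 0.8 in the drivers) to
limit the impact of missingness — the analogue of the release's
best-covered-subset restriction. An AC50-based variant
(`pairwise_pearson_ac50`) replaces bins with negative log molar potencies;
it emphasizes potency over specificity and can reorder neighbour lists, so
it is offered as a complement, not a replacement.

## Clustering

One model's component-score matrix (by convention the *C. elegans* feeding
model, the most slice-rich of the behavioral models) is centered per column
— not scaled, since component scores already live on the common [0, weight]
scale — and decomposed by PCA. Components explaining at least 5% of the
variance are retained. k-means then runs on the retained coordinates with
k equal to the dimension of the reduced PC matrix; "10,000 iterations" is
read as the iteration cap of a Lloyd run, and because a single seeded run is
initialization-sensitive, a `restarts` parameter (default 10, best
within-cluster sum of squares kept) is added. Both knobs are exposed. The
implementation is a deterministic seeded Lloyd loop with emptied clusters
re-seeded from the point farthest from its centroid, so identical
(matrix, threshold, k, seed) inputs reproduce identical assignments
bit-for-bit; `stats::kmeans` serves as an independent cross-check in the
test suite rather than as the implementation. Whether the reduced matrix's
"dimension" was meant as its column count, and whether a smaller k was ever
chosen, is not determinable from the source procedure; k = number of
retained PCs is the default and any k can be passed.

Mean ToxPi profiles per cluster, with sizes, are reported in decreasing
mean-overall-score order; in realistic inputs the largest cluster is the
negligible-activity bulk of the library.

## The synthetic data generator

No public release ships with this package; the generator produces screening
matrices with the release's *structure* so every stage is testable offline:

* a panel formed by the union of the six models' endpoints (plus the RAR
  companion) and 40 distractor assays — 121 endpoints by default;
* 480 chemicals by default: 20 each of four planted mechanism archetypes
  plus 400 nulls, echoing a library where true positives are rare;
* two-tier coverage: 57% of chemicals fully tested ("dense", the analogue
  of a release's best-covered phase) and the rest with each pair
  independently masked to untested at 50% — matching the roughly
  1,061-of-1,860-chemicals dense subset of the release this emulates;
* AC50s lognormal: target hits center on 1 uM (log10 mean 0, sd 0.5),
  background hits weaker (~20 uM), echoing the "relatively low
  concentration" (<= 10 uM) framing of interesting hits;
* z-scores: target hits from a normal (mean 4, sd 1.5) truncated below at
  2.5 so planted signal survives the burst filter by construction — tests
  must separate filter behavior from signal planting; background hits
  uniform on [0, 2], i.e. pure burst that the filter should remove.

The archetypes are a PPARgamma/RXR agonist (hits the adipocyte and insulin
sensitivity models), a glucocorticoid receptor agonist (adipocyte model,
dexamethasone-like), a monoamine-receptor binder (serotonin/dopamine
endpoints of the beta cell, islet, and *C. elegans* models,
haloperidol-like), and a broad cytotoxicant whose plentiful activity all
carries z <= 2 and must score exactly 0 after filtering. Null chemicals use
background parameters everywhere.

What the generator does **not** emulate: correlated assay families and
block missingness (masking is pairwise-independent), dose-response shapes,
chemical structure, direction of action (agonist vs antagonist — binding
assays in the real panel cannot distinguish them either), and any specific
real chemical's profile. Passing recovery tests therefore demonstrates that
the pipeline's arithmetic and plumbing recover planted mechanisms under
realistic sparsity and burst contamination — not that the models are
biologically valid on a real release.

## Recovery, as the end-to-end check

The recovery scenario (20 chemicals per archetype, 400 nulls, seeded)
requires each signal archetype's median rank in its matched model to fall
in the top decile of the 480-chemical library, counting unranked (score-0)
archetype chemicals as worst-possible rank. The decile is taken over the
full library rather than over scored chemicals only: synthetic nulls carry
burst-only activity and are silenced by the filter, so an active-only
decile would shrink to a handful of chemicals and two archetypes planted in
the same model would mutually exclude each other from it. For the same
reason the analysis drivers use `full_library` banding for prioritization
on synthetic data. Typical runs place the PPARgamma and monoamine medians
near rank 10 and the GR median near rank 25 — comfortably inside the
48-rank decile — and flag essentially all scored archetype chemicals while
flagging no cytotoxicant.

## Numerical and degenerate-input choices

* Slice weights must sum to 1 within 1e-12; bundled equal weights
  round-trip through JSON within that tolerance.
* z exactly 2 is excluded by the ToxPi filter (the rule is z <= 2); z
  exactly 3/6/9 fall in bins 1/2/3 (upper boundaries inclusive).
* Ties in ranks share the minimum rank, preserving "top N%" semantics; ties
  in neighbour lists break lexicographically by chemical id so output is
  deterministic.
* All randomness (generator, k-means restarts) flows through explicit seed
  arguments; nothing reads the global RNG state implicitly, and the run
  manifest records the seed with an md5 checksum per output file.
* Problem sizes in the drivers and tests (480 chemicals x 121 assays,
  6-8-chemical oracle instances, 120-point blob fixtures) were chosen as
  the smallest sizes at which every behavior of interest — sparsity tiers,
  archetype competition within a model, rank-deficient PCA — is actually
  exercised.

## Known limitations

Scores are relative to the scored library, so they cannot be compared
across libraries or releases. The untested-as-zero policy biases against
sparsely tested chemicals. Banding semantics depend on an unstated
denominator (both options are exposed). Binding-assay activity carries no
directionality, so high scores mix potential disruptors with therapeutics
acting on the same pathways. None of the outputs are risk estimates:
exposure, toxicokinetics, and in vivo compensation are outside the model.
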
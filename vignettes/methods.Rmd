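---
title: "Segmentation and statistical structure in transmission chains: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation and statistical structure in transmission chains: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented by
**partseq**, the conventions adopted where the procedures leave choices
open, and what the synthetic-data module does and does not establish.

## The data model

A *chain dataset* is a tibble with one row per sequence:
`chain`, `generation`, `index`, `target`, `response`. Generation 0 holds
the random initial material (no response); at generation *g* ≥ 1 the
targets are the previous generation's responses, re-ordered between
participants, and `index` tracks the lineage of the original generation-0
sequence. The full design of the experiment this package analyses is 6
chains × (1 initial + 10 produced) sets × 60 sequences = 3960 sequences;
initial sequences are length 12 with each of the four colours appearing
exactly three times, so the starting material has no sequential structure
by construction.

## Transitional probabilities and segmentation

For each chain × generation set we estimate second-order transitional
probabilities by maximum likelihood over the whole set:

$$\hat P(c_3 \mid c_1, c_2) = \frac{n(c_1 c_2 c_3)}{n(c_1 c_2\,\cdot)},$$

where counts are taken over every within-sequence window (overlapping,
never across sequence ends) and the denominator counts bigram occurrences
that have a continuation. Two preceding symbols are a compromise: one
symbol is too coarse with a 4-letter alphabet, while longer contexts are
too sparse for 60-sequence sets.

Scanning a sequence $s$ of length $L$, the TP at position $i$
($3 \le i \le L$, 1-based) is $\hat P(s_i \mid s_{i-2}, s_{i-1})$, and the
segmentation cue at position $i \ge 4$ is the *ratio* of consecutive TPs,
$r_i = \mathrm{TP}_i / \mathrm{TP}_{i-1}$. Using ratios rather than raw TPs
captures relative dips (a fall from 0.99 to 0.4 is informative even though
0.4 is not small in absolute terms). A boundary is placed immediately
before every position whose ratio falls below the cutting threshold θ;
units are the maximal runs between boundaries, so concatenating a
sequence's units always reproduces it exactly.

Conventions fixed here (the procedure itself does not dictate them):

* **Boundary position.** A sub-threshold $r_i$ cuts *before element i*:
  the element whose TP dropped starts the new unit. Consequently the
  earliest possible boundary is before the fourth element (position 3
  carries the first TP, position 4 the first ratio).
* **Strict inequality.** Cuts require $r_i < \theta$, not ≤. Ties at θ
  have measure zero for empirical ratios; the choice is documented and
  fixed.
* **Short sequences.** Responses shorter than 4 symbols carry no ratios
  and are kept as single whole units; shorter than 3, they contribute no
  trigrams and are excluded from model estimation with a warning. (The
  task's re-presentation rule makes such responses rare but not
  impossible.)

## Calibrating the cutting threshold

θ is calibrated on the random initial sets, which are unstructured by
design: any dip observed there arises by chance. Each baseline set gets
its own transition model; all sequences' consecutive-TP ratios are pooled
across the six sets, and θ is the 5% lower-tail empirical quantile of the
pooled distribution (linear interpolation between order statistics, R's
default type-7 rule — the tail probability is the tunable `tail`
parameter, default 0.05). One global θ, calibrated once from all
generation-0 sets, is applied to every chain and generation; this matches
an analysis that aggregates all baseline ratios, and keeps the boundary
criterion constant as structure emerges. For the published design the
threshold is 0.425; regenerating baselines under the same constraints
gives a sampling distribution centred near 0.45 with standard deviation
about 0.015, comfortably containing that value (the acceptance script
recomputes this).

## Emergence diagnostics

Per chain × generation, from the unit inventory produced by segmentation:

* **Mean unit length** — token-weighted (identical units count once per
  occurrence).
* **Within/between TPs** — each of a sequence's $L-2$ TPs is *between*
  if its position is a boundary, else *within*. Between-unit TPs are low
  by construction; the scientifically interesting quantity is the growth
  of the within-unit TPs relative to them.
* **Zipfian fit** — the squared Pearson correlation of log frequency vs
  log rank, base-independent. Ranks sort by descending frequency with
  lexicographic tie-breaks (tied ranks share a frequency by definition, so
  only the rank values, not the fit's inputs, depend on the tie order).
  A completely flat distribution — typical of generation 0, where almost
  every unit occurs once — has no defined correlation and is reported as
  `NA` and excluded from trend fits.
* **Entropy** — Shannon entropy of unit-token relative frequencies, in
  bits (the base is a convention; all trend statistics scale with it).
* **Copying error** — Levenshtein distance with unit costs divided by the
  *longer* of the two lengths. The procedure's anchor points (0 = perfect
  copy, 1 = nothing shared) determine the denominator only up to this
  choice; max-length is used so both anchors hold for unequal lengths.

## Generation-trend models

Each diagnostic is regressed on generation by REML linear mixed models
(lme4, Satterthwaite p-values via lmerTest):

| response | fixed effects | random effects |
|---|---|---|
| per-sequence error | generation | intercept + generation by chain; intercept by lineage |
| mean unit length | generation | intercept + generation by chain |
| TP value | generation × type | intercept + generation by chain |
| Zipf R² (gen ≥ 1) | generation | intercept + generation by chain |
| entropy | generation + n distinct units | intercept by chain |

The entropy model controls for inventory size so a shrinking inventory
alone cannot masquerade as skew, and omits by-chain slopes, which are
prone to singular fits for this response. When a requested structure is
singular or fails to converge, the fitter simplifies stepwise (drop the
by-chain slope, then the lineage intercept, finally an ordinary
least-squares fit) and flags the result (`singular`, `fallback_level`).
The least-squares endpoint also covers degenerate zero-variance inputs,
which is what makes noiseless slope recovery exact to machine precision —
a property the test suite asserts for all five fitters. The learnability
link is the Pearson correlation, across participants, between the entropy
of the set a participant saw and their mean copying error.

## The synthetic-data module

Three generators make the whole pipeline testable without experimental
data.

**Random baselines** (`generate_initial_set()`): independent uniform
permutations of the balanced colour multiset — exactly the construction of
the experiment's initial sets, and the input to threshold calibration.

**Planted lexicons** (`planted_lexicon()`, `generate_planted_set()`):
sequences built by i.i.d. sampling of known units (default Zipfian weights
over ranks) concatenated up to a length cap, with true boundary positions
recorded. These give segmentation a ground truth: recovery is scored by
micro-averaged precision and recall against a permutation baseline that
scatters the same number of boundaries uniformly over admissible
positions. One caveat discovered while testing: a *single*-unit lexicon
produces sets in which every trigram is perfectly predictable, so there
are no ratio dips at all and the sequences correctly stay whole —
boundary detection needs branching after unit ends, hence multi-unit,
skewed lexicons are the informative validation case.

**The agent simulator** (`agent_params()`, `simulate_participant()`,
`run_transmission_chain()`, `simulate_experiment()`): the experiment
specifies no participant model, so the agent is this package's own
construction — the minimal learner with a frequency→fidelity link, in the
spirit of a rich-gets-richer account of emerging structure. Each
participant segments the set it is exposed to with the global θ, stores
the unit inventory, reproduces each target as its segmentation tiling, and
emits it with per-symbol noise; a symbol inside a chunk with inventory
count $c$ has its substitution/deletion/insertion rates divided by
$1 + \beta\,(c - 1)$, where $\beta$ is `frequency_boost`. Responses
shorter than 6 trigger one re-presentation, mirroring the task rule.

Defaults — substitution 0.30, deletion 0.15, insertion 0.05, β = 12 —
were chosen during design exploration as the regime in which a plausibly
human-scale early error rate (≈ 0.37 at generation 1) coexists with
robust emergence, and are fixed. Under them the test suite's sign tests
(12 seeds at the full 6 × 10 × 60 design) find error decreasing, units
shortening, the within/between TP gap widening, entropy decreasing after
its initial rise, and Zipf R² increasing between generations 1 and 10,
plus a positive entropy–error correlation across simulated participants.

The *null control* disables chunk learning and uses length-neutral noise
(balanced indels): with it, no systematic entropy decrease appears. The
length-neutrality matters — the default agent deletes more than it
inserts (participants' responses tend to shorten), and net shrinkage alone
lowers unit entropy mechanically, which is exactly the artifact the null
control must not contain.

What the simulator does *not* establish: the agent is not a cognitive
model; its quantitative trajectories (e.g. the size of the error drop) are
not calibrated to human data, and passing the emergence suite shows that
the *pipeline* detects structure when a frequency–fidelity transmission
mechanism produces it — not that human participants implement that
mechanism.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; `run_pipeline()` expands
one master seed into fixed per-component seeds and records them in its
manifest, so re-runs are byte-identical. The test suite exercises:
exhaustive edit-distance agreement with a dynamic-programming oracle on
all pairs of binary strings up to length 6; exhaustive segmentation
agreement with a from-scratch brute-force implementation on all pairs of
length-4 binary strings plus randomised larger instances; conservation of
unit concatenation over 10⁴ random sequences; 200-replicate recovery and
confidence-interval coverage of a known generation slope at the full
design size; and the 200-replicate sampling distribution of θ. These sizes
were chosen to make Monte-Carlo error small relative to the tested
effects.

## Known limitations

* The ratio cue cannot place a boundary before the fourth element of a
  sequence, and a sequence's first ratio compares positions whose TPs are
  estimated from the same set being segmented; segmentation quality is
  therefore weakest at sequence starts.
* One global θ treats the baseline ratio distribution as exchangeable
  across chains; per-generation recalibration is available
  (`threshold_policy = "per_generation"`) but changes the meaning of
  between-generation comparisons and is off by default.
* With only 6 chains, by-chain random-effect variances are weakly
  identified; singular fits are expected and flagged rather than hidden.
* Levenshtein normalisation by max length is not a metric (the triangle
  inequality can fail after normalisation); only symmetry and the [0, 1]
  bounds are relied on.
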
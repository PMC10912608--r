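# partseq

Analysis of iterated sequence-learning ("transmission chain") experiments,
in which sets of colour sequences are copied from one participant to the
next and — purely through repeated learning — acquire the two statistical
hallmarks of language: recombinable *parts*, and a skewed, near-Zipfian
frequency distribution over those parts.

The package is aimed at researchers in cultural evolution and statistical
learning who have (or want to simulate) chain data of the form
*chain × generation × sequence*, where each sequence is a string over the
four-colour alphabet {R, G, Y, B} of a Simon-game-style copying task.

## What it computes

**Segmentation by transitional-probability dips.** For each 60-sequence set
(one generation in one chain) the trigram transitional probabilities are
estimated by maximum likelihood over the whole set,

> P(c₃ | c₁, c₂) = count(c₁c₂c₃) / count(c₁c₂·),

and scanned along each sequence. The cue for a unit boundary is *relative*:
the ratio TPᵢ / TPᵢ₋₁ of consecutive transitional probabilities. A boundary
is placed wherever this ratio falls below a cutting threshold θ calibrated
on unstructured baselines: θ is the 5% lower-tail quantile of the pooled
ratio distribution of the six random generation-0 sets (θ ≈ 0.425 for the
published design; regenerated baselines land near 0.45 on average). Cutting
every sequence yields a unit inventory — an emergent lexicon — per
generation.

**Emergence diagnostics.** Per chain × generation: token-weighted mean unit
length, mean within- vs between-unit TPs, the R² of log(frequency) against
log(rank) (Zipfian fit), Shannon entropy of the unit distribution (bits),
and copying error (normalised Levenshtein distance between target and
response, 0 = perfect, 1 = nothing shared).

**Generation trends.** Linear mixed-effects models (REML, Satterthwaite
p-values; lme4/lmerTest) with the random-effect structures appropriate to
each response — e.g. error ~ generation with a random intercept and
by-chain slope plus a random intercept for the original-sequence lineage —
with a documented simplification cascade for singular fits, plus the
participant-level Pearson correlation between input-set entropy and
copying error.

**Synthetic data.** Balanced random baseline generators, planted-lexicon
sets with known boundaries (for segmentation validation with
precision/recall against permutation chance), and a chunk-based
noisy-recall agent iterated over transmission chains, which reproduces all
the qualitative emergence signatures without any human data.

## Worked example

```r
library(partseq)

sim <- simulate_experiment(seed = 42)   # 6 chains x 10 generations x 60 sequences
sim$threshold
#> <cut_threshold: theta = 0.4279 (5% lower tail of 3240 baseline ratios)>

mets <- generation_metrics(sim$dataset, sim$threshold)
dplyr::summarise(mets, error = mean(set_error), unit_len = mean(mean_unit_length),
                 entropy = mean(entropy_bits), zipf_r2 = mean(zipf_r2, na.rm = TRUE),
                 .by = generation) |>
  dplyr::filter(generation %in% c(0, 1, 5, 10))
#>   generation  error unit_len entropy zipf_r2
#> 1          0 NA         8.38    6.37   0.341
#> 2          1  0.382     8.97    6.15   0.187
#> 3          5  0.371     5.86    6.10   0.364
#> 4         10  0.336     4.60    5.90   0.471

trends <- fit_all_trends(sim$dataset, sim$threshold, metrics = mets)
glance(trends$unit_length)
#>   response         term        beta     se  p_value singular fallback_level
#> 1 mean_unit_length generation -0.479 0.0264  1.8e-08 TRUE     1
trends$entropy_error
#>       r p_value  n conf_low conf_high
#> 1 0.309  0.0162 60    0.060     0.522
```

Reading the output: over ten simulated generations copying error falls
(0.38 → 0.34), units shorten (9.0 → 4.6 symbols), the unit distribution
skews (entropy 6.15 → 5.90 bits) and becomes more Zipfian (R² 0.19 → 0.47);
the unit-length trend slope is −0.48 symbols per generation, and
participants exposed to lower-entropy sets copy with less error (r = 0.31).
The same functions run unchanged on real chain data supplied as CSV
(`read_chain_data()`, columns `chain,generation,index,target,response`),
or end-to-end via `run_pipeline()`, which writes `units.csv`,
`metrics.csv`, `trends.json`, `threshold.json` and a run manifest.

Plots: `autoplot()` on the metrics table or any trend fit,
`plot_tp_types()`, `plot_rank_frequency()`, `plot_entropy_error()`.

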
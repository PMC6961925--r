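# elevrich

Geometric-constraints null models and richness statistics for banded
elevational gradients.

## What problem this solves

Observed species richness along a mountainside confounds three things:
the geometry of a bounded domain (randomly placed *cohesive* ranges pile
up mid-domain — the mid-domain effect), environmental gradients such as
temperature, and the behaviour of ranges at the domain edges. A survey
window is usually a truncated subset of the real gradient, so an edge may
be *soft*: species ranges continue beyond it, and randomized placements
that overhang it should be shifted back ("niche truncation") rather than
forbidden. `elevrich` is for ecologists who want to disentangle these
effects with explicit, testable null models, and for anyone who needs the
surrounding toolkit — sample-based incidence rarefaction, Chao2, Moran's I
with permutation inference, Poisson GLMM selection by AICc — in one
reproducible pipeline.

## The core model

Each species keeps its observed range size *s* (in bands); its location is
randomized on a domain of *n* bands. For cohesive models a midpoint band
*m* is drawn with probability proportional to the environmental weight
*w(m)* (or uniformly), implying the block of bands
`[m − ⌊(s−1)/2⌋, …]`. Blocks that overhang a **hard** edge are excluded
(and the distribution renormalized); blocks that overhang a **soft** edge
are clamped to the nearest feasible position, piling probability onto the
edge placement. Expected richness at band *b* is the sum over species of
the probability that its randomized block covers *b* — computed exactly by
enumeration, or by Monte Carlo with empirical 95% envelopes. Five standard
configurations (`model1` scatter+weighted … `model5` soft-low/hard-high on
a truncated domain) are compared by deviance-ratio
`R² = 1 − dev(candidate)/dev(model1)`, with
`dev = Σ_bands (observed − predicted richness)²` over the surveyed window.
Range contiguity itself is tested by the relative increment in matrix
fill, `(fill(interpolated) − fill(raw))/fill(raw)`, against a scatter null
(SES = (obs − null mean)/null sd).

## Worked example

Generate a synthetic survey at the default study conditions (nine 200 m
bands, 600–2400 m, temperature-weighted cohesive placement with a soft
low edge, ~157 detected species), then run the contiguity test, the model
suite and the regression:

```r
library(elevrich)

ds     <- synth_dataset(synth_config(seed = 42))
raw    <- ds$survey$observed_incidence          # detected band occupancy
ranges <- incidence_to_ranges(raw)              # interpolated extents

ses_fill(raw, n_reps = 999, seed = 42)
#> Matrix-fill range-contiguity test
#>   observed relative fill increment: 0.114
#>   null mean 0.656, sd 0.039 (999 replicates)
#>   SES -13.84, null 0.025 quantile 0.584

summary(run_model_suite(ranges, ds$grid, n_reps = 5000, seed = 42))
#> Geometric-constraints model suite (null = model1)
#>   model deviance r2_vs_null r2_vs_mean
#>  model1  5130.29       0.00       0.01
#>  model2  3359.47       0.35       0.35
#>  model3  3669.83       0.28       0.29
#>  model4  2555.15       0.50       0.51
#>  model5  1397.73       0.73       0.73
#> Best candidate by R2 vs model1: model5
#> Variance explained by the null model itself (vs mean): 1%

fit_count_model(ds$survey$transects, "rarefied_richness", "mat_c",
                random_intercept = "band_elevation_m")
#> Poisson GLMM (random intercept: band_elevation_m): rarefied_richness ~ mat_c
#>             estimate std_error
#> (Intercept)    2.509     0.337
#> mat_c          0.506     0.343
#> ...
```

Reading the output: the observed fill increment (0.114) sits far below
the scatter null (0.656 ± 0.039), SES −13.8 — species occupy adjacent
bands far more than chance, justifying interpolation. Among the
geometric-constraints models, the generating configuration (`model5`:
temperature-weighted cohesion, soft low boundary, hard top) wins with
R² = 0.73 against the scatter null, which on its own explains almost none
of the band-to-band variance. The GLMM recovers a positive effect of
mean annual temperature on rarefied transect richness (0.51 ± 0.34 per
SD of MAT).

`run_pipeline(pipeline_config(...))` chains all stages (plus Moran's I
and the AICc regression comparison) and writes CSV outputs and a summary;
`inst/cli/elevrich.R` wraps the same functions for shell use
(`synth`, `validate`, `run` subcommands).

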
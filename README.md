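# InvarianceDynamics

Comparing how strongly — and how quickly — a visual neural population
generalizes across identity-preserving image transformations (size,
position, in-plane rotation, in-depth view) is only meaningful when the
transformations are **balanced**: each must produce the same net image
change. `InvarianceDynamics` implements that balanced comparison end to
end, for researchers studying invariant object representations who want a
fully synthetic, ground-truth-controlled version of the analysis chain.

The balancing currency is the net pixel change between two images,

    Δ(A, B) = Σ_xy |A_xy − B_xy|,

the summed absolute difference of 8-bit intensities. Per object, the view
(in-depth) change at two levels defines targets Δ1 < Δ2; size, position
and rotation magnitudes are then solved by bisection so each matches the
same targets, giving 90 stimuli for 10 objects. On top of this design the
package provides:

* **Stimuli** — parametric radial-frequency silhouettes, a net-pixel-change
  balance solver, PNG + manifest IO (`randomShapes`, `buildStimulusSet`,
  `solveBalance`, `netPixelChange`).
* **Simulation** — inhomogeneous-Poisson populations whose invariance
  *strength* and invariance *latency* are configurable per transformation,
  so every analysis has a recovery target (`populationConfig`,
  `simulatePopulation`, `studyScenario`).
* **Per-neuron invariance** — tuning correlations r between responses to
  reference and transformed images across objects, static and in 20-ms
  bins, with peak latencies, invariant-neuron fractions, covariation, and
  the co-occurrence chi-square against independence
  (`invarianceTable`, `binnedInvariance`, `cooccurrenceTest`).
* **Population decoding** — a shrinkage linear discriminant trained on
  reference trials and tested on transformed trials (and vice versa),
  time-resolved, with neuron-bootstrap peak-latency statistics and
  neuron/object subsets (`generalizationAccuracy`, `binnedDecoding`,
  `bootstrapLatencies`, `subsetDecoding`).
* **Model comparison** — pixel, Gabor-V1 and file-based deep-network
  representations, unit invariance, representational dissimilarity
  matrices (1 − Pearson r), RDM matches, and split-half reliability with
  the Spearman-Brown correction rc = 2r/(1+r) (`pixelFeatures`,
  `v1Features`, `rdm`, `rdmMatch`, `splitHalfReliability`).
* **Pipeline** — `runPipeline(runConfig(...))` runs everything from one
  master seed into a directory of CSV/PNG artifacts; `reportSummary()`
  assembles the headline tables. See the methods vignette
  (`vignettes/balanced-invariance-methods.Rmd`) for the models,
  assumptions and numerical choices.

## Worked example

```r
library(InvarianceDynamics)

stimuli <- buildStimulusSet(randomShapes(10, seed = 7042))  # 90 balanced images
sc      <- studyScenario(seed = 1, stimuli = stimuli)   # 127 neurons, 8 repeats
tensor  <- shuffleRepetitions(windowRates(sc$spikes), seed = 1)

inv <- invarianceTable(tensor)
subset(inv@summary, level == 2)
#>  transformation level mean_r  sem_r n_defined n_invariant fraction_invariant
#>            size     2   0.90 0.0067       127         126               0.99
#>        position     2   0.88 0.0092       127         123               0.97
#>        rotation     2   0.34 0.0236       127          17               0.13
#>            view     2   0.32 0.0247       127          18               0.14

generalizationAccuracy(tensor, "view", 2)
#> DecodingResult (chance = 0.1 )
#>  transformation level direction accuracy n_test
#>            view     2      mean    0.762    160
```

The scenario's ground truth — size/position tuning preserved at strength
0.85 versus 0.45 for rotation/view at the large change level — is
recovered: mean tuning correlations of 0.90/0.88 versus 0.34/0.32, with
99%/97% versus 13%/14% of neurons individually invariant (p < 0.05), and
view generalization decoding at 76% against a 10% chance level.
Time-resolved decoding (`binnedDecoding`, `bootstrapLatencies`) likewise
recovers the configured latency ordering: view decoding peaks later than
size decoding in >90% of neuron-bootstrap resamples.

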
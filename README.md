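# nicheflip

Glial niche cells in the developing *Drosophila* nervous system grow into
huge multinucleated syncytia that ensheath neural stem cell (NSC)
lineages, and neighbouring syncytial units can partially fuse with each
other. Demonstrating that two regions of such a network actually share
cytoplasm — and mapping where the diffusion barriers are — takes careful
quantification of live-imaging experiments. `nicheflip` implements that
quantitative toolbox as a tidyverse-native R package:

* **FLIP statistics.** The percentage of fluorescence loss for a region
  of interest, `%FL = (I_start − I_end) / I_start` on mean ROI
  intensities, with a Monte-Carlo significance threshold: `%FL` is
  sampled over 10,000 randomly placed 10 × 10 µm squares in the
  unbleached fluorophore's channel, and the empirical quantile at the
  chosen confidence level (default 95%) is the largest loss still
  attributable to chance. Losses strictly above it are attributed to the
  photobleaching.
* **Photoconversion propagation.** Detection of converted Kaede in
  distal zones (mean converted intensity > background mean + 3 SD) and
  the fraction of adjacent clones reached.
* **Compartment-map inference.** Pairwise bleach experiments become
  `connected` / `barrier` / `dynamic` / `untested` relations; union-find
  merging, violation flags (barrier pairs inside one merged block, the
  signature of temporally dynamic connectivity) and the exact minimum
  number of distinct compartments consistent with the evidence.
* **Clonal-dynamics simulator.** Stochastic growth of founder glial
  cells under endoreplication, acytokinetic mitosis and homotypic
  fusion, with four-colour single-copy label induction at any
  developmental time, clone statistics and the case 1–4 classifier for
  induction outcomes.
* **Niche quantification.** Cube-sampled membrane-per-NSC ratios with
  deterministic 1-D k-means intensity segmentation, and individual
  ensheathing percentages.
* **Synthetic data.** A compartment-graph reaction model (RK4-integrated
  bleaching/conversion dynamics with per-acquisition imaging decay)
  rendered into noisy TIFF movies with known ground truth, so every
  stage is testable without any imaging download.

## A worked example

Two compartments joined by an open cytoplasmic bridge; green is bleached
continuously in the first one. Is the loss in the *second* compartment
significant?

```r
library(nicheflip)

movie <- make_fixture("two_open", seed = 3)
null  <- monte_carlo_null(movie, channel = "red", seed = 4, t_start = 0:4)
null
#> <flip_null> channel red: threshold 0.1605 (95% confidence, 10000 squares of 50 px)

trace <- measure_zone_trace(movie, roi_rect(11, 70, 75, 134, id = "n2"),
                            channel = "green")
loss  <- percent_fluorescence_loss(trace, t_start = 0:4)
loss$percent_loss
#> [1] 0.9065904

classify_loss(dplyr::mutate(loss, channel = "green"), null$threshold)
#> # A tibble: 1 × 9
#>   roi   channel t_start   t_end i_start i_end percent_loss threshold significant
#>   <chr> <chr>   <list>    <int>   <dbl> <dbl>        <dbl>     <dbl> <lgl>
#> 1 n2    green   <int [5]>    99    110.  10.3        0.907     0.160 TRUE
```

The unbleached neighbour lost 91% of its signal while chance alone
(imaging decay plus noise, measured by the random-square null in the red
channel) explains at most 16.1% — the two compartments exchange
cytoplasm. On the `two_closed` fixture the same call returns
`significant = FALSE`.

Downstream, `accumulate_evidence()` + `build_map()` turn a set of such
calls into a compartment map, and `glance()` on any result gives a
one-row tidy summary. `autoplot()` methods exist for null
distributions, concentration series, compartment maps and clone
statistics.

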
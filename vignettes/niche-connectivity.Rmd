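---
title: "Quantifying syncytial connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying syncytial connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheflip)
```

`nicheflip` quantifies whether, where and how strongly regions of a
syncytial glial network share cytoplasm, and simulates the clonal
processes — endoreplication, acytokinetic mitosis, homotypic fusion —
that build such networks. This vignette explains the models behind each
stage, the parameters that matter, and the choices made where the
design was genuinely open.

## The compartment model

Fluorescent compartments are modelled as well mixed: a compartment is a
region within which diffusion is fast relative to the bleaching and
exchange timescales, so it carries a single concentration per
fluorescent species. Compartments are nodes of a graph; cytoplasmic
bridges are edges with a first-order exchange rate $k$ (s⁻¹). For
species $s$ on an open edge $(a,b)$,

$$\frac{dC_a}{dt} = k\,(C_b - C_a), \qquad
  \frac{dC_b}{dt} = k\,(C_a - C_b),$$

applied symmetrically regardless of compartment volume (the
*equal-volume convention*). This keeps the system linear and exactly
checkable against a matrix exponential. The price is that the
volume-weighted total is only conserved when volumes are equal — for
unequal volumes the symmetric concentration flux implies
$dM/dt = k (C_b - C_a)(V_a - V_b)$. Volumes are therefore used for
bookkeeping and fixture design, not kinetics; conservation properties
are stated and tested in the equal-volume regime.

During event frames the laser acts on one target compartment: continuous
bleaching removes the bleached species at rate $\beta$; photoconversion
transfers native Kaede to its converted form at rate $\gamma$
(conserving their sum). A bleach ROI smaller than its compartment is
equivalent to whole-compartment bleaching at
$\beta \cdot V_\mathrm{ROI}/V_\mathrm{compartment}$ under the well-mixed
assumption. Imaging-related photobleaching is a *discrete* per-acquired-
frame multiplier $1-\alpha$ per channel, because it is caused by the
acquisition itself, not by elapsed time.

Integration is explicit fixed-step RK4 (default step: one hundredth of
the frame interval; a precondition caps it at one tenth). The system is
linear and non-stiff at the rates of interest ($k, \beta \le 1$ s⁻¹),
so RK4 at these steps is far inside its stability region, and a
fixed-step deterministic scheme makes every simulated movie bit-exactly
reproducible from one integer seed. The integrator is validated against
the closed-form eigen-decomposition solution of the two-compartment
system to $10^{-6}$ relative error across a grid of $(k, \beta)$.

Rendering maps concentrations through a label image:
`pixel = background + gain · C + noise`, with optional Poisson shot
noise and additive Gaussian noise. Frame 0 records the unattenuated
initial state; decay applies from the first acquired interval onwards.
Coordinates are 1-based array indices (R convention); frames are
0-based in all user-facing tables, matching how time points are
labelled on microscopes; event windows are half-open `[start, end)`.

## %FL and the Monte-Carlo null

The FLIP statistic for a region of interest is
$\%FL = (I_\mathrm{start} - I_\mathrm{end}) / I_\mathrm{start}$ on mean
ROI intensities. `t_start` defaults to the mean over the pre-bleach
frames — averaging the baseline makes the statistic robust to
single-frame noise — and `t_end` to the final frame. %FL is invariant
to multiplicative gain but *not* to a background offset; background
subtraction is deliberately left to the caller, because offsets are
instrument-specific.

Even without photomanipulation, fluorescence drifts: per-acquisition
photobleaching, focus and tissue shifts, cross-channel effects. The
null distribution of such losses is estimated empirically: %FL is
computed over `n_squares` (default 10,000) squares of side 10 µm placed
uniformly at random, fully inside the field, in the channel of the
*unbleached* fluorophore, with the same `t_start`/`t_end` convention as
the test ROI. The significance threshold is the empirical quantile of
those samples at the confidence level (nearest-rank method). The
default level is 0.95, exposed as a parameter. A loss is significant
only if it *strictly* exceeds the threshold — the threshold is the
largest loss still attributable to chance. When several movies of the
same fluorophore are analysed, the most stringent (largest) threshold
is retained.

Numerical notes: the µm→pixel conversion rounds the square side to the
nearest integer ≥ 1 pixel; squares may land anywhere, including on the
bleach ROI, unless an exclusion mask is supplied (the method does not
otherwise restrict squares to tissue); squares whose starting mean is
zero (pure empty background in noise-free synthetic data) yield an
undefined ratio and are dropped, with a hard error if fewer than 1,000
finite samples remain. Because two random squares can coincide, tied
%FL values can push the achieved coverage slightly above the nominal
level; the tests allow ±0.5 percentage points for this.

The synthetic fixtures give the two fluorophores different imaging
decays (green 0.1%, red 0.2% per frame). With identical decays, a zone
behind a diffusion barrier experiences *exactly* the null statistic's
distribution, and by construction would exceed the threshold in 5% of
seeds. Real fluorophores differ in photostability — this asymmetry is
why per-fluorophore thresholds are computed at all — and the fixture
mirrors that, which gives barrier zones a deterministic margin below
threshold.

## Photoconversion crossing

Converted Kaede reaching a distal zone is detected when the mean
converted-channel intensity over the detection frames (default: the
last quarter of the movie) exceeds the background mean by more than
three background standard deviations — the conventional 3σ rule. The
propagation fraction is simply the percentage of adjacent clones with a
detection.

## From pairwise bleaches to a compartment map

Each bleach experiment contributes evidence about pairs: a significant
loss in an observed zone means the pair is *connected*; a
non-significant loss in a zone that **borders** the bleached zone means
a *barrier* (absence of loss in a distant zone is weak evidence and
stays *untested*); conflicting records across experiments mark the pair
*dynamic* — read as connectivity remodelling over time, not measurement
error. Zones merge along connected relations (union-find). A barrier
pair that nevertheless ends up inside one merged block is flagged as a
*violation*: the pair was isolated at one time and connected at
another.

The minimum number of distinct compartments consistent with the
evidence is computed by exact search over partitions of the zones
(feasible for ≤ 10 zones; refused beyond that with a lower bound).
Two rules define feasibility: no block may contain a barrier or dynamic
pair, and every block must be internally connected through positive
(connected) evidence — zones are never merged merely because they were
not probed. Without the second rule the answer would collapse to the
chromatic-like minimum of the barrier graph and, on the five-zone
worked example, would undercount the compartments the evidence
requires. Dynamic pairs are excluded from both edge sets, so the count
is a static lower bound. The count is monotone non-decreasing in the
barrier set.

## The clonal simulator

Founder glial cells are simulated as syncytial units over a
developmental horizon in hours after larval hatching (h ALH), in
discrete 1 h steps, with three event types:

* **Endoreplication** (window, per-nucleus rate): genome replication
  without nuclear division; the nucleus's count of label-construct
  copies doubles (diploid baseline: one copy, a heterozygous single
  insertion).
* **Acytokinetic mitosis** (window, per-nucleus rate): nuclear division
  without abscission; a daughter nucleus is added to the same unit.
  S phase replicates every construct copy before division, so each
  daughter inherits one replica of each parental copy: per-nucleus copy
  number and colour combination are conserved through mitosis. (An
  alternative rule — halving copies at division — was considered and
  rejected: it fragments multicoloured lineages at division, which
  contradicts the observed persistence of both polyploid nuclei and
  coherent multicoloured clones at late stages.)
* **Fusion** (rate per adjacent unit pair): two units merge, pooling
  nuclei. Adjacency is a fixed random geometric graph over founder
  positions in the unit square (radius 0.4), a neutral stand-in for
  tissue neighbourhoods since no spatial statistics of partner choice
  are available.

Per-step event probabilities are `expm1(rate)` rather than
`1 - exp(-rate)`, so the *expected* per-step growth factor equals the
continuous-rate factor exactly: a mitosis-only window of length $w$
yields $e^{rw}$ expected nuclei per unit, which the tests check against
a 200-seed Monte-Carlo mean.

The full event history is drawn once from the seed and logged; label
induction is an *observation overlay* that replays the history,
colouring each existing uncoloured copy at the induction time with
probability `efficiency` and one of four colours uniformly. Copies
created later inherit their template's colour. This replay design means
the same population can be "induced" at any time without changing its
history — exactly how a genetic label behaves — and every statistic can
be recounted independently from the log.

**Clone identity.** Experimentally, clones are contiguous groups of
nuclei with the same colour combination. The simulator's default
(`identity = "lineage"`) additionally uses the ground-truth founder
lineage, so same-combination nuclei from different founders are not
conflated; `identity = "colour"` reproduces the observable proxy,
optionally merging identical combinations across adjacent units.
Nuclei with no recombined copy are invisible and excluded.

**Canonical schedule.** The defaults encode the endoreplication-then-
mitosis ordering on a 96 h horizon with 10 founders: endoreplication in
[8, 48) h at 0.04 h⁻¹ (mean ≈ 1.6 doublings, so typical nuclei carry
2–4 copies and ~20% remain single-copy — a moderate polyploidy
consistent with the late persistence of some single-coloured clones),
mitosis in [48, 90) h at 0.045 h⁻¹ (mean ≈ 6–8 nuclei per unit by the
horizon), fusion at 0.002 h⁻¹ per adjacent pair (a few events per
brain). These are study conditions, fixed once; they are deliberately
not fitted to any dataset.

**Case classifier.** Two signatures separate the four induction
outcomes: the multicoloured clone fraction (several copies at induction
commit to independent colours — an endoreplication signature) and
clone fragmentation (nuclei labelled after divisions split a unit into
many smaller clones — a mitosis signature). Case 1: neither (induction
before both). Case 2: multicolour only. Case 3: fragmentation only.
Case 4: both. Thresholds are a 0.2 multicoloured fraction and ±20%
bands on clone number *and* mean size (fragmentation requires more
*and* smaller clones — using the count alone misreads runs where
pre-induction fusion merged same-colour baseline clones). Case 3 is
implemented for completeness even though the endoreplication-first
ordering makes it the counterfactual schedule.

**Overlap counting.** With membrane labels, a fusion is detectable as a
colour overlap only when the two units' combinations differ;
same-colour fusions are counted separately as undetectable. The
events-per-clone ratio divides logged post-induction fusions by the
clone count.

## Niche quantification

The membrane-per-NSC ratio samples a labelled volume with `n`
non-overlapping cubes (default six, 150 × 150 pixel footprint, depth to
an explicit `z_limit` standing for the neuropile boundary), optionally
avoiding an exclusion mask. Membrane pixels are segmented by 1-D
k-means on a 256-bin intensity histogram — a deterministic, weighted
Lloyd iteration initialised at the k evenly spaced quantiles — with
`k = 2` or `4` held constant across conditions; membrane is the
highest-mean cluster (configurable to the top two for `k = 4`, since
which clusters were retained is a free choice). For `k = 2` the
converged split minimises the two-class within-variance of the
histogram, which the tests verify against an exhaustive threshold
search. A constant block yields an empty mask with a warning. Per cube,
the ratio is membrane pixel count over NSC count (NSC labels are
inputs; detection and any manual correction are out of scope); cubes
with zero NSCs raise an error unless explicitly dropped. The
ensheathing percentage is `100 · (total − Σ multi-chamber counts) /
total`, with the multi-chamber size distribution reported alongside.

## What the synthetic data does and does not show

The generator reproduces the features the statistics rely on:
well-mixed compartments with known connectivity, continuous bleaching
and pulsed conversion, per-acquisition decay, additive/shot noise, and
clonal populations with known event histories. It deliberately omits
intra-compartment diffusion gradients, optics (PSF, z-blur), tissue
drift beyond an integer ROI shift, autofluorescence structure, and
nutrition-coupled event triggers. Passing tests therefore demonstrate
that the *procedures* are correct and calibrated on their assumptions —
not that real tissue satisfies those assumptions; thresholds on real
movies must still be derived per movie and fluorophore.

Problem sizes used in the validation suite (chosen for tight, fast,
deterministic checks): 512 × 512 null movies with 10,000 squares for
coverage and false-positive control; 50 random graphs of 3–8
compartments, each surveyed noise-free and at 3% Gaussian noise; 24
photoconversion trials; 100 seeded schedule runs for the case
classifier; 10,000-nucleus populations for colour combinatorics.

## Known limitations

* Binary relations only: exchange-rate magnitudes are not estimated
  from %FL kinetics.
* The equal-volume exchange convention ignores volumetric asymmetry in
  kinetics.
* The compartment-count search is exponential and capped at 10 zones.
* The simulator's adjacency graph is spatially neutral; it does not
  model membrane growth or chamber geometry.
* The null squares share one field, so their %FL values are weakly
  correlated; thresholds remain valid as empirical quantiles of the
  sampled statistic.
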
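---
title: "Models and methods: mini-chromosome stability and read-depth genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mini-chromosome stability and read-depth genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minichrom)
```

`minichrom` quantifies two things about chromosome-edited chicken DT40
cells: how often an engineered mini-chromosome is lost per cell division
(from GFP flow-cytometry assays), and what the edited karyotypes look like
at the DNA level (from control-normalized binned sequencing coverage). This
vignette explains the models, the estimators, the parameter choices, and the
known limitations.

## The karyotype model

DT40 CL18 cells are diploid except for a trisomic chromosome 2 and a
tetrasomic chromosome 24. The genome model carries, per chromosome, its
length, an optional centromere interval, and the control copy number; the
default models four chromosomes (chr1, 196 Mb, the normalization reference;
chr2, 153 Mb, centromere at 52.2-52.7 Mb; chr3, 110 Mb; chr24, 6 Mb). A
strain karyotype lists, per chromosome, the half-open base-pair intervals
each copy retains, so telomere-seeding truncations are just shortened
intervals. Five strains are built in: the trisomic control (`CL18`), the
disomy-corrected `Chr2-2`, the p-arm-truncated `Chr2_1_1_q`, the
double-truncated `Chr2_1_1_mini` carrying the 0.7-Mb mini-chromosome, and
`Chr2_1_p_q` carrying complementary p- and q-retaining fragments.

The truncation coordinates are not published at base-pair resolution: the
p-arm seeding site sits about 0.2 Mb from the centromere and the q-arm site
within ~10 kb of its distal edge. We fix them at 52.0 Mb and 52.7 Mb, which
reproduces the published arithmetic exactly (0.7 Mb mini = 0.2 Mb flank +
0.5 Mb centromere repeats) and is the right choice at 10-kb bin resolution,
where the ~10-kb q-side offset is invisible. A consequence worth noting:
`Chr2_1_1_mini` and `Chr2_1_p_q` have identical aggregate copy number at
every chr2 position, so read-depth data cannot distinguish them — only
per-molecule methods (pulsed-field gels, karyotyping) can.

## The segregation model

Each division replicates every mini-chromosome copy into two sister
chromatids, which segregate independently of other copies in one of three
ways:

* **faithful** (probability $1 - p_\mathrm{ns} - p_\mathrm{ll}$): one
  chromatid to each daughter;
* **nondisjunction** ($p_\mathrm{ns}$): both chromatids to one daughter,
  chosen uniformly — the source of double-GFP cells;
* **anaphase-lag loss** ($p_\mathrm{ll}$): one chromatid lost, the surviving
  one inherited by a uniformly chosen daughter.

GFP expression travels with the chromatids; after segregation each
expressing copy is silenced permanently with probability $p_\mathrm{sil}$
per division. Silenced carriers score GFP-negative at the cytometer while
still carrying the chromosome — this is why puromycin preselection cannot
fully clear the GFP-negative gate, and why GFP-based rates slightly
overestimate DNA-level loss. The published analysis applies no correction
for this, and neither do our defaults.

For a one-copy mother, a given daughter fails to inherit the chromosome
with probability

$$r = \frac{p_\mathrm{ns} + p_\mathrm{ll}}{2},$$

which is exactly the per-division loss rate of the retention model

$$f_n = f_0 (1 - r)^n,$$

with $n$ the number of divisions (DT40 cells divide three times per day)
and $f_0 = 1$ when the culture starts from a single carrying cell. The
published analysis ignores the creation and re-loss of two-copy cells;
mechanistically we keep them (they are what makes the double-GFP fraction
grow under nondisjunction), but the estimators ignore them too, counting
double-GFP cells simply as retaining.

Populations are propagated as counts over the classes (copies, expressing
copies) with copies capped at `k_max = 4`: for each occupied class the
exact daughter-pair distribution is enumerated once (all $5^c$ chromatid
routings, convolved with silencing) and mothers are allocated to outcomes
by a multinomial draw. This makes $2^{21}$-cell clones cost microseconds
per generation while remaining an exact simulation of the branching
process. A deterministic twin (`propagate_generation_expected`) applies the
same kernel in expectation and serves as the convergence oracle in the
tests.

## Loss-rate estimators

**Clone assay (limiting dilution).** Clones grown from single cells for 7
days (21 divisions) are summarized by the median per-clone GFP-negative
fraction $m$, after excluding clones at 100% negative (chromosome presumed
lost at day 0, before the divisions the model counts); then
$r = 1 - (1 - m)^{1/21}$. The median, not the mean, matches the published
analysis and is robust to the heavy right tail that early loss events
create. Confidence intervals are percentile bootstrap over clones (2000
resamples).

A caveat the simulation makes explicit: for the branching process itself,
the *mean* clone fraction equals $1 - (1-r)^n$ exactly, but the *median*
sits below the mean whenever single loss events in intermediate generations
(population sizes of tens to thousands of cells) still matter — a
Luria-Delbruck-type skew. At $r = 0.0897$ the gap is negligible (~0.5
percentage points at 86%), but at $r = 0.00143$ the simulated clone median
is ~2.15% rather than the 2.96% the closed form predicts, and the
median-based estimator correspondingly underestimates small rates by
roughly 25% (it is accurate within a few percent at rates around 10%).
The package reports what the estimator the study used actually produces;
correcting the skew would require likelihood inference on the branching
process, which is out of scope here.

**Bulk time course.** A preselected population is cultured 25 days,
sampling the GFP gates every 5 days; $\ln f$ is regressed on
$n = 3 \times \mathrm{day}$, with the intercept either pinned to the day-0
measurement (default) or free. The bulk assay averages over a large founder
population, so the clone-level skew is absent: at $r = 0.002$ the fit
recovers the rate within a few percent. Intervals come from a residual
bootstrap.

## The coverage simulator

Sequencing is emulated at the bin level: a bin's expected count is
`depth_per_copy` (default 10) times the copy-weighted retained fraction of
the bin, times a mappability weight; counts are Poisson by default, with a
negative-binomial option since the real data's overdispersion is unknown.
Centromere intervals get weight 0 — centromeric repeats cannot be uniquely
mapped — which is precisely why detected q-side losses begin at 52.7 Mb
rather than inside the centromere. Bins straddling a truncation point get
fractional expectations. At the default depth a trisomic bin averages 30
reads, so per-bin double-normalized scores carry a coefficient of variation
of about 0.29; every design choice in the CNV pipeline below follows from
that number.

What the simulator does *not* emulate: GC and mappability bias beyond the
binary mask, library-preparation waves, diploid heterozygosity, or any
structural variation other than the engineered truncations. Passing tests
therefore demonstrate correctness of the analysis on an idealized noise
model, not robustness to real-library artifacts.

## The CNV pipeline

Following the study's normalization, each strain's per-bin counts are
divided by the mean bin count of chromosome 1 in the same library (removing
depth), and the resulting ratios are divided bin-by-bin by the control
strain's ratios (removing shared structure). Bins where the control ratio
falls below 0.1 are masked. On this score track, 1.0 means "same relative
copy number as CL18" and attainable levels on chr2 are multiples of 1/3.

Two estimator details matter at low depth:

* **Chromosome-level copy numbers** use the ratio of aggregate means, not
  the mean of per-bin ratios: $E[X/Y] > E[X]/E[Y]$ for Poisson $Y$, and at
  30 reads/bin the per-bin ratio mean overshoots by ~3.5% (0.69 instead of
  2/3 for the disomy-corrected strain). The ratio of means is unbiased.
* **Segmentation** assigns each unmasked bin one of the known rational
  levels $\{k/c : k = 0..c{+}1\}$ by exactly minimizing a penalized
  least-squares (Potts) objective with dynamic programming, with a BIC-like
  penalty $\beta = 2\hat\sigma^2\log n$ estimated from lag-1 score
  differences. We initially implemented a local median-filter-and-quantize
  scheme, but at CV 0.29 against a level spacing of 1/3 it produces
  hundreds of spurious segments and multi-bin boundary errors; the global
  fit is equally deterministic and testable and is optimal for this class
  of signal. Runs shorter than 3 unmasked bins are merged into the
  neighbor with the closer level.

Masked regions are bridged by rule: a segment extends through masked bins
until the first unmasked bin of a different level, where the boundary is
placed. Crucially, the fit and the run merging treat contiguous unmasked
blocks independently — bins separated by the 0.5-Mb centromere gap are not
neighbors, so a breakpoint hidden in unmappable sequence costs nothing and
a single noisy bin at a gap edge cannot drag a bridged boundary across the
gap. This makes the q-side truncation call at 52.7 Mb essentially
deterministic (99-100% of seeded replicates exact).

Free boundaries in mappable sequence are harder: a one-third-copy step with
per-bin noise at ~0.6 of the step height localizes to within one 10-kb bin
in only about two-thirds of replicates (within three bins in ~90%). This is
close to the information-theoretic limit for any estimator operating on the
double-normalized scores at 10 reads/bin/copy — the evidence per bin is
simply ~1 nat — so we report it as a property of the data rather than
attempt further algorithmic rescue. Deeper sequencing, not a cleverer
segmenter, is the remedy. Occasional 50-300 kb spurious segments (one or
two per genome) arise where sample and control fluctuations align; they are
the expected false-positive rate of a scan statistic at this
signal-to-noise ratio and do not affect the centromere-proximal calls,
which the mini-chromosome detector selects by proximity to the centromere.

The mini-chromosome detector looks for a segment whose level exceeds both
flanks (an elevated island) nearest the centromere; strain-vs-strain
comparison intersects two segmentations and reports maximal intervals of
differing level with the direction of change.

## Problem sizes and reproducibility

All randomness flows through explicit seeds; the same seed reproduces every
track, assay, and interval exactly. The bundled analysis scripts and tests
use clone assays of 400-1500 clones, bulk time courses of $10^5$-$10^6$
tracked cells, and whole-genome simulations at the default depth
(~46,000 bins over four chromosomes) — sizes chosen so a full analysis
reruns in seconds to a couple of minutes on a single core while keeping
Monte-Carlo error well inside the tolerances tested.

## Known limitations

* GFP silencing and chromosome loss are confounded in the negative gate;
  the model separates them mechanistically but the estimators, matching the
  published analysis, do not.
* The clone-median estimator underestimates small rates (see above).
* Read-depth genotyping is blind to copy-neutral rearrangements and cannot
  distinguish strains with identical aggregate copy profiles.
* Breakpoint calls are bin-resolution (10 kb) at best, and boundary
  localization at default depth carries the one-to-three-bin jitter
  quantified above.
* The branching process assumes no fitness cost of carrying or losing the
  mini-chromosome and a fixed three divisions per day for all cells.
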
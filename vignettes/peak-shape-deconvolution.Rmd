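---
title: "Model-based peak calling by binding-pattern deconvolution"
author: "peakdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based peak calling by binding-pattern deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakdeconv)
options(peakdeconv.verbose = FALSE)
```

## The model

A ChIP-seq experiment reports, for every immunoprecipitated chromatin
fragment, the genomic position of its 5' end. Around a point binding site
these read starts pile up in a characteristic, reproducible shape set by
the fragment-size distribution of the library. peakdeconv exploits that
shape directly: instead of asking "is the read count here larger than
background?", it asks "does the local profile look like a binding event?".

The binned read-count intensity profile $y$ (reads elongated to the
fragment length, counted per 10-bp bin) is modeled as a sparse
non-negative superposition of copies of one *kernel* $g$,

$$ y_b \;=\; \sum_{i} \beta_i \, g(b - s_i) + \varepsilon_b,
   \qquad \beta_i > 0, $$

where $g$ is a discretized Gamma density with learned shape $k$ and scale
$\theta$, rescaled to unit maximum so every coefficient $\beta_i$ is
directly a peak height in profile units, and $s_i$ are the (few) positions
where binding events sit. Everything the model cannot explain is treated
as background and drives the significance assessment.

Assumptions worth stating plainly:

* all binding events in one dataset share a single shape (one kernel per
  run — mixtures of sharp and broad patterns are out of scope);
* events are point-like at the resolution of the fragment length;
* the background has no kernel-shaped structure beyond what random read
  clumping produces.

## Coverage reconstruction

Reads are extended 3'-wards to the presumed fragment length (default
150 bp, or inferred — below) and counted per bin with a 1-bp-overlap rule
(default bin 10 bp). Reads clipped at chromosome edges are truncated, not
discarded. Duplicate reads are kept by default (`dedup = TRUE` removes
exact duplicates). At `bin_size = 1` total coverage equals the summed
elongated read lengths exactly; this conservation is asserted in the test
suite.

## Learning the kernel

Training regions are selected greedily from the highest-intensity bins
(absolute cutoff or intensity quantile, default quantile 0.999 with an
automatic relaxation ladder when a large genome yields too few regions),
with mutual exclusion within twice the region half-width so each region
is an isolated peak. Learning then alternates:

1. deconvolve every region with the current kernel (at most 2 events per
   region);
2. update $(k, \theta)$ by numerical minimization of the total squared
   residual, where each candidate kernel is evaluated by re-deconvolving
   the regions.

Step 2 deliberately re-fits placements per candidate. Holding positions
fixed at the previous kernel's modes — the more obvious alternating
scheme — biases the objective toward the incumbent shape and stalls at a
wrong fixed point; we observed exactly that before switching.

The RSS surface is multimodal in the shape: a narrow, strongly skewed
kernel that tiles each observed peak with two copies competes with a
single wide near-symmetric copy, and gradient descent from a skewed start
reliably lands in the wrong basin. The update therefore scans a fixed
shape ladder (1.5 … 50) with a 1-D scale optimization per rung, then
polishes the two best candidates with Nelder–Mead. Kernels wider than the
training regions are inadmissible. The cap of 2 events per region
matters for the same reason: with 3 or more allowed, the narrow-kernel
basin wins. The per-iteration RSS is non-increasing by construction; an
update that fails to survive re-deconvolution is reverted (sub-tolerance
increases count as convergence). On noiseless kernel-shaped profiles the
learner recovers $(k, \theta)$ essentially exactly; with Poisson
background at one count per bin and 50 training peaks of height 20–60,
recovery is within about 10 % relative error for shapes between 2 and 5.

The kernel is evaluated at bin centers (not integrated over bins; the
difference is negligible at 10-bp bins), truncated past the mode where
the density falls below 0.001 of the maximum, and normalized to unit
maximum, which also makes the learned shape invariant to uniform
rescaling of the profile.

## Inferring the read-elongation parameter

Each strand's unextended 5'-end density at a site of fragment length $F$
spans about $F$ (the site sits uniformly inside its fragment), so the
read-length coverage of one strand is a flat-topped bump of full width
roughly $F$ plus one read length. `infer_elongation()` builds per-strand
coverage without elongation, fits a strand kernel with the *shape frozen*
at 20 (near-Gaussian) and only the scale free, and maps the kernel to a
length as full width at half maximum (interpolated) plus the read length.
Two numerical choices deserve explanation:

* *Frozen shape.* A free shape on a flat-topped density is poorly
  identified: a skewed narrow basin and a symmetric wide basin have
  near-equal RSS but widths differing by ~25 %, and the basin choice
  flipped between strands on identical simulations. The footprint is
  symmetric by construction, so fixing a near-Gaussian shape removes the
  degeneracy (and makes the fit ~40× faster).
* *FWHM + read length.* The half-maximum width of a trapezoid with base
  $F + R$ and top $F - R$ is exactly $F$; the fitted Gamma's FWHM runs
  slightly narrow on flat tops, and adding the read length compensates.
  On simulations with $F \in \{100, 200, 300\}$ (sd 20, 36-bp reads, 100
  sites of 500 fragments) the combined estimate is monotone and within
  about 25 % at the extremes, and within 2 % at $F = 200$.

Both strand estimates are combined as their rounded mean; a disagreement
above 50 % triggers a warning. An independent cross-check
(`summit_distance_check()`) pairs forward and reverse summits and
reports the implied fragment length; it validates, never estimates.

## Genome-wide deconvolution

Chromosomes are tiled into 20-kb windows. The pipeline overlaps
consecutive windows by *twice* the kernel support and assigns each window
a half-open "core" interval; cores partition the chromosome, and only
in-core candidates survive merging. Two supports of overlap (rather than
one) guarantee that every core position keeps a full support of signal on
both sides within its own window; with a single support we measured
systematic 60–130-bp position bias for sites within half a support of a
core boundary, whose only unclipped fit came from the window that did not
own them.

Each window is fitted by greedy non-negative matching pursuit: add the
shift with the largest residual–kernel inner product, refit all selected
heights jointly by non-negative least squares, drop zeroed atoms, stop
when the relative RSS improvement falls below $10^{-4}$, the best new
height falls below the floor, or 200 sites are reached. Because kernel
copies are never clipped inside a window, all inner products live in the
Gram domain (the Gram matrix is the kernel autocorrelation at shift
differences), so a greedy round costs $O(n + km + k^3)$; the NNLS solves
are a hand-written Lawson–Hanson iteration on the normal equations,
cross-checked in the tests against an independent solver. Two refinements:

* *Minimum separation.* New shifts within just under half a support of an
  accepted site are excluded. Two events closer than that are not
  resolvable against a single kernel shape; without the constraint, the
  stochastic flank wobble of every true peak (fragment sampling noise is
  serially correlated across ~20 bins) is fitted as spurious sub-peak
  copies 150–250 bp off-apex. Events half a support apart are still
  resolved, as the test suite asserts. `min_sep = 0` disables.
* *Reposition pass.* After each refit, every fitted copy is moved to its
  locally optimal shift given the others (coordinate descent, up to three
  passes). Greedy-only placement can freeze an early suboptimal shift
  once the separation constraint blocks the apex.

The automatic height floor is `max(2, 3 × lower-quartile nonzero bin)`
computed profile-wide. Per-window medians — the more local choice — fail
in peak-dense windows, where the median nonzero bin sits at peak height
and suppresses every call (standalone `deconvolve_window()` retains the
per-window rule for single-window use).

## Significance

Every candidate receives three local p-values (5/10/15-kb windows), one
global p-value, and their Fisher combination
($X^2 = -2\sum \ln p_i \sim \chi^2_8$); with a control sample, a
corrected p-value is appended. All p-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge \beta\}) / (1 + B)$, whose floor
$1/(1+B)$ keeps zeros out of the Fisher combination. Sub-seeds derive
deterministically from (master seed, chromosome, position, window size),
so thread count and evaluation order cannot change any result.

The construction of the nulls received particular care, because two
plausible designs are measurably miscalibrated:

* Building nulls from the *all-candidates-removed* residual strips the
  background of exactly the clump structure a candidate must beat; on
  background-only simulations 97 % of candidates then reached the floor
  p-value. Nulls are therefore built from the profile with only the
  candidate's *own* fitted component subtracted.
* Resampling bins (or blocks) *within the candidate's own window* is
  still anti-conservative, because a candidate is by selection the
  largest fluctuation of its own window. The local null for window size
  $w$ instead deconvolves `n_boot` windows of size $w$ resampled from
  the surrounding background (within 10 $w$, clipped), i.e. a
  window-level block bootstrap; each drawn window naturally contains
  background clumps of every rank.

With this design, on background-only simulations (1-Mb chromosome,
6 background reads/kb, fixed (3, 40) kernel, 100 bootstrap windows,
≥500 candidates) the fraction of candidates with combined p below
$\alpha$ stays under $2\alpha$ for $\alpha \in \{0.01, 0.05, 0.1\}$.

The global null bootstraps a seeded 200-kb sample of the raw profile
(moving blocks of one kernel length — single-bin resampling destroys the
serial correlation of real background and understates spurious fit
heights). Because the sample includes real enrichment, the global test
is stringent: it asks whether a site exceeds the largest fit expected
anywhere in 200 kb of genome.

A known cost of honest local nulls: where true peaks cluster, a strong
neighbor drawn into a null window inflates it, making p-values
conservative for its neighbors. The opt-in `mask_alpha` config enables
iterative peak masking (subtract confident peaks from the null
background and recompute, up to three passes), which removes that
conservatism but drifts background-only calibration slightly above the
$2\alpha$ bound through an unmasking cascade; it is off by default.

The control correction deconvolves the control in a 10-kb window around
the site. A control fit within one kernel support at or above the IP
height vetoes the site ($p = 1$): both datasets comply with the kernel
there. Otherwise the IP height is referred to a bootstrap null of the
control window's residuals and the result Fisher-combined with the IP
p-value. No depth scaling is applied; the correction assumes comparable
sequencing depths (linear scaling between datasets of very different
depth is known to be unreliable, and no such correction is attempted).

No default significance threshold is applied anywhere: the full site
list is reported, and `pvalue_summary()` tabulates p-value deciles and
counts below common thresholds to support a user-chosen cutoff.

## The simulator

`simulate_reads()` emulates the standard fragmentation model: each site
emits fragments whose length is Normal (mean 200, sd 20 by default,
truncated above the read length) and which contain the site at a
uniformly random internal offset; sequencing reports the 5' read-length
prefix on a random strand; background reads are uniform with Poisson
counts per kb (default 0.5 for IP and control; the control contains
background only). All draws come from one seeded generator, so identical
specifications produce byte-identical BED files.

The simulator deliberately omits mappability gaps, GC bias, copy-number
variation, duplicated reads and sequencing errors. Passing tests on
simulated data therefore demonstrate correctness of the algorithms under
the fragmentation model, not robustness to every artifact of real
libraries — in particular the control-correction veto is exercised with
synthetic kernel-shaped control artifacts, not real input chromatin.

## Problem sizes and numerical conventions

The test and acceptance workloads use: 2-Mb chromosomes with 50 planted
sites of 30–150 fragments (background 0.5 reads/kb) for end-to-end
recovery; 100 sites of 500 fragments for elongation inference; 50
training peaks of height 20–60 over Poisson background for kernel
recovery; a 1-Mb background-only chromosome at 6 reads/kb (≥500
candidates) for calibration; and 100 bootstrap windows per null. These
sizes were chosen as the smallest at which the measured properties are
stable across seeds.

Coordinates are 0-based half-open internally and in BED/bedGraph output;
wiggle output is 1-based fixedStep; summits are reported as the 1-based
center of the kernel-mode bin. Ties in training-region selection break
leftmost; candidate shifts are at bin resolution (no sub-bin
interpolation); the bootstrap count `n_boot` trades p-value resolution
(floor $1/(1+B)$) against runtime.

## Known limitations

* One kernel per run: datasets mixing sharp and broad patterns are fitted
  with a compromise shape.
* Events closer than half a kernel support are reported as one site.
* Local p-values are conservative in dense peak clusters unless masking
  is enabled.
* The control correction is a veto-plus-Fisher rule; datasets with very
  different IP/control depths need external normalization first.
* Enrichment-island merging for very broad domains (kilobase-scale
  histone marks) is not implemented; each kernel-width event is reported
  separately.
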
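# peakdeconv

Model-based ChIP-seq peak calling by binding-pattern deconvolution, in R.

ChIP-seq reads mark the 5' ends of immunoprecipitated chromatin
fragments; around a genuine binding site they accumulate in a
reproducible shape set by the fragment-size distribution. Most peak
callers test read counts against a background distribution; peakdeconv
instead *learns the shape* of a binding event from the dataset itself
and then asks, genome-wide, where the profile looks like that shape.
This buys sharp positional resolution (summits at bin resolution) and
discrimination between true events and background read clumps of similar
height, which matters increasingly at high sequencing depth.

The binned, elongated read-count profile $y$ is modeled as a sparse
non-negative sum of shifted copies of a learned kernel — a discretized
Gamma($k$, $\theta$) density with unit maximum:

$$ y_b = \sum_i \beta_i\, g(b - s_i) + \varepsilon_b, \qquad \beta_i > 0 $$

The pipeline: (1) reconstruct the profile from BED reads (default
elongation 150 bp or inferred strand-specifically, 10-bp bins);
(2) learn $(k, \theta)$ by iterative regression on high-intensity
training regions; (3) deconvolve overlapping 20-kb windows by greedy
non-negative matching pursuit with joint NNLS refits; (4) assign each
candidate three local (5/10/15-kb) bootstrap p-values and a global one,
combined by Fisher's method, with optional control-sample correction.
No default significance threshold is applied — the complete site list is
reported with its confidence descriptors, plus a p-value summary table
for choosing a cutoff. A seeded read simulator with ground truth makes
every stage testable without external data.

## Worked example

Simulate a small experiment with known truth, call peaks, and inspect:

```r
library(peakdeconv)

spec <- simulation_spec(
  chrom_len = 5e5,
  sites = data.frame(position = c(60000, 180000, 270000, 390000, 460000),
                     n_fragments = c(120, 60, 150, 90, 80)),
  background_rate = 0.5, seed = 7)
sim <- simulate_reads(spec)

calls <- call_peaks(sim$ip, sim$sizes, control = sim$control,
                    config = run_config(elongation = 200, seed = 1,
                                        quantile = 0.995, min_regions = 5))
calls
```

```
peak_calls: 5 site(s)
  kernel: Gamma(shape=100.000, scale=6.02), support 850 bp
   chrom    pos      coef p_local_5k p_local_10k p_local_15k  p_global
1 chrSim  59995 134.59604 0.00990099  0.00990099  0.00990099 0.6435644
2 chrSim 179995  62.36882 0.00990099  0.02970297  0.13861386 0.8316832
3 chrSim 269995 165.39823 0.00990099  0.00990099  0.00990099 0.3168317
4 chrSim 389995  98.47473 0.00990099  0.00990099  0.06930693 0.6831683
5 chrSim 459995  90.57322 0.00990099  0.08910891  0.09900990 0.7029703
    p_combined  p_corrected
1 0.0003768310 5.036415e-05
2 0.0083385884 8.587905e-04
3 0.0002122844 2.957838e-05
4 0.0018443350 2.174993e-04
5 0.0128795073 1.271021e-03
```

All five planted sites are recovered within 5 bp of truth. `coef` is the
fitted peak height in profile units (tracking the planted fragment
counts); the 5-kb local p-values sit at the bootstrap floor 1/(1+100)
while the wider windows and the deliberately stringent global null (it
samples the profile *including* its enrichment) are larger; the Fisher
combination ranks the sites, and the background-only control sharpens
each p further. `write_peak_table()`, `write_summit_bed()` and
`pvalue_summary()` export the table, a BED of summits
(score = −10·log10 p, capped at 1000) and a threshold summary — no
default cutoff is ever applied.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/cli/peakdeconv.R`) with subcommands `simulate`, `coverage`,
`learn-kernel`, `call-peaks` and `summary`:

```sh
Rscript inst/cli/peakdeconv.R call-peaks --bed ip.bed --sizes chrom.sizes \
    --control control.bed --elongation auto --seed 7 --out-prefix run1
```

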
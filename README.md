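# ladconnect

Gene regulation at the nuclear periphery: an analysis toolkit for enhancer
connectivity and chromatin states at **lamina-associated domains (LADs)**.

Most genes inside LADs are repressed by the nuclear lamina, yet a minority
sit in local euchromatic islands and stay active. This package implements
the computational side of asking how: it partitions the genome into
constitutive LADs (cLADs), variable LADs and inter-LADs from multi-timepoint
LAD calls; delimits H3K4me1-marked euchromatic regions inside cLADs and
contrasts their lamin enrichment; classifies enhancer-capture Hi-C baits in
cLADs as K4 (H3K4me1-overlapping) or nonK4 and quantifies their connection
density and target categories; segments chromatin states with a
Bernoulli-emission hidden Markov model; and analyses dual-color FISH
gene-enhancer distances at the nuclear periphery. A seeded synthetic-data
generator produces every input with known ground truth, so the full
pipeline runs and is tested without any external download.

Intended users: computational biologists working on nuclear organisation,
LAD dynamics, or capture Hi-C connectivity who want these analyses as
tested, reusable functions rather than one-off scripts.

## Core statistics

* **LAD partition** (base-level): cLAD = ∩ timepoints, vLAD = ∪ − ∩,
  inter-LAD = complement of ∪. All overlap tests require ≥ 1 bp shared
  sequence on 0-based half-open coordinates.
* **Fold enrichment** of an annotation over a chromatin state:

  ((bases in state ∩ annotation) / (bases in state)) /
  ((bases in annotation) / (genome size))

* **Chromatin-state model**: hidden Markov chain with independent Bernoulli
  emissions per mark over 200-bp binarized bins (Poisson upper-tail
  binarization, p < 1e-4 against the genome-wide rate), trained by
  Baum-Welch with per-bin scaling and a monotone log-likelihood guarantee,
  decoded by max posterior (or Viterbi).
* **Group contrasts**: unpaired two-tailed Welch t-test
  (Welch-Satterthwaite degrees of freedom) for lamin region means, per-bait
  connection counts and FISH distances.
* **Relative expression**: fold change = 2^−ΔΔCt against a reference gene
  and calibrator condition.
* **FISH geometry**: Euclidean probe-probe distances; probe-to-periphery
  distance as the closest-point distance to an axis-aligned ellipsoid
  boundary (Lagrange root-finding, 1e-6 µm); peripheral = ≤ 2 µm.

## Worked example

Generate a synthetic dataset at the default study conditions and run the
connectivity stage:

```r
library(ladconnect)

truth <- generate_synthetic(synthetic_config(), seed = 1)

lc  <- load_connections(truth$connections[, 1:8], truth$genome, p_threshold = 0.01)
cb  <- baits_in_clads(lc$baits, truth$partition)
cls <- classify_baits(cb, truth$peaks$H3K4me1, truth$partition$clads)
print(cls)
#> 768 cLAD baits: 225 K4, 543 nonK4

cd <- connection_density(lc$connections, cls)
cd$class_stats[, c("class", "n_baits", "mean_connections")]
#>   class n_baits mean_connections
#> 1    K4     225         27.72444
#> 2 nonK4     543         14.59116
print(cd$welch)
#> Welch t = 32.67, df = 309, p = 3.166e-102 (means 27.72 vs 14.59)
```

768 baits fall in cLADs, of which 225 overlap an H3K4me1 peak (K4 baits);
K4 baits carry about twice the connections per bait of nonK4 baits
(generator rates 27.5 and 14.7), and the class contrast is significant far
below p = 1e-4. The same objects feed the target-category summary
(`annotate_targets` + `summarize_proportions`: ~70% of K4-bait targets fall
inside cLADs), the lamin contrast (`annotate_clad_regions` +
`region_mean_signal` + `welch_test`: K4 regions are depleted by ~1 log2
unit, p ≈ 6e-16), and the FISH stage (`pair_alleles` +
`fish_distance_records` + `compare_conditions`: the simulated
differentiation shift of +0.5 µm is recovered at 100 alleles per
condition).

The numbered scripts under `analysis/` run the whole pipeline from files:
`01_simulate.R` writes the synthetic inputs (BED/bedGraph/TSV plus
`truth.json`), and `02`-`06` perform LAD partitioning, TSS profiles,
connectivity, chromatin-state segmentation and FISH statistics, writing
tables under `results/`.

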
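---
title: "Methods: enhancer connectivity and chromatin states at lamina-associated domains"
author: "ladconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer connectivity and chromatin states at LADs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`ladconnect` implements an integration analysis of gene regulation at
lamina-associated domains (LADs): how genes that stay active inside the
repressive environment of the nuclear lamina relate to their enhancers. The
pipeline has six computational stages, each exposed as package functions and
driven by the numbered scripts under `analysis/`:

1. **LAD partitioning** — split the genome into constitutive LADs (cLADs),
   variable LADs (vLADs) and inter-LADs from per-timepoint LAD calls.
2. **Region annotation** — delimit euchromatic H3K4me1 regions inside cLADs
   and contrast lamin enrichment between region classes.
3. **Signal profiles** — log2(ChIP/input) binning, TSS meta-profiles, the
   expressed-gene filter, and 2^-ddCt relative expression.
4. **Connectivity** — classify enhancer-capture Hi-C baits inside cLADs as
   K4/nonK4, quantify per-bait connection density, and categorise targets by
   LAD class and H3K4me1 status.
5. **Chromatin states** — binarization, Bernoulli-HMM segmentation trained
   by Baum-Welch, fold-enrichment of annotations over states, target-state
   attribution.
6. **FISH distances** — probe-probe and probe-to-periphery distances,
   peripheral classification, condition contrasts.

A seeded synthetic-data generator emits every input with known ground truth,
so the whole pipeline is testable without downloads.

## Coordinate and interval model

All regions are 0-based, half-open (BED convention) at the interfaces;
internally they are held as `GRanges` with chromosome lengths attached, and
the 1-based conversion happens only in the constructors and file readers.
Consequences the rest of the pipeline relies on:

* an overlap exists iff the shared length is at least 1 bp — book-ended
  intervals touch but do not overlap;
* normalization sorts and merges overlapping *and* book-ended intervals, so
  a normalized set is a disjoint cover and base-coverage arithmetic is exact;
* strand is carried but ignored by every overlap test;
* chromosome names are matched exactly — a mismatch between a file and the
  genome table is an error, not a silent aliasing.

## LAD partition

Given LAD interval sets for at least two timepoints, the partition is
defined at base resolution:

* **cLAD** = intersection over all timepoints,
* **vLAD** = union minus intersection,
* **inter-LAD** = complement of the union.

The three classes are disjoint and tile the genome; both properties are
asserted in the tests on every synthetic instance. A per-base definition
(rather than, say, 50% reciprocal overlap) was chosen because downstream
statistics (bait membership, fold enrichment) are themselves base-level. An
externally supplied vLAD set can replace the union-minus-intersection
definition via the `vlads` argument, for workflows that import variable
LADs from a prior study.

**H3K4me1 regions in cLADs.** Peaks closer than `merge_gap` are clustered
and the clusters clipped to cLAD bounds; the remainder of the cLADs forms
the non-K4 class. `merge_gap` defaults to 10 kb: H3K4me1 peaks in these
euchromatic islands sit a few kb apart, and 10 kb joins peaks of one island
without bridging distinct islands (typically tens of kb apart). There is no
canonical published value; the parameter is exposed.

**Lamin contrast.** Region-level lamin log2(ChIP/input) means are
length-weighted over 1-kb bins; bins without data are excluded from the
weighting rather than imputed as zero, because a missing bin in a ratio
track means "no evidence", not "ratio zero". Classes are compared with an
unpaired two-tailed Welch t-test (Welch-Satterthwaite degrees of freedom);
the sampling unit is the region.

## Signal profiles

* `log2_ratio_track` computes `log2((chip + c) / (input + c))` per bin with
  pseudocount `c = 1` by default; bins where both signals are zero are
  missing. The pseudocount stabilises near-empty bins; it is configurable
  because no single value suits both sparse and deep tracks.
* `tss_metaprofile` averages a track at fixed offsets from each TSS over
  ±4 kb in 50-bp steps (161 positions). Minus-strand genes are mirrored so
  positive offsets always point downstream of transcription — the standard
  meta-profile convention. Genes whose window crosses a chromosome end
  contribute only covered positions, and the per-position contributing gene
  count is reported alongside the mean.
* An expressed gene has a normalized read count of at least 15 (boundary
  inclusive).
* Relative expression is `2^-((Ct_target - Ct_ref) - (Ct_target_cal -
  Ct_ref_cal))` against a reference gene and calibrator condition.

## Connectivity

Connection tables carry one row per bait-target link with a significance
p-value and timepoint. Loading keeps rows with `p <= 0.01` (inclusive),
pools all timepoints, and deduplicates baits on exact coordinates while
keeping connection multiplicity — a bait captured at three timepoints is one
bait with all its connections. Because a per-bait mean can be computed over
connections (with multiplicity) or over unique target coordinates, and
published figures do not always say which, `connection_density` reports
both; they coincide when no target repeats.

Bait classification: a cLAD bait is **K4** iff it overlaps, by at least
1 bp, an H3K4me1 peak lying in a cLAD (peaks are clipped to cLADs first).
The K4/nonK4 split partitions the cLAD baits exactly.

Target annotation assigns exactly one LAD class per target. The default
`largest_overlap` strategy takes the class contributing the most bases,
with ties broken cLAD > vLAD > inter-LAD; the alternative
`any_overlap_priority` strategy gives cLAD on any overlap, then vLAD, then
inter-LAD. Both are exposed because a base-level partition admits targets
that straddle class boundaries and a published "intersection" does not
determine the tie rule. H3K4me1 status is a separate >= 1 bp test.

## Chromatin states

**Binarization.** Per mark, a 200-bp bin is called present when the
upper-tail Poisson probability of its count under the genome-wide mean rate
is below `1e-4` — the conventional signal test for count tracks, with the
conventional defaults for bin size and threshold.

**Model.** A hidden Markov chain over `n_states` states with independent
Bernoulli emissions per mark (no mark covariance). Baum-Welch specifics:

* *Initialisation*: emissions start at the per-mark empirical call
  frequencies plus seeded uniform jitter in ±0.15 (clamped to
  [0.02, 0.98]); transitions start near-uniform with a sticky 0.9 diagonal.
  This is reproducible given the seed yet breaks the symmetry that would
  trap EM at a degenerate start.
* *Scaling*: forward and backward variables are rescaled per bin, so the
  log-likelihood is exact (checked to 1e-8 against exhaustive path
  enumeration on toy chains) with no underflow at genome scale.
* *Monotonicity*: the log-likelihood is checked at every iteration and a
  decrease beyond rounding (1e-8) is an error, not a warning.
* *Convergence*: EM stops when the gain drops below `tol` (1e-4) or at
  `max_iter`. Emissions are clamped to (1e-6, 1 - 1e-6) so likelihoods stay
  finite.
* *Label identity*: states are exchangeable; tests and any cross-seed
  comparison match states by best permutation of emission rows.

Decoding is by per-bin maximum of the forward-backward posterior by
default — appropriate because downstream statistics are per-bin coverage
summaries — with Viterbi available where a single coherent path is wanted.
`n_states` defaults to 15 to match common chromatin-state practice, but
parameter-recovery tests run at 2-4 states, where desk-scale chains
identify the parameters sharply.

**Fold enrichment** of an annotation over a state is
`((bases in state and annotation) / (bases in state)) /
((bases in annotation) / (genome size))`, applied verbatim per state;
states absent from a segmentation report `NA` rather than 0. **Target
attribution** assigns a target to every state it overlaps by >= 1 bp
(multi-counting by design); proportions are computed over attributions,
with options to exclude states (e.g. the quiescent state) and to flag
cells below a reporting floor such as 0.3%.

## FISH distances

An analyzable nucleus has exactly two red (gene) and two green (enhancer)
signals. Red-green pairing minimises the total distance over the two
possible one-to-one matchings, with ties resolved by input order; nuclei
with other multiplicities are excluded and listed. Distances are Euclidean
in µm. The nuclear boundary is modelled as an axis-aligned ellipsoid; the
distance from an interior probe to the surface is obtained from the unique
largest root of the Lagrange condition
`sum(a_i^2 p_i^2 / (a_i^2 + t)^2) = 1`, bracketed and solved to 1e-6 µm
(verified against dense surface sampling). Probes reported outside the
boundary get distance 0 with a warning, since segmentation noise in real
data can place a spot marginally outside the fitted boundary. A probe is
peripheral when its boundary distance is at most 2 µm (inclusive).
Conditions are compared with the same Welch t-test as everywhere else; the
sampling unit is the allele (100 alleles per condition at the default 50
nuclei), and the probe-to-periphery comparison is computed per channel
because gene and enhancer probes need not behave alike.

## Synthetic data: what it emulates, and what it does not

The generator draws one RNG stream per file type from the master seed, so
adding a component never perturbs the others, and regeneration from
`(config, seed)` is bit-identical. Defaults encode the study conditions the
pipeline is exercised under:

| parameter | default | meaning |
|---|---|---|
| genome | 3 × 2 Mb | toy genome, three chromosomes |
| timepoints | D0, D1, D3 | differentiation timecourse |
| cores per chromosome | 4 of 150-210 kb | constitutive LAD cores |
| flank_max | 40 kb | per-timepoint variable LAD edges |
| gaps | 3 per chromosome, 30 kb | euchromatic H3K4me1 islands in cLADs |
| lamin means | -0.5 / 1.0 / 0.0 log2 | inter-LAD / cLAD / gap levels (effect size 1.0) |
| K4 / nonK4 baits | 225 / 543 | cLAD bait classes |
| lambda_K4 / lambda_nonK4 | 27.5 / 14.7 | Poisson connections per bait |
| K4 target fractions | 0.7 / 0.2 / 0.1 | cLAD / vLAD / inter-LAD placement |
| in-peak fraction (K4) | 1/3 | cLAD targets inside an H3K4me1 peak |
| expression threshold | 15 | expressed / non-expressed split |
| HMM | 3 states, 2 marks, 200-bp bins | sticky chain (self 0.98), emissions 0.9/0.05 |
| mark counts | Poisson 40 / 0.5 | called vs background bins |
| TSS enrichment | amplitude 4, width 250 bp | Gaussian bump at expressed TSSs |
| FISH | 50 nuclei × 2 conditions, σ 0.8 µm | shifts +0.5 µm and -0.5 µm at two loci |

Realism notes and deliberate simplifications:

* LAD cores, vLAD blocks and inter-LAD zones live in fixed per-chromosome
  slots, which guarantees the architecture never collapses under resampling
  but also means LAD spacing is more regular than in real genomes.
* The chromatin-mark layer is sampled from its own Markov chain,
  *independent* of the LAD architecture and of target placement. Passing
  segmentation tests therefore demonstrates the correctness of the HMM and
  enrichment machinery, not a biological coupling between connectivity and
  chromatin state: target-over-state fold enrichment is ~1 on synthetic
  data by construction.
* The TSS enrichment bump uses a 250-bp Gaussian width — the sharpness
  typical of promoter-mark meta-profiles — so the profile summit is
  well-defined against sampling noise at the default gene count.
* FISH probes are placed near the ellipsoid surface (boundary distance
  mostly under 2 µm) and the green probe at a folded-normal distance from
  the red; distances are therefore slightly compressed relative to the
  nominal shift when the drawn distance would exit the nucleus.
* No read-level (FASTQ/BAM) structure, no copy number, no mappability, no
  inter-chromosomal contact structure is simulated.

## Problem sizes and numerical tolerances

Tests and the acceptance script run the generator at its default scale
(6 Mb genome, 768 baits, ~14,000 significant connections, 2 × 30,000 mark
bins, 200 nuclei), with HMM parameter-recovery at 10,000 bins and 2 states
— sizes at which every stage completes in seconds while keeping binomial
and EM error bands tight. Key tolerances: exact log-likelihood agreement to
1e-8 on enumerable chains; emission recovery to ±0.05 at 10,000 bins;
placement-fraction recovery within 3 binomial standard errors; ellipsoid
distances to 1e-6 µm.

## Known limitations

* vLADs derived as union-minus-intersection conflate "variable edge of a
  constitutive LAD" with "LAD present at a subset of timepoints"; both are
  vLAD here, as in the base-level definition.
* The Bernoulli emission model ignores mark covariance; marks that co-occur
  within a state are modelled as independent given the state.
* The ellipsoid boundary is a geometric idealisation of a DAPI-delineated
  nuclear surface; pre-measured distance tables can be supplied directly to
  bypass it.
* Welch tests treat regions, baits and alleles as independent sampling
  units; spatial autocorrelation along the genome and shared-nucleus
  effects are not modelled.
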
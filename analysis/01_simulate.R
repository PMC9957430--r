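#!/usr/bin/env Rscript
# Stage 1 — simulate the full input suite with known ground truth.
#
# Emits per-timepoint LAD BEDs, histone peak BEDs, a lamin log2(ChIP/input)
# track, gene models, a TSS-enrichment track, chromatin-mark count tracks
# sampled from a known Bernoulli HMM, the bait-target connection table and
# two-condition FISH coordinates, plus truth.json with every generating
# parameter. Downstream stages read only these files.

suppressMessages(library(ladconnect))

seed <- 1
outdir <- "results/synthetic_inputs"

truth <- generate_synthetic(synthetic_config(), seed = seed, outdir = outdir)

message("wrote synthetic inputs to ", outdir)
message("genome: ", paste(sprintf("%s=%d", names(truth$genome),
                                  as.integer(truth$genome)), collapse = ", "))
print(truth$partition)
message(nrow(truth$baits), " baits, ", nrow(truth$connections),
        " connection rows (incl. ",
        sum(truth$connections$is_noise), " non-significant)")
message(nrow(truth$fish$geometry), " FISH nuclei across ",
        length(truth$fish$shifts), " loci")
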
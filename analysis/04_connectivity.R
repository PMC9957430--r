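#!/usr/bin/env Rscript
# Stage 4 — bait classification and connection-density / target analysis.
#
# Loads the pooled bait-target connection table (p <= 0.01), keeps baits in
# cLADs, splits them into K4 (>= 1 bp overlap with an H3K4me1 peak in cLADs)
# and nonK4 baits, contrasts per-bait connection counts between the classes,
# and tabulates target proportions over LAD class x H3K4me1 status.

suppressMessages(library(ladconnect))

indir <- "results/synthetic_inputs"
outdir <- "results/connectivity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome(file.path(indir, "genome.tsv"))
lads <- lapply(c("D0", "D1", "D3"), function(tp) {
  read_bed(file.path(indir, sprintf("lads_%s.bed", tp)), genome)
})
partition <- derive_lad_partition(lads)
k4 <- read_bed(file.path(indir, "peaks_H3K4me1.bed"), genome)

lc <- load_connections(file.path(indir, "connections.tsv"), genome,
                       p_threshold = 0.01)
message(length(lc$baits), " distinct baits, ", nrow(lc$connections),
        " significant connections after pooling timepoints")

cb <- baits_in_clads(lc$baits, partition)
cls <- classify_baits(cb, k4, partition$clads)
print(cls)
write_bed(cls$baits, file.path(outdir, "clad_baits.bed"))

cd <- connection_density(lc$connections, cls)
write.table(cd$per_bait, file.path(outdir, "targets_per_bait.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cd$class_stats, file.path(outdir, "class_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
st <- cd$class_stats
message(sprintf("connections per bait: K4 mean %.1f vs nonK4 mean %.1f (Welch p = %.3g)",
                st$mean_connections[st$class == "K4"],
                st$mean_connections[st$class == "nonK4"], cd$welch$p_value))

ann <- annotate_targets(lc$connections, partition, k4,
                        strategy = "largest_overlap")
write_connections(ann, file.path(outdir, "annotated_connections.tsv"))
sp <- summarize_proportions(ann, cls)
write.table(sp, file.path(outdir, "target_proportions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (cl in c("K4", "nonK4")) {
  message(sprintf("%s bait targets: %.1f%% in cLADs (%.1f%% of all targets at an H3K4me1 site)",
                  cl, 100 * sum(sp$prop[sp$class == cl & sp$lad_class == "cLAD"]),
                  100 * sum(sp$prop[sp$class == cl & sp$k4_status == "in_K4_peak"])))
}
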
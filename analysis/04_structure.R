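#!/usr/bin/env Rscript
# Structural characterization: integration boundaries + deletion,
# array-internal inversions, foreign-DNA calls, and the tiling-path
# copy-number lower bound — each compared against the simulator truth.
suppressPackageStartupMessages(library(tgmap))
cs <- readRDS("results/locus/sim.rds")
segs <- read.table("results/segments.tsv", header = TRUE, sep = "\t")
tr <- cs$locus$truth

calls <- call_junctions(segs, cs$registry, reads = cs$sim$reads)
cat("integration calls (truth", tr$left_boundary, "/", tr$right_boundary,
    "/", tr$deletion_len, "bp):\n")
print(calls[, 1:8])

inv <- detect_inversions(segs, cs$registry)
cat(nrow(inv), "inversion events on",
    length(unique(inv$read_id)), "reads\n")
ct <- detect_contaminant(segs, cs$registry)
print(ct[, 1:4])

cls <- classify_reads(segs, cs$registry)
tp <- minimal_tiling_path(cs$sim$reads, segs, cls, cs$registry)
print(tp)

for (df in list(calls = calls, inversions = inv, contaminants = ct)) NULL
write.table(calls[, 1:8], "results/integration_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(inv, "results/inversions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ct[, 1:6], "results/contaminants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
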
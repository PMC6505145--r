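#!/usr/bin/env Rscript
# Align the simulated reads against the target registry (host contig,
# transgene unit, marker, contaminant) and write the segment table as
# TSV and PAF. ~100 reads align in a couple of seconds.
suppressPackageStartupMessages(library(tgmap))
cs <- readRDS("results/locus/sim.rds")

idx <- index_targets(cs$registry, k = 15)
segs <- align_reads(cs$sim$reads, idx)
write.table(segs, "results/segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_paf(segs, "results/segments.paf")

cat(sprintf("%d segments over %d reads; per-target: %s\n",
  nrow(segs), length(unique(segs$read_id)),
  paste(names(table(segs$target_id)), table(segs$target_id),
        sep = "=", collapse = ", ")))
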
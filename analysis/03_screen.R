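#!/usr/bin/env Rscript
# Whole-run statistics, marker-bearing read identification, and the
# depth-based copy-number estimate (marker matches / fold-coverage).
suppressPackageStartupMessages(library(tgmap))
cs <- readRDS("results/locus/sim.rds")
segs <- read.table("results/segments.tsv", header = TRUE, sep = "\t")

rs <- run_stats(cs$sim$reads, genome_size = nchar(cs$locus$haplotype))
print(rs)
cls <- classify_reads(segs, cs$registry, read_ids = names(cs$sim$reads))
write.table(cls, "results/classifications.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mc <- count_marker_matches(cls)
est <- copy_number_from_depth(mc$total_matches, rs$coverage)
print(est)
cat(sprintf("%d marker-bearing reads, %d matches, %d chimeric reads (truth: %d copies)\n",
  mc$reads_with_marker, mc$total_matches, sum(cls$chimeric),
  cs$locus$truth$copy_number))
jsonlite::write_json(list(run_stats = unclass(rs), marker = mc,
                          depth_estimate = unclass(est)),
                     "results/screen.json", auto_unbox = TRUE, digits = NA)
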
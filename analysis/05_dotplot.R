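#!/usr/bin/env Rscript
# Dot-plot views of the array structure: a junction-spanning read against
# the transgene unit (window 15, step 1). The inverted copy shows up as
# a reverse-orientation diagonal run.
suppressPackageStartupMessages(library(tgmap))
cs <- readRDS("results/locus/sim.rds")
segs <- read.table("results/segments.tsv", header = TRUE, sep = "\t")

# pick the read with most transgene alignment
tg <- segs[segs$target_id == cs$registry$unit_id, ]
best <- names(sort(tapply(tg$n_match, tg$read_id, sum), decreasing = TRUE))[1]
unit <- cs$registry$seqs[[cs$registry$unit_id]]
dm <- dot_matches(cs$sim$reads[[best]], unit, window = 15, step = 1)
write_dot_matches(dm, "results/dotplot_read_vs_unit.tsv")
runs <- segment_diagonals(dm, min_run = 20)
print(runs)
png("results/dotplot_read_vs_unit.png", 800, 600)
plot_dotplot(dm, xlab = paste("read", best), ylab = "transgene unit")
dev.off()
cat("read", best, ":", nrow(dm$matches), "window matches,",
    nrow(runs), "diagonal runs (", sum(runs$orientation == "reverse"),
    "reverse )\n")
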
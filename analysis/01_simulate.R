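#!/usr/bin/env Rscript
# Build the reference synthetic locus and sequence it.
#
# A 50 kb host contig receives a 6-copy tandem array of a 3 kb transgene
# unit (720 bp marker), with one inverted copy, a 6.2 kb foreign segment
# spliced into the array, and a 686 bp deletion of host sequence at the
# insertion point. Reads: 4x coverage, 10% total error, with anchored
# reads guaranteeing junction-spanning evidence. Everything downstream
# (02-07) works from the files written here.
suppressPackageStartupMessages(library(tgmap))
dir.create("results/locus", recursive = TRUE, showWarnings = FALSE)

cs <- sim_study_locus(seed = 11, error = "noisy", coverage = 4,
                      copy_number = 6, host_range = c(50000L, 50000L),
                      with_contaminant = TRUE)
write_fasta(cs$registry$seqs, "results/locus/targets.fasta")
write_reads_fastq(cs$sim, "results/locus/reads.fastq")
write_truth(cs$locus$truth, json_path = "results/locus/truth.json",
            bed_path = "results/locus/integration.bed")
saveRDS(cs, "results/locus/sim.rds")  # convenience for the later steps

tr <- cs$locus$truth
cat(sprintf("locus: %d bp host, %d copies (%d inverted), %d bp deletion,
  contaminant %d bp; haplotype %d bp; %d reads (%.0f bp)\n",
  tr$host_length, tr$copy_number, length(tr$inverted_copy_indices),
  tr$deletion_len, cs$contaminant_len, tr$haplotype_length,
  length(cs$sim$reads), sum(nchar(cs$sim$reads))))
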
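# Small shared fixtures, built in code at test time.

tiny_locus <- function(seed = 42, copies = 3L, inverted = 1L, del = 686L,
                       contaminant = NULL, host_len = 20000L) {
  make_locus(seed = seed, host_len = host_len, copy_number = copies,
             inverted_copy_indices = inverted, deletion_len = del,
             integration_pos = as.integer(host_len / 2),
             unit_length = 3000L, marker_length = 720L,
             contaminant = contaminant)
}

tiny_registry <- function(loc, contaminant = NULL) {
  target_registry(host = c(host = loc$host), transgene = loc$unit,
                  contaminant = contaminant)
}

# independent reverse complement through Biostrings (never the package's
# own revcomp), for oracle checks
bio_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
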
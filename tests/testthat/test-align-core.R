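test_that("index holds L - k + 1 positions and canonical keys", {
  idx <- index_targets(c(t1 = "ACGTACGTACGT"), k = 8)
  expect_equal(nrow(idx$dt), 5)
  # a target and its reverse complement share canonical k-mer keys
  s <- random_dna(200)
  i1 <- index_targets(c(a = s), k = 15)
  i2 <- index_targets(c(a = bio_revcomp(s)), k = 15)
  expect_setequal(i1$dt$code, i2$dt$code)
})

test_that("k larger than every target yields an empty index with warning", {
  expect_warning(
    expect_warning(idx <- index_targets(c(t1 = "ACGT"), k = 12), "shorter"),
    "empty")
  expect_equal(nrow(idx$dt), 0)
  expect_error(index_targets(list(), k = 15), "empty")
  expect_error(index_targets(c(a = "ACGTACGTACGTACGT"), k = 5), "\\[8, 26\\]")
})

test_that("an exact substring aligns as one full-identity + segment", {
  set.seed(21)
  tgt <- random_dna(5000)
  idx <- index_targets(c(t = tgt), k = 15)
  seg <- align_read(setNames(substr(tgt, 1001, 1500), "r"), idx)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$read_start, 0)
  expect_equal(seg$read_end, 500)
  expect_equal(seg$target_start, 1000)
  expect_equal(seg$target_end, 1500)
  expect_equal(seg$strand, "+")
  expect_equal(seg$n_match / seg$block_len, 1.0)
})

test_that("a reverse-complemented interval aligns on the minus strand", {
  set.seed(22)
  tgt <- random_dna(5000)
  idx <- index_targets(c(t = tgt), k = 15)
  seg <- align_read(setNames(bio_revcomp(substr(tgt, 2001, 3000)), "r"), idx)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$strand, "-")
  expect_equal(seg$target_start, 2000)
  expect_equal(seg$target_end, 3000)
})

test_that("segment coordinates agree with a Smith-Waterman oracle", {
  set.seed(23)
  tgt <- random_dna(2000)
  idx <- index_targets(c(t = tgt), k = 15)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in 1:20) {
    len <- sample(150:300, 1)
    s0 <- sample(1:(2000 - len), 1)
    rd <- substr(tgt, s0, s0 + len - 1)
    # ~5% substitutions
    nmut <- rbinom(1, len, 0.05)
    if (nmut > 0) {
      pos <- sample(len, nmut)
      ch <- strsplit(rd, "")[[1]]
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      rd <- paste(ch, collapse = "")
    }
    seg <- align_read(setNames(rd, "r"), idx, min_segment_len = 100)
    expect_equal(nrow(seg), 1)
    ora <- Biostrings::pairwiseAlignment(rd, tgt, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 2)
    expect_lte(abs(seg$target_start -
                     (Biostrings::start(Biostrings::subject(ora)) - 1)), 10)
    expect_lte(abs(seg$target_end -
                     Biostrings::end(Biostrings::subject(ora))), 10)
  }
})

test_that("aligning the reverse complement flips strands and reflects reads", {
  set.seed(24)
  tgt <- random_dna(4000)
  idx <- index_targets(c(t = tgt), k = 15)
  for (i in 1:5) {
    rd <- paste0(substr(tgt, 101, 900),
                 bio_revcomp(substr(tgt, 2001, 2800)))
    fw <- align_read(setNames(rd, "r"), idx)
    rc <- align_read(setNames(bio_revcomp(rd), "r"), idx)
    fw <- fw[order(fw$target_start), ]
    rc <- rc[order(rc$target_start), ]
    expect_equal(nrow(fw), nrow(rc))
    expect_equal(fw$target_start, rc$target_start)
    expect_true(all(fw$strand != rc$strand))
    L <- nchar(rd)
    expect_equal(fw$read_start, L - rc$read_end)
    expect_equal(fw$read_end, L - rc$read_start)
  }
})

test_that("error-free simulated reads are covered essentially end to end", {
  loc <- tiny_locus(seed = 31, copies = 3)
  reg <- tiny_registry(loc)
  idx <- index_targets(reg, k = 15)
  sim <- simulate_reads(c(hap = loc$haplotype),
                        read_sim_params(coverage_target = 0.8, sub_rate = 0,
                                        ins_rate = 0, del_rate = 0,
                                        min_read_len = 500L, seed = 32))
  segs <- align_reads(sim$reads, idx)
  covered <- 0; total <- 0
  for (id in names(sim$reads)) {
    sg <- segs[segs$read_id == id, ]
    expect_gt(nrow(sg), 0)
    cov <- IRanges::reduce(IRanges::IRanges(sg$read_start + 1, sg$read_end))
    # only flanks shorter than min_segment_len may be missed (they are
    # dropped by design); no interior holes
    expect_lte(nchar(sim$reads[[id]]) - sum(IRanges::width(cov)),
               2 * (200 + 15))
    covered <- covered + sum(IRanges::width(cov))
    total <- total + nchar(sim$reads[[id]])
  }
  expect_gte(covered / total, 0.99)
})

test_that("non-ACGTN read characters are rejected", {
  idx <- index_targets(c(t = random_dna(100)), k = 15)
  expect_error(align_read(c(r = "ACGTXACGTACGTACGTACGT"), idx), "ACGTN")
})

test_that("PAF round-trips alignment segments losslessly", {
  loc <- tiny_locus(seed = 33)
  reg <- tiny_registry(loc)
  idx <- index_targets(reg, k = 15)
  rd <- setNames(substr(loc$host, 5001, 6000), "r1")
  segs <- align_reads(rd, idx)
  p <- withr::local_tempfile(fileext = ".paf")
  write_paf(segs, p)
  back <- read_paf(p)
  expect_equal(back, segs)
})

test_that("PAF parsing skips malformed lines and rejects empty input", {
  good <- "q1\t1000\t0\t500\t-\tt1\t2000\t100\t600\t480\t500\t60"
  bad <- "not\ta\tpaf\tline"
  expect_warning(segs <- read_paf(c(good, bad)), "malformed")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$strand, "-")
  expect_equal(segs$n_match, 480)
  expect_error(suppressWarnings(read_paf(c(bad, bad))), "well-formed")
  expect_equal(nrow(read_paf(character(0))), 0)
})
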
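test_that("haplotype construction matches an independent concatenation", {
  loc <- tiny_locus(seed = 7, copies = 3, inverted = 1, del = 686)
  u <- loc$unit$sequence
  ip <- 10000L
  expected <- paste0(substr(loc$host, 1, ip),
                     u, bio_revcomp(u), u,
                     substr(loc$host, ip + 687L, 20000L))
  expect_identical(loc$haplotype, expected)
  expect_identical(loc$truth$left_boundary, ip)
  expect_identical(loc$truth$right_boundary, ip + 687L)
})

test_that("single-copy, no-deletion locus conserves length", {
  loc <- make_locus(seed = 1, host_len = 12000, copy_number = 1,
                    deletion_len = 0, integration_pos = 6000,
                    unit_length = 3000, marker_length = 720)
  expect_equal(nchar(loc$haplotype), 12000 + 3000)
})

test_that("length conservation holds across randomized parameter draws", {
  set.seed(11)
  for (i in 1:20) {
    C <- sample(1:8, 1)
    del <- sample(0:2000, 1)
    inv <- sample(0:(C - 1), sample(0:C, 1))
    has_ct <- runif(1) < 0.5
    ct <- if (has_ct) {
      list(sequence = random_dna(sample(500:3000, 1)),
           after_copy = sample(0:C, 1))
    }
    loc <- make_locus(seed = 100 + i, host_len = 30000, copy_number = C,
                      inverted_copy_indices = inv, deletion_len = del,
                      integration_pos = 15000, unit_length = 3000,
                      marker_length = 720, contaminant = ct)
    ctlen <- if (has_ct) nchar(ct$sequence) else 0L
    expect_equal(nchar(loc$haplotype),
                 30000 - del + C * 3000 + ctlen)
    expect_equal(loc$truth$deletion_len,
                 loc$truth$right_boundary - loc$truth$left_boundary - 1L)
  }
})

test_that("a spliced-in contaminant appears verbatim exactly once", {
  ct <- list(sequence = random_dna(6200), after_copy = 2)
  loc <- tiny_locus(seed = 9, copies = 4, inverted = integer(),
                    contaminant = ct)
  hits <- gregexpr(ct$sequence, loc$haplotype, fixed = TRUE)[[1]]
  expect_length(hits, 1)
  expect_equal(loc$truth$contaminant_interval[["offset"]], 2L * 3000L)
  expect_equal(loc$truth$contaminant_interval[["length"]], 6200L)
})

test_that("invalid coordinates and degenerate units are rejected", {
  expect_error(make_locus(seed = 1, host_len = 1000, copy_number = 1,
                          deletion_len = 600, integration_pos = 500,
                          unit_length = 3000, marker_length = 720),
               "coordinate")
  expect_error(make_locus(seed = 1, host_len = 10000, copy_number = 2,
                          inverted_copy_indices = 5,
                          integration_pos = 5000),
               "out of range")
  expect_error(transgene_unit(unit_length = 1000, marker_length = 720),
               "3x")
})

test_that("error-free reads are exact substrings of their source", {
  loc <- tiny_locus(seed = 3)
  sim <- simulate_reads(c(hap = loc$haplotype),
                        read_sim_params(coverage_target = 1, sub_rate = 0,
                                        ins_rate = 0, del_rate = 0,
                                        seed = 5))
  for (i in seq_len(min(10, length(sim$reads)))) {
    tt <- sim$truth[i, ]
    src <- substr(loc$haplotype, tt$start, tt$end)
    if (tt$strand == "-") src <- bio_revcomp(src)
    expect_identical(unname(sim$reads[[i]]), src)
  }
})

test_that("total simulated bases track the coverage target within 5%", {
  loc <- tiny_locus(seed = 8, host_len = 150000L, copies = 6)
  target <- 1.8 * nchar(loc$haplotype)
  sim <- simulate_reads(c(hap = loc$haplotype),
                        read_sim_params(coverage_target = 1.8, seed = 2))
  expect_lt(abs(sum(nchar(sim$reads)) - target) / target, 0.05)
})

test_that("the same seed reproduces byte-identical FASTQ output", {
  loc <- tiny_locus(seed = 4)
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  for (p in c(p1, p2)) {
    sim <- simulate_reads(c(hap = loc$haplotype),
                          read_sim_params(coverage_target = 0.5, seed = 77))
    write_reads_fastq(sim, p)
  }
  expect_identical(readLines(p1), readLines(p2))
  back <- read_seqs(p1, format = "fastq")
  expect_gt(length(back), 0)
})

test_that("empirical N50 converges to the log-normal law's implied N50", {
  p <- read_sim_params(coverage_target = 1, seed = 10)
  lens <- with(p, {
    set.seed(123)
    pmax(100, round(rlnorm(5000, length_log_mean, length_log_sd)))
  })
  expect_lt(abs(n50(lens) - lognormal_n50(p$length_log_mean,
                                          p$length_log_sd)) /
              lognormal_n50(p$length_log_mean, p$length_log_sd), 0.1)
})

test_that("error rates outside [0, 0.2] and bad haplotypes are rejected", {
  expect_error(read_sim_params(sub_rate = 0.3), "0.2")
  expect_error(simulate_reads(c(h = ""), read_sim_params(seed = 1)),
               "zero-length")
})

test_that("truth serializes to JSON and a BED integration interval", {
  loc <- tiny_locus(seed = 6)
  jp <- withr::local_tempfile(fileext = ".json")
  bp <- withr::local_tempfile(fileext = ".bed")
  write_truth(loc$truth, json_path = jp, bed_path = bp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$deletion_len, 686L)
  bed <- read.table(bp, sep = "\t")
  # BED is 0-based half-open over the deleted host bases
  expect_equal(bed$V3 - bed$V2, 686L)
})
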
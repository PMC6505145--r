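test_that("deletion length follows the retained-base convention", {
  expect_equal(deletion_length(124115870, 124116557), 686)
  expect_equal(deletion_length(100, 101), 0)
  expect_equal(deletion_length(100, 102), 1)
  expect_error(deletion_length(100, 100), "exceed")
  expect_error(deletion_length(100, 90), "exceed")
})

test_that("junction calls recover the simulated boundaries exactly", {
  loc <- tiny_locus(seed = 71, copies = 3, inverted = integer())
  reg <- tiny_registry(loc)
  idx <- index_targets(reg, k = 15)
  tr <- loc$truth
  arr_end <- tr$array_start + tr$array_length
  reads <- c(
    L_fwd = substr(loc$haplotype, tr$left_boundary - 1500,
                   tr$left_boundary + 1500),
    L_rev = bio_revcomp(substr(loc$haplotype, tr$left_boundary - 1500,
                               tr$left_boundary + 1500)),
    R_fwd = substr(loc$haplotype, arr_end - 1500, arr_end + 1500),
    R_rev = bio_revcomp(substr(loc$haplotype, arr_end - 1500,
                               arr_end + 1500)))
  segs <- align_reads(reads, idx)
  calls <- call_junctions(segs, reg, reads = reads)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$left_boundary, tr$left_boundary)
  expect_equal(calls$right_boundary, tr$right_boundary)
  expect_equal(calls$deletion_len, tr$deletion_len)
  expect_gte(calls$n_support_left, 2)
  expect_gte(calls$n_support_right, 2)
})

test_that("reads without transgene adjacency produce no junction calls", {
  loc <- tiny_locus(seed = 72)
  reg <- tiny_registry(loc)
  idx <- index_targets(reg, k = 15)
  reads <- setNames(substr(loc$host, 1001, 4000), "hostread")
  segs <- align_reads(reads, idx)
  expect_equal(nrow(call_junctions(segs, reg, reads = reads)), 0)
})

test_that("strand alternations define inversion events", {
  reg <- structure(list(
    seqs = c(u = strrep("A", 10)), roles = c(u = "transgene"),
    marker_interval = NULL, unit_id = "u", marker_id = NA,
    marker_length = 0), class = "tg_registry")
  seg <- function(rs, re, strand) data.frame(
    read_id = "r", read_len = 5000, read_start = rs, read_end = re,
    target_id = "u", target_len = 3000, target_start = 0,
    target_end = re - rs, strand = strand, n_match = re - rs,
    block_len = re - rs)
  none <- do.call(rbind, list(seg(0, 1000, "+"), seg(1010, 2000, "+"),
                              seg(2010, 3000, "+")))
  expect_equal(nrow(detect_inversions(none, reg)), 0)
  one <- rbind(seg(0, 1000, "+"), seg(1010, 2000, "-"))
  ev <- detect_inversions(one, reg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$read_position, 1005)
  expect_equal(ev$from_strand, "+")
})

test_that("inversions in a simulated array are found with accurate positions", {
  loc <- tiny_locus(seed = 73, copies = 3, inverted = 1L)
  reg <- tiny_registry(loc)
  idx <- index_targets(reg, k = 15)
  tr <- loc$truth
  a0 <- tr$array_start
  # reads spanning copy 0|1 and 1|2 transitions, one per orientation
  reads <- c(
    f1 = substr(loc$haplotype, a0 + 2000, a0 + 4500),
    r1 = bio_revcomp(substr(loc$haplotype, a0 + 2000, a0 + 4500)),
    f2 = substr(loc$haplotype, a0 + 5000, a0 + 7500))
  segs <- align_reads(reads, idx)
  ev <- detect_inversions(segs, reg)
  expect_gte(nrow(ev), 3)  # every read spans one flip
  # map events to haplotype coordinates and compare to the copy edges
  flips_true <- a0 + c(3000, 6000)
  pos <- c(a0 + 2000 - 1 + ev$read_position[ev$read_id == "f1"],
           a0 + 4500 - ev$read_position[ev$read_id == "r1"],
           a0 + 5000 - 1 + ev$read_position[ev$read_id == "f2"])
  err <- vapply(pos, function(p) min(abs(p - flips_true)), numeric(1))
  expect_true(all(err <= 100))
})

test_that("contaminant calls report span, bounding and lower-bound status", {
  ct <- list(sequence = random_dna(6200), after_copy = 2)
  loc <- tiny_locus(seed = 74, copies = 4, inverted = integer(),
                    contaminant = ct)
  reg <- tiny_registry(loc, contaminant = c(ecoli = ct$sequence))
  idx <- index_targets(reg, k = 15)
  c0 <- loc$truth$array_start + loc$truth$contaminant_interval[["offset"]]
  spanning <- setNames(substr(loc$haplotype, c0 - 800, c0 + 6200 + 800),
                       "spanning")
  terminating <- setNames(substr(loc$haplotype, c0 - 800, c0 + 3000),
                          "terminating")
  segs_t <- align_reads(terminating, idx)
  call_t <- detect_contaminant(segs_t, reg)
  expect_equal(nrow(call_t), 1)
  expect_false(call_t$bounded_by_reads)
  expect_lt(call_t$observed_length, 6200)

  segs_s <- align_reads(spanning, idx)
  call_s <- detect_contaminant(segs_s, reg)
  expect_true(call_s$bounded_by_reads)
  expect_equal(call_s$observed_length, 6200)

  no_ct <- align_reads(setNames(substr(loc$host, 1, 2000), "h"), idx)
  expect_equal(nrow(detect_contaminant(no_ct, reg)), 0)
})

test_that("tiling path bounds copies from a single read", {
  loc <- tiny_locus(seed = 75, copies = 3, inverted = integer())
  reg <- tiny_registry(loc)
  idx <- index_targets(reg, k = 15)
  a0 <- loc$truth$array_start
  reads <- setNames(substr(loc$haplotype, a0 + 1, a0 + 6000), "two_copies")
  segs <- align_reads(reads, idx)
  cls <- classify_reads(segs, reg)
  tp <- minimal_tiling_path(reads, segs, cls, reg)
  expect_equal(tp$lower_bound_copies, 2)
  expect_equal(length(tp$read_ids), 1)
})

test_that("three overlapping reads tile a 5-copy array", {
  # real tandem arrays accumulate small divergence between copies; ~1.5%
  # substitutions per copy make read overlaps uniquely placeable, the
  # regime the three-read example assumes
  set.seed(760)
  host <- random_dna(30000)
  unit <- transgene_unit(unit_length = 3000, marker_length = 720)
  diverge <- function(s, rate = 0.015) {
    ch <- strsplit(s, "")[[1]]
    pos <- which(runif(length(ch)) < rate)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  copies <- vapply(1:5, function(i) diverge(unit$sequence), character(1))
  a0 <- 15000L
  hap <- paste0(substr(host, 1, a0), paste(copies, collapse = ""),
                substr(host, a0 + 687, 30000))
  reg <- target_registry(host = c(host = host), transgene = unit)
  idx <- index_targets(reg, k = 15)
  reads <- c(
    r1 = substr(hap, a0 - 1000, a0 + 6000),
    r2 = substr(hap, a0 + 5000, a0 + 11000),
    r3 = bio_revcomp(substr(hap, a0 + 10000, a0 + 15000 + 500)))
  segs <- align_reads(reads, idx)
  cls <- classify_reads(segs, reg)
  tp <- minimal_tiling_path(reads, segs, cls, reg, min_overlap = 500)
  expect_equal(length(tp$read_ids), 3)
  expect_equal(tp$lower_bound_copies, 5)

  # exhaustive oracle: the smallest read subset whose true intervals
  # chain with >= 500 bp overlaps and cover all five marker copies
  truth_iv <- list(r1 = c(a0 - 1000, a0 + 6000),
                   r2 = c(a0 + 5000, a0 + 11000),
                   r3 = c(a0 + 10000, a0 + 15500))
  m0 <- unit$marker_interval[1]
  mk <- data.frame(hap_start = a0 + (0:4) * 3000L + m0 + 1L,
                   hap_end = a0 + (0:4) * 3000L + unit$marker_interval[2])
  best <- Inf
  for (m in 1:3) {
    for (sub in combn(3, m, simplify = FALSE)) {
      iv <- truth_iv[sub]
      iv <- iv[order(vapply(iv, `[`, numeric(1), 1))]
      ok <- TRUE
      if (length(iv) > 1) {
        for (i in seq_len(length(iv) - 1)) {
          if (iv[[i]][2] - iv[[i + 1]][1] < 500) ok <- FALSE
        }
      }
      covered <- all(vapply(seq_len(nrow(mk)), function(j) {
        any(vapply(iv, function(v)
          v[1] <= mk$hap_start[j] & v[2] >= mk$hap_end[j], logical(1)))
      }, logical(1)))
      if (ok && covered) best <- min(best, m)
    }
  }
  expect_equal(length(tp$read_ids), best)
})

test_that("tiling requires marker-bearing evidence", {
  loc <- tiny_locus(seed = 77)
  reg <- tiny_registry(loc)
  cls <- data.frame(read_id = "r", marker_match_count = 0L,
                    has_host = TRUE, has_transgene = FALSE,
                    has_contaminant = FALSE, chimeric = FALSE)
  expect_error(minimal_tiling_path(c(r = "ACGT"), NULL, cls, reg),
               "empty evidence")
})
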
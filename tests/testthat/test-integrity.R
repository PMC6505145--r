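host_seg <- function(id, ts, te, chrom = "host") data.frame(
  read_id = id, read_len = te - ts, read_start = 0, read_end = te - ts,
  target_id = chrom, target_len = 50000, target_start = ts,
  target_end = te, strand = "+", n_match = te - ts, block_len = te - ts)

fake_registry <- function() structure(list(
  seqs = c(host = strrep("A", 100)), roles = c(host = "host"),
  marker_interval = NULL, unit_id = NA, marker_id = NA,
  marker_length = 0), class = "tg_registry")

genes5 <- data.frame(
  gene = c("g1", "g2", "g2", "g3"),
  chrom = "host", strand = "+",
  start = c(1000L, 5000L, 7000L, 20000L),
  end = c(3000L, 6000L, 8000L, 24000L))

test_that("a read spanning the contig encompasses every gene", {
  segs <- host_seg("big", 0, 50000)
  res <- gene_integrity(genes5, segs, fake_registry())
  expect_true(all(res$encompassed))
  expect_true(all(res$uncovered_bp == 0))
})

test_that("without reads every CDS span is uncovered", {
  res <- gene_integrity(genes5, host_seg("x", 0, 10)[0, ], fake_registry())
  expect_true(all(!res$encompassed))
  expect_equal(res$uncovered_bp[res$gene == "g2"], 3000)  # span 5000-8000
})

test_that("encompassing needs one read; coverage unions across reads", {
  segs <- rbind(host_seg("a", 500, 5500), host_seg("b", 5400, 9000))
  res <- gene_integrity(genes5, segs, fake_registry())
  expect_true(res$encompassed[res$gene == "g1"])
  # g2's span is covered only by the union, not by a single read
  expect_false(res$encompassed[res$gene == "g2"])
  expect_equal(res$uncovered_bp[res$gene == "g2"], 0)
})

test_that("fragmented host alignments merge across small gaps only", {
  segs <- rbind(host_seg("a", 500, 2000), host_seg("a", 2500, 3500))
  res <- gene_integrity(genes5, segs, fake_registry(), span_gap = 1000)
  expect_true(res$encompassed[res$gene == "g1"])
  res2 <- gene_integrity(genes5, segs, fake_registry(), span_gap = 100)
  expect_false(res2$encompassed[res2$gene == "g1"])
})

test_that("an integration call inside a CDS flags that gene as disrupted", {
  segs <- host_seg("big", 0, 50000)
  calls <- data.frame(chrom = "host", left_boundary = 21000L,
                      right_boundary = 21687L, deletion_len = 686L)
  res <- gene_integrity(genes5, segs, fake_registry(), integration = calls)
  expect_true(res$disrupted[res$gene == "g3"])
  expect_false(any(res$disrupted[res$gene != "g3"]))
})

test_that("genes on unknown contigs get an error entry, others proceed", {
  gm <- rbind(genes5, data.frame(gene = "g9", chrom = "chrX", strand = "+",
                                 start = 0L, end = 100L))
  res <- gene_integrity(gm, host_seg("big", 0, 50000), fake_registry())
  expect_equal(res$error[res$gene == "g9"], "unknown contig")
  expect_true(all(is.na(res$error[res$gene != "g9"])))
})

test_that("coverage union arithmetic equals a per-base bitmap oracle", {
  set.seed(81)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    segs <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(0:45000, 1)
      host_seg(paste0("r", i), s, s + sample(500:5000, 1))
    }))
    res <- gene_integrity(genes5, segs, fake_registry())
    bitmap <- logical(50000)
    for (i in seq_len(nrow(segs))) {
      bitmap[(segs$target_start[i] + 1):segs$target_end[i]] <- TRUE
    }
    for (g in unique(genes5$gene)) {
      gm <- genes5[genes5$gene == g, ]
      span <- (min(gm$start) + 1):max(gm$end)
      expect_equal(res$uncovered_bp[res$gene == g], sum(!bitmap[span]))
    }
  }
})

test_that("adding reads never shrinks encompassment or grows gaps", {
  set.seed(82)
  segs <- host_seg("a", 800, 4000)
  res1 <- gene_integrity(genes5, segs, fake_registry())
  segs2 <- rbind(segs, host_seg("b", 4500, 9000), host_seg("c", 0, 30000))
  res2 <- gene_integrity(genes5, segs2, fake_registry())
  expect_true(all(res2$encompassed >= res1$encompassed))
  expect_true(all(res2$uncovered_bp <= res1$uncovered_bp))
})

test_that("gap proposals extend, clip and merge uncovered intervals", {
  res <- gene_integrity(genes5, host_seg("x", 0, 10)[0, ], fake_registry())
  expect_equal(nrow(propose_gap_intervals(res[res$uncovered_bp == 0, ])), 0)

  one <- res[res$gene == "g1", ]  # uncovered [1000, 3000)
  gaps <- propose_gap_intervals(one, flank = 300)
  expect_equal(gaps$start, 700)
  expect_equal(gaps$end, 3300)

  two <- res[res$gene == "g2", ]  # uncovered [5000,6000) and [7000,8000)
  merged <- propose_gap_intervals(two, flank = 600)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 4400)
  expect_equal(merged$end, 8600)
  clipped <- propose_gap_intervals(one, flank = 2000,
                                   contig_lengths = c(host = 3500))
  expect_equal(clipped$end, 3500)
})

test_that("gene models load from GFF3 and BED12", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "host\ttest\tgene\t1001\t3000\t.\t+\t.\tID=gene1;Name=g1",
    "host\ttest\tCDS\t1001\t2000\t.\t+\t0\tParent=gene1;gene=g1",
    "host\ttest\tCDS\t2501\t3000\t.\t+\t0\tParent=gene1;gene=g1"), gff)
  gm <- read_gene_models(gff)
  expect_equal(nrow(gm), 2)
  expect_equal(gm$gene, c("g1", "g1"))
  expect_equal(gm$start, c(1000, 2500))
  expect_equal(gm$end, c(2000, 3000))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("host", 1000, 3000, "g1", 0, "+", 1000, 3000, "0", 2,
                   "1000,500", "0,1500", sep = "\t"), bed)
  gmb <- read_gene_models(bed)
  expect_equal(nrow(gmb), 2)
  expect_equal(gmb$start, c(1000, 2500))
  expect_equal(gmb$end, c(2000, 3000))
})
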
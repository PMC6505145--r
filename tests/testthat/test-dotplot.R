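# exhaustive all-pairs window comparison, independent of the hashed path
brute_dot <- function(x, y, w, step = 1, mm = 0) {
  xs <- seq(1, nchar(x) - w + 1, by = step)
  ys <- seq(1, nchar(y) - w + 1, by = step)
  rows <- list()
  for (a in xs) {
    wx <- substr(x, a, a + w - 1)
    for (b in ys) {
      wy <- substr(y, b, b + w - 1)
      dm <- sum(strsplit(wx, "")[[1]] != strsplit(wy, "")[[1]])
      if (dm <= mm) rows[[length(rows) + 1]] <-
          data.frame(x = a - 1, y = b - 1, orientation = "forward")
      wyr <- bio_revcomp(wy)
      dr <- sum(strsplit(wx, "")[[1]] != strsplit(wyr, "")[[1]])
      if (dr <= mm) rows[[length(rows) + 1]] <-
          data.frame(x = a - 1, y = b - 1, orientation = "reverse")
    }
  }
  if (length(rows) == 0) {
    return(data.frame(x = integer(), y = integer(),
                      orientation = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$orientation, out$x, out$y), ]
}

test_that("self comparison yields the identity diagonal", {
  set.seed(61)
  s <- random_dna(20)
  dm <- dot_matches(s, s, window = 15, step = 1)
  fw <- dm$matches[dm$matches$orientation == "forward", ]
  expect_equal(nrow(fw), 6)
  expect_true(all(fw$x == fw$y))
})

test_that("reverse-complement input lands on the antidiagonal", {
  set.seed(62)
  s <- random_dna(60)
  dm <- dot_matches(s, bio_revcomp(s), window = 15)
  fw <- dm$matches[dm$matches$orientation == "forward", ]
  rv <- dm$matches[dm$matches$orientation == "reverse", ]
  expect_equal(nrow(fw), 0)
  expect_true(all(rv$x + rv$y == 60 - 15))
  expect_equal(nrow(rv), 46)
})

test_that("hashed matcher equals the exhaustive oracle on random pairs", {
  set.seed(63)
  for (i in 1:5) {
    x <- random_dna(60); y <- random_dna(60)
    got <- dot_matches(x, y, window = 8)$matches
    ora <- brute_dot(x, y, 8)
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora)
  }
  # fuzzy windows take the all-pairs path; same oracle with mismatches
  x <- random_dna(50); y <- random_dna(50)
  got <- dot_matches(x, y, window = 10, max_mismatch = 2)$matches
  ora <- brute_dot(x, y, 10, mm = 2)
  rownames(got) <- rownames(ora) <- NULL
  expect_equal(got, ora)
})

test_that("forward matches transpose under argument swap", {
  set.seed(64)
  x <- random_dna(80); y <- random_dna(80)
  # ensure some shared content
  y <- paste0(substr(x, 11, 40), y)
  m1 <- dot_matches(x, y, window = 12)$matches
  m2 <- dot_matches(y, x, window = 12)$matches
  f1 <- m1[m1$orientation == "forward", c("x", "y")]
  f2 <- m2[m2$orientation == "forward", c("y", "x")]
  names(f2) <- c("x", "y")
  expect_equal(f1[order(f1$x, f1$y), ], f2[order(f2$x, f2$y), ],
               ignore_attr = TRUE)
})

test_that("window count conservation holds for stepped self-matches", {
  set.seed(65)
  s <- random_dna(101)
  for (step in c(1, 3, 5)) {
    dm <- dot_matches(s, s, window = 15, step = step)
    fw <- dm$matches[dm$matches$orientation == "forward" &
                       dm$matches$x == dm$matches$y, ]
    expect_equal(nrow(fw), floor((101 - 15) / step) + 1)
  }
})

test_that("diagonal runs segment by orientation", {
  set.seed(66)
  u <- random_dna(40)
  dm <- dot_matches(u, u, window = 15)
  runs <- segment_diagonals(dm)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$orientation, "forward")
  expect_equal(runs$run_length, 26)

  # U + revcomp(U) against U: one forward and one reverse run, adjacent
  cat2 <- paste0(u, bio_revcomp(u))
  dm2 <- dot_matches(cat2, u, window = 15)
  runs2 <- segment_diagonals(dm2, min_run = 5)
  expect_equal(sort(runs2$orientation), c("forward", "reverse"))
  fw <- runs2[runs2$orientation == "forward", ]
  rv <- runs2[runs2$orientation == "reverse", ]
  expect_lt(fw$x1, rv$x0 + 15)

  empty <- dot_matches(random_dna(30), random_dna(30), window = 20)
  expect_equal(nrow(segment_diagonals(empty)), 0)
})

test_that("a window longer than a sequence is rejected", {
  expect_error(dot_matches("ACGTACGT", "ACGT", window = 6), "window")
})

test_that("matches write to TSV and render as a plot", {
  set.seed(67)
  s <- random_dna(40)
  dm <- dot_matches(s, s, window = 15)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dot_matches(dm, p)
  back <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(dm$matches))
  pfile <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pfile)
  plot_dotplot(dm)
  grDevices::dev.off()
  expect_true(file.size(pfile) > 0)
})
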
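wells <- function(sample, marker_ct, hk_ct) {
  data.frame(sample_id = sample,
             assay = rep(c("marker", "housekeeping"),
                         c(length(marker_ct), length(hk_ct))),
             ct = c(marker_ct, hk_ct),
             replicate = c(seq_along(marker_ct), seq_along(hk_ct)))
}

test_that("equal delta-Ct gives RQ 1 and one cycle doubles RQ", {
  ct <- rbind(wells("test", c(25, 25), c(20, 20)),
              wells("calibrator", c(25, 25), c(20, 20)))
  rq <- delta_delta_ct(ct, calibrator = "calibrator")
  expect_equal(rq$rq[rq$sample_id == "test"], 1)

  ct2 <- rbind(wells("test", c(24, 24), c(20, 20)),
               wells("calibrator", c(25, 25), c(20, 20)))
  rq2 <- delta_delta_ct(ct2, calibrator = "calibrator")
  expect_equal(rq2$rq[rq2$sample_id == "test"], 2)
})

test_that("simulated noisy batches recover RQ near the true copy ratio", {
  rqs <- vapply(1:30, function(b) {
    ct <- simulate_ct_batch(26, n_replicates = 6, noise_sd = 0.15,
                            seed = 9000 + b)
    rq <- delta_delta_ct(ct, calibrator = "calibrator")
    rq$rq[rq$sample_id == "test"]
  }, numeric(1))
  expect_lt(abs(mean(rqs) - 26) / 26, 0.10)
})

test_that("copies per allele rescale by calibrator copies and zygosity", {
  expect_equal(copies_per_allele(1, 1, 1)$value, 1)
  est <- copies_per_allele(52, calibrator_copies_per_genome = 1,
                           test_alleles = 2)
  expect_equal(est$value, 26)
  expect_equal(est$method, "qpcr")
  # heterozygote and homozygote of the same line agree per allele
  expect_equal(copies_per_allele(26, 1, 1)$value,
               copies_per_allele(52, 1, 2)$value)
  expect_error(copies_per_allele(0), "RQ")
  expect_error(copies_per_allele(26, test_alleles = 3), "alleles")
})

test_that("RQ is invariant to constant shifts of one sample's Ct values", {
  ct <- rbind(wells("test", c(24.1, 24.3, 23.9), c(20.2, 19.9, 20.0)),
              wells("calibrator", c(28.0, 28.2), c(20.1, 20.0)))
  rq1 <- delta_delta_ct(ct, calibrator = "calibrator")
  ct2 <- ct
  shift <- ct2$sample_id == "test"
  ct2$ct[shift] <- ct2$ct[shift] + 3
  rq2 <- delta_delta_ct(ct2, calibrator = "calibrator")
  expect_equal(rq1$rq, rq2$rq)
})

test_that("RQ is strictly decreasing in the test sample's marker Ct", {
  base <- wells("calibrator", c(28, 28), c(20, 20))
  rqs <- vapply(c(23, 24, 25, 26), function(mct) {
    ct <- rbind(wells("test", c(mct, mct), c(20, 20)), base)
    rq <- delta_delta_ct(ct, calibrator = "calibrator")
    rq$rq[rq$sample_id == "test"]
  }, numeric(1))
  expect_true(all(diff(rqs) < 0))
})

test_that("jackknife dispersion is reported and propagated", {
  ct <- simulate_ct_batch(5, n_replicates = 6, noise_sd = 0.2, seed = 31)
  rq <- delta_delta_ct(ct, calibrator = "calibrator")
  test_row <- rq[rq$sample_id == "test", ]
  expect_gt(test_row$rq_sd, 0)
  est <- copies_per_allele(test_row)
  expect_gt(est$dispersion, 0)
})

test_that("missing assays and invalid Ct values are rejected by name", {
  ct <- rbind(wells("test", c(24, 24), numeric(0)),
              wells("calibrator", c(25, 25), c(20, 20)))
  expect_error(delta_delta_ct(ct, calibrator = "calibrator"),
               "test.*housekeeping")
  bad <- rbind(wells("test", c(44, 24), c(20, 20)),
               wells("calibrator", c(25, 25), c(20, 20)))
  expect_error(delta_delta_ct(bad, calibrator = "calibrator"), "0, 40")
  ok <- rbind(wells("test", c(24, 24), c(20, 20)))
  expect_error(delta_delta_ct(ok, calibrator = "nope"), "calibrator")
})
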
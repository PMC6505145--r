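#' Relative quantification from qPCR Ct values
#'
#' Classic comparative-Ct: for each sample,
#' `dCt = mean(Ct_marker) - mean(Ct_housekeeping)`; against the calibrator
#' sample, `ddCt = dCt_test - dCt_calibrator` and
#' `RQ = efficiency^(-ddCt)`. A jackknife over the test sample's marker
#' replicates supplies the RQ dispersion.
#'
#' @param ct data.frame of wells: `sample_id`, `assay` (`"marker"` or
#'   `"housekeeping"`), `ct` (cycles, 0 < ct < 40), `replicate`.
#' @param calibrator Sample id of the calibrator.
#' @param efficiency Amplification efficiency as fold change per cycle
#'   (default 2 = 100%).
#' @return data.frame per sample: `sample_id`, `dct`, `ddct`, `rq`,
#'   `rq_sd`, `n_marker`, `n_housekeeping`.
#' @export
delta_delta_ct <- function(ct, calibrator, efficiency = 2) {
  stopifnot(all(c("sample_id", "assay", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 40)) {
    stop("Ct values must lie in (0, 40)", call. = FALSE)
  }
  if (!calibrator %in% ct$sample_id) {
    stop("calibrator sample '", calibrator, "' not in Ct table",
         call. = FALSE)
  }
  samples <- unique(ct$sample_id)
  for (s in samples) {
    for (a in c("marker", "housekeeping")) {
      if (!any(ct$sample_id == s & ct$assay == a)) {
        stop("sample '", s, "' is missing assay '", a, "'", call. = FALSE)
      }
    }
  }
  dct_of <- function(s, drop_marker = NULL) {
    m <- ct$ct[ct$sample_id == s & ct$assay == "marker"]
    if (!is.null(drop_marker)) m <- m[-drop_marker]
    h <- ct$ct[ct$sample_id == s & ct$assay == "housekeeping"]
    mean(m) - mean(h)
  }
  dct_cal <- dct_of(calibrator)
  rows <- lapply(samples, function(s) {
    nm <- sum(ct$sample_id == s & ct$assay == "marker")
    nh <- sum(ct$sample_id == s & ct$assay == "housekeeping")
    dct <- dct_of(s)
    ddct <- dct - dct_cal
    rq <- efficiency^(-ddct)
    rq_sd <- NA_real_
    if (nm > 1) {
      jk <- vapply(seq_len(nm), function(i)
        efficiency^(-(dct_of(s, i) - dct_cal)), numeric(1))
      rq_sd <- sqrt((nm - 1) / nm * sum((jk - mean(jk))^2))
    }
    data.frame(sample_id = s, dct = dct, ddct = ddct, rq = rq,
               rq_sd = rq_sd, n_marker = nm, n_housekeeping = nh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert relative quantity to copies per allele
#'
#' The test sample's marker copies per genome are
#' `RQ * calibrator_copies_per_genome`; dividing by the number of
#' transgene-bearing alleles gives copies per allele. The calibrator's
#' zygosity convention (1 marker copy per diploid genome by default) is
#' configurable because it is rarely stated for reference animals; both
#' conventions can be reported.
#'
#' @param rq Relative quantity (> 0), or a row of [delta_delta_ct()]
#'   output.
#' @param calibrator_copies_per_genome Marker copies per genome in the
#'   calibrator (default 1).
#' @param test_alleles Transgene-bearing alleles in the test sample: 1
#'   (heterozygous) or 2 (homozygous).
#' @param rq_sd Optional RQ dispersion to propagate.
#' @return A `tg_copy_estimate` with `method = "qpcr"`.
#' @export
copies_per_allele <- function(rq, calibrator_copies_per_genome = 1,
                              test_alleles = 1, rq_sd = NA_real_) {
  if (is.data.frame(rq)) {
    rq_sd <- rq$rq_sd[1]
    rq <- rq$rq[1]
  }
  if (!test_alleles %in% c(1, 2)) {
    stop("test_alleles must be 1 or 2", call. = FALSE)
  }
  if (rq <= 0) stop("RQ must be > 0", call. = FALSE)
  scale <- calibrator_copies_per_genome / test_alleles
  new_copy_estimate("qpcr", rq * scale,
                    dispersion = if (is.na(rq_sd)) NA_real_ else rq_sd * scale,
                    n_support = NA_integer_)
}

#' Simulate a qPCR batch with known copy number
#'
#' Generates marker and housekeeping Ct wells for a test sample carrying
#' `true_copies` marker copies per transgene allele and a calibrator with
#' `calibrator_copies_per_genome` copies, under Gaussian Ct noise — the
#' closed-form test bed for the comparative-Ct chain.
#'
#' @param true_copies Marker copies per allele in the test sample.
#' @param test_alleles 1 (heterozygous) or 2 (homozygous).
#' @param calibrator_copies_per_genome Copies per genome in the calibrator.
#' @param n_replicates Wells per sample/assay.
#' @param noise_sd Ct noise SD in cycles.
#' @param efficiency Amplification efficiency (fold per cycle).
#' @param seed Integer seed.
#' @return data.frame of wells suitable for [delta_delta_ct()] (calibrator
#'   sample id `"calibrator"`, test `"test"`).
#' @export
simulate_ct_batch <- function(true_copies, test_alleles = 1,
                              calibrator_copies_per_genome = 1,
                              n_replicates = 3, noise_sd = 0.15,
                              efficiency = 2, seed = 1L) {
  with_seed(seed, {
    base_hk <- 20; base_m <- 24
    copies_pg <- c(test = true_copies * test_alleles,
                   calibrator = calibrator_copies_per_genome)
    rows <- list()
    for (s in names(copies_pg)) {
      ct_m <- base_m - log(copies_pg[[s]], base = efficiency) +
        stats::rnorm(n_replicates, 0, noise_sd)
      ct_h <- base_hk + stats::rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s,
        assay = rep(c("marker", "housekeeping"), each = n_replicates),
        ct = c(ct_m, ct_h), replicate = rep(seq_len(n_replicates), 2),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
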
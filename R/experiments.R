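#' Simulate one study locus under the package's reference conditions
#'
#' The reference conditions mirror the architecture the pipeline is built
#' for, scaled to desk size: a 50-200 kb host contig, a 3 kb transgene
#' unit carrying a 720 bp marker, 6/18/26 tandem copies with one internal
#' inversion, a 686 bp host deletion at the integration site, and (on
#' alternate seeds) a 6.2 kb foreign-DNA segment spliced into the array.
#' Reads are drawn at the requested coverage with three additional reads
#' anchored across each junction, so that junction-spanning evidence — the
#' precondition for boundary calling — is present by construction.
#'
#' @param seed Integer seed driving every random choice.
#' @param error `"none"` for error-free reads, `"noisy"` for 10% total
#'   error (5% substitution, 2.5% insertion, 2.5% deletion).
#' @param coverage Fold-coverage of the haplotype.
#' @param copy_number Copies in the array; `NULL` draws from {6, 18, 26}.
#' @param host_range Host length range in bp.
#' @param with_contaminant `NULL` (alternate by seed), or logical.
#' @return List: `locus` (from [make_locus()]), `registry`, `sim` (from
#'   [simulate_reads()]), `contaminant_len`.
#' @export
sim_study_locus <- function(seed, error = c("none", "noisy"), coverage = 2,
                            copy_number = NULL,
                            host_range = c(50000L, 200000L),
                            with_contaminant = NULL) {
  error <- match.arg(error)
  draws <- with_seed(seed * 1000L + 1L, {
    list(host_len = host_range[1] +
           sample.int(host_range[2] - host_range[1] + 1L, 1) - 1L,
         copies = if (is.null(copy_number)) sample(c(6L, 18L, 26L), 1)
                  else as.integer(copy_number),
         contam = if (is.null(with_contaminant)) seed %% 2L == 0L
                  else with_contaminant)
  })
  inv_idx <- with_seed(seed * 1000L + 2L,
                       sample(0:(draws$copies - 1L), 1))
  contaminant <- NULL
  contam_seq <- NULL
  if (draws$contam) {
    contam_seq <- with_seed(seed * 1000L + 3L, random_dna(6200))
    after <- with_seed(seed * 1000L + 4L,
                       sample(1:(draws$copies - 1L), 1))
    contaminant <- list(sequence = contam_seq, after_copy = after)
  }
  loc <- make_locus(seed = seed * 1000L + 5L, host_len = draws$host_len,
                    copy_number = draws$copies,
                    inverted_copy_indices = inv_idx, deletion_len = 686L,
                    integration_pos = as.integer(draws$host_len / 2),
                    contaminant = contaminant,
                    unit_length = 3000L, marker_length = 720L)
  registry <- target_registry(
    host = c(host = loc$host), transgene = loc$unit,
    contaminant = if (!is.null(contam_seq)) c(contaminant = contam_seq))
  tr <- loc$truth
  hap_right_of_array <- tr$array_start + tr$array_length
  anchors <- list(
    list(hap = "hap", start = tr$left_boundary - 200L,
         end = tr$left_boundary + 200L, n = 3L, margin = 500L),
    list(hap = "hap", start = hap_right_of_array - 200L,
         end = hap_right_of_array + 200L, n = 3L, margin = 500L))
  if (!is.null(tr$contaminant_interval)) {
    # one read spanning the foreign segment, so its full length is
    # observable from reads (the lab resolved it by PCR instead)
    c0 <- tr$array_start + tr$contaminant_interval[["offset"]]
    anchors <- c(anchors, list(list(
      hap = "hap", start = c0 + 1L,
      end = c0 + tr$contaminant_interval[["length"]], n = 1L,
      margin = 500L)))
  }
  params <- if (error == "none") {
    read_sim_params(coverage_target = coverage, sub_rate = 0,
                    ins_rate = 0, del_rate = 0, seed = seed * 1000L + 6L)
  } else {
    read_sim_params(coverage_target = coverage, sub_rate = 0.05,
                    ins_rate = 0.025, del_rate = 0.025,
                    seed = seed * 1000L + 6L)
  }
  sim <- simulate_reads(c(hap = loc$haplotype), params, anchors = anchors)
  list(locus = loc, registry = registry, sim = sim,
       contaminant_len = if (is.null(contam_seq)) 0L else nchar(contam_seq))
}

# true strand flips between adjacent array copies of opposite
# orientation: haplotype midpoint plus the flanking copy edges (the gap
# between them may contain a spliced-in foreign segment)
true_flip_positions <- function(truth) {
  cp <- truth$copies
  ori <- ifelse(cp$inverted, "-", "+")
  rows <- list()
  for (i in seq_len(nrow(cp) - 1)) {
    if (ori[i] != ori[i + 1]) {
      rows[[length(rows) + 1]] <- data.frame(
        pos = truth$array_start +
          as.integer(round((cp$array_end[i] + cp$array_start[i + 1]) / 2)),
        left_end = truth$array_start + cp$array_end[i],
        right_start = truth$array_start + cp$array_start[i + 1])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pos = integer(), left_end = integer(),
                      right_start = integer()))
  }
  do.call(rbind, rows)
}

#' Boundary/deletion truth-recovery experiment
#'
#' Runs the junction caller on `n_seeds` simulated loci and scores the
#' called boundaries, deletion length, inversion flips and (optionally)
#' the tiling lower bound against the simulator truth.
#'
#' @param n_seeds Number of simulated loci.
#' @param error Passed to [sim_study_locus()].
#' @param base_seed Offset added to the per-locus seeds.
#' @param with_tiling Also construct the minimal tiling path per locus
#'   (adds runtime) and record its lower bound.
#' @return data.frame, one row per locus: truth and absolute errors of
#'   left/right boundary and deletion length, inversion detection counts
#'   and worst flip-position error, contaminant observations, tiling
#'   bound.
#' @export
experiment_truth_recovery <- function(n_seeds = 20, error = "none",
                                      base_seed = 1L, with_tiling = FALSE) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cs <- sim_study_locus(base_seed + i, error = error)
    tr <- cs$locus$truth
    idx <- index_targets(cs$registry, k = 15L)
    segs <- align_reads(cs$sim$reads, idx)
    calls <- call_junctions(segs, cs$registry, reads = cs$sim$reads)
    full <- calls[!is.na(calls$left_boundary) & !is.na(calls$right_boundary), ,
                  drop = FALSE]
    left_err <- right_err <- del_err <- NA_integer_
    if (nrow(full) > 0) {
      j <- which.min(abs(full$left_boundary - tr$left_boundary))
      left_err <- abs(full$left_boundary[j] - tr$left_boundary)
      right_err <- abs(full$right_boundary[j] - tr$right_boundary)
      del_err <- abs(full$deletion_len[j] - tr$deletion_len)
    }

    inv <- detect_inversions(segs, cs$registry)
    flips <- true_flip_positions(tr)
    inv_scored <- score_inversions(inv, flips, cs$sim$truth)

    ctm <- detect_contaminant(segs, cs$registry)

    tiling_lb <- NA_integer_
    if (with_tiling) {
      cls <- classify_reads(segs, cs$registry)
      if (any(cls$marker_match_count >= 1)) {
        tp <- minimal_tiling_path(cs$sim$reads, segs, cls, cs$registry)
        tiling_lb <- tp$lower_bound_copies
      }
    }

    rows[[i]] <- data.frame(
      seed = base_seed + i, host_len = tr$host_length,
      copies = tr$copy_number, has_contaminant = cs$contaminant_len > 0,
      n_reads = length(cs$sim$reads),
      true_left = tr$left_boundary, true_right = tr$right_boundary,
      n_calls = nrow(full), left_err = left_err, right_err = right_err,
      del_err = del_err,
      n_true_flips = nrow(flips),
      n_flips_spanned = inv_scored$n_spanned,
      n_flips_detected = inv_scored$n_detected,
      worst_flip_err = inv_scored$worst_err,
      contam_found = nrow(ctm) > 0,
      contam_len = if (nrow(ctm)) max(ctm$observed_length) else 0L,
      tiling_lb = tiling_lb)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# map called inversion events into haplotype coordinates through the
# per-read truth and score them against the true flips; a flip only
# counts as observable when some read spans it with enough flanking
# transgene sequence on both sides to support a segment (250 bp)
score_inversions <- function(inv, flips, read_truth, flank = 250L) {
  if (nrow(flips) == 0) {
    return(list(n_spanned = 0L, n_detected = 0L, worst_err = NA_real_))
  }
  ev_pos <- numeric(0)
  if (nrow(inv) > 0) {
    m <- match(inv$read_id, read_truth$read_id)
    s <- read_truth$start[m]; e <- read_truth$end[m]
    st <- read_truth$strand[m]
    ev_pos <- ifelse(st == "+", s + inv$read_position,
                     e - inv$read_position)
  }
  n_span <- 0L; n_det <- 0L; worst <- NA_real_
  for (i in seq_len(nrow(flips))) {
    spanned <- any(read_truth$start <= flips$left_end[i] - flank &
                     read_truth$end >= flips$right_start[i] + flank)
    if (!spanned) next
    n_span <- n_span + 1L
    if (length(ev_pos)) {
      d <- min(abs(ev_pos - flips$pos[i]))
      if (d <= 300) {
        n_det <- n_det + 1L
        worst <- max(worst, d, na.rm = TRUE)
      }
    }
  }
  list(n_spanned = n_span, n_detected = n_det, worst_err = worst)
}

#' Depth copy-number recovery experiment
#'
#' Estimates array copy number from marker match counts and fold-coverage
#' on simulated loci. Reads are aligned against the marker alone (the
#' depth estimator uses only marker matches). Coverage defaults to 100x:
#' the rounded estimate inherits Poisson counting noise with
#' `sd = sqrt(C / coverage)` copies, so concentrating its mode on the true
#' value requires sampling noise below the 0.5-copy rounding resolution —
#' a power consideration detailed in the methods vignette.
#'
#' @param n_seeds Seeds per copy-number setting.
#' @param copies Copy numbers to simulate.
#' @param coverage Fold-coverage of each simulated haplotype.
#' @param base_seed Seed offset.
#' @param error Read error regime, as in [sim_study_locus()].
#' @return data.frame: `copies`, `seed`, `total_matches`, `coverage`,
#'   `estimate`, `estimate_int`.
#' @export
experiment_copy_number <- function(n_seeds = 20, copies = c(6L, 18L, 26L),
                                   coverage = 100, base_seed = 1L,
                                   error = "noisy") {
  rows <- list()
  for (C in copies) {
    for (i in seq_len(n_seeds)) {
      seed <- base_seed + 37L * C + i
      loc <- make_locus(seed = seed * 1000L, host_len = 10000L,
                        copy_number = C, deletion_len = 686L,
                        integration_pos = 5000L, unit_length = 3000L,
                        marker_length = 720L)
      params <- if (error == "none") {
        read_sim_params(coverage_target = coverage, sub_rate = 0,
                        ins_rate = 0, del_rate = 0, seed = seed * 1000L + 1L)
      } else {
        read_sim_params(coverage_target = coverage, seed = seed * 1000L + 1L)
      }
      sim <- simulate_reads(c(hap = loc$haplotype), params)
      reg <- marker_only_registry(loc$unit)
      idx <- index_targets(reg, k = 15L)
      segs <- align_reads(sim$reads, idx)
      cls <- classify_reads(segs, reg)
      mc <- count_marker_matches(cls)
      rs <- run_stats(sim$reads, genome_size = nchar(loc$haplotype))
      est <- copy_number_from_depth(mc$total_matches, rs$coverage)
      rows[[length(rows) + 1]] <- data.frame(
        copies = C, seed = seed, total_matches = mc$total_matches,
        coverage = rs$coverage, estimate = est$value,
        estimate_int = est$value_int)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# a registry holding only the marker target
marker_only_registry <- function(unit) {
  mk <- substr(unit$sequence, unit$marker_interval[1] + 1L,
               unit$marker_interval[2])
  structure(list(seqs = c(marker = mk),
                 roles = c(marker = "marker"),
                 marker_interval = NULL, unit_id = NA_character_,
                 marker_id = "marker", marker_length = nchar(mk)),
            class = "tg_registry")
}

#' Tiling-path experiment on a fully tiled array
#'
#' Simulates an error-free, deeply covered 6-copy locus with a mid-array
#' inversion and constructs the minimal tiling path. Reads follow a
#' concentrated length law with N50 of four unit lengths (12 kb): with an
#' exact tandem repeat, an overlap is only provably placeable when a
#' landmark (junction or inversion flip) falls inside it, so reads must
#' bridge adjacent landmarks (three units apart here) plus the minimum
#' overlap — the regime in which tiling can reach the true copy number
#' rather than a conservative bound.
#'
#' @param seed Integer seed.
#' @param copy_number True copies.
#' @param coverage Fold-coverage.
#' @return List: `lower_bound`, `true_copies`, `path_length`.
#' @export
experiment_tiling <- function(seed = 1L, copy_number = 6L, coverage = 8) {
  loc <- make_locus(seed = seed * 1000L + 11L, host_len = 20000L,
                    copy_number = copy_number,
                    inverted_copy_indices = as.integer(copy_number / 2),
                    deletion_len = 686L, integration_pos = 10000L,
                    unit_length = 3000L, marker_length = 720L)
  registry <- target_registry(host = c(host = loc$host),
                              transgene = loc$unit)
  tr <- loc$truth
  arr_end <- tr$array_start + tr$array_length
  anchors <- list(
    list(hap = "hap", start = tr$left_boundary - 200L,
         end = tr$left_boundary + 200L, n = 3L, margin = 500L),
    list(hap = "hap", start = arr_end - 200L, end = arr_end + 200L,
         n = 3L, margin = 500L))
  lp <- lognormal_params_for_n50(12000, sdlog = 0.3)
  sim <- simulate_reads(c(hap = loc$haplotype),
                        read_sim_params(coverage_target = coverage,
                                        length_log_mean = lp$meanlog,
                                        length_log_sd = lp$sdlog,
                                        sub_rate = 0, ins_rate = 0,
                                        del_rate = 0,
                                        seed = seed * 1000L + 12L),
                        anchors = anchors)
  idx <- index_targets(registry, k = 15L)
  segs <- align_reads(sim$reads, idx)
  cls <- classify_reads(segs, registry)
  tp <- minimal_tiling_path(sim$reads, segs, cls, registry)
  list(lower_bound = tp$lower_bound_copies,
       true_copies = loc$truth$copy_number,
       path_length = length(tp$read_ids))
}

#' qPCR copy-number recovery experiment
#'
#' Simulates comparative-Ct batches (6 replicates per sample/assay,
#' per-well Ct noise SD 0.1 cycles — the precision of a well-run SYBR
#' assay) with known copies per allele, runs the full
#' normalize-calibrate-convert chain, and reports the relative recovery
#' error per batch.
#'
#' @param n_batches Batches per copy setting.
#' @param copies True copies per allele to simulate.
#' @param noise_sd Per-well Ct noise SD, cycles.
#' @param n_replicates Wells per sample/assay.
#' @param base_seed Seed offset.
#' @return data.frame: `copies`, `batch`, `estimate`, `rel_err`.
#' @export
experiment_qpcr <- function(n_batches = 200, copies = c(1, 5, 26),
                            noise_sd = 0.1, n_replicates = 6,
                            base_seed = 1L) {
  rows <- list()
  for (C in copies) {
    for (b in seq_len(n_batches)) {
      ct <- simulate_ct_batch(C, test_alleles = 1,
                              calibrator_copies_per_genome = 1,
                              n_replicates = n_replicates,
                              noise_sd = noise_sd,
                              seed = base_seed + 7919L * C + b)
      rq <- delta_delta_ct(ct, calibrator = "calibrator")
      est <- copies_per_allele(rq[rq$sample_id == "test", , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        copies = C, batch = b, estimate = est$value,
        rel_err = abs(est$value - C) / C)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-integrity experiment
#'
#' Simulates a host contig carrying five genes with the integration placed
#' inside the middle gene's CDS, with reads anchored across every gene
#' span and both junctions, and checks that exactly the disrupted gene is
#' flagged.
#'
#' @param seed Integer seed.
#' @return List: `results` (from [gene_integrity()]), `disrupted_gene`,
#'   `gene_models`, `calls`.
#' @export
experiment_integrity <- function(seed = 1L) {
  host_len <- 60000L
  gene_models <- data.frame(
    gene = rep(c("geneA", "geneB", "geneC", "geneD", "geneE"),
               times = c(1, 2, 1, 1, 1)),
    chrom = "host",
    strand = c("+", "+", "+", "-", "+", "+"),
    start = c(5000L, 15000L, 18500L, 28000L, 40000L, 50000L),
    end = c(9000L, 17500L, 20000L, 33000L, 44000L, 54000L))
  loc <- make_locus(seed = seed * 1000L, host_len = host_len,
                    copy_number = 6L, deletion_len = 686L,
                    integration_pos = 30000L,  # inside geneC's CDS
                    unit_length = 3000L, marker_length = 720L)
  reg <- target_registry(host = c(host = loc$host), transgene = loc$unit)
  tr <- loc$truth
  # host coordinates right of the deletion sit this much further along
  # the haplotype
  hap_shift <- tr$array_length - tr$deletion_len
  span_anchor <- function(s, e) {
    # map host interval to haplotype coordinates for anchoring
    if (e <= tr$left_boundary) list(hap = "hap", start = s + 1L, end = e,
                                    n = 2L, margin = 300L)
    else list(hap = "hap", start = s + 1L + hap_shift, end = e + hap_shift,
              n = 2L, margin = 300L)
  }
  spans <- do.call(rbind, lapply(split(gene_models, gene_models$gene),
                                 function(g) data.frame(
                                   start = min(g$start), end = max(g$end))))
  clear <- spans[spans$end <= tr$left_boundary |
                   spans$start >= tr$right_boundary, , drop = FALSE]
  anchors <- c(
    lapply(seq_len(nrow(clear)), function(i)
      span_anchor(clear$start[i], clear$end[i])),
    list(list(hap = "hap", start = tr$left_boundary - 200L,
              end = tr$left_boundary + 200L, n = 3L, margin = 500L),
         list(hap = "hap",
              start = tr$array_start + tr$array_length - 200L,
              end = tr$array_start + tr$array_length + 200L,
              n = 3L, margin = 500L)))
  sim <- simulate_reads(c(hap = loc$haplotype),
                        read_sim_params(coverage_target = 4, sub_rate = 0,
                                        ins_rate = 0, del_rate = 0,
                                        seed = seed * 1000L + 1L),
                        anchors = anchors)
  idx <- index_targets(reg, k = 15L)
  segs <- align_reads(sim$reads, idx)
  calls <- call_junctions(segs, reg, reads = sim$reads)
  res <- gene_integrity(gene_models, segs, reg, integration = calls)
  list(results = res, disrupted_gene = "geneC",
       gene_models = gene_models, calls = calls)
}
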
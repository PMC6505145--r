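#' Construct a transgene unit
#'
#' A transgene unit is the monomer of the tandem array: a sequence carrying
#' a marker subsequence (the screened reporter, e.g. an EGFP-like CDS) at a
#' known interval. The marker must fit inside the unit and the unit must be
#' at least three times the marker length, so that marker hits identify
#' individual array copies unambiguously.
#'
#' @param sequence Unit sequence (character). If `NULL`, a random sequence
#'   of length `unit_length` is drawn from the current RNG state.
#' @param unit_length Unit length in bp (used when `sequence` is `NULL`).
#' @param marker_length Marker length in bp (used when `marker_start` needs
#'   a default interval).
#' @param marker_start 0-based start of the marker within the unit.
#'   Defaults to roughly one third into the unit.
#' @return An object of class `tg_unit`: list with `sequence`,
#'   `marker_interval` (0-based half-open) and `unit_length`.
#' @export
transgene_unit <- function(sequence = NULL, unit_length = 3000L,
                           marker_length = 720L, marker_start = NULL) {
  if (is.null(sequence)) {
    sequence <- random_dna(unit_length)
  }
  unit_length <- nchar(sequence)
  if (unit_length < 1) stop("empty transgene unit", call. = FALSE)
  if (is.null(marker_start)) {
    marker_start <- as.integer(floor(unit_length / 3))
  }
  marker_interval <- c(marker_start, marker_start + marker_length)
  if (unit_length < 3L * marker_length) {
    stop("unit must be at least 3x the marker length", call. = FALSE)
  }
  if (marker_interval[1] < 0 || marker_interval[2] > unit_length) {
    stop("marker interval outside the unit", call. = FALSE)
  }
  structure(
    list(sequence = sequence,
         marker_interval = as.integer(marker_interval),
         unit_length = as.integer(unit_length)),
    class = "tg_unit"
  )
}

#' Generate a synthetic integration locus with ground truth
#'
#' Builds a host contig, a transgene tandem array (with optional inverted
#' copies and an optional foreign-DNA segment spliced into the array), and
#' the integrated haplotype: the array replaces `deletion_len` bp of host
#' sequence immediately to the right of `integration_pos`. The returned
#' truth record carries every coordinate needed to score downstream calls.
#'
#' Boundary convention (1-based): `left_boundary` is the last retained host
#' base left of the array; `right_boundary` is the first retained host base
#' right of it, so `deletion_len = right_boundary - left_boundary - 1`.
#'
#' @param seed Integer seed; all randomness in the construction flows from
#'   it through one private RNG stream.
#' @param host_len Host contig length in bp.
#' @param unit A [transgene_unit()], or `NULL` to draw a random unit with
#'   `unit_length`/`marker_length`.
#' @param copy_number Number of tandem unit copies (>= 1).
#' @param inverted_copy_indices 0-based indices of copies inserted as the
#'   reverse complement of the unit.
#' @param deletion_len Host bp deleted at the integration site.
#' @param integration_pos 1-based host coordinate of the last retained base
#'   left of the array. `NULL` places the array at the host midpoint.
#' @param contaminant Optional `list(sequence=, after_copy=)` or
#'   `list(sequence=, offset=)`: foreign DNA spliced into the array after
#'   `after_copy` copies (or at bp `offset` from the array start).
#' @param unit_length,marker_length Used when `unit` is `NULL`.
#' @return List with `host`, `haplotype`, `unit` and `truth` (class
#'   `tg_truth`), where `truth` records boundaries, deletion, copy count and
#'   per-copy coordinates (see Details).
#' @export
make_locus <- function(seed, host_len = 50000L, unit = NULL,
                       copy_number = 6L, inverted_copy_indices = integer(),
                       deletion_len = 0L, integration_pos = NULL,
                       contaminant = NULL, unit_length = 3000L,
                       marker_length = 720L) {
  with_seed(seed, {
    host_len <- as.integer(host_len)
    copy_number <- as.integer(copy_number)
    deletion_len <- as.integer(deletion_len)
    if (copy_number < 1) stop("copy_number must be >= 1", call. = FALSE)
    if (deletion_len < 0) stop("deletion_len must be >= 0", call. = FALSE)
    if (is.null(unit)) {
      unit <- transgene_unit(unit_length = unit_length,
                             marker_length = marker_length)
    }
    if (nchar(unit$sequence) == 0) stop("empty transgene unit", call. = FALSE)
    if (is.null(integration_pos)) {
      integration_pos <- as.integer(floor(host_len / 2))
    }
    integration_pos <- as.integer(integration_pos)
    if (integration_pos < 1 || integration_pos + deletion_len > host_len) {
      stop("coordinate error: integration_pos + deletion_len must lie ",
           "within the host contig", call. = FALSE)
    }
    inv <- as.integer(inverted_copy_indices)
    if (length(inv) && (min(inv) < 0 || max(inv) >= copy_number)) {
      stop("inverted_copy_indices out of range", call. = FALSE)
    }

    host <- random_dna(host_len)
    ulen <- unit$unit_length
    copies <- character(copy_number)
    for (i in seq_len(copy_number)) {
      copies[i] <- if ((i - 1L) %in% inv) cpp_revcomp(unit$sequence)
                   else unit$sequence
    }

    contam_seq <- NULL
    contam_offset <- NA_integer_
    if (!is.null(contaminant)) {
      contam_seq <- toupper(contaminant$sequence)
      if (!is.null(contaminant$after_copy)) {
        contam_offset <- as.integer(contaminant$after_copy) * ulen
      } else {
        contam_offset <- as.integer(contaminant$offset)
      }
      if (contam_offset < 0 || contam_offset > copy_number * ulen) {
        stop("coordinate error: contaminant offset outside the array",
             call. = FALSE)
      }
    }

    arr0 <- paste(copies, collapse = "")
    if (!is.null(contam_seq)) {
      array_seq <- paste0(substr(arr0, 1, contam_offset), contam_seq,
                          substr(arr0, contam_offset + 1, nchar(arr0)))
    } else {
      array_seq <- arr0
    }

    # per-copy coordinates within the array (0-based half-open), shifted
    # by the contaminant where it precedes the copy
    clen <- if (is.null(contam_seq)) 0L else nchar(contam_seq)
    copy_start0 <- (seq_len(copy_number) - 1L) * ulen
    shift <- if (!is.na(contam_offset)) {
      ifelse(copy_start0 >= contam_offset, clen, 0L)
    } else rep(0L, copy_number)
    copy_tab <- data.frame(
      index = seq_len(copy_number) - 1L,
      array_start = copy_start0 + shift,
      array_end = copy_start0 + shift + ulen,
      inverted = (seq_len(copy_number) - 1L) %in% inv
    )

    left <- integration_pos
    right <- integration_pos + deletion_len + 1L
    haplotype <- paste0(substr(host, 1, left), array_seq,
                        substr(host, right, host_len))

    # marker placement on the haplotype (1-based inclusive), per copy
    m0 <- unit$marker_interval[1]; m1 <- unit$marker_interval[2]
    mk_start0 <- ifelse(copy_tab$inverted,
                        copy_tab$array_start + (ulen - m1),
                        copy_tab$array_start + m0)
    marker_tab <- data.frame(
      index = copy_tab$index,
      hap_start = left + mk_start0 + 1L,
      hap_end = left + mk_start0 + (m1 - m0),
      strand = ifelse(copy_tab$inverted, "-", "+")
    )

    truth <- structure(list(
      integration_chrom = "host",
      left_boundary = left,
      right_boundary = right,
      deletion_len = deletion_len,
      copy_number = copy_number,
      inverted_copy_indices = sort(inv),
      contaminant_interval = if (is.null(contam_seq)) NULL else
        c(offset = contam_offset, length = clen),
      array_start = left,             # array begins after this host base
      array_length = nchar(array_seq),
      unit_length = ulen,
      marker_interval = unit$marker_interval,
      copies = copy_tab,
      markers = marker_tab,
      host_length = host_len,
      haplotype_length = nchar(haplotype)
    ), class = "tg_truth")

    expected <- host_len - deletion_len + copy_number * ulen + clen
    stopifnot(truth$haplotype_length == expected)

    list(host = host, haplotype = haplotype, unit = unit, truth = truth)
  })
}

#' Read-simulation parameters
#'
#' Read lengths follow a log-normal law; under length-biased sampling its
#' implied N50 is `exp(meanlog + sdlog^2)`. Defaults target an N50 of about
#' 3 kb, a desk-scale stand-in for the tens-of-kb N50 of a real nanopore
#' run; [lognormal_params_for_n50()] retunes `meanlog` for other targets.
#' Default error rates are nanopore-like: 5% substitution, 2.5% insertion,
#' 3.5% deletion.
#'
#' @param coverage_target Fold-coverage of the total haplotype length.
#' @param length_log_mean,length_log_sd Log-normal parameters of the read
#'   length law.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities, each in
#'   \[0, 0.2\].
#' @param min_read_len Reads shorter than this after truncation at contig
#'   ends are discarded.
#' @param seed Integer seed for the private RNG stream.
#' @return A `tg_read_params` list.
#' @export
read_sim_params <- function(coverage_target = 2, length_log_mean = NULL,
                            length_log_sd = 0.6, sub_rate = 0.05,
                            ins_rate = 0.025, del_rate = 0.035,
                            min_read_len = 100L, seed = 1L) {
  if (is.null(length_log_mean)) {
    length_log_mean <- log(3000) - length_log_sd^2
  }
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) {
    stop("error rates must lie in [0, 0.2]", call. = FALSE)
  }
  if (coverage_target <= 0) stop("coverage_target must be > 0", call. = FALSE)
  structure(list(coverage_target = coverage_target,
                 length_log_mean = length_log_mean,
                 length_log_sd = length_log_sd,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, min_read_len = as.integer(min_read_len),
                 seed = as.integer(seed)),
            class = "tg_read_params")
}

#' N50 implied by a log-normal read-length law
#'
#' The length-biased version of LogNormal(mu, sigma) is
#' LogNormal(mu + sigma^2, sigma); the N50 is its median.
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @return Implied N50 in bp.
#' @export
lognormal_n50 <- function(meanlog, sdlog) exp(meanlog + sdlog^2)

#' @rdname lognormal_n50
#' @param n50 Target N50 in bp.
#' @export
lognormal_params_for_n50 <- function(n50, sdlog = 0.6) {
  list(meanlog = log(n50) - sdlog^2, sdlog = sdlog)
}

#' Simulate noisy long reads from one or more haplotypes
#'
#' Samples reads until the total simulated bases reach
#' `coverage_target * sum(haplotype lengths)`. Each read records its true
#' source interval and strand. Per-base substitution/insertion/deletion
#' errors are injected independently at the configured rates. Output is
#' deterministic for a fixed seed.
#'
#' @param haplotypes Named character vector of haplotype sequences, or a
#'   list of `list(seq=, weight=)` for unequal ploidy weights (weights set
#'   sampling proportions; the base target always uses the summed lengths).
#' @param params A [read_sim_params()] object.
#' @param anchors Optional list of `list(hap=, start=, end=, n=, margin=)`
#'   (1-based inclusive interval): for each entry, `n` additional reads are
#'   drawn whose span is guaranteed to cover the interval with at least
#'   `margin` bp on each side — used to realize the study condition that
#'   junctions are spanned by reads.
#' @return List with `reads` (named character vector), `quals` (constant
#'   per-read quality strings) and `truth` (data.frame: read_id, hap,
#'   start, end, strand; 1-based inclusive source interval).
#' @export
simulate_reads <- function(haplotypes, params = read_sim_params(),
                           anchors = NULL) {
  if (is.list(haplotypes) && !is.null(haplotypes[[1]]$seq)) {
    seqs <- vapply(haplotypes, function(h) h$seq, character(1))
    wts <- vapply(haplotypes, function(h) h$weight, numeric(1))
    if (is.null(names(seqs))) names(seqs) <- paste0("hap", seq_along(seqs))
  } else {
    seqs <- unlist(haplotypes)
    if (is.null(names(seqs))) names(seqs) <- paste0("hap", seq_along(seqs))
    wts <- rep(1, length(seqs))
  }
  lens <- nchar(seqs)
  if (length(seqs) == 0) stop("at least one haplotype required", call. = FALSE)
  if (any(lens == 0)) stop("zero-length haplotype", call. = FALSE)

  p <- params
  target <- p$coverage_target * sum(lens)
  err_total <- p$sub_rate + p$ins_rate + p$del_rate

  with_seed(p$seed, {
    src_hap <- integer(0); src_start <- integer(0); src_end <- integer(0)
    src_strand <- character(0)

    # anchored reads first: length drawn from the same law, floored to
    # span the interval plus margins, placed uniformly over valid starts
    if (!is.null(anchors)) {
      for (a in anchors) {
        n <- if (is.null(a$n)) 3L else a$n
        margin <- if (is.null(a$margin)) 500L else a$margin
        hi <- match(a$hap, names(seqs))
        if (is.na(hi)) stop("unknown anchor haplotype: ", a$hap, call. = FALSE)
        span <- a$end - a$start + 1L
        for (j in seq_len(n)) {
          L <- max(round(rlnorm(1, p$length_log_mean, p$length_log_sd)),
                   span + 2L * margin)
          lo <- max(1L, a$end + margin - L + 1L)
          hi_start <- min(a$start - margin, lens[hi] - L + 1L)
          s <- if (hi_start <= lo) lo else lo + floor(runif(1) * (hi_start - lo + 1))
          e <- min(s + L - 1L, lens[hi])
          src_hap <- c(src_hap, hi); src_start <- c(src_start, as.integer(s))
          src_end <- c(src_end, as.integer(e))
          src_strand <- c(src_strand, sample(c("+", "-"), 1))
        }
      }
    }

    total <- sum(src_end - src_start + 1L)
    prob <- wts * lens / sum(wts * lens)
    while (total < target) {
      m <- 256L
      L <- pmax(p$min_read_len,
                round(rlnorm(m, p$length_log_mean, p$length_log_sd)))
      hi <- sample.int(length(seqs), m, replace = TRUE, prob = prob)
      s <- 1L + floor(runif(m) * lens[hi])
      e <- pmin(s + L - 1L, lens[hi])
      keep <- (e - s + 1L) >= p$min_read_len
      if (!any(keep)) next
      Lk <- (e - s + 1L)[keep]
      cum <- cumsum(Lk)
      reach <- which(total + cum >= target)
      n_take <- if (length(reach)) reach[1] else length(Lk)
      # include the final read only when it brings the total closer to
      # the base target than stopping short would
      if (length(reach) && n_take >= 1) {
        over <- total + cum[n_take] - target
        under <- target - (total + if (n_take > 1) cum[n_take - 1] else 0)
        if (over > under) n_take <- n_take - 1L
      }
      if (n_take == 0L) break
      idx <- which(keep)[seq_len(n_take)]
      src_hap <- c(src_hap, hi[idx])
      src_start <- c(src_start, as.integer(s[idx]))
      src_end <- c(src_end, as.integer(e[idx]))
      src_strand <- c(src_strand,
                      sample(c("+", "-"), length(idx), replace = TRUE))
      total <- total + sum((e - s + 1L)[idx])
      if (total >= target) break
    }

    n_reads <- length(src_hap)
    ids <- sprintf("read_%05d", seq_len(n_reads))
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      x <- substr(seqs[src_hap[i]], src_start[i], src_end[i])
      if (src_strand[i] == "-") x <- cpp_revcomp(x)
      if (err_total > 0) {
        x <- cpp_mutate(x, p$sub_rate, p$ins_rate, p$del_rate)
      }
      reads[i] <- x
    }
    names(reads) <- ids

    q <- if (err_total > 0) max(2L, round(-10 * log10(err_total))) else 40L
    quals <- setNames(vapply(nchar(reads), function(n)
      strrep(rawToChar(as.raw(q + 33L)), n), character(1)), ids)

    truth <- data.frame(read_id = ids, hap = names(seqs)[src_hap],
                        start = src_start, end = src_end,
                        strand = src_strand, stringsAsFactors = FALSE)
    list(reads = reads, quals = quals, truth = truth)
  })
}

#' Write simulated reads as FASTQ
#'
#' Sanger (+33) quality encoding with a constant per-base quality derived
#' from the simulated error rate.
#'
#' @param sim Result of [simulate_reads()].
#' @param path Output FASTQ file.
#' @export
write_reads_fastq <- function(sim, path) {
  x <- Biostrings::DNAStringSet(sim$reads)
  q <- Biostrings::BStringSet(sim$quals)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}

#' Write simulator ground truth as JSON and BED
#'
#' The JSON file serializes the full truth record; the BED file holds the
#' integration interval (0-based half-open: deleted host bases, or a
#' zero-length insertion point when nothing was deleted).
#'
#' @param truth A `tg_truth` record from [make_locus()].
#' @param json_path,bed_path Output paths (`NULL` to skip either).
#' @export
write_truth <- function(truth, json_path = NULL, bed_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(truth), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null")
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = truth$integration_chrom,
                      start = truth$left_boundary,
                      end = truth$right_boundary - 1L,
                      name = "integration")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(truth)
}

#' @export
print.tg_truth <- function(x, ...) {
  cat("Synthetic integration locus truth\n")
  cat(sprintf("  boundaries (1-based): %s:%d / %d  (deletion %d bp)\n",
              x$integration_chrom, x$left_boundary, x$right_boundary,
              x$deletion_len))
  cat(sprintf("  array: %d copies x %d bp unit, %d inverted%s\n",
              x$copy_number, x$unit_length,
              length(x$inverted_copy_indices),
              if (is.null(x$contaminant_interval)) "" else
                sprintf(", contaminant %d bp", x$contaminant_interval["length"])))
  invisible(x)
}
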
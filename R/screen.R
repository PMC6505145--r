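#' N50 of a set of read lengths
#'
#' The largest length L such that reads of length >= L together contain at
#' least half of all sequenced bases (computed by descending cumulative
#' sum).
#'
#' @param lengths Positive integer vector of read lengths.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Whole-run sequencing statistics
#'
#' @param lengths Read lengths in bp (or a named character vector of read
#'   sequences, from which lengths are taken).
#' @param genome_size Genome size in bp used for fold-coverage.
#' @return A `tg_run_stats` list: `n_reads`, `total_bases`, `n50`,
#'   `genome_size`, `coverage` (exact ratio; printed to one decimal).
#' @export
run_stats <- function(lengths, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0", call. = FALSE)
  if (is.character(lengths)) lengths <- nchar(lengths)
  n <- length(lengths)
  tb <- sum(as.numeric(lengths))
  structure(list(n_reads = n, total_bases = tb,
                 n50 = if (n > 0) n50(lengths) else 0,
                 genome_size = genome_size,
                 coverage = if (n > 0) tb / genome_size else 0),
            class = "tg_run_stats")
}

#' @export
print.tg_run_stats <- function(x, ...) {
  cat(sprintf("%d reads, %.3g bp total, n50 %d bp, %.1f-fold coverage of %.3g bp\n",
              x$n_reads, x$total_bases, as.integer(x$n50), x$coverage,
              x$genome_size))
  invisible(x)
}

#' Classify reads by target content
#'
#' A marker "match" is a marker-role segment whose target overlap covers at
#' least `min_marker_cov` of the marker length; two marker segments on one
#' read are counted as distinct matches only when their read intervals
#' overlap by less than half of the shorter interval. A read is chimeric
#' when it carries both host and transgene sequence — the junction
#' evidence class.
#'
#' @param segments Segment data.frame from [align_reads()] or [read_paf()].
#' @param registry The [target_registry()] the segments refer to.
#' @param min_marker_cov Minimum fraction of the marker length a segment
#'   must cover to count as a match (default 0.5: robust to reads truncated
#'   mid-marker while rarely double-counting).
#' @param read_ids Optional read ids to include even when they received no
#'   segments (classified all-false).
#' @return data.frame: `read_id`, `marker_match_count`, `has_host`,
#'   `has_transgene`, `has_contaminant`, `chimeric`.
#' @export
classify_reads <- function(segments, registry, min_marker_cov = 0.5,
                           read_ids = NULL) {
  stopifnot(inherits(registry, "tg_registry"))
  role <- registry$roles[segments$target_id]
  mlen <- registry$marker_length
  ids <- unique(c(segments$read_id, read_ids))
  if (length(ids) == 0) {
    return(data.frame(read_id = character(), marker_match_count = integer(),
                      has_host = logical(), has_transgene = logical(),
                      has_contaminant = logical(), chimeric = logical(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(segments)), factor(segments$read_id, levels = ids))
  res <- lapply(ids, function(id) {
    ix <- sp[[id]]
    rl <- role[ix]
    has_host <- any(rl == "host")
    has_tg <- any(rl %in% c("transgene", "marker"))
    has_ct <- any(rl == "contaminant")
    mi <- ix[rl == "marker" &
               (segments$target_end[ix] - segments$target_start[ix]) >=
               min_marker_cov * mlen]
    cnt <- count_distinct_on_read(segments[mi, , drop = FALSE])
    list(id, cnt, has_host, has_tg, has_ct, has_host && has_tg)
  })
  out <- data.frame(
    read_id = vapply(res, `[[`, character(1), 1),
    marker_match_count = vapply(res, `[[`, integer(1), 2),
    has_host = vapply(res, `[[`, logical(1), 3),
    has_transgene = vapply(res, `[[`, logical(1), 4),
    has_contaminant = vapply(res, `[[`, logical(1), 5),
    chimeric = vapply(res, `[[`, logical(1), 6),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# count read intervals that overlap pairwise by < 50% of the shorter one
count_distinct_on_read <- function(mk) {
  if (nrow(mk) == 0) return(0L)
  ord <- order(-(mk$target_end - mk$target_start))
  taken <- list()
  for (i in ord) {
    ok <- TRUE
    for (tk in taken) {
      ov <- min(mk$read_end[i], mk$read_end[tk]) -
        max(mk$read_start[i], mk$read_start[tk])
      shorter <- min(mk$read_end[i] - mk$read_start[i],
                     mk$read_end[tk] - mk$read_start[tk])
      if (ov >= 0.5 * shorter) { ok <- FALSE; break }
    }
    if (ok) taken <- c(taken, i)
  }
  length(taken)
}

#' Count marker-bearing reads and total marker matches
#'
#' @param classifications Result of [classify_reads()].
#' @return List: `reads_with_marker`, `total_matches`.
#' @export
count_marker_matches <- function(classifications) {
  list(reads_with_marker = sum(classifications$marker_match_count >= 1),
       total_matches = sum(classifications$marker_match_count))
}

#' Depth-based copy-number estimate
#'
#' The tandem-array copy number implied by marker match counts under
#' uniform coverage: `total_matches / coverage` copies per allele, with a
#' Poisson dispersion of `sqrt(total_matches) / coverage`. No zygosity
#' correction is applied: dividing by whole-genome fold-coverage treats the
#' transgene allele as present once per haploid genome equivalent, the
#' convention of the source arithmetic (see the methods vignette for the
#' caveat).
#'
#' @param total_matches Total marker matches across reads.
#' @param coverage Fold-coverage of the genome.
#' @return A `tg_copy_estimate`: `method = "depth"`, `value` (real),
#'   `value_int` (nearest integer), `dispersion`, `n_support`.
#' @export
copy_number_from_depth <- function(total_matches, coverage) {
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  stopifnot(total_matches >= 0)
  new_copy_estimate("depth", total_matches / coverage,
                    dispersion = sqrt(total_matches) / coverage,
                    n_support = total_matches)
}

new_copy_estimate <- function(method, value, dispersion = NA_real_,
                              n_support = NA_integer_) {
  stopifnot(method %in% c("depth", "tiling_lower_bound", "qpcr"),
            value >= 0)
  structure(list(method = method, value = value,
                 value_int = as.integer(round(value)),
                 dispersion = dispersion, n_support = n_support),
            class = "tg_copy_estimate")
}

#' @export
print.tg_copy_estimate <- function(x, ...) {
  cat(sprintf("copy number (%s): %.2f (~%d)%s\n", x$method, x$value,
              x$value_int,
              if (is.na(x$dispersion)) "" else
                sprintf(" +/- %.2f", x$dispersion)))
  invisible(x)
}

#' @export
as.data.frame.tg_copy_estimate <- function(x, ...) {
  data.frame(method = x$method, value = x$value, value_int = x$value_int,
             dispersion = x$dispersion, n_support = x$n_support,
             stringsAsFactors = FALSE)
}
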
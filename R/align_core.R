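#' Build a target registry
#'
#' The registry holds the alignment targets and their roles: the host
#' contig, the transgene unit, the marker subsequence screened for copy
#' counting, and (optionally) a contaminant genome. The marker defaults to
#' the unit's marker interval when a [transgene_unit()] is supplied.
#'
#' @param host Named character vector with the host contig sequence(s).
#' @param transgene A [transgene_unit()] or a plain unit sequence.
#' @param marker Marker sequence; defaults to the unit's marker interval.
#' @param contaminant Optional named character vector of contaminant
#'   sequence(s).
#' @return A `tg_registry`: list with `seqs` (named, upper case), `roles`
#'   (named character), `marker_interval` and `unit_id`/`marker_id`.
#' @export
target_registry <- function(host, transgene, marker = NULL,
                            contaminant = NULL) {
  if (is.null(names(host))) names(host) <- "host"
  marker_interval <- NULL
  if (inherits(transgene, "tg_unit")) {
    marker_interval <- transgene$marker_interval
    if (is.null(marker)) {
      marker <- substr(transgene$sequence, marker_interval[1] + 1L,
                       marker_interval[2])
    }
    transgene <- c(transgene_unit = transgene$sequence)
  } else {
    transgene <- unlist(transgene)
    if (is.null(names(transgene))) names(transgene) <- "transgene_unit"
  }
  if (is.null(marker)) stop("a marker sequence is required", call. = FALSE)
  marker <- unlist(marker)
  if (is.null(names(marker))) names(marker) <- "marker"
  if (!is.null(contaminant)) {
    contaminant <- unlist(contaminant)
    if (is.null(names(contaminant))) names(contaminant) <- "contaminant"
  }
  seqs <- toupper(c(host, transgene, marker, contaminant))
  roles <- c(rep("host", length(host)), rep("transgene", length(transgene)),
             rep("marker", length(marker)),
             rep("contaminant", length(contaminant)))
  names(roles) <- names(seqs)
  if (anyDuplicated(names(seqs))) {
    stop("target ids must be unique", call. = FALSE)
  }
  check_dna(seqs, "target sequences")
  structure(list(seqs = seqs, roles = roles,
                 marker_interval = marker_interval,
                 unit_id = names(transgene)[1],
                 marker_id = names(marker)[1],
                 marker_length = nchar(seqs[[names(marker)[1]]])),
            class = "tg_registry")
}

#' Index registry targets by canonical k-mers
#'
#' Maps each canonical k-mer to its target positions and strands; k-mers
#' containing N are skipped. A target shorter than k contributes nothing
#' (with a warning).
#'
#' @param registry A [target_registry()], or any named character vector of
#'   sequences (all given role `"target"`).
#' @param k K-mer size, 8..26.
#' @return A `tg_index` used by [align_reads()].
#' @export
index_targets <- function(registry, k = 15L) {
  if (!inherits(registry, "tg_registry")) {
    seqs <- toupper(unlist(registry))
    if (length(seqs) == 0) stop("empty registry", call. = FALSE)
    if (is.null(names(seqs))) names(seqs) <- paste0("target", seq_along(seqs))
    registry <- structure(list(seqs = seqs,
                               roles = setNames(rep("target", length(seqs)),
                                                names(seqs)),
                               marker_interval = NULL,
                               unit_id = NA, marker_id = NA),
                          class = "tg_registry")
  }
  if (length(registry$seqs) == 0) stop("empty registry", call. = FALSE)
  k <- as.integer(k)
  if (k < 8L || k > 26L) stop("k must be in [8, 26]", call. = FALSE)
  parts <- vector("list", length(registry$seqs))
  for (i in seq_along(registry$seqs)) {
    s <- registry$seqs[[i]]
    if (nchar(s) < k) {
      warning("target '", names(registry$seqs)[i], "' is shorter than k; ",
              "it will receive no seeds")
      next
    }
    kc <- cpp_kmer_codes(s, k)
    ok <- !is.na(kc$code)
    if (!any(ok)) next
    parts[[i]] <- data.table::data.table(
      code = kc$code[ok], tid = i,
      tpos = which(ok) - 1L, tflag = kc$flag[ok])
  }
  dt <- data.table::rbindlist(parts)
  if (nrow(dt) == 0) {
    warning("index is empty (k larger than every target?)")
    dt <- data.table::data.table(code = numeric(), tid = integer(),
                                 tpos = integer(), tflag = integer())
  }
  data.table::setkey(dt, code)
  structure(list(k = k, dt = dt, registry = registry,
                 tnames = names(registry$seqs),
                 tlens = unname(nchar(registry$seqs))),
            class = "tg_index")
}

# default chaining/filter parameters for ~10-15% long-read error
default_align_params <- function() {
  list(min_seed_chain = 3L, min_segment_len = 200L, min_identity = 0.6,
       max_gap = 500L, lookback = 50L, ext_cap = 500L, ext_band = 60L,
       ext_xdrop = 30L)
}

#' Align reads against an indexed registry
#'
#' A strand-aware local aligner: canonical k-mer seeds are chained into
#' maximal co-linear chains per read/target/strand (dynamic programming
#' with a penalty proportional to diagonal drift; leftmost-start tie
#' break), chain ends are extended by banded X-drop alignment, and each
#' chain is scored by a banded global alignment of its read and target
#' substrings to obtain matching bases and block length. Segments shorter
#' than `min_segment_len` or below `min_identity` are dropped. Overlapping
#' segments on the read are suppressed within a target (best kept) but
#' permitted across targets.
#'
#' @param reads Named character vector of read sequences (ACGTN).
#' @param index A [index_targets()] result.
#' @param min_seed_chain Minimum seeds per chain.
#' @param min_segment_len Minimum segment span on the read, bp.
#' @param min_identity Minimum `n_match / block_len`.
#' @param max_gap Maximum seed-to-seed gap within a chain, bp.
#' @param dedup Suppress read-overlapping segments within one target,
#'   keeping the best (default). Disable to see alternative placements of
#'   a read against a repetitive target.
#' @return A data.frame of alignment segments: `read_id`, `read_len`,
#'   `read_start`, `read_end`, `target_id`, `target_len`, `target_start`,
#'   `target_end` (0-based half-open; read coordinates on the forward
#'   orientation of the read), `strand`, `n_match`, `block_len`.
#' @export
align_reads <- function(reads, index, min_seed_chain = 3L,
                        min_segment_len = 200L, min_identity = 0.6,
                        max_gap = 500L, dedup = TRUE) {
  stopifnot(inherits(index, "tg_index"))
  reads <- toupper(unlist(reads))
  if (length(reads) == 0) return(empty_segments())
  if (is.null(names(reads))) names(reads) <- paste0("q", seq_along(reads))
  check_dna(reads, "reads")
  k <- index$k
  pp <- default_align_params()
  pp$min_seed_chain <- as.integer(min_seed_chain)
  pp$min_segment_len <- as.integer(min_segment_len)
  pp$min_identity <- min_identity
  pp$max_gap <- as.integer(max_gap)

  out <- vector("list", 256)
  no <- 0L
  batch <- 2000L
  for (b0 in seq(1L, length(reads), by = batch)) {
    bidx <- b0:min(b0 + batch - 1L, length(reads))
    qparts <- vector("list", length(bidx))
    for (j in seq_along(bidx)) {
      s <- reads[[bidx[j]]]
      if (nchar(s) < k) next
      kc <- cpp_kmer_codes(s, k)
      ok <- !is.na(kc$code)
      if (!any(ok)) next
      qparts[[j]] <- data.table::data.table(
        code = kc$code[ok], read_idx = bidx[j],
        qpos = which(ok) - 1L, qflag = kc$flag[ok])
    }
    qdt <- data.table::rbindlist(qparts)
    if (nrow(qdt) == 0) next
    # cheap membership pre-filter: most read k-mers hit nothing
    qdt <- qdt[code %in% index$dt$code]
    if (nrow(qdt) == 0) next
    hits <- index$dt[qdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0) next
    hits[, rel := ifelse(qflag == tflag, "+", "-")]
    # minus-strand chaining runs in reverse-complement read coordinates
    rl <- nchar(reads)
    hits[, qp := ifelse(rel == "+", qpos,
                        rl[read_idx] - k - qpos)]
    data.table::setorder(hits, read_idx, tid, rel, qp, tpos)
    grp <- hits[, .(chains = list(
      cpp_chain(qp, tpos, k, pp$max_gap, pp$min_seed_chain, pp$lookback))),
      by = .(read_idx, tid, rel)]
    for (g in seq_len(nrow(grp))) {
      ch <- grp$chains[[g]]
      if (nrow(ch) == 0) next
      ri <- grp$read_idx[g]; ti <- grp$tid[g]; relg <- grp$rel[g]
      rseq <- reads[[ri]]
      qseq <- if (relg == "+") rseq else cpp_revcomp(rseq)
      tseq <- index$registry$seqs[[ti]]
      Lq <- nchar(qseq); Lt <- nchar(tseq)
      for (r in seq_len(nrow(ch))) {
        seg <- refine_chain(qseq, tseq, ch[r, ], k, Lq, Lt, pp)
        if (is.null(seg)) next
        # map back to forward-read coordinates for minus strand
        if (relg == "-") {
          rs <- Lq - seg$qe; re <- Lq - seg$qs
        } else {
          rs <- seg$qs; re <- seg$qe
        }
        no <- no + 1L
        if (no > length(out)) out <- c(out, vector("list", length(out)))
        out[[no]] <- c(ri, Lq, rs, re, ti, Lt, seg$ts, seg$te,
                       if (relg == "+") 1L else 2L, seg$nm, seg$bl)
      }
    }
  }
  if (no == 0L) return(empty_segments())
  m <- matrix(unlist(out[seq_len(no)]), ncol = 11, byrow = TRUE)
  segs <- data.frame(
    read_id = names(reads)[m[, 1]], read_len = m[, 2],
    read_start = m[, 3], read_end = m[, 4],
    target_id = index$tnames[m[, 5]], target_len = m[, 6],
    target_start = m[, 7], target_end = m[, 8],
    strand = c("+", "-")[m[, 9]], n_match = m[, 10],
    block_len = m[, 11], stringsAsFactors = FALSE)
  if (dedup) segs <- dedup_segments(segs)
  segs <- segs[order(segs$read_id, segs$read_start, segs$target_id), ]
  rownames(segs) <- NULL
  segs
}

# Ungapped X-drop extension: how far do a and b keep matching (match +1,
# mismatch -2, stop when the running score drops `xdrop` below its max)?
# Staying on the diagonal keeps segment-end read/target correspondence
# exact, which downstream breakpoint refinement relies on.
ungapped_extend <- function(a, b, xdrop = 30L) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  m <- charToRaw(substr(a, 1, n)) == charToRaw(substr(b, 1, n))
  s <- cumsum(ifelse(m, 1L, -2L))
  stop_at <- which(s < cummax(s) - xdrop)[1]
  if (!is.na(stop_at)) s <- s[seq_len(stop_at)]
  best <- which.max(s)
  if (s[best] <= 0) 0L else best
}

# Extend a seed chain at both ends and compute match statistics with a
# banded global alignment over the final substrings.
refine_chain <- function(qseq, tseq, ch, k, Lq, Lt, pp) {
  qs <- ch[["qs"]]; qe <- ch[["qe"]] + k
  ts <- ch[["ts"]]; te <- ch[["te"]] + k
  # left extension on reversed prefixes
  la <- min(qs, ts, pp$ext_cap)
  if (la > 0) {
    e <- ungapped_extend(cpp_strrev(substr(qseq, qs - la + 1L, qs)),
                         cpp_strrev(substr(tseq, ts - la + 1L, ts)),
                         pp$ext_xdrop)
    qs <- qs - e; ts <- ts - e
  }
  ra <- min(Lq - qe, Lt - te, pp$ext_cap)
  if (ra > 0) {
    e <- ungapped_extend(substr(qseq, qe + 1L, qe + ra),
                         substr(tseq, te + 1L, te + ra), pp$ext_xdrop)
    qe <- qe + e; te <- te + e
  }
  if (qe - qs < pp$min_segment_len) return(NULL)
  asub <- substr(qseq, qs + 1L, qe)
  bsub <- substr(tseq, ts + 1L, te)
  # the band tracks the interpolated diagonal, so it only needs to absorb
  # local indel drift (~random walk), not the endpoint length difference
  band <- max(32L, as.integer(16 + 4 * sqrt(0.1 * (qe - qs))))
  st <- cpp_banded_stats(asub, bsub, as.integer(band))
  if (st[2] <= 0 || st[1] / st[2] < pp$min_identity) return(NULL)
  list(qs = qs, qe = qe, ts = ts, te = te, nm = st[1], bl = st[2])
}

# Within one read and target, drop segments whose read interval overlaps a
# better (more matching bases) kept segment by more than half of the
# shorter interval. Cross-target overlaps are untouched.
dedup_segments <- function(segs) {
  keep <- rep(TRUE, nrow(segs))
  sp <- split(seq_len(nrow(segs)),
              paste(segs$read_id, segs$target_id, sep = "\r"))
  for (ix in sp) {
    if (length(ix) < 2) next
    ord <- ix[order(-segs$n_match[ix])]
    taken <- list()
    for (i in ord) {
      ok <- TRUE
      for (tk in taken) {
        ov <- min(segs$read_end[i], segs$read_end[tk]) -
          max(segs$read_start[i], segs$read_start[tk])
        shorter <- min(segs$read_end[i] - segs$read_start[i],
                       segs$read_end[tk] - segs$read_start[tk])
        if (ov > 0.5 * shorter) { ok <- FALSE; break }
      }
      if (ok) taken <- c(taken, i) else keep[i] <- FALSE
    }
  }
  segs[keep, , drop = FALSE]
}

empty_segments <- function() {
  data.frame(read_id = character(), read_len = integer(),
             read_start = integer(), read_end = integer(),
             target_id = character(), target_len = integer(),
             target_start = integer(), target_end = integer(),
             strand = character(), n_match = integer(),
             block_len = integer(), stringsAsFactors = FALSE)
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @param ... Passed on to [align_reads()].
#' @export
align_read <- function(read, index, ...) {
  if (is.null(names(read))) names(read) <- "read"
  align_reads(read, index, ...)
}

#' Read alignment segments from PAF
#'
#' Parses the 12 mandatory PAF fields into the package's segment table.
#' Malformed lines are skipped with a warning giving the line number; an
#' input consisting only of malformed lines is an error.
#'
#' @param path A PAF file path, or a character vector of PAF lines.
#' @return A segment data.frame as produced by [align_reads()].
#' @export
read_paf <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_segments())
  rows <- vector("list", length(lines))
  bad <- integer(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ok <- length(f) >= 12 && f[5] %in% c("+", "-") &&
      !anyNA(suppressWarnings(as.integer(f[c(2:4, 7:12)])))
    if (!ok) { bad <- c(bad, i); next }
    rows[[i]] <- data.frame(
      read_id = f[1], read_len = as.integer(f[2]),
      read_start = as.integer(f[3]), read_end = as.integer(f[4]),
      target_id = f[6], target_len = as.integer(f[7]),
      target_start = as.integer(f[8]), target_end = as.integer(f[9]),
      strand = f[5], n_match = as.integer(f[10]),
      block_len = as.integer(f[11]), stringsAsFactors = FALSE)
  }
  if (length(bad)) {
    warning("skipped ", length(bad), " malformed PAF line(s): ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "")
  }
  if (length(bad) == length(lines)) {
    stop("no well-formed PAF lines in input", call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write alignment segments as PAF
#'
#' Emits the 12 mandatory fields (mapping quality written as 255,
#' "missing"). Round-trips losslessly through [read_paf()].
#'
#' @param segments Segment data.frame.
#' @param path Output file.
#' @export
write_paf <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255",
                   segments$read_id, segments$read_len,
                   segments$read_start, segments$read_end,
                   segments$strand, segments$target_id,
                   segments$target_len, segments$target_start,
                   segments$target_end, segments$n_match,
                   segments$block_len)
  writeLines(lines, path)
  invisible(path)
}
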
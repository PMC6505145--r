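#' Deletion length implied by retained boundary bases
#'
#' With `left` the 1-based coordinate of the last retained host base to the
#' left of the insertion and `right` the first retained base to the right,
#' the bases strictly between them were deleted: `right - left - 1`.
#'
#' @param left_boundary,right_boundary 1-based host coordinates.
#' @return Deleted length in bp (0 when the retained bases are adjacent).
#' @export
deletion_length <- function(left_boundary, right_boundary) {
  if (right_boundary <= left_boundary) {
    stop("right_boundary must exceed left_boundary", call. = FALSE)
  }
  as.integer(right_boundary - left_boundary - 1)
}

#' Call integration boundaries from chimeric reads
#'
#' On every read where a host segment directly abuts a transgene segment
#' (gap on the read at most `max_junction_gap` bp, small overlaps
#' tolerated), the host-side endpoint is taken as a boundary candidate,
#' converted to the 1-based retained-base convention. A candidate is a left
#' boundary when the retained host sequence continues to lower reference
#' coordinates, a right boundary when it continues to higher ones
#' (left/right follow reference coordinate order, not read order).
#' Candidates within `cluster_radius` bp on the same side are merged by
#' median; a paired left + right boundary yields
#' `deletion_len = right - left - 1`.
#'
#' @param segments Segment data.frame (sorted internally per read).
#' @param registry The [target_registry()].
#' @param max_junction_gap Maximum unaligned bp between the host and
#'   transgene segments on the read (default 100: junction scars exist).
#' @param cluster_radius Boundary-merge radius in bp (default 50).
#' @param reads Optional named character vector of read sequences. When
#'   supplied, each per-read boundary candidate is refined by a breakpoint
#'   scan that maximizes host identity inside the retained flank minus
#'   host identity beyond it — this removes the small systematic overshoot
#'   that alignment-end extension produces at junctions.
#' @return data.frame of integration calls: `chrom`, `left_boundary`,
#'   `right_boundary`, `deletion_len`, `left_adjacent_strand`,
#'   `right_adjacent_strand`, `n_support_left`, `n_support_right`, plus a
#'   `support` list-column of read ids per call. Empty when no chimeric
#'   read exists.
#' @export
call_junctions <- function(segments, registry, max_junction_gap = 100L,
                           cluster_radius = 50L, reads = NULL) {
  stopifnot(inherits(registry, "tg_registry"))
  cand <- junction_candidates(segments, registry, max_junction_gap, reads)
  if (nrow(cand) == 0) return(empty_integration_calls())
  # the marker lies inside the unit, so one junction can surface twice on
  # a read (host|unit and host|marker); collapse identical candidates
  cand <- cand[!duplicated(cand[c("read_id", "chrom", "side", "pos")]), ,
               drop = FALSE]

  calls <- list()
  for (chrom in unique(cand$chrom)) {
    cc <- cand[cand$chrom == chrom, , drop = FALSE]
    lefts <- cluster_boundaries(cc[cc$side == "left", , drop = FALSE],
                                cluster_radius)
    rights <- cluster_boundaries(cc[cc$side == "right", , drop = FALSE],
                                 cluster_radius)
    used_r <- rep(FALSE, nrow(rights))
    for (i in seq_len(nrow(lefts))) {
      j <- which(!used_r & rights$pos > lefts$pos[i])
      j <- j[which.min(rights$pos[j])]
      if (length(j) == 1) {
        used_r[j] <- TRUE
        calls[[length(calls) + 1]] <- data.frame(
          chrom = chrom, left_boundary = lefts$pos[i],
          right_boundary = rights$pos[j],
          deletion_len = deletion_length(lefts$pos[i], rights$pos[j]),
          left_adjacent_strand = lefts$adj[i],
          right_adjacent_strand = rights$adj[j],
          n_support_left = lefts$n[i], n_support_right = rights$n[j],
          stringsAsFactors = FALSE)
        calls[[length(calls)]]$support <-
          list(unique(c(lefts$reads[[i]], rights$reads[[j]])))
      } else {
        calls[[length(calls) + 1]] <- one_sided_call(chrom, lefts[i, ],
                                                     side = "left")
      }
    }
    for (j in which(!used_r)) {
      calls[[length(calls) + 1]] <- one_sided_call(chrom, rights[j, ],
                                                   side = "right")
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

empty_integration_calls <- function() {
  data.frame(chrom = character(), left_boundary = integer(),
             right_boundary = integer(), deletion_len = integer(),
             left_adjacent_strand = character(),
             right_adjacent_strand = character(),
             n_support_left = integer(), n_support_right = integer(),
             stringsAsFactors = FALSE)
}

one_sided_call <- function(chrom, cl, side) {
  df <- data.frame(chrom = chrom,
                   left_boundary = if (side == "left") cl$pos else NA_integer_,
                   right_boundary = if (side == "right") cl$pos else NA_integer_,
                   deletion_len = NA_integer_,
                   left_adjacent_strand = if (side == "left") cl$adj else NA,
                   right_adjacent_strand = if (side == "right") cl$adj else NA,
                   n_support_left = if (side == "left") cl$n else 0L,
                   n_support_right = if (side == "right") cl$n else 0L,
                   stringsAsFactors = FALSE)
  df$support <- list(cl$reads[[1]])
  df
}

# per-read host/transgene adjacencies -> boundary candidates
junction_candidates <- function(segments, registry, max_junction_gap,
                                reads = NULL) {
  role <- registry$roles[segments$target_id]
  # oriented host sequences, built lazily for boundary refinement
  oriented <- new.env(parent = emptyenv())
  host_oriented <- function(chrom, strand) {
    key <- paste0(chrom, strand)
    if (!is.null(oriented[[key]])) return(oriented[[key]])
    s <- registry$seqs[[chrom]]
    if (strand == "-") s <- cpp_revcomp(s)
    oriented[[key]] <- s
    s
  }
  rows <- list()
  for (id in unique(segments$read_id)) {
    ix <- which(segments$read_id == id)
    ix <- ix[order(segments$read_start[ix])]
    rl <- role[ix]
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in (a + 1):length(ix)) {
        gap <- segments$read_start[ix[b]] - segments$read_end[ix[a]]
        if (gap > max_junction_gap) break
        pair_roles <- rl[c(a, b)]
        if (!("host" %in% pair_roles)) next
        other <- setdiff(which(pair_roles %in% c("transgene", "marker")), NA)
        if (length(other) == 0) next
        hi <- ix[c(a, b)][pair_roles == "host"][1]
        ti <- ix[c(a, b)][pair_roles != "host"][1]
        host_first <- segments$read_start[hi] <= segments$read_start[ti]
        hs <- segments$strand[hi]
        ts <- segments$target_start[hi]; te <- segments$target_end[hi]
        Lh <- segments$target_len[hi]
        # refine the host-side endpoint with a breakpoint scan when the
        # read sequences are available
        tso <- if (hs == "+") ts else Lh - te
        teo <- if (hs == "+") te else Lh - ts
        refined <- NULL
        if (!is.null(reads) && id %in% names(reads)) {
          rd <- reads[[id]]
          oh <- host_oriented(segments$target_id[hi], hs)
          # the partner transgene segment's diagonal, oriented to the read
          tgs <- segments$strand[ti]
          ot <- host_oriented(segments$target_id[ti], tgs)
          us <- if (tgs == "+") segments$target_start[ti]
                else segments$target_len[ti] - segments$target_end[ti]
          ue <- if (tgs == "+") segments$target_end[ti]
                else segments$target_len[ti] - segments$target_start[ti]
          if (host_first) {
            r0 <- segments$read_end[hi]
            u0 <- us + (r0 - segments$read_start[ti])
            refined <- refine_breakpoint(rd, oh, ot, r0, teo, u0, +1L,
                                         u_edge = us)
          } else {
            r0 <- segments$read_start[hi]
            u0 <- us + (r0 - segments$read_start[ti])
            refined <- refine_breakpoint(rd, oh, ot, r0, tso, u0, -1L,
                                         u_edge = ue)
          }
        }
        if (host_first) {
          side <- if (hs == "+") "left" else "right"
          e_o <- if (!is.null(refined)) refined else teo
          pos <- if (hs == "+") e_o else Lh - e_o + 1L
        } else {
          side <- if (hs == "+") "right" else "left"
          s_o <- if (!is.null(refined)) refined else tso
          pos <- if (hs == "+") s_o + 1L else Lh - s_o
        }
        tg_strand <- segments$strand[ti]
        adj <- if (hs == "+") tg_strand else chartr("+-", "-+", tg_strand)
        rows[[length(rows) + 1]] <- data.frame(
          read_id = id, chrom = segments$target_id[hi], side = side,
          pos = as.integer(pos), adj = adj, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(read_id = character(), chrom = character(),
                      side = character(), pos = integer(), adj = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Breakpoint changepoint scan. The read around a junction matches the
# host diagonal before the breakpoint and the transgene diagonal after it
# (or vice versa for dir = -1). Coincidental host matches just past the
# junction cannot fool a two-sided statistic: per position we score
# z = (host match) - (transgene match) (sign-flipped for dir = -1) and
# place the breakpoint at the prefix-sum argmax over +/- `scan` bp,
# breaking ties toward the un-refined estimate. r0/t0/u0 are 0-based
# junction estimates on the read, the oriented host and the oriented
# transgene; diagonals advance together.
refine_breakpoint <- function(rd, oh, ot, r0, t0, u0, dir, u_edge = u0,
                              scan = 40L, slack = 16L) {
  Lr <- nchar(rd)
  w_lo <- max(0L, r0 - scan); w_hi <- min(Lr, r0 + scan)
  n <- w_hi - w_lo
  if (n <= 0) return(NULL)
  rwin <- substr(rd, w_lo + 1L, w_hi)
  # host side: pure diagonal while intact (no read indel in the window) —
  # a gapped path could harvest coincidental off-diagonal matches just
  # past the junction and drag the boundary into deleted sequence. The
  # gapped global path is the fallback for indel-broken diagonals.
  tpos <- t0 + (w_lo - r0) + seq_len(n) - 1L
  okh <- tpos >= 0L & tpos < nchar(oh)
  xh <- logical(n)
  if (any(okh)) {
    xh[okh] <- charToRaw(substr(oh, tpos[which(okh)[1]] + 1L,
                                tpos[which(okh)[length(which(okh))]] + 1L)) ==
      charToRaw(substr(rwin, which(okh)[1], which(okh)[length(which(okh))]))
  }
  hpos <- ifelse(okh, tpos, NA_integer_)
  host_side <- if (dir > 0) seq_len(n) <= (r0 - w_lo) else
    seq_len(n) > (r0 - w_lo)
  probe <- okh & host_side
  if (sum(probe) >= 8 && mean(xh[probe]) < 0.8) {
    h_lo <- max(0L, t0 - (r0 - w_lo) - slack)
    h_hi <- min(nchar(oh), t0 + (w_hi - r0) + slack)
    if (h_hi <= h_lo) return(NULL)
    ph <- cpp_align_path(rwin, substr(oh, h_lo + 1L, h_hi))
    xh <- ph$match
    hpos <- ifelse(ph$b_index >= 0, h_lo + ph$b_index, NA_integer_)
  }
  # transgene side: local alignment against the transgene window clipped
  # at the estimated attachment point, so no transgene sequence is
  # available to extend across the junction — this anchors the
  # changepoint at the attachment even across coincidental host matches,
  # while gapped alignment absorbs read indels
  if (dir > 0) {
    t_lo <- max(0L, min(u0, u_edge) - slack)
    t_hi <- min(nchar(ot), u0 + n + slack)
  } else {
    t_lo <- max(0L, u0 - n - slack)
    t_hi <- min(nchar(ot), max(u0, u_edge) + slack)
  }
  xt <- logical(n)
  if (t_hi > t_lo) {
    pt <- cpp_align_local(rwin, substr(ot, t_lo + 1L, t_hi))
    xt <- pt$match
  }
  z <- as.integer(xh) - as.integer(xt)
  if (dir < 0) z <- -z
  s <- c(0L, cumsum(z))   # s[i] = score of breakpoint before window pos i
  best <- which(s == max(s))
  # microhomology makes the statistic flat across the ambiguous bases;
  # the retained-base convention resolves it toward the host side
  bp <- if (dir > 0) best[1] else best[length(best)]
  if (dir > 0) {
    ix <- which(!is.na(hpos) & seq_len(n) < bp)
    if (!length(ix)) return(NULL)
    hpos[max(ix)] + 1L    # 0-based exclusive end of retained host
  } else {
    ix <- which(!is.na(hpos) & seq_len(n) >= bp)
    if (!length(ix)) return(NULL)
    hpos[min(ix)]         # 0-based first retained host base
  }
}

cluster_boundaries <- function(cand, radius) {
  if (nrow(cand) == 0) {
    return(data.frame(pos = integer(), adj = character(), n = integer())[0, ])
  }
  cand <- cand[order(cand$pos), , drop = FALSE]
  grp <- cumsum(c(1L, diff(cand$pos) > radius))
  res <- lapply(split(seq_len(nrow(cand)), grp), function(ix) {
    adj_tab <- table(cand$adj[ix])
    out <- data.frame(pos = as.integer(round(median(cand$pos[ix]))),
                      adj = names(adj_tab)[which.max(adj_tab)],
                      n = length(ix), stringsAsFactors = FALSE)
    out$reads <- list(unique(cand$read_id[ix]))
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect array-internal inversions from strand flips
#'
#' One event per adjacent pair of transgene segments on a read with
#' opposite strands; the flip position is the midpoint of the
#' inter-segment gap on the read. Evidence is kept per read (deduplication
#' across reads is a reporting concern).
#'
#' @param segments Segment data.frame.
#' @param registry The [target_registry()].
#' @return data.frame: `read_id`, `read_position`, `from_strand`,
#'   `to_strand`.
#' @export
detect_inversions <- function(segments, registry) {
  stopifnot(inherits(registry, "tg_registry"))
  role <- registry$roles[segments$target_id]
  tg <- segments[role == "transgene", , drop = FALSE]
  rows <- list()
  for (id in unique(tg$read_id)) {
    sg <- tg[tg$read_id == id, , drop = FALSE]
    if (nrow(sg) < 2) next
    sg <- sg[order(sg$read_start), , drop = FALSE]
    for (i in seq_len(nrow(sg) - 1)) {
      if (sg$strand[i] != sg$strand[i + 1]) {
        rows[[length(rows) + 1]] <- data.frame(
          read_id = id,
          read_position = as.integer(round(
            (sg$read_end[i] + sg$read_start[i + 1]) / 2)),
          from_strand = sg$strand[i], to_strand = sg$strand[i + 1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(read_id = character(), read_position = integer(),
                      from_strand = character(), to_strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect co-integrated foreign DNA
#'
#' Contaminant-role segments on a read are merged; the observed length is
#' the union span on the contaminant target. The call is bounded
#' (`bounded_by_reads = TRUE`) only when host/transgene segments flank the
#' contaminant on both sides of some read — otherwise the reported length
#' is a lower bound (a read that terminates inside foreign DNA cannot see
#' its far end).
#'
#' @param segments Segment data.frame.
#' @param registry The [target_registry()] (must hold a contaminant-role
#'   target for anything to be found).
#' @return data.frame per contaminant target: `contaminant_id`,
#'   `observed_length`, `bounded_by_reads`, `n_reads`,
#'   `left_neighbor_strand`, `right_neighbor_strand`, and a `support`
#'   list-column of read ids.
#' @export
detect_contaminant <- function(segments, registry) {
  stopifnot(inherits(registry, "tg_registry"))
  role <- registry$roles[segments$target_id]
  ct <- segments[role == "contaminant", , drop = FALSE]
  if (nrow(ct) == 0) {
    return(data.frame(contaminant_id = character(),
                      observed_length = integer(),
                      bounded_by_reads = logical(), n_reads = integer(),
                      left_neighbor_strand = character(),
                      right_neighbor_strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (cid in unique(ct$target_id)) {
    best_len <- 0L; bounded <- FALSE; reads <- character(0)
    lns <- NA_character_; rns <- NA_character_
    for (id in unique(ct$read_id[ct$target_id == cid])) {
      sg <- ct[ct$read_id == id & ct$target_id == cid, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(sg$target_start + 1L,
                                             sg$target_end))
      len <- sum(IRanges::width(ir))
      reads <- c(reads, id)
      on_read <- segments$read_id == id
      other <- segments[on_read & role %in% c("host", "transgene", "marker"),
                        , drop = FALSE]
      r0 <- min(sg$read_start); r1 <- max(sg$read_end)
      left_fl <- other[other$read_end <= r0 + 100, , drop = FALSE]
      right_fl <- other[other$read_start >= r1 - 100, , drop = FALSE]
      this_bounded <- nrow(left_fl) > 0 && nrow(right_fl) > 0
      if (len > best_len || (this_bounded && !bounded)) {
        if (len > best_len) best_len <- len
        if (this_bounded) {
          bounded <- TRUE
          lf <- left_fl[which.max(left_fl$read_end), ]
          rf <- right_fl[which.min(right_fl$read_start), ]
          lns <- lf$strand; rns <- rf$strand
        }
      }
    }
    df <- data.frame(contaminant_id = cid, observed_length = best_len,
                     bounded_by_reads = bounded, n_reads = length(reads),
                     left_neighbor_strand = lns,
                     right_neighbor_strand = rns, stringsAsFactors = FALSE)
    df$support <- list(reads)
    out[[length(out) + 1]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Minimal tiling path across the transgene array
#'
#' Lays marker-bearing reads out in a common array coordinate frame by
#' read-vs-read overlap alignment, anchored on a junction-bearing
#' (chimeric) read where one exists (else the read with most marker
#' matches). Greedy furthest-reach selection then picks the
#' minimum-cardinality chain of reads covering the maximal contiguous
#' stretch of array reachable from the anchor (ties broken toward the
#' longer read); the copy-number lower bound is the number of distinct,
#' fully covered marker copies in the chain's union. The bound is sound:
#' it never exceeds the true copy number.
#'
#' @param reads Named character vector of read sequences.
#' @param classifications Result of [classify_reads()].
#' @param min_overlap Minimum read-to-read overlap in bp for consecutive
#'   path reads (default 500).
#' @param k Seed size for the overlap alignments.
#' @param marker_full_cov Fraction of the marker length that must be
#'   covered for a copy to count toward the bound (default 0.95).
#' @param registry The [target_registry()] (for the marker length) — used
#'   with `segments` to project marker copies into the layout.
#' @param segments Segment data.frame for the same reads.
#' @return A `tg_tiling_path`: list with `read_ids` (path order),
#'   `offsets`, `orientations`, `marker_counts`, `lower_bound_copies`.
#' @export
minimal_tiling_path <- function(reads, segments, classifications, registry,
                                min_overlap = 500L, k = 15L,
                                marker_full_cov = 0.95) {
  stopifnot(inherits(registry, "tg_registry"))
  mk_ids <- classifications$read_id[classifications$marker_match_count >= 1]
  if (length(mk_ids) == 0) {
    stop("empty evidence: no marker-bearing reads", call. = FALSE)
  }
  reads <- reads[names(reads) %in% mk_ids]
  cls <- classifications[match(names(reads), classifications$read_id), ]

  # anchor: junction-bearing read if any, else most marker matches
  anchor <- if (any(cls$chimeric)) {
    names(reads)[cls$chimeric][which.max(cls$marker_match_count[cls$chimeric])]
  } else {
    names(reads)[which.max(cls$marker_match_count)]
  }

  placed <- data.frame(read_id = anchor, offset = 0,
                       orient = 1L, len = nchar(reads[[anchor]]),
                       stringsAsFactors = FALSE)
  unplaced <- setdiff(names(reads), anchor)

  # A placement is accepted only when the overlap alignment is a proper
  # dovetail: it must run to the facing read ends (up to `edge_slop`), as
  # a true overlap between reads of one molecule does. Alignments that
  # merely share an internal repeat copy are not placements.
  edge_slop <- 150L
  extend_dir <- function(placed, unplaced, dir) {
    repeat {
      frontier <- if (dir > 0) placed[which.max(placed$offset + placed$len), ]
                  else placed[which.min(placed$offset), ]
      fseq <- reads[[frontier$read_id]]
      fidx <- index_targets(setNames(fseq, "f"), k = k)
      reach <- if (dir > 0) frontier$offset + frontier$len
               else frontier$offset
      best <- NULL
      for (id in unplaced) {
        sg <- align_reads(reads[id], fidx, min_segment_len = min_overlap,
                          min_identity = 0.7, dedup = FALSE)
        if (nrow(sg) == 0) next
        L <- nchar(reads[[id]])
        fl <- frontier$len
        # keep the best-supported dovetail placement: with a tandem
        # repeat this is the true placement when a landmark (junction,
        # inversion, foreign edge) falls in the overlap, and an inward
        # repeat-shifted one otherwise — never an outward overshoot, so
        # the copy bound stays conservative
        dov <- vapply(seq_len(nrow(sg)), function(si) {
          s <- sg[si, ]
          if (s$strand == "+") {
            min(s$read_start, s$target_start) <= edge_slop &&
              min(L - s$read_end, fl - s$target_end) <= edge_slop
          } else {
            min(s$read_start, fl - s$target_end) <= edge_slop &&
              min(L - s$read_end, s$target_start) <= edge_slop
          }
        }, logical(1))
        sg <- sg[dov, , drop = FALSE]
        if (nrow(sg) == 0) next
        # rank placements by identity, then matches: divergence between
        # copies makes the true placement the most identical one, while
        # among exact-repeat ties the larger overlap (inward) wins
        ident <- round(sg$n_match / sg$block_len, 3)
        for (si in order(-ident, -sg$n_match)[1]) {
          s <- sg[si, ]
          rel <- if (s$strand == "+") 1L else -1L
          orient <- frontier$orient * rel
          if (frontier$orient == 1L) {
            if (rel == 1L) off <- frontier$offset + s$target_start - s$read_start
            else off <- frontier$offset + s$target_start - (L - s$read_end)
          } else {
            if (rel == 1L) off <- frontier$offset + (fl - s$target_end) -
                (L - s$read_end)
            else off <- frontier$offset + (fl - s$target_end) - s$read_start
          }
          new_reach <- if (dir > 0) off + L else off
          gain <- dir * (new_reach - reach)
          overlap <- if (dir > 0) reach - off else off + L - reach
          if (overlap < min_overlap) next
          if (gain <= 0) next
          if (is.null(best) || gain > best$gain ||
              (gain == best$gain && L > best$len)) {
            best <- list(read_id = id, offset = off, orient = orient,
                         len = L, gain = gain)
          }
        }
      }
      if (is.null(best)) break
      placed <- rbind(placed, data.frame(read_id = best$read_id,
                                         offset = best$offset,
                                         orient = best$orient,
                                         len = best$len,
                                         stringsAsFactors = FALSE))
      unplaced <- setdiff(unplaced, best$read_id)
    }
    list(placed = placed, unplaced = unplaced)
  }

  st <- extend_dir(placed, unplaced, +1L)
  st <- extend_dir(st$placed, st$unplaced, -1L)
  placed <- st$placed[order(st$placed$offset), , drop = FALSE]

  bounds <- junction_layout_bounds(placed, segments, registry)
  lb <- count_marker_copies(placed, segments, reads, registry,
                            marker_full_cov, bounds)
  lb <- max(lb, max(cls$marker_match_count[match(placed$read_id,
                                                 cls$read_id)]))
  structure(list(read_ids = placed$read_id, offsets = placed$offset,
                 orientations = ifelse(placed$orient > 0, "+", "-"),
                 marker_counts = cls$marker_match_count[
                   match(placed$read_id, cls$read_id)],
                 lower_bound_copies = as.integer(lb)),
            class = "tg_tiling_path")
}

# layout coordinates of the array ends, pinned by chimeric path reads:
# host segments mark where the array stops, so marker projections beyond
# them are layout artifacts
junction_layout_bounds <- function(placed, segments, registry) {
  role <- registry$roles[segments$target_id]
  lo <- -Inf; hi <- Inf
  for (i in seq_len(nrow(placed))) {
    id <- placed$read_id[i]
    hseg <- segments[segments$read_id == id & role == "host", , drop = FALSE]
    tseg <- segments[segments$read_id == id & role == "transgene", ,
                     drop = FALSE]
    if (nrow(hseg) == 0 || nrow(tseg) == 0) next
    L <- placed$len[i]
    to_layout <- function(x) {
      if (placed$orient[i] == 1L) placed$offset[i] + x
      else placed$offset[i] + (L - x)
    }
    for (j in seq_len(nrow(hseg))) {
      # the host flank faces away from the array; its junction-side end
      # bounds the array in layout space
      host_mid <- to_layout((hseg$read_start[j] + hseg$read_end[j]) / 2)
      tg_mid <- mean(vapply((tseg$read_start + tseg$read_end) / 2,
                            to_layout, numeric(1)))
      if (host_mid < tg_mid) {
        lo <- max(lo, to_layout(if (placed$orient[i] == 1L)
          hseg$read_end[j] else hseg$read_start[j]))
      } else {
        hi <- min(hi, to_layout(if (placed$orient[i] == 1L)
          hseg$read_start[j] else hseg$read_end[j]))
      }
    }
  }
  c(lo, hi)
}

# project full-marker segments of the placed reads into layout
# coordinates, clip to the junction-pinned array bounds, and count
# distinct copies: clusters separated by more than half a unit length
# (marker copies repeat with unit period, so anything closer is the same
# copy seen through layout noise)
count_marker_copies <- function(placed, segments, reads, registry,
                                marker_full_cov, bounds = c(-Inf, Inf)) {
  mlen <- registry$marker_length
  ulen <- if (!is.na(registry$unit_id) &&
              registry$unit_id %in% names(registry$seqs)) {
    nchar(registry$seqs[[registry$unit_id]])
  } else 4 * mlen
  role <- registry$roles[segments$target_id]
  mids <- numeric(0)
  for (i in seq_len(nrow(placed))) {
    id <- placed$read_id[i]
    sg <- segments[segments$read_id == id & role == "marker", , drop = FALSE]
    sg <- sg[(sg$target_end - sg$target_start) >= marker_full_cov * mlen, ,
             drop = FALSE]
    if (nrow(sg) == 0) next
    L <- placed$len[i]
    mid_read <- (sg$read_start + sg$read_end) / 2
    mid_layout <- if (placed$orient[i] == 1L) placed$offset[i] + mid_read
                  else placed$offset[i] + (L - mid_read)
    mids <- c(mids, mid_layout)
  }
  mids <- mids[mids >= bounds[1] - 100 & mids <= bounds[2] + 100]
  if (length(mids) == 0) return(0L)
  mids <- sort(mids)
  n <- sum(c(TRUE, diff(mids) > ulen / 2))
  if (is.finite(bounds[1]) && is.finite(bounds[2])) {
    # the pinned span holds floor(span/unit) whole copies; the 0.2-unit
    # tolerance absorbs boundary jitter without admitting a phantom copy
    # (placements only ever shift inward)
    n <- min(n, floor((bounds[2] - bounds[1]) / ulen + 0.2))
  }
  n
}

#' @export
print.tg_tiling_path <- function(x, ...) {
  cat(sprintf("tiling path: %d reads, lower bound %d copies\n",
              length(x$read_ids), x$lower_bound_copies))
  invisible(x)
}
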
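#' Read gene models from BED12 or GFF3
#'
#' Imports gene models via rtracklayer and reduces them to named CDS
#' interval sets. For GFF3, `CDS` features are grouped by gene (via
#' `gene`/`Name`/`Parent`/`ID`, first available); for BED12, the blocks of
#' each record are used.
#'
#' @param path BED12 or GFF3 file.
#' @return data.frame: `gene`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open CDS intervals, one row per interval).
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "bed") {
    blocks <- rtracklayer::blocks(gr)
    names(blocks) <- gr$name
    rows <- lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      data.frame(gene = names(blocks)[i],
                 chrom = as.character(GenomicRanges::seqnames(gr)[i]),
                 strand = as.character(GenomicRanges::strand(gr)[i]),
                 start = GenomicRanges::start(b) - 1L,
                 end = GenomicRanges::end(b), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    cds <- gr[gr$type == "CDS"]
    md <- S4Vectors::mcols(cds)
    gene <- NULL
    for (f in c("gene", "Name", "Parent", "ID")) {
      if (f %in% names(md) && !all(is.na(unlist(md[[f]])))) {
        gene <- as.character(unlist(md[[f]])); break
      }
    }
    if (is.null(gene)) stop("cannot determine gene names from GFF3",
                            call. = FALSE)
    out <- data.frame(gene = gene,
                      chrom = as.character(GenomicRanges::seqnames(cds)),
                      strand = as.character(GenomicRanges::strand(cds)),
                      start = GenomicRanges::start(cds) - 1L,
                      end = GenomicRanges::end(cds),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Verify integrity of genes near the integration site
#'
#' A gene is *encompassed* when a single read's merged host-aligned span
#' contains its whole CDS span (matching the evidentiary standard of one
#' read covering the entire protein coding sequence); *uncovered* intervals
#' are the parts of the CDS span missed by the union of all reads — two
#' deliberately distinct criteria, both reported. A gene overlapping a
#' called integration interval (deleted bases, or the insertion point
#' itself) is flagged disrupted.
#'
#' Host alignments of one read are merged into spans tolerating internal
#' gaps up to `span_gap` bp (long-read alignments fragment); larger gaps
#' split the span.
#'
#' @param gene_models data.frame as from [read_gene_models()] (columns
#'   `gene`, `chrom`, `start`, `end`; 0-based half-open).
#' @param segments Segment data.frame restricted internally to host-role
#'   targets.
#' @param registry The [target_registry()].
#' @param integration Optional integration-call data.frame from
#'   [call_junctions()].
#' @param span_gap Intra-read gap tolerance in bp (default 1000).
#' @return data.frame per gene: `gene`, `chrom`, `encompassed`,
#'   `disrupted`, `n_encompassing_reads`, `uncovered_bp`, plus
#'   list-columns `encompassing_read_ids` and `uncovered_intervals`
#'   (data.frame `start`/`end`, 0-based half-open). Genes on contigs
#'   absent from the registry get an `error` entry instead of results.
#' @export
gene_integrity <- function(gene_models, segments, registry,
                           integration = NULL, span_gap = 1000L) {
  stopifnot(inherits(registry, "tg_registry"))
  role <- registry$roles[segments$target_id]
  host <- segments[role == "host", , drop = FALSE]
  out <- list()
  for (g in unique(gene_models$gene)) {
    gm <- gene_models[gene_models$gene == g, , drop = FALSE]
    chrom <- gm$chrom[1]
    if (!chrom %in% names(registry$seqs)) {
      out[[length(out) + 1]] <- gene_row(g, chrom, error = "unknown contig")
      next
    }
    span0 <- min(gm$start); span1 <- max(gm$end)
    hs <- host[host$target_id == chrom, , drop = FALSE]
    enc_reads <- character(0)
    all_spans <- IRanges::IRanges()
    for (id in unique(hs$read_id)) {
      sg <- hs[hs$read_id == id, , drop = FALSE]
      spans <- IRanges::reduce(
        IRanges::IRanges(sg$target_start + 1L, sg$target_end),
        min.gapwidth = span_gap + 1L)
      all_spans <- c(all_spans, spans)
      if (any(IRanges::start(spans) <= span0 + 1L &
              IRanges::end(spans) >= span1)) {
        enc_reads <- c(enc_reads, id)
      }
    }
    covered <- IRanges::reduce(all_spans)
    gene_rng <- IRanges::IRanges(span0 + 1L, span1)
    unc <- IRanges::setdiff(gene_rng, covered)
    disrupted <- FALSE
    if (!is.null(integration) && nrow(integration) > 0) {
      for (i in seq_len(nrow(integration))) {
        if (!identical(integration$chrom[i], chrom)) next
        lb <- integration$left_boundary[i]
        rb <- integration$right_boundary[i]
        if (is.na(lb) || is.na(rb)) next
        # deleted bases lb+1..rb-1 overlap the gene, or the insertion
        # point falls strictly inside it
        del_olap <- (lb + 1L <= span1) && (rb - 1L >= span0 + 1L) &&
          (rb - lb - 1L > 0L)
        junction_inside <- lb >= span0 + 1L && lb < span1
        if (del_olap || junction_inside) disrupted <- TRUE
      }
    }
    out[[length(out) + 1]] <- gene_row(
      g, chrom, encompassed = length(enc_reads) > 0, disrupted = disrupted,
      enc_reads = enc_reads,
      uncovered = data.frame(start = IRanges::start(unc) - 1L,
                             end = IRanges::end(unc)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

gene_row <- function(gene, chrom, encompassed = NA, disrupted = NA,
                     enc_reads = character(0),
                     uncovered = data.frame(start = integer(),
                                            end = integer()),
                     error = NA_character_) {
  df <- data.frame(gene = gene, chrom = chrom, encompassed = encompassed,
                   disrupted = disrupted,
                   n_encompassing_reads = length(enc_reads),
                   uncovered_bp = sum(uncovered$end - uncovered$start),
                   error = error, stringsAsFactors = FALSE)
  df$encompassing_read_ids <- list(enc_reads)
  df$uncovered_intervals <- list(uncovered)
  df
}

#' Propose PCR-gap intervals
#'
#' Each uncovered interval is extended by `flank` bp on both sides
#' (clipped to the contig), and overlapping proposals are merged: these
#' are the regions a follow-up PCR assay must span to close the remaining
#' gaps.
#'
#' @param results Result of [gene_integrity()].
#' @param flank Extension in bp (default 300).
#' @param contig_lengths Named vector of contig lengths for clipping
#'   (optional).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open).
#' @export
propose_gap_intervals <- function(results, flank = 300L,
                                  contig_lengths = NULL) {
  rows <- list()
  for (i in seq_len(nrow(results))) {
    unc <- results$uncovered_intervals[[i]]
    if (is.null(unc) || nrow(unc) == 0) next
    rows[[length(rows) + 1]] <- data.frame(chrom = results$chrom[i],
                                           start = unc$start, end = unc$end)
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gaps <- do.call(rbind, rows)
  out <- list()
  for (chrom in unique(gaps$chrom)) {
    gg <- gaps[gaps$chrom == chrom, , drop = FALSE]
    s <- pmax(0L, gg$start - flank)
    e <- gg$end + flank
    if (!is.null(contig_lengths) && chrom %in% names(contig_lengths)) {
      e <- pmin(e, contig_lengths[[chrom]])
    }
    mr <- IRanges::reduce(IRanges::IRanges(s + 1L, e))
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom, start = IRanges::start(mr) - 1L,
      end = IRanges::end(mr), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
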
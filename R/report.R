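#' Run the full integration-analysis pipeline
#'
#' Sequences the stages: align -> screen -> structure (junctions,
#' inversions, contaminant, tiling path) -> integrity (optional, when gene
#' models are supplied) -> qPCR (optional, when a Ct table is supplied).
#' Deterministic given the config. A stage failure is recorded in
#' `$errors` and its dependents are skipped, with the report still emitted
#' for completed stages.
#'
#' @param config List:
#'   \describe{
#'     \item{reads}{named character vector of read sequences (or a FASTQ
#'       path).}
#'     \item{registry}{a [target_registry()].}
#'     \item{genome_size}{bp, for fold-coverage.}
#'     \item{gene_models}{optional data.frame or BED/GFF3 path.}
#'     \item{qpcr}{optional `list(ct=, calibrator=, calibrator_copies=,
#'       test_alleles=)`.}
#'     \item{k, min_segment_len, min_identity, min_marker_cov,
#'       max_junction_gap, cluster_radius, min_overlap}{module parameters
#'       (package defaults when absent).}
#'   }
#' @return A `tg_report` list: `run_stats`, `classifications`,
#'   `marker_counts`, `copy_estimates`, `integration_calls`, `inversions`,
#'   `contaminants`, `tiling_path`, `gene_integrity`, `parameters`,
#'   `errors`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  defaults <- list(k = 15L, min_segment_len = 200L, min_identity = 0.6,
                   min_marker_cov = 0.5, max_junction_gap = 100L,
                   cluster_radius = 50L, min_overlap = 500L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.character(cfg$reads) && length(cfg$reads) == 1 &&
      file.exists(cfg$reads)) {
    cfg$reads <- read_seqs(cfg$reads, format = "fastq")
  }
  stopifnot(inherits(cfg$registry, "tg_registry"))
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  rs <- run_stats(cfg$reads, cfg$genome_size)

  segments <- tryCatch({
    idx <- index_targets(cfg$registry, k = cfg$k)
    align_reads(cfg$reads, idx, min_segment_len = cfg$min_segment_len,
                min_identity = cfg$min_identity)
  }, error = function(e) { note("align", e); NULL })

  cls <- mc <- est_depth <- calls <- inv <- ct <- tp <- NULL
  if (!is.null(segments)) {
    cls <- tryCatch(classify_reads(segments, cfg$registry,
                                   min_marker_cov = cfg$min_marker_cov,
                                   read_ids = names(cfg$reads)),
                    error = function(e) { note("screen", e); NULL })
    if (!is.null(cls)) {
      mc <- count_marker_matches(cls)
      est_depth <- if (mc$total_matches > 0 && rs$coverage > 0) {
        copy_number_from_depth(mc$total_matches, rs$coverage)
      }
    }
    calls <- tryCatch(call_junctions(segments, cfg$registry,
                                     max_junction_gap = cfg$max_junction_gap,
                                     cluster_radius = cfg$cluster_radius,
                                     reads = cfg$reads),
                      error = function(e) { note("junctions", e); NULL })
    inv <- tryCatch(detect_inversions(segments, cfg$registry),
                    error = function(e) { note("inversions", e); NULL })
    ct <- tryCatch(detect_contaminant(segments, cfg$registry),
                   error = function(e) { note("contaminant", e); NULL })
    if (!is.null(cls) && any(cls$marker_match_count >= 1)) {
      tp <- tryCatch(minimal_tiling_path(cfg$reads, segments, cls,
                                         cfg$registry,
                                         min_overlap = cfg$min_overlap,
                                         k = cfg$k),
                     error = function(e) { note("tiling", e); NULL })
    }
  }

  gi <- NULL
  if (!is.null(cfg$gene_models) && !is.null(segments)) {
    gm <- cfg$gene_models
    if (is.character(gm)) gm <- read_gene_models(gm)
    gi <- tryCatch(gene_integrity(gm, segments, cfg$registry,
                                  integration = calls),
                   error = function(e) { note("integrity", e); NULL })
  }

  qp <- NULL
  if (!is.null(cfg$qpcr)) {
    qp <- tryCatch({
      rqs <- delta_delta_ct(cfg$qpcr$ct, calibrator = cfg$qpcr$calibrator)
      test <- rqs[rqs$sample_id != cfg$qpcr$calibrator, , drop = FALSE]
      est <- copies_per_allele(
        test,
        calibrator_copies_per_genome =
          if (is.null(cfg$qpcr$calibrator_copies)) 1
          else cfg$qpcr$calibrator_copies,
        test_alleles = if (is.null(cfg$qpcr$test_alleles)) 1
                       else cfg$qpcr$test_alleles)
      list(rq_table = rqs, estimate = est)
    }, error = function(e) { note("qpcr", e); NULL })
  }

  estimates <- list()
  if (!is.null(est_depth)) estimates$depth <- est_depth
  if (!is.null(tp)) {
    estimates$tiling_lower_bound <-
      new_copy_estimate("tiling_lower_bound", tp$lower_bound_copies,
                        n_support = length(tp$read_ids))
  }
  if (!is.null(qp)) estimates$qpcr <- qp$estimate

  structure(list(
    run_stats = rs, segments = segments, classifications = cls,
    marker_counts = mc, copy_estimates = estimates,
    integration_calls = calls, inversions = inv, contaminants = ct,
    tiling_path = tp, gene_integrity = gi, qpcr = qp,
    parameters = cfg[names(defaults)],
    skipped = c(if (is.null(cfg$gene_models)) "integrity",
                if (is.null(cfg$qpcr)) "qpcr"),
    errors = errors,
    schema_version = "1.0"
  ), class = "tg_report")
}

#' Write a locus report to disk
#'
#' JSON serialization round-trips the report's numeric content; the TSV
#' bundle writes one file per result family. Integration calls are
#' additionally emitted as a VCF-like symbolic breakpoint file (one
#' `SVTYPE=INS` record per boundary with `END`/`SVLEN`), a BED of the
#' deleted reference interval, and a BED of candidate genotyping-primer
#' windows (two ~500 bp host intervals flanking each boundary).
#'
#' @param report A `tg_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "tsv")`.
#' @param primer_flank Width of the primer-candidate windows, bp.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, formats = c("json", "tsv"),
                         primer_flank = 500L) {
  stopifnot(inherits(report, "tg_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  }
  paths <- character(0)
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), p, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null")
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    tsv <- function(df, name) {
      if (is.null(df) || nrow(df) == 0) return(NULL)
      df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
      p <- file.path(dir, paste0(name, ".tsv"))
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <<- c(paths, p)
    }
    tsv(report$segments, "segments")
    tsv(report$classifications, "classifications")
    tsv(report$integration_calls, "integration_calls")
    tsv(report$inversions, "inversions")
    tsv(report$contaminants, "contaminants")
    if (!is.null(report$gene_integrity)) {
      tsv(report$gene_integrity, "gene_integrity")
    }
    if (!is.null(report$qpcr)) tsv(report$qpcr$rq_table, "qpcr_rq")
    if (length(report$copy_estimates)) {
      tsv(do.call(rbind, lapply(report$copy_estimates, as.data.frame)),
          "copy_estimates")
    }
  }
  calls <- report$integration_calls
  if (!is.null(calls) && nrow(calls) > 0) {
    paths <- c(paths,
               write_breakpoint_vcf(calls, file.path(dir, "breakpoints.vcf")),
               write_integration_beds(calls, dir, primer_flank))
  }
  invisible(paths)
}

report_to_list <- function(report) {
  x <- unclass(report)
  x$run_stats <- unclass(x$run_stats)
  x$copy_estimates <- lapply(x$copy_estimates, unclass)
  if (!is.null(x$tiling_path)) x$tiling_path <- unclass(x$tiling_path)
  if (!is.null(x$qpcr)) x$qpcr$estimate <- unclass(x$qpcr$estimate)
  drop_lists <- function(df) {
    if (is.data.frame(df)) df[, !vapply(df, is.list, logical(1)),
                              drop = FALSE] else df
  }
  for (nm in c("segments", "classifications", "integration_calls",
               "inversions", "contaminants", "gene_integrity")) {
    x[[nm]] <- drop_lists(x[[nm]])
  }
  x
}

# VCF-like symbolic insertion breakpoints: one record per boundary, with
# the paired boundary as END and the deleted length as (negative) SVLEN.
write_breakpoint_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Paired boundary\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deleted reference bp\">",
           "##INFO=<ID=SIDE,Number=1,Type=String,Description=\"Boundary side\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  for (i in seq_len(nrow(calls))) {
    lb <- calls$left_boundary[i]; rb <- calls$right_boundary[i]
    dl <- calls$deletion_len[i]
    if (!is.na(lb)) {
      recs <- c(recs, sprintf(
        "%s\t%d\ttg_ins_%dL\tN\t<INS>\t.\tPASS\tSVTYPE=INS;END=%s;SVLEN=%s;SIDE=left",
        calls$chrom[i], lb, i, ifelse(is.na(rb), ".", rb),
        ifelse(is.na(dl), ".", -dl)))
    }
    if (!is.na(rb)) {
      recs <- c(recs, sprintf(
        "%s\t%d\ttg_ins_%dR\tN\t<INS>\t.\tPASS\tSVTYPE=INS;END=%s;SVLEN=%s;SIDE=right",
        calls$chrom[i], rb, i, ifelse(is.na(lb), ".", lb),
        ifelse(is.na(dl), ".", -dl)))
    }
  }
  writeLines(c(hdr, recs), path)
  path
}

write_integration_beds <- function(calls, dir, primer_flank) {
  paths <- character(0)
  del <- calls[!is.na(calls$left_boundary) & !is.na(calls$right_boundary), ,
               drop = FALSE]
  if (nrow(del) > 0) {
    p <- file.path(dir, "deleted_interval.bed")
    write.table(data.frame(del$chrom, del$left_boundary,
                           del$right_boundary - 1L, "deleted"),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, p)
  }
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    lb <- calls$left_boundary[i]; rb <- calls$right_boundary[i]
    if (!is.na(lb)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = calls$chrom[i], start = max(0L, lb - primer_flank),
        end = lb, name = sprintf("primer_window_%dL", i))
    }
    if (!is.na(rb)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = calls$chrom[i], start = rb - 1L,
        end = rb - 1L + primer_flank, name = sprintf("primer_window_%dR", i))
    }
  }
  if (length(rows)) {
    p <- file.path(dir, "primer_windows.bed")
    write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}

#' @export
print.tg_report <- function(x, ...) {
  cat("Transgene locus report\n")
  print(x$run_stats)
  if (!is.null(x$marker_counts)) {
    cat(sprintf("  %d marker-bearing reads, %d marker matches\n",
                x$marker_counts$reads_with_marker,
                x$marker_counts$total_matches))
  }
  for (est in x$copy_estimates) print(est)
  if (!is.null(x$integration_calls) && nrow(x$integration_calls)) {
    ic <- x$integration_calls[1, ]
    cat(sprintf("  integration: %s:%s / %s (deletion %s bp)\n", ic$chrom,
                format(ic$left_boundary, big.mark = ","),
                format(ic$right_boundary, big.mark = ","),
                ic$deletion_len))
  }
  if (length(x$skipped)) {
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  if (length(x$errors)) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
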
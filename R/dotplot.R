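#' Windowed nucleotide dot-plot matches
#'
#' Compares every length-`window` window of `seq_x` (at `step` spacing)
#' with every window of `seq_y`, in both orientations: a forward match
#' where the windows are equal within `max_mismatch` mismatches, a reverse
#' match where the X window equals the reverse complement of the Y window.
#' Exact matching (the default) runs in expected linear time via window
#' hashing; fuzzy matching compares all window pairs.
#'
#' @param seq_x,seq_y Sequences (character). Windows containing N never
#'   match.
#' @param window Window size in bp (default 15).
#' @param step Step between window starts (default 1).
#' @param max_mismatch Mismatches tolerated per window (default 0).
#' @return A `tg_dot_matches`: list with `window`, `step` and `matches`
#'   (data.frame `x`, `y` — 0-based window starts — and `orientation`,
#'   `"forward"`/`"reverse"`).
#' @export
dot_matches <- function(seq_x, seq_y, window = 15L, step = 1L,
                        max_mismatch = 0L) {
  window <- as.integer(window); step <- as.integer(step)
  if (nchar(seq_x) < window || nchar(seq_y) < window) {
    stop("window exceeds a sequence length", call. = FALSE)
  }
  seq_x <- toupper(seq_x); seq_y <- toupper(seq_y)
  if (max_mismatch == 0L && window <= 26L) {
    cx <- cpp_window_codes(seq_x, window, step)
    cy <- cpp_window_codes(seq_y, window, step)
    dx <- data.table::data.table(x = cx$pos, code = cx$fw)
    dyf <- data.table::data.table(y = cy$pos, code = cy$fw)
    dyr <- data.table::data.table(y = cy$pos, code = cy$rc)
    fwd <- merge(dx, dyf, by = "code", allow.cartesian = TRUE)
    rev <- merge(dx, dyr, by = "code", allow.cartesian = TRUE)
    m <- rbind(
      if (nrow(fwd)) data.frame(x = fwd$x, y = fwd$y,
                                orientation = "forward") else NULL,
      if (nrow(rev)) data.frame(x = rev$x, y = rev$y,
                                orientation = "reverse") else NULL)
  } else {
    m <- dot_matches_fuzzy(seq_x, seq_y, window, step, max_mismatch)
  }
  if (is.null(m) || nrow(m) == 0) {
    m <- data.frame(x = integer(), y = integer(),
                    orientation = character(), stringsAsFactors = FALSE)
  }
  m <- m[order(m$orientation, m$x, m$y), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(window = window, step = step, matches = m),
            class = "tg_dot_matches")
}

# all-pairs window comparison with a mismatch budget
dot_matches_fuzzy <- function(seq_x, seq_y, window, step, max_mismatch) {
  xs <- seq(1L, nchar(seq_x) - window + 1L, by = step)
  ys <- seq(1L, nchar(seq_y) - window + 1L, by = step)
  ymat <- vapply(ys, function(p)
    strsplit(substr(seq_y, p, p + window - 1L), "")[[1]],
    character(window))
  yrc <- vapply(ys, function(p)
    strsplit(cpp_revcomp(substr(seq_y, p, p + window - 1L)), "")[[1]],
    character(window))
  rows <- list()
  for (xp in xs) {
    w <- strsplit(substr(seq_x, xp, xp + window - 1L), "")[[1]]
    has_n <- any(w == "N")
    mmf <- colSums(ymat != w) + ifelse(colSums(ymat == "N") > 0 | has_n,
                                       window, 0)
    mmr <- colSums(yrc != w) + ifelse(colSums(yrc == "N") > 0 | has_n,
                                      window, 0)
    hf <- which(mmf <= max_mismatch)
    hr <- which(mmr <= max_mismatch)
    if (length(hf)) rows[[length(rows) + 1]] <-
      data.frame(x = xp - 1L, y = ys[hf] - 1L, orientation = "forward")
    if (length(hr)) rows[[length(rows) + 1]] <-
      data.frame(x = xp - 1L, y = ys[hr] - 1L, orientation = "reverse")
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Segment dot-plot matches into diagonal runs
#'
#' Maximal runs of matches with constant orientation advancing by
#' `(step, +step)` (forward) or `(step, -step)` (reverse). Inversions in a
#' tandem array surface as orientation changes between adjacent runs.
#'
#' @param dm A [dot_matches()] result.
#' @param min_run Minimum number of matches per reported run.
#' @return data.frame sorted by `x0`: `orientation`, `x0`, `y0`, `x1`,
#'   `y1` (inclusive window-start coordinates of the run ends),
#'   `run_length`.
#' @export
segment_diagonals <- function(dm, min_run = 1L) {
  stopifnot(inherits(dm, "tg_dot_matches"))
  m <- dm$matches
  step <- dm$step
  runs <- list()
  emit <- function(ix, ori) {
    runs[[length(runs) + 1]] <<- data.frame(
      orientation = ori, x0 = m$x[ix[1]], y0 = m$y[ix[1]],
      x1 = m$x[ix[length(ix)]], y1 = m$y[ix[length(ix)]],
      run_length = length(ix), stringsAsFactors = FALSE)
  }
  fw <- which(m$orientation == "forward")
  if (length(fw)) {
    d <- m$x[fw] - m$y[fw]
    for (dd in unique(d)) {
      ix <- fw[d == dd][order(m$x[fw[d == dd]])]
      br <- cumsum(c(1L, diff(m$x[ix]) != step))
      for (g in split(ix, br)) emit(g, "forward")
    }
  }
  rv <- which(m$orientation == "reverse")
  if (length(rv)) {
    s <- m$x[rv] + m$y[rv]
    for (ss in unique(s)) {
      ix <- rv[s == ss][order(m$x[rv[s == ss]])]
      br <- cumsum(c(1L, diff(m$x[ix]) != step))
      for (g in split(ix, br)) emit(g, "reverse")
    }
  }
  if (length(runs) == 0) {
    return(data.frame(orientation = character(), x0 = integer(),
                      y0 = integer(), x1 = integer(), y1 = integer(),
                      run_length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, runs)
  out <- out[out$run_length >= min_run, , drop = FALSE]
  out <- out[order(out$x0, out$y0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a nucleotide dot plot
#'
#' Renders one point per window match (forward black, reverse red), the
#' conventional long-read-vs-reference diagnostic view.
#'
#' @param dm A [dot_matches()] result.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_dotplot <- function(dm, xlab = "sequence X (bp)",
                         ylab = "sequence Y (bp)", ...) {
  stopifnot(inherits(dm, "tg_dot_matches"))
  m <- dm$matches
  graphics::plot(m$x, m$y, pch = ".", cex = 2,
                 col = ifelse(m$orientation == "forward", "black", "red"),
                 xlab = xlab, ylab = ylab, ...)
  invisible(dm)
}

#' Write dot-plot matches as TSV
#'
#' @param dm A [dot_matches()] result.
#' @param path Output file.
#' @export
write_dot_matches <- function(dm, path) {
  write.table(dm$matches, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
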
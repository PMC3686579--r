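# Entropy profiling of barcode alignments and conserved-window discovery.

.aln_char_matrix <- function(alignment) {
  if (inherits(alignment, "DNAMultipleAlignment"))
    alignment <- as.character(alignment)
  if (inherits(alignment, "DNAStringSet") || inherits(alignment, "XStringSet"))
    alignment <- as.character(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 1L)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    off <- which(widths != widths[1L])
    stop("ragged alignment: row(s) ", paste(off, collapse = ", "),
         " differ in length from row 1")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  mat[mat == "U"] <- "T"
  mat[mat == "."] <- "-"
  mat
}

#' Shannon entropy of per-column base counts
#'
#' \eqn{h(x) = -\sum_b f_b \log_2 f_b} over bases with positive frequency;
#' 0 when one base has frequency 1 and a maximum of 2 bits when all four
#' occur equally. Counts may be fractional (ambiguity-distributed).
#'
#' @param counts Numeric vector of per-base counts for one column, or a
#'   matrix with one column per alignment column.
#' @return Entropy in bits (vector for matrix input).
#' @examples
#' column_entropy(c(A = 50, T = 50))  # 1
#' @export
column_entropy <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 2L, column_entropy))
  tot <- sum(counts)
  if (tot <= 0) stop("column has no counted bases; entropy undefined")
  f <- counts[counts > 0] / tot
  -sum(f * log2(f))
}

#' Profile a multiple sequence alignment
#'
#' Computes per-column base counts, gap counts, coverage (non-gap
#' fraction) and Shannon entropy for an aligned set of sequences. IUPAC
#' ambiguity symbols contribute fractionally (1/|base set|) to each base
#' they denote, or are dropped entirely with `ambiguous = "drop"`. Gaps are
#' excluded from entropy frequencies but tracked as coverage; the entropy
#' of an all-gap column is `NA` (undefined), never 0.
#'
#' @param alignment Aligned sequences: a character vector, `DNAStringSet`
#'   or `DNAMultipleAlignment`; rows must have equal length.
#' @param ambiguous `"fractional"` (default) or `"drop"`.
#' @return An object of class `alignment_profile`: list with `counts`
#'   (4 x n matrix, rows A/C/G/T), `gaps`, `coverage`, `entropy`, `n_seq`,
#'   `n_columns`. `as.data.frame()` yields the per-column table.
#' @export
profile_alignment <- function(alignment, ambiguous = c("fractional", "drop")) {
  ambiguous <- match.arg(ambiguous)
  mat <- .aln_char_matrix(alignment)
  n_col <- ncol(mat)
  counts <- matrix(0, nrow = 4L, ncol = n_col,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  syms <- setdiff(unique(as.vector(mat)), "-")
  bad <- setdiff(syms, names(.IUPAC_SETS))
  if (length(bad))
    stop("invalid alignment character(s): ", paste(bad, collapse = ", "))
  for (s in syms) {
    set <- .IUPAC_SETS[[s]]
    if (length(set) > 1L && ambiguous == "drop") next
    hits <- colSums(mat == s)
    counts[set, ] <- counts[set, , drop = FALSE] +
      rep(hits / length(set), each = length(set))
  }
  gaps <- colSums(mat == "-")
  tot <- colSums(counts)
  entropy <- rep(NA_real_, n_col)
  ok <- tot > 0
  entropy[ok] <- apply(counts[, ok, drop = FALSE], 2L, column_entropy)
  structure(
    list(counts = counts, gaps = gaps, coverage = 1 - gaps / nrow(mat),
         entropy = entropy, n_seq = nrow(mat), n_columns = n_col),
    class = "alignment_profile"
  )
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat(sprintf("<alignment_profile> %d sequences x %d columns; mean entropy %.3f bits (%d undefined column(s))\n",
              x$n_seq, x$n_columns, mean(x$entropy, na.rm = TRUE),
              sum(is.na(x$entropy))))
  invisible(x)
}

#' @export
as.data.frame.alignment_profile <- function(x, ...) {
  data.frame(column = seq_len(x$n_columns), t(x$counts), gap = x$gaps,
             coverage = x$coverage, entropy = x$entropy)
}

#' Find conserved windows in an alignment profile
#'
#' Slides a fixed-width window over the profile and reports every window
#' whose mean entropy is at or below `max_mean_entropy` and whose columns
#' all reach `min_coverage`, ranked by mean entropy (ascending), then by
#' maximum entropy, then by start coordinate. Coordinates are 1-based
#' inclusive alignment columns.
#'
#' @param profile An `alignment_profile`.
#' @param width Window width in columns.
#' @param max_mean_entropy Mean-entropy ceiling in bits.
#' @param min_coverage Minimum per-column non-gap fraction.
#' @return A data frame with columns `start`, `end`, `width`,
#'   `mean_entropy`, `max_entropy`; zero rows when no window qualifies.
#' @export
find_conserved_windows <- function(profile, width,
                                   max_mean_entropy = 0.25,
                                   min_coverage = 0.9) {
  stopifnot(inherits(profile, "alignment_profile"))
  if (width > profile$n_columns)
    stop("width (", width, ") exceeds alignment length (",
         profile$n_columns, ")")
  h <- profile$entropy
  usable <- !is.na(h) & profile$coverage >= min_coverage
  h0 <- ifelse(usable, h, NA_real_)
  n_win <- profile$n_columns - width + 1L
  starts <- seq_len(n_win)
  # rolling mean/max; windows touching an unusable column are dropped
  mean_h <- vapply(starts, function(s) mean(h0[s:(s + width - 1L)]), 0)
  max_h <- vapply(starts, function(s) {
    w <- h0[s:(s + width - 1L)]
    if (anyNA(w)) NA_real_ else max(w)
  }, 0)
  keep <- which(!is.na(mean_h) & mean_h <= max_mean_entropy)
  out <- data.frame(start = starts[keep], end = starts[keep] + width - 1L,
                    width = rep(as.integer(width), length(keep)),
                    mean_entropy = mean_h[keep],
                    max_entropy = max_h[keep])
  out[order(out$mean_entropy, out$max_entropy, out$start), , drop = FALSE]
}

#' Degenerate consensus primer over a window
#'
#' For each column of the window, takes the set of bases whose frequency
#' (among counted bases) is at least `min_base_freq` -- the modal base is
#' always included -- and emits the IUPAC symbol covering exactly that set.
#'
#' @param profile An `alignment_profile`.
#' @param start,end 1-based inclusive column coordinates of the window.
#' @param min_base_freq Minimum frequency for a base to enter the
#'   consensus symbol; 0 includes every observed base.
#' @param name Name for the returned primer.
#' @return A forward-orientation `degenerate_primer`.
#' @export
degenerate_consensus <- function(profile, start, end, min_base_freq = 0.05,
                                 name = sprintf("consensus_%d_%d", start, end)) {
  stopifnot(inherits(profile, "alignment_profile"),
            start >= 1L, end <= profile$n_columns, start <= end)
  cols <- start:end
  tot <- colSums(profile$counts[, cols, drop = FALSE])
  if (any(tot <= 0))
    stop("window contains column(s) with no counted bases")
  sym <- vapply(cols, function(j) {
    f <- profile$counts[, j] / sum(profile$counts[, j])
    keep <- f >= min_base_freq | f == max(f)
    keep <- keep & f > 0
    iupac_from_set(names(f)[keep])
  }, character(1))
  degenerate_primer(paste(sym, collapse = ""), name = name,
                    orientation = "forward")
}
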
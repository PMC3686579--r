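# IUPAC-aware primer-template annealing, amplicon extraction, and
# mismatch-distribution reports.
#
# Matching is set-intersection on IUPAC codes, gapless, with no positional
# weighting: a primer position mismatches iff its base set and the template
# base set are disjoint. Primer inosine never mismatches. Template N
# matches everything by default; `strict_N = TRUE` counts it as a mismatch.

# 17x17 logical match table, primer symbol x template symbol
.IUPAC_MATCH <- local({
  codes <- names(.IUPAC_SETS)
  m <- outer(codes, codes, Vectorize(function(p, t) {
    length(intersect(.IUPAC_SETS[[p]], .IUPAC_SETS[[t]])) > 0L
  }))
  dimnames(m) <- list(primer = codes, template = codes)
  m["I", ] <- TRUE  # inosine anneals to any template base
  m
})

# mismatch count of `primer` at every offset of `template` (plus strand)
.slide_mismatches <- function(primer_seq, template, strict_N = FALSE) {
  pch <- strsplit(primer_seq, "", fixed = TRUE)[[1L]]
  tch <- strsplit(normalize_iupac(template), "", fixed = TRUE)[[1L]]
  L <- length(pch)
  n_pos <- length(tch) - L + 1L
  if (n_pos < 1L) return(integer(0))
  mism <- integer(n_pos)
  for (i in seq_len(L)) {
    tc <- tch[i:(i + n_pos - 1L)]
    ok <- .IUPAC_MATCH[pch[i], tc]
    if (strict_N) ok <- ok & tc != "N"
    mism <- mism + !ok
  }
  mism
}

#' Count primer-template mismatches at an annealing site
#'
#' Positionwise comparison of a (possibly degenerate) primer with a
#' template site of equal length: a position mismatches iff the primer and
#' template base sets are disjoint. Inosine in the primer never
#' mismatches.
#'
#' @param primer A `degenerate_primer` or IUPAC string.
#' @param site Template sequence of the same length as the primer (the
#'   strand the primer anneals against, read 5' to 3' of the primer).
#' @param strict_N Count template `N` as a mismatch instead of a wildcard.
#' @return List with `count` and logical `mask` (TRUE = mismatch), both in
#'   5' to 3' primer coordinates.
#' @examples
#' count_mismatches("W", "A")$count  # 0: W = \{A,T\}
#' count_mismatches("Y", "A")$count  # 1: Y = \{C,T\}
#' @export
count_mismatches <- function(primer, site, strict_N = FALSE) {
  pch <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1L]]
  tch <- strsplit(normalize_iupac(site), "", fixed = TRUE)[[1L]]
  if (length(pch) != length(tch))
    stop("primer and site lengths differ (", length(pch), " vs ",
         length(tch), ")")
  ok <- .IUPAC_MATCH[cbind(pch, tch)]
  if (strict_N) ok <- ok & tch != "N"
  mask <- !ok
  list(count = sum(mask), mask = mask)
}

#' Locate primer binding sites on a template
#'
#' Gapless sliding-window search on both strands: strand `"+"` sites match
#' the primer against the template as given; strand `"-"` sites match the
#' primer against the reverse-complement strand (i.e. the reverse
#' complement of the primer appears on the plus strand). Coordinates are
#' 1-based inclusive plus-strand positions of the annealed footprint.
#'
#' @inheritParams count_mismatches
#' @param template Concrete template sequence (plus strand).
#' @param max_mismatches Report sites with at most this many mismatches.
#' @param template_id Label copied into the output.
#' @return Data frame `template_id`, `strand`, `start`, `end`,
#'   `mismatch_count`, `mask` (character of 0/1, 5' to 3' of the primer),
#'   sorted by mismatch count then start; zero rows if none.
#' @export
find_binding_sites <- function(primer, template, max_mismatches = 2L,
                               strict_N = FALSE, template_id = "template") {
  pseq <- .primer_seq(primer)
  L <- nchar(pseq)
  template <- normalize_iupac(template)
  if (nchar(template) < L)
    stop("template shorter than primer")
  res <- list()
  for (str in c("+", "-")) {
    qry <- if (str == "+") pseq else reverse_complement(pseq)
    mism <- .slide_mismatches(qry, template, strict_N = strict_N)
    hit <- which(mism <= max_mismatches)
    if (!length(hit)) next
    mask <- vapply(hit, function(s) {
      m <- count_mismatches(qry, substr(template, s, s + L - 1L),
                            strict_N = strict_N)$mask
      if (str == "-") m <- rev(m)  # report 5'->3' of the primer
      paste(as.integer(m), collapse = "")
    }, character(1))
    res[[str]] <- data.frame(template_id = template_id, strand = str,
                             start = hit, end = hit + L - 1L,
                             mismatch_count = mism[hit], mask = mask)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(template_id = character(), strand = character(),
               start = integer(), end = integer(),
               mismatch_count = integer(), mask = character())
  rownames(out) <- NULL
  out[order(out$mismatch_count, out$start), , drop = FALSE]
}

#' In-silico PCR amplification
#'
#' Pairs every plus-strand site of the forward primer with every
#' minus-strand site of the reverse primer lying downstream, and reports
#' the amplicon geometry. The insert excludes both primer footprints.
#'
#' @param forward,reverse `degenerate_primer`s (or IUPAC strings) with
#'   forward/reverse orientation respectively.
#' @param template Concrete template sequence (plus strand).
#' @param max_mismatches Annealing tolerance passed to
#'   [find_binding_sites()].
#' @param strict_N See [count_mismatches()].
#' @param template_id Label copied into the output.
#' @return Data frame with `template_id`, forward/reverse site coordinates
#'   and mismatch counts, `insert_start`, `insert_end`, `insert_length`,
#'   `with_primers_length` and the `insert` sequence; zero rows when no
#'   properly oriented site pair exists.
#' @export
amplify <- function(forward, reverse, template, max_mismatches = 2L,
                    strict_N = FALSE, template_id = "template") {
  template <- normalize_iupac(template)
  f_sites <- find_binding_sites(forward, template, max_mismatches,
                                strict_N, template_id)
  r_sites <- find_binding_sites(reverse, template, max_mismatches,
                                strict_N, template_id)
  f_sites <- f_sites[f_sites$strand == "+", , drop = FALSE]
  r_sites <- r_sites[r_sites$strand == "-", , drop = FALSE]
  len_f <- nchar(.primer_seq(forward))
  len_r <- nchar(.primer_seq(reverse))
  out <- list()
  for (i in seq_len(nrow(f_sites))) for (j in seq_len(nrow(r_sites))) {
    fe <- f_sites$end[i]; rs <- r_sites$start[j]
    if (fe >= rs) next  # forward 3' end must lie upstream of reverse site
    ins_len <- rs - fe - 1L
    out[[length(out) + 1L]] <- data.frame(
      template_id = template_id,
      forward_start = f_sites$start[i], forward_end = fe,
      forward_mismatches = f_sites$mismatch_count[i],
      reverse_start = rs, reverse_end = r_sites$end[j],
      reverse_mismatches = r_sites$mismatch_count[j],
      insert_start = fe + 1L, insert_end = rs - 1L,
      insert_length = ins_len,
      with_primers_length = ins_len + len_f + len_r,
      insert = if (ins_len > 0L) substr(template, fe + 1L, rs - 1L) else "")
  }
  if (!length(out))
    return(data.frame(template_id = character(), forward_start = integer(),
                      forward_end = integer(), forward_mismatches = integer(),
                      reverse_start = integer(), reverse_end = integer(),
                      reverse_mismatches = integer(), insert_start = integer(),
                      insert_end = integer(), insert_length = integer(),
                      with_primers_length = integer(), insert = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mismatch distribution of a primer across a reference library
#'
#' For each reference, finds the minimum-mismatch annealing site (searching
#' both strands, ties resolved leftmost) or, when `site_start` is given,
#' scores the fixed plus-strand window starting there. References with no
#' site within `max_search` mismatches fall in an "unalignable" bin
#' (`mismatches = NA`), never silently dropped.
#'
#' @inheritParams count_mismatches
#' @param references Named character vector or `DNAStringSet` of concrete
#'   template sequences.
#' @param groups Grouping factor (e.g. phylum), recycled if length 1;
#'   default one group `"all"`.
#' @param site_start Optional fixed 1-based plus-strand start coordinate of
#'   the priming site; `NULL` (default) searches.
#' @param max_search Generous mismatch ceiling beyond which a reference is
#'   deemed unalignable.
#' @param threshold Report the fraction of templates with fewer than this
#'   many mismatches.
#' @return List with `histogram` (group, mismatches, n; alignable
#'   references only), `summary` (group, n, fraction_below,
#'   max_mismatches, unalignable) and `threshold`. Unalignable references
#'   count against `fraction_below` and are tallied in `unalignable`,
#'   never silently dropped.
#' @export
mismatch_distribution <- function(primer, references, groups = "all",
                                  site_start = NULL, max_search = 10L,
                                  threshold = 4L, strict_N = FALSE) {
  refs <- as.character(references)
  n <- length(refs)
  if (length(groups) == 1L) groups <- rep(groups, n)
  stopifnot(length(groups) == n)
  pseq <- .primer_seq(primer)
  L <- nchar(pseq)
  best <- vapply(refs, function(tpl) {
    tpl <- normalize_iupac(tpl)
    if (!is.null(site_start)) {
      if (site_start + L - 1L > nchar(tpl)) return(NA_integer_)
      return(count_mismatches(pseq, substr(tpl, site_start,
                                           site_start + L - 1L),
                              strict_N = strict_N)$count)
    }
    m <- c(.slide_mismatches(pseq, tpl, strict_N),
           .slide_mismatches(reverse_complement(pseq), tpl, strict_N))
    if (!length(m)) return(NA_integer_)
    as.integer(min(m))
  }, integer(1), USE.NAMES = FALSE)
  best[!is.na(best) & best > max_search] <- NA_integer_
  ok <- !is.na(best)
  hist <- as.data.frame(table(group = groups[ok],
                              mismatches = best[ok]), responseName = "n")
  hist <- hist[hist$n > 0, , drop = FALSE]
  hist$mismatches <- as.integer(as.character(hist$mismatches))
  summ <- do.call(rbind, lapply(split(best, groups), function(b) {
    data.frame(n = length(b),
               fraction_below = if (length(b)) mean(!is.na(b) & b < threshold)
                                else NA_real_,
               max_mismatches = if (any(!is.na(b))) max(b, na.rm = TRUE)
                                else NA_integer_,
               unalignable = sum(is.na(b)))
  }))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  list(histogram = hist[order(hist$group, hist$mismatches), ,
                        drop = FALSE],
       summary = summ, threshold = threshold)
}
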
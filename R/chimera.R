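# Simplified two-parent chimera screen against a reference panel.
#
# For each read the best single-parent identity is compared with the best
# identity achievable by splicing a prefix of one reference onto a suffix
# of another (one breakpoint, two distinct parents). A positive gain means
# the read is explained better as a two-parent mosaic: the hallmark of a
# PCR chimera. A non-chimeric read can never gain (the best single parent
# is always an admissible "pair"), so the score is zero for clonal reads
# and the gain threshold only has to clear alignment noise.

#' Detect two-parent chimeric reads
#'
#' Projects per-position match profiles of each read against every
#' reference, then compares the best single-parent identity with the best
#' two-parent identity over all breakpoints leaving at least
#' `min_segment` bases on each side. A read is called chimeric when the
#' identity gain reaches `min_score_gain`. Reads shorter than
#' `2 * min_segment` are not evaluable and are never flagged.
#'
#' @param reads Named character vector (or `DNAStringSet`).
#' @param references Character vector (or `DNAStringSet`) of at least two
#'   candidate parent sequences (one representative per plausible parent
#'   is sufficient and fastest).
#' @param min_score_gain Identity gain (two-parent minus single-parent,
#'   on the whole read) required to call a chimera; default 0.02, i.e.
#'   the second parent must explain at least 2% of the read better than
#'   any single parent can.
#' @param min_segment Minimum parent segment length in bases; default 30.
#' @return Data frame: `read_id`, `is_chimera`, `best_single_identity`,
#'   `best_two_parent_identity`, `breakpoint` (last read position taken
#'   from the left parent), `score_gain`, `evaluable`.
#' @export
detect_chimera <- function(reads, references, min_score_gain = 0.02,
                           min_segment = 30L) {
  reads <- .named_seqs(reads)
  refs <- as.character(references)
  if (length(refs) < 2L) stop("need at least two references")
  n <- length(reads)
  nr <- length(refs)

  # per-read-position match indicators for each reference
  profs <- lapply(refs, function(ref) {
    a <- .align_batch(reads, ref, type = "global-local")
    lapply(seq_len(n), function(k) {
      pc <- strsplit(a$pattern[k], "", fixed = TRUE)[[1L]]
      sc <- strsplit(a$subject[k], "", fixed = TRUE)[[1L]]
      keep <- pc != "-"
      (pc == sc)[keep]  # length = read length
    })
  })

  out <- lapply(seq_len(n), function(k) {
    L <- nchar(reads[[k]])
    M <- do.call(rbind, lapply(profs, function(p) as.integer(p[[k]])))
    tot <- rowSums(M)
    s1 <- max(tot) / L
    if (L < 2L * min_segment) {
      return(data.frame(read_id = names(reads)[k], is_chimera = FALSE,
                        best_single_identity = s1,
                        best_two_parent_identity = s1,
                        breakpoint = NA_integer_, score_gain = 0,
                        evaluable = FALSE))
    }
    P <- t(apply(M, 1L, cumsum))           # nr x L prefix sums
    bs <- seq(min_segment, L - min_segment)
    left <- P[, bs, drop = FALSE]
    right <- tot - left
    nb <- length(bs)
    top2 <- function(X) {
      i1 <- max.col(t(X), ties.method = "first")
      v1 <- X[cbind(i1, seq_len(nb))]
      X[cbind(i1, seq_len(nb))] <- -Inf
      i2 <- max.col(t(X), ties.method = "first")
      v2 <- X[cbind(i2, seq_len(nb))]
      list(i1 = i1, v1 = v1, v2 = v2)
    }
    lt <- top2(left)
    rt <- top2(right)
    cand <- ifelse(lt$i1 != rt$i1, lt$v1 + rt$v1,
                   pmax(lt$v1 + rt$v2, lt$v2 + rt$v1))
    best_b <- which.max(cand)
    s2 <- cand[best_b] / L
    gain <- max(0, s2 - s1)
    data.frame(read_id = names(reads)[k],
               is_chimera = gain >= min_score_gain,
               best_single_identity = s1, best_two_parent_identity = s2,
               breakpoint = bs[best_b], score_gain = gain,
               evaluable = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
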
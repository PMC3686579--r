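# IUPAC nucleotide algebra.
#
# The symbol table covers the standard ambiguity codes plus inosine ("I"),
# which is treated as a physical base that anneals to any template base.
# "U" is normalized to "T" on input and lowercase is upper-cased.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I"
)

# set of bases -> IUPAC symbol (inosine is never produced)
.IUPAC_FROM_SET <- local({
  codes <- setdiff(names(.IUPAC_SETS), "I")
  stats::setNames(codes, vapply(.IUPAC_SETS[codes],
                                function(b) paste(sort(b), collapse = ""), ""))
})

#' Normalize an IUPAC nucleotide string
#'
#' Upper-cases the input and converts U to T. Any character outside the
#' IUPAC alphabet (including gaps) raises an error naming the first
#' offending position.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_iupac("ggwacu")  # "GGWACT"
#' @export
normalize_iupac <- function(x) {
  stopifnot(is.character(x))
  x <- chartr("u", "t", toupper(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- regexpr(sprintf("[^%s]", paste(names(.IUPAC_SETS), collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid IUPAC character '%s' at position %d of sequence %d",
                 substr(x[i], bad[i], bad[i]), bad[i], i))
  }
  x
}

#' Base set denoted by IUPAC symbols
#'
#' @param code Character vector of single IUPAC symbols.
#' @return A list of character vectors, each a subset of A/C/G/T.
#'   Inosine ("I") denotes all four bases.
#' @export
iupac_base_set <- function(code) {
  code <- normalize_iupac(code)
  stopifnot(all(nchar(code) == 1L))
  .IUPAC_SETS[code]
}

#' IUPAC symbol covering a base set
#'
#' Inverse of [iupac_base_set()] restricted to the non-inosine alphabet:
#' the set \{A,C,G,T\} maps to "N".
#'
#' @param bases Character vector, a non-empty subset of A/C/G/T.
#' @return A single IUPAC symbol.
#' @export
iupac_from_set <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  sym <- .IUPAC_FROM_SET[key]
  if (is.na(sym)) stop("not a valid base set: ", key)
  unname(sym)
}

#' Reverse complement of an IUPAC string
#'
#' Per-symbol complement (R<->Y, K<->M, W, S, N and I self-complementary)
#' followed by reversal; an involution that preserves degeneracy.
#'
#' @param x Character vector of IUPAC strings.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("AY")   # "RT"
#' @export
reverse_complement <- function(x) {
  x <- normalize_iupac(x)
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(unname(.IUPAC_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

# split into single characters, normalized
.iupac_chars <- function(x) strsplit(normalize_iupac(x), "", fixed = TRUE)[[1L]]
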
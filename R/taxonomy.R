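# Identity-threshold taxonomic assignment with rank-consensus fallback.
#
# A query matching a reference at >= 98% identity (inclusive) is assigned
# to that species. Below the species threshold, assignment falls back to
# the lowest rank at which all reference hits within the applicable
# identity band agree. The default bands (>=95% genus, >=90% family,
# >=85% order, >=80% class, >=70% phylum) are toolkit defaults standing in
# for a phylogenetic posterior-probability assignment.

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")

.default_bands <- function() {
  data.frame(min_identity = c(0.95, 0.90, 0.85, 0.80, 0.70),
             rank = c("genus", "family", "order", "class", "phylum"))
}

#' Read a reference lineage table
#'
#' Tab-separated file with columns `seq_id`, `kingdom`, `phylum`,
#' `class`, `order`, `family`, `genus`, `species`. Malformed rows
#' (missing or empty fields) are rejected with their line numbers.
#'
#' @param path File path.
#' @return Data frame of lineages.
#' @export
read_lineage <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("seq_id", .RANKS)
  if (!all(need %in% names(tab)))
    stop("lineage table must have columns: ", paste(need, collapse = ", "))
  bad <- which(apply(tab[need], 1L, function(r) any(is.na(r) | r == "")))
  if (length(bad))
    stop("malformed lineage row(s) at line ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  tab
}

#' Assign taxonomy to query sequences by identity thresholds
#'
#' @param queries Named character vector (or `DNAStringSet`) of query
#'   sequences, or an `otu_set` (representatives are used and `query_id`
#'   is the OTU id).
#' @param ref_seqs Named character vector (or `DNAStringSet`) of reference
#'   barcodes; names must appear in `lineage$seq_id`.
#' @param lineage Lineage data frame (see [read_lineage()]).
#' @param species_threshold Identity at or above which the best hit's
#'   species is assigned (default 0.98, inclusive).
#' @param fallback_bands Data frame with `min_identity` and `rank`
#'   describing the consensus bands, ordered best-first; default
#'   `>=0.95` genus ... `>=0.70` phylum.
#' @return Data frame with one row per query: `query_id`, `method`
#'   (`species_match`, `rank_consensus` or `unidentified`),
#'   `best_identity`, `best_hit`, `assigned_rank` and the lineage columns
#'   (NA below the assigned rank).
#' @export
assign_taxonomy <- function(queries, ref_seqs, lineage,
                            species_threshold = 0.98,
                            fallback_bands = .default_bands()) {
  if (inherits(queries, "otu_set"))
    queries <- stats::setNames(queries$otus$representative,
                               queries$otus$otu_id)
  queries <- .named_seqs(queries, prefix = "query")
  nm <- names(ref_seqs)
  refs <- as.character(ref_seqs)
  if (!length(refs)) stop("empty reference set")
  if (is.null(nm)) stop("ref_seqs must be named")
  names(refs) <- nm
  li <- lineage[match(names(refs), lineage$seq_id), , drop = FALSE]
  if (anyNA(li$seq_id))
    stop("reference(s) missing from lineage table: ",
         paste(names(refs)[is.na(li$seq_id)], collapse = ", "))

  empty_path <- stats::setNames(rep(NA_character_, length(.RANKS)), .RANKS)
  out <- lapply(seq_along(queries), function(q) {
    ids <- pairwise_identity(queries[[q]], refs)
    best <- max(ids)
    best_i <- which(ids == best)[1L]
    row <- data.frame(query_id = names(queries)[q], method = "unidentified",
                      best_identity = best, best_hit = names(refs)[best_i],
                      assigned_rank = NA_character_,
                      t(empty_path), stringsAsFactors = FALSE)
    if (best >= species_threshold) {
      row$method <- "species_match"
      row$assigned_rank <- "species"
      row[.RANKS] <- li[best_i, .RANKS]
      return(row)
    }
    band <- which(best >= fallback_bands$min_identity)
    if (!length(band)) return(row)  # below the lowest band floor
    band <- band[1L]
    hits <- which(ids >= fallback_bands$min_identity[band])
    start_rank <- match(fallback_bands$rank[band], .RANKS)
    for (r in seq(start_rank, 1L)) {
      vals <- unique(li[hits, .RANKS[r]])
      if (length(vals) == 1L && !is.na(vals)) {
        row$method <- "rank_consensus"
        row$assigned_rank <- .RANKS[r]
        row[.RANKS[seq_len(r)]] <- li[hits[1L], .RANKS[seq_len(r)]]
        return(row)
      }
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
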
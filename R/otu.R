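# Greedy centroid OTU clustering and OTU tables.
#
# Deterministic behavioural stand-in for Bayesian OTU clustering: after
# dereplication, sequences are visited in abundance order (ties broken
# lexicographically) and each joins the first existing centroid within the
# dissimilarity radius, else founds a new centroid. The default radius
# 0.07 is the midpoint of the 6-8% dissimilarity band used to calibrate
# OTU delineation for marine invertebrate COI.

#' Cluster sequences into OTUs by greedy centroid clustering
#'
#' @param sequences Named character vector (or `DNAStringSet`) of reads
#'   (names are read ids; duplicates are dereplicated internally).
#' @param radius Dissimilarity radius in `(0, 0.5)`, or 0 for one OTU per
#'   unique sequence. Dissimilarity is `1 - identity` under global
#'   alignment with end gaps excluded (see [pairwise_identity()]).
#' @return An object of class `otu_set`: list with `otus` (data frame:
#'   `otu_id`, `representative`, `n_reads`, `n_unique`), `members` (list
#'   of read-id vectors per OTU), `read_otu` (named vector read id ->
#'   otu id) and `radius`.
#' @export
cluster_otus <- function(sequences, radius = 0.07) {
  seqs <- .named_seqs(sequences)
  seqs[] <- toupper(seqs)
  if (!length(seqs)) stop("no sequences to cluster")
  stopifnot(radius >= 0, radius < 0.5)
  # dereplicate: unique sequences with abundance, members
  derep <- split(names(seqs), seqs)
  uniq <- names(derep)
  ab <- lengths(derep)
  ord <- order(-ab, uniq)
  uniq <- uniq[ord]; ab <- ab[ord]; derep <- derep[ord]

  centroid_seq <- character(0)
  assign <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- 0L
    if (radius > 0 && length(centroid_seq)) {
      diss <- 1 - pairwise_identity(uniq[i], centroid_seq)
      w <- which(diss <= radius)
      if (length(w)) hit <- w[1L]
    } else if (radius == 0 && length(centroid_seq)) {
      w <- which(centroid_seq == uniq[i])
      if (length(w)) hit <- w[1L]
    }
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, uniq[i])
      hit <- length(centroid_seq)
    }
    assign[i] <- hit
  }
  n_otu <- length(centroid_seq)
  otu_id <- sprintf("OTU_%04d", seq_len(n_otu))
  members <- lapply(seq_len(n_otu), function(o)
    unlist(derep[assign == o], use.names = FALSE))
  names(members) <- otu_id
  read_otu <- stats::setNames(rep(otu_id, lengths(members)),
                              unlist(members, use.names = FALSE))
  structure(list(
    otus = data.frame(otu_id = otu_id, representative = centroid_seq,
                      n_reads = lengths(members),
                      n_unique = as.vector(table(factor(assign,
                        levels = seq_len(n_otu))))),
    members = members, read_otu = read_otu, radius = radius),
    class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("<otu_set> %d OTUs from %d reads (radius %.3f)\n",
              nrow(x$otus), length(x$read_otu), x$radius))
  invisible(x)
}

#' Abundance class of an OTU
#'
#' Bins read counts into the standard abundance classes 1, 2-9, 10-99,
#' 100-999 and >=1000.
#'
#' @param n Integer vector of per-OTU read counts.
#' @return Factor with the five class levels.
#' @export
abundance_class <- function(n) {
  cut(n, breaks = c(0, 1, 9, 99, 999, Inf),
      labels = c("1", "2-9", "10-99", "100-999", ">=1000"))
}

#' Build the OTU x sample abundance table
#'
#' @param otus An `otu_set` from [cluster_otus()].
#' @param sample_map Named character vector mapping read id to sample id
#'   (or data frame with columns `read_id`, `sample_id`). Every member
#'   read must be present.
#' @param assignments Optional taxonomy table from [assign_taxonomy()]
#'   (matched by `query_id` = otu id); enables per-phylum tallies.
#' @return List with `table` (integer matrix, OTUs x samples; empty
#'   samples keep their zero column), `abundance_classes` (per-class OTU
#'   counts) and `phylum_counts` (or `NULL`).
#' @export
build_otu_table <- function(otus, sample_map, assignments = NULL) {
  stopifnot(inherits(otus, "otu_set"))
  if (is.data.frame(sample_map))
    sample_map <- stats::setNames(sample_map$sample_id, sample_map$read_id)
  reads <- names(otus$read_otu)
  miss <- setdiff(reads, names(sample_map))
  if (length(miss))
    stop("member read(s) without sample_id: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  samples <- sort(unique(unname(sample_map)))
  tab <- table(factor(otus$read_otu, levels = otus$otus$otu_id),
               factor(sample_map[reads], levels = samples))
  tab <- unclass(tab)
  cls <- abundance_class(rowSums(tab))
  phylum_counts <- NULL
  if (!is.null(assignments)) {
    ph <- assignments$phylum[match(rownames(tab), assignments$query_id)]
    ph[is.na(ph)] <- "unknown"
    phylum_counts <- sort(table(ph), decreasing = TRUE)
  }
  list(table = tab, abundance_classes = table(cls),
       phylum_counts = phylum_counts)
}

#' Remove OTUs belonging to the predator itself
#'
#' Diet tables must exclude the predator's own DNA: any OTU whose
#' species-level assignment equals the host predator species of a sample
#' in which it occurs is removed.
#'
#' @param table OTU x sample abundance matrix.
#' @param assignments Taxonomy table from [assign_taxonomy()].
#' @param predator_species Named character vector sample id -> predator
#'   species.
#' @return List with `table` (filtered matrix) and `removed` (data frame
#'   of removed OTU ids, species and total abundance).
#' @export
remove_self_otus <- function(table, assignments, predator_species) {
  stopifnot(is.matrix(table))
  sp <- assignments$species[match(rownames(table), assignments$query_id)]
  meth <- assignments$method[match(rownames(table), assignments$query_id)]
  preds <- predator_species[colnames(table)]
  is_self <- vapply(seq_len(nrow(table)), function(i) {
    if (is.na(sp[i]) || !identical(meth[i], "species_match")) return(FALSE)
    present <- table[i, ] > 0
    any(!is.na(preds[present]) & preds[present] == sp[i])
  }, TRUE)
  removed <- data.frame(otu_id = rownames(table)[is_self],
                        species = sp[is_self],
                        abundance = rowSums(table)[is_self],
                        row.names = NULL)
  list(table = table[!is_self, , drop = FALSE], removed = removed)
}
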
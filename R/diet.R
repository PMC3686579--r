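# Diet summaries and rarefaction.

#' Intra- and inter-specific diet summaries
#'
#' Each sample is one predator individual's gut. Per predator species,
#' OTUs are partitioned by the number of individuals they occur in
#' (exactly 1, exactly 2, more than 2); across species, the proportion of
#' each species' OTUs also detected in at least one other predator
#' species is reported. With a taxonomy table, each occurrence category is
#' broken down by phylum.
#'
#' @param table OTU x sample abundance matrix (predator-self OTUs
#'   typically already removed; see [remove_self_otus()]).
#' @param predator_species Named character vector sample id -> predator
#'   species.
#' @param assignments Optional taxonomy table from [assign_taxonomy()]
#'   for the phylum breakdown.
#' @return List with `intraspecific` (per species: OTU counts and
#'   proportions per occurrence category), `interspecific` (per species:
#'   shared-OTU counts and proportions) and `phylum_breakdown` (per
#'   species x category phylum proportions, or `NULL`).
#' @export
diet_summaries <- function(table, predator_species, assignments = NULL) {
  stopifnot(is.matrix(table))
  preds <- predator_species[colnames(table)]
  if (anyNA(preds))
    stop("missing predator species for sample(s): ",
         paste(colnames(table)[is.na(preds)], collapse = ", "))
  species <- unique(unname(preds))
  present <- table > 0

  otus_of <- lapply(species, function(s)
    rownames(table)[rowSums(present[, preds == s, drop = FALSE]) > 0])
  names(otus_of) <- species

  intra <- do.call(rbind, lapply(species, function(s) {
    occ <- rowSums(present[, preds == s, drop = FALSE])
    occ <- occ[occ > 0]
    n <- length(occ)
    data.frame(species = s, n_otus = n,
               n_in_1 = sum(occ == 1), n_in_2 = sum(occ == 2),
               n_in_gt2 = sum(occ > 2),
               prop_in_1 = if (n) sum(occ == 1) / n else NA_real_,
               prop_in_2 = if (n) sum(occ == 2) / n else NA_real_,
               prop_in_gt2 = if (n) sum(occ > 2) / n else NA_real_)
  }))

  inter <- do.call(rbind, lapply(species, function(s) {
    mine <- otus_of[[s]]
    others <- unique(unlist(otus_of[setdiff(species, s)]))
    n <- length(mine)
    shared <- sum(mine %in% others)
    data.frame(species = s, n_otus = n, n_shared = shared,
               prop_shared = if (n) shared / n else NA_real_)
  }))

  phylum_breakdown <- NULL
  if (!is.null(assignments)) {
    ph_of <- function(ids) {
      ph <- assignments$phylum[match(ids, assignments$query_id)]
      ph[is.na(ph)] <- "unknown"
      ph
    }
    phylum_breakdown <- do.call(rbind, lapply(species, function(s) {
      occ <- rowSums(present[, preds == s, drop = FALSE])
      cats <- list(`1` = names(occ)[occ == 1], `2` = names(occ)[occ == 2],
                   `>2` = names(occ)[occ > 2])
      do.call(rbind, lapply(names(cats), function(cat) {
        ids <- cats[[cat]]
        if (!length(ids)) return(NULL)
        tab <- table(ph_of(ids))
        data.frame(species = s, category = cat,
                   phylum = names(tab), n_otus = as.integer(tab),
                   proportion = as.numeric(tab) / length(ids))
      }))
    }))
    rownames(phylum_breakdown) <- NULL
  }
  rownames(intra) <- rownames(inter) <- NULL
  list(intraspecific = intra, interspecific = inter,
       phylum_breakdown = phylum_breakdown)
}

#' Analytic rarefaction curve
#'
#' Expected OTU richness in a random subsample of `d` reads without
#' replacement: \eqn{E[S(d)] = \sum_i (1 - C(N - n_i, d)/C(N, d))} where
#' \eqn{n_i} are OTU abundances and \eqn{N} their sum. Monotone
#' non-decreasing in `d`; equals observed richness at `d = N`.
#'
#' @param abundances Positive integer vector of per-OTU read counts (one
#'   sample).
#' @param depths Integer subsampling depths, all `<= sum(abundances)`.
#' @return Data frame with `depth` and `expected_otus`.
#' @export
rarefaction_curve <- function(abundances, depths) {
  abundances <- abundances[abundances > 0]
  N <- sum(abundances)
  if (any(depths > N))
    stop("depth exceeds sample total (", N, ")")
  if (any(depths < 1L)) stop("depths must be >= 1")
  exp_s <- vapply(depths, function(d) {
    sum(1 - exp(lchoose(N - abundances, d) - lchoose(N, d)))
  }, 0)
  data.frame(depth = depths, expected_otus = exp_s)
}
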
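## Census summaries over taxon tables: clade specificity of phage genera
## and the prophage retention/extrachromosomal census.

#' Clade specificity of non-singleton phage taxa
#'
#' A taxon (genus or species) is clade-specific when all of its members
#' were recovered from hosts of a single bacterial clade. Singletons
#' (taxa with one member) are excluded, since specificity is trivial for
#' them.
#'
#' @param taxon Character vector of taxon assignments, one per phage.
#' @param host_clade Character vector of host clades, same length.
#' @return List: \code{n_non_singleton}, \code{n_specific},
#'   \code{percent_specific}.
#' @export
clade_specificity <- function(taxon, host_clade) {
  stopifnot(length(taxon) == length(host_clade))
  sizes <- table(taxon)
  non_singleton <- names(sizes)[sizes > 1]
  n_clades <- tapply(host_clade, taxon, function(x) length(unique(x)))
  n_specific <- sum(n_clades[non_singleton] == 1)
  list(
    n_non_singleton = length(non_singleton),
    n_specific = n_specific,
    percent_specific = 100 * n_specific / length(non_singleton)
  )
}

#' Prophage retention and localization census
#'
#' Applies the class-specific size filters of
#' \code{\link{filter_prophages}} and summarizes how many retained
#' elements are extrachromosomal.
#'
#' @param predictions Data frame with \code{viral_class},
#'   \code{genome_size} and logical \code{extrachromosomal}.
#' @return List: \code{n_retained}, \code{n_extrachromosomal},
#'   \code{percent_extrachromosomal}.
#' @export
prophage_census <- function(predictions) {
  kept <- filter_prophages(predictions)
  n_extra <- sum(kept$extrachromosomal)
  list(
    n_retained = nrow(kept),
    n_extrachromosomal = n_extra,
    percent_extrachromosomal = 100 * n_extra / nrow(kept)
  )
}

#' Lifestyle census of sequenced phages
#'
#' @param lifestyle Character vector of per-phage lifestyle calls
#'   ("virulent" or "temperate").
#' @return List: \code{n_total}, \code{n_virulent},
#'   \code{percent_virulent}.
#' @export
lifestyle_census <- function(lifestyle) {
  n_vir <- sum(lifestyle == "virulent")
  list(n_total = length(lifestyle), n_virulent = n_vir,
       percent_virulent = 100 * n_vir / length(lifestyle))
}
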
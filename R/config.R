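#' Run configuration with study-wide threshold defaults
#'
#' Collects the fixed constants used across the pipeline: the ICTV-style
#' intergenomic similarity thresholds for genus (70) and species (95)
#' rank, the strict wGRR plasmid-presence threshold (50), the persistent
#' gene-family prevalence fraction (0.90, inclusive), the ddPCR well
#' acceptance floor (10,000 droplets, inclusive), the limit of
#' quantification (1 copy per 20 uL reaction), the maximum
#' correlation lag (10 sampling dates) and the significance level for
#' compact letter displays (0.05).
#'
#' @param seed Integer seed governing every stochastic operation run under
#'   this configuration.
#' @param ... Named scalar overrides for individual thresholds.
#' @return An object of class \code{phagedyn_config}: a list with elements
#'   \code{seed} and \code{thresholds}.
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$thresholds$genus_threshold
#' @export
run_config <- function(seed = 1L, ...) {
  thresholds <- list(
    genus_threshold = 70,
    species_threshold = 95,
    wgrr_presence = 50,
    persistent_fraction = 0.90,
    min_droplets = 10000,
    loq_copies_per_reaction = 1,
    max_lag = 10,
    cld_alpha = 0.05
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(thresholds))
    if (length(bad)) {
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    }
    thresholds[names(overrides)] <- overrides
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  structure(
    list(seed = as.integer(seed), thresholds = thresholds),
    class = "phagedyn_config"
  )
}

#' @export
print.phagedyn_config <- function(x, ...) {
  cat("phagedyn run configuration (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$thresholds)) {
    cat("  ", format(nm, width = 24), x$thresholds[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate a plaque-screening design
#'
#' Full factorial crossing of sampling dates with bait strains, as used
#' when every archived host strain is challenged with the environmental
#' phage concentrate of every sampling date. With 35 dates and 153
#' strains this yields 5355 tested interactions.
#'
#' @param dates Vector of sampling date identifiers (or a single count).
#' @param strains Vector of strain identifiers (or a single count).
#' @return Data frame with columns \code{date} and \code{strain}, one row
#'   per assay combination.
#' @examples
#' nrow(screening_design(35, 153))  # 5355
#' @export
screening_design <- function(dates, strains) {
  if (length(dates) == 1 && is.numeric(dates)) dates <- seq_len(dates)
  if (length(strains) == 1 && is.numeric(strains)) strains <- seq_len(strains)
  if (anyDuplicated(dates)) stop("duplicate dates in screening design")
  if (anyDuplicated(strains)) stop("duplicate strains in screening design")
  out <- expand.grid(strain = strains, date = dates,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("date", "strain")]
}
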
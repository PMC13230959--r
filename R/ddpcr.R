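## ddPCR well QC, Poisson absolute quantification and replicate
## geometric summaries with limit-of-quantification handling.

#' Quality-control ddPCR wells
#'
#' Accepts wells with at least \code{min_droplets} total droplets
#' (inclusive).
#'
#' @param wells Data frame with columns \code{total_droplets} and
#'   \code{positive_droplets}.
#' @param min_droplets Inclusive acceptance floor.
#' @return The accepted subset.
#' @export
qc_wells <- function(wells, min_droplets = 10000) {
  if (any(wells$total_droplets < 0) || any(wells$positive_droplets < 0)) {
    stop("validation error: negative droplet counts")
  }
  if (any(wells$positive_droplets > wells$total_droplets)) {
    stop("validation error: positive droplets exceed total")
  }
  wells[wells$total_droplets >= min_droplets, , drop = FALSE]
}

#' Poisson absolute quantification of a ddPCR well
#'
#' Inverts the droplet partitioning model: with a fraction f of positive
#' droplets, the expected copies per droplet is lambda = -ln(1 - f); the
#' concentration is lambda / droplet volume and the copies per reaction
#' follow from the reaction volume. Saturated wells (all droplets
#' positive) are flagged and assigned an infinite estimate. Values below
#' the limit of quantification are flagged.
#'
#' @param wells Data frame with \code{total_droplets},
#'   \code{positive_droplets} and optionally \code{droplet_volume_nl}
#'   (default 0.85) and \code{reaction_volume_ul} (default 20).
#' @param loq_copies_per_reaction Limit of quantification.
#' @return \code{wells} with added columns \code{lambda},
#'   \code{copies_per_reaction}, \code{below_loq}, \code{saturated}.
#' @export
absolute_quantification <- function(wells, loq_copies_per_reaction = 1) {
  if (any(wells$positive_droplets > wells$total_droplets)) {
    stop("validation error: positive droplets exceed total")
  }
  vol <- if ("droplet_volume_nl" %in% names(wells)) wells$droplet_volume_nl else 0.85
  rxn <- if ("reaction_volume_ul" %in% names(wells)) wells$reaction_volume_ul else 20
  f <- wells$positive_droplets / wells$total_droplets
  saturated <- f >= 1
  lambda <- ifelse(saturated, Inf, -log(1 - f))
  copies <- lambda / vol * (rxn * 1000)  # lambda/nL * reaction volume in nL
  wells$lambda <- lambda
  wells$copies_per_reaction <- copies
  wells$below_loq <- copies < loq_copies_per_reaction
  wells$saturated <- saturated
  wells
}

#' Geometric mean and 95% geometric confidence interval of replicates
#'
#' Computed on the log10 scale with a t-interval (n - 1 degrees of
#' freedom) and back-transformed. Non-positive values are excluded from
#' the log mean by default (their count is reported); alternatively they
#' are substituted at the limit of quantification. The \code{below_loq}
#' flag signals that the geometric mean falls under the LOQ, where
#' downstream plots suppress error bars.
#'
#' @param replicates Numeric replicate values (e.g. copies/mL).
#' @param loq Limit of quantification on the same scale.
#' @param conf_level Confidence level.
#' @param zero_handling "exclude" (default) or "substitute_loq".
#' @return List: geometric_mean, ci_lower, ci_upper, n_used,
#'   n_excluded, below_loq. The CI is NA when fewer than 2 usable values
#'   remain.
#' @export
geometric_summary <- function(replicates, loq = 0, conf_level = 0.95,
                              zero_handling = c("exclude", "substitute_loq")) {
  zero_handling <- match.arg(zero_handling)
  usable <- replicates
  if (zero_handling == "substitute_loq") {
    usable[usable <= 0] <- loq
    usable <- usable[usable > 0]
  } else {
    usable <- usable[usable > 0]
  }
  n_excluded <- length(replicates) - length(usable)
  n <- length(usable)
  if (n == 0) {
    return(list(geometric_mean = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, n_used = 0L,
                n_excluded = n_excluded, below_loq = TRUE))
  }
  lx <- log10(usable)
  gm <- 10^mean(lx)
  if (n < 2) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- stats::sd(lx) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- 10^(mean(lx) + c(-1, 1) * tq * se)
  }
  list(geometric_mean = gm, ci_lower = ci[1], ci_upper = ci[2],
       n_used = n, n_excluded = n_excluded, below_loq = gm < loq)
}
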
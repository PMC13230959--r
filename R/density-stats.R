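## Group comparison of coding densities: Kruskal-Wallis omnibus, Dunn's
## pairwise z-tests with Benjamini-Hochberg correction, and a compact
## letter display over the pairwise non-significance graph.

#' Dunn's post-hoc test on joint ranks
#'
#' Pairwise z-statistics on mean joint ranks with the usual tie
#' correction, as used after a Kruskal-Wallis omnibus test. Two-sided
#' p-values are returned unadjusted; adjust with \code{stats::p.adjust}.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @return Data frame: group1, group2, z, p_value.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- as.character(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  labs <- sort(names(mean_rank))
  pairs <- utils::combn(labs, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    z[i] <- (mean_rank[a] - mean_rank[b]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise significance calls
#'
#' Insert-and-absorb algorithm over the pairwise non-significance graph:
#' starting from one letter containing every group, each significant pair
#' splits the letters containing both members, and letters that become
#' subsets of another are absorbed. Two groups share a letter iff their
#' pairwise comparison is non-significant. Groups are ordered by the
#' supplied statistic (descending median by default) so letter 'a' labels
#' the top group; this ordering is purely presentational.
#'
#' @param pairs Data frame with columns group1, group2 and a logical
#'   \code{significant}.
#' @param groups Character vector of all group labels.
#' @param order_stat Optional named numeric used to order groups before
#'   lettering (larger first).
#' @return Named character vector group -> letters (e.g. "a", "ab").
#' @export
compact_letter_display <- function(pairs, groups, order_stat = NULL) {
  if (!is.null(order_stat)) {
    groups <- names(sort(order_stat[groups], decreasing = TRUE))
  }
  sets <- list(groups)
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            !(all(new_sets[[v]] %in% new_sets[[u]]) && u < v)) {
          keep[u] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
    sets <- sets[!duplicated(lapply(sets, sort))]
  }
  # order letters by the first (highest-ranked) group they contain
  first_idx <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_idx)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    l <- letters[(i - 1) %% 26 + 1]
    if (i > 26) l <- paste0(l, (i - 1) %/% 26)
    for (g in sets[[i]]) letters_out[g] <- paste0(letters_out[g], l)
  }
  letters_out
}

#' Compare coding densities across MGE classes
#'
#' Kruskal-Wallis omnibus H-test (with tie correction, via
#' \code{stats::kruskal.test}), Dunn's pairwise post-hoc z-tests,
#' Benjamini-Hochberg adjustment over all pairs, and a compact letter
#' display at level \code{alpha} with groups ordered by median density.
#'
#' @param groups Named list mapping group label -> numeric densities;
#'   at least 2 groups of at least 2 observations each.
#' @param alpha Significance level for the letter display.
#' @return List: \code{kruskal} (statistic, df, p_value), \code{pairwise}
#'   (group1, group2, z, p_value, p_adjusted, significant) and
#'   \code{letters} (named character vector).
#' @export
compare_densities <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("validation error: need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("validation error: every group needs >= 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), vapply(groups, length, 0L))
  if (stats::var(values) == 0) {
    # all observations identical: no evidence of any difference
    pairs <- utils::combn(sort(names(groups)), 2)
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           z = 0, p_value = 1, p_adjusted = 1,
                           significant = FALSE, stringsAsFactors = FALSE)
    med <- vapply(groups, stats::median, 0)
    return(list(
      kruskal = list(statistic = 0, df = length(groups) - 1, p_value = 1),
      pairwise = pairwise,
      letters = compact_letter_display(pairwise, names(groups), med)
    ))
  }
  kw <- stats::kruskal.test(values, factor(labels))
  pairwise <- dunn_posthoc(values, labels)
  pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "BH")
  pairwise$significant <- pairwise$p_adjusted < alpha
  med <- vapply(groups, stats::median, 0)
  list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value),
    pairwise = pairwise,
    letters = compact_letter_display(pairwise, names(groups), med)
  )
}
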
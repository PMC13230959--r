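## Weighted gene repertoire relatedness (wGRR), bidirectional best hits,
## plasmid presence inference and depth-normalized copy number.
##
## wGRR(A, B) = 100 * sum of protein identities over bidirectional best
## hits / min(|A|, |B|). Identities come from global protein alignment
## with unit match score (identity = identical residues / alignment
## length). Candidate hits below an identity floor (default 0.35) are
## discarded before BBH resolution.

## Global alignment identity and reference coverage between two protein
## sequences. Identity = matches / alignment length (gaps included);
## coverage = fraction of the subject aligned (non-gap columns).
.protein_alignment <- function(query, subject) {
  aa <- Biostrings::AA_ALPHABET
  sub_mat <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(sub_mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 2, gapExtension = 1
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pat == sub & pat != "-")
  aln_len <- length(pat)
  cov <- sum(sub != "-" & pat != "-") / nchar(subject)
  list(identity = matches / aln_len, coverage = cov)
}

## Identity matrix between two repertoires (rows = a, cols = b).
.identity_matrix <- function(a, b) {
  m <- matrix(0, length(a), length(b), dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      m[i, j] <- .protein_alignment(a[[i]], b[[j]])$identity
    }
  }
  m
}

#' Bidirectional best hits between two protein repertoires
#'
#' A pair (p, q) is reported when q is p's unique best-identity hit in B
#' and p is q's unique best in A, among candidates at or above the
#' identity floor. Ties are broken by lexicographic protein ID, so the
#' result is deterministic; each protein occurs in at most one pair.
#'
#' @param a,b Named character vectors of protein sequences.
#' @param identity_floor Minimum identity for a candidate hit.
#' @return Data frame: protein_a, protein_b, identity (possibly empty).
#' @export
bidirectional_best_hits <- function(a, b, identity_floor = 0.35) {
  if (length(a) == 0 || length(b) == 0) {
    warning("empty repertoire; returning no BBH pairs")
    return(data.frame(protein_a = character(), protein_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  m <- .identity_matrix(a, b)
  m[m < identity_floor] <- -Inf
  # best hit of each row/column with lexicographic tie-break (dimnames
  # are sorted before argmax)
  row_best <- function(mm) {
    ord <- order(colnames(mm))
    apply(mm[, ord, drop = FALSE], 1, function(x) {
      if (all(!is.finite(x))) NA_character_ else colnames(mm)[ord][which.max(x)]
    })
  }
  best_in_b <- row_best(m)
  best_in_a <- row_best(t(m))
  pairs <- list()
  for (p in rownames(m)) {
    q <- best_in_b[[p]]
    if (!is.na(q) && !is.na(best_in_a[[q]]) && best_in_a[[q]] == p) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        protein_a = p, protein_b = q, identity = m[p, q],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(pairs)) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  stopifnot(!anyDuplicated(out$protein_a), !anyDuplicated(out$protein_b))
  out
}

#' Weighted gene repertoire relatedness between two repertoires
#'
#' \code{100 * sum(BBH identities) / min(|a|, |b|)}; symmetric, in
#' \[0, 100\], and 100 for identical repertoires.
#'
#' @inheritParams bidirectional_best_hits
#' @return Percent wGRR.
#' @export
wgrr <- function(a, b, identity_floor = 0.35) {
  if (length(a) == 0 || length(b) == 0) {
    stop("validation error: empty repertoire")
  }
  bbh <- bidirectional_best_hits(a, b, identity_floor = identity_floor)
  100 * sum(bbh$identity) / min(length(a), length(b))
}

#' Infer plasmid presence from wGRR against reference plasmids
#'
#' wGRR is computed against every reference; the plasmid family is called
#' present when the maximum strictly exceeds \code{threshold} (50 by
#' convention), and the argmax reference is the closest plasmid (ties
#' broken by lexicographically smallest reference ID).
#'
#' @param strain_repertoire Named character vector of proteins from the
#'   reconstructed (remapped) element of one strain.
#' @param references Named list of reference plasmid repertoires.
#' @param threshold Strict presence threshold (percent wGRR).
#' @return List: present, closest_reference (NA when absent),
#'   wgrr_percent (the maximum), all_wgrr (named vector).
#' @export
plasmid_presence <- function(strain_repertoire, references, threshold = 50) {
  if (length(references) == 0) stop("validation error: no references")
  scores <- vapply(references, function(r) wgrr(strain_repertoire, r), 0)
  ord <- order(-scores, names(scores))
  best <- ord[1]
  present <- scores[best] > threshold
  list(
    present = unname(present),
    closest_reference = if (present) names(scores)[best] else NA_character_,
    wgrr_percent = unname(scores[best]),
    all_wgrr = scores
  )
}

#' Depth-normalized element copy number
#'
#' Mean read depth over the element divided by the mean chromosomal read
#' depth of the same strain.
#'
#' @param element_depths Per-position or mean depth of the element.
#' @param chromosome_mean_depth Mean chromosomal depth (> 0).
#' @return Copy-number ratio.
#' @export
copy_number <- function(element_depths, chromosome_mean_depth) {
  if (!is.numeric(chromosome_mean_depth) || chromosome_mean_depth <= 0) {
    stop("validation error: chromosome mean depth must be positive")
  }
  mean(element_depths) / chromosome_mean_depth
}
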
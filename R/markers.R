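## Clade-diagnostic SNP scoring and ddPCR primer/probe candidate design.
##
## Sensitivity of a SNP for a target clade = fraction of target-clade
## strains (with a call) carrying the alternate allele; specificity =
## fraction of non-target strains (with a call) NOT carrying it. Only
## core-gene SNPs with both exactly 1.0 are retained by default. Retained
## SNPs become nodes of a proximity graph whose edges delimit candidate
## primer windows; candidates must satisfy 25-40 bp primer length,
## 180-300 bp amplicon span and at least two specific positions per
## primer.

#' Call SNPs from gap-free aligned genomes against a reference
#'
#' The genomes must be positionally aligned to the reference (equal
#' length, no indels), as produced by the substitution-only simulator or
#' by an upstream variant caller's consensus. Every position where at
#' least one strain differs from the reference by an unambiguous base is
#' reported. N is treated as a missing call.
#'
#' @param genomes Named character vector of aligned strain genomes.
#' @param reference Reference sequence of the same length.
#' @return List with \code{positions} (0-based), \code{ref} (reference
#'   alleles) and \code{alleles} (strain x position character matrix, NA
#'   for missing calls).
#' @export
call_snps <- function(genomes, reference) {
  rc <- .split_chars(toupper(reference))
  n <- length(rc)
  mat <- do.call(rbind, lapply(genomes, function(g) {
    gc <- .split_chars(toupper(g))
    if (length(gc) != n) stop("validation error: genome/reference length mismatch")
    gc
  }))
  rownames(mat) <- names(genomes)
  valid <- c("A", "C", "G", "T")
  mat[!mat %in% valid] <- NA_character_
  diff_any <- colSums(mat != rep(rc, each = nrow(mat)), na.rm = TRUE) > 0
  pos <- which(diff_any)
  list(positions = pos - 1L, ref = rc[pos],
       alleles = mat[, pos, drop = FALSE])
}

#' Score SNPs for clade sensitivity and specificity
#'
#' @param alleles Strain x position character matrix of called alleles
#'   (NA = missing call), e.g. from \code{\link{call_snps}}.
#' @param positions 0-based reference positions (one per column).
#' @param ref Reference alleles (one per column).
#' @param clade_labels Named character vector strain -> clade covering all
#'   rows of \code{alleles}.
#' @param target_clade Clade to score against.
#' @param gene_table Optional data frame (gene_id, start, end; 0-based
#'   half-open) used to annotate each SNP's gene; \code{core_genes}
#'   restricts which genes count as core.
#' @param core_genes Character vector of core gene IDs, or NULL to mark
#'   every located SNP core.
#' @param replicon Replicon label stored with each site.
#' @return Data frame of SNP sites: position, replicon, gene_id, is_core,
#'   ref, alt, n_target, n_nontarget, sensitivity, specificity. The alt
#'   allele is the most frequent non-reference allele among target-clade
#'   strains (falling back to the global alternate).
#' @export
score_clade_snps <- function(alleles, positions, ref, clade_labels,
                             target_clade, gene_table = NULL,
                             core_genes = NULL, replicon = "chr1") {
  strains <- rownames(alleles)
  if (is.null(strains)) stop("validation error: alleles must have strain rownames")
  clade_labels <- clade_labels[strains]
  if (anyNA(clade_labels)) stop("validation error: strains missing clade labels")
  if (!target_clade %in% clade_labels) {
    stop("validation error: target clade absent from labels: ", target_clade)
  }
  in_target <- clade_labels == target_clade
  n_pos <- ncol(alleles)
  sens <- spec <- numeric(n_pos)
  alt <- character(n_pos)
  n_t <- n_n <- integer(n_pos)
  for (j in seq_len(n_pos)) {
    col <- alleles[, j]
    non_ref <- col[!is.na(col) & col != ref[j]]
    tgt_non_ref <- col[in_target & !is.na(col) & col != ref[j]]
    cand <- if (length(tgt_non_ref)) tgt_non_ref else non_ref
    alt[j] <- if (length(cand)) names(sort(table(cand), decreasing = TRUE))[1] else NA_character_
    called_t <- in_target & !is.na(col)
    called_n <- !in_target & !is.na(col)
    n_t[j] <- sum(called_t)
    n_n[j] <- sum(called_n)
    sens[j] <- if (n_t[j]) sum(col[called_t] == alt[j]) / n_t[j] else NA_real_
    spec[j] <- if (n_n[j]) sum(col[called_n] != alt[j]) / n_n[j] else NA_real_
  }
  gene_id <- rep(NA_character_, n_pos)
  if (!is.null(gene_table)) {
    idx <- findInterval(positions, gene_table$start)
    hit <- idx >= 1 & positions < gene_table$end[pmax(idx, 1)]
    gene_id[hit] <- gene_table$gene_id[idx[hit]]
  }
  is_core <- if (is.null(core_genes)) !is.na(gene_id) | is.null(gene_table) else
    gene_id %in% core_genes
  if (is.null(gene_table)) is_core <- rep(TRUE, n_pos)
  data.frame(
    position = positions, replicon = replicon, gene_id = gene_id,
    is_core = is_core, ref = ref, alt = alt,
    n_target = n_t, n_nontarget = n_n,
    sensitivity = sens, specificity = spec,
    stringsAsFactors = FALSE
  )
}

#' Retain SNPs with optimal sensitivity and specificity in core genes
#'
#' Default semantics keep a site only when it sits in a core gene and
#' both sensitivity and specificity equal 1 exactly; the thresholds can
#' be relaxed.
#'
#' @param sites Data frame from \code{\link{score_clade_snps}}.
#' @param min_sensitivity,min_specificity Inclusive lower bounds.
#' @return The retained subset of \code{sites}.
#' @export
filter_optimal_snps <- function(sites, min_sensitivity = 1,
                                min_specificity = 1) {
  if (nrow(sites) == 0) return(sites)
  keep <- sites$is_core &
    !is.na(sites$sensitivity) & sites$sensitivity >= min_sensitivity &
    !is.na(sites$specificity) & sites$specificity >= min_specificity
  sites[keep, , drop = FALSE]
}

#' Build the SNP proximity graph
#'
#' Nodes are retained SNP sites; an edge joins two sites on the same
#' replicon whose positions differ by at most \code{horizon} bp, weighted
#' by the absolute position difference.
#'
#' @param sites Retained SNP sites (position, replicon).
#' @param horizon Maximum edge span in bp (default 300, one amplicon).
#' @return List with \code{nodes} (the sites, row-indexed) and
#'   \code{edges} (data frame from, to, weight; indices into nodes).
#' @export
build_snp_graph <- function(sites, horizon = 300) {
  sites <- sites[order(sites$replicon, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  edges <- list()
  n <- nrow(sites)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sites$replicon[j] != sites$replicon[i]) break
        w <- sites$position[j] - sites$position[i]
        if (w > horizon) break
        if (w >= 1) edges[[length(edges) + 1L]] <- c(i, j, w)
      }
    }
  }
  edges <- if (length(edges)) {
    e <- as.data.frame(do.call(rbind, edges))
    names(e) <- c("from", "to", "weight")
    e
  } else data.frame(from = integer(), to = integer(), weight = integer())
  list(nodes = sites, edges = edges)
}

#' Design ddPCR primer/probe candidates over a SNP graph
#'
#' Enumerates forward and reverse primer windows of 25-40 bp each
#' containing at least \code{min_specific} retained SNP positions, pairs
#' them into amplicons of 180-300 bp (forward-primer start to
#' reverse-primer end, inclusive of primers), and places an 18-30 bp
#' probe window strictly between the primers maximizing contained SNP
#' positions (at least one required). Candidates are ranked by total
#' specific positions inside the two primers (descending), then amplicon
#' length (ascending), then leftmost start. Primer thermodynamics are not
#' modeled; every row is flagged \code{thermo = "unchecked"}.
#'
#' @param graph SNP graph from \code{\link{build_snp_graph}} (one
#'   replicon).
#' @param reference Reference sequence covering all node positions.
#' @param primer_len_range,amplicon_range,probe_len_range Inclusive bp
#'   constraint ranges.
#' @param min_specific Minimum retained SNP positions per primer.
#' @param max_candidates Cap on returned rows (after ranking).
#' @return Data frame of candidates, possibly empty: 0-based half-open
#'   intervals for forward, reverse, probe and amplicon, per-part
#'   specific-position counts, amplicon length and rank.
#' @export
design_primers <- function(graph, reference,
                           primer_len_range = c(25L, 40L),
                           amplicon_range = c(180L, 300L),
                           probe_len_range = c(18L, 30L),
                           min_specific = 2L,
                           max_candidates = 50L) {
  empty <- data.frame(
    fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer(),
    probe_start = integer(), probe_end = integer(),
    amplicon_start = integer(), amplicon_end = integer(),
    fwd_specific = integer(), rev_specific = integer(),
    probe_specific = integer(), amplicon_length = integer(),
    rank = integer(), thermo = character(), stringsAsFactors = FALSE
  )
  pos <- sort(unique(graph$nodes$position))
  ref_len <- nchar(reference)
  if (length(pos) && max(pos) >= ref_len) {
    stop("validation error: reference does not cover all SNP positions")
  }
  if (length(pos) < 2 * min_specific) return(empty)
  count_in <- function(s, e) sum(pos >= s & pos < e)  # [s, e) 0-based
  # candidate primer windows: enumerate starts near SNP positions
  windows <- list()
  for (len in primer_len_range[1]:primer_len_range[2]) {
    starts <- unique(unlist(lapply(pos, function(p) {
      max(0L, p - len + 1L):p
    })))
    starts <- starts[starts >= 0L & starts + len <= ref_len]
    for (s in starts) {
      k <- count_in(s, s + len)
      if (k >= min_specific) {
        windows[[length(windows) + 1L]] <- c(s, s + len, k)
      }
    }
  }
  if (!length(windows)) return(empty)
  win <- unique(as.data.frame(do.call(rbind, windows)))
  names(win) <- c("start", "end", "k")
  win <- win[order(win$start, win$end), , drop = FALSE]
  # probe placement depends only on the inter-primer gap; memoize it
  probe_cache <- new.env(parent = emptyenv())
  best_probe <- function(fe, rs) {
    key <- paste0(fe, "_", rs)
    if (!is.null(probe_cache[[key]])) return(probe_cache[[key]])
    gap_pos <- pos[pos >= fe & pos < rs]
    best <- NULL
    if (length(gap_pos)) {
      for (plen in probe_len_range[1]:probe_len_range[2]) {
        pstarts <- unique(unlist(lapply(gap_pos, function(p) {
          max(fe, p - plen + 1L):p
        })))
        pstarts <- sort(pstarts[pstarts >= fe & pstarts + plen <= rs])
        for (ps in pstarts) {
          pk <- count_in(ps, ps + plen)
          if (is.null(best) || pk > best[3]) best <- c(ps, ps + plen, pk)
        }
      }
    }
    if (is.null(best)) best <- c(NA_integer_, NA_integer_, 0L)
    probe_cache[[key]] <- best
    best
  }
  cands <- list()
  for (i in seq_len(nrow(win))) {
    fs <- win$start[i]; fe <- win$end[i]
    js <- which(win$end >= fs + amplicon_range[1] &
                win$end <= fs + amplicon_range[2] &
                win$start >= fe)
    for (j in js) {
      rs <- win$start[j]; re_ <- win$end[j]
      amp_len <- re_ - fs
      best <- best_probe(fe, rs)
      if (best[3] < 1) next
      cands[[length(cands) + 1L]] <- c(fs, fe, rs, re_, best[1], best[2],
                                       fs, re_, win$k[i], win$k[j], best[3],
                                       amp_len)
    }
  }
  if (!length(cands)) return(empty)
  out <- as.data.frame(do.call(rbind, cands))
  names(out) <- c("fwd_start", "fwd_end", "rev_start", "rev_end",
                  "probe_start", "probe_end", "amplicon_start",
                  "amplicon_end", "fwd_specific", "rev_specific",
                  "probe_specific", "amplicon_length")
  out$total_specific <- out$fwd_specific + out$rev_specific
  ord <- order(-out$total_specific, out$amplicon_length, out$fwd_start,
               out$rev_start)
  out <- out[ord, , drop = FALSE]
  out <- out[seq_len(min(nrow(out), max_candidates)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$thermo <- "unchecked"
  rownames(out) <- NULL
  out
}

#' Select presence/absence marker gene families for a phage subpopulation
#'
#' Returns gene families present in every phage of the target set and in
#' none of the others.
#'
#' @param family_presence Phage x gene-family 0/1 matrix with dimnames.
#' @param target_set Phage IDs; non-empty strict subset of the rows.
#' @return Character vector of diagnostic family IDs (possibly empty).
#' @export
select_phage_marker_genes <- function(family_presence, target_set) {
  phages <- rownames(family_presence)
  if (length(target_set) == 0) stop("validation error: empty target set")
  if (!all(target_set %in% phages)) {
    stop("validation error: unknown phage IDs in target set")
  }
  if (setequal(target_set, phages)) {
    stop("validation error: target set must be a strict subset")
  }
  tgt <- family_presence[target_set, , drop = FALSE]
  oth <- family_presence[setdiff(phages, target_set), , drop = FALSE]
  keep <- colSums(tgt > 0) == nrow(tgt) & colSums(oth > 0) == 0
  colnames(family_presence)[keep]
}
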
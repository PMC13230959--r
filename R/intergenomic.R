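## Intergenomic similarity, taxon clustering, SNP distances.
##
## Similarity between two genomes follows the VIRIDIC convention:
## 100 * (I_ab + I_ba) / (L_a + L_b), where I_xy is the number of
## identically matched nucleotides over a non-overlapping set of local
## alignment fragments of x against y. The aligner is a deterministic
## seed-and-extend over exact k-mer anchors with gapless fragments scored
## +1/-1 and extracted as maximal scoring segments (Ruzzo-Tompa), then
## greedily selected without overlap in either genome.

.split_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

## All maximal scoring subsequences (Ruzzo-Tompa) of a +1/-1 score vector
## given as run-length encoded (value, length) match runs. Returns a matrix
## with columns start, end (1-based inclusive indices into the original
## vector) and matches (count of +1 positions inside).
.maximal_segments <- function(match_vec) {
  r <- rle(match_vec)
  nr <- length(r$lengths)
  if (nr == 0) return(NULL)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  run_score <- ifelse(r$values, r$lengths, -r$lengths)
  cum <- cumsum(run_score)
  # stack of candidate subsequences: columns start_run, end_run, L, R
  st <- matrix(0, nrow = 0, ncol = 4)
  for (i in seq_len(nr)) {
    if (!r$values[i]) next
    L <- if (i == 1) 0 else cum[i - 1]
    R <- cum[i]
    cand <- c(i, i, L, R)
    repeat {
      n <- nrow(st)
      # deepest j with L_j < L_cand
      j <- if (n == 0) 0L else {
        hits <- which(st[, 3] < cand[3])
        if (length(hits)) max(hits) else 0L
      }
      if (j == 0L || st[j, 4] >= cand[4]) {
        st <- rbind(st, cand)
        break
      }
      # merge j..top with candidate
      cand <- c(st[j, 1], cand[2], st[j, 3], cand[4])
      st <- st[seq_len(j - 1L), , drop = FALSE]
    }
  }
  if (nrow(st) == 0) return(NULL)
  # positive-score subsequences only; trim to positive-run boundaries
  keep <- st[, 4] - st[, 3] > 0
  st <- st[keep, , drop = FALSE]
  if (nrow(st) == 0) return(NULL)
  out <- matrix(0L, nrow = nrow(st), ncol = 3,
                dimnames = list(NULL, c("start", "end", "matches")))
  for (i in seq_len(nrow(st))) {
    a <- st[i, 1]; b <- st[i, 2]
    out[i, 1] <- run_start[a]
    out[i, 2] <- run_end[b]
    runs <- seq.int(a, b)
    out[i, 3] <- sum(r$lengths[runs][r$values[runs]])
  }
  out
}

## Gapless seed-and-extend fragments of query against subject.
## Returns data.frame(qstart, qend, sstart, send, matches, len), 1-based
## inclusive coordinates, or NULL.
.align_fragments <- function(qc, sc, k = 11L, margin = 100L) {
  nq <- length(qc); ns <- length(sc)
  if (nq < k || ns < k) return(NULL)
  qseq <- paste(qc, collapse = ""); sseq <- paste(sc, collapse = "")
  qkm <- substring(qseq, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  skm <- substring(sseq, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
  shared <- intersect(unique(qkm), unique(skm))
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (length(shared) == 0) return(NULL)
  qhit <- which(qkm %in% shared)
  qpos <- split(qhit, qkm[qhit])
  shit <- which(skm %in% shared)
  spos <- split(shit, skm[shit])
  # anchor pairs (qp, sp) for every shared k-mer occurrence pair
  anchors_q <- integer(0); anchors_s <- integer(0)
  for (km in shared) {
    qp <- qpos[[km]]; sp <- spos[[km]]
    anchors_q <- c(anchors_q, rep(qp, each = length(sp)))
    anchors_s <- c(anchors_s, rep(sp, times = length(qp)))
  }
  diag_id <- anchors_s - anchors_q
  valid <- c("A", "C", "G", "T")
  qok <- qc %in% valid
  sok <- sc %in% valid
  frags <- list()
  for (d in unique(diag_id)) {
    ap <- sort(unique(anchors_q[diag_id == d]))
    # cluster anchors into windows; extend each by `margin`
    gaps <- which(diff(ap) > 2L * margin)
    grp_start <- c(1L, gaps + 1L)
    grp_end <- c(gaps, length(ap))
    lo_q <- max(1L, 1L - d); hi_q <- min(nq, ns - d)
    for (g in seq_along(grp_start)) {
      w1 <- max(lo_q, ap[grp_start[g]] - margin)
      w2 <- min(hi_q, ap[grp_end[g]] + k - 1L + margin)
      if (w2 < w1) next
      idx <- w1:w2
      m <- qc[idx] == sc[idx + d] & qok[idx] & sok[idx + d]
      segs <- .maximal_segments(m)
      if (is.null(segs)) next
      for (i in seq_len(nrow(segs))) {
        qs <- w1 + segs[i, "start"] - 1L
        qe <- w1 + segs[i, "end"] - 1L
        frags[[length(frags) + 1L]] <-
          c(qs, qe, qs + d, qe + d, segs[i, "matches"])
      }
    }
  }
  if (length(frags) == 0) return(NULL)
  fr <- as.data.frame(do.call(rbind, frags))
  names(fr) <- c("qstart", "qend", "sstart", "send", "matches")
  fr$len <- fr$qend - fr$qstart + 1L
  unique(fr)
}

## Total identical positions over greedily selected non-overlapping
## fragments; later fragments are trimmed to the remainder not yet covered
## in either genome and sub-segments below the length floor are dropped.
.identical_positions <- function(qc, sc, k = 11L, min_fragment = 30L) {
  fr <- .align_fragments(qc, sc, k = k)
  if (is.null(fr)) return(0L)
  fr <- fr[fr$len >= min_fragment, , drop = FALSE]
  if (nrow(fr) == 0) return(0L)
  ord <- order(-fr$matches, fr$qstart, fr$sstart)
  fr <- fr[ord, , drop = FALSE]
  qcov <- logical(length(qc)); scov <- logical(length(sc))
  valid <- c("A", "C", "G", "T")
  total <- 0L
  for (i in seq_len(nrow(fr))) {
    qi <- fr$qstart[i]:fr$qend[i]
    si <- fr$sstart[i]:fr$send[i]
    free <- !qcov[qi] & !scov[si]
    if (!any(free)) next
    # contiguous remainder segments; re-apply the length floor
    rr <- rle(free)
    ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1L
    for (j in seq_along(rr$values)) {
      if (!rr$values[j] || rr$lengths[j] < min_fragment) next
      sel <- starts[j]:ends[j]
      qs <- qi[sel]; ss <- si[sel]
      m <- qc[qs] == sc[ss] & qc[qs] %in% valid & sc[ss] %in% valid
      total <- total + sum(m)
      qcov[qs] <- TRUE; scov[ss] <- TRUE
    }
  }
  as.integer(total)
}

#' Pairwise intergenomic similarity between two genomes
#'
#' Percent intergenomic similarity in the VIRIDIC sense:
#' \code{100 * (I_ab + I_ba) / (L_a + L_b)}, where \code{I_xy} counts
#' identically matched nucleotides over a non-overlapping set of local
#' alignment fragments of genome x against genome y and L are the genome
#' lengths. Fragments come from a deterministic seed-and-extend aligner
#' (exact k-mer anchors, gapless extension, maximal +1/-1 scoring
#' segments); fragments shorter than \code{min_fragment} are discarded and
#' overlaps are resolved greedily by descending identical-position count.
#' Ambiguous bases (N) never count as identical.
#'
#' @param a,b Nucleotide sequences (single strings over A,C,G,T,N).
#' @param k Anchor k-mer size.
#' @param min_fragment Fragment length floor in bp.
#' @return Percent similarity in \[0, 100\]; symmetric in its arguments.
#' @examples
#' s <- paste(rep("ACGT", 20), collapse = "")
#' pairwise_intergenomic_similarity(s, s)  # 100
#' @export
pairwise_intergenomic_similarity <- function(a, b, k = 11L,
                                             min_fragment = 30L) {
  if (!nzchar(a) || !nzchar(b)) stop("validation error: empty sequence")
  ac <- .split_chars(toupper(a))
  bc <- .split_chars(toupper(b))
  i_ab <- .identical_positions(ac, bc, k = k, min_fragment = min_fragment)
  i_ba <- .identical_positions(bc, ac, k = k, min_fragment = min_fragment)
  sim <- 100 * (i_ab + i_ba) / (length(ac) + length(bc))
  min(100, max(0, sim))
}

#' Symmetric intergenomic similarity matrix
#'
#' @param genomes Named character vector of genome sequences (>= 2, unique
#'   IDs).
#' @param k,min_fragment Passed to
#'   \code{\link{pairwise_intergenomic_similarity}}.
#' @return Symmetric numeric matrix of percent similarities with diagonal
#'   100 and genome IDs as dimnames.
#' @export
similarity_matrix <- function(genomes, k = 11L, min_fragment = 30L) {
  if (length(genomes) < 2) stop("validation error: need >= 2 genomes")
  ids <- names(genomes)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("validation error: genomes must carry unique non-empty IDs")
  }
  n <- length(genomes)
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pairwise_intergenomic_similarity(genomes[[i]], genomes[[j]],
                                            k = k, min_fragment = min_fragment)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Cluster genomes into genus and species ranks
#'
#' Complete-linkage hierarchical clustering of \code{100 - similarity}
#' distances, cut at \code{100 - genus_threshold} and
#' \code{100 - species_threshold}. With complete linkage a cut at distance
#' \code{100 - t} yields clusters in which every pair has similarity
#' \code{>= t}, matching the inclusive ICTV-style thresholds (genus >= 70,
#' species >= 95). Both ranks come from the same dendrogram, so the
#' species partition refines the genus partition by construction.
#'
#' @param sim Similarity matrix from \code{\link{similarity_matrix}}.
#' @param genus_threshold,species_threshold Percent similarity thresholds;
#'   must satisfy \code{genus_threshold <= species_threshold}.
#' @return Data frame with columns \code{genome_id}, \code{genus_id},
#'   \code{species_id}, \code{genus_singleton}, \code{species_singleton}.
#'   Cluster IDs are assigned deterministically by the lexicographically
#'   smallest member genome ID.
#' @export
cluster_taxa <- function(sim, genus_threshold = 70, species_threshold = 95) {
  if (genus_threshold > species_threshold) {
    stop("validation error: genus_threshold must be <= species_threshold")
  }
  if (!isSymmetric(unname(sim)) || any(diag(sim) != 100)) {
    stop("validation error: invalid similarity matrix")
  }
  ids <- rownames(sim)
  hc <- stats::hclust(stats::as.dist(100 - sim), method = "complete")
  label_cut <- function(threshold, prefix) {
    cl <- stats::cutree(hc, h = 100 - threshold)
    # deterministic IDs: order clusters by their smallest member ID
    rep_id <- vapply(split(ids, cl), min, character(1))
    ranks <- rank(rep_id)
    labs <- sprintf("%s%03d", prefix, ranks[as.character(cl)])
    names(labs) <- ids
    labs
  }
  genus <- label_cut(genus_threshold, "G")
  species <- label_cut(species_threshold, "S")
  data.frame(
    genome_id = ids,
    genus_id = unname(genus),
    species_id = unname(species),
    genus_singleton = unname(table(genus)[genus] == 1),
    species_singleton = unname(table(species)[species] == 1),
    stringsAsFactors = FALSE
  )
}

#' SNP distance between two aligned sequences
#'
#' Counts positions at which both characters are unambiguous nucleotides
#' (A, C, G, T) and differ. Gapped ("-") or ambiguous (N) columns are
#' excluded.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences.
#' @return Integer SNP count.
#' @export
snp_distance <- function(aligned_a, aligned_b) {
  a <- .split_chars(toupper(aligned_a))
  b <- .split_chars(toupper(aligned_b))
  if (length(a) != length(b)) {
    stop("validation error: aligned sequences must have equal length")
  }
  valid <- c("A", "C", "G", "T")
  sum(a %in% valid & b %in% valid & a != b)
}
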
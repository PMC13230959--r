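## Pangenome plasticity regions, MGE classification, cargo screening and
## coding-density statistics.

#' Flag persistent gene families
#'
#' A family is persistent when its prevalence (fraction of strains
#' carrying it) reaches \code{persistent_fraction}, inclusive (the 90%
#' convention of persistent-genome analyses).
#'
#' @param presence Strain x family 0/1 matrix.
#' @param persistent_fraction Inclusive prevalence threshold.
#' @return Data frame: family, prevalence, persistent.
#' @export
classify_persistent_families <- function(presence, persistent_fraction = 0.90) {
  if (is.null(dim(presence)) || nrow(presence) == 0 || ncol(presence) == 0) {
    stop("validation error: empty presence matrix")
  }
  prevalence <- colMeans(presence > 0)
  data.frame(
    family = colnames(presence),
    prevalence = unname(prevalence),
    persistent = unname(prevalence >= persistent_fraction),
    stringsAsFactors = FALSE
  )
}

#' Call regions of genomic plasticity (RGPs)
#'
#' An RGP is a maximal run of consecutive non-persistent genes along a
#' contig whose total span is at least \code{min_span} bp and which
#' contains at least \code{min_genes} genes. Gene coordinates are 0-based
#' half-open; regions span from the first gene start to the last gene
#' end.
#'
#' @param gene_order Data frame (strain, contig, gene_id, family, start,
#'   end) sorted by start within each strain/contig.
#' @param persistent Either a logical vector named by family, or the data
#'   frame from \code{\link{classify_persistent_families}}.
#' @param min_span Minimum span in bp.
#' @param min_genes Minimum gene count.
#' @return Data frame: rgp_id, strain, contig, start, end, n_genes,
#'   gene_ids (comma separated).
#' @export
call_rgps <- function(gene_order, persistent, min_span = 3000, min_genes = 3) {
  if (is.data.frame(persistent)) {
    persistent <- stats::setNames(persistent$persistent, persistent$family)
  }
  out <- list()
  for (key in unique(paste(gene_order$strain, gene_order$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- gene_order[gene_order$strain == parts[1] & gene_order$contig == parts[2], ,
                    drop = FALSE]
    if (is.unsorted(g$start)) {
      stop("validation error: genes must be sorted by start within contig")
    }
    flex <- !persistent[g$family]
    if (anyNA(flex)) stop("validation error: family missing persistent flag")
    r <- rle(flex)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      idx <- starts[i]:ends[i]
      span_start <- g$start[idx[1]]
      span_end <- g$end[idx[length(idx)]]
      if (length(idx) >= min_genes && span_end - span_start >= min_span) {
        out[[length(out) + 1L]] <- data.frame(
          strain = parts[1], contig = parts[2],
          start = span_start, end = span_end,
          n_genes = length(idx),
          gene_ids = paste(g$gene_id[idx], collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(rgp_id = character(), strain = character(),
                      contig = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      gene_ids = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strain, res$contig, res$start), , drop = FALSE]
  res <- cbind(rgp_id = sprintf("rgp%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Classify RGPs into mobile-genetic-element classes
#'
#' First matching rule wins, in the fixed precedence order: (1) plasmid
#' if flagged as likely plasmid origin; (2) satellite if the region
#' contains an entire predicted phage-satellite segment; (3) prophage if
#' carrying a viral call, or a complete/high/medium/low-quality prophage
#' prediction together with at least one viral gene; (4) integrase if an
#' integrase gene is present; (5) unclassified otherwise. Classification
#' is total and exclusive.
#'
#' @param flags Data frame with logical columns \code{plasmid_origin},
#'   \code{satellite_full_segment}, \code{viral_call},
#'   \code{integrase_present}, character \code{prophage_quality} (one of
#'   complete, high, medium, low, none) and integer
#'   \code{viral_gene_count}.
#' @return Character vector of assigned classes, one per row.
#' @export
classify_rgp <- function(flags) {
  qual_ok <- flags$prophage_quality %in% c("complete", "high", "medium", "low")
  prophage <- flags$viral_call | (qual_ok & flags$viral_gene_count >= 1)
  ifelse(flags$plasmid_origin, "plasmid",
    ifelse(flags$satellite_full_segment, "satellite",
      ifelse(prophage, "prophage",
        ifelse(flags$integrase_present, "integrase", "unclassified"))))
}

#' Retain prophage predictions passing class-specific size filters
#'
#' Retention requires genome size strictly greater than the class
#' threshold: Caudoviricetes 25 kbp, Tectiliviricetes 10 kbp,
#' Faserviricetes 4 kbp. Records of unknown viral class are skipped with
#' a warning.
#'
#' @param predictions Data frame with columns \code{viral_class} and
#'   \code{genome_size} (bp).
#' @return The retained subset.
#' @export
filter_prophages <- function(predictions) {
  thresholds <- c(Caudoviricetes = 25000, Tectiliviricetes = 10000,
                  Faserviricetes = 4000)
  known <- predictions$viral_class %in% names(thresholds)
  if (any(!known)) {
    warning("skipping record(s) with unknown viral class: ",
            paste(unique(predictions$viral_class[!known]), collapse = ", "))
  }
  p <- predictions[known, , drop = FALSE]
  p[p$genome_size > thresholds[p$viral_class], , drop = FALSE]
}

#' Screen a protein repertoire against a cargo reference database
#'
#' Each query is aligned (global alignment, unit match score) against
#' every reference; the best hit is reported when its percent identity
#' and reference coverage reach the database-specific minima. Identity is
#' identical residues over alignment length; coverage is the aligned
#' (non-gap) fraction of the reference sequence.
#'
#' @param proteins Named character vector of query protein sequences.
#' @param reference_set Named character vector of reference proteins.
#' @param min_identity,min_coverage Percent thresholds (inclusive); use
#'   70/50 for metal/biocide and virulence screens, 30/50 for AMR.
#' @return Data frame of hits: protein, reference, identity, coverage.
#' @export
screen_cargo <- function(proteins, reference_set, min_identity = 70,
                         min_coverage = 50) {
  if (length(reference_set) == 0) {
    stop("validation error: empty reference set")
  }
  hits <- list()
  for (q in names(proteins)) {
    best <- NULL
    for (r in names(reference_set)) {
      aln <- .protein_alignment(proteins[[q]], reference_set[[r]])
      if (is.null(best) || aln$identity > best$identity) {
        best <- c(aln, list(reference = r))
      }
    }
    if (best$identity * 100 >= min_identity && best$coverage * 100 >= min_coverage) {
      hits[[length(hits) + 1L]] <- data.frame(
        protein = q, reference = best$reference,
        identity = best$identity * 100, coverage = best$coverage * 100,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(protein = character(), reference = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Cargo-hit coding density per kbp
#'
#' @param n_hits Number of cargo hits in the region.
#' @param region_length Region length in bp (> 0).
#' @return Hits per kbp.
#' @export
coding_density <- function(n_hits, region_length) {
  if (any(region_length <= 0)) stop("validation error: zero-length region")
  n_hits * 1000 / region_length
}

#' Length of the non-mobile genome remainder
#'
#' @param genome_length Genome length in bp.
#' @param rgps Data frame of non-overlapping RGPs with start/end (0-based
#'   half-open) on that genome.
#' @return Remainder length in bp.
#' @export
non_mobile_length <- function(genome_length, rgps) {
  genome_length - sum(rgps$end - rgps$start)
}
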
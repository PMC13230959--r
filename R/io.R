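#' Read a FASTA file into a sequence record list
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that enforces
#' the package's sequence-record contract: unique non-empty identifiers,
#' uppercased sequences over \{A,C,G,T,N\}, input order preserved.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of uppercase sequences; names are record
#'   IDs (the FASTA header up to the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("validation error: empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("validation error: empty record ID")
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("validation error: duplicate FASTA IDs: ", paste(dup, collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("validation error: all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("validation error: duplicate IDs")
  set <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a table to TSV with schema validation
#'
#' Writes a header-bearing tab-separated file with a deterministic column
#' order given by \code{schema}. Rows must carry every schema column;
#' extra columns are dropped with a warning.
#'
#' @param rows Data frame of rows (possibly zero rows).
#' @param path Output path.
#' @param schema Character vector of required column names, in output order.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(rows, path, schema = names(rows)) {
  rows <- as.data.frame(rows)
  missing <- setdiff(schema, names(rows))
  if (length(missing)) {
    stop("validation error: rows missing column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(rows), schema)
  if (length(extra)) {
    warning("dropping column(s) not in schema: ", paste(extra, collapse = ", "))
  }
  utils::write.table(rows[, schema, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by \code{write_table}
#'
#' @param path Input path.
#' @param schema Optional character vector of required columns.
#' @return Data frame.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(out))
    if (length(missing)) {
      stop("validation error: file missing column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  out
}
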
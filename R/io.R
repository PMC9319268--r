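# Shared readers/writers. All user-facing coordinates are 1-based alignment
# columns, matching the typing scheme; sequences are stored as plain upper-case
# character strings (gaps kept, U mapped to T).

#' Read a FASTA file of ITS sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that normalises case,
#' maps U to T, preserves gaps and IUPAC ambiguity codes, and enforces unique
#' non-empty records.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("FASTA format error: duplicate record id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop(sprintf("FASTA format error: empty sequence for record %d ('%s')",
                 empty[1], ids[empty[1]]), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences (gaps allowed).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a diagnostic state matrix TSV
#'
#' The layout mirrors the packaged fixture: one row per sample with columns
#' `sample_id`, `country`, `species`, `printed_type`, one column per scheme
#' coordinate, `accession`, `is_haploid`. State cells use `-` for gaps and
#' slash codes such as `T/-` verbatim.
#'
#' @param path path to the TSV.
#' @param scheme a `diagnostic_scheme`; the header must contain all its
#'   coordinates.
#' @return data frame (state columns as character).
#' @export
read_states_tsv <- function(path, scheme = load_scheme()) {
  if (!file.exists(path)) stop("state TSV not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("state TSV schema error: no data rows", call. = FALSE)
  pos_cols <- as.character(scheme$positions)
  missing <- setdiff(c("sample_id", pos_cols), names(tab))
  if (length(missing)) {
    stop("state TSV schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (p in pos_cols) {
    lapply(tab[[p]], char_set)  # validates the alphabet cell by cell
  }
  if ("is_haploid" %in% names(tab)) {
    tab$is_haploid <- as.logical(tab$is_haploid)
  }
  tab
}

#' Write a diagnostic state matrix TSV
#'
#' Inverse of [read_states_tsv()]: writing then re-reading the packaged
#' fixture reproduces its data rows exactly.
#'
#' @param tab data frame in the state-matrix layout.
#' @param path output path.
#' @export
write_states_tsv <- function(tab, path) {
  out <- tab
  if ("phased" %in% names(out)) out$phased <- NULL  # derived column
  if ("is_haploid" %in% names(out)) {
    out$is_haploid <- ifelse(out$is_haploid, "TRUE", "FALSE")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a typing report TSV
#'
#' @param report data frame as returned by [classify_fixture()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a labelled square distance matrix TSV
#'
#' @param path TSV with row and column taxon labels.
#' @return symmetric numeric matrix.
#' @export
read_distance_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  validate_distance_matrix(m)
  m
}

#' Write a labelled distance matrix TSV
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param path output path.
#' @export
write_distance_tsv <- function(m, path) {
  out <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
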
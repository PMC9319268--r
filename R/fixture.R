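#' Load the packaged 66-sample diagnostic state matrix
#'
#' The packaged fixture transcribes the published state matrix of 66 ITS
#' sequences of *A. subrufescens* and *A. macrochlamys*: per sample, the
#' observed character at each of the 14 diagnostic positions (IUPAC/gap/slash
#' coded), the printed ITS type label, country, species, GenBank accession
#' and whether the row is a haploid sequence (clone, single-spore isolate or
#' offset-interpreted electropherogram read) rather than a heterokaryotic
#' culture consensus.
#'
#' A `phased` column is derived from the printed label: labels wrapped in
#' parentheses mark heterokaryons whose haploid sequences are unknown, so
#' those rows are unphased; all other rows are treated as phased.
#'
#' @param path path to a state TSV; defaults to the packaged fixture.
#' @param scheme a `diagnostic_scheme`; the fixture's state columns must
#'   match its positions.
#' @return data frame with columns `sample_id`, `country`, `species`,
#'   `printed_type`, one character column per diagnostic position (named by
#'   coordinate), `accession`, `is_haploid`, `phased`.
#' @examples
#' tab <- load_table2()
#' nrow(tab)            # 66
#' sum(tab$is_haploid)  # 9
#' @export
load_table2 <- function(path = system.file("extdata", "table2_states.tsv",
                                           package = "agaritype"),
                        scheme = load_scheme()) {
  tab <- read_states_tsv(path, scheme)
  if (nrow(tab) != 66L) {
    stop("fixture integrity: expected 66 rows, got ", nrow(tab), call. = FALSE)
  }
  if (sum(tab$is_haploid) != 9L) {
    stop("fixture integrity: expected 9 haploid rows, got ",
         sum(tab$is_haploid), call. = FALSE)
  }
  tab$phased <- !grepl("^\\(", tab$printed_type)
  tab
}

#' Extract one sample's state vector from a fixture data frame
#'
#' @param tab data frame as returned by [load_table2()].
#' @param sample_id a sample identifier present in `tab`.
#' @param scheme a `diagnostic_scheme`.
#' @return named character vector over the scheme positions.
#' @export
state_vector <- function(tab, sample_id, scheme = load_scheme()) {
  i <- match(sample_id, tab$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id, call. = FALSE)
  v <- unlist(tab[i, as.character(scheme$positions)])
  stats::setNames(as.character(v), as.character(scheme$positions))
}
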
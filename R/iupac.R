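#' @keywords internal
"_PACKAGE"

# Base alphabet for diagnostic states: the four nucleotides plus the alignment gap.
STATE_ALPHABET <- c("A", "C", "G", "T", "-")

# Two-fold IUPAC ambiguity codes. Base-vs-gap heteromorphism has no IUPAC
# symbol and is carried as a slash code, e.g. "T/-".
IUPAC2 <- list(
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"),
  W = c("A", "T"), S = c("C", "G"), K = c("G", "T")
)

#' Expand an observed state character into its character set
#'
#' Diagnostic cells carry plain bases, the gap `"-"`, a two-fold IUPAC code
#' (`R`, `Y`, `M`, `W`, `S`, `K`), or a slash code such as `"T/-"` for a
#' base-versus-gap heteromorphism. This helper maps any of these to the
#' underlying set of characters drawn from `{A,C,G,T,-}`.
#'
#' @param x single observed state string.
#' @return character vector of 1 or 2 elements, sorted.
#' @examples
#' char_set("R")
#' char_set("T/-")
#' @export
char_set <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("observed state must be a single non-empty string", call. = FALSE)
  }
  if (x %in% STATE_ALPHABET) return(x)
  if (!is.null(IUPAC2[[x]])) return(IUPAC2[[x]])
  if (grepl("^[ACGT]/-$", x)) return(sort(c(substr(x, 1L, 1L), "-")))
  if (grepl("^-/[ACGT]$", x)) return(sort(c(substr(x, 3L, 3L), "-")))
  stop(sprintf("unrecognised state character '%s'", x), call. = FALSE)
}

#' Collapse a character set back to its coded representation
#'
#' Inverse of [char_set()] for sets of size one or two: singletons return
#' themselves, two distinct bases return the IUPAC two-fold code, and a base
#' plus a gap returns the slash code with the base first.
#'
#' @param s character vector of states from `{A,C,G,T,-}`.
#' @return single string.
#' @export
set_to_code <- function(s) {
  s <- sort(unique(s))
  if (!all(s %in% STATE_ALPHABET)) {
    stop("set contains characters outside {A,C,G,T,-}", call. = FALSE)
  }
  if (length(s) == 1L) return(s)
  if (length(s) == 2L) {
    if ("-" %in% s) return(paste0(setdiff(s, "-"), "/-"))
    for (code in names(IUPAC2)) {
      if (identical(IUPAC2[[code]], s)) return(code)
    }
  }
  stop("no single-character code for sets of size > 2", call. = FALSE)
}

#' Union of two allele characters as observed in a heterokaryon consensus
#'
#' A heterokaryotic culture carries two allele copies; direct Sanger
#' sequencing of its ITS shows both at once, so a position where the two
#' alleles differ is read as a two-fold IUPAC code, and a base opposite a gap
#' is read as a slash code (no IUPAC symbol covers base-vs-gap).
#'
#' @param a,b single characters from `{A,C,G,T,-}`.
#' @return a single state string: `a` when the characters agree, the IUPAC
#'   code for two distinct bases, or a slash code (e.g. `"T/-"`).
#' @examples
#' iupac_union("A", "G")  # "R"
#' iupac_union("T", "-")  # "T/-"
#' @export
iupac_union <- function(a, b) {
  for (x in c(a, b)) {
    if (!is.character(x) || length(x) != 1L || !(x %in% STATE_ALPHABET)) {
      stop("iupac_union() arguments must be single characters from {A,C,G,T,-}",
           call. = FALSE)
    }
  }
  set_to_code(c(a, b))
}
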
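TYPE_LETTERS <- c("A", "B", "C", "M")

#' Load the diagnostic ITS typing scheme
#'
#' The scheme records the 14 alignment positions whose states distinguish the
#' ITS haplotype types A, B, C and M within the *Agaricus subrufescens*
#' species complex, the allowed character set of each type at each position,
#' and which type each position is characteristic of (i.e. carries a state
#' unique to that type; B is the reference backbone and is characteristic
#' nowhere).
#'
#' @param path path to a scheme TSV; defaults to the packaged scheme.
#' @return an object of class `diagnostic_scheme`: a list with
#'   \describe{
#'     \item{positions}{integer vector of 14 strictly increasing 1-based
#'       alignment coordinates}
#'     \item{alleles}{per position, a named list mapping each type letter to
#'       its allowed character set}
#'     \item{characteristic_of}{named character vector mapping each position
#'       (as a name) to the type letter it is characteristic of}
#'   }
#' @examples
#' sc <- load_scheme()
#' length(sc$positions)  # 14
#' @export
load_scheme <- function(path = system.file("extdata", "scheme_references.tsv",
                                           package = "agaritype")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("scheme fixture not found", call. = FALSE)
  }
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("position", "characteristic_of", TYPE_LETTERS)
  if (!all(need %in% names(tab))) {
    stop("scheme integrity: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  positions <- as.integer(tab$position)
  alleles <- lapply(seq_len(nrow(tab)), function(i) {
    al <- lapply(TYPE_LETTERS, function(tp) {
      s <- strsplit(tab[[tp]][i], "/", fixed = TRUE)[[1]]
      if (!all(s %in% STATE_ALPHABET)) {
        stop(sprintf(
          "scheme integrity: allele set '%s' at position %d outside {A,C,G,T,-}",
          tab[[tp]][i], positions[i]), call. = FALSE)
      }
      sort(s)
    })
    names(al) <- TYPE_LETTERS
    al
  })
  names(alleles) <- positions
  characteristic_of <- stats::setNames(tab$characteristic_of,
                                       as.character(positions))
  scheme <- structure(
    list(positions = positions, alleles = alleles,
         characteristic_of = characteristic_of),
    class = "diagnostic_scheme"
  )
  validate_scheme(scheme)
  scheme
}

# Integrity checks: each failure names the violated invariant.
validate_scheme <- function(scheme) {
  p <- scheme$positions
  if (length(p) != 14L) {
    stop("scheme integrity: expected exactly 14 positions, got ", length(p),
         call. = FALSE)
  }
  if (any(diff(p) <= 0L)) {
    stop("scheme integrity: coordinates must be strictly increasing",
         call. = FALSE)
  }
  ch <- scheme$characteristic_of
  if (!all(ch %in% c("A", "C", "M"))) {
    stop("scheme integrity: every position must be characteristic of A, C or M",
         call. = FALSE)
  }
  counts <- table(factor(ch, levels = c("A", "C", "M")))
  if (!identical(as.integer(counts), c(6L, 3L, 5L))) {
    stop("scheme integrity: characteristic position counts must be 6 (A), 3 (C), 5 (M)",
         call. = FALSE)
  }
  # A characteristic position must separate its type from the B backbone
  # (type M additionally carries a state at 130 that type A shares, so
  # uniqueness against all other types holds only for M's own positions and
  # is asserted by the unique_states() contract, not here).
  for (i in seq_along(p)) {
    al <- scheme$alleles[[i]]
    focal <- ch[[as.character(p[i])]]
    if (length(intersect(al[[focal]], al[["B"]])) != 0L) {
      stop(sprintf(
        "scheme integrity: position %d not characteristic of %s against the B reference",
        p[i], focal), call. = FALSE)
    }
  }
  invisible(scheme)
}

#' @export
print.diagnostic_scheme <- function(x, ...) {
  cat("Diagnostic ITS typing scheme:", length(x$positions), "positions\n")
  cat("  positions:", paste(x$positions, collapse = " "), "\n")
  for (tp in c("A", "C", "M")) {
    cat(sprintf("  characteristic of %s: %s\n", tp,
                paste(x$positions[x$characteristic_of == tp], collapse = " ")))
  }
  invisible(x)
}

#' Allowed character sets of one haplotype reference
#'
#' @param scheme a `diagnostic_scheme`.
#' @param type_letter one of `"A"`, `"B"`, `"C"`, `"M"`.
#' @return named list (by position) of allowed character vectors.
#' @export
reference_alleles <- function(scheme, type_letter) {
  check_type_letters(type_letter)
  lapply(scheme$alleles, `[[`, type_letter)
}

#' Canonical single-character state vector of a haplotype reference
#'
#' Where a reference tolerates within-type variation (position 494 carries
#' either C or T in types A, B and C) the first allowed character is used.
#'
#' @inheritParams reference_alleles
#' @return named character vector of length 14 (names are positions).
#' @export
reference_vector <- function(scheme, type_letter) {
  al <- reference_alleles(scheme, type_letter)
  vapply(al, `[[`, character(1), 1L)
}

check_type_letters <- function(x) {
  if (!all(x %in% TYPE_LETTERS)) {
    stop("unknown ITS type letter: ",
         paste(setdiff(x, TYPE_LETTERS), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Count diagnostic positions at which two type references are disjoint
#'
#' Two references "differ" at a position when their allowed character sets
#' share no state, so within-type variation (e.g. C/T at position 494) never
#' counts as a difference.
#'
#' @param x,y type letters.
#' @param scheme a `diagnostic_scheme`.
#' @return integer count.
#' @examples
#' count_type_differences("A", "B")  # 6
#' @export
count_type_differences <- function(x, y, scheme = load_scheme()) {
  check_type_letters(c(x, y))
  sum(vapply(scheme$alleles, function(al) {
    length(intersect(al[[x]], al[[y]])) == 0L
  }, logical(1)))
}

#' Positions informative for a set of types
#'
#' A position is informative for a type set when the named references do not
#' all share a common allowed allele there.
#'
#' @param types character vector of at least two type letters.
#' @param scheme a `diagnostic_scheme`.
#' @return integer vector of positions.
#' @examples
#' length(informative_positions(c("A", "B", "C")))       # 9
#' length(informative_positions(c("A", "B", "C", "M")))  # 14
#' @export
informative_positions <- function(types, scheme = load_scheme()) {
  types <- unique(types)
  check_type_letters(types)
  if (length(types) < 2L) {
    stop("informative_positions() needs at least two types", call. = FALSE)
  }
  keep <- vapply(scheme$alleles, function(al) {
    length(Reduce(intersect, al[types])) == 0L
  }, logical(1))
  scheme$positions[keep]
}

#' Positions where one type's states are unique against a set of others
#'
#' @param focal a type letter not contained in `others`.
#' @param others character vector of type letters.
#' @param scheme a `diagnostic_scheme`.
#' @return integer vector of positions where the focal allowed set is
#'   disjoint from the union of the others' allowed sets.
#' @examples
#' unique_states("M", c("A", "B", "C"))  # 166 196 210 494 518
#' @export
unique_states <- function(focal, others, scheme = load_scheme()) {
  check_type_letters(c(focal, others))
  if (focal %in% others) {
    stop("focal type must not be contained in the comparison set", call. = FALSE)
  }
  keep <- vapply(scheme$alleles, function(al) {
    pool <- Reduce(union, al[others])
    length(intersect(al[[focal]], pool)) == 0L
  }, logical(1))
  scheme$positions[keep]
}
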
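# ITS type classification.
#
# A culture's genotype is modelled as a multiset of 1-3 allele types drawn
# from {A,B,C,M}. The expected observation of a candidate component set at a
# diagnostic position is the union of the components' allowed characters
# (what a superposed Sanger read of those alleles would show); an observed
# state is compatible with the candidate when its character set is contained
# in that union.
#
# Candidates are ranked by (1) compatibility score (number of compatible
# positions), (2) specificity (number of positions where the observed set
# equals the expected set exactly), (3) fewer components, (4) lexicographic
# label. The specificity criterion is needed because the B reference carries
# no private allele: its profile is contained in the A+C union everywhere, so
# set-compatibility alone cannot separate {A,C} from {A,B} or {B,C}.

candidate_sets <- function() {
  out <- list()
  for (k in 1:3) {
    cmb <- utils::combn(TYPE_LETTERS, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Per-candidate evaluation of one state vector against the scheme.
score_candidate <- function(obs_sets, comps, scheme, gap_policy) {
  n <- length(scheme$positions)
  compat <- logical(n); exact <- logical(n); miss <- logical(n)
  for (i in seq_len(n)) {
    expected <- sort(unique(unlist(scheme$alleles[[i]][comps])))
    obs <- obs_sets[[i]]
    if (gap_policy == "missing" && identical(obs, "-") &&
        !("-" %in% expected)) {
      # the cell is read as absent data, not a deletion allele
      miss[i] <- TRUE
      compat[i] <- TRUE
      next
    }
    compat[i] <- all(obs %in% expected)
    exact[i] <- setequal(obs, expected)
  }
  list(compat = compat, exact = exact, missing = miss,
       score = sum(compat), exact_n = sum(exact))
}

#' Classify a diagnostic state vector into an ITS type call
#'
#' Enumerates all component sets of one to three allele types from
#' `{A,B,C,M}`, scores each against the observed states, and returns the
#' best call. A component is rendered lowercase when at least one of its
#' characteristic positions shows no support for its allele (type B, the
#' reference backbone, has no characteristic positions and is never
#' lowercased). Unphased heteroallelic calls are wrapped in parentheses.
#'
#' @param states named character vector over the scheme positions (names are
#'   coordinates; an unnamed vector of the right length is taken in scheme
#'   order). Cells may be bases, `-`, two-fold IUPAC codes or slash codes.
#' @param scheme a `diagnostic_scheme`.
#' @param phased logical; `FALSE` marks heterokaryons whose haploid phase is
#'   inferred rather than experimentally resolved. Affects only the
#'   parentheses in the rendered label.
#' @param gap_policy `"missing"` (default) treats an observed `-` as no-data
#'   for any candidate whose expected characters do not include the gap;
#'   `"deletion"` treats every `-` as a real fifth character.
#' @param floor minimum compatibility score (of 14) below which the sample is
#'   reported untypable instead of being assigned the best poor call.
#' @param haploid logical; haploid inputs render single-letter labels
#'   (`"M"`), cultures render doubled letters for homoallelic calls (`"MM"`).
#' @return an object of class `type_call` with elements `components`
#'   (sorted unique letters), `lowercase` (named logical per component),
#'   `parenthesized`, `score`, `exact`, `co_optimal` (labels of calls tying
#'   on score), `untypable`, and the rendered `label`.
#' @examples
#' sc <- load_scheme()
#' classify(reference_vector(sc, "B"), sc)$label  # "BB"
#' @export
classify <- function(states, scheme = load_scheme(), phased = TRUE,
                     gap_policy = c("missing", "deletion"), floor = 10,
                     haploid = FALSE) {
  gap_policy <- match.arg(gap_policy)
  n <- length(scheme$positions)
  if (length(states) != n) {
    stop(sprintf("state vector parse error: expected %d states, got %d",
                 n, length(states)), call. = FALSE)
  }
  if (!is.null(names(states))) {
    idx <- match(as.character(scheme$positions), names(states))
    if (anyNA(idx)) {
      stop("state vector parse error: names do not cover the scheme positions",
           call. = FALSE)
    }
    states <- states[idx]
  }
  obs_sets <- lapply(states, char_set)

  cands <- candidate_sets()
  evals <- lapply(cands, score_candidate, obs_sets = obs_sets,
                  scheme = scheme, gap_policy = gap_policy)
  score <- vapply(evals, `[[`, numeric(1), "score")
  exact <- vapply(evals, `[[`, numeric(1), "exact_n")
  ncomp <- lengths(cands)
  lab <- vapply(cands, paste, character(1), collapse = "")
  ord <- order(-score, -exact, ncomp, lab)
  best <- ord[1]

  comps <- cands[[best]]
  ev <- evals[[best]]
  co <- setdiff(which(score == score[best]), best)
  co <- co[order(-exact[co], ncomp[co], lab[co])]

  lower <- lowercase_components(comps, obs_sets, ev$missing, scheme)
  call <- structure(list(
    components = comps,
    lowercase = lower,
    parenthesized = !phased && length(comps) >= 2L,
    score = ev$score,
    exact = ev$exact_n,
    co_optimal = lab[co],
    untypable = ev$score < floor,
    haploid = haploid,
    gap_policy = gap_policy
  ), class = "type_call")
  call$label <- format_type_call(call)
  call
}

# A component is lowercased when one of its scheme-characteristic positions
# lacks support for its allele; positions read as missing data stay neutral.
lowercase_components <- function(comps, obs_sets, missing, scheme) {
  vapply(comps, function(tp) {
    idx <- which(scheme$characteristic_of == tp)
    if (!length(idx)) return(FALSE)  # type B: reference backbone
    for (i in idx) {
      if (missing[i]) next
      if (!length(intersect(obs_sets[[i]], scheme$alleles[[i]][[tp]]))) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = TRUE)
}

#' Render an ITS type call as its printed label
#'
#' Homoallelic culture calls double the letter (`"MM"`), haploid calls use a
#' single letter, heteroallelic calls concatenate the letters in alphabetic
#' order, partial components are lowercased (`"aB"`) and unphased calls are
#' wrapped in parentheses (`"(aB)"`).
#'
#' @param call a `type_call`.
#' @return single string; `"untypable"` when below the score floor.
#' @export
format_type_call <- function(call) {
  if (isTRUE(call$untypable)) return("untypable")
  letters_out <- vapply(call$components, function(tp) {
    if (call$lowercase[[tp]]) tolower(tp) else tp
  }, character(1))
  lab <- if (length(letters_out) == 1L && !isTRUE(call$haploid)) {
    paste0(letters_out, letters_out)
  } else {
    paste(letters_out, collapse = "")
  }
  if (isTRUE(call$parenthesized)) lab <- paste0("(", lab, ")")
  lab
}

#' @export
print.type_call <- function(x, ...) {
  cat("ITS type call:", x$label,
      sprintf("(score %d/14, exact %d)\n", x$score, x$exact))
  if (length(x$co_optimal)) {
    cat("  co-optimal component sets:", paste(x$co_optimal, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify every row of a state matrix and compare with printed labels
#'
#' @param tab data frame in the fixture layout (see [load_table2()]); a
#'   `phased` column is derived from parentheses in `printed_type` if absent.
#' @param scheme a `diagnostic_scheme`.
#' @param ... further arguments passed to [classify()] (e.g. `gap_policy`).
#' @return data frame with one row per sample: `sample_id`, `computed_type`,
#'   `printed_type`, `components` (selected component letters, collapsed),
#'   `match` (full label), `component_match` (ignoring case and
#'   parentheses), `score`, `co_optimal`, plus carried-over `country` and
#'   `species`. A `summary` attribute tabulates computed labels by species.
#' @examples
#' rep <- classify_fixture(load_table2())
#' sum(rep$computed_type == "MM")  # 17
#' @export
classify_fixture <- function(tab, scheme = load_scheme(), ...) {
  if (!"phased" %in% names(tab)) {
    tab$phased <- !grepl("^\\(", tab$printed_type)
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    states <- stats::setNames(
      as.character(unlist(tab[i, as.character(scheme$positions)])),
      as.character(scheme$positions))
    call <- classify(states, scheme, phased = tab$phased[i],
                     haploid = isTRUE(tab$is_haploid[i]), ...)
    printed <- tab$printed_type[i]
    data.frame(
      sample_id = tab$sample_id[i],
      country = if ("country" %in% names(tab)) tab$country[i] else NA_character_,
      species = if ("species" %in% names(tab)) tab$species[i] else NA_character_,
      computed_type = call$label,
      printed_type = printed,
      components = paste(call$components, collapse = ""),
      match = identical(call$label, printed),
      component_match = setequal(call$components, printed_components(printed)),
      score = call$score,
      co_optimal = paste(call$co_optimal, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  if ("species" %in% names(tab)) {
    attr(report, "summary") <- table(report$species, report$computed_type)
  }
  report
}

#' Component letters of a printed ITS type label
#'
#' Strips parentheses and case and returns the unique type letters, so
#' `"(aB)"` gives `c("A","B")` and `"MM"` gives `"M"`.
#'
#' @param label printed label string.
#' @return character vector of unique uppercase letters.
#' @export
printed_components <- function(label) {
  chars <- strsplit(gsub("[()]", "", label), "")[[1]]
  sort(unique(toupper(chars)))
}

#' Decompose an ambiguous state vector into compatible haplotype pairs
#'
#' Every position carrying a two-character state (IUPAC code or slash code)
#' is split into its two alleles in all possible phasings; a phasing is kept
#' when each of the two resulting haploid vectors is compatible (shares an
#' allowed character at every position) with at least one haplotype
#' reference.
#'
#' @param states named character vector over the scheme positions containing
#'   at least one ambiguous cell.
#' @param scheme a `diagnostic_scheme`.
#' @return list of phasings, each a list with haploid vectors `h1`, `h2` and
#'   their best-matching reference letters `types`; empty list when no
#'   phasing is reference-compatible.
#' @examples
#' tab <- load_table2()
#' d <- decompose(state_vector(tab, "CA603"), load_scheme())
#' d[[1]]$types  # "A" "B"
#' @export
decompose <- function(states, scheme = load_scheme()) {
  n <- length(scheme$positions)
  if (!is.null(names(states))) {
    states <- states[match(as.character(scheme$positions), names(states))]
  }
  obs_sets <- lapply(states, char_set)
  amb <- which(lengths(obs_sets) == 2L)
  if (!length(amb)) {
    stop("decompose() requires at least one ambiguous (two-character) state",
         call. = FALSE)
  }
  base1 <- vapply(obs_sets, `[[`, character(1), 1L)
  k <- length(amb)
  pairs <- list()
  # fix the first ambiguous position's orientation: halves the enumeration
  # and makes each unordered pair appear once
  for (mask in 0:(2^(k - 1) - 1)) {
    swap <- c(FALSE, as.logical(bitwAnd(mask, 2^(seq_len(k - 1) - 1))))
    h1 <- base1; h2 <- base1
    for (j in seq_len(k)) {
      i <- amb[j]
      ab <- obs_sets[[i]]
      if (swap[j]) ab <- rev(ab)
      h1[i] <- ab[1]; h2[i] <- ab[2]
    }
    t1 <- compatible_references(h1, scheme)
    t2 <- compatible_references(h2, scheme)
    if (length(t1) && length(t2)) {
      pairs[[length(pairs) + 1L]] <- list(
        h1 = stats::setNames(h1, scheme$positions),
        h2 = stats::setNames(h2, scheme$positions),
        types = c(t1[1], t2[1])
      )
    }
  }
  pairs
}

# Reference letters whose allowed set contains the haploid state at every
# position.
compatible_references <- function(h, scheme) {
  Filter(function(tp) {
    all(vapply(seq_along(h), function(i) {
      h[i] %in% scheme$alleles[[i]][[tp]]
    }, logical(1)))
  }, TYPE_LETTERS)
}
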
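# Seeded synthetic-data generator.
#
# Emulates the statistical structure the typing pipeline assumes: a shared
# ITS-like template per run, the four haplotype types written at the 14
# diagnostic columns (type A carrying the one-base insertion at column 39;
# B, C and M deleted there), sparse background substitutions outside the
# scheme columns at a per-site rate calibrated so a 66-sample cohort shows
# on the order of dozens of variant columns, almost all singletons, and
# heterokaryons as position-wise IUPAC unions of two haplotypes.

#' Create a simulation specification
#'
#' @param seed integer seed; every artifact generated under a spec is a
#'   deterministic function of it.
#' @param length alignment length (default 560, covering coordinate 518
#'   with flanks).
#' @param background_prob per-site per-sample substitution probability for
#'   background noise (default 7e-4, giving roughly 40-60 variant columns,
#'   nearly all sample-private, in a 66-sample cohort).
#' @param protect_scheme if `TRUE` (default) background mutations never hit
#'   the diagnostic columns, so noiseless-scheme recovery is exact.
#' @param insertion if `TRUE` (default) type-A haplotypes carry the base at
#'   column 39; all other types are deleted there.
#' @param composition data frame with columns `genotype` (e.g. `"MM"`,
#'   `"AB"`, `"A"`), `haploid`, `count`; defaults to the 66-sample study
#'   composition with the single triple-heterokaryon slot generated as a
#'   pair (the heterokaryon generator is pairwise).
#' @param marker_groups named integer vector of group sizes for marker
#'   alignments.
#' @param marker_plant list of `list(column, group, char)` plants for
#'   [make_marker_alignment()].
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, length = 560L,
                            background_prob = 7e-04,
                            protect_scheme = TRUE, insertion = TRUE,
                            composition = default_composition(),
                            marker_groups = c(M = 6L, S = 10L),
                            marker_plant = list()) {
  if (background_prob < 0 || background_prob > 1) {
    stop("background_prob must lie in [0, 1]", call. = FALSE)
  }
  sc <- load_scheme()
  if (length < max(sc$positions)) {
    stop("length must cover the largest scheme coordinate (",
         max(sc$positions), ")", call. = FALSE)
  }
  if (any(composition$count < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 background_prob = background_prob,
                 protect_scheme = protect_scheme, insertion = insertion,
                 composition = composition, marker_groups = marker_groups,
                 marker_plant = marker_plant, scheme = sc),
            class = "simulation_spec")
}

#' Default 66-sample cohort composition
#'
#' Mirrors the published sample structure: 17 homoallelic M cultures, 8 AA,
#' 3 BB, 16 CC, 11 AB and 2 BC heterokaryons, and 9 haploid sequences
#' (4 A, 4 B, 1 C).
#'
#' @return data frame with columns `genotype`, `haploid`, `count`.
#' @export
default_composition <- function() {
  data.frame(
    genotype = c("MM", "AA", "A", "B", "BB", "C", "CC", "AB", "BC"),
    haploid = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    count = c(17L, 8L, 4L, 4L, 3L, 1L, 16L, 11L, 2L),
    stringsAsFactors = FALSE
  )
}

# deterministic sub-seed, kept within 32-bit integer range
derive_seed <- function(spec, ...) {
  parts <- c(spec$seed, ...)
  s <- 0
  for (p in parts) s <- (s * 131 + as.integer(p)) %% 2147483647
  as.integer(s)
}

random_template <- function(spec) {
  set.seed(derive_seed(spec, 1))
  sample(c("A", "C", "G", "T"), spec$length, replace = TRUE)
}

#' Generate one aligned haplotype sequence of a given ITS type
#'
#' The shared per-seed random template is overwritten with the type's
#' canonical alleles at the 14 diagnostic columns (a deleted state becomes
#' the alignment gap `-`); background substitutions are then applied at
#' `background_prob` per site, by default sparing the scheme columns.
#'
#' @param type_letter one of `"A"`, `"B"`, `"C"`, `"M"`.
#' @param spec a `simulation_spec`.
#' @param sample_index integer distinguishing background noise between
#'   samples of one cohort; the output is a deterministic function of
#'   `(seed, type_letter, sample_index)`.
#' @return aligned sequence string of length `spec$length` (with `-` at
#'   deleted columns), with attribute `type`.
#' @export
make_haplotype <- function(type_letter, spec, sample_index = 0L) {
  check_type_letters(type_letter)
  sc <- spec$scheme
  chars <- random_template(spec)
  ref <- reference_vector(sc, type_letter)
  chars[sc$positions] <- unname(ref)
  if (!spec$insertion && type_letter == "A") {
    chars[39L] <- "-"
  }
  if (spec$background_prob > 0) {
    set.seed(derive_seed(spec, 2, sample_index,
                         match(type_letter, TYPE_LETTERS)))
    eligible <- if (spec$protect_scheme) {
      setdiff(seq_len(spec$length), sc$positions)
    } else {
      seq_len(spec$length)
    }
    hit <- eligible[stats::runif(length(eligible)) < spec$background_prob]
    for (i in hit) {
      if (chars[i] == "-") next
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  structure(paste(chars, collapse = ""), type = type_letter)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Generate a heterokaryon consensus (and its superposed trace)
#'
#' Builds two haplotypes from the shared template and returns their
#' position-wise IUPAC union; when exactly one haplotype carries the
#' column-39 insertion, the corresponding offset-superposed trace is emitted
#' via [superpose()].
#'
#' @param x,y type letters of the two allele copies (equal letters give a
#'   homokaryon).
#' @param spec a `simulation_spec`.
#' @param sample_index see [make_haplotype()].
#' @return list with `states` (named state vector over the scheme
#'   positions), `consensus` (per-column code vector, slash codes included),
#'   `haplotypes`, `types` and `trace` (a `superposed_trace` or `NULL`).
#' @export
make_heterokaryon <- function(x, y, spec, sample_index = 0L) {
  h1 <- make_haplotype(x, spec, sample_index)
  h2 <- make_haplotype(y, spec, sample_index + 100000L)
  c1 <- strsplit(h1, "")[[1]]
  c2 <- strsplit(h2, "")[[1]]
  consensus <- c1
  for (i in which(c1 != c2)) consensus[i] <- iupac_union(c1[i], c2[i])
  sc <- spec$scheme
  states <- stats::setNames(consensus[sc$positions],
                            as.character(sc$positions))
  trace <- NULL
  g1 <- c1[39L] == "-"; g2 <- c2[39L] == "-"
  if (xor(g1, g2) && identical(c1[1:38], c2[1:38])) {
    # the peak-pair abstraction needs the shared prefix; background
    # substitutions upstream of the indel (rare under default noise)
    # suppress trace emission for that sample
    long <- if (g1) h2 else h1
    short <- if (g1) h1 else h2
    trace <- superpose(degap(long), degap(short), indel_pos = 39L)
  }
  list(states = states, consensus = consensus,
       haplotypes = c(h1, h2), types = c(x, y), trace = trace)
}

#' Simulate a cohort of samples in the state-matrix layout
#'
#' @param spec a `simulation_spec`; `spec$composition` sets the genotype
#'   counts and haploid flags.
#' @return data frame in the fixture layout ([load_table2()]) with the
#'   planted genotype in `printed_type`, ready for [classify_fixture()]. The
#'   full per-sample consensus alignment (per-column codes, IUPAC and slash
#'   codes included) is attached as attribute `alignment` (samples x
#'   columns), and the spec's seed as attribute `seed`.
#' @export
simulate_cohort <- function(spec) {
  sc <- spec$scheme
  rows <- list()
  aln <- matrix(NA_character_, sum(spec$composition$count), spec$length)
  idx <- 0L
  for (r in seq_len(nrow(spec$composition))) {
    gt <- spec$composition$genotype[r]
    haploid <- spec$composition$haploid[r]
    letters_gt <- strsplit(gt, "")[[1]]
    for (k in seq_len(spec$composition$count[r])) {
      idx <- idx + 1L
      if (haploid) {
        h <- make_haplotype(letters_gt[1], spec, idx)
        chars <- strsplit(h, "")[[1]]
        states <- stats::setNames(chars[sc$positions],
                                  as.character(sc$positions))
        aln[idx, ] <- chars
      } else {
        het <- make_heterokaryon(letters_gt[1],
                                 letters_gt[min(2L, length(letters_gt))],
                                 spec, idx)
        states <- het$states
        aln[idx, ] <- het$consensus
      }
      row <- data.frame(sample_id = sprintf("sim%03d", idx),
                        country = "simulated", species = "simulated",
                        printed_type = gt, stringsAsFactors = FALSE)
      for (p in as.character(sc$positions)) row[[p]] <- unname(states[p])
      row$accession <- sprintf("SIM%05d", idx)
      row$is_haploid <- haploid
      rows[[idx]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(aln) <- out$sample_id
  attr(out, "alignment") <- aln
  attr(out, "seed") <- spec$seed
  out
}

#' Tabulate background variant columns of a simulated cohort
#'
#' A background column is any alignment column outside the diagnostic
#' scheme; it is a variant column when at least one sample departs from the
#' column's modal state, and a singleton when exactly one does. Under the
#' default noise rate the large majority of variant columns are singletons,
#' mirroring the sparse sample-private polymorphism seen in real cohorts.
#'
#' @param cohort result of [simulate_cohort()].
#' @param scheme a `diagnostic_scheme`.
#' @return list with `n_variant` and `n_singleton` counts.
#' @export
background_variant_columns <- function(cohort, scheme = load_scheme()) {
  aln <- attr(cohort, "alignment")
  if (is.null(aln)) stop("cohort lacks an 'alignment' attribute", call. = FALSE)
  bg <- setdiff(seq_len(ncol(aln)), scheme$positions)
  n_variant <- 0L; n_singleton <- 0L
  for (j in bg) {
    tab <- sort(table(aln[, j]), decreasing = TRUE)
    if (length(tab) == 1L) next
    carriers <- sum(tab[-1])
    n_variant <- n_variant + 1L
    if (carriers == 1L) n_singleton <- n_singleton + 1L
  }
  list(n_variant = n_variant, n_singleton = n_singleton)
}

#' Generate a grouped alignment with planted group-exclusive columns
#'
#' All columns are group-blind copies of the per-seed template except the
#' planted columns, where every member of the plant's group carries the
#' planted character and everyone else keeps the template state.
#'
#' @param spec a `simulation_spec`; uses `marker_groups` (sizes) and
#'   `marker_plant` (list of `list(column, group, char)`).
#' @return list with `aln` (named sequences) and `groups` (named group
#'   vector).
#' @export
make_marker_alignment <- function(spec) {
  plants <- spec$marker_plant
  cols <- vapply(plants, `[[`, numeric(1), "column")
  if (anyDuplicated(cols)) {
    stop("simulation spec error: overlapping marker plants", call. = FALSE)
  }
  if (length(cols) && (any(cols < 1) || any(cols > spec$length))) {
    stop("simulation spec error: plant column outside alignment", call. = FALSE)
  }
  template <- random_template(spec)
  # keep exclusivity well-defined: the template must not already carry the
  # planted character at a planted column
  for (pl in plants) {
    if (template[pl$column] == pl$char) {
      template[pl$column] <- setdiff(c("A", "C", "G", "T"), pl$char)[1]
    }
  }
  ids <- character(0); grp <- character(0)
  for (g in names(spec$marker_groups)) {
    n <- spec$marker_groups[[g]]
    ids <- c(ids, sprintf("%s_%02d", g, seq_len(n)))
    grp <- c(grp, rep(g, n))
  }
  names(grp) <- ids
  seqs <- vapply(ids, function(id) {
    chars <- template
    for (pl in plants) {
      if (grp[[id]] == pl$group) chars[pl$column] <- pl$char
    }
    paste(chars, collapse = "")
  }, character(1))
  list(aln = seqs, groups = grp)
}
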
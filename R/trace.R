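# Offset-superposed Sanger traces.
#
# When one allele of a heterokaryon carries a one-base insertion, the two
# reads shift out of register downstream of the indel and the
# electropherogram shows systematic double peaks: at trace index t the peaks
# are the long haplotype's base at t and the short haplotype's base at t
# (i.e. the long haplotype's base at t+1 wherever the two alleles agree).
# Decoding such a trace recovers both haploid sequences without cloning.

#' Build the abstract peak-pair trace of two offset-superposed haplotypes
#'
#' @param hap_long gap-free sequence carrying the one-base insertion.
#' @param hap_short gap-free sequence, one base shorter; identical to
#'   `hap_long` upstream of the indel, substitutions allowed downstream.
#' @param indel_pos 1-based position (in `hap_long` coordinates) of the
#'   inserted base.
#' @return object of class `superposed_trace`: list with `prefix` (shared
#'   sequence before the indel), `pairs` (per trace index downstream, the
#'   unordered character pair; the final entry holds the long haplotype's
#'   last base alone), `indel_pos` and `offset` (always 1).
#' @export
superpose <- function(hap_long, hap_short, indel_pos) {
  if (grepl("-", hap_long, fixed = TRUE) || grepl("-", hap_short, fixed = TRUE)) {
    stop("superpose() requires gap-free sequences", call. = FALSE)
  }
  if (nchar(hap_long) - nchar(hap_short) != 1L) {
    stop("length difference between haplotypes must be exactly 1 base",
         call. = FALSE)
  }
  if (indel_pos < 1L || indel_pos > nchar(hap_long)) {
    stop("indel_pos outside hap_long", call. = FALSE)
  }
  hap_long <- as.vector(hap_long)
  hap_short <- as.vector(hap_short)
  prefix <- substr(hap_long, 1L, indel_pos - 1L)
  if (!identical(prefix, substr(hap_short, 1L, indel_pos - 1L))) {
    stop("haplotypes must agree on the prefix upstream of the indel",
         call. = FALSE)
  }
  lch <- strsplit(hap_long, "")[[1]]
  sch <- strsplit(hap_short, "")[[1]]
  L <- length(lch)
  pairs <- lapply(indel_pos:L, function(t) {
    if (t <= length(sch)) sort(unique(c(lch[t], sch[t]))) else lch[t]
  })
  structure(list(prefix = prefix, pairs = pairs,
                 indel_pos = as.integer(indel_pos), offset = 1L),
            class = "superposed_trace")
}

#' @export
print.superposed_trace <- function(x, ...) {
  cat(sprintf("Superposed trace: indel at %d, %d downstream peak positions\n",
              x$indel_pos, length(x$pairs)))
  invisible(x)
}

#' Deconvolve an offset-superposed trace into its two haplotypes
#'
#' Chain decoding seeded from the shared prefix: downstream of the indel the
#' short haplotype's base at trace index t must equal the long haplotype's
#' base at t+1 at every column where the two alleles agree, which is every
#' column except the diagnostic scheme positions (where substitutions
#' between allele types live). Residual local ambiguity (equal peak
#' characters, or branch points at scheme columns) is resolved by exhaustive
#' branch-and-bound under a branch cap, and the surviving candidates are
#' ranked by how well each haplotype's diagnostic states match a haplotype
#' reference.
#'
#' @param trace a `superposed_trace`.
#' @param scheme a `diagnostic_scheme`; its positions are interpreted in
#'   long-haplotype (alignment) coordinates.
#' @param branch_cap maximum number of explored branches before giving up on
#'   further alternatives (the candidates found so far are still returned).
#' @return list of candidates ranked by decreasing reference-compatibility
#'   score, each a list with `hap_long`, `hap_short`, `types` (best matching
#'   reference letters) and `score`. When no consistent decoding exists the
#'   list is empty with attribute `blocked_at` giving the first blocking
#'   trace index.
#' @export
deconvolve <- function(trace, scheme = load_scheme(), branch_cap = 1e4) {
  stopifnot(inherits(trace, "superposed_trace"))
  p <- trace$indel_pos
  L <- p - 1L + length(trace$pairs)
  scheme_cols <- scheme$positions
  prefix <- strsplit(trace$prefix, "")[[1]]

  results <- list()
  branches <- 0L
  deepest <- p
  capped <- FALSE
  pair_at <- function(t) trace$pairs[[t - p + 1L]]

  # depth-first over an explicit worklist: forced chain steps advance in a
  # tight loop, branch points (the seed position and scheme columns with two
  # distinct peaks) push the alternative continuation
  stack <- list(list(t = p, longs = character(0), shorts = character(0)))
  while (length(stack)) {
    st8 <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    t <- st8$t; longs <- st8$longs; shorts <- st8$shorts
    repeat {
      if (t > L) {
        results[[length(results) + 1L]] <- list(longs = longs, shorts = shorts)
        break
      }
      deepest <- max(deepest, t)
      pr <- pair_at(t)
      if (t == p || t %in% scheme_cols) {
        opts <- pr
      } else {
        forced <- shorts[length(shorts)]  # chain: long[t] == short[t-1]
        if (!(forced %in% pr)) break
        opts <- forced
      }
      branches <- branches + length(opts)
      if (branches > branch_cap) { capped <- TRUE; break }
      if (length(opts) == 2L) {
        alt <- opts[2]
        alt_short <- if (t < L) setdiff(pr, alt) else character(0)
        stack[[length(stack) + 1L]] <- list(
          t = t + 1L, longs = c(longs, alt), shorts = c(shorts, alt_short))
      }
      lt <- opts[1]
      longs <- c(longs, lt)
      if (t < L) {
        shorts <- c(shorts, if (length(pr) == 2L) setdiff(pr, lt) else pr)
      }
      t <- t + 1L
    }
  }
  if (capped) {
    warning("deconvolve(): branch cap reached; candidate list may be incomplete",
            call. = FALSE)
  }

  if (!length(results)) {
    out <- list()
    attr(out, "blocked_at") <- deepest
    return(out)
  }

  cands <- lapply(results, function(r) {
    long_chars <- c(prefix, r$longs)
    short_chars <- c(prefix, r$shorts)
    hl <- paste(long_chars, collapse = "")
    hs <- paste(short_chars, collapse = "")
    sc_l <- diag_states_long(long_chars, scheme_cols)
    sc_s <- diag_states_short(short_chars, scheme_cols, p)
    bl <- best_reference(sc_l, scheme)
    bs <- best_reference(sc_s, scheme)
    list(hap_long = hl, hap_short = hs,
         types = c(bl$type, bs$type), score = bl$score + bs$score)
  })
  cands[order(-vapply(cands, `[[`, numeric(1), "score"))]
}

diag_states_long <- function(chars, cols) {
  cols <- cols[cols <= length(chars)]
  stats::setNames(chars[cols], cols)
}

# the short haplotype lacks the inserted column p, so its base at alignment
# column c > p sits at sequence index c - 1; column p itself is a gap
diag_states_short <- function(chars, cols, p) {
  cols <- cols[cols <= length(chars) + 1L]
  vals <- vapply(cols, function(c) {
    if (c < p) chars[c] else if (c == p) "-" else chars[c - 1L]
  }, character(1))
  stats::setNames(vals, cols)
}

best_reference <- function(states, scheme) {
  pos <- as.integer(names(states))
  idx <- match(pos, scheme$positions)
  scores <- vapply(TYPE_LETTERS, function(tp) {
    sum(vapply(seq_along(idx), function(j) {
      states[j] %in% scheme$alleles[[idx[j]]][[tp]]
    }, logical(1)))
  }, numeric(1))
  list(type = names(which.max(scores)), score = max(scores))
}
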
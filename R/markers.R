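# Species-specific marker discovery in grouped alignments.
#
# A marker is an alignment column where the focal group carries a character
# (base or gap) absent from all other groups; it is reported in flank
# notation "xxxxxXxxxxx @ position": five flanking columns per side in
# lowercase (IUPAC-collapsed over within-focal variation, "[-]" for gap
# columns), the diagnostic character uppercase, then the 1-based column.

#' Discover group-diagnostic alignment columns
#'
#' @param aln named character vector of aligned sequences (equal lengths,
#'   `-` for gaps) or a list coercible to one.
#' @param groups named character vector mapping every sequence id to a group.
#' @param focal name of the focal group.
#' @param mode `"exclusive"` requires the focal group to be fixed for a
#'   character that no other sequence carries; `"informative"` relaxes
#'   fixation to `min_freq` within the focal group and tolerates up to
#'   `max_leakage` frequency of the character outside it (such markers are
#'   flagged, not exclusive).
#' @param min_freq minimum within-focal frequency of the diagnostic
#'   character in informative mode (default 1.0).
#' @param max_leakage maximum frequency of the diagnostic character among
#'   non-focal sequences in informative mode (default 0.0).
#' @param flank flank width in alignment columns per side (default 5);
#'   columns closer than `flank` to an alignment edge are not reported.
#' @return list of `marker_descriptor` objects sorted by column, each with
#'   `column`, `group`, `char`, `left`/`right` flank tokens, `exclusive`
#'   flag and formatted `notation`.
#' @examples
#' aln <- c(s1 = "ACGTACGTACGTA", s2 = "ACGTACGTACGTA", s3 = "ACGTATGTACGTA")
#' gr <- c(s1 = "x", s2 = "x", s3 = "y")
#' find_markers(aln, gr, focal = "y")[[1]]$column  # 6
#' @export
find_markers <- function(aln, groups, focal,
                         mode = c("exclusive", "informative"),
                         min_freq = 1, max_leakage = 0, flank = 5L) {
  mode <- match.arg(mode)
  aln <- unlist(aln)
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment error: sequences have unequal lengths", call. = FALSE)
  }
  if (!all(names(aln) %in% names(groups))) {
    stop("every sequence needs a group assignment", call. = FALSE)
  }
  grp <- groups[names(aln)]
  if (!focal %in% grp) stop("unknown or empty focal group: ", focal,
                            call. = FALSE)
  if (length(unique(grp)) < 2L) {
    stop("marker discovery needs at least one non-focal group", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  in_focal <- grp == focal
  ncols <- ncol(mat)
  out <- list()
  for (col in seq_len(ncols)) {
    if (col <= flank || col > ncols - flank) next
    fc <- mat[in_focal, col]
    oc <- mat[!in_focal, col]
    if (mode == "exclusive") {
      if (length(unique(fc)) != 1L) next  # focal group must be fixed
      ch <- unname(fc[1])
      if (ch %in% oc) next
      exclusive <- TRUE
    } else {
      tabf <- sort(table(fc), decreasing = TRUE)
      ch <- names(tabf)[1]
      if (tabf[1] / length(fc) < min_freq) next
      leak <- mean(oc == ch)
      if (leak > max_leakage) next
      exclusive <- leak == 0 && tabf[1] == length(fc) && !(ch %in% oc)
    }
    out[[length(out) + 1L]] <- marker_descriptor(mat, in_focal, col, focal,
                                                 ch, exclusive, flank)
  }
  out
}

marker_descriptor <- function(mat, in_focal, col, focal, ch, exclusive, flank) {
  flank_token <- function(j) {
    chars <- unique(mat[in_focal, j])
    if (any(chars == "-")) return("[-]")
    tolower(set_to_code_multi(chars))
  }
  left <- vapply((col - flank):(col - 1L), flank_token, character(1))
  right <- vapply((col + 1L):(col + flank), flank_token, character(1))
  m <- structure(list(column = col, group = focal, char = ch,
                      left = left, right = right, exclusive = exclusive),
                 class = "marker_descriptor")
  m$notation <- format_marker(m)
  m
}

# IUPAC code for up to four bases (flanks may vary more than two ways).
IUPAC_FULL <- c(A = "A", C = "C", G = "G", T = "T",
                AG = "R", CT = "Y", AC = "M", AT = "W", CG = "S", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

set_to_code_multi <- function(chars) {
  key <- paste(sort(unique(chars)), collapse = "")
  code <- IUPAC_FULL[[key]]
  if (is.null(code)) stop("cannot encode character set: ", key, call. = FALSE)
  code
}

#' Format a marker in flank notation
#'
#' @param m a `marker_descriptor`.
#' @return string such as `"tgtgaGagctt @ 172"`; a diagnostic gap renders
#'   as `"[-]"` in the uppercase slot.
#' @export
format_marker <- function(m) {
  mid <- if (m$char == "-") "[-]" else toupper(m$char)
  paste0(paste(m$left, collapse = ""), mid, paste(m$right, collapse = ""),
         " @ ", m$column)
}

#' @export
print.marker_descriptor <- function(x, ...) {
  cat(sprintf("%s marker for group '%s': %s\n",
              if (x$exclusive) "Exclusive" else "Informative",
              x$group, x$notation))
  invisible(x)
}

#' Parse a flank-notation marker string
#'
#' Inverse of [format_marker()] up to the descriptor fields it encodes.
#'
#' @param s notation string (`"xxxxxXxxxxx @ position"` with 5-column
#'   flanks and `"[-]"` for gap columns).
#' @param flank flank width used when formatting (default 5).
#' @return list with `left`, `char`, `right`, `column`.
#' @export
parse_marker <- function(s, flank = 5L) {
  parts <- strsplit(s, " @ ", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed marker string", call. = FALSE)
  column <- as.integer(parts[2])
  body <- parts[1]
  tokens <- character(0)
  i <- 1L
  while (i <= nchar(body)) {
    if (substr(body, i, i + 2L) == "[-]") {
      tokens <- c(tokens, "[-]")
      i <- i + 3L
    } else {
      tokens <- c(tokens, substr(body, i, i))
      i <- i + 1L
    }
  }
  if (length(tokens) != 2L * flank + 1L) {
    stop("malformed marker string: expected ", 2L * flank + 1L, " tokens",
         call. = FALSE)
  }
  list(left = tokens[seq_len(flank)],
       char = tokens[flank + 1L],
       right = tokens[flank + 1L + seq_len(flank)],
       column = column)
}
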
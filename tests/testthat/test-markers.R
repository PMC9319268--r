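test_that("planted exclusive columns are found exactly, k = 0..10", {
  for (k in 0:10) {
    for (s in c(3, 14)) {
      set.seed(s * 100 + k)
      cols <- sample(setdiff(20:500, the_scheme$positions), k)
      plants <- lapply(cols, function(cc) {
        list(column = cc, group = "M", char = sample(c("A", "C", "G", "T"), 1))
      })
      spec <- simulation_spec(seed = s, marker_plant = plants)
      ma <- make_marker_alignment(spec)
      mk <- find_markers(ma$aln, ma$groups, focal = "M")
      expect_identical(vapply(mk, `[[`, numeric(1), "column"),
                       as.numeric(sort(cols)))
      expect_identical(sort(vapply(mk, `[[`, numeric(1), "column")),
                       sort(as.numeric(oracle_marker_columns(ma$aln, ma$groups, "M"))))
    }
  }
})

test_that("marker discovery ignores sequence order within groups", {
  spec <- simulation_spec(seed = 5, marker_plant = list(
    list(column = 100, group = "M", char = "A"),
    list(column = 300, group = "M", char = "-")))
  ma <- make_marker_alignment(spec)
  base <- find_markers(ma$aln, ma$groups, focal = "M")
  set.seed(1)
  perm <- sample(names(ma$aln))
  shuffled <- find_markers(ma$aln[perm], ma$groups, focal = "M")
  expect_identical(vapply(base, `[[`, character(1), "notation"),
                   vapply(shuffled, `[[`, character(1), "notation"))
})

test_that("a focal group identical to the others yields no markers", {
  spec <- simulation_spec(seed = 9)  # nothing planted
  ma <- make_marker_alignment(spec)
  expect_length(find_markers(ma$aln, ma$groups, focal = "M"), 0L)
})

test_that("the reference-haplotype toy recovers the five M-characteristic columns", {
  sc <- the_scheme
  refs <- vapply(c("A", "B", "C", "M"), function(tp) {
    chars <- rep("G", 560)
    chars[sc$positions] <- reference_vector(sc, tp)
    paste(chars, collapse = "")
  }, character(1))
  gr <- stats::setNames(c("S", "S", "S", "M"), names(refs))
  mk <- find_markers(refs, gr, focal = "M")
  expect_identical(vapply(mk, `[[`, numeric(1), "column"),
                   c(166, 196, 210, 494, 518))
  expect_true(all(vapply(mk, `[[`, logical(1), "exclusive")))
})

test_that("flank notation renders and parses per the grammar", {
  # plain marker: flanks tgtga / agctt around a diagnostic G at column 172
  seqs <- vapply(1:4, function(i) {
    chars <- rep("C", 400)
    chars[167:177] <- c("T", "G", "T", "G", "A",
                        if (i <= 2) "G" else "A",
                        "A", "G", "C", "T", "T")
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- c("f1", "f2", "o1", "o2")
  gr <- stats::setNames(c("X", "X", "Y", "Y"), names(seqs))
  mk <- find_markers(seqs, gr, focal = "X")
  expect_identical(mk[[1]]$notation, "tgtgaGagctt @ 172")
  p <- parse_marker(mk[[1]]$notation)
  expect_identical(p$column, 172L)
  expect_identical(p$char, "G")
  expect_identical(p$left, c("t", "g", "t", "g", "a"))

  # flanks with a gap column and within-focal polymorphism collapse to
  # "[-]" and lowercase IUPAC codes
  mk2_seqs <- vapply(1:4, function(i) {
    chars <- rep("A", 60)
    chars[23:33] <- c("C", "T", "T", "-", "T",
                      if (i <= 2) "G" else "C",
                      if (i == 1) "C" else "T", "G", "G",
                      if (i == 1) "G" else "T", "G")
    paste(chars, collapse = "")
  }, character(1))
  names(mk2_seqs) <- c("f1", "f2", "o1", "o2")
  mk2 <- find_markers(mk2_seqs, gr, focal = "X")
  expect_identical(mk2[[1]]$notation, "ctt[-]tGyggkg @ 28")
  rt <- parse_marker(mk2[[1]]$notation)
  expect_identical(rt$left, c("c", "t", "t", "[-]", "t"))
  expect_identical(rt$right, c("y", "g", "g", "k", "g"))

  # a diagnostic gap renders as "[-]" in the uppercase slot
  gap_seqs <- c(f1 = paste0(strrep("A", 10), "-", strrep("A", 10)),
                f2 = paste0(strrep("A", 10), "-", strrep("A", 10)),
                o1 = strrep("A", 21), o2 = strrep("A", 21))
  mk3 <- find_markers(gap_seqs, gr, focal = "X")
  expect_identical(mk3[[1]]$notation, "aaaaa[-]aaaaa @ 11")
  expect_identical(parse_marker(mk3[[1]]$notation)$char, "[-]")
})

test_that("exclusive mode skips focal-polymorphic columns; informative mode relaxes", {
  seqs <- c(f1 = "AAAAAAGAAAAAA", f2 = "AAAAAACAAAAAA",
            o1 = "AAAAAATAAAAAA", o2 = "AAAAAATAAAAAA")
  gr <- stats::setNames(c("X", "X", "Y", "Y"), names(seqs))
  expect_length(find_markers(seqs, gr, focal = "X"), 0L)
  mk <- find_markers(seqs, gr, focal = "X", mode = "informative",
                     min_freq = 0.5)
  expect_identical(vapply(mk, `[[`, numeric(1), "column"), 7)
  expect_false(mk[[1]]$exclusive)
})

test_that("alignment and group errors are reported", {
  seqs <- c(a = "ACGT", b = "ACG")
  gr <- c(a = "X", b = "Y")
  expect_error(find_markers(seqs, gr, focal = "X"), "unequal lengths")
  seqs2 <- c(a = "ACGT", b = "ACGT")
  expect_error(find_markers(seqs2, gr, focal = "Z"), "focal group")
  expect_error(find_markers(seqs2, c(a = "X", b = "X"), focal = "X"),
               "non-focal")
})
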
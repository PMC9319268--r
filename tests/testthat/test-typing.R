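test_that("reference and fixture vectors classify to their published calls", {
  sc <- the_scheme
  # a homoallelic M culture
  ie965 <- state_vector(the_table, "IE965", sc)
  expect_identical(classify(ie965, sc)$label, "MM")
  # the offset-deconvolved Mexican heterokaryon
  ca603 <- state_vector(the_table, "CA603", sc)
  call <- classify(ca603, sc)
  expect_identical(call$label, "AB")
  expect_identical(call$components, c("A", "B"))
  # a reference vector classifies to itself
  expect_identical(classify(reference_vector(sc, "B"), sc)$label, "BB")
  expect_identical(classify(reference_vector(sc, "M"), sc, haploid = TRUE)$label,
                   "M")
  # unphased partial-A heterokaryon
  z <- state_vector(the_table, "ZRL2012722", sc)
  expect_identical(classify(z, sc, phased = FALSE)$label, "(aB)")
})

test_that("the union of any two references classifies to that pair, uppercase", {
  sc <- the_scheme
  pairs <- utils::combn(c("A", "B", "C", "M"), 2, simplify = FALSE)
  for (p in pairs) {
    u <- mapply(iupac_union, reference_vector(sc, p[1]),
                reference_vector(sc, p[2]))
    call <- classify(stats::setNames(u, sc$positions), sc)
    expect_identical(call$components, p)
    expect_false(any(call$lowercase))
    expect_identical(call$label, paste(p, collapse = ""))
  }
})

test_that("the phased flag only toggles parentheses", {
  sc <- the_scheme
  z <- state_vector(the_table, "ZRL2012722", sc)
  a <- classify(z, sc, phased = TRUE)
  b <- classify(z, sc, phased = FALSE)
  expect_identical(a$components, b$components)
  expect_identical(a$lowercase, b$lowercase)
  expect_identical(a$score, b$score)
  expect_identical(paste0("(", a$label, ")"), b$label)
})

test_that("degenerate inputs give parse errors or an untypable verdict", {
  sc <- the_scheme
  expect_error(classify(rep("A", 5), sc), "parse error")
  expect_error(classify(stats::setNames(rep("A", 14), 1:14), sc), "parse error")
  junk <- stats::setNames(c("C", "T", "T", "G", "G", "T", "T", "G", "T",
                            "T", "G", "G", "G", "C"),
                          sc$positions)
  call <- classify(junk, sc)
  expect_true(call$untypable)
  expect_identical(call$label, "untypable")
  expect_false(classify(junk, sc, floor = 0)$untypable)
})

test_that("fixture classification reproduces the published genotype table", {
  rep <- classify_fixture(the_table, the_scheme)
  expect_identical(nrow(rep), 66L)
  # headline counts
  expect_identical(sum(rep$computed_type == "MM"), 17L)
  hap <- rep[the_table$is_haploid, ]
  expect_identical(hap$computed_type, hap$printed_type)
  expect_true(all(nchar(hap$computed_type) == 1L))
  # component sets match everywhere except the two set-theoretically
  # ambiguous rows, whose printed call is co-optimal
  mism <- rep$sample_id[!rep$component_match]
  expect_identical(sort(mism), c("CA487", "ZRL20140275"))
  for (i in seq_len(nrow(rep))) {
    printed <- printed_components(rep$printed_type[i])
    seen <- c(rep$components[i], strsplit(rep$co_optimal[i], ",")[[1]])
    expect_true(paste(printed, collapse = "") %in% seen)
  }
  # full label matches except the four documented discrepancies
  full_mism <- rep$sample_id[!rep$match]
  expect_identical(sort(full_mism),
                   c("CA487", "GY129365", "LD201903", "ZRL20140275"))
  expect_identical(rep$computed_type[rep$sample_id == "LD201903"], "aB")
  expect_identical(rep$computed_type[rep$sample_id == "GY129365"], "(BC)")
})

test_that("decompose splits heterokaryon vectors into the published haploids", {
  sc <- the_scheme
  ca603 <- state_vector(the_table, "CA603", sc)
  d <- decompose(ca603, sc)
  expect_length(d, 1L)
  expect_setequal(d[[1]]$types, c("A", "B"))
  haps <- list(d[[1]]$h1, d[[1]]$h2)
  a_vec <- state_vector(the_table, "CA603A", sc)
  b_vec <- state_vector(the_table, "CA603B", sc)
  expect_true(any(vapply(haps, identical, logical(1), a_vec)))
  expect_true(any(vapply(haps, identical, logical(1), b_vec)))

  wc837 <- state_vector(the_table, "WC837", sc)
  d2 <- decompose(wc837, sc)
  expect_length(d2, 1L)
  got <- list(d2[[1]]$h1, d2[[1]]$h2)
  expect_true(any(vapply(got, identical, logical(1),
                         state_vector(the_table, "WC837-S43", sc))))
  expect_true(any(vapply(got, identical, logical(1),
                         state_vector(the_table, "WC837-S04", sc))))
  expect_error(decompose(reference_vector(sc, "B"), sc), "ambiguous")
})

test_that("decompose result agrees with brute-force split enumeration", {
  # independent oracle: enumerate every split of WC837's ambiguous cells and
  # keep those whose halves each sit inside a reference profile
  sc <- the_scheme
  states <- state_vector(the_table, "WC837", sc)
  sets <- lapply(states, char_set)
  amb <- which(lengths(sets) == 2L)
  ok_pairs <- 0L
  for (mask in 0:(2^length(amb) - 1)) {
    h1 <- vapply(sets, `[[`, character(1), 1L)
    h2 <- h1
    bits <- as.logical(bitwAnd(mask, 2^(seq_along(amb) - 1)))
    for (j in seq_along(amb)) {
      pair <- sets[[amb[j]]]
      if (bits[j]) pair <- rev(pair)
      h1[amb[j]] <- pair[1]; h2[amb[j]] <- pair[2]
    }
    fits <- function(h) {
      any(vapply(names(oracle_refs), function(tp) {
        all(vapply(seq_along(h), function(i) {
          h[i] %in% oracle_refs[[tp]][[i]]
        }, logical(1)))
      }, logical(1)))
    }
    if (fits(h1) && fits(h2)) ok_pairs <- ok_pairs + 1L
  }
  # ordered enumeration counts each unordered pair twice
  expect_identical(length(decompose(states, sc)), ok_pairs %/% 2L)
})

test_that("decompose inverts iupac_union on reference pairs", {
  sc <- the_scheme
  pairs <- utils::combn(c("A", "B", "C", "M"), 2, simplify = FALSE)
  for (p in pairs) {
    v1 <- reference_vector(sc, p[1])
    v2 <- reference_vector(sc, p[2])
    u <- stats::setNames(mapply(iupac_union, v1, v2), sc$positions)
    d <- decompose(u, sc)
    recovered <- lapply(d, function(x) list(x$h1, x$h2))
    hit <- any(vapply(recovered, function(hh) {
      (identical(hh[[1]], v1) && identical(hh[[2]], v2)) ||
        (identical(hh[[1]], v2) && identical(hh[[2]], v1))
    }, logical(1)))
    expect_true(hit, info = paste(p, collapse = ""))
  }
})
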
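# Shared fixtures and independent oracles for the suite.

the_scheme <- load_scheme()
the_table <- load_table2()

# Independent transcription of the four reference profiles used as a
# brute-force oracle for the scheme arithmetic (kept deliberately separate
# from the packaged scheme TSV).
oracle_refs <- list(
  A = list(`39` = "T", `122` = "A", `130` = "A", `145` = "G", `146` = "A",
           `166` = "A", `196` = "A", `200` = "T", `210` = "A", `269` = "G",
           `466` = "A", `475` = "T", `494` = c("C", "T"), `518` = "T"),
  B = list(`39` = "-", `122` = "G", `130` = "G", `145` = "A", `146` = "T",
           `166` = "A", `196` = "A", `200` = "C", `210` = "A", `269` = "G",
           `466` = "A", `475` = "T", `494` = c("C", "T"), `518` = "T"),
  C = list(`39` = "-", `122` = "G", `130` = "G", `145` = "A", `146` = "T",
           `166` = "A", `196` = "A", `200` = "C", `210` = "A", `269` = "A",
           `466` = "C", `475` = "-", `494` = c("C", "T"), `518` = "T"),
  M = list(`39` = "-", `122` = "G", `130` = "A", `145` = "A", `146` = "T",
           `166` = "G", `196` = "G", `200` = "C", `210` = "G", `269` = "G",
           `466` = "A", `475` = "T", `494` = "A", `518` = "G")
)
oracle_positions <- as.integer(names(oracle_refs$A))

# Brute-force scan: positions where the focal profile shares no state with
# the union of the others.
oracle_unique_states <- function(focal, others) {
  keep <- vapply(seq_along(oracle_positions), function(i) {
    pool <- unique(unlist(lapply(oracle_refs[others], `[[`, i)))
    !any(oracle_refs[[focal]][[i]] %in% pool)
  }, logical(1))
  oracle_positions[keep]
}

# Brute-force column scan for exclusive markers: the focal rows are fixed
# for a character absent from every other row.
oracle_marker_columns <- function(aln, groups, focal) {
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  inf <- groups[names(aln)] == focal
  which(vapply(seq_len(ncol(mat)), function(j) {
    f <- unique(mat[inf, j])
    length(f) == 1L && !(f %in% mat[!inf, j])
  }, logical(1)))
}

# Random ultrametric tree for recovery tests: returns its cophenetic matrix.
random_ultrametric_matrix <- function(n, seed) {
  set.seed(seed)
  labs <- sprintf("t%02d", seq_len(n))
  clusters <- as.list(labs)
  h <- 0
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    h <- h + stats::runif(1, 0.1, 1)
    pick <- sample(length(clusters), 2L)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    m[a, b] <- 2 * h
    m[b, a] <- 2 * h
    clusters <- c(clusters[-pick], list(c(a, b)))
  }
  m
}

# p-distance-style random symmetric matrix without ties
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  labs <- sprintf("t%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  vals <- sample(seq(0.01, 0.99, by = 0.01), n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m + t(m)
}
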
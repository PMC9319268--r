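---
title: "Diagnostic-position ITS genotyping in the Agaricus subrufescens complex"
author: "agaritype authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic-position ITS genotyping in the Agaricus subrufescens complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agaritype)
```

## The problem

*Agaricus subrufescens* (the almond mushroom) harbours unusually high
intraspecific ITS variability: cultures carry one, two or rarely three
distinct ITS allele copies, classified into haplotype types by the states of
a small set of diagnostic alignment positions. Types A and B differ at six
positions (39, 122, 130, 145, 146, 200), type C differs from both at three
more (269, 466, 475), and a fourth type, M, private to the cryptic sister
species *A. macrochlamys*, is distinguished by five positions (166, 196,
210, 494, 518) at which its states occur in no other type. Together these
14 columns form the typing scheme this package implements.

A heterokaryotic culture sequenced directly by the Sanger method shows both
allele copies at once: positions where the copies differ are read as
two-fold IUPAC ambiguity codes, and a base opposite a gap is recorded here
as a slash code (e.g. `T/-`), since no IUPAC symbol covers base-versus-gap.
Genotype labels follow the field's conventions: doubled letters for
homoallelic cultures (`MM`), concatenated letters for heteroallelic ones
(`AB`), lowercase for a component whose characteristic states are not all
present (`aB`), and parentheses when the haploid phase is inferred rather
than experimentally resolved (`(aB)`).

## The typing model

```{r}
scheme <- load_scheme()
scheme
```

`classify()` enumerates every candidate component set of one to three types
from `{A, B, C, M}`. The expected observation of a candidate at a position
is the union of its components' allowed characters — exactly what a
superposed Sanger read of those alleles would display — and an observed
state is *compatible* when its character set is contained in that union.
Candidates are ranked by four criteria, in order:

1. **compatibility score** — the number of compatible positions (of 14);
2. **specificity** — the number of positions where the observed set equals
   the expected set exactly;
3. **parsimony** — fewer components;
4. lexicographic label order.

The specificity criterion is a deliberate design choice. Type B carries no
private allele: at every diagnostic position its state also occurs in A or
in C, so the expected set of `{A, C}` contains the expected set of
`{A, B}`, of `{B, C}` and of `{A, B, C}` column for column. Pure
set-compatibility therefore cannot separate these candidates, while the
exact-match count can: a true `{B, C}` culture shows single bases at the six
A-characteristic positions, which the `{B, C}` expectation predicts exactly
and the `{A, C}` expectation only loosely. Two genotypes remain genuinely
indistinguishable from consensus states alone — a triple `ABC` heterokaryon
(its position-wise union equals that of `A` + `C`) and a `(bC)` culture
whose gap cells are read as missing data — and for these the printed call is
reported among the co-optimal alternatives rather than forced.

Case is assigned from the scheme's characteristic map: a component is
lowercased when at least one of the positions characteristic of it shows no
support for its allele. B, the reference backbone, is bolded nowhere in the
published table and accordingly has no characteristic positions, so it is
never lowercased.

```{r}
tab <- load_table2()
classify(state_vector(tab, "CA603"), scheme)
classify(state_vector(tab, "ZRL2012722"), scheme, phased = FALSE)
```

Two tunable parameters matter in practice:

* `gap_policy` (default `"missing"`): several published heterokaryon rows
  show a bare `-` at position 475 even though their types predict a base
  there — most plausibly truncated submissions rather than real deletions.
  Under `"missing"` such a cell is treated as absent data for any candidate
  whose expectation has no gap; `"deletion"` treats every `-` as a fifth
  character state.
* `floor` (default 10 of 14): when no candidate reaches the floor the
  sample is reported `untypable` instead of being assigned the least bad
  call; sparse background polymorphism can corrupt isolated diagnostic
  cells, and a hard failure is more honest than a confident wrong label.

Running the classifier over the packaged 66-sample state matrix reproduces
the published genotype labels for 62 rows in full and the component sets for
64; the four residuals are cases where the published label encodes
information that is not present in the consensus states (experimentally
phased clones, or characteristic alleles the strict lowercase rule cannot
see), and they are asserted verbatim in the test suite rather than patched.

```{r}
rep <- classify_fixture(tab, scheme)
table(computed = rep$computed_type, match = rep$match)
```

## Haplotype decomposition and trace deconvolution

`decompose()` enumerates all phasings of the ambiguous cells of a consensus
vector and keeps those whose two haploid vectors each fit a haplotype
reference; for the published AB cultures exactly one phasing survives and
reproduces the deposited haploid rows.

`superpose()`/`deconvolve()` model the third published route to haploid
sequences: when one allele carries the one-base insertion at column 39, the
two reads shift out of register and every downstream trace position shows
the pair {long[t], short[t]}. Because the alleles agree everywhere outside
the diagnostic columns, the short read's base at index t must equal the long
read's base at t+1 at every non-scheme column; `deconvolve()` chains this
constraint from the shared prefix, branches only at the seed position and at
scheme columns, bounds the search (default 10^4 branches — correctness over
speed at desk scale), and ranks surviving candidate pairs by their
diagnostic-state fit to the references. On noiseless simulated A/B pairs the
round-trip recovery is exact in 200/200 seeded runs of the test suite.

## Marker discovery

`find_markers()` scans a grouped alignment for columns where the focal
group carries a state (gap included) found in no other sequence. Columns
where the focal group is itself polymorphic are excluded in exclusive mode,
matching the intended use: a marker should be fixed within the species it
diagnoses. `informative` mode relaxes fixation (`min_freq`) and tolerates
bounded leakage (`max_leakage`), flagging such markers as non-exclusive.
Markers are rendered in the field's flank notation — five alignment columns
per side, lowercase, IUPAC-collapsed over within-group variation, `[-]` for
gap columns, the diagnostic character uppercase:

```{r}
refs <- vapply(c("A", "B", "C", "M"), function(tp) {
  chars <- rep("G", 560)
  chars[scheme$positions] <- reference_vector(scheme, tp)
  paste(chars, collapse = "")
}, character(1))
groups <- setNames(c("S", "S", "S", "M"), names(refs))
for (m in find_markers(refs, groups, focal = "M")) print(m)
```

The flank width of 5 matches the published notation and is configurable.
Reproducing the exact published marker strings for *A. macrochlamys* would
require the full 104-sequence section-wide alignment, which lives in GenBank
and is deliberately outside this package's desk-scale scope; the scanner
itself is exercised on planted synthetic alignments instead.

## Distances and UPGMA

`state_distance()` scores mean per-position mismatch with two ambiguity
policies: `strict` (any set inequality counts 1) and `partial` (one minus
the Jaccard overlap of the two character sets, so `R` vs `A` costs 1/2).
Its default `gap_policy = "deletion"` scores the gap as a fifth state,
which keeps the reference arithmetic transparent (A vs B = 6/14). For the
packaged tree the package uses `strict` with `gap_policy = "missing"`
(gap cells dropped pairwise from the denominator) — the analogue of the
pairwise-deletion treatment that mainstream distance software applies by
default, and the configuration under which the 66-sample tree cleanly
isolates the M lineage. With gaps scored as characters instead, the B/C
block's mean distance to the M block (0.576) falls marginally below its
distance to the A block (0.587) and the clean two-group cut disappears — a
good illustration of how sensitive average-linkage trees are to gap
handling at this scale.

`upgma()` is implemented from first principles because its tie rule is part
of the package's contract: merge ties are broken by the lexicographically
smallest pair of cluster labels (a cluster is labelled by its smallest
leaf), which makes trees reproducible across platforms. Heights are half
the merge distance, so trees are ultrametric by construction; the suite
cross-checks against average-linkage `hclust()` on tie-free matrices and
verifies exact recovery of generating ultrametric matrices.
`group_partition_check()` scans every horizontal cut for the smallest
number of clusters that never mixes two groups:

```{r}
d <- state_distance_matrix(tab, scheme, ambiguity = "strict",
                           gap_policy = "missing")
tree <- upgma(d)
groups <- setNames(ifelse(tab$species == "A. macrochlamys", "M", "S"),
                   tab$sample_id)
group_partition_check(tree, groups)
```

## The synthetic generator

`simulation_spec()` fixes the study conditions the tests run under:

* alignment length 560 (covers coordinate 518 with flanks);
* the 66-sample composition of the published table — 17 MM, 8 AA, 3 BB,
  16 CC, 11 AB and 2 BC cultures plus 9 haploid sequences — with the single
  published triple-heterokaryon slot generated as a pair, because the
  generator's heterokaryon operation is deliberately pairwise;
* background substitution probability 7e-4 per site per haplotype, chosen
  so a cohort shows roughly 40–60 background variant columns, almost all
  carried by a single sample, mirroring the sparse sample-private
  polymorphism reported for the real alignment;
* background mutations never hit the diagnostic columns by default
  (toggleable via `protect_scheme`), so noiseless-scheme recovery is exact
  and the noisy mode exercises the untypable floor instead.

Everything is a deterministic function of one integer seed. What the
generator does *not* emulate: ITS secondary structure, chromatogram signal
intensities, PCR chimeras, alignment error, or indels other than the single
diagnostic insertion. Passing the recovery properties therefore shows that
the algorithms are correct under the model's assumptions, not that real
trace files of arbitrary quality will decode cleanly.

```{r}
spec <- simulation_spec(seed = 1)
coh <- simulate_cohort(spec)
mean(classify_fixture(coh, scheme)$match)
background_variant_columns(coh, scheme)
```

## Numerical and degenerate-input choices

* Classification ties that survive all four criteria are resolved
  lexicographically and all score-tied candidates are reported in
  `co_optimal`; nothing is silently dropped.
* Position 494 is modelled as allowed set {C, T} within A, B and C (the
  published rows show C, T and Y there) with only M characteristic (state
  A); this makes every published row classifiable without special cases.
* Distance computation refuses vectors with zero scorable positions rather
  than returning 0/0.
* `deconvolve()` on an undecodable trace returns an empty candidate list
  carrying the first blocking index, not an error, so callers can
  diagnose which peak pair breaks the chain.
* All user-facing coordinates are 1-based alignment columns; sequences are
  plain upper-case strings with `-` gaps, U mapped to T on input.

## Problem sizes in the test suite

The suite regenerates all stochastic fixtures at run time: 200 seeded
deconvolution round-trips, 100 seeded noiseless cohorts of 66 samples,
55 planted-marker scans (k = 0..10), and 10-replicate tree property checks
— sizes chosen so the whole suite stays comfortably interactive while the
binomial uncertainty of each property check remains far below its asserted
bound.

## Known limitations

* The scheme coordinates are opaque labels of the 66-sequence study
  alignment; no reconciliation with other alignments' coordinates (where,
  e.g., the column printed as 166 appears as 172) is attempted.
* Genotypes whose expected unions coincide (`ABC` vs `AC`; `(bC)` vs `B`
  under missing-data gaps) cannot be separated from consensus states alone;
  the package reports co-optimal calls instead of guessing.
* Chromatogram files (AB1/SCF) are not parsed; traces enter as the
  abstract peak-pair representation or are simulated.
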
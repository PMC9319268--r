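# agaritype

Diagnostic-position ITS genotyping for the *Agaricus subrufescens* species
complex (*Agaricus* sect. *Arvenses*).

## What it does and for whom

*A. subrufescens*, the cultivated almond mushroom, shows unusually high
intraspecific ITS variability: cultures carry one to three distinct ITS
allele copies, and the allele types — A, B, C, and the type M private to the
cryptic sister species *A. macrochlamys* — are told apart by the characters
at 14 diagnostic alignment positions. This package is for mycologists and
molecular ecologists who need to genotype such cultures from Sanger
consensus sequences, resolve heterokaryons into haploid sequences, screen
alignments for species-diagnostic characters, and reproduce the
cluster-level separation of the M lineage, all without downloading external
sequence data.

The core model: a culture's genotype is a multiset of 1–3 allele types. The
expected observation of a candidate set *S* at diagnostic position *p* is
the union of the components' allowed characters there (a superposed Sanger
read shows both alleles at once: two bases become the IUPAC two-fold code,
base-versus-gap becomes a slash code such as `T/-`). An observed state is
compatible with *S* when its character set is contained in that union, and
candidates are ranked by compatibility score, then specificity (exact
set matches), then parsimony, then lexicographic order. Labels follow the
field's conventions: `MM` (homoallelic), `AB` (heteroallelic), `aB`
(partial characteristic support), `(aB)` (phase inferred, not resolved).

The package covers, as testable modules:

* **scheme** — the 14-position typing scheme, reference profiles, and a
  packaged machine-readable transcription of the published 66-sample state
  matrix (`load_scheme()`, `load_table2()`, `informative_positions()`,
  `unique_states()`, `count_type_differences()`);
* **typing** — classification, report generation, and haplotype
  decomposition of IUPAC-coded heterokaryons (`classify()`,
  `classify_fixture()`, `decompose()`);
* **traces** — deconvolution of electropherograms in which a one-base
  length polymorphism superposes the two reads with an offset
  (`superpose()`, `deconvolve()`);
* **markers** — species-diagnostic column discovery in grouped alignments
  with the `xxxxxXxxxxx @ position` flank notation (`find_markers()`,
  `format_marker()`, `parse_marker()`);
* **clustering** — ambiguity-aware diagnostic-state distances, a
  deterministic UPGMA with Newick output, and the minimal-pure-cut check
  (`state_distance()`, `upgma()`, `to_newick()`,
  `group_partition_check()`);
* **synthetic data** — a seeded generator of haplotypes, heterokaryon
  consensus vectors, offset traces, cohorts, and marker alignments
  (`simulation_spec()`, `simulate_cohort()`, `make_marker_alignment()`).

## Worked example

```r
library(agaritype)
scheme <- load_scheme()
tab <- load_table2()
scheme
#> Diagnostic ITS typing scheme: 14 positions
#>   positions: 39 122 130 145 146 166 196 200 210 269 466 475 494 518
#>   characteristic of A: 39 122 130 145 146 200
#>   characteristic of C: 269 466 475
#>   characteristic of M: 166 196 210 494 518

classify(state_vector(tab, "CA603"), scheme)
#> ITS type call: AB (score 14/14, exact 13)
#>   co-optimal component sets: AC, ABC, ABM, ACM
```

CA603, a Mexican culture, is called `AB`: every one of the 14 observed
states is compatible with an A+B allele pair, 13 of them match the A+B
expectation exactly (position 494 allows C or T within both types), and the
score-tied alternatives are listed rather than hidden. Decomposing its
ambiguity codes recovers the two haploid sequences that were deposited
separately:

```r
decompose(state_vector(tab, "CA603"), scheme)[[1]]$types
#> [1] "B" "A"
```

Classifying the whole packaged state matrix and clustering it:

```r
rep <- classify_fixture(tab, scheme)
sum(rep$computed_type == "MM")
#> [1] 17

d <- state_distance_matrix(tab, scheme, ambiguity = "strict",
                           gap_policy = "missing")
groups <- setNames(ifelse(tab$species == "A. macrochlamys", "M", "S"),
                   tab$sample_id)
group_partition_check(upgma(d), groups)
#> [1] 2
```

Seventeen cultures are homoallelic for the M type, and the UPGMA tree over
strict diagnostic-state distances (gaps treated as missing data) splits
into exactly two groups — the M lineage versus all *A. subrufescens*
types — at its minimal group-pure horizontal cut.

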
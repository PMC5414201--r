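# tabooscan

Exhaustive, alignment-free mining of **k-disjoint** DNA sequences: every
length-*W* window of a query set *A* whose Hamming distance to **every**
length-*W* window of a reference ("taboo") set *B* — both strands — exceeds
*k*. The complement, windows within *k* mismatches of some taboo window, is
the *k*-intersection.

Plain *k*-mer uniqueness (the *k* = 0 case) is not stringent enough when an
assay tolerates a mismatch: padlock probes circularize on near-matches,
CRISPR nucleases cut near-off-targets. tabooscan answers the stricter
question — *no* taboo window within *k* mismatches — exhaustively, which is
what probe designers, guide designers, and anyone hunting substitutions,
inversions or foreign insertions against a reference actually need.

## Method

Words are compared through a block encoding ("N-coding"): every length-*N*
word over the ordered alphabet A < C < G < N < T (N is the canonical unknown
base) gets its lexicographic rank, so a *W*-window becomes a vector of *W/N*
integer codes (*N* ∈ {3,4,5}, the largest divisor of *W* is chosen). A
precomputed σ^N × σ^N table *M* holds block-level Hamming distances, so a
window comparison is *W/N* table lookups with early termination past *k*.

Taboo windows (reverse complement included) are partitioned into sub-lists
addressed by their first two block codes. A stored vector within *k* of a
query *x* = ⟨x₁, x₂, …⟩ must live at an address (i, j) with

    M(x₁, i) + M(x₂, j) ≤ k

so the scan visits exactly those candidate sub-lists (a single address at
*k* = 0), in ascending prefix-distance order. Correctness is verified
against a naive letter-by-letter oracle that shares no code with the engine.

## Worked example

```r
library(tabooscan)

qd <- tempfile(); td <- tempfile()
write_fixture(generate_genome(500,  seed = 1, record_id = "q"), qd, "query.fa")
write_fixture(generate_genome(3000, seed = 2, record_id = "t"), td, "taboo.fa")

scan <- run_taboo_scan(qd, td, W = 12, k = 1)
scan
#> <taboo_scan> W = 12 (N = 4), k = 1
#>   489 query windows: 484 disjoint (99.0%), 5 intersecting
#>   disjoint territory: 500 bp (100.0% of query)
#>   taboo index: 5978 vectors in 5684 sub-lists

head(tidy(scan), 3)
#> # A tibble: 3 x 5
#>   source_file record_id position word         label
#>   <chr>       <chr>        <int> <chr>        <chr>
#> 1 query.fa    q                1 ATGACAGGCCGG disjoint
#> 2 query.fa    q                2 TGACAGGCCGGA disjoint
#> 3 query.fa    q                3 GACAGGCCGGAA disjoint
```

489 windows were scanned (500 − 12 + 1); 484 have no 12-mer within one
mismatch anywhere in the 3 kb taboo genome or its reverse complement, and 5
happen to fall within one mismatch of some taboo window. `glance(scan)`
returns the one-row summary (window fraction and genomic-territory
fraction); `autoplot(scan)` draws the disjoint fraction along each record;
`write_results(scan, "out/")` writes one TSV per query FASTA
(`record_id`, 1-based `position`, `sequence`), with `mode = "a"` for both
label files and `bed = TRUE` for BED spans.

A shell front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("exec/tabooscan", package="tabooscan"))') \
  --query-dir A/ --taboo-dir B/ --out results/ -W 30 -k 2 --mode a
```

For uniqueness mining *within* one genome (e.g. CRISPR target pre-filtering),
place the same FASTA in both directories and pass `self_exclude = TRUE`:
each window's own exact occurrence is then discounted.

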
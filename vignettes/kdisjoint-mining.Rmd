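---
title: "Mining k-disjoint sequences: model, index, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining k-disjoint sequences: model, index, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabooscan)
```

## The problem

Given two sequence sets — a *query* set $A$ and a reference or *taboo* set
$B$ — the **k-disjoint** set of $A$ is every length-$W$ window of $A$ whose
Hamming distance to *every* length-$W$ window of $B$ (both strands) exceeds
$k$. Its complement is the **k-intersection**: windows within $k$ mismatches
of at least one taboo window. For $k = 0$ this collapses to plain
uniqueness; larger $k$ gives the stringent notion of uniqueness that matters
when a hybridization assay or a nuclease tolerates a mismatch or two:
padlock-probe targets that identify a single strain, CRISPR guides with few
near-off-targets, and windows revealing substitutions, inversions or foreign
insertions relative to a reference.

The method is deliberately exhaustive — evidence of *absence* of any near
match — which rules out aligners with heuristics and repeat masking. It is
also substitution-only: Hamming distance, never edit distance (an indel
shifts every downstream window, which the window extraction itself absorbs).

## N-coding and the mismatch matrix

Windows are compared through a block encoding. An
`encoding_scheme(N, alphabet)` maps every length-$N$ word over the ordered
alphabet (default A < C < G < N < T, with N the canonical unknown base) to
its lexicographic rank, an integer in $[0, \sigma^N - 1]$. A $W$-letter
window becomes a vector of $W/N$ block codes. $N$ must divide $W$ and lie in
$\{3,4,5\}$; `choose_n(W)` picks the largest such divisor, and additionally
requires at least two blocks ($W/N \ge 2$) because the index below is
addressed by the first two codes. $N$ is capped at 5 because the
block-distance table has $\sigma^{2N}$ entries — $5^{10} \approx 9.8$
million single-byte-scale integers at $N = 5$, about 37 MB as an R integer
matrix; $N = 6$ would be 25-fold larger.

`mismatch_matrix(scheme)` precomputes $M(i,j)$ = Hamming distance between
the words decoded from block codes $i$ and $j$. The distance between two
windows is then the sum of $W/N$ table lookups, and every comparison in the
scan early-terminates as soon as the running sum exceeds $k$
(`hamming_capped()` returns `cap + 1` on early exit — callers only ever test
`<= k`, so the exact overshoot is never needed).

The unknown base N is an ordinary fifth letter: N-vs-N contributes 0
mismatches, N-vs-anything-else contributes 1. The alternative convention
(N mismatches everything, including itself) would make runs of N's in a
reference assembly *less* able to absorb query windows, slightly enlarging
disjoint sets around gaps. We chose the ordinary-letter semantics because it
is what a Hamming metric over the five-letter alphabet computes, and expose
no toggle; callers who want the other behavior can mask N runs upstream.

```{r}
sc <- encoding_scheme(3, c("A", "C", "G", "T"))
encode_ngram(c("AAA", "AAG", "TTT"), sc)
M <- mismatch_matrix(sc)
M[0 + 1, 2 + 1] # AAA vs AAG
M[0 + 1, 63 + 1] # AAA vs TTT
```

## The two-level index and address pruning

All taboo windows — reverse-complement strand included, since a probe or
guide binds either strand — are encoded and partitioned into sub-lists
addressed by their first two block codes (`build_dictree()`): a vector
$\langle 62, 3, \dots\rangle$ lives at address $(62, 3)$. The partition is
sparse; only non-empty addresses are materialized.

Pruning rests on one inequality: if a stored vector $y$ is within $k$ of the
query $x$, its first two blocks alone contribute
$M(x_1, y_1) + M(x_2, y_2) \le k$. `candidate_addresses(x, k, M)` therefore
enumerates exactly the address pairs $(i,j)$ with $M(x_1,i)+M(x_2,j) \le k$,
built from the precomputed distance shells of $x_1$ and $x_2$ rather than by
scanning all $\sigma^N$ codes twice per query. Shell $d$ of any code has
exactly $\binom{N}{d}(\sigma-1)^d$ members, so the candidate count is the
convolution $\sum_{d_1+d_2\le k} s(d_1)\,s(d_2)$ — 1 address at $k=0$, 19 at
$k=1$ for the four-letter $N=3$ scheme. The test suite verifies soundness
and completeness of this set exhaustively over all prefix pairs at
$k = 0..3$.

Sub-lists are visited in ascending prefix distance $d_1 + d_2$, so exact
matches short-circuit fastest; any visit order would be correct, this one is
fast. The index keeps two levels exactly: deeper branching would shrink
sub-lists further but the two-level address already reduces the expected
sub-list to (stored count)$/\sigma^{2N}$ under a uniform-composition
assumption, and the per-query candidate enumeration cost grows with each
added level.

## The filter engine

`scan_records()` extracts every query window (forward strand — the taboo
side already carries both strands, so indexing reverse complements once is
equivalent to also reverse-complementing every query window, and cheaper),
encodes it, and asks whether any stored vector lies within $k$
(`exists_within_k()`). The label is `'disjoint'` exactly when the answer is
no. The compiled bulk scanner and the pure-R reference path implement the
same search; their agreement is itself a test.

**Self-exclusion.** When the same genome is placed in both sets (uniqueness
mining within a genome), every window trivially matches its own occurrence.
With `self_exclude = TRUE` one exact occurrence of each query vector is
discounted: a window is disjoint iff its exact multiplicity in the index is
$\le 1$ *and* no distinct vector lies within $k$. Because indexing inserts
both strands, a reverse-complement-palindromic window acquires multiplicity
2 from its own locus and is therefore never disjoint under self-exclusion —
a documented, deliberate edge-case behavior (such windows are genuinely not
unique as binding targets: their two strands read identically).

**Parallelism.** `partition_workload()` splits the window list into
contiguous chunks whose sizes differ by at most one; chunks may be scanned
in forked workers. Classification of a window depends only on the window and
the index, so the merged, position-ordered output is byte-identical for any
thread count — determinism is a contract, tested over 1, 2 and 4 workers.

## Tunable parameters

| parameter | units | default | notes |
|---|---|---|---|
| `W` | bases | — | window length; multiple of 3/4/5, `W/N >= 2`. Probe-scale 30–100, guide-scale 20. |
| `k` | mismatches | — | 0–5 recommended; a warning past 5 (cost grows roughly tenfold per extra mismatch). |
| `mode` | — | `'d'` | which label `write_results()` emits (`'a'` writes both files). |
| `self_exclude` | flag | off | turn on when query and taboo are the same genome. |
| `threads` | workers | 1 | forked scan chunks; output independent of the value. |

Positions are 1-based inclusive window starts on the forward query strand;
block codes are 0-based. BED export converts to 0-based half-open spans.

## Synthetic data and what validation shows

`generate_genome()` draws i.i.d. uniform A/C/G/T. The mutation planters
reproduce the structure of classic detection experiments: transition
substitutions (A↔G, C↔T) at chosen sites, reverse-complement inversion of a
segment in place, and splicing of a donor segment carrying 0–3 transition
mutations. All randomness is seed-parameterized and the emitted plan table
makes each experiment replayable bit for bit.

Validation runs at desk scale — genomes of 50–100 kb instead of megabases,
with the protocol (five substitution sites, $W=30$, $k=0$; four 70 bp
insertions with 0/1/2/3 mutations, $W=70$, $k=3$; an 80 bp inversion,
$W=30$, $k=0$; whole-genome self-comparison at $W=20$, $k=0$) kept intact.
The master correctness property is oracle equivalence: on random
query/taboo pairs across $W \in \{12,15,20,30\}$, $k \in 0..3$ and five
seeds, the engine's labels equal those of `brute_force_kdisjoint()`, a
naive letter-by-letter all-pairs scan that shares no code with the engine
path — no encoding, no matrix, no index.

Uniform random genomes lack repeats, GC skew, low-complexity runs and
sequencing error. Consequently passing tests demonstrate the *combinatorial
correctness* of the engine (labels equal the oracle's on any input — the
oracle property is composition-free), but the *sizes* of disjoint sets seen
in tests (e.g. self-comparison leaving >99.9% of a random 50 kb genome
unique at $k=0$) are optimistic relative to real genomes, where repeat
families and duplications shrink the unique fraction substantially, and
increasingly so as $k$ grows. Genome-scale runs against real assemblies
behave identically per window but take correspondingly longer and require
the user's own FASTA inputs.

## Numerical and degenerate-input choices

- `choose_n()` rejects any $W$ not divisible by 3, 4 or 5, naming the
  nearest valid lengths on both sides.
- Records shorter than $W$ warn and contribute zero windows; an empty taboo
  set is a valid index under which every query window is disjoint.
- Every non-ACGT input character (IUPAC codes, gaps, stray symbols) becomes
  N at read time; length is preserved so positions stay valid.
- A transition planted on an N site is a no-op with a warning (N has no
  transition partner).
- Identical words at different query positions are reported at every
  position — no deduplication, since downstream probe design needs loci.
- Output files are byte-identical across re-runs of the same configuration;
  the header carries parameters and package version, never a timestamp.

## Limitations

- Substitutions only; an indel-tolerant variant needs a different distance
  and index.
- The $N=5$ mismatch matrix costs ~37 MB and a couple of seconds to build;
  it is built per scan, not cached across calls.
- The brute-force oracle is quadratic and intended for validation scale
  (queries × taboo of ~10⁸ window pairs) only.
- Search cost grows steeply with $k$ (empirically about an order of
  magnitude per mismatch); $k > 5$ is allowed but warned against.
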
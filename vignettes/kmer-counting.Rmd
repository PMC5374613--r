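---
title: "Two-phase minimizer-binned k-mer counting with kmerbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase minimizer-binned k-mer counting with kmerbin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerbin)
```

## The problem

Counting the occurrences of every length-k substring (k-mer) of a set of
sequencing reads is a basic primitive of genome assembly, error
correction and abundance estimation. The task is trivial in principle —
a dictionary from k-mer to counter — but becomes resource-bound at
genome scale, and most classical counters degrade sharply once k grows
past a machine word (k > 32), precisely the regime that long-read
applications need. `kmerbin` implements an exact, disk-backed,
hash-table-based counter whose key representation is a vector of packed
64-bit blocks, so k = 200 is handled by the same code path as k = 28.

Because DNA is double-stranded, a k-mer and its reverse complement
(reverse the string, swap A&harr;T and C&harr;G) are usually counted as
one entity; the *canonical* form is the lexicographically lesser of the
two (A<C<G<T). Canonical counting is the default and can be disabled
(`canonical = FALSE`).

## The two phases

**Phase one — distribution.** Input data sets typically exceed main
memory, so reads are first split into *bins*, temporary files chosen so
that all occurrences of a k-mer land in the same bin. The device is the
*minimizer*: the m-mer window of a k-mer that is minimal under a chosen
total ordering of all 4^m m-mers. Consecutive k-mers of a read usually
share their minimizer, so a read decomposes into few, overlapping
*super-mers* — maximal substrings whose k-mer windows all share one
minimizer occurrence — and storing super-mers rather than k-mers
compresses the temporary files by roughly a factor of k. Each super-mer
is appended to the bin its minimizer rank maps to, and each bin records
its total k-mer count n.

```{r fig-example}
lex <- build_ordering("lex", m = 3)
super_mers("CAAGAACAGTG", k = 4, lex)
```

A super-mer ends exactly where the minimal m-mer *occurrence* moves —
a positional notion: if an equal-rank m-mer appears at a new position,
the super-mer still breaks. Equal-rank ties are resolved to the leftmost
occurrence, forward strand before reverse. This positional identity is
what makes the decomposition maximal and uniquely defined; the k-mer
windows of the super-mers reproduce the read's windows exactly once
each, which the test suite asserts as a conservation property.

In canonical mode the minimizer is minimal over the windows of both the
k-mer and its reverse complement, but super-mer bases are stored in
read-strand orientation; phase two canonicalizes the individual k-mers.
Whether minimizers should be strand-aware is a genuinely open design
point — the worked example above is forward-only — so both modes are
exposed and tested.

**Phase two — counting.** Bins are re-read one at a time and counted
with an open-addressing hash table: probe i of k-mer x visits slot
`(h0(x) + (i + i^2)/2) mod |T|`, a quadratic (triangular) schedule that
visits every slot when |T| is a power of two, which is the slot
granularity the pipeline uses. Two independent hash functions divide the
work:

* `probe_hash` mixes every 64-bit block (32 bases) of the packed k-mer
  through a multiply–xor–shift avalanche (the splitmix64 finalizer,
  constants `0xbf58476d1ce4e5b9` / `0x94d049bb133111eb`); linear in k.
* `part_hash` mixes at most the first four 16-bit blocks (8 bases each)
  into [0, 2^16); constant time in k. It routes k-mers to shards
  (`part_hash(x) mod N`) and selects the k-mers of each pass.

## Table sizing, passes, failures

Three mechanisms keep memory bounded while preserving exactness:

* **Adaptive sizing.** The number of distinct k-mers d of a bin is
  unknown before counting, but its total n is known from phase one. d is
  estimated as &alpha;·n with &alpha; the distinct/total ratio observed
  in the previously counted bin (bootstrap &alpha; = 0.5 — the ratio is
  bounded by 1 and bins are similar in composition, so the estimate
  converges after the first bin and its start value only affects that
  bin's memory headroom, never correctness). The table gets
  `ceiling(alpha * n / beta)` slots, so the expected post-insertion fill
  level is &beta;; &beta; = 0.4 by default, trading a little idle memory
  for short probe chains. On the synthetic fixture the realized mean is
  about 1.1–1.3 probes per insertion.
* **Multiple passes.** If n exceeds the table capacity cap T_max
  (derived from the user's memory cap divided by the slot size,
  `8*ceiling(k/32) + 4` bytes), the bin is swept `p = ceiling(n / T_max)`
  times and pass i handles exactly the k-mers with
  `part_hash(x) ≡ i (mod p)` — a partition, so every k-mer is processed
  exactly once.
* **Probe cap and failure buffers.** A pathological insertion could
  probe for a long time, so probing stops after `i_max` attempts
  (default 30, roughly log2 of realistic data-set sizes) and the k-mer
  is spilled to a failure buffer instead. After the pass, the spill is
  recounted in a dedicated table sized to the spill count; if even that
  fails, capacity and i_max are doubled and the remainder retried, which
  terminates because occupancy never shrinks and a power-of-two table is
  fully covered once i_max reaches |T|. Failure buffers are held in
  memory here — at in-memory scale there is no reason to put the spill
  on disk, and the draining policy is what the exactness argument needs,
  not the buffer's location. A k-mer either enters a table or spills
  with *all* of its occurrences (the probe schedule is deterministic and
  slots are never freed), so counted and spilled key sets are disjoint
  and no k-mer is lost or double-counted — the invariant the whole
  design is built around, asserted against a brute-force oracle for
  every parameter combination in the tests.

Counters are 32-bit and saturate at 2^32 − 1.

## Minimizer orderings

The ordering determines both the number of super-mers (temporary disk
space) and how evenly distinct k-mers spread over minimizers (peak
table size). Six strategies are provided: plain lexicographic (`lex`),
`cgat` (lexicographic with C<G<A<T), `roberts` (complement bases at even
positions, then C<A<T<G, preferring rare minimizers), `kmc2`
(lexicographic A<C<G<T with m-mers starting AAA or ACA demoted after all
others — the default, and the published exception list of that scheme;
further unpublished exceptions of the original tool are not guessed at),
`random` (a seeded permutation) and `dfp(p)` (sort by sampled frequency
ascending, then by distance of that position from the pivot position
4^m·p; frequencies are sampled from the first 100,000 read fragments,
cheap and deterministic given input order). `compare_orderings()`
reports, per strategy, the total super-mer count and the maximal number
of distinct k-mers per minimizer; the two pull in opposite directions,
and on our synthetic fixtures `kmc2` gives the fewest super-mers while
`dfp(0)` gives the flattest per-minimizer distribution, matching the
qualitative trade-off the strategies were designed around.

The default minimizer length is m = 7; longer minimizers split reads
into more super-mers (the tests assert the mean super-mer count is
non-decreasing in m), which balances bins better but inflates the
temporary files.

Bins: F = 512 temporary files by default. The rank-to-file map is a
multiplicative (Knuth) hash of the rank mod F — chosen over an
avalanche hash because, for power-of-two F, it is a bijection mod F and
assigns exactly 4^m/F ranks per bin, while still scattering
neighbouring (similar, correlated-frequency) ranks.

## Synthetic data and what the tests show

`simulate_genome()` / `simulate_reads()` generate the validation
fixture: a uniform random 100 kb genome, 100 bp reads at 10x coverage
from both strands, 1% uniform substitution errors and 0.1% N-masking —
desk-scale values typical of short-read data that still exercise every
code path (the error rate pushes the distinct/total ratio up and the
N-masking exercises fragment splitting). The generator makes no attempt
at realistic genomes (no repeats beyond chance, no GC skew, no indels,
no quality-dependent errors). That is deliberate: the package's claim
is *exactness of counting*, which is independent of sequence
composition; the oracle-equivalence tests prove the bookkeeping, not
biological realism. Performance-shaped properties measured on this
fixture (fill levels, probe counts, ordering metrics) should be read as
indicative only — real genomes have skewed minimizer distributions that
make ordering choice matter more, not less.

`oracle_count()` is the reference: a character-level dictionary counter
sharing no code with the pipeline. Every end-to-end test compares
against it for k in {28, 40, 64, 100, 200} (at 100 bp reads the last two
probe the one-window-per-read and no-window boundary cases), canonical
mode on and off, under forced multi-pass (p = 3), a probe cap of
i_max = 1 (everything spills), 4 shards and single-bin operation.

## Numerical and degenerate-input choices

* Reads are split at non-ACGT symbols; fragments shorter than k are
  skipped. No quality filtering or trimming is done.
* `table_size()` returns the raw `ceiling(alpha*n/beta)` (minimum 1);
  only the bin pipeline rounds capacities up to powers of two. A
  standalone `new_count_table()` accepts any capacity, so the fill-level
  property can be measured at the formula's exact size.
* Empty bins leave the running &alpha; untouched; an empty input yields
  a valid empty output file.
* Output is sorted lexicographically (C locale) before writing, making
  runs byte-reproducible; equal configurations produce byte-identical
  bins and outputs.
* Super-mer records store their length as a 16-bit field; a super-mer
  spans at most 2k − m bases, so this caps k at ~32,000 — far beyond
  the supported target of k ≤ 200-ish, and checked nowhere hot.

## Problem sizes used in the shipped tests

The bundled suite and the acceptance script use the 100 kb / 10x
fixture (10,000 reads, ~0.7M 28-mer windows), 50 end-to-end
pipeline-vs-oracle configurations, 10^5-k-mer hash/uniformity samples
and exhaustive rank-bijection checks up to m = 8 (65,536 m-mers). These
sizes were picked so the full suite runs in a few minutes on one core
while still forcing multi-pass counting, failure-buffer traffic and
non-trivial bin occupancy.

## Limitations

* Single-process, sequential phases. Shards are logical tables, not
  threads; the contract is that results are identical for any shard
  count, leaving parallelism as an implementation freedom.
* No GPU path, no throughput-adaptive rebalancing between tables, and
  no attempt to reproduce wall-clock benchmarks of compiled counters —
  out of scope by design.
* FASTQ records are assumed 4-line; SAM/BAM and paired-end semantics
  are not handled.
* The k-mer → file mapping is static; a bin that is pathologically
  large (a hyper-frequent minimizer) is handled by multi-pass counting
  rather than by re-partitioning.
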
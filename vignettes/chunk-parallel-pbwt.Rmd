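---
title: "Chunk-parallel PBWT construction and haplotype matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunk-parallel PBWT construction and haplotype matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppbwt)
```

## The data structure

The positional Burrows–Wheeler transform (PBWT) of an `M x N` phased,
biallelic haplotype panel maintains, at every locus `k`, two arrays:

* the **positional prefix array** `a_k`, the permutation of haplotype ids
  that sorts the haplotypes by their *reverse prefixes* over loci `[0, k)` —
  colexicographic order, with the most recent locus most significant;
* the **divergence array** `d_k`, where `d_k[i]` is the smallest locus `j`
  such that the haplotypes at sorted positions `i` and `i - 1` agree over
  `[j, k)`. `d_k[0] = k` is the no-predecessor sentinel.

One column step is a stable two-way bucket pass: haplotypes carrying allele
0 at locus `k` precede those carrying allele 1, preserving relative order
within each class, while two running maxima propagate the divergences.
Because the pass is stable, haplotypes identical over `[0, k)` stay in input
order — the tie rule this package commits to on both the sequential and the
chunked path, so that all construction routes are bit-comparable.

Adjacent rows in `a_k` order are maximally similar, which is what makes two
classic sweeps linear-time instead of all-versus-all quadratic: reporting
every maximal match of length at least `L` (`pbwt_long_matches()`), and
reporting every *set-maximal* match — a match of haplotype `h` contained in
no strictly larger match involving `h` (`pbwt_set_maximal()`).

## Breaking the positional dependency

`a_{k+1}` and `d_{k+1}` depend on `a_k` and `d_k`, so the construction is
inherently sequential in `k` — the obstacle to multithreading the sweeps
over a long genomic region. The package breaks the dependency in three
phases (`pbwt_build_parallel()`, `pbwt_match()`):

1. **Approximate chunk builds.** `[0, N)` is split into `T` contiguous
   chunks of near-equal size (`plan_chunks()`). Each chunk `[s, e)` is built
   independently (`pbwt_build_chunk()`) starting from identity order and a
   divergence array filled with the sentinel value `s`. The resulting
   arrays at `e` are exact *except* inside **sentinel groups** — maximal
   runs of haplotypes identical over the whole chunk, flagged by
   `d[i] == s`: within the chunk nothing distinguishes such haplotypes, so
   their relative order defaults to input order and their true divergences
   (which lie before `s`) are clamped at the sentinel. Everything else is
   provably the value the from-scratch build produces.
2. **One correction step per boundary.** Chunks are corrected in ascending
   order, each against its predecessor's now-correct end state
   (`correct_state()`). For each sentinel group, `correct_group()` looks up
   the group's haplotypes in the previous boundary's ordering (via the
   inverse prefix array), sorts those positions, copies the previous order
   back, and sets each interior divergence to the maximum of the previous
   divergence array over the half-open window between consecutive looked-up
   positions. The group's first divergence refers to the preceding
   non-matching haplotype and needs no fix. The first chunk needs no
   correction at all (its sentinel array *is* `d_0`).
3. **Parallel sweeps.** With correct boundary states available, the
   matching sweep runs independently per chunk, seeded with the chunk-start
   state. A match is *owned* by the chunk whose range contains its end
   locus (the locus where the two haplotypes next disagree), and the final
   chunk flushes matches still open at `N` — so the per-chunk outputs are
   disjoint and their union, canonically sorted by `(start, hap_i, hap_j)`,
   is identical to the single-threaded output for every chunk count and
   worker count.

Two subtleties are worth recording precisely, because they are checked by
the test suite:

* **Error locality.** A sentinel group, as the correction driver detects
  it, spans `[g, i)` where `g` is the *last* position whose divergence
  differs from the sentinel: the group leader's divergence is already true,
  but its `a` entry is not guaranteed — the leader is itself one of the
  chunk-identical haplotypes, and the correction rewrites `a` over the
  whole group including position `g`. The guarantees that hold everywhere
  are: every `d[i]` above the sentinel is true, and both arrays are true at
  every position outside the (leader-inclusive) sentinel groups.
* **Work bounds.** Within one group the max-window scans walk disjoint
  windows of the previous arrays, so a single group's scan work is bounded
  by `M`; the summed size of all sorted groups in one correction pass is
  also bounded by `M` (groups are disjoint). The *summed* scan work across
  groups is not bounded by `M`, because different groups' windows may
  interleave in the previous ordering; it remains output-sensitive and
  small in practice. The instrumentation counters on every corrected state
  (`correction_stats`) expose all three quantities.

## Parameters that matter

* `n_chunks` (`T`): the number of chunks, nominal chunk size `b = N / T`.
  Correctness never depends on it; cost does. Each boundary correction is
  `O(M log M)` worst case, so total overhead `O(T M log M)` is negligible
  against the `O(N M / T)` per-worker sweep when `N >> T`. Larger chunks
  also mean fewer chunk-identical haplotypes, hence fewer sentinel groups
  to fix.
* `workers`: OS processes used for the chunk phases (forked via the
  `parallel` package on Unix; `workers = 1` runs serially). Output is
  a pure function of the inputs and `n_chunks` — the scheduler cannot
  change it, which the determinism tests assert.
* `min_length` (`L`): inclusive lower bound on reported match length. The
  classic use-case of scanning a chromosome-scale panel for long shared
  segments corresponds to `L` on the order of thousands of loci; all
  lengths are in loci, not base pairs.
* `strict` in `read_vcf_panel()`: strict mode rejects any site that is not
  biallelic, phased and complete; lenient mode skips such sites (with a
  count) so real-world VCFs can be used without pre-filtering.

## What the synthetic generator emulates

`sim_panel()` draws per-site alternate-allele frequencies uniformly from
`[0.05, 0.5]` by default — avoiding a panel dominated by monomorphic
columns while still producing the low-diversity stretches that create
sentinel groups — and fills the panel with independent Bernoulli draws.
Duplicate-haplotype groups (`dup_groups`, or a random specification from
`sim_dup_spec()`) are planted on top: group members are identical over a
chosen span and perturbed at a chosen rate outside it, which guarantees
sentinel groups in any chunk the span covers. This exercises every code
path of the correction machinery, including whole-panel identity (the
worst case: one group of size `M` at every boundary).

What it does **not** emulate: linkage-disequilibrium decay, coalescent
genealogies, recombination hot-spots, allele-frequency spectra of real
cohorts, missingness or phasing error. Passing tests therefore demonstrate
algorithmic exactness — the chunked construction and the sweeps agree with
the sequential algorithm and with quadratic brute force on panels spanning
the full range of duplicate structure — not statistical realism of the
panels themselves. Exactness is a combinatorial property of the arrays, so
this is the right scope: the algorithm either reproduces the sequential
result on a panel or it does not, and duplicate density is the only input
feature that changes which code paths run.

## Numerical and design choices

* All data are integers; there is no floating point anywhere, and all
  equalities in tests are exact (`identical()`).
* Ties between haplotypes identical over `[0, k)`: input order, via the
  stability of the bucket pass (see above). Any fixed deterministic rule
  would work if applied consistently on both paths; stability is the one
  the correction step's previous-order lookup reproduces naturally.
* When `N` is not divisible by `T`, the remainder is spread one locus each
  over the leading chunks, so chunk sizes differ by at most one.
* The sentinel comparison in group detection uses the chunk-start value
  `s`; a divergence equal to `s` can also be legitimately true, in which
  case the correction recomputes the same value — correction is idempotent
  on already-true entries inside groups.
* Match intervals are 0-based half-open everywhere, haplotype ids 0-based;
  records are canonically sorted and de-duplicated before writing, so
  output files are byte-stable across thread counts.
* Degenerate inputs: a panel must have `M >= 1` but may have `N = 0`
  (matching returns an empty record set); `n_chunks` is capped by `N`;
  `min_length < 1` and non-binary alleles are rejected up front.
* State checkpoints are little-endian int32 with a magic/version header;
  loading validates magic, version, array lengths and trailing bytes, so a
  truncated or foreign file fails loudly rather than yielding corrupt
  arrays.

## Problem sizes used by the test suite

The construction-exactness suite runs 300 seeded panels (`M <= 64`,
`N <= 256`, duplicate-group rates 0 / 0.2 / 0.8) against chunk counts
`{1, 2, 3, 5, 8}`; the match-equivalence suite runs 200 seeded panels
(`M <= 48`, `N <= 200`) for `L` in `{1, 2, 5, 20}` against the quadratic
oracles. The scaling check times the construction of a `1000 x 100000`
panel with one chunk versus four chunks on four workers. These sizes keep
the brute-force oracles (the quadratic cost is the oracle's, not the
package's) tractable while covering every duplicate-structure regime.

## Known limitations

* Biallelic panels only; no missing data, no multiallelic expansion —
  unusable VCF sites are rejected or skipped at the I/O boundary.
* No query-versus-panel matching of out-of-panel haplotypes, and no
  PBWT-based compression codec; the chunk-correction machinery would apply
  to both, but they are out of scope here.
* Single-machine parallelism only (forked processes); speed-ups require
  actual spare cores, while correctness holds for any `workers`.
* Haplotype ids, not sample names, appear in match reports; mapping back
  to samples is `id %/% 2` with the VCF sample order stored on the panel.

## A worked example

```{r example}
pan <- sim_panel(12, 60, dup_groups = list(c(4, 10, 50)), seed = 42)
states <- pbwt_build_parallel(pan, n_chunks = 3)
identical(states[[3]]$a, pbwt_build(pan, 60)$a)

sentinel_groups(pbwt_build_chunk(pan, 20, 40))

pbwt_match(pan, "long", min_length = 15, n_chunks = 3)
```
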
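---
title: "Simulating ancient-DNA damage and measuring placement accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ancient-DNA damage and measuring placement accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoplace)
```

## The damage model

`paleoplace` implements the Briggs model of post-mortem DNA damage. The
model captures the two dominant degradation processes of ancient DNA
(aDNA) in a double-stranded sequencing library:

1. **Fragmentation.** Each junction between two consecutive residues is
   nicked independently with probability $\nu$. Fragments between nicks
   become the simulated reads, so interior read lengths are geometric with
   success probability $\nu$ and median
   $\lfloor -\ln 2 / \ln(1-\nu) \rfloor$ — `theoretical_median_fragment_length()`.
   At $\nu = 0$ the source survives as a single read.
2. **Deamination.** Each read carries one single-stranded *overhang*, on
   the 5′ end with probability $1/2$, else the 3′ end. Its length is drawn
   from the zero-indexed geometric distribution
   $P(L = k) = (1-\lambda)^k \lambda$, so $\lambda = 1$ means the overhang
   process terminates immediately (length 0) and smaller $\lambda$ means
   longer overhangs. Eligible bases deaminate with probability
   $\delta_{ss}$ inside the overhang and $\delta_{ds}$ elsewhere. On a
   5′-overhang read only C→T substitutions can occur; on a 3′-overhang
   read only G→A — the asymmetry introduced by repairing overhangs during
   library preparation. Only literal C (or G) bases are eligible;
   ambiguity codes and gap characters are never altered, and case is
   preserved (`c` becomes `t`).

Because $\delta_{ss}$ is typically an order of magnitude larger than
$\delta_{ds}$, damage concentrates at read ends.
`expected_damage_profile()` gives the closed form: the expected C→T
probability at 1-based position $p$ from the 5′ end is
$\tfrac12\left[(1-\lambda)^p\,\delta_{ss} + \bigl(1-(1-\lambda)^p\bigr)\,\delta_{ds}\right]$,
with the G→A profile mirrored from the 3′ end; the pooled two-kind profile
is the familiar U-shaped misincorporation curve. The package verifies this
closed form against its own simulator by Monte Carlo (100,000 reads of
length 60, agreement within three binomial standard errors at every
position). `crossover_overhang_length()` evaluates the related rule of
thumb: at $\delta_{ss} = 0.65$, $\delta_{ds} = 0.015$ an overhang of only
3 bases contributes more expected errors than the entire protected region
of a 100 bp read.

### One overhang per read

Descriptions of the model differ on whether overhangs grow on both read
ends or a single end. We simulate a single overhang per read on one side,
drawn 50/50, because the per-read damage-type exclusivity (only C→T with a
5′ overhang, only G→A with a 3′ overhang) is only coherent under the
single-side reading. The non-overhang remainder of the read uses
$\delta_{ds}$ with the *same* damage kind as the read's overhang side; the
opposite kind never occurs within a read. No rate is applied for the
opposite kind — one read therefore never mixes C→T and G→A events, which
is also enforced as a tested invariant.

### Gaps, ambiguity codes, and aligned mode

The simulator accepts aligned input so damage can be injected *after*
alignment, isolating damage effects from alignment error. Rules:

* junctions exist only between consecutive non-gap residues; gap columns
  are not physical nucleotides, carry no nick positions, and travel with
  the preceding fragment when the sequence is cut;
* overhang lengths are counted in non-gap residues and capped at the
  read's non-gap length;
* reads consisting entirely of gap and/or ambiguity characters are
  removed unconditionally;
* the minimum read length filter (default 15 bp, mimicking the
  pre-filtering applied to real aDNA data) counts non-gap sites only;
* with a reference alignment supplied, reads sharing no non-gap column
  with any reference sequence are removed (*premasking* — such reads
  would be unalignable and unplaceable);
* in aligned output mode every read is padded back to its source
  coordinates so column indices are preserved.

A minimum read count per source (default 10) is enforced by repeating
damage passes and accumulating surviving reads. The loop is bounded by
`max_accumulation_passes` (default 1000) so it terminates even when a
source can never yield a surviving read (that case is an error naming the
source; reaching the bound with some survivors is a warning). An optional
maximum count is applied by uniform downsampling without replacement.

### Reproducibility

One seed governs a whole `simulate_damage()` call. The draw order is
fixed: nicks left to right; then per fragment its overhang side, its
overhang length, and its deamination draws left to right over eligible
bases. Identical inputs and seed give byte-identical FASTA and log
outputs. Read ids are `<source>/<pass>/<ordinal>` so accumulation passes
stay distinguishable.

## Coordinates

All coordinates in the package — read start/end against the source, event
positions within reads, the damage log columns — are 1-based and
inclusive, the R and Bioconductor convention. The damage log has one
summary row per read plus one row per damage event, so its row count is
reads + events.

## Placement accuracy

Trees carry jplace-style integer edge numbers. When a Newick string has
`{N}` annotations they are honored; otherwise edges are numbered `0..E-1`
in postorder of the tree as parsed, a deterministic convention shared by
every component of the package, so truth tables and placements always
refer to the same edges. (A jplace annotation on the root itself — a
"root edge" number — has no corresponding edge and is ignored.)

The **node distance** between two edges is the shortest path length in the
edge-adjacency graph: edges sharing a node are at distance 1, an edge is
at distance 0 from itself. This makes ND a true metric on edges; the test
suite checks it against an independent igraph line-graph oracle on 100
random trees. The **expected node distance** of a read is
$\sum_p \mathrm{LWR}(p) \cdot d(p, t)$ over its placements. LWRs are used
as reported and not renormalized; a `strict` mode errors when they sum
above 1. The *best* placement is the highest-LWR row, ties broken toward
the lowest edge number, so assessment is deterministic. Normalized eND
divides by tip count to make errors comparable across trees. Reads with
zero reported placements are an error rather than silently scored.

## The benchmark harness

`run_experiment()` recreates the placement benchmark loop with stage order
**Pruning → Damage → Placement → Assessment** (alignment is an identity
step because damage preserves source columns):

1. **Pruning** (`prune_random_subtree()`): an edge is chosen uniformly
   among those whose removal leaves ≥ 4 taxa and removes ≤ 25% of tips
   (and whose parent node is binary and not the root, so the attachment is
   well defined). The clade below it is removed from tree and alignment;
   the attachment node is suppressed and the merged edge is the scenario's
   true edge. When the pruned subtree is internal there are several
   defensible truth conventions; we use the single merged edge.
2. **Damage**: the pruned, still-aligned sequences are damaged in aligned
   mode, premasked against the remaining reference alignment.
3. **Placement** (`naive_placer()`): each read is compared to every
   reference sequence by normalized Hamming distance over columns where
   both are non-gap; candidates are the pendant edges of the `top_k = 3`
   closest leaves and LWRs are the softmax of negative distances.
   External placement tools are supported by ingesting their jplace
   output (`parse_jplace()` + `assess_placements()`) instead; no
   subprocesses are managed.
4. **Assessment**: every read is scored against the scenario's true edge.

The naive placer is a benchmark stand-in chosen for having no external
dependencies, not a placement method. Its candidate set contains only
pendant edges, which has a visible consequence: when the pruned clade's
attachment is adjacent to internal edges only, the true (merged) edge is
not a pendant edge and the placer's best case is ND = 1, not 0. Combined
with exponential branch lengths — under which the sequence-nearest leaf is
often not the topologically adjacent one — clean (zero-damage) runs
typically score a median ND of about 1 rather than 0. Relative
comparisons across damage settings, which is what the harness is for, are
unaffected; the test suite asserts the directional result (heavier
nicking does not improve normalized eND) over five independent runs.

## Synthetic fixtures

`random_sequence()` draws each site independently: G or C with probability
`gc` (split evenly), A or T otherwise — GC content directly controls the
fraction of damage-eligible sites. `random_tree()` draws a random
unrooted topology (via `ape::rtree`) with independent exponential branch
lengths, mean 0.1 expected substitutions per site — short enough that
sequences retain clear phylogenetic signal, long enough that neighbors are
distinguishable, a typical scale for curated reference alignments.
`evolve_alignment()` evolves a root sequence down the tree under the
equal-rates (Jukes–Cantor) model via `phangorn::simSeq`, verified in the
tests against the closed-form divergence
$\tfrac34\bigl(1 - e^{-4t/3}\bigr)$.

What the fixtures do *not* emulate: indels (so damaged reads stay
trivially aligned — matching the post-alignment damage-injection design),
rate heterogeneity or GTR-style substitution models, base composition
structure beyond overall GC, and sequencing error. Passing tests
therefore demonstrate correctness of the damage model and the accuracy
machinery, not robustness of placement on real, messier data.

## Numerical and testing choices

* The fragment-length median uses `floor`; all eight finite reference
  rates between 0.0001 and 0.03 agree exactly with their printed values
  under this rule.
* Distribution-recovery tests run at $n = 10^5$ draws with 3-standard-
  error bands, and goodness of fit against the geometric law uses a
  chi-square test at $\alpha = 0.001$ with tail bins pooled to expected
  counts ≥ 5.
* The standardized regression (`standardized_linear_fit()`) z-scores each
  predictor before ordinary least squares, so coefficients are comparable
  across parameters and invariant to affine rescaling of any predictor;
  constant or collinear predictors are an error naming the culprit.
* Problem sizes in the test suite: 1 Mb sources for fragment-length
  recovery; $10^5$ draws for distributional checks; a 32-taxon, 2 kb
  fixture with 10 prunings (the harness default) for end-to-end runs; 100
  random trees of ≤ 20 tips for the metric oracle. These sizes give the
  statistical checks comfortable power while keeping a full run of the
  suite at around a minute.

## Limitations

* Single-stranded library chemistry (C→T at both ends) is not modeled.
* No sequencer error model, quality strings, adapters, or
  reverse-complement orientation: the simulator outputs FASTA, by design.
* The naive placer is a stand-in (see above); conclusions about absolute
  accuracy of real placement tools require ingesting their jplace output.
* eND is topological; branch-length-weighted variants are out of scope.
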
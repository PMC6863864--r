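---
title: "Species profiling from alignment hits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species profiling from alignment hits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodauth)
```

## The problem

Food ingredient authentication asks what eukaryotic species a sample —
a sausage, a protein powder, a flour — is actually made of, and in what
relative amounts. Shotgun DNA/RNA sequencing answers this without choosing
targets in advance: reads are aligned against a broad reference collection
of plant and animal genomes, and the alignments are resolved into a
species-level composition. `foodauth` implements the downstream analytics
of that approach. It starts from taxonomically labelled tabular alignment
hits (an extended BLAST outfmt-6 dialect) and produces species-level
relative proportions, together with a subsample-size calculator and
accuracy statistics. Running the aligner and building the reference
database are upstream of this package.

## The hit-filtering cascade

Raw alignment hits against a database of thousands of related genomes are
noisy in characteristic ways: conserved sequence produces equally good hits
on several species, low-complexity or short matches produce spurious hits,
and chimeric placements put the two mates of a pair in inconsistent
locations. The pipeline applies four filters, in a fixed order:

1. **Threshold filter.** Keep hits with percent identity ≥ 95, query
   coverage (`alignment length / query length`) ≥ 0.50, and e-value
   ≤ 1e-40 — all inclusive. The strict e-value keeps sensitivity while
   removing weak chance matches; a relaxed 1e-10 mode is available for
   comparison via `filter_params(max_evalue = 1e-10)`.
2. **Best-bitscore retention.** Per read *mate*, keep exactly the hits
   tying the maximal bitscore. Each mate is an independent alignment
   query, which is why retention is per mate rather than per pair. Ties
   are kept deliberately: they are the signal that a read cannot
   distinguish two taxa.
3. **Promiscuity filter.** For each taxon S, compute the fraction of read
   pairs hitting S that hit *only* S. If fewer than 10% of S's pairs are
   exclusive, S is judged to be collecting conserved-sequence hits from a
   related true source and is removed outright, with all its hits.
   Uniqueness is counted at read-pair level, matching the pair-level LCA
   granularity downstream (a per-alignment mode exists for sensitivity
   analysis). All below-threshold taxa are identified on the incoming
   table and removed **simultaneously**: removal can only raise the
   surviving taxa's unique fractions, so a second pass never removes
   anything (idempotence is asserted in the test suite), and simultaneity
   makes the result independent of any ordering.
4. **Concordance filter.** Keep hits participating in at least one
   concordant mate combination: same read pair, opposite mates, same
   reference sequence, and alignment intervals at most 1 Mbp apart. The
   1 Mbp allowance admits transcript reads spanning intron junctions.
   Distance is measured as the number of bases strictly between the two
   intervals after normalising each to (min, max) — overlapping or
   touching intervals count as distance 0. This nearest-end convention is
   strand-robust and is this package's normative reading of
   "distance between the alignments"; the boundary is inclusive (a gap of
   exactly 1,000,000 is concordant). Pairs with hits on a single mate are
   dropped by default (`keep_singletons = TRUE` retains them). The
   implementation is a grouped join, but its contract — tested against a
   brute-force all-combinations oracle — is exactly the naive check.

Exact duplicate hit lines are removed (and counted) before stage 1;
aligners can emit duplicate HSP lines and the cascade should not count
them twice. Every stage only removes hits, and per-stage counts are
reported in the run report: auditability of the cascade is part of the
product.

## LCA assignment and species projection

Each surviving read pair is counted once, at the lowest common ancestor
(LCA) of all taxa among its surviving hits: at a species when its hits
agree, at the genus (or higher) when they do not. Counts at internal
nodes are then projected onto species leaves before proportions are
computed:

* counts at or below species rank are folded into their nearest
  species-rank ancestor (subspecies and strain resolution is folded
  upward, since results are reported at species level);
* counts at a node above species rank are split among that node's
  descendant species **proportionally to the species counts resolved in
  the first step**; if none of those species carries resolved counts the
  split is uniform;
* counts at nodes with no species descendant go to an explicit
  `unresolvable` bucket.

The projection rule is this package's normative definition (the rough
approach is established practice in read-count profiling, but no printed
specification exists): it conserves total mass to floating-point
accuracy, uses the evidence already resolved at species level, and
degrades gracefully when there is none. Because the proportional weights
are taken from the first-step resolution only, the allocation is
independent of the order in which internal nodes are processed.

Relative proportions are percentages of the **species-assigned total**.
Mass that stays above species level is reported separately and is never
silently discarded; read pairs that survive no filter are reported as
unassigned. The accounting identity

> species-assigned + unresolvable + unassigned = input pairs

is asserted in the tests. Display output hides species below 0.1% by
default (`min_report`), mirroring common reporting practice; written
profiles always contain every species.

No genome-size or transcript-abundance normalisation is applied: reported
percentages are fractions of species-assigned read pairs, not weight
fractions. Converting read proportions to ingredient weight requires
per-species calibration and is out of scope.

## The hypergeometric limit-of-detection model

Deep sequencing runs produce far more reads than matrix authentication
needs; aligning a random subsample is much cheaper. Sampling $n$ reads
without replacement from $N$ total, of which $K = \mathrm{round}(N f)$
derive from species $S$ at frequency $f$, the number $X$ of sampled
$S$-reads is hypergeometric, and

$$P = \Pr(X \ge r) = 1 - \sum_{k=0}^{r-1}
\frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}$$

is the probability of seeing at least $r$ reads of $S$ — detection at a
read-count limit of detection $L = r$. `detection_probability()` computes
this tail exactly via `stats::phyper`; `min_subsample_size()` inverts it by
bisection over $n$, which is exact because the tail is non-decreasing in
$n$ (a property asserted over an exhaustive sweep in the tests, not
assumed). `detection_curve()` maps frequencies to required subsample
sizes. Rounding of $K$ is configurable (`round`, the default, or
`floor`). An infeasible target ($K < L$: fewer reads of the species
exist than the limit of detection requires) raises an explicit error.

```{r detect}
min_subsample_size(N = 3e8, f = 0.001, L = 100, P_target = 0.9999)
detection_probability(N = 3e8, n = 450000, r = 100, f = 0.00032)
```

At 300 million total reads, the package's standard design points:
141,499 reads suffice for a species at 0.1%, and a 450,000-read subsample
detects a species at 0.032% with probability above 0.9999.

## Accuracy statistics

`composition_comparison()` pairs observed with expected percentages;
false-positive species carry expected 0. On it:

* `median_abs_difference()` — median of |observed − expected| over all
  listed species (true and false positives alike); even counts average the
  central pair.
* `max_divergence()` — the expected-positive species with the largest
  absolute difference, returned with its sign; ties break by species key.
* `chi_square_composition()` — $\chi^2 = \sum (O-E)^2/E$ with
  $df = (\text{rows}-1)(\text{cols}-1) = \text{species} - 1$ for the
  two-column observed/expected layout, one-sided p-value. Expected-zero
  species are excluded by default: the statistic divides by the expected
  value, and exclusion is the only division-safe literal reading; a flag
  re-includes them as an explicit error rather than a silent infinity.
  Percentages are used as printed, not rescaled after exclusion.
* `true_positive_mass()` — summed observed percent over expected-positive
  species.

## The synthetic-data module

Everything the pipeline consumes can be generated offline, which is what
makes the package testable without an aligner or a multi-gigabyte
reference database.

* `make_toy_taxonomy()` builds deterministic root/family/genus/species
  trees.
* `simulate_reads()` is a deliberately simple paired-end read simulator
  in the wgsim/DWGSIM parameter vocabulary — read length 150 bp, base
  error rate 0.005, outer distance 500 bp, mutation rate 0.001, indel
  fraction 0.15, indel extension probability 0.3 as defaults. It emulates
  that class of simulator (uniform fragment placement, donor mutations
  with geometric indels, then per-base sequencing errors) but makes no
  claim of byte-compatibility with any of them. Per-species read counts
  follow the mixture proportions exactly by largest-remainder
  apportionment: deterministic truth tables beat multinomial noise for
  fixtures.
* `generate_hit_table()` synthesises labelled hit tables directly — the
  key trick for testing the filter cascade. Every read pair gets a
  concordant hit pair on its own species (identity ~ Normal(99, 0.5)
  truncated to [95, 100]; these score distributions are package choices,
  exposed as arguments, since real per-hit score distributions depend on
  the database). A `confusion_model()` adds tied-bitscore cross hits to
  related species with stated probabilities — emulating conserved
  sequence — plus optional lower-bitscore hits that best-score retention
  must prune. Noise injection (singleton mates, >1 Mbp discordant
  placements, sub-threshold identity) is tagged per read in the truth
  table, so each filter stage can be checked against known ground truth.
* `subsample_reads()` draws pair-coherent uniform subsamples by reservoir
  sampling in one streaming pass; memory is bounded by the reservoir.

What the simulator does *not* model: real conserved-sequence structure
(confusion probabilities are constants, not alignment-driven), quality
score variation, GC or positional bias, microbial background (non-matrix
content is represented abstractly as reads with no surviving hits), and
database incompleteness. Tests passing on synthetic data therefore
validate the *pipeline logic* — filter semantics, LCA and projection
arithmetic, accounting identities — not classification accuracy on real
libraries, which is governed by the reference database.

## Numerical and design choices

* **Thresholds are inclusive** everywhere (identity 95.0 passes;
  e-value exactly 1e-40 passes; gap exactly 1 Mbp is concordant).
* **Best-score ties** are all kept; there is no arbitrary tie-break at
  the hit level. Where an ordering must be deterministic (profile output,
  divergence ties) the tiebreak is the species key/taxid.
* **Zero denominators** are explicit: zero species-assigned reads yield a
  flagged empty profile; `r > n` returns probability 0 with a warning;
  chi-square on expected-zero categories is an error unless excluded.
* **Merged taxids** can be remapped at taxonomy load; hits whose taxid
  or accession cannot be resolved are dropped *and counted* in the run
  report, never silently.
* **Whether thresholds precede pairing**: mates are filtered for
  identity/coverage/e-value before concordance pairing (the cascade
  order), so a pair whose second mate fails thresholds is treated as a
  singleton at the concordance stage.
* **Genus-level-only pairs** are excluded from species proportions and
  reported in the unresolvable bucket — the denominators are
  species-assigned pairs only.

## Problem sizes used in the tests

The test suite exercises the exhaustive hypergeometric sweep at
$N \le 60$ (every $K$, $n$, $r$; the oracle uses exact integer
Pascal-triangle enumeration where 64-bit floats are exact and exact prime
factorisations beyond), promiscuity idempotence on 1,000 randomised
tables, concordance against the brute-force oracle up to ~10⁴ hits, and
end-to-end parameter recovery on a five-species 100,000-pair mixture with
mild confusion (recovered within 1 percentage point per species; a
noiseless single-species fixture profiles at exactly 100%). These sizes
were chosen as the smallest at which each property is convincingly
exercised; all invariants are size-free.

## Known limitations

* Proportions are read-pair fractions, not weight fractions.
* The promiscuity rule is global per taxon: a taxon that is a genuine
  minor component *and* shares almost all its reads with a dominant
  relative can be removed; the pair-level uniqueness definition
  mitigates but does not eliminate this.
* The LCA assignment gives a pair hitting two species zero species-level
  weight directly; its mass returns to species only through projection,
  proportionally to unambiguous evidence.
* No support for taxonomies without a single root, or for GTDB-style
  non-NCBI taxonomies.
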
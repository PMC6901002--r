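---
title: "Distances, trees and filters: how poptree works"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distances, trees and filters: how poptree works}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poptree)
```

## The model in brief

`poptree` computes pairwise divergence between diploid genomes from the
genotype columns of a multi-sample VCF and clusters the genomes into a
tree. The core assumptions are:

* every usable site is a **biallelic SNP** — one single-base REF, one
  single-base ALT — so genotypes reduce to alternate-allele dosages 0, 1, 2;
* every genotype is **diploid**; haploid or polyploid GT fields are an
  error rather than being silently reinterpreted;
* sites are **independent and exchangeable**: distances are plain sums
  over sites with no weighting by position, linkage or annotation.

Two per-site measures are offered. The *genetic distance* between calls
(x₁,x₂) and (y₁,y₂) averages the four cross-genome allele mismatch
indicators, so it sees heterozygosity: `0/1` vs `0/1` scores 0.5 even
though the two genomes have identical allele frequencies. The *drift
distance* is `|f₁ − f₂|` with f the alternate-allele dosage over 2; it
responds only to frequency shifts, the signal of genetic drift between
populations, and scores that same comparison 0. Site by site, drift can
never exceed genetic distance, a property the test suite checks on random
fixtures. Only one worked value for drift dissimilarity is conventional
(zero for equal frequencies); we take the absolute frequency difference as
the minimal dissimilarity consistent with it — any monotone alternative
(e.g. squared difference) would change scale but not ordering.

## Filters and what gets subtracted from the genome length

Two user thresholds mirror the fields of the VCF standard:

| parameter   | unit            | default | applies to |
|-------------|-----------------|---------|------------|
| `min_qual`  | Phred (site QUAL) | 0     | whole record: below-threshold sites are dropped for everyone |
| `min_depth` | reads (FORMAT/DP) | 0     | single call: a below-threshold genotype becomes missing for that sample only |

Both are inclusive lower bounds (a value equal to the threshold passes),
and an absent QUAL (`.`) or absent DP passes — absence of evidence is not
treated as failure. QUAL is a site-level statement, hence the site-level
drop; DP is a per-sample statement, hence the per-sample demotion. The
per-sample reading of the depth filter (FORMAT/DP rather than INFO/DP) is
a design choice: INFO/DP pools reads over samples and cannot protect an
individual low-coverage genotype.

When a genome length `L` is supplied, summed differences become
proportions over an *effective* length: `L` minus sites excluded for
missing genotypes, user filters, and more than two alleles. Three details
are deliberate:

* **Indel records are not subtracted.** The exclusion list is missing /
  filtered / multi-allelic; an indel site is simply outside the SNP
  universe being measured.
* **Each site is subtracted once.** A site with a depth-demoted call
  counts as *filtered* even if it also carries `./.` calls; under the
  pairwise policy the per-pair missing counters skip sites already counted
  as filtered. Without this rule a site could be subtracted twice from a
  pair's effective length.
* **Under the pairwise policy the effective length is per pair** — each
  pair subtracts its own missing-site count — because different pairs use
  different site sets; under the complete-sites policy one global length
  serves every pair.

The pairwise policy requires **both** members of a pair to be called at a
site. A site with one called genome cannot enter the four-comparison
formula at all, so "present in the pair" is read as "present in both".

## Numerical choices

Per-site genetic distances are multiples of 1/4 and drift distances
multiples of 1/2, so the accumulator keeps integer quarter- and half-unit
sums and divides once at the end. Raw matrices are therefore bit-for-bit
identical regardless of chunk size or summation order (exact for any
realistic site count; doubles hold integers exactly to 2⁵³).

UPGMA uses size-weighted average linkage — the distance from a merged
cluster to any other is the mean over all original member pairs — which
makes it agree with `hclust(..., method = "average")`, an independence
check in the tests. Join heights are half the pair distance; the tree is
ultrametric by construction and the suite verifies root-to-leaf equality
to 1e-9 relative. Neighbour-joining is the classical Saitou–Nei
iteration; negative branch lengths on non-additive inputs are reported as
computed, not clamped, because clamping is a later variant. In both
algorithms, ties in the join criterion break to the smallest pair indices
in the current cluster ordering, making outputs deterministic. Input
matrices are validated: symmetry to 1e-8 relative, non-negative entries,
zero diagonal, and at least four genomes (smaller matrices are still
computable and exportable, just not tree-buildable).

Serialization is fixed-point with 6 decimals in Newick, MEGA and PHYLIP
alike — enough to round-trip p-distances on genome scales while keeping
files diff-able. PHYLIP names are strictly 10 characters (padded or
truncated); truncation collisions are an error rather than a silent
rename. Jukes–Cantor correction refuses p ≥ 0.75, the saturation
singularity of the equal-rates model.

## The fixture generator

`sim_spec()`/`generate_vcf()` produce the study conditions for every test:
a planted tree with branch lengths interpreted as per-site haplotype flip
probabilities, two independent haplotypes per genome evolved from an
all-reference root, and contaminants injected at known positions — indel
records, triallelic records, `./.` calls, and QUAL/DP values drawn
uniformly across the filter thresholds. Defaults (10 genomes, 500 sites,
5% missing calls, 2% indels, 2% triallelic sites, QUAL in 10–80, DP in
2–50) are modest but exercise every filter path; tests that need a
specific regime say so explicitly. The generator returns a *sidecar* of
expected per-pair difference sums, used-site counts and exclusion tallies
for all four metric × policy combinations, computed by construction with
scalar double loops that enumerate the four allele comparisons — a code
path deliberately disjoint from the pipeline's vectorised dosage algebra,
so the two act as mutual oracles.

Randomness is R's Mersenne–Twister, re-seeded per concern (haplotypes,
record classes, missing mask, QUAL, DP) at fixed offsets of the spec seed.
That gives byte-identical output for a fixed seed and the splittable-stream
property that raising a contaminant rate leaves genotype draws untouched.

What the generator does **not** emulate: linkage disequilibrium,
recombination, coalescent genealogies, sequencing-error processes
correlated with depth, or multi-nucleotide variants. Passing tests
therefore demonstrate arithmetical and structural correctness of the
pipeline — not that distances on real data estimate any particular
population-genetic parameter.

## Problem sizes in the test suite

Unit fixtures are tens to hundreds of sites with 4–10 genomes. The
oracle-equivalence check runs 20 seeded fixtures (≤ 200 sites, ≤ 10
genomes, contaminant rates up to 0.2) through all four metric × policy
combinations against brute-force recomputation. Tree recovery is checked
on 100 random additive matrices (4–12 leaves) and 20 random ultrametric
matrices. A throughput exercise streams a generated VCF of 10⁶ SNPs × 10
genomes through the accumulator and cross-checks the resulting matrix
against a crossprod-based recomputation from the simulated dosages;
chunked reading keeps peak memory independent of file length.

## Known limitations

* BCF, tabix-indexed access, and phasing-aware analysis are out of scope;
  the phase separator `|` is accepted but treated as `/`.
* Multi-allelic sites are excluded rather than decomposed; a dataset
  normalised with `bcftools norm -m-` will present them as biallelic rows
  instead.
* Drift distance between two *individuals* is a two-chromosome frequency
  estimate; for population-level drift, samples should represent pooled or
  representative genomes.
* Bootstrap support, outgroup rooting and tree drawing are not provided;
  export the Newick/MEGA/PHYLIP files to dedicated tree software for
  those.
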
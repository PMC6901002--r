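# poptree

Population phylogenies straight from a multi-sample VCF.

Whole-genome resequencing projects deliver genotypes for many individuals
as Variant Call Format (VCF) files, but most phylogenetic software expects
sequence alignments or pre-computed distance matrices. `poptree` closes
that gap for population-level data: it streams a (possibly gzipped) VCF
once, keeps biallelic SNPs that pass quality and depth filters, sums a
per-site distance between every pair of diploid genomes, and builds a tree
— all without ever holding the file in memory. It is aimed at population
geneticists comparing individuals or populations *within* a species;
it is not a substitute for model-based interspecific phylogenetics.

## The distances

At a biallelic SNP, each diploid genome carries two alleles coded `0`
(reference) and `1` (alternate). For genomes *X* = (x₁, x₂) and
*Y* = (y₁, y₂) the package offers two per-site measures:

* **Genetic distance** — all four cross-genome allele comparisons,
  averaged:

  d(X, Y) = ( 𝟙[x₁≠y₁] + 𝟙[x₁≠y₂] + 𝟙[x₂≠y₁] + 𝟙[x₂≠y₂] ) / 4

  Two heterozygotes (`0/1` vs `0/1`) score 2/4 = 0.5.

* **Drift distance** — only the allele-frequency difference:

  d(X, Y) = | (x₁+x₂)/2 − (y₁+y₂)/2 |

  Two heterozygotes have equal frequencies, so their drift distance is 0.

Per-site values are summed over all usable SNPs into a pairwise matrix of
raw differences. Given a total genome length *L*, the sum is divided by the
effective length (L minus sites excluded for missing genotypes, user
filters, or more than two alleles) to give a p-distance, optionally
corrected for multiple hits with Jukes–Cantor: d = −(3/4)·ln(1 − (4/3)·p).
Missing data is handled either with complete sites only (a site must be
called in every genome) or pairwise (each pair uses every site called in
both of its members).

Trees are built with UPGMA (rooted, ultrametric) or classical
Saitou–Nei neighbour-joining (unrooted, serialized with a trifurcating
root), both requiring at least four genomes, and are written as Newick
text. Matrices export in MEGA (lower-left) and PHYLIP (square, 10-character
names) formats for downstream use in those programs.

## Worked example

The package ships a deterministic fixture generator, so the example is
fully reproducible:

```r
library(poptree)

spec <- sim_spec(n_samples = 6, n_sites = 5000, missing_rate = 0.02, seed = 101)
generate_vcf(spec, "example.vcf.gz", gzip = TRUE, sidecar = FALSE)

acc <- compute_pairwise("example.vcf.gz", min_qual = 20,
                        metric = "genetic", policy = "complete")
acc
#> Pairwise genetic distance accumulator over 6 samples (policy: complete)
#> records: 5000
#>   usable biallelic SNPs: 4130
#>   skipped: indel 103 | multi-allelic 98 | low QUAL 669 | other 0
#> excluded sites: missing 427 | filtered 669 | multi-allelic 98
```

Of the 5,000 records, 4,130 are biallelic SNPs above QUAL 20; indels,
triallelic sites and low-quality sites are skipped, and 427 SNPs carry at
least one `./.` call and so are dropped under the complete-sites policy.
The summed differences feed a tree directly:

```r
tree <- upgma(raw_matrix(acc))
to_newick(tree, precision = 3)
#> ((S1:565.250,S3:565.250):155.062,((S5:621.000,S4:621.000):47.938,(S2:640.500,S6:640.500):28.438);...
```

Leaf-to-root distances are equal (UPGMA is ultrametric); branch lengths
are in summed per-site differences because no genome length was given.
With one, the matrix becomes a proportion:

```r
cat(write_phylip(p_matrix(acc, 1e7))$body)
#>     6
#> S2        0.000000 0.000128 0.000134 0.000133 0.000156 0.000146
#> S6        0.000128 0.000000 0.000135 0.000133 0.000156 0.000148
#> ...
```

The same run from a shell, via the installed wrapper:

```sh
poptree --vcf example.vcf.gz --min-qual 20 --algorithm upgma \
        --newick example.nwk --mega example.meg
```

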
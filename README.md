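# tetrassoc

Candidate-gene marker–trait association analysis for autotetraploid potato
(*Solanum tuberosum*), where a biallelic SNP segregates in five genotype
classes (AAAA, AAAB, AABB, ABBB, BBBB — minor-allele dosage 0–4) and allele
dosage is read from the height ratio of overlapping Sanger base-calling
peaks (1:3, 2:2, 3:1 for heterozygotes).

The package is aimed at plant geneticists running candidate-gene association
scans for tuber quality traits — chip color after harvest and after cold
storage (CQA/CQS, scored 1–9), tuber starch content (TSC, % fresh weight),
tuber yield and starch yield (TY/TSY, dt/ha), and cold-storage reducing-sugar
time series — but every component is generic over dosage-scored markers.

## What it computes

* **Dosage genotyping** — the minor-allele peak fraction
  f = h_alt / (h_ref + h_alt) is assigned to the nearest of the expected
  fractions {0, ¼, ½, ¾, 1} (decision boundaries at the midpoints
  0.125/0.375/0.625/0.875); triallelic signals are matched against all 15
  compositions of 4 into 3 parts. Minor-frequency-allele (MFA) copy
  frequency is Σd/(4N), and markers are filtered by MFA *carrier count*
  (≥ 8 carrier genotypes in discovery mode, ≥ 3 in validation mode).
* **Association** — per marker × trait, a one-way fixed-effects ANOVA across
  observed genotype classes: F on (k−1, n−k) df, and percent variance
  explained η² = SS_between / SS_total × 100. Genotype is categorical, so
  recessive and non-monotone class patterns are captured; the direction of
  the MFA effect (↑ / ↓ / ↑↓ for inconsistent) is a separate derived
  quantity from the dosage-ordered class means. Significance tiers: ns
  (p > 0.05), \* (0.05 > p ≥ 0.01), \*\* (0.01 > p ≥ 0.001),
  \*\*\* (p < 0.001); markers are "reportable" at p < 0.01 for ≥ 1 trait.
* **Linkage disequilibrium** — a phase-free χ² independence test on the
  genotype-class contingency table of each marker pair (sparse dosage
  classes pooled with the adjacent class), with Benjamini–Hochberg or
  Storey q-values and single-linkage LD-block grouping of same-locus
  markers within 700 bp.
* **cDNA haplotypes** — clone-consensus SNP calling (a variant is factual
  iff seen in ≥ 3 clones from ≥ 2 independent amplifications), haplotype
  deduplication and pattern matching, Hamming distances, marker-concordance
  fractions, and ORF coordinate arithmetic
  (residue = ⌊(pos−1)/3⌋ + 1, position 1 = A of ATG).
* **Synthetic populations** — tetrasomic dosages Binomial(4, p), two-locus
  LD via four independent haplotype draws per individual, traits calibrated
  to a target variance fraction, noisy peak signals, and clone tables with
  batch structure — so the whole pipeline is testable end to end without
  unpublished phenotype data.

## Worked example

```r
library(tetrassoc)

cfg <- simulation_config(seed = 42)       # 208 individuals, 5 markers, 5 traits
ds  <- simulate_population(cfg)
res <- associate_all(ds$dosage_matrix, ds$trait_table, mode = "discovery")
association_wide(res)
```

```
           marker mfa_percent      CQA     CQS       TSC TY      TSY
 AGPaseS-T_1259_C         9.9 7.1*** ↑ 5.1** ↑ 15.2*** ↑ ns 9.2*** ↑
   PHO1b-T_4404_C         9.7       ns      ns        ns ns       ns
    PWD-T_10547_C        46.8   4.8* ↓      ns        ns ns       ns
 INV-8/2-T_2076_C        36.9       ns      ns        ns ns       ns
    BMY1-G_2657_A         9.1       ns      ns        ns ns       ns
```

The configured causal marker (`AGPaseS-T_1259_C`, simulated MFA 8.5%, true
TSC variance fraction 0.199) is recovered with an estimated 15.2% variance
explained in this single replicate (p = 4.4e-08, \*\*\*, effect direction
up); the four null markers are ns except one chance \* hit — the expected
behavior at a per-test α of 0.05. Each cell is "percent variance + tier +
MFA direction arrow"; the long format with exact p-values is in `res`.

The same objects feed the other stages:

```r
ld  <- ld_scan(ds$dosage_matrix)                 # chi-square LD + q-values
blk <- ld_blocks(ld)                             # same-locus blocks <= 700 bp
cns <- consensus_snps(ds$clone_table)            # >=3 clones, >=2 batches
match_haplotype(pho1a_haplotypes(),
                c("22" = "T", "322" = "A", "824" = "G", "2776" = "A"))
#> [1] "v5"   # the starch-associated cDNA allele
```

A command-line front end with `simulate`, `genotype`, `associate`, `ld`,
and `haplotype` subcommands is installed at
`system.file("cli", "tetrassoc.R", package = "tetrassoc")`.

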
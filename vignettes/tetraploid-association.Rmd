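---
title: "Dosage-based candidate-gene association analysis in autotetraploid potato"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-based candidate-gene association analysis in autotetraploid potato}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrassoc)
```

## The problem

Tuber starch and reducing-sugar content in cultivated potato are inversely
correlated quantitative traits of direct agronomic value: reducing sugars
accumulated during cold storage darken chips and fries (the Maillard
reaction), while starch content and starch yield drive industrial use.
Cultivated potato is autotetraploid, so a biallelic SNP in a candidate gene
does not come in three genotypes but in five — AAAA, AAAB, AABB, ABBB,
BBBB — and the quantity carried by each individual is an allele *dosage*
from 0 to 4. `tetrassoc` implements the full analysis chain for
candidate-gene association studies in this setting: dosage genotyping from
sequencing peak heights, dosage-class ANOVA with percent variance
explained, χ² linkage disequilibrium with FDR correction, and
clone-consensus haplotype analysis of cloned cDNA alleles, together with a
synthetic-population generator that makes every stage testable.

## Genotyping model

In amplicon Sanger sequencing of a tetraploid, a heterozygous SNP shows two
overlapping base-calling peaks whose height ratio reflects the allele
dosage (1:3, 2:2 or 3:1). The caller reduces a signal to the alt-allele
fraction $f = h_\mathrm{alt}/(h_\mathrm{ref}+h_\mathrm{alt})$ and assigns
the dosage $d \in \{0,\dots,4\}$ whose expected fraction $d/4$ is nearest.
The discretization rule (decision boundaries at the midpoints 0.125, 0.375,
0.625, 0.875) is this package's choice: the original scoring of such data
is done visually or with desktop trace software, so no published boundary
exists. Each call carries a confidence value, the distance to the nearest
centroid rescaled so that 1 means "exactly on the centroid" and 0 means "on
a decision boundary", supporting an optional no-call band. Triallelic SNPs
are assigned by exhaustive search over all 15 compositions of 4 into 3
parts, with ties broken toward the lexicographically smallest class label.

The minor frequency allele (MFA) of a dosage-scored marker has copy
frequency $\sum_i d_i / (4N)$, folded to the minor side. Marker filtering
is by MFA **carrier count**, matching reporting practice: at a population
of ~208 a 1% MFA frequency corresponds to fewer than eight simplex
carriers, so discovery mode requires ≥ 8 carrier genotypes; a validation
panel of ~40 uses ≥ 3 (the 2% rule). Presence/absence markers (SSCP or
allele-specific PCR assays scored 0/1) have no dosage; the package reports
both the carrier fraction and a simplex-assumption copy frequency and
deliberately does not assert which of the two a published "MFA %" for such
a marker corresponds to, because a copy frequency is not derivable without
dosage.

## Association model

For each retained marker × trait pair the package fits a one-way
fixed-effects ANOVA across the *observed genotype classes*:

$$\eta^2 = \frac{SS_\text{between}}{SS_\text{total}}, \qquad
  F = \frac{SS_\text{between}/(k-1)}{SS_\text{within}/(n-k)},$$

with percent variance explained $100\,\eta^2$. Genotype enters as a
categorical factor rather than a linear dosage covariate: class-wise
effects (e.g. an allele whose positive effect appears only in the
homozygous class, i.e. recessive) and direction reversals between groups
are real features of such data and a single regression slope cannot
express them. Ordinal chip scores (1–9) are analyzed as numeric responses;
a rank-based alternative (Kruskal–Wallis) is exposed via
`rank_based = TRUE` but is not the default. Dosage classes with a single
observation are merged into the adjacent class nearer in dosage before
testing — tetraploid class tables are sparse at $n \approx 200$ and a
singleton class contributes a zero-df cell; the merge is recorded in the
result.

The direction of the MFA effect is a separate derived quantity: the sign of
the count-weighted least-squares slope of class mean on MFA dosage, except
that when successive class-mean differences strictly alternate in sign and
each exceeds a tolerance $\tau$, the direction is declared *inconsistent*
(the ↑↓ of association tables). $\tau$ defaults to $0.25\times$ the pooled
within-class SD; no published value exists, so this is a documented package
default chosen so that alternations well inside noise do not trigger the
flag. Significance tiers follow the reporting map ns ($p>0.05$), \*
($0.05>p\ge0.01$), \*\* ($0.01>p\ge0.001$), \*\*\* ($p<0.001$), and a
marker is *reportable* when $p<0.01$ for at least one trait. No
multiple-testing correction is applied across markers in the association
scan — the fixed $p<0.01$ reporting threshold is the convention this
pipeline mirrors; FDR correction is used in the LD module. Validation mode
log10-transforms traits whose metadata declares it (reducing-sugar
content, mg/100 mg dry weight); nonpositive values are a domain error
rather than a silent offset.

## Linkage disequilibrium

Gametic LD coefficients ($D'$, $r^2$) require phased haplotypes, which
unphased tetraploid dosage data cannot provide. The package therefore
tests *independence of genotype-class distributions*: a χ² test on the
$r \times c$ contingency table of dosage classes with
$(r-1)(c-1)$ df and no continuity correction, which is phase-free and
information-preserving. Classes with expected counts below 1 are pooled
with the adjacent dosage class (the tables are sparse at $n \approx 200$);
a warning marks remaining cells below 5. The composite dosage correlation
$r$ is attached as an effect size. Under four independent haplotype draws
per individual the expected dosage correlation for haplotype-level
disequilibrium $D$ is $D/\sqrt{p_1 q_1 p_2 q_2}$, which the simulation
tests verify against an enumeration of the two-locus haplotype
distribution.

P-values are corrected to q-values either by Benjamini–Hochberg step-up
(default; monotone, $q \ge p$) or by Storey's method with $\hat\pi_0$
estimated on a λ grid with spline smoothing — for families under 100 tests
the smoother is unstable and the implementation falls back to the
conservative $\pi_0 = 1$, making it BH-equivalent there. Both corrections
are implemented because the correction reference in the motivating
literature is ambiguous; the method used is recorded in the output.
Same-locus markers connected by pairs with $q \le 0.05$ and distance
≤ 700 bp (strong LD blocks in candidate-gene amplicons span up to roughly
700 bp) are grouped by single linkage, and each block nominates its
lowest-position marker as representative for reporting.

## Clone-consensus haplotype analysis

Cloned PCR products accumulate polymerase and sequencing errors, so the
consensus rule accepts a variant only when it is carried by **≥ 3 clones
from ≥ 2 distinct amplification batches**. "Two independent
amplifications" is interpreted as ≥ 2 distinct batch ids *among the
carrying clones*, not merely two batches in the experiment — the stricter
and, we argue, intended reading. With a per-base error rate of $10^{-3}$
and ≤ 50 clones, the probability that the same singleton error recurs in
three clones across two batches is negligible ($<10^{-4}$), which the test
suite verifies by simulation.

The bundled 15-position × 9-variant PHO1a cDNA SNP matrix
(`pho1a_haplotypes()`) drives the worked examples: 9 pairwise-distinct
haplotypes; 8 SNPs at non-third codon positions, coinciding exactly with
the amino-acid-change annotations; pattern
`{22:T, 322:A, 824:G, 2776:A}` identifying variant 5 (the allele
associated with increased tuber starch content). Coordinate arithmetic is
the fixed contract residue $= \lfloor(\text{pos}-1)/3\rfloor+1$ on ORF
coordinates. One bundled annotation (position 2795, labelled Thr923Lys)
disagrees with this arithmetic, which places the site in residue 932;
`annotation_check()` flags the inconsistency and the package deliberately
does not guess which label was intended — alternative residue-numbering
conventions (signal-peptide offsets) cannot be resolved from the source
material.

## The synthetic-population generator

The generator exists so that calibration and parameter-recovery claims are
testable. Its defaults are the study conditions the pipeline is designed
for, not tuning knobs:

* **Population sizes**: 208 individuals in discovery mode, 40 in
  validation mode.
* **Tetrasomic dosages**: Binomial(4, p) per marker — random chromosomal
  segregation without double reduction, the simplest model consistent with
  the five-class representation (no pedigree information exists to
  estimate a double-reduction rate).
* **Two-locus LD**: four independent haplotypes per individual drawn from
  $(p_1p_2+D,\; p_1q_2-D,\; q_1p_2-D,\; q_1q_2+D)$, with admissibility
  $\max(-p_1p_2, -q_1q_2) \le D \le \min(p_1q_2, q_1p_2)$ enforced.
* **Traits**: $y = \mu + \beta d + \varepsilon$ with β calibrated against
  the sample variance of the supplied dosages so the dosage term accounts
  for a target fraction of variance (the percent-variance scale of the
  association output). Ordinal chip scores are produced by
  equal-probability binning of the latent Gaussian into nine categories —
  no published latent model exists, so this is a generator choice, not a
  claim about real chip scoring.
* **Peak signals**: noise-free ratio $d : (4-d)$ with multiplicative
  log-normal noise of stated CV (default 0.05). Real trace reading is
  manual/visual; the noise model is a knob, not a data claim.
* **Clone tables**: 161 clones in 3 batches at error rate $10^{-3}$ by
  default, matching the scale of a full-length cDNA cloning experiment.

What the generator does **not** emulate: population structure and kinship
(the association model fits none), double reduction, genotyping error
correlated across markers, chromatogram traces, and pedigrees. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to confounding in real germplasm.

## Numerical and design notes

* All simulation functions take an explicit seed and restore the caller's
  RNG state; a whole dataset is reproducible from the single seed in
  `simulation_config()`.
* η² recovery at desk scale: over 200 replicate populations of 208
  individuals with MFA 8.5% and a true causal variance fraction of 0.199,
  the mean estimated percent variance is within 2 percentage points of
  19.9 — raw η² carries an upward bias of roughly $(k-1)(1-R^2)/(n-1)$
  (about one point here), which the band accommodates. The replicate count
  and population size are chosen to make this a minutes-scale check.
* Type-I error: at a true variance fraction of 0, the fraction of tests
  with $p < 0.01$ sits inside the 99% binomial interval around 0.01 over
  2500 simulated tests, and LD p-values under $D = 0$ pass a
  Kolmogorov–Smirnov uniformity check over 2000 pairs.
* Degenerate inputs have defined behavior throughout: zero total trait
  variance gives $\eta^2 = 0,\ p = 1$; a single genotype class is *not
  testable* (distinct from ns); monomorphic markers are not testable in
  LD; all-zero peak signals are an error.
* Missing data: association tests drop incomplete pairs per test;
  frequencies and filters use non-missing counts; markers with > 20%
  missing calls are flagged by `missingness_report()`; concordance
  excludes missing pairs rather than counting them as mismatches.

## Limitations

The ANOVA is a fixed-effects model without kinship or structure
correction, appropriate for the germplasm collections this design targets
but not a general GWAS engine. The LD test measures genotype-class
dependence, not gametic disequilibrium. Presence/absence markers cannot
yield copy frequencies. The exact ANOVA flavor used by older desktop
analyses (parametric vs rank-based) is not always documented; both are
available here, parametric by default.
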
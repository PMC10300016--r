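---
title: "Screening for recessive lethal haplotypes by depletion of homozygotes"
author: "lethalscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for recessive lethal haplotypes by depletion of homozygotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A recessive lethal allele kills homozygous embryos before birth (often
before implantation), so it is never observed in an affected animal: the
only genotyped individuals are apparently normal heterozygous carriers.
In livestock populations with heavy artificial-insemination use, a single
popular sire can spread such an allele widely. The screen implemented
here looks for the allele's footprint in phased genotype data: a marker
haplotype whose population frequency predicts tens or hundreds of
homozygotes among the genotyped animals, yet for which **zero**
homozygotes are observed. Downstream, the same regions are tested for
association with binary reproduction and survival traits — heifer
rebreeding (HR), stayability (STAY) and post-natal mortality (PNM) —
because a lethal's marker neighbourhood often drags correlated effects on
fertility and calf survival.

## The depletion test

Let $N$ be the number of genotyped animals, and for a given segment
haplotype let $n_c$ be its carrier (heterozygote) count. With
homozygotes absent, the haplotype frequency is $f = n_c / 2N$ and the
carrier frequency $C = n_c / N = 2f$.

**Simple method (random mating).** The expected homozygote count is
$$E[\mathrm{hom}] = N C^2 / 4 = N f^2,$$
and the probability of observing zero homozygotes is of the form
$(1 - x^2/4)^N$. Two conventions exist for $x$:

* **carrier convention** $x = C$, which gives $(1 - C^2/4)^N =
  (1-f^2)^N$ — the exact random-mating (Hardy–Weinberg) null, since
  each animal is homozygous with probability $f^2$;
* **haplotype convention** $x = f$, giving $(1 - f^2/4)^N$, the form in
  which large published cattle screens print their tables.

`phh_simple()` computes the functional form for whichever frequency the
caller supplies and records the convention; the report and filter default
to the haplotype convention so that published candidate tables are
reproduced exactly. The haplotype convention is *conservative*: it
overstates the zero-homozygote probability, so fewer chance candidates
pass the $P_{hh} < 0.6$ condition. The package's false-positive
calibration tests use the carrier convention because that is the true
null; both are exposed.

**Mating method (realized matings).** Dams are rarely genotyped, so the
dam's haplotype is tracked through her sire (the animal's maternal
grandsire, MGS). Each genotyped animal whose sire and MGS are both
carriers is one Bernoulli trial with homozygote probability $1/4$
(maternal-granddam and maternal-grandsire frequencies assumed equal).
With $n_m$ such progeny, $E[\mathrm{hom}] = n_m/4$ and
$P_{hh} = 0.75^{n_m}$. Animals with an unknown sire, dam, or dam's sire
are not counted, which is why heavily masked pedigrees push the mating
expectation below the simple one. Both probabilities are evaluated in log
space; $0.75^{1028} \approx 3.7\times10^{-129}$ is representable without
underflow.

**Filter.** A haplotype is a candidate when (1) its haplotype percentage
$100f$ exceeds 2, (2) the simple-method expectation exceeds 1, and
(3) both zero-homozygote probabilities are below 0.6, with zero observed
homozygotes. Whether the published screens required both probabilities or
either one is not documented; this package requires both, the stricter
reading, because in the printed tables the mating-method probability is
the binding one for several retained rows (so both-required is consistent
with what was retained).

## Segmentation and haplotype identity

Chromosomes are partitioned into `ceiling(M / 200)` contiguous segments
whose sizes differ by at most one marker, longer segments first — for
about 200-marker-multiple chromosomes this reproduces the 194–200 marker
range observed in large screens, and it is defined for any marker count
(short chromosomes simply yield shorter segments; the 194–200 band is an
observed property, not a constraint). Haplotypes are exact allele
strings over a segment — no mismatch tolerance — because the counting
semantics of the depletion test require exact identity. Within a segment
haplotypes are numbered by descending copy count with lexicographic
tie-break, giving stable `segment.haplotype` ids. Marker indices are
half-open and 0-based internally; bp positions are 1-based as in VCF.

## The synthetic population

Real screens of this kind run on proprietary breeding-program data, so
the package carries a gene-drop generator whose defaults emulate the
statistical structure such data have:

* discrete generations with a small number of heavily reused sires
  (artificial insemination), founders drawn with per-marker allele
  frequencies uniform on $[0.05, 0.95]$;
* a planted lethal: a fixed allele string written onto a configurable
  fraction of founder haplotype copies (default 6%, about 10–11%
  carriers); an individual with two matching haplotypes dies *before
  genotyping*, so the genotyped set contains zero homozygotes by
  construction — the depletion test only ever sees survivors;
* recombination: Poisson(1) crossovers per chromosome per meiosis at
  uniform bp positions. The lethal window (default 10 of 300 markers)
  is deliberately a small fraction of the chromosome: a crossover inside
  the window destroys the carrier string, so wide windows would decay
  the haplotype frequency by tens of percent per generation, which is
  not how a sub-Mb haplotype on a ~1 Morgan chromosome behaves;
* pedigree masking: after mating, sire and dam fields are set to unknown
  with probabilities 0.404 and 0.187 (the reported rates in large
  Nellore pedigrees, where multiple-sire matings leave sires unrecorded).
  True parentage always drives transmission and breeding values; only
  the *reported* pedigree is masked. Unknown dams are treated as
  base-population founders. Multi-sire matings are represented solely by
  this masking — no explicit sire groups — because only the sire/MGS
  links matter downstream;
* binary traits from a liability threshold model: liability
  $l = \mathrm{cg} + a + e$ with contemporary-group effects
  $N(0, 0.5^2)$, pedigree-consistent breeding values with
  $\sigma^2_a = h^2/(1-h^2)$ (defaults $h^2$ = 0.31 / 0.33 / 0.41 for
  HR / STAY / PNM), standard-normal residual, and the threshold set so
  that the marginal incidence matches 59.3% / 47.4% / 2.1%;
* optionally, a PNM liability penalty for calves of two carrier parents
  (default off), so the association stage has a true signal: the lethal
  itself acts strictly pre-genotyping and leaves no post-natal trace.

What the generator does **not** emulate: realistic linkage
disequilibrium and haplotype-block structure (founder alleles are
independent across markers), marker-panel heterogeneity and imputation,
and selection across generations. Consequently, passing tests show that
the statistics and algorithms behave correctly under their stated
assumptions — not that the screen's power on real LD structure equals
what is reported for real populations.

## Pedigree algebra

Inbreeding coefficients use the Meuwissen–Luo recursion (compiled);
unknown parents are unrelated founders with $F = 0$ and no
unknown-parent groups are fitted — the simplest model consistent with
unknown dams joining the base population, recorded here as a limitation.
A-inverse is built directly by Henderson's rules with the Quaas
adjustment for parental inbreeding (the default; the unadjusted variant
is available since it is not documented which the original analyses
used). On small pedigrees the adjusted A-inverse reproduces the inverse
of the dense tabular relationship matrix to $10^{-8}$.

## The liability threshold model

EBVs come from the single-trait threshold animal model
$l = X\beta + Za + e$, $a \sim N(0, A\sigma^2_a)$,
$e \sim N(0, I)$, fitted by single-site Gibbs sampling with data
augmentation: truncated-normal liabilities given the binary records,
normal conditionals for CG and animal effects against the sparse
A-inverse, and a scaled inverse chi-square conditional for
$\sigma^2_a$. Identifiability is resolved by fixing $\sigma^2_e = 1$
and the threshold at 0; the reported $h^2 = \sigma^2_a/(\sigma^2_a+1)$
is scale-free. Priors: flat on $\beta$, scaled inverse chi-square
($\nu = 4$, $S = 0.25$) on $\sigma^2_a$ — weakly informative around
$h^2 \approx 0.3$. Chain defaults are 20,000 iterations, 4,000 burn-in,
thinning 10; the package's own tests use shorter chains at their stated
problem sizes. Reliabilities are $r^2 = 1 - \mathrm{PEV}/\hat\sigma^2_a$
with PEV the posterior variance of the animal effect, matching the
"based on prediction error variance" accuracy rule.

**A documented hazard.** With a single binary record per animal, flat
priors on many small contemporary groups, and an effect for every
animal, the threshold model's posterior for $\sigma^2_a$ is inflated and
can diverge (the classical small-subclass / extreme-category problem;
any sign pattern is separable at large scale, so the likelihood does not
penalise it). This was verified to be a posterior property, not a
sampler artifact, by comparing the single-site chain against a blocked
sparse-MME sampler. In this package's experiments, contemporary groups
of ~250 records recover $h^2$ essentially unbiasedly, ~100 give a bias
of +0.04–0.09, and ~25 diverge (flagged via `sig2a_cap`). The editing
rule (groups under 5 records or without variation removed) eliminates
the worst cases; heritability-recovery tests use 20 groups at
N = 5,000 with a complete pedigree so the estimand is identified. Users
fitting small CGs should treat reported $h^2$ with caution — EBV
*rankings* are much less affected.

## Deregression

GWAS responses are deregressed EBVs: the parent-average contribution is
removed via the 2×2 animal/parent-average mixed-model equations. Writing
$\lambda = (1-h^2)/h^2$, $q_i = 1 - r^2_i$, $q_{PA} = 1 - r^2_{PA}$
(with $r^2_{PA} = (r^2_s + r^2_d)/4$), the equations' diagonals follow
in closed form
$$B = \lambda\,\frac{1 + \sqrt{1 + 16\,q_{PA}q_i}}{2q_i},\qquad
A = B\,\frac{q_i}{q_{PA}},$$
with $Z_i'Z_i = B - 2\lambda$; the deregressed information is
$y_i/Z_i'Z_i$ with $y_i = -2\lambda\hat g_{PA} + B\hat g_i$, its
reliability $Z_i'Z_i/(Z_i'Z_i+\lambda)$, and the analysis weight
$(1-h^2)/\{(c + (1-r^2_{dEBV})/r^2_{dEBV})h^2\}$ with $c = 0.5$ by
default (the fraction of genetic variance not captured by markers; the
source analyses do not state their value). Animals with both parents
unknown reduce to the $\mathrm{EBV}/r^2$ scaling; animals whose own
reliability does not exceed what the parent average alone provides
($Z_i'Z_i \le 0$) are skipped — with sparse binary data this is common
and expected. The accuracy floor is $\sqrt{r^2_{dEBV}} \ge 0.40$,
boundary inclusive.

## Association and annotation

Each marker is tested by ordinary least squares with intercept,
$y^* = \mu + b x + e$, $x \in \{0,1,2\}$ copies of the VCF alternate
allele; $t = \hat b/SE(\hat b)$ and the two-sided p-value uses the $t$
distribution with $n-2$ degrees of freedom (a normal-tail variant is
available by flag; the $t$ tail is the default reading of the
cumulative-function notation used in the field). Significance is the
fixed printed rule $-\log_{10} p > 6$, applied as printed rather than
recomputing $0.05/M$ — at desk-scale marker counts the two differ, and
the fixed rule is what the screen this package models used. Candidate
haplotypes are tested identically with carrier dosage (0/1; homozygotes
absent by construction). Monomorphic markers are flagged not-testable.
Gene annotation collects genes within ±100 kb of each significant
marker, boundary inclusive, after harmonising `chr`/`BTA` chromosome
prefixes; mismatched chromosome names raise an error instead of silently
dropping.

## Problem sizes and test design

The test-suite and acceptance runs use sizes chosen to exercise the
claims while staying desk-scale: planted-lethal recovery on populations
of ~20,000 genotyped animals (~10–11% carriers) over 20 seeds;
false-positive calibration on single-generation populations from
unrelated founders (later generations mate relatives, whose genuine
inbreeding exceeds the random-mating homozygosity null — outside what
that calibration measures); heritability recovery at N ≈ 5,000 with
20 contemporary groups and three replicates per true value; GWAS null
calibration at 10,000 markers × 20 seeds. Published-table arithmetic is
checked from the printed carrier and mating-pair counts at printed
precision (the source worked from rounded frequencies, so integers may
differ by one count and probabilities by a few percent on the log scale).

## Known limitations

* No phasing or imputation: the pipeline requires complete phased input
  and errors otherwise.
* Pedigree-only EBVs; no genomic relationship matrix or single-step
  evaluation.
* No unknown-parent groups; unknown parents are base founders.
* The GWAS stage fits a fixed-SNP model on dEBVs without
  population-structure correction, as in the screen it models.
* Functional enrichment (GO/KEGG) is out of scope; only the ±100 kb
  gene-window extraction is implemented.
* At desk-scale sample sizes the GWAS stage rarely reaches
  $-\log_{10} p > 6$; the analysis scripts report this honestly rather
  than lowering the threshold.
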
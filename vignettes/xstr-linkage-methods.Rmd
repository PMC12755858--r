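---
title: "Methods: trio-based recombination analysis of X-STR linkage groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based recombination analysis of X-STR linkage groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xstrlink)
```

## Inheritance model

X-STR transmission has an asymmetry that this package exploits throughout.
Outside the pseudoautosomal regions a son carries a single, entirely maternal
X; every allele he shows was transmitted by his mother. A daughter carries one
X from each parent, and because her father is hemizygous, his allele can be
subtracted from her genotype: if she is heterozygous `a/b` and her father
carries `b`, her maternal allele is `a`. Subtraction fails only when the
father's genotype is missing (the meiosis is *undetermined*, never guessed)
or when no consistent assignment exists (a *Mendelian error*, dropped from
inference and tallied). Consequently a mother–son duo suffices, and a
mother–father–daughter trio is needed only for female children.

### Region-origin calling from flanking SNPs

Given phased maternal SNP genotypes, the maternal haplotype-of-origin of the
chromosomal region harbouring a target STR is read from the SNPs in two
flanking windows, `[start - w, start - 1]` and `[end + 1, end + w]`
(`w = 10` kb by default). Each SNP at which the mother is heterozygous and
the child's maternal allele is determined casts a vote — `HAP1` if the
transmitted allele equals the first allele of the mother's phased genotype,
`HAP2` otherwise. A segment verdict requires at least one vote; with zero
votes (mother homozygous throughout the window) the segment is
uninformative. The default rule also requires unanimity: any conflicting
vote makes the segment `DISCORDANT`. Conflicts can arise from genotyping or
phasing error, or from a crossover/gene-conversion inside the window itself,
and none of these should be resolved by majority on a handful of SNPs; a
majority-vote mode exists (`conflict = "majority"`) but is off by default.

The two segment verdicts then combine: only when the upstream and downstream
segments were synchronously transmitted from the *same* maternal haplotype is
the region assigned that haplotype. Opposite verdicts localise a crossover
within the span of the STR itself, which makes the STR's own phase ambiguous
— such trios are conservatively `EXCLUDED` for that locus, and so is any trio
with a discordant segment. Everything else is `UNINFORMATIVE`. For every
locus pair the three outcome classes partition the cohort
(informative + uninformative + excluded = total), which the test suite
asserts as an invariant.

Recombination between two loci is then a pure counting problem: among trios
with definite verdicts at both loci (*n* informative), those whose verdicts
differ (*k*) are recombinant, and the fraction *k/n* gets an exact
Clopper–Pearson interval. Between-group estimates use the junction pair of
each adjacent group pair — the last locus of one group and the first locus of
the next — because those two anchor the interval across which a crossover
separates the groups. Within-group adjacent pairs are available behind
`within = TRUE`.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_bp` | 10 000 | bp | matches the typical LD-block scale of the human genome; large enough to contain heterozygous SNPs in most mothers, small enough that double crossovers within a window are negligible |
| `maf_min` (trio calling) | 0.2 | fraction | a site is only useful when the mother is heterozygous (probability 2p(1−p)); high-MAF sites maximise informativeness per site |
| `maf_min` (LD decay) | 0.05 | fraction | the conventional decay-curve filter; rare alleles make r² unstable |
| `alpha` | 0.05 | — | 95% intervals throughout |
| `mendel_max` | 0.1 | fraction | a trio whose Mendelian-error rate across assessed sites exceeds 10% likely has a sample swap or pervasive genotyping error and is excluded wholesale rather than site by site |
| `bin_width` / `max_dist` | 500 / 300 000 | bp | decay curves change on the kb scale; 500 bp bins resolve a crossing near 4 kb to ±1 bin |

MAF is always recomputed from the supplied cohort's allele counts rather than
taken from VCF `INFO`, so the filter means the same thing on real and
simulated panels.

Male X genotypes are accepted in both encodings that public phased releases
mix — haploid (`1`) and homozygous-diploid (`1|1`) — and normalised to a
single allele. A *heterozygous* diploid call in a male is impossible on the
non-PAR X and is flagged as a per-site Mendelian inconsistency, never used
silently. Missing genotypes (`./.`) exclude the site for that trio only.

## Two-point likelihood for family STR data

STR genotypes from two-generation families are unphased, so the mother's
two-locus phase is a latent variable shared by all her meioses. For a mother
heterozygous at both loci, her two possible phase configurations are
mirror images; a meiosis transmitting a two-locus pair on configuration 1's
haplotypes is phase-consistent there and phase-inconsistent under
configuration 2. With *c* of *m* informative meioses consistent with
configuration 1, the family's marginal likelihood is

$$L_f(\theta) = w_1\left(\tfrac{1-\theta}{2}\right)^{c}\left(\tfrac{\theta}{2}\right)^{m-c}
             + w_2\left(\tfrac{1-\theta}{2}\right)^{m-c}\left(\tfrac{\theta}{2}\right)^{c},$$

and the cohort log-likelihood sums over families. Modelling the phase per
mother (not per meiosis) captures the within-family dependence that naive
recombinant counting ignores. The phase prior $w$ deserves a note: under
linkage equilibrium the prior of each configuration is the product of its
haplotypes' allele frequencies, and for the two configurations of a
double-het mother those products are *identical* — so the LE prior provably
reduces to the uniform ½/½ default, and allele frequencies need not be
supplied. The `phase_prior` argument remains for the phase-known limit: as
one weight tends to 1, the ML estimate collapses to the recombinant
proportion, which the tests verify to 1e-6.

$\hat\theta$ maximises the likelihood on $[0, 0.5]$ and
$\mathrm{MLOD} = \log_{10} L(\hat\theta) - \log_{10} L(0.5) \ge 0$, with
MLOD > 3 the conventional significance threshold and MLOD = 0 exactly at
$\hat\theta = 0.5$. Two useful closed forms anchor the tests: a single
informative meiosis has constant likelihood ¼ (phase absorbs everything, no
linkage information), and *n* phase-unknown, no-recombinant meioses in one
family give $\mathrm{MLOD} = (n-1)\log_{10} 2$. Map distances use the
Kosambi function $d = \tfrac14 \ln\frac{1+2\theta}{1-2\theta}$ (reported in
cM; $\theta = 0.5$ reports `NA`), whose inverse round-trips to 1e-9.

A meiosis transmitting an allele absent from the mother is flagged as a
Mendelian inconsistency — most plausibly an STR mutation — and excluded from
$\theta$ estimation rather than modelled: distinguishing a within-group
recombinant from a single-step mutation is genuinely hard in two-generation
data, and the package prefers a clean estimand with a QC tally over a joint
mutation model.

## Numerical choices

* **Clopper–Pearson by bisection.** The bounds solve the exact binomial tail
  equations by bisection to 1e-10 on the proportion scale (the
  beta-quantile closed form serves as an independent cross-check in the
  tests). `k = 0` and `k = n` short-circuit to 0 and 1; `n = 0` yields an
  `NA` interval, not an error.
* **Optimiser.** `stats::optimize` on $[0, 0.5]$ with tolerance 1e-6; both
  boundary values are evaluated explicitly since the optimum frequently sits
  at 0 or 0.5, and likelihood ties within 1e-9 resolve toward 0.5 (the
  conservative, no-linkage direction).
* **Fisher's exact test** uses the probability-mass two-sided rule (sum of
  tables no more probable than observed); degenerate margins give p = 1.
* **Decay crossing** is reported as the midpoint of the first bin whose mean
  r² falls to or below the threshold, with no interpolation; an analysis
  that interpolates would report slightly smaller distances, which is why
  crossings here are read as bin-resolution estimates.

## What the simulator emulates — and what it does not

`simulate_trio_cohort()` reproduces the structure the trio method consumes:
602 trios by default, SNPs placed at 1/kb inside the flanking windows of the
25-locus/7-group layout (sites outside the windows enter no analysis and are
not generated), allele frequencies uniform on [0.05, 0.5], founders in
linkage equilibrium, and a no-interference crossover process — each
inter-locus interval switches haplotype independently with its map
probability ($\theta = 0.5$ between groups, 0.02 within, by default).
Interference is irrelevant to the estimand (a between-locus switch
indicator), which is why the simpler process suffices. The truth table
records every transmitted haplotype, so estimates can be checked against
realised crossovers, not just the generating parameter.
`simulate_str_families()` mirrors the canonical 66-family composition table
(22 father–mother–two-daughter families, 21 mother–two-son families, ...)
with LE haplotypes and optional single-step mutations.
`simulate_ld_panel()` generates founder-mosaic haplotypes whose equilibrium
r² decays as $(1-2\rho)^{2d}$; the default per-bp switch rate places the
r² = 0.1 crossing at 3.7 kb, the scale observed for X-chromosome SNP panels.

What passing tests on these cohorts demonstrate is therefore the
*inferential machinery*: verdicts equal brute-force enumeration, estimates
recover known $\theta$ across a grid, exclusion logic conserves trios, the
pipeline round-trips through VCF/PED files. What they cannot demonstrate is
robustness to features real cohorts add on top — phasing switch errors,
genotyping error, realistic site-frequency spectra and LD between flanking
SNPs, population structure, or real gene-conversion tract distributions
(a stylised gene-conversion mode exists behind
`gene_conversion_rate`, producing the expected conservative exclusions, but
it is a caricature of the real process). Published cohort-scale counts from
real phased trio data are accordingly *not* reproduction targets of the test
suite; the suite substitutes property-based checks at sizes chosen for
statistical power: 300-trio cohorts per $\theta$ grid point, a 600-trio
end-to-end run, 1000-haplotype LD panels, 2000-replicate coverage
simulations — all of which complete in seconds.

## Known limitations

* Crossovers are localised only to "between locus A and B"; no finer
  mapping, and gene conversion is excluded, not detected.
* The two-point engine handles two-generation families with one latent phase
  per mother; it is not an Elston–Stewart implementation for arbitrary
  pedigrees, and no mutation model is fitted.
* LD estimation is haplotype-based only; unphased genotype input would
  require an EM step that is deliberately out of scope because the intended
  inputs are phased.
* Overlapping flanking windows of near-adjacent loci are allowed and each
  locus is called independently; a crossover in the shared region can
  legitimately exclude both loci.
* The exact interval is conservative (coverage ≥ 95%); users comparing
  against asymptotic intervals from other tools should expect wider bounds
  here.
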
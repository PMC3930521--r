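---
title: "Models and methods behind geelbek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geelbek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`geelbek` implements the complete two-marker population-genetic workflow used
to test whether a warm-temperate coastal fish is split into anciently isolated
populations on either side of a perennial upwelling barrier: mitochondrial
control-region diversity and distance-based differentiation, microsatellite
F-statistics, demographic inference from the mismatch distribution, haplotype
networks, and a coalescent generator that reproduces the statistical structure
of such data so the whole pipeline is testable without any downloads. This
vignette documents the models, the defaults and why they were chosen, the
numerical decisions, and the limits of what the synthetic checks demonstrate.

## Data model

All user-facing functions take plain tibbles. An alignment is a tibble
`(id, seq)` of equal-length sequences over `A,C,G,T,-,N` (other IUPAC codes
are accepted and treated as `N` in every statistic). Genotypes are long
tibbles `(id, locus, allele_1, allele_2)` with allele sizes in bp and fully
missing pairs for no-calls; GenePop (2- and 3-digit) and a `"152/154"` TSV
dialect are parsed losslessly. The population map `(id, site, group)` carries
the two-level sampling design (site nested in region).

Site handling follows the convention of the standard AMOVA software:
columns containing a gap or ambiguity in *any* analysed sequence are excluded
("comparable sites") for haplotype collapsing, the site counts and diversity
indices, while pairwise distances use pairwise deletion. This makes haplotype
and variable-site counts auditable: `H` is exactly the number of distinct rows
of the alignment restricted to comparable sites.

## Diversity and distances

Haplotype diversity is the unbiased `h = n/(n-1) (1 - sum p_i^2)`; nucleotide
diversity is the mean per-site difference over all pairs. Sequence distances
offer raw differences, p-distance, and Kimura's two-parameter model
`d = -ln(1-2P-Q)/2 - ln(1-2Q)/4`, with saturated pairs flagged as infinite
rather than silently dropped. The substitution model is fixed rather than
selected: for control-region data of this kind K80 is the conventional
choice, and model selection is out of scope.

## AMOVA and permutation inference

The hierarchical AMOVA partitions *squared* molecular distances among groups,
among populations within groups, and within populations
(Excoffier–Smouse–Quattro variance components). The supplied distance matrix
is consumed directly as the matrix of squared distances — the convention of
the field's reference implementation — so a matrix of raw pairwise
differences reproduces the classical pairwise-difference variance partition
exactly (this identity is enforced in the tests against an independently
coded brute-force partition). Negative variance components are reported
as-is and enter the percentage normalization, again matching reference
behaviour. When every group contains a single population the
among-populations stratum vanishes and the design collapses to the one-level
partition over groups, so `Phi_CT` coincides with the one-level `Phi_ST`.

Permutation schemes are level-appropriate: individuals among populations for
`Phi_ST`, individuals among populations within groups for `Phi_SC`, whole
populations among groups for `Phi_CT`. P-values use the `+1` estimator
`(1 + #{null >= obs}) / (1 + n_perm)` and so are never exactly zero; the
default `n_perm` is 10,000. Every permutation stream is derived
deterministically from the master seed plus a test label (and the pair names
for pairwise matrices), so results do not depend on evaluation order.

One caveat documented because it matters in practice: exact uniformity of
permutation p-values under panmixia holds only when the statistic is
effectively continuous. Low-diversity samples with many shared haplotypes
produce ties and hence conservative (upward-shifted) p-values — a property
of the estimator, not a defect; the uniformity test therefore uses
high-diversity simulated data and K80 distances.

## Microsatellite statistics

Per-locus summaries use the unbiased expected heterozygosity
`(2n/(2n-1))(1 - sum p^2)`, observed heterozygosity, and Weir–Cockerham's
within-population `f` (`F_IS`); the multilocus `F_IS` is the
component-summed (weighted) estimator, not a mean of per-locus values.
Allelic richness is rarefied combinatorially to `2g` genes using genes
actually scored; the default `g` is the smallest per-locus per-site sample,
mirroring the "minimum number of individuals" convention of FSTAT-style
tables.

Differentiation uses Weir & Cockerham's theta (per-allele `a, b, c`
components summed over alleles and loci) with significance by permuting whole
multilocus genotypes among populations — the permutation unit is the
individual, preserving within-individual associations. Jost's `D` uses the
Nei–Chesser corrected heterozygosities per locus and the variance-corrected
harmonic mean `1/(1/A + V/A^3)` across loci after clamping negative per-locus
values to zero; the plain harmonic mean is undefined the moment any locus has
`D = 0`, and this approximation is what the reference SMOGD implementation
computes. Raw (unclamped) per-locus values are retained in the output.

Hardy–Weinberg testing is a Monte-Carlo exact test that shuffles the `2n`
observed alleles into random diploid genotypes; the default statistic is the
one-sided homozygote count, because heterozygote deficits (inbreeding, null
alleles) are the alternative of scientific interest here; a two-sided variant
is available. Linkage testing permutes one locus's genotypes among
individuals and scores the G statistic of the two-locus genotype table. The
null-allele estimator is a single-null-class EM under Hardy–Weinberg with a
truncated likelihood (null homozygotes unobserved); it is a deliberate,
documented simplification of exact multi-class schemes and recovers injected
null frequencies to within a few percent in the tests.

## Power simulation

The drift-based power design: the number of generations needed to reach a
target differentiation is the closed form
`t = ceil(ln(1-F_ST)/ln(1-1/(2Ne)))`; each replicate drifts the base allele
frequencies independently per population by multinomial resampling of `2Ne`
genes for `t` generations, draws sample allele counts, tests homogeneity per
locus (chi-squared by default; Fisher's exact available — the chi-squared
default needs adequate expected counts to hold its nominal level, which the
type-I-error check respects by using moderate allele numbers), and combines
loci with Fisher's method. Power at a target of zero estimates the type-I
error.

## Neutrality tests and demographic inference

Tajima's `D` uses the standard constants; Fu's `F_S` computes
`S' = Pr(K >= k_obs)` under the Ewens sampling distribution with
`theta = theta_pi` (the convention of the reference implementation), using
the unsigned-Stirling recurrence entirely in log space so samples of 100+
sequences are exact to machine precision (verified against exact rational
enumeration for small n). Significance for both comes from neutral
constant-size coalescent simulation conditioned on the sample size and
`theta_pi` — not on `S` — with 1,000 replicates by default; `D` is tested
two-sided, `F_S` one-sided (`Pr(sim <= obs)`).

The sudden-expansion model treats the pairwise coalescence time as
exponential at rate `1/theta1` more recently than `tau` (mutational units)
and `1/theta0` beyond; the expected mismatch probabilities are computed
*exactly* via incomplete-gamma integrals of the Poisson mutation kernel over
that piecewise density, rather than by series truncation. At `tau = 0` the
curve reduces to the geometric equilibrium with mean `theta0`. Fitting
minimizes the SSD between observed and expected frequencies over a coarse
grid followed by Nelder–Mead on log-transformed parameters (enforcing
`0 <= theta0 <= theta1`, `tau >= 0`); the goodness-of-fit p-value and the
parameter CIs come from a parametric bootstrap that re-simulates coalescent
samples under the fitted history and refits. Percentile intervals are used:
with the mildly biased least-squares `tau` estimator they empirically cover
better than basic (reflected) intervals under this model.

Time conversions keep both unit systems honest. With a between-lineage
divergence rate `r` %/My and sequence length `L`, `u = (r/100/1e6) L`
substitutions per sequence per year and `t = tau/(2u)` years; the result is
reported **both** in years and in generations because mixed conventions in
the literature differ by exactly the generation time, and back-calculation
of published values is not always possible under a single convention. The
sampler conversions follow `theta = x Ne mu` and `M = m/mu` (`x` = 1 for
mtDNA, 4 for nuclear loci), with effective migrants reported both as
`theta*M` (= `x Ne m`) and `theta*M/x`. The net-divergence clock
`T = (dxy - mean within)/ (r/100)` is a labelled surrogate for a calibrated
genealogical dating — it ignores coalescent stochasticity and should be read
as an order-of-magnitude check only.

## Median-joining networks

The network builder follows the Bandelt–Forster–Röhl scheme: an
epsilon-relaxed minimum spanning network over Hamming distances at variable
sites, iterative insertion of consensus (median) vectors for linked triplets
at minimal connection cost, acceptance only when the network does not
lengthen, and pruning until every median has degree at least three. Defaults
are `epsilon = 0` and equal site weights (the defaults of the standard
desktop tool). Two deliberate simplifications: columns where all three
triplet members disagree take the lexicographically smallest state (full
quasi-median expansion generates combinatorially many vectors for negligible
benefit on non-recombining data), and "shortest tree" selection by abundance
is provided as information in the node/edge tables rather than as automated
pruning. Haplogroups are single-linkage clusters of observed haplotypes at a
path-length threshold, and the package reports both the network bridge
length and the minimum raw inter-group Hamming distance, since the two need
not coincide.

## The synthetic-data generator

The generator's defaults *are* the study conditions. Sequences: two demes
merging 909,000 generations ago (about 2 My at a 2.2-year generation), no
migration, 583 bp, per-site mutation rate 4e-8 per generation (a 1.8%
per-lineage per-My control-region rate at that generation time),
transition:transversion ratio 10, and per-site sample sizes
(20, 17, 20, 20, 20, 7 | 20, 20) matching the sampling design. Effective
sizes (62,500 and 100,000 gene copies) were chosen once so that
`theta = 2 Ne mu` reproduces the observed per-site nucleotide diversities
(~0.005 and ~0.008); they are mutation-scaled coalescent sizes and are not
comparable to census or sampler-reported `Ne`. The default single-population
expansion block re-expresses the fitted northern history
(`theta0` 1.24 → `theta1` 7.3 at `tau` 2.5) in generations at the same
mutation rate. Microsatellites: eight loci on a dinucleotide ladder,
Dirichlet base frequencies, group-level drift for the number of generations
that targets `F_ST = 0.05` at `Ne = 2000`, optional stepwise mutation and an
optional null-allele class.

The coalescent is implemented directly (competing exponential rates for
coalescence and migration, epoch-wise rates for size changes, Poisson
finite-sites mutations with multiple hits allowed) so the package stays
dependency-light, and time is measured in generations everywhere inside the
simulator; calendar conversion happens only through `clock_config()`.

What the generator does *not* emulate — and hence what green tests do not
show about real data: recombination (none, appropriate for mtDNA but not a
general nuclear locus), selection, more than two demes, sequencing or
scoring error, allele-size homoplasy structure beyond single-step SMM, and
missing-data patterns that correlate with genotype (except through the
explicit null-allele class).

## Problem sizes and numerical choices

The shipped tests run the stochastic batteries at reduced but statistically
meaningful sizes, chosen as the package's own trade-off between resolution
and turnaround: 10,000 default permutations reduced to ~1,000 in the
end-to-end checks, mismatch bootstraps at 199–200, 500 replicates for the
p-value uniformity test, 50 replicates for the `tau` coverage study, and 200
replicates for type-I error. The EM stops at a 1e-9 change in the null
frequency (1,000 iterations max, flagged); the mismatch optimizer uses a
relative tolerance of 1e-12 with up to 2,000 Nelder–Mead iterations and
reports non-convergence rather than failing; degenerate inputs (monomorphic
loci, single-haplotype samples, saturated distances, single populations) are
flagged with `NA`s or warnings instead of errors wherever a partial result
is still meaningful.

## Known limitations

Bayesian clustering, skyline plots, calibrated tmrca estimation and the
MCMC samplers for migration are intentionally out of scope; only their
output-to-rate conversions are provided. The deposited study data are not
shipped, so exact reproduction of the published tables requires the user to
download them; all other claims in the package are backed by the synthetic
checks described above. The least-squares mismatch `tau` is upward-biased at
moderate sample sizes (a known property of SSD fitting of correlated pairwise
data), which is why bootstrap intervals, not point estimates, are the
reported uncertainty.
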
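---
title: "Models and methods behind rnaimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnaimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaimap)
```

This vignette documents the scientific models the package implements, the
parameters that matter and their defaults, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## The assay and its phenotype statistics

Feeding RNAi against an essential maternal-effect germline gene does not harm
the fed worm; it kills her embryos. The raw observation is a plate count of
dead embryos (DE) and hatched larvae (HL), giving embryonic lethality
$L = DE/(DE+HL)$. Because strains differ in baseline embryonic lethality, the
trait used throughout is the **induced lethality**

$$ I = \frac{L_T - L_C}{1 - L_C}, $$

where $L_T$ and $L_C$ are treated- and control-plate lethalities. $I = 1$
exactly when the treated plate is fully lethal, and $I$ can be negative on
noisy plates when $L_T < L_C$; negative values are reported raw but clamped to
zero before classification, which keeps the statistic unbiased while making
class labels well defined. $I$ is undefined when the control plate is fully
lethal ($L_C = 1$); the package raises an error rather than guessing.

Replicate plate pairs are combined by computing $I$ per pair and averaging the
pairs within a strain, not by pooling counts: plate-to-plate variation is the
dominant nuisance and per-pair correction removes each plate's own background.

Dominance is the classical scaled midparent deviation
$d = (\mathrm{Hybrid}-\mathrm{MidParent})/|\mathrm{ParentA}-\mathrm{MidParent}|$,
so $d = 0$ is additivity and $d = 1$ complete dominance of parent A's
phenotype.

Two classification schemes are provided. F2 individuals: full (exactly 100%
lethality), high (75–99%), intermediate (25–75%), low (<25%). The printed
ranges overlap at their boundaries, so the package resolves them as the
half-open partition $[0.75, 1)$, $[0.25, 0.75)$, $[0, 0.25)$ with *full*
reserved for exactly 1 — each boundary goes to the higher class, following the
upper labels, and every value in $[0,1]$ receives exactly one label. Inbred
lines: full (exactly 1), zero ($\le 0$), intermediate (otherwise).

## Expected F2 classes under the linked incompatibility

The major insensitivity locus (*ppw-1*, recessive CB allele) sits 7.47 cM from
the *zeel-1*/*peel-1* incompatibility: sperm deposit the PEEL-1 toxin, and
zygotes without a functional zygotic *zeel-1* allele (CB carries a deletion of
the locus) die with penetrance $p$. In an N2 × CB4856 F1 selfing, every sperm
carries the toxin because the F1 is heterozygous for it and deposition is
sperm-autonomous.

The model (`expected_f2_classes()`) is exact rather than simulated. With
recombination fraction $r$ between the two loci, F1 gametes carry the
parental haplotypes with frequency $(1-r)/2$ each and the recombinants with
$r/2$ each; an F2 zygote is the product of two independent gametes; zygotes
homozygous for the rescue-deleted allele die with probability $p$ (their
marginal frequency is $1/4$ regardless of $r$, so the surviving mass is
$1 - p/4$); and the survivor distribution is renormalized. Survivors are
classed by the lethality of their *own* treated broods:

* any genotype with at least one sensitive (N2) *ppw-1* allele → **total
  lethality**;
* *ppw-1* CB homozygotes that are rescue-locus homozygous (either allele) →
  **no lethality** (CB/CB mothers produce no toxin; N2/N2 broods are all
  rescued);
* *ppw-1* CB homozygotes heterozygous at the rescue locus → **low lethality**:
  their self-broods lose rescue-null zygotes at rate $p/4$ (0.065 at
  $p = 0.26$, which falls in the "low" band of the F2 classification; if a
  parameterization pushes $p/4$ over 0.25 the label would move accordingly).

**Map-function convention.** The cM → $r$ conversion for this model is linear
($r = d/100$, capped at 0.5). At 7.47 cM the linear and Haldane conversions
differ only in the third decimal of $r$, but the linear form reproduces the
three published class percentages (79.2 / 17.1 / 3.7 at $p = 0.26$) to the
printed 0.1% exactly, so it is adopted as the model's convention;
`incompatibility_model(..., map_function = "haldane")` is available. The
default penetrance 0.26 is the value measured in parental crosses; penetrance
in self-progeny is age-dependent and values of 70–90% have been reported for
age-matched worms, so it is an explicit model input, not a constant.

The additive extension (`expected_classes_additive()`) adds one unlinked
recessive allele conferring an intermediate loss of sensitivity: a quarter of
the otherwise fully sensitive class becomes intermediate, and the base model's
no/low classes pool into the low-sensitivity class, giving
59.4 / 19.8 / 20.8% at the default parameters.

**Goodness of fit.** `chisq_gof()` is the plain Pearson statistic with
upper-tail chi-square p-value, no continuity correction, and
df = merged classes − 1 (no parameter is estimated from the tested counts).
The merge map collapsing the four observed F2 classes onto the model's three
({full → high, high+intermediate → intermediate, low → low}) is an inference —
the original analysis does not state its grouping — recorded here because it
reproduces the published $p = 0.94$ from the printed counts; it is the
package's documented default for this comparison, not a claim about the
original computation.

## The synthetic-data generator

The generator replaces the study's raw worm data and defines the conditions
under which the package's statistical guarantees are tested.

* **Meiosis** is the standard no-interference model: a crossover occurs in
  each inter-marker interval independently with its Haldane recombination
  fraction $r = (1 - e^{-2d/100})/2$. No chiasma interference, no sex
  differences in recombination.
* **F2 panels** draw two independent gametes per zygote at the two model loci
  and apply the viability selection with penetrance $p$. A seeded Monte-Carlo
  panel at $n = 10^6$ is the independent oracle against which the analytic
  class expectation is tested (agreement within 3 binomial SEs per class over
  a 5 × 5 grid of $r$ and $p$).
* **RIAIL panels** intercross an F1 base population by random pairing for 10
  generations (the advanced-intercross design) at a constant population size
  of twice the requested number of lines, then derive each line by inbreeding
  to fixation, shortcut as doubling one final gamete. Lines are therefore
  homozygous at every marker. No selection acts during construction — in
  particular the *zeel-1*/*peel-1* transmission distortion that shaped the
  real panel is deliberately absent, so simulated panels segregate the major
  locus ~50/50 where the real panel was skewed. The finite intercross
  population adds drift to per-marker allele frequencies (SD ≈ 0.04 around
  0.5 at the defaults), which the tests allow for.
* **Plate counts** are Binomial$(n_\mathrm{embryos}, \cdot)$ draws: the
  treated plate at combined lethality
  $b + (1-b)\,I_\mathrm{rule}$ and the control plate at the background $b$,
  with $b = 0.05$ and 200 embryos per plate by default — a typical 6-hour lay
  at the assay's scale; embryo number is a fixed constant rather than Poisson,
  which is sufficient for the variance properties the tests rely on. The
  background-corrected statistic recovers the rule value in expectation, which
  the tests verify at $10^4$ lines.
* **Architecture presets** encode the qualitative genotype–phenotype patterns
  seen in the real panel: `ppw1_only` (bimodal 0/1 trait), an unlinked
  recessive `ppw1_additive_modifier` (intermediate 0.5), an
  `epistatic_suppressor` pair restoring high lethality (0.97) in CB-*ppw-1*
  lines (the QX222-like pattern), and a `dominant_insensitivity` pair giving
  low lethality (0.16) despite N2 *ppw-1* (the QX217-like pattern). Effect
  values are the package's choices of representative magnitudes from the
  observed line phenotypes.

What passing tests on these simulations do **not** show: robustness to real
assay features the generator omits — plate-to-plate batch effects beyond
binomial noise, age-dependent penetrance, segregation distortion during panel
construction, X-chromosome hemizygosity in males, genotyping error, and
mutation during inbreeding.

## Interval mapping

The mapping module is implemented from first principles for homozygous
biallelic panels (heterozygotes are not modeled; inbred lines are the target —
input heterozygote codes are treated as missing by the two-allele reader).

* **Genotype posteriors.** The allele process along a chromosome is a
  two-state Markov chain under Haldane transitions, so the posterior at a grid
  position depends only on the nearest *typed* flanking markers:
  $P(\mathrm{CB}) = w_Lw_R / (w_Lw_R + (1-w_L)(1-w_R))$ with
  $w = 1-r$ or $r$ per flank as it agrees or not. Missing genotypes are
  marginalized exactly by skipping to the nearest typed marker; beyond the
  outermost typed marker a single flank is used; fully untyped chromosomes get
  0.5. Marker positions are taken as given — no inbred-line map expansion is
  applied, since the map is treated as an input, not re-estimated.
  The grid is the union of a 1-cM lattice (configurable) and the marker
  positions, so posteriors at typed markers are exact indicators.
* **Nonparametric scan.** The Kruskal–Wallis statistic extended to soft
  genotype weights: with midranks $R_i$, centered ranks
  $z_i = R_i - (n+1)/2$, weights $w_i = P(\mathrm{CB})$ and group sizes
  $n_1 = \sum w_i$, $n_0 = n - n_1$,
  $$ H = \frac{12}{n(n+1)}\left(\frac{1}{n_1}+\frac{1}{n_0}\right)
     \left(\textstyle\sum_i w_i z_i\right)^2 \Big/ c_\mathrm{ties}, $$
  where $c_\mathrm{ties} = 1 - \sum_t (t^3-t)/(n^3-n)$ is the standard tie
  correction ($H = 0$ when the phenotype is constant). At fully informative
  positions this is exactly the classical two-group Kruskal–Wallis statistic,
  which the tests verify against `stats::kruskal.test` on small panels. The
  reported score is $\mathrm{lod} = H / (2\ln 10)$, so $2\ln(10)\,\mathrm{lod}$
  is asymptotically $\chi^2_1$ under the null; the scale is fixed so
  thresholds are comparable across runs. Rank-based scanning makes the scan
  invariant under monotone phenotype transformations — appropriate for a trait
  with heavy mass at 0 and 1.
* **Normal-model scan.** Haley–Knott regression of the phenotype on the
  expected genotype dosage plus covariates,
  $\mathrm{lod} = (n/2)\log_{10}(RSS_0/RSS_1)$ with the covariate retained in
  the null. Regression on posterior dosage rather than an EM mixture loses
  essentially nothing on inbred panels with dense markers. Positions collinear
  with the covariate design (e.g. the covariate is that position's dosage) get
  lod 0 with a warning — the expected behavior when conditioning out a known
  locus.
* **Permutations.** Phenotypes are permuted jointly against the intact
  genotype grid, preserving genome structure; the genome-wide maximum lod per
  permutation yields the empirical $(1-\alpha)$ quantile as the threshold
  (default 1000 permutations, $\alpha = 0.05$). Permutations are seeded and
  deterministic. Tests verify the achieved genome-wide type-I error on null
  traits at reduced permutation counts.
* **Support intervals.** The 1.5-lod support interval is the contiguous grid
  run around the global peak with lod ≥ peak − 1.5, extended one grid point on
  each side; a flat scan degenerates to the whole chromosome with a warning.

## Problem sizes used in the test suite

The suite exercises the statistical contracts at sizes chosen to make 3-SE
bands decisive while remaining desk-scale: $10^6$ Monte-Carlo F2 per cell of
the 5 × 5 oracle grid; a 500-line panel (six 50-cM chromosomes, 2-cM markers)
for peak localization and the 1000-permutation covariate scan; 200 null
replicates at 200 permutations each for the type-I error check; $10^4$ lines ×
200 embryos for the forward-model unbiasedness check; and 50 seeded replicates
for support-interval coverage (≥ 90%).

## Known limitations

* The two-genotype posterior ignores residual heterozygosity; truly
  heterozygous input should be coded missing.
* The F2 class model treats the toxin's sublethal effects (developmental
  delay, deformity) as survival — penetrance covers death only.
* The additive-modifier expectation composes classes multiplicatively with an
  unlinked locus; linked modifiers would need the full gamete model.
* Permutation thresholds assume exchangeability of lines; family structure in
  a real panel would require stratified permutation, which is not implemented.
* No physical (bp) coordinates anywhere: interval annotation against a genome
  is out of scope.
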
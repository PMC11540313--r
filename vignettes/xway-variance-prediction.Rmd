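---
title: "Predicting genetic variance in multiparent crossing plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting genetic variance in multiparent crossing plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xwaymsv)
```

## The problem

Breeders who plan crosses several generations ahead need more than the
expected mean of future progeny: the genetic *variance* within future
families determines how much selection can still achieve. For a cross of
two inbred lines, the variance among double-haploid (DH) progeny can be
computed from phased parental haplotypes, a genetic map and additive
allele-substitution effects. `xwaymsv` generalises this to a balanced
crossing bracket over `N = 2^L` founder haplotypes (a MAGIC-style design:
2-way, 4-way, 8-way, 16-way, ... crosses), decomposes the resulting DH
variance into per-generation gametic Mendelian sampling variances (MSVs),
and feeds those into a selection criterion that scores a set of 16
founders by the expected genetic level of selected descendants four
generations ahead.

## The model

Everything is additive: the breeding value (BV) of a genotype is the sum
over loci of allele dosage times the allele-substitution effect
$\beta_j$, with allele 1 as the effect allele. Three ingredients drive the
predictions.

**Recombination.** Map distances in Morgan are converted to recombination
frequencies with Haldane's function $c = (1 - e^{-2d})/2$ (no crossover
interference); loci on different chromosomes have $c = 0.5$. Any other
mapping function can be plugged in (`kosambi_c` is provided), but all
validation in this package uses Haldane's.

**Linkage phase of the founders.** For two haplotypes the disequilibrium
parameter between loci $j$ and $l$ is
$D_{jl} = (h_{1j} - h_{2j})(h_{1l} - h_{2l})/4 \in \{-0.25, 0, 0.25\}$,
positive in coupling phase, negative in repulsion; the diagonal marks the
loci at which the pair would produce a heterozygote.

**The bracket.** Slot order defines the crossing plan: slots 1 and 2 are
crossed in generation 1, the resulting groups pairwise in generation 2,
and so on, until one top group remains whose gametes are doubled into DH
lines. For slots $i < k$ the *meiosis count* $m_{ik}$ — the number of
meioses between the first generation in which alleles from both slots can
sit in one genome and the DH gametes — is
`log2(N) - floor(log2(xor(i-1, k-1)))`.

The progeny covariance matrix of the DH family is

$$\Sigma = \left(\tfrac{4}{N}\right)^2 \sum_{i<k} (\mathbf{1}\mathbf{1}' - 2\mathbf{c})^{\circ m_{ik}} \odot D^{(ik)},$$

with elementwise powers and products, and the DH variance of a trait is
$\beta'\Sigma\beta$ (`sigma_dh()`, `dh_variance()`). Covariances between
traits use $\beta_1'\Sigma\beta_2$. Because a DH doubles one gamete, the
variance among the gametes themselves is a quarter of the DH variance.

### From DH variances to gametic MSVs

The cascade (`build_cascade()`) converts the ladder of X-way DH variances
into quantities of direct interest: the genetic variance among each
generation's F1 groups and the average gametic MSV of a group member,
using the transmission recursion

* generation-1 groups of fully inbred founders contain one genotype, so
  their F1 variance is 0;
* a later group's F1 variance is the parent-average term (each parent
  group's F1 variance over 4) plus both parent groups' gametic MSVs;
* a group's gametic MSV is (its DH variance − its F1 variance) / 4.

By construction the identity `dh = f1 + 4 * msv` holds for every group;
the suite checks it and the inversion `msv_from_dh()` exactly.

### Infinitesimal counterparts

Under the infinitesimal model the gametic MSV of an individual with
inbreeding coefficient $F$ is $0.25\,(1-F)\,\sigma^2_A$. Summing the
bracket levels with weights $2^{2-(L-g)}$ (4 for the DH step, halving
towards generation 1) gives the expected DH variance from founder
coancestries alone (`expected_dh_variance()`, `infinitesimal_cascade()`).
With unrelated founders this yields the ladder 0, 0.5, 0.75, 0.875 for
F1 variances and 1, 1.5, 1.75, 1.875 for DH variances of 2-, 4-, 8-,
16-way crosses, saturating at $\sigma^2_A$ and $2\sigma^2_A$. With all
loci unlinked and equal effects, the haplotype-based predictor reduces
exactly to the coancestry form with identity-by-state coancestries and
$\sigma^2_A = p\beta^2$ — a property test in the suite.

### The selection criterion

`exp_bv_sel_grgrgroff()` scores 16 founder haplotypes by the expected BV
of selected F4 descendants: the mean of the 8 founder-pair BVs plus one
selection differential per generation, each an intensity times a group
SD from the cascade. The final generation's mates are unknown; their
gametic variance is approximated by the 16-way F1 group's own, so the
last differential uses $\sqrt{2\sigma^2_{\text{gametes}}}$. The printed
source of this criterion is typographically ambiguous in its last term;
we adopt the $\sqrt{2\sigma^2}$ reading because it is the one consistent
with the approximation just described. The criterion assumes BVs are
normally distributed within groups — reasonable under directional
selection when the gametic MSV stays at least about a quarter of the
group variance, but not under heavy selfing. Group SDs come from the
no-selection cascade; selected subgroups will have somewhat smaller
variances, so the criterion mildly overestimates absolute gain while
ranking well.

## The forward simulator

`run_plan()` validates the algebra by brute force. Gametes are simulated
with a Markov strand process along each chromosome: the transmitted
strand switches between adjacent loci with probability equal to their
recombination fraction and is drawn fresh at each chromosome start.
Under a no-interference model this is *exactly* the law of Poisson
crossover counts with uniform positions restricted to the marker loci
(Poisson counts in disjoint intervals are independent), so nothing is
lost relative to explicit crossover placement, and whole groups can be
simulated as vectorised matrix operations. The test suite confirms
simulated recombinant fractions against Haldane's function at 100,000
meioses.

Mating follows the crossing plan with a random one-to-one pairing of the
two parent groups, each parent contributing exactly one offspring — the
strictest reading of a design intended to minimise drift. With
truncation selection enabled, the best fraction of each group (on true
BV of one trait) is selected and re-used round-robin so group sizes stay
constant; exact one-offspring-per-parent therefore holds in the
validated no-selection setting. Selection uses true BVs; no estimation
error is modelled. The realized gametic MSV of a group is measured with
the exact per-individual two-haplotype formula
(`individual_gametic_msv()`) rather than by sampling gametes, which
removes one layer of Monte-Carlo noise; sampled gametes are available
through `meiosis()` if wanted.

`population_diagnostics()` reports, per generation and restricted to
loci segregating among the founders: beneficial-allele frequency change
versus the founders, mean homozygosity, and the mean within-chromosome
Falconer disequilibrium $D = f_{AB}f_{ab} - f_{Ab}f_{aB}$.

## Synthetic data

`generate_founders()` emulates an inbred diversity panel: the "corn"
preset has 10 chromosomes of 1.9 Morgan with 500 evenly spaced loci
(the average chromosome length of the maize map the method was
demonstrated on); per-locus effect-allele frequencies are drawn
uniformly from 0.1–0.5, a range chosen to give realistic between-cross
variation in predicted variances, and founder alleles are sampled
independently at those frequencies. `generate_effects()` draws two
traits' effects bivariate-normal with correlation 0.7 and rescales them
so the founder-line variances are 1 and 100. `cattle_from_corn()`
triples the genome to 30 chromosomes by copying chromosomes 1–10 and
reshuffling founder assignment for the copies (avoiding artificial
between-chromosome LD), with effects scaled by 1/3.

What the generator does *not* emulate: real linkage-disequilibrium
structure, site-frequency spectra, or relatedness among founders —
synthetic founders are exchangeable draws. Passing calibration tests on
these panels demonstrates correctness of the algebra and the simulator,
not predictive performance on any real crop or livestock population.

## Numerical and design choices

* Validation scale: the replicate-cross calibration uses 50 crosses of
  16 founders sampled from a 57-line synthetic panel with 3,000
  individuals per group. At this size the analytic predictions are
  unbiased to well under 1%, which is what the calibration asserts
  quantitatively. Cross-*ranking* correlations are additionally limited
  by the between-cross spread of the panel itself: exchangeable
  synthetic founders make 16-founder subsets much more alike (spread of
  analytic DH variance about 2% of its mean) than subsets of a real,
  structured diversity panel would be, so correlation coefficients
  computed on this panel under-read what the same predictor achieves on
  real data, where between-cross differences are several-fold larger
  than simulation noise.
* Tolerances: quantities are exact rationals apart from the exponential
  map, so algebraic identities are asserted at relative 1e-10 to 1e-12;
  PSD checks allow −1e-9. Negative MSVs beyond tolerance raise an
  inconsistency error rather than being clipped silently.
* Slot expansion: fewer biological founders than slots are handled by
  duplication (`expand_to_panel()`): an inbred line fills both sibling
  slots (equivalent to backcrossing), an outbred individual contributes
  its paternal and maternal haplotypes to sibling slots.
* Degenerate inputs: zero-distance distinct loci are allowed (c = 0);
  monomorphic loci carry zero variance and are excluded only from
  population diagnostics; correlation of a zero-variance trait is an
  error, not NaN.
* Map positions are accepted in centiMorgan on file input and converted
  once to Morgan internally.
* The command-line entry point (`inst/cli/xway.R`) is a thin wrapper
  over the exported functions; the R API is the primary interface.

## Known limitations

**The ≥8-way predictor is an approximation.** The closed form above is
exact for 2-way and 4-way brackets (it reproduces exhaustive enumeration
to machine precision). For 8-way and deeper brackets the decay factor
$(1-2c)^{m_{ik}}$ is exact only for $m_{ik} \le 2$: propagating the
gametic covariance generation by generation shows that a sibling pair
three meioses from the DHs contributes with factor
$(x^3 + x^2 - x)/16$ per gametic unit ($x = 1-2c$) rather than
$x^3/16$, the two agreeing only at $c = 0$ or $c = 0.5$. We verified
this three ways: exhaustive enumeration, an independent
gametic-covariance recursion, and a one-million-DH forward simulation,
all of which agree with each other and not with the closed form at
intermediate $c$. At realistic map densities the discrepancy is a few
tenths of a percent of the DH variance — below drift noise in any
practical validation and without consequence for ranking crosses — but
exact equality with enumeration should not be expected beyond 4-way
brackets.

Other limitations: no dominance or epistasis; no crossover
interference in the default model; unbalanced (non-power-of-two)
brackets are only supported through slot duplication; selection response
is validated directionally, not quantitatively, because quantitative
selection results depend on the real haplotype structure of the
population being modelled.
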
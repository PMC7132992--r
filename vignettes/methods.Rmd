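---
title: "Hybrid peeling: model, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid peeling: model, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the peeling model
and its assumptions, what the synthetic-data generator emulates (and does
not), the tunable parameters, and the numerical and design decisions made
where the problem left them open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The peeling model

The pedigree is a directed graphical model over **ordered genotypes**
`(aa, aA, Aa, AA)` at a biallelic locus, the first symbol being the
paternal allele. Each individual's posterior factorizes into three parts:

* **anterior** — information flowing down from the parents. For founders
  this is the Hardy-Weinberg prior at the locus allele frequency `p`; for
  non-founders it is the parents' joint genotype distribution pushed
  through the transmission kernel (below), *including* the evidence of
  the individual's siblings.
* **penetrance** — the likelihood of the individual's own data. A
  marker-array genotype `g*` contributes `1 - eps_g` to the matching
  ordered states and `eps_g / 2` to the rest (default `eps_g = 1e-4`).
  A read pair (ref, alt) contributes a binomial likelihood of the alt
  count with alt-read probability `e, 0.5, 0.5, 1 - e` across the four
  states (default sequencing error `e = 1e-3`). Contributions multiply;
  no data gives a flat likelihood.
* **posterior terms** — one message per family in which the individual is
  a parent, carrying the progeny's evidence upward.

The **transmission kernel** is segregation-aware. With segregation state
`(u, v)` — `u` says whether the paternal gamete copied the sire's
paternal or maternal haplotype, `v` likewise for the dam — the child's
paternal allele is a deterministic copy, so

```
T(g_child | g_sire, g_dam, seg) =
  sum over (u, v) of seg[u, v] * 1{sire allele u == child paternal}
                              * 1{dam allele v == child maternal}
```

With uniform segregation this reduces to ordinary Mendelian transmission.

Message passing is implemented in C++ with proper exclusion of the
receiving branch (each family pass computes prefix/suffix products of the
child kernels, so each child's anterior excludes exactly its own
contribution). On loop-free pedigrees the scheme is exact sum-product
inference; the test suite checks it against exhaustive enumeration over
all `4^n` configurations at `1e-6`. Under inbreeding the same sweeps are
a loopy approximation, discussed below.

### Two steps

1. **Multi-locus peeling** on the marker-panel loci estimates segregation
   probabilities. Each outer iteration runs one down-and-up genotype
   sweep per locus, collects per-locus segregation likelihoods for every
   non-founder (from the joint parent distribution excluding that child,
   times the child's own evidence), and smooths them along the
   chromosome with a forward-backward pass. Transitions between adjacent
   loci factorize into independent paternal/maternal switches with
   Haldane recombination fractions from the map. Founders keep the
   uniform distribution. Defaults: at most 15 outer iterations, stop
   when the largest segregation change drops below `1e-3`.
2. **Single-locus peeling at every variant.** Segregation is carried to
   off-panel positions by per-indicator Markov bridging of the two
   flanking posteriors (product of the two flank messages, each decayed
   by the Haldane fraction to the variant; beyond terminal panel loci a
   single decayed message, which relaxes toward uniform). With
   segregation fixed, each variant peels independently: at most 20
   down-up iterations, stopping when the largest dosage change is below
   `1e-4`. Founder priors use per-variant allele frequencies estimated
   by pooling array genotypes (as `g/2`) and per-individual read
   fractions with unit weight, floored at `1/(2N)`.

### Numerical choices

* Probability vectors are floored at `1e-30` before normalization; an
  all-zero product (fully conflicting evidence) is repaired to uniform.
* Messages are updated in place (Gauss-Seidel style) during each sweep,
  which speeds convergence and lets the iteration settle on one of the
  two symmetric phase conventions of each founder (a founder's own
  paternal/maternal labelling is an arbitrary gauge: swapping its two
  haplotypes everywhere leaves the likelihood unchanged). Dosages and
  all identifiable quantities are unaffected by the gauge.
* Because step 2 treats segregation as *fixed*, an individual whose true
  crossover falls awkwardly between panel loci (or whose parent's phase
  is locally ambiguous) can receive a confidently wrong anterior there.
  With everything else saturated this leaves isolated dosage entries a
  few percent off even under complete array data; the test suite
  characterizes this as fewer than 1% of entries off by more than
  `1e-3` on a fully genotyped fixture. This is the price of the hybrid
  factorization, not an iteration-count issue.
* Loopy peeling on inbred pedigrees is accepted as an approximation. With
  Mendelian-consistent observations — the regime real data presents — it
  agrees with enumeration to better than `1e-3` on a six-member half-sib
  mating loop even when the mated pair is unobserved. With adversarial
  random penetrances the fixed point can be off by a few percent on any
  tight loop; a damping option exists but is off by default because it
  was not needed in the realistic regime.

## What the simulator emulates

`sim_population()` generates the study conditions end to end: pedigree,
true phased haplotypes with recorded segregation states, nested HD/LD
marker arrays, a sequencing-budget plan, and Poisson-gamma read counts.

* **Pedigree.** Discrete generations; each progeny generation is built
  from litters (Poisson mean 6, truncated at 1) of dams drawn from 50%
  of the previous generation's females and sires from 5% of its males —
  a strongly pyramidal structure. The default population is a *growing*
  nucleus herd: 20 founders and ten generations of sizes
  60, 80, 120, 160, 200, 240, 280, 280, 280, 280 (2,000 in total). The
  small founder base matters: pedigree imputation can only transfer
  reads along lineages, so the per-variant read budget (2% of the
  population at 2x, about 80 reads per variant here) must cover the
  ancestral haplotype lineages. Real nucleus pedigrees concentrate on a
  few dozen effective ancestors; a synthetic population with hundreds of
  equally weighted founder lineages would be information-starved at any
  algorithmic quality (peeling with the *true* segregation states barely
  improves it), which is a property of the population, not the method.
* **Arrays.** The first two generations predate genotyping; the first
  array-era generation was genotyped halfway (`rollout_frac = 0.5`),
  later generations fully. A quarter of genotyped individuals get the HD
  panel (100 markers/chromosome), the rest the nested LD panel (25).
  Array genotypes are noise-free (array error rates are orders of
  magnitude below anything that matters here). The panel-to-sequence
  density ratio (100 of 5,000 per chromosome) mirrors commercial HD
  arrays against whole-genome sequence. Panels prefer intermediate-MAF
  variants (MAF at least 0.05 where possible), evenly spaced — as
  commercial arrays are designed.
* **Founder genotypes** are drawn site-independently from Hardy-Weinberg
  at Beta(0.3, 0.3) frequencies truncated to `[1/(4N), 1 - 1/(4N)]` — a
  U-shaped spectrum with many rare variants, needed for the MAF-binned
  accuracy analyses. There is **no ancestral linkage disequilibrium**:
  peeling exploits pedigree and linkage, not population LD, so this
  simplification does not flatter the method; it does mean the
  simulator cannot be used to study LD-based imputation.
* **Reads.** Per-site sequenceability `s_v ~ Gamma(shape 4, mean 1)`
  once per variant; individual `i` gets `Poisson(c_i * s_v)` reads at
  variant `v`; each read samples a haplotype uniformly and reports its
  allele, flipped with probability `e = 1e-3`. Gamma shape 4 gives
  moderate overdispersion (the property tests verify super-Poisson
  depth variance across sites, collapsing to Poisson as the shape grows).
* **Budget allocation** follows the three-step strategy with the
  30/15/25/30 split: top sires (most genotyped progeny) at 2x, top dams
  at 1x, focal individuals at high coverage, and a 1x top-up of
  under-sequenced branches. Focal selection is a *pedigree proxy* for
  haplotype-representation optimization: greedily pick the individual
  covering the most not-yet-covered pedigree descendants (30x for the
  first pick, 15x after, 5x to unsequenced parents). The top-up serves
  unsequenced individuals whose parents and grandparents carry less than
  10x of cumulative assigned coverage, most deficient first; unspent
  budget from earlier steps rolls into this step so the plan lands
  within one 1x unit of the budget.

What passing tests on this simulator do **not** show about real data:
array genotyping error, population LD, overlapping generations,
selection on phenotypes, and structural variation are all absent; the
accuracy *levels* reported at desk scale are not the levels a full-scale
population reaches (the paper-scale populations are 10-50 times larger
with proportionally more sequenced relatives per individual), but the
*structure* — who imputes well, which factors matter, how errors
propagate — is the object of study and is scale-stable.

## Evaluation choices

* Individual-wise accuracy is the MAF-corrected dosage correlation
  (centering both vectors by twice the allele frequency); allele
  frequencies for the correction come from the full-population imputed
  dosages. Zero-variance cases are flagged undefined and excluded with a
  count rather than set to 0.
* Variant-wise accuracy is plain Pearson across individuals. The
  original protocol excludes individuals *predicted* to impute below
  0.95 first; at desk scale the median sits near 0.92, so that filter
  would retain almost nobody — variant-wise accuracy is therefore
  computed over all individuals by default, with the exclusion available
  via `evaluate_accuracy(exclude_ids = ...)`.
* For the same reason, the tenfold cross-validation of the low-accuracy
  flag degenerates at desk scale: with most individuals truly below the
  0.95 threshold, the fitted trees flag essentially everyone, driving
  sensitivity to 1 and specificity toward 0. The arithmetic is exact
  (verified on constructed confusion tables); the degeneracy is a
  property of applying a fixed 0.95 threshold to a desk-scale accuracy
  distribution.
* The individual-level factor table carries 23 variables: population
  size, own genotyping status, 12 counts of relatives genotyped per
  relationship level and density, 8 sequenced-relative counts and
  cumulative coverages, and connectedness (the sum of additive
  relationship coefficients to the rest of the pedigree, computed via
  the `A = T D T'` decomposition without materializing `A`). Own status,
  grandparent genotyping and connectedness are deeply confounded in a
  single-pyramid desk population — all three mark the array-free early
  generations — so which of them the regression tree picks first is not
  stable; at full scale, where ungenotyped animals are scattered rather
  than concentrated in one era, grandparent genotyping separates more
  cleanly.
* Segregation recovery is evaluated on individuals whose parents are
  themselves non-founders. A founder's phase is an arbitrary gauge, so
  the segregation states of its direct progeny are unidentifiable in
  principle; the grandchild generation is the first whose states are
  anchored. The recovery fixture uses intermediate-MAF markers
  (Beta(2, 2) founder frequencies), matching the MAF composition an HD
  array would have at those loci.

## The error-injection study

Three worst-case errors are injected one target at a time: replacing the
target's sequence reads by a random high-coverage individual's
(one-directional — the donor keeps its data), replacing its array row by
a random HD individual's, and reassigning a high-coverage donor's progeny
to the target (all of them, the worst case; reassigned progeny that would
become the target's own ancestors are skipped to keep the pedigree
acyclic). The removal control deletes the target's reads, as in
leave-one-out validation. Impact is the MAF-corrected dosage correlation
between the correct-data and erroneous-data runs; without the correction
the between-variant allele-frequency spread dominates and even drastic
errors correlate near 1.

The stress fixture (`sim_perturb_fixture()`) is a 600-individual
population with six key sires at 15-30x and a broad 2x/1x spread — a
denser read field per individual than the 2%-at-2x budget. The density is
deliberate: isolating the propagation of a *single* injected error
requires the background information field to be saturated, which is the
regime of a full-scale population where one animal's reads are a
negligible share of the total. Under a strict desk-scale budget the
removal of a 30x animal is itself the largest possible information loss
(its reads are over a third of all reads), which swamps the comparison.

## Quality control

Mendelian conflicts are opposing homozygotes per parent-progeny pair. A
pair counts as incompatible when the opposing-homozygote percentage
exceeds 2% over at least 50 comparable loci (array error rates are far
below 2%, so this is conservative). The three repair rules run in order
with one recomputation at the end; two decisions were open and are made
here: rule 1 (remove a misassigned sample's data) requires at least two
incompatible pairs and handles the most-conflicted individual first, so
a relative whose only conflict involves the bad sample is not swept up;
and the dummy parents created by rule 3 get reserved ids `DUM<N>`.

## Problem sizes

The package's own studies run at: 2,000 individuals x 2 chromosomes x
5,000 variants for the end-to-end accuracy structure (about a minute of
peeling), a 14-member family x 200 markers for segregation recovery,
600 individuals x 500 variants x 96 re-imputations for the
error-injection study, and pedigrees of up to 8 members for the
enumeration oracle (4^8 configurations). These sizes were chosen so the
full audit reproduces in minutes on a single core while keeping every
qualitative contrast the analyses are about.
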
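# hybridpeel

Pedigree-based imputation of whole-genome allele dosages with **two-step
hybrid peeling**, plus the machinery to design a low-coverage sequencing
strategy for a pedigreed livestock population and to audit the resulting
imputation accuracy.

The package is aimed at quantitative geneticists working with breeding
nucleus populations in which most animals carry low- or high-density
marker-array genotypes, a small fraction (about 2%) is sequenced — mostly
at 1-2x, with a few key ancestors at 15-30x — and whole-genome dosages are
wanted for *everyone* in the pedigree.

## The method

Peeling treats the pedigree as a graphical model. Each individual's
posterior over **ordered genotypes** (aa, aA, Aa, AA; first allele
paternal) factorizes as

```
posterior  ∝  anterior  ×  penetrance  ×  Π (family posterior terms)
```

where the *anterior* flows from the parents through a transmission kernel,
the *penetrance* is the likelihood of the individual's own data (array
genotype with observation error ε_g; sequencing reads as a binomial with
alt-read probabilities e, ½, ½, 1−e for the four genotypes), and the
posterior terms flow up from each family of progeny.

Hybrid peeling runs this in two steps:

1. **Multi-locus iterative peeling** on the marker-panel loci estimates,
   for every individual and locus, the **segregation state** — which
   grandparental haplotype each gamete copied (pp, pm, mp, mm). A
   forward-backward pass along each chromosome links loci, with
   recombination fractions from Haldane's map function.
2. **Segregation-aware single-locus peeling** imputes every sequence
   variant: the segregation probabilities (interpolated between panel
   loci) fix the inheritance pathways, so each variant peels
   independently and fast, with allele frequencies estimated from the
   data as founder priors. Dosage = P(aA) + P(Aa) + 2·P(AA).

Accuracy is measured as the **MAF-corrected dosage correlation**: Pearson
correlation of true genotypes and imputed dosages after subtracting twice
the allele frequency per variant, which stops rare variants from inflating
individual-wise accuracy.

## Worked example

```r
library(hybridpeel)

## a seeded desk-scale population: 2,000 pigs over 10 generations,
## 2 chromosomes x 5,000 variants, nested 100/25-marker arrays per
## chromosome, and a 2%-at-2x sequencing budget allocated to top sires,
## top dams, focal ancestors and a 1x top-up
pop <- sim_population(sim_params(), seed = 1)
coverage_histogram(pop$plan)
#> # A tibble: 1 x 6
#>   n_sequenced  n_1x  n_2x  n_5x n_15_30x total_coverage
#> 1          50    36    12     1        1             80

## impute whole-genome dosages for all 2,000 individuals
res <- hybrid_peel(pop$ped, pop$genotypes, pop$reads, pop$map, pop$panels)

## audit accuracy against the recorded truth on 2,000 random variants
rep <- evaluate_accuracy(pop, res, subsample = 2000, seed = 1)
median(rep$individuals$accuracy, na.rm = TRUE)
#> [1] 0.9201049

## which factors drive accuracy? (rpart tree, R^2 gain >= 0.005 per split)
itab <- build_individual_factors(pop$ped, pop$status, pop$plan)
itab$accuracy <- rep$individuals$accuracy[match(itab$id, rep$individuals$id)]
first_split(fit_accuracy_tree(itab))
#> [1] "status"

plot_accuracy_by_position(rep)   # early-pedigree individuals impute worst
```

The 50 sequenced animals are 2.5% of the population; the median
MAF-corrected dosage correlation of 0.92 means a typical animal's imputed
dosages track its true genotypes almost perfectly at common variants
(its raw correlation is about 0.99), with most of the loss concentrated
in rare variants and in the earliest, array-free generations.

A YAML-driven end-to-end run (simulate, plan, peel, evaluate, factor
trees, optional error-injection study) is available as

```r
run_pipeline(default_config(), out_dir = "run1")
# or from a shell:
#   Rscript inst/scripts/hybridpeel.R run-all --out run1 --seed 1
```

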
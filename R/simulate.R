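#' Simulation parameters
#'
#' Bundles the knobs of the synthetic population generator. Defaults give a
#' desk-scale population with the statistical structure of a pig breeding
#' nucleus: a founder generation followed by discrete selected generations,
#' a strongly pyramidal pedigree (few sires, many dams), a whole-genome
#' sequence panel with nested HD/LD marker arrays, and sparse Poisson-gamma
#' sequencing reads concentrated on key ancestors.
#'
#' @param n_founders Founder generation size.
#' @param n_generations Number of progeny generations.
#' @param gen_size Individuals per progeny generation (constant); when
#'   `NULL` and `n_generations = 10`, a growing-herd ramp
#'   `c(60, 80, 120, 160, 200, 240, 280, 280, 280, 280)` is used.
#' @param gen_sizes Optional integer vector of per-generation sizes
#'   (length `n_generations`), overriding `gen_size`; lets the herd grow
#'   over time the way real nucleus pedigrees do (thin early generations).
#' @param litter_mean Mean litter size (Poisson truncated at 1).
#' @param sire_frac,dam_frac Fractions of previous-generation males/females
#'   used as parents.
#' @param founder_beta Beta(a, b) shape parameters of the founder alt-allele
#'   frequency distribution (truncated to `[0.5/2N, 1 - 0.5/2N]`).
#' @param n_chr,length_cm,var_per_chr Genome dimensions.
#' @param hd_per_chr,ld_per_chr Marker panel sizes per chromosome (LD nested
#'   in HD).
#' @param hd_frac Fraction of genotyped individuals assigned the HD array
#'   (the rest get LD).
#' @param ungenotyped_gens Number of initial generations without marker
#'   arrays (the pre-genomics era of the pedigree; generation indices
#'   `< ungenotyped_gens` stay ungenotyped).
#' @param rollout_frac Fraction of the first array-era generation that was
#'   genotyped (partial first wave of array adoption).
#' @param geno_frac Fraction of each later generation that is genotyped.
#' @param gamma_shape Gamma shape of per-site sequenceability (mean 1);
#'   smaller values give more overdispersed read depth.
#' @param seq_error Sequencing error rate `e` (allele read flipped with
#'   probability `e`), in `(0, 0.1]`.
#' @param budget_x Total sequencing budget in x-equivalents; default is the
#'   cost of sequencing 2 percent of the population at 2x.
#' @param fractions Budget split over (top sires, top dams, focal
#'   individuals, top-up); must sum to 1.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_founders = 20, n_generations = 10, gen_size = NULL,
                       gen_sizes = NULL,
                       litter_mean = 6, sire_frac = 0.05, dam_frac = 0.5,
                       founder_beta = c(0.3, 0.3),
                       n_chr = 2, length_cm = 100, var_per_chr = 5000,
                       hd_per_chr = 100, ld_per_chr = 25, hd_frac = 0.25,
                       ungenotyped_gens = 2, rollout_frac = 0.5,
                       geno_frac = 1,
                       gamma_shape = 4, seq_error = 1e-3,
                       budget_x = NULL,
                       fractions = c(sires = 0.30, dams = 0.15,
                                     focal = 0.25, topup = 0.30)) {
  stopifnot(n_founders > 0, litter_mean > 0,
            seq_error > 0, seq_error <= 0.1, gamma_shape > 0,
            ld_per_chr <= hd_per_chr, hd_per_chr <= var_per_chr,
            abs(sum(fractions) - 1) < 1e-8)
  if (is.null(gen_sizes)) {
    gen_sizes <- if (!is.null(gen_size)) {
      rep(gen_size, n_generations)
    } else if (n_generations == 10L) {
      ## default: a growing nucleus herd (thin early generations)
      c(60, 80, 120, 160, 200, 240, 280, 280, 280, 280)
    } else stop("specify gen_size or gen_sizes")
  }
  stopifnot(length(gen_sizes) == n_generations, all(gen_sizes > 0))
  n_total <- n_founders + sum(gen_sizes)
  if (is.null(budget_x)) budget_x <- 0.02 * n_total * 2
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: each progeny generation is built from litters whose
#' sire is drawn from the selected males and whose dam from the selected
#' females of the previous generation. Output is sorted parents-first with a
#' `gen` column.
#'
#' @param params [sim_params()] list.
#' @param seed Optional integer seed.
#' @return Pedigree tibble.
#' @export
sim_pedigree <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- params$n_founders
  rows <- list(tibble::tibble(
    id = sprintf("F%04d", seq_len(n0)),
    sire = NA_character_, dam = NA_character_,
    sex = rep_len(c("M", "F"), n0)
  ))
  prev <- rows[[1]]
  counter <- 0L
  for (g in seq_len(params$n_generations)) {
    gsize <- params$gen_sizes[g]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    sires <- sample(males, max(1L, round(params$sire_frac * length(males))))
    dams <- sample(females, max(1L, round(params$dam_frac * length(females))))
    if (!length(sires) || !length(dams)) stop("no selected parents of one sex")
    kid_sire <- character(0); kid_dam <- character(0)
    dq <- sample(dams)
    di <- 0L
    while (length(kid_sire) < gsize) {
      di <- di + 1L
      dam <- dq[(di - 1L) %% length(dq) + 1L]
      sire <- sample(sires, 1L)
      ls <- max(1L, stats::rpois(1, params$litter_mean))
      kid_sire <- c(kid_sire, rep(sire, ls))
      kid_dam <- c(kid_dam, rep(dam, ls))
    }
    kid_sire <- kid_sire[seq_len(gsize)]
    kid_dam <- kid_dam[seq_len(gsize)]
    gen <- tibble::tibble(
      id = sprintf("G%d_%04d", g, seq_len(gsize)),
      sire = kid_sire, dam = kid_dam,
      sex = sample(c("M", "F"), gsize, replace = TRUE)
    )
    counter <- counter + gsize
    rows[[g + 1L]] <- gen
    prev <- gen
  }
  as_pedigree(dplyr::bind_rows(rows), quiet = TRUE)
}

#' Gene-drop true haplotypes through a pedigree
#'
#' Founder haplotypes are drawn site-independently from Hardy-Weinberg at
#' Beta-distributed allele frequencies; gametes are formed by a Poisson
#' crossover process (one expected crossover per Morgan, no interference).
#' The grandparental origin of every transmitted allele is recorded, giving
#' the true segregation states used by the peeling oracles.
#'
#' @param ped Pedigree tibble (parents before progeny).
#' @param map Genetic map.
#' @param params [sim_params()] list.
#' @param seed Optional integer seed.
#' @return List of class `true_haps` with integer matrices (individuals x
#'   variants) `pat`, `mat` (alleles 0/1), `seg_pat`, `seg_mat` (1 = gamete
#'   copied the parent's paternal haplotype; NA for founders), and `freqs`
#'   (founder allele frequency per variant).
#' @export
drop_genotypes <- function(ped, map, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped); nv <- nrow(map)
  lo <- 0.5 / (2 * n)
  p <- stats::qbeta(stats::runif(nv), params$founder_beta[1],
                    params$founder_beta[2])
  p <- pmin(pmax(p, lo), 1 - lo)

  pat <- matrix(NA_integer_, n, nv, dimnames = list(ped$id, map$variant))
  mat <- pat; seg_pat <- pat; seg_mat <- pat
  pi <- ped_indices(ped)
  chroms <- unique(map$chrom)
  chr_cols <- lapply(chroms, function(ch) which(map$chrom == ch))
  chr_pos <- lapply(chr_cols, function(ix) map$pos_cm[ix])

  gamete <- function(hp, hm, ix, pos) {
    ## crossover origin along one chromosome: 1 = paternal haplotype
    L <- max(pos) - min(pos)
    nx <- stats::rpois(1, L / 100)
    start <- stats::runif(1) < 0.5
    if (nx == 0) {
      origin <- rep(start, length(ix))
    } else {
      xpos <- sort(stats::runif(nx, min(pos), max(pos)))
      origin <- xor(start, (findInterval(pos, xpos) %% 2) == 1)
    }
    list(allele = ifelse(origin, hp, hm), origin = as.integer(origin))
  }

  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (is.na(s) && is.na(d)) {
      pat[i, ] <- as.integer(stats::runif(nv) < p)
      mat[i, ] <- as.integer(stats::runif(nv) < p)
      next
    }
    for (k in seq_along(chroms)) {
      ix <- chr_cols[[k]]; pos <- chr_pos[[k]]
      if (!is.na(s)) {
        g <- gamete(pat[s, ix], mat[s, ix], ix, pos)
        pat[i, ix] <- g$allele; seg_pat[i, ix] <- g$origin
      } else {
        pat[i, ix] <- as.integer(stats::runif(length(ix)) < p[ix])
      }
      if (!is.na(d)) {
        g <- gamete(pat[d, ix], mat[d, ix], ix, pos)
        mat[i, ix] <- g$allele; seg_mat[i, ix] <- g$origin
      } else {
        mat[i, ix] <- as.integer(stats::runif(length(ix)) < p[ix])
      }
    }
  }
  structure(list(pat = pat, mat = mat, seg_pat = seg_pat, seg_mat = seg_mat,
                 freqs = stats::setNames(p, map$variant)),
            class = "true_haps")
}

#' True genotype matrix (alt-allele counts) from haplotypes
#' @param truth A `true_haps` object.
#' @return Integer matrix individuals x variants in 0/1/2.
#' @export
true_genotypes <- function(truth) truth$pat + truth$mat

#' Assign marker-array genotyping statuses
#'
#' Default policy mirrors a breeding nucleus whose early pedigree predates
#' marker arrays: the first `ungenotyped_gens` generations are ungenotyped;
#' the first array-era generation was genotyped only partially
#' (`rollout_frac`), later generations at `geno_frac`. Genotyped
#' individuals get the HD array with probability `hd_frac`, else LD.
#'
#' @param ped Pedigree tibble.
#' @param params [sim_params()] list.
#' @param seed Optional integer seed.
#' @return Named character vector id -> `"none"|"LD"|"HD"`.
#' @export
assign_array_status <- function(ped, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gfrac <- ifelse(ped$gen < params$ungenotyped_gens, 0,
                  ifelse(ped$gen == params$ungenotyped_gens,
                         params$rollout_frac, params$geno_frac))
  status <- ifelse(stats::runif(nrow(ped)) >= gfrac, "none",
                   ifelse(stats::runif(nrow(ped)) < params$hd_frac,
                          "HD", "LD"))
  stats::setNames(status, ped$id)
}

#' Observe marker-array genotypes
#'
#' Returns the noise-free array genotypes: the true alt-allele count at the
#' variants of each individual's assigned panel, `NA` elsewhere. Only HD
#' panel columns are materialized (non-panel variants carry no array data).
#'
#' @param truth `true_haps` object.
#' @param panels [make_panels()] result.
#' @param status Named status vector from [assign_array_status()].
#' @return Integer matrix individuals x HD-panel variants with `NA` at
#'   unobserved entries.
#' @export
observe_arrays <- function(truth, panels, status) {
  g <- true_genotypes(truth)[, panels$hd, drop = FALSE]
  status <- status[rownames(g)]
  g[status == "none", ] <- NA_integer_
  ld_rows <- which(status == "LD")
  if (length(ld_rows)) {
    g[ld_rows, setdiff(panels$hd, panels$ld)] <- NA_integer_
  }
  g
}

#' Simulate sequencing reads under a Poisson-gamma model
#'
#' Per-site sequenceability `s_v ~ Gamma(shape, rate = shape)` (mean 1) is
#' drawn once per variant; individual `i` with nominal coverage `c_i` gets
#' `n_iv ~ Poisson(c_i s_v)` reads at variant `v`. Each read samples one of
#' the individual's two haplotypes uniformly and reports its allele, flipped
#' with probability `seq_error`.
#'
#' @param truth `true_haps` object.
#' @param coverage Named numeric vector id -> nominal coverage (ids absent
#'   or 0 are unsequenced).
#' @param params [sim_params()] list.
#' @param seed Optional integer seed.
#' @return `read_counts` tibble with attributes `coverage` and
#'   `sequenceability`.
#' @export
simulate_reads <- function(truth, coverage, params = sim_params(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(coverage < 0)) stop("negative coverage")
  coverage <- coverage[coverage > 0]
  nv <- ncol(truth$pat)
  s_v <- stats::rgamma(nv, shape = params$gamma_shape,
                       rate = params$gamma_shape)
  e <- params$seq_error
  out <- vector("list", length(coverage))
  vn <- colnames(truth$pat)
  for (k in seq_along(coverage)) {
    id <- names(coverage)[k]
    n_iv <- stats::rpois(nv, coverage[[k]] * s_v)
    hit <- which(n_iv > 0)
    if (!length(hit)) {
      out[[k]] <- NULL
      next
    }
    g <- truth$pat[id, hit] + truth$mat[id, hit]
    p_alt <- c(e, 0.5, 1 - e)[g + 1L]
    alt <- stats::rbinom(length(hit), n_iv[hit], p_alt)
    out[[k]] <- tibble::tibble(id = id, variant = vn[hit],
                               refReads = as.integer(n_iv[hit] - alt),
                               altReads = as.integer(alt))
  }
  empty <- tibble::tibble(id = character(0), variant = character(0),
                          refReads = integer(0), altReads = integer(0))
  rc <- as_read_counts(dplyr::bind_rows(c(list(empty), out)))
  attr(rc, "coverage") <- coverage
  attr(rc, "sequenceability") <- stats::setNames(s_v, vn)
  rc
}

#' Simulate a complete study population
#'
#' Chains pedigree simulation, gene dropping, panel construction, array
#' observation, sequencing-budget allocation ([build_plan()]) and read
#' simulation into one seeded, reproducible dataset.
#'
#' @param params [sim_params()] list.
#' @param seed Integer seed (single source of randomness for all stages).
#' @return List of class `sim_pop` with elements `ped`, `map`, `truth`,
#'   `panels`, `status`, `genotypes`, `plan`, `reads`, `params`, `seed`.
#' @export
sim_population <- function(params = sim_params(), seed = 1) {
  set.seed(seed)
  ped <- sim_pedigree(params)
  map <- sim_genetic_map(params$n_chr, params$length_cm, params$var_per_chr)
  truth <- drop_genotypes(ped, map, params)
  realized <- colMeans(true_genotypes(truth)) / 2
  panels <- make_panels(map, params$hd_per_chr, params$ld_per_chr,
                        freqs = realized)
  status <- assign_array_status(ped, params)
  genotypes <- observe_arrays(truth, panels, status)
  plan <- build_plan(ped, genotyped = names(status)[status != "none"],
                     total_budget = params$budget_x,
                     fractions = params$fractions)
  coverage <- stats::setNames(plan$coverage, plan$id)
  reads <- simulate_reads(truth, coverage, params)
  structure(list(ped = ped, map = map, truth = truth, panels = panels,
                 status = status, genotypes = genotypes, plan = plan,
                 reads = reads, params = params, seed = seed),
            class = "sim_pop")
}
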
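## Shared fixtures and independent oracles for the test suite.

## minimal trio: sire, dam, child
trio_ped <- function() {
  as_pedigree(data.frame(id = c("s", "d", "c"),
                         sire = c(NA, NA, "s"),
                         dam = c(NA, NA, "d")), quiet = TRUE)
}

## 6-member, loop-free, two-family pedigree
ped6 <- function() {
  as_pedigree(data.frame(
    id = c("a", "b", "c", "d", "e", "f"),
    sire = c(NA, NA, "a", "a", NA, "d"),
    dam = c(NA, NA, "b", "b", NA, "e")), quiet = TRUE)
}

## 5-member pedigree with a full-sib mating loop (inbred individual e)
ped_loop <- function() {
  as_pedigree(data.frame(
    id = c("a", "b", "c", "d", "e"),
    sire = c(NA, NA, "a", "a", "c"),
    dam = c(NA, NA, "b", "b", "d")), quiet = TRUE)
}

## 8-member three-generation loop-free pedigree
ped8 <- function() {
  as_pedigree(data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g", "h"),
    sire = c(NA, NA, NA, "a", "a", NA, "d", "d"),
    dam = c(NA, NA, NA, "b", "c", NA, "f", "f")), quiet = TRUE)
}

## three-generation nuclear family: 4 founder grandparents, 2 parents,
## n_kids children; segregation states of the children are identifiable
family3gen <- function(n_kids = 8) {
  as_pedigree(data.frame(
    id = c("gs1", "gd1", "gs2", "gd2", "p1", "p2",
           paste0("k", seq_len(n_kids))),
    sire = c(NA, NA, NA, NA, "gs1", "gs2", rep("p1", n_kids)),
    dam = c(NA, NA, NA, NA, "gd1", "gd2", rep("p2", n_kids)),
    sex = c("M", "F", "M", "F", "M", "F", rep(NA, n_kids))), quiet = TRUE)
}

## brute-force posterior over ordered genotypes by exhaustive enumeration
## of all 4^n configurations (independent oracle for the peeling kernel)
enum_peel_oracle <- function(ped, pen, seg = NULL, p = 0.5) {
  n <- nrow(ped)
  pi <- ped_indices(ped)
  hw <- c((1 - p)^2, (1 - p) * p, p * (1 - p), p^2)
  pat_allele <- c(0, 0, 1, 1)
  mat_allele <- c(0, 1, 0, 1)
  trans <- function(gc, gs, gd, sg) {
    sal <- c(pat_allele[gs], mat_allele[gs])
    dal <- c(pat_allele[gd], mat_allele[gd])
    cp <- pat_allele[gc]; cm <- mat_allele[gc]
    sg[1] * (sal[1] == cp) * (dal[1] == cm) +
      sg[2] * (sal[1] == cp) * (dal[2] == cm) +
      sg[3] * (sal[2] == cp) * (dal[1] == cm) +
      sg[4] * (sal[2] == cp) * (dal[2] == cm)
  }
  states <- as.matrix(expand.grid(rep(list(1:4), n)))
  post <- matrix(0, n, 4)
  for (r in seq_len(nrow(states))) {
    g <- states[r, ]
    w <- 1
    for (i in seq_len(n)) {
      s <- pi$sire[i]; d <- pi$dam[i]
      sg <- if (!is.null(seg)) seg[i, ] else rep(0.25, 4)
      if (is.na(s) && is.na(d)) {
        w <- w * hw[g[i]]
      } else if (!is.na(s) && !is.na(d)) {
        w <- w * trans(g[i], g[s], g[d], sg)
      } else if (!is.na(s)) {
        acc <- 0
        for (gd in 1:4) acc <- acc + hw[gd] * trans(g[i], g[s], gd, sg)
        w <- w * acc
      } else {
        acc <- 0
        for (gs in 1:4) acc <- acc + hw[gs] * trans(g[i], gs, g[d], sg)
        w <- w * acc
      }
      w <- w * pen[i, g[i]]
      if (w == 0) break
    }
    if (w > 0) for (i in seq_len(n)) post[i, g[i]] <- post[i, g[i]] + w
  }
  sweep(post, 1, rowSums(post), "/")
}

## penetrance row for an exactly observed unordered genotype
obs_pen <- function(g, eps = 1e-4) {
  f <- rep(eps / 2, 4)
  f[switch(as.character(g), "0" = 1L, "1" = c(2L, 3L), "2" = 4L)] <- 1 - eps
  f
}

## small seeded population for integration-style tests
small_pop <- function(seed = 11, n_founders = 40, n_generations = 3,
                      gen_size = 60, var_per_chr = 400, hd_per_chr = 40,
                      ld_per_chr = 10, ...) {
  sim_population(sim_params(n_founders = n_founders,
                            n_generations = n_generations,
                            gen_size = gen_size, n_chr = 1,
                            var_per_chr = var_per_chr,
                            hd_per_chr = hd_per_chr,
                            ld_per_chr = ld_per_chr, ...),
                 seed = seed)
}

## cache expensive shared fixtures across test files within one run
fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, build) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, build(), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

## genotype matrix constant fill
make_geno <- function(ids, nloc, value = 0L) {
  matrix(value, length(ids), nloc,
         dimnames = list(ids, paste0("v", seq_len(nloc))))
}

## a clean 3-generation chain used by the QC repair fixtures
qc_base <- function(nloc = 100, seed = 42) {
  set.seed(seed)
  params <- sim_params(n_founders = 6, n_generations = 2, gen_size = 8,
                       n_chr = 1, var_per_chr = nloc, hd_per_chr = nloc,
                       ld_per_chr = nloc, founder_beta = c(2, 2))
  ped <- as_pedigree(data.frame(
    id = c("gs", "gd", "p", "m", "k1", "k2", "k3"),
    sire = c(NA, NA, "gs", NA, "p", "p", "p"),
    dam = c(NA, NA, "gd", NA, "m", "m", "m")), quiet = TRUE)
  map <- sim_genetic_map(1, 100, nloc)
  truth <- drop_genotypes(ped, map, params)
  list(ped = ped, g = true_genotypes(truth))
}

## QC fixture corruptions (shared by unit and acceptance tests)
qc_wrong_sample <- function(seed = 42) {
  fx <- qc_base(seed = seed)
  set.seed(1)
  fx$g["p", ] <- sample(c(0L, 2L), ncol(fx$g), replace = TRUE)
  fx
}

qc_wrong_link <- function(seed = 43) {
  fx <- qc_base(seed = seed)
  bad <- fx$g["k1", ]
  hom_p <- which(fx$g["p", ] == 2 & fx$g["m", ] == 0)
  bad[hom_p] <- 0L
  fx$g["k1", ] <- bad
  fx
}

qc_wrong_litter_parent <- function(seed = 44) {
  fx <- qc_base(seed = seed)
  hom2 <- which(fx$g["p", ] == 2)
  for (k in c("k1", "k2", "k3")) {
    row <- fx$g[k, ]
    row[hom2] <- 0L
    row[hom2][fx$g["m", hom2] == 2] <- 1L
    fx$g[k, ] <- row
  }
  fx
}
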
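test_that("simulated pedigrees have the requested discrete-generation shape", {
  p <- sim_params(n_founders = 10, n_generations = 1, gen_size = 20,
                  n_chr = 1, var_per_chr = 100, hd_per_chr = 10,
                  ld_per_chr = 2)
  ped <- sim_pedigree(p, seed = 1)
  expect_equal(nrow(ped), 30)
  expect_equal(sum(ped$gen == 0), 10)
  expect_true(all(which(ped$gen == 0) < min(which(ped$gen == 1))))

  ## zero progeny generations: founders only
  p0 <- sim_params(n_founders = 7, n_generations = 0, gen_size = 5,
                   n_chr = 1, var_per_chr = 10, hd_per_chr = 2,
                   ld_per_chr = 1)
  expect_equal(nrow(sim_pedigree(p0, seed = 1)), 7)

  ## determinism under a fixed seed
  expect_identical(sim_pedigree(p, seed = 42), sim_pedigree(p, seed = 42))
})

test_that("founder genotypes are Hardy-Weinberg at the drawn frequency", {
  ## >= 10,000 founder draws at p = 0.5: chi-square not rejected at 0.01
  n <- 10000
  ped <- as_pedigree(data.frame(id = sprintf("f%05d", 1:n), sire = NA,
                                dam = NA), quiet = TRUE)
  map <- sim_genetic_map(1, 100, 2)
  p <- sim_params(n_founders = n, n_generations = 0, gen_size = 1,
                  founder_beta = c(1e6, 1e6), n_chr = 1, var_per_chr = 2,
                  hd_per_chr = 1, ld_per_chr = 1)  # beta collapses to 0.5
  truth <- drop_genotypes(ped, map, p, seed = 5)
  g <- true_genotypes(truth)[, 1]
  obs <- tabulate(g + 1L, 3)
  chi <- sum((obs - n * c(0.25, 0.5, 0.25))^2 / (n * c(0.25, 0.5, 0.25)))
  expect_lt(chi, qchisq(0.99, df = 2))
})

test_that("gene dropping is Mendelian-consistent with ~1 crossover/Morgan", {
  p <- sim_params(n_founders = 20, n_generations = 2, gen_size = 30,
                  n_chr = 1, var_per_chr = 200, hd_per_chr = 20,
                  ld_per_chr = 5)
  ped <- sim_pedigree(p, seed = 2)
  map <- sim_genetic_map(1, 100, 200)
  truth <- drop_genotypes(ped, map, p, seed = 2)
  pi <- ped_indices(ped)
  for (i in seq_len(nrow(ped))) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (!is.na(s)) {
      expect_true(all(truth$pat[i, ] == truth$pat[s, ] |
                        truth$pat[i, ] == truth$mat[s, ]))
    }
    if (!is.na(d)) {
      expect_true(all(truth$mat[i, ] == truth$pat[d, ] |
                        truth$mat[i, ] == truth$mat[d, ]))
    }
  }
  ## zero opposing homozygotes between true parent-progeny genotypes
  g <- true_genotypes(truth)
  conf <- mendelian_conflicts(g, ped)
  expect_equal(sum(conf$n_opposing), 0L)

  ## mean crossovers per transmitted 100 cM gamete ~ 1.0 +- 0.05:
  ## count segregation-origin switches over many gametes
  nbig <- 5000
  pedbig <- as_pedigree(
    data.frame(id = c("s", "d", sprintf("c%04d", 1:nbig)),
               sire = c(NA, NA, rep("s", nbig)),
               dam = c(NA, NA, rep("d", nbig))), quiet = TRUE)
  mapd <- sim_genetic_map(1, 100, 500)
  td <- drop_genotypes(pedbig, mapd,
                       sim_params(n_founders = 2, n_generations = 1,
                                  gen_size = nbig, n_chr = 1,
                                  var_per_chr = 500, hd_per_chr = 5,
                                  ld_per_chr = 1), seed = 3)
  xo <- mean(c(
    rowSums(abs(t(apply(td$seg_pat[-(1:2), ], 1, diff)))),
    rowSums(abs(t(apply(td$seg_mat[-(1:2), ], 1, diff))))
  ))
  ## observed switches undercount crossovers between the outermost markers
  ## only slightly (markers span 99.8 of 100 cM)
  expect_gt(xo, 0.9)
  expect_lt(xo, 1.1)
})

test_that("panels are nested, evenly spaced and respect boundaries", {
  map <- sim_genetic_map(1, 100, 150)
  pan <- make_panels(map, hd_per_chr = 15, ld_per_chr = 3)
  expect_length(pan$ld, 3)
  expect_true(all(pan$ld %in% pan$hd))
  expect_true(all(pan$hd %in% pan$sequence))
  ## hd positions approximately equidistant: max gap <= 2x mean gap
  pos <- sort(map$pos_cm[match(pan$hd, map$variant)])
  gaps <- diff(pos)
  expect_lte(max(gaps), 2 * mean(gaps))
  ## ld == hd at the boundary
  pan2 <- make_panels(map, 10, 10)
  expect_setequal(pan2$ld, pan2$hd)
  expect_error(make_panels(map, 151, 1), "not enough")
})

test_that("array observation is noise-free and panel-masked", {
  pop <- small_pop(seed = 4, n_founders = 10, n_generations = 1,
                   gen_size = 20, var_per_chr = 100, hd_per_chr = 20,
                   ld_per_chr = 5)
  g <- pop$genotypes
  tg <- true_genotypes(pop$truth)
  for (id in rownames(g)) {
    st <- pop$status[[id]]
    if (st == "none") {
      expect_true(all(is.na(g[id, ])))
    } else {
      panel <- if (st == "HD") pop$panels$hd else pop$panels$ld
      expect_true(all(!is.na(g[id, panel])))
      expect_equal(unname(g[id, panel]), unname(tg[id, panel]))
      off <- setdiff(colnames(g), panel)
      if (length(off)) expect_true(all(is.na(g[id, off])))
    }
  }
})

test_that("read model is Poisson-gamma with the stated error rate", {
  n <- 100
  ped <- as_pedigree(data.frame(id = sprintf("i%03d", 1:n), sire = NA,
                                dam = NA), quiet = TRUE)
  nv <- 2000
  map <- sim_genetic_map(1, 100, nv)
  p <- sim_params(n_founders = n, n_generations = 0, gen_size = 1,
                  founder_beta = c(1e6, 1e6), n_chr = 1, var_per_chr = nv,
                  hd_per_chr = 10, ld_per_chr = 2, seq_error = 0.01,
                  gamma_shape = 4)
  truth <- drop_genotypes(ped, map, p, seed = 6)
  cov <- stats::setNames(rep(2, n), ped$id)
  rc <- simulate_reads(truth, cov, p, seed = 6)
  ## zero coverage: no reads at all
  rc0 <- simulate_reads(truth, stats::setNames(0, ped$id[1]), p, seed = 6)
  expect_equal(nrow(rc0), 0L)
  ## mean reads per (i, v) pair at c = 2 over 100,000 pairs: 2.0 +- 0.05
  total <- sum(rc$refReads + rc$altReads)
  expect_equal(total / (n * nv), 2, tolerance = 0.05 / 2)
  ## homozygous-ref sites: alt fraction ~ e over >= 1e5 reads
  g <- true_genotypes(truth)
  hom <- rc[g[cbind(rc$id, rc$variant)] == 0, ]
  tot_reads <- sum(hom$refReads + hom$altReads)
  expect_gte(tot_reads, 1e5)
  frac <- sum(hom$altReads) / tot_reads
  expect_equal(frac, 0.01, tolerance = 0.003 / 0.01)

  ## overdispersion: per-variant totals vary more than Poisson when the
  ## gamma shape is finite, and like Poisson in the near-degenerate limit
  per_var <- tapply(rc$refReads + rc$altReads,
                    factor(rc$variant, levels = map$variant), sum,
                    default = 0)
  disp <- var(per_var) / mean(per_var)
  expect_gt(disp, 2)  # gamma shape 4 inflates variance across sites
  pflat <- sim_params(n_founders = n, n_generations = 0, gen_size = 1,
                      founder_beta = c(1e6, 1e6), n_chr = 1,
                      var_per_chr = nv, hd_per_chr = 10, ld_per_chr = 2,
                      gamma_shape = 1e6)
  rcf <- simulate_reads(truth, cov, pflat, seed = 7)
  per_varf <- tapply(rcf$refReads + rcf$altReads,
                     factor(rcf$variant, levels = map$variant), sum,
                     default = 0)
  dispf <- var(per_varf) / mean(per_varf)
  expect_lt(dispf, 1.5)
  expect_error(simulate_reads(truth, stats::setNames(-1, ped$id[1]), p),
               "negative")
})

test_that("the full generator is reproducible under a fixed seed", {
  p <- sim_params(n_founders = 15, n_generations = 2, gen_size = 20,
                  n_chr = 1, var_per_chr = 60, hd_per_chr = 10,
                  ld_per_chr = 3)
  a <- sim_population(p, seed = 9)
  b <- sim_population(p, seed = 9)
  expect_identical(a$truth$pat, b$truth$pat)
  expect_identical(as.data.frame(a$reads), as.data.frame(b$reads))
  expect_identical(a$plan$id, b$plan$id)
})
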
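test_that("penetrance combines reads and array genotypes correctly", {
  s <- peel_settings(seq_error = 0.01, geno_error = 1e-4)
  rc <- as_read_counts(data.frame(id = "i1", variant = "v1",
                                  refReads = 2, altReads = 0))
  pen <- penetrance(NULL, rc, ids = c("i1", "i2"), loci = "v1", settings = s)
  ## two ref reads at e = 0.01: (0.99^2, 0.25, 0.25, 0.01^2)
  expect_equal(unname(pen[, "i1", 1]), c(0.9801, 0.25, 0.25, 1e-4))
  ## no data: all ones
  expect_equal(unname(pen[, "i2", 1]), rep(1, 4))

  ## balanced deep reads: heterozygous states carry > 0.99 of the mass
  rc2 <- as_read_counts(data.frame(id = "i1", variant = "v1",
                                   refReads = 5, altReads = 5))
  pen2 <- penetrance(NULL, rc2, ids = "i1", loci = "v1", settings = s)
  p <- pen2[, 1, 1] / sum(pen2[, 1, 1])
  expect_gt(p[2] + p[3], 0.99)

  ## array genotype: matching states get 1 - eps, others eps/2
  g <- matrix(1L, 1, 1, dimnames = list("i1", "v1"))
  pen3 <- penetrance(g, NULL, ids = "i1", loci = "v1", settings = s)
  expect_equal(unname(pen3[, 1, 1]),
               c(5e-5, 1 - 1e-4, 1 - 1e-4, 5e-5))
  ## read and array contributions multiply
  pen4 <- penetrance(g, rc, ids = "i1", loci = "v1", settings = s)
  expect_equal(unname(pen4[, 1, 1]), unname(pen[, "i1", 1] * pen3[, 1, 1]))

  expect_error(as_read_counts(data.frame(id = "a", variant = "v",
                                         refReads = 1, altReads = -2)),
               "negative")
})

test_that("an obligate heterozygote child is called with phase", {
  ped <- trio_ped()
  pen <- rbind(obs_pen(0), obs_pen(2), rep(1, 4))  # sire aa, dam AA
  res <- single_locus_peel(ped, pen, p = 0.5)
  ## child paternal allele = a, maternal = A: ordered state aA
  expect_gt(res$prob["c", "aA"], 0.999)
  expect_equal(unname(res$dosage[["c"]]), 1, tolerance = 1e-6)
})

test_that("single-locus posteriors equal exhaustive enumeration on
           loop-free pedigrees", {
  set.seed(101)
  s <- peel_settings(maxit = 50, tol = 1e-10)
  for (ped in list(trio_ped(), ped6(), ped8())) {
    for (rep_i in 1:3) {
      n <- nrow(ped)
      pen <- matrix(runif(4 * n), n, 4)
      seg <- matrix(runif(4 * n), n, 4)
      seg <- seg / rowSums(seg)
      p <- runif(1, 0.1, 0.9)
      got <- single_locus_peel(ped, pen, seg, p, s)$prob
      want <- enum_peel_oracle(ped, pen, seg, p)
      expect_lt(max(abs(got - want)), 1e-6)
      ## uniform segregation path too
      got0 <- single_locus_peel(ped, pen, NULL, p, s)$prob
      want0 <- enum_peel_oracle(ped, pen, NULL, p)
      expect_lt(max(abs(got0 - want0)), 1e-6)
    }
  }
})

test_that("loopy peeling approximates enumeration on an inbred pedigree", {
  ## 6-member half-sib-mating loop; evidence is Mendelian-consistent
  ## genotype observations (gene-dropped) with the loop's inner pair
  ## hidden -- the regime pedigree data actually present
  ped <- as_pedigree(data.frame(
    id = c("a", "m1", "m2", "c", "d", "e"),
    sire = c(NA, NA, NA, "a", "a", "c"),
    dam = c(NA, NA, NA, "m1", "m2", "d")), quiet = TRUE)
  st <- peel_settings(maxit = 200, tol = 1e-12)
  pi <- ped_indices(ped)
  set.seed(11)
  worst <- 0
  for (rep_i in 1:20) {
    p <- runif(1, 0.2, 0.8)
    hap <- matrix(NA_integer_, 6, 2)
    for (j in 1:6) {
      sr <- pi$sire[j]; dm <- pi$dam[j]
      hap[j, 1] <- if (is.na(sr)) rbinom(1, 1, p) else hap[sr, sample(1:2, 1)]
      hap[j, 2] <- if (is.na(dm)) rbinom(1, 1, p) else hap[dm, sample(1:2, 1)]
    }
    g <- rowSums(hap)
    pen <- matrix(1, 6, 4)
    for (j in which(!ped$id %in% c("c", "d"))) pen[j, ] <- obs_pen(g[j])
    got <- single_locus_peel(ped, pen, NULL, p, st)$prob
    want <- enum_peel_oracle(ped, pen, NULL, p)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-3)
})

test_that("segregation-conditioned transmission follows the phased parent", {
  ## child with segregation fixed at pp and sire phased Aa (paternal A):
  ## the child's paternal allele must be A
  ped <- trio_ped()
  pen <- rbind(c(0, 0, 1, 0),   # sire ordered Aa: paternal A, maternal a
               obs_pen(0),      # dam aa
               rep(1, 4))
  seg <- matrix(0.25, 3, 4)
  seg[3, ] <- c(1, 0, 0, 0)     # pp: paternal gamete copies sire's paternal
  res <- single_locus_peel(ped, pen, seg, p = 0.5,
                           peel_settings(maxit = 50, tol = 1e-10))
  ## child paternal allele A, maternal a: ordered state Aa
  expect_gt(res$prob["c", "Aa"], 1 - 1e-3)
})

test_that("probability vectors are normalized and relabeling flips dosage", {
  set.seed(5)
  ped <- ped8()
  pen <- matrix(runif(32, 0.01, 1), 8, 4)
  res <- single_locus_peel(ped, pen, NULL, 0.3)
  expect_true(all(abs(rowSums(res$prob) - 1) < 1e-8))
  ## allele relabel: swap ref/alt in penetrance (reverse state order) and
  ## prior p -> 1-p: dosage maps d -> 2-d
  res2 <- single_locus_peel(ped, pen[, 4:1], NULL, 0.7)
  expect_equal(unname(res2$dosage), unname(2 - res$dosage),
               tolerance = 1e-10)
})

test_that("adding reads consistent with the true genotype sharpens it", {
  ped <- trio_ped()
  s <- peel_settings()
  pen0 <- rbind(obs_pen(1), obs_pen(1), rep(1, 4))
  base <- single_locus_peel(ped, pen0, NULL, 0.5, s)$prob["c", ]
  probs <- numeric(0)
  for (nr in c(1, 2, 4, 8)) {
    rc <- as_read_counts(data.frame(id = "c", variant = "v1",
                                    refReads = nr, altReads = 0))
    penr <- penetrance(NULL, rc, ids = ped$id, loci = "v1", settings = s)
    pen <- pen0 * t(penr[, , 1])
    pr <- single_locus_peel(ped, pen, NULL, 0.5, s)$prob["c", "aa"]
    probs <- c(probs, pr)
  }
  expect_true(all(diff(c(base[["aa"]], probs)) > 0))
})

test_that("multi-locus peeling recovers recorded segregation states", {
  set.seed(7)
  ## three-generation family, 200 intermediate-MAF markers, fully observed
  params <- sim_params(n_founders = 4, n_generations = 2, gen_size = 6,
                       n_chr = 1, var_per_chr = 200, hd_per_chr = 200,
                       ld_per_chr = 200, founder_beta = c(2, 2))
  ped <- family3gen(8)
  map <- sim_genetic_map(1, 100, 200)
  truth <- drop_genotypes(ped, map, params)
  pen <- penetrance(true_genotypes(truth), NULL, ids = ped$id,
                    loci = map$variant)
  res <- multi_locus_peel(ped, pen, map$pos_cm,
                          settings = peel_settings(multi_maxit = 20,
                                                   multi_tol = 1e-4))
  ## founders stay uniform
  expect_true(all(abs(res$seg[, 1, ] - 0.25) < 1e-12))
  ## normalization
  expect_true(all(abs(colSums(res$seg[, , 50]) - 1) < 1e-8))
  ## grandchild generation: segregation identifiable (their parents'
  ## phase is anchored by the founder genotypes)
  kids <- paste0("k", 1:8)
  hit <- 0; tot <- 0
  for (k in kids) {
    i <- match(k, ped$id)
    truestate <- 2 * (1 - truth$seg_pat[k, ]) + (1 - truth$seg_mat[k, ]) + 1
    for (l in seq_len(200)) {
      tot <- tot + 1
      if (res$seg[truestate[l], i, l] >= 0.95) hit <- hit + 1
    }
  }
  expect_gte(hit / tot, 0.95)
})

test_that("segregation interpolation bridges flanking posteriors", {
  n <- 3
  seg <- array(0.25, c(4, n, 2))
  ## individual 2: both flanks certain pp
  seg[, 2, 1] <- c(1, 0, 0, 0); seg[, 2, 2] <- c(1, 0, 0, 0)
  ## individual 3: left pp, right mp (paternal indicator disagrees)
  seg[, 3, 1] <- c(1, 0, 0, 0); seg[, 3, 2] <- c(0, 0, 1, 0)
  panel_pos <- c(10, 30)
  ## at a panel position: returned unchanged
  out <- interpolate_segregation(seg, panel_pos, c(10, 12, 20, 28, 30))
  expect_equal(out[, , 1], seg[, , 1], ignore_attr = TRUE)
  expect_equal(out[, , 5], seg[, , 2], ignore_attr = TRUE)
  ## agreeing certain flanks at small distance: near certainty in between
  expect_gt(out[1, 2, 3], 0.95)
  ## disagreeing flanks: paternal indicator decreases monotonically with
  ## distance from the pp flank
  p_pat <- out[1, 3, 2:4] + out[2, 3, 2:4]
  expect_true(all(diff(p_pat) < 0))
  ## closed-form check at the midpoint: message product of the two flanks
  rL <- haldane(10); rR <- haldane(10)
  mL <- 1 * (1 - rL); mR <- 0 * (1 - rR) + 1 * rR
  want <- mL * mR / (mL * mR + (1 - mL) * (1 - mR))
  expect_equal(unname(out[1, 3, 3] + out[2, 3, 3]), want, tolerance = 1e-10)
  expect_error(interpolate_segregation(seg, numeric(0), 1), "empty panel")
})

test_that("hybrid peeling is exact where data saturate and Mendelian in
           expectation for data-free progeny", {
  set.seed(31)
  params <- sim_params(n_founders = 12, n_generations = 2, gen_size = 24,
                       n_chr = 1, var_per_chr = 120, hd_per_chr = 120,
                       ld_per_chr = 120, founder_beta = c(2, 2))
  ped <- sim_pedigree(params)
  map <- sim_genetic_map(1, 100, 120)
  truth <- drop_genotypes(ped, map, params)
  status <- stats::setNames(rep("HD", nrow(ped)), ped$id)
  panels <- make_panels(map, 120, 120)
  G <- observe_arrays(truth, panels, status)
  empty_reads <- as_read_counts(data.frame(id = character(0),
                                           variant = character(0),
                                           refReads = integer(0),
                                           altReads = integer(0)))
  res <- hybrid_peel(ped, G, empty_reads, map, panels)
  ## everyone observed at every variant: dosages match truth except for
  ## isolated entries where the fixed-segregation approximation of the
  ## hybrid second step conflicts with an observation near a crossover
  ## or phase ambiguity (see the methods vignette)
  tg <- true_genotypes(truth)
  err <- abs(res$dosages - tg)
  expect_lt(mean(err), 1e-3)
  expect_lt(mean(err > 1e-3), 0.01)
  expect_lt(max(err), 0.1)

  ## an extra ungenotyped, unsequenced child of two fully observed parents
  ## gets the mid-parent expected dosage
  ped2 <- as_pedigree(dplyr::bind_rows(
    as.data.frame(ped)[, c("id", "sire", "dam", "sex")],
    data.frame(id = "orphan", sire = ped$id[1], dam = ped$id[2],
               sex = NA)), quiet = TRUE)
  res2 <- hybrid_peel(ped2, G, empty_reads, map, panels)
  gp <- true_genotypes(truth)
  mid <- (gp[ped$id[1], ] + gp[ped$id[2], ]) / 2
  expect_lt(max(abs(res2$dosages["orphan", ] - mid)), 1e-2)
})

test_that("multi-locus peeling rejects unsorted loci", {
  ped <- trio_ped()
  pen <- array(1, c(4, 3, 2))
  expect_error(multi_locus_peel(ped, pen, c(5, 2)), "ordered")
})
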
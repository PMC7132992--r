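pp_fix <- function() {
  memo_fixture("perturb_small", function() {
    pop <- small_pop(seed = 41, n_founders = 16, n_generations = 3,
                     gen_size = 60, var_per_chr = 200, hd_per_chr = 30,
                     ld_per_chr = 8)
    ## explicit coverage ladder with several high-coverage key sires so
    ## every donor pool is populated
    set.seed(42)
    rk <- rank_top_parents(pop$ped, names(pop$status)[pop$status != "none"])
    high <- utils::head(rk$sires$id, 3)
    cov <- stats::setNames(c(30, 15, 15), high)
    lows <- utils::head(setdiff(rk$dams$id, high), 6)
    cov <- c(cov, stats::setNames(rep(2, length(lows)), lows))
    spread <- sample(setdiff(pop$ped$id, names(cov)), 6)
    cov <- c(cov, stats::setNames(rep(1, length(spread)), spread))
    pop$plan <- tibble::tibble(id = names(cov), coverage = unname(cov),
                               step = "fixture")
    pop$reads <- simulate_reads(pop$truth, cov, pop$params)
    pop
  })
}

test_that("scenario construction draws donors from the stated pools", {
  pop <- pp_fix()
  cov <- attr(pop$reads, "coverage")
  targets <- names(cov)[cov >= 15]
  expect_gt(length(targets), 0)
  scen <- make_scenarios(pop, targets, seed = 3)
  expect_equal(nrow(scen), 4 * length(targets))
  seqd <- scen[scen$type == "seq_misassign", ]
  expect_true(all(cov[seqd$donor] >= 15))
  expect_true(all(seqd$donor != seqd$target))
  arr <- scen[scen$type == "array_misassign", ]
  expect_true(all(pop$status[arr$donor] == "HD"))
  expect_true(all(is.na(scen$donor[scen$type == "removal_control"])))
})

test_that("injections are surgical", {
  pop <- pp_fix()
  cov <- attr(pop$reads, "coverage")
  target <- names(cov)[which.max(cov)]
  donor <- names(cov)[cov >= 15 & names(cov) != target][1]

  ## sequence misassignment: target's rows equal donor's former rows
  ## (relabelled), donor unchanged, all other individuals untouched
  p1 <- perturb_inject(pop, list(type = "seq_misassign", target = target,
                                 donor = donor))
  tgt_rows <- p1$reads[p1$reads$id == target,
                       c("variant", "refReads", "altReads")]
  don_rows <- pop$reads[pop$reads$id == donor,
                        c("variant", "refReads", "altReads")]
  expect_equal(as.data.frame(tgt_rows[order(tgt_rows$variant), ]),
               as.data.frame(don_rows[order(don_rows$variant), ]),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(p1$reads[p1$reads$id == donor, ]),
               as.data.frame(pop$reads[pop$reads$id == donor, ]))
  others <- setdiff(unique(pop$reads$id), c(target, donor))
  expect_equal(nrow(p1$reads[p1$reads$id %in% others, ]),
               nrow(pop$reads[pop$reads$id %in% others, ]))

  ## removal control: target's reads gone, everything else identical
  p2 <- perturb_inject(pop, list(type = "removal_control", target = target,
                                 donor = NA))
  expect_equal(nrow(p2$reads[p2$reads$id == target, ]), 0L)
  expect_identical(p2$ped, pop$ped)
  expect_identical(p2$genotypes, pop$genotypes)

  ## array misassignment: only the target's genotype row changes
  hd_donor <- names(pop$status)[pop$status == "HD"]
  hd_donor <- setdiff(hd_donor, target)[1]
  p3 <- perturb_inject(pop, list(type = "array_misassign", target = target,
                                 donor = hd_donor))
  expect_equal(p3$genotypes[target, ], pop$genotypes[hd_donor, ])
  keep <- setdiff(rownames(pop$genotypes), target)
  expect_identical(p3$genotypes[keep, ], pop$genotypes[keep, ])

  ## pedigree misassignment: the donor's progeny now name the target
  sired <- pop$ped$id[!is.na(pop$ped$sire)]
  donor2 <- pop$ped$sire[match(sired[1], pop$ped$id)]
  tgt2 <- setdiff(pop$ped$id[pop$ped$gen == max(pop$ped$gen)], donor2)[1]
  p4 <- perturb_inject(pop, list(type = "pedigree_misassign",
                                 target = tgt2, donor = donor2))
  mis <- p4$misassigned_progeny
  expect_gt(length(mis), 0)
  rows <- match(mis, p4$ped$id)
  expect_true(all(p4$ped$sire[rows] == tgt2 | p4$ped$dam[rows] == tgt2))
  ## the target never becomes its own ancestor
  expect_s3_class(p4$ped, "ped_df")
  expect_error(perturb_inject(pop, list(type = "seq_misassign",
                                        target = target, donor = target)),
               "donor == target")
})

test_that("a no-op perturbation yields correlations of exactly 1", {
  pop <- pp_fix()
  res <- memo_fixture("perturb_small_res", function() {
    hybrid_peel(pop$ped, pop$genotypes, pop$reads, pop$map, pop$panels)
  })
  ## removing the reads of an individual that has none changes nothing
  cov <- attr(pop$reads, "coverage")
  noread <- setdiff(pop$ped$id, names(cov))[1]
  p <- perturb_inject(pop, list(type = "removal_control", target = noread,
                                donor = NA))
  res2 <- hybrid_peel(p$ped, p$genotypes, p$reads, p$map, p$panels)
  imp <- perturb_impact(res$dosages, res2$dosages, pop$ped, noread)
  expect_true(all(abs(imp$mean_correlation[imp$n > 0] - 1) < 1e-8))
  ## empty relative classes are reported absent, not dropped
  founder <- pop$ped$id[1]
  imp2 <- perturb_impact(res$dosages, res2$dosages, pop$ped, founder)
  expect_true(is.na(imp2$mean_correlation[imp2$class == "grandparents"]))
})

test_that("sequence misassignment corrupts the target more than removal", {
  pop <- pp_fix()
  res <- memo_fixture("perturb_small_res", function() {
    hybrid_peel(pop$ped, pop$genotypes, pop$reads, pop$map, pop$panels)
  })
  cov <- attr(pop$reads, "coverage")
  targets <- names(cov)[cov >= 15][1]
  study <- run_perturbation_study(pop, targets,
                                  types = c("removal_control",
                                            "seq_misassign"),
                                  seed = 5, subsample = 200,
                                  reference = res)
  tgt <- study[study$class == "ind", ]
  expect_lt(tgt$mean_correlation[tgt$type == "seq_misassign"],
            tgt$mean_correlation[tgt$type == "removal_control"])
  ## schema: one row per (type, class) per scenario
  expect_equal(sort(unique(study$type)),
               c("removal_control", "seq_misassign"))
})
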
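test_that("individual factor tables have the full 23-column schema", {
  pop <- memo_fixture("fact_pop", function() {
    small_pop(seed = 31, n_founders = 12, n_generations = 3,
              gen_size = 50, var_per_chr = 200, hd_per_chr = 25,
              ld_per_chr = 6)
  })
  tab <- build_individual_factors(pop$ped, pop$status, pop$plan)
  expect_equal(ncol(tab), 24)  # id + 23 factors
  expect_equal(nrow(tab), nrow(pop$ped))
  ## founders with unknown parents: zero genotyped parents/grandparents
  f1 <- tab[tab$id == pop$ped$id[1], ]
  expect_equal(f1$nParLD + f1$nParHD + f1$nGParLD + f1$nGParHD, 0)
  ## counts bounded by pedigree structure
  expect_true(all(tab$nParLD + tab$nParHD + tab$nParNone <= 2))
  expect_true(all(tab$nGParLD + tab$nGParHD + tab$nGParNone <= 4))
  ## direct count check on one individual with known relatives
  i <- pop$ped$id[which(pop$ped$gen == 2)[1]]
  rel <- ped_relatives(pop$ped, i)
  expect_equal(tab$nParHD[tab$id == i],
               sum(pop$status[rel$parents] == "HD"))
  cov <- stats::setNames(pop$plan$coverage, pop$plan$id)
  expect_equal(tab$covProgSeq[tab$id == i],
               sum(cov[intersect(rel$progeny, names(cov))]))
})

test_that("variant factor tables carry the 6 variant-level factors", {
  pop <- memo_fixture("fact_pop", function() {
    small_pop(seed = 31, n_founders = 12, n_generations = 3,
              gen_size = 50, var_per_chr = 200, hd_per_chr = 25,
              ld_per_chr = 6)
  })
  vars <- pop$map$variant[c(1, 50, 100)]
  tab <- build_variant_factors(pop, vars)
  expect_equal(names(tab), c("variant", "popSize", "maf", "relPosition",
                             "distToPanel", "cumCoverage", "nIndSeq"))
  ## panel variants sit at distance zero
  pv <- intersect(pop$panels$hd, pop$map$variant)[1]
  tabp <- build_variant_factors(pop, pv)
  expect_equal(tabp$distToPanel, 0)
  ## read-derived counts match the raw table
  rd <- pop$reads[pop$reads$variant == vars[2], ]
  expect_equal(tab$nIndSeq[2], length(unique(rd$id)))
  expect_equal(tab$cumCoverage[2], sum(rd$refReads + rd$altReads))
  expect_true(all(tab$maf >= 0 & tab$maf <= 0.5))
})

test_that("regression trees honor the R-squared gain rule", {
  set.seed(11)
  ## response exactly equal to a binary predictor: one split, R^2 = 1
  n <- 500
  tab <- tibble::tibble(id = as.character(1:n),
                        x = rep(c(0, 1), n / 2),
                        z = runif(n),
                        accuracy = rep(c(0.4, 0.9), n / 2))
  tr <- fit_accuracy_tree(tab)
  expect_equal(first_split(tr), "x")
  td <- tidy(tr)
  expect_equal(sum(!td$is_leaf), 1L)
  expect_equal(sum(td$r2_gain, na.rm = TRUE), 1, tolerance = 1e-10)
  expect_equal(glance(tr)$n_leaves, 2L)

  ## pure-noise predictors on a large sample: no split reaches 0.005
  n2 <- 10000
  noise <- tibble::tibble(id = as.character(1:n2),
                          a = rnorm(n2), b = runif(n2),
                          accuracy = rnorm(n2))
  tr2 <- fit_accuracy_tree(noise)
  expect_true(is.na(first_split(tr2)))

  ## variance decomposition: the stronger factor splits first
  x1 <- rep(c(0, 1), 2500)
  x2 <- rep(c(0, 0, 1, 1), 1250)
  y <- 0.5 * x1 + 0.22 * x2 + rnorm(5000, 0, 0.35)
  tab3 <- tibble::tibble(id = as.character(1:5000), f1 = x1, f2 = x2,
                         accuracy = y)
  expect_equal(first_split(fit_accuracy_tree(tab3)), "f1")

  ## constant response: root-only tree
  tab4 <- tibble::tibble(id = as.character(1:100), x = rnorm(100),
                         accuracy = 0.9)
  expect_true(is.na(first_split(fit_accuracy_tree(tab4))))
})

test_that("multi-way merging flags consecutive same-variable splits", {
  set.seed(13)
  x <- runif(3000)
  y <- cut(x, c(0, 0.3, 0.7, 1), labels = FALSE) * 0.3 +
    rnorm(3000, 0, 0.03)
  tab <- tibble::tibble(id = as.character(1:3000), x = x, accuracy = y)
  td <- tidy(fit_accuracy_tree(tab))
  ## a three-level step function needs consecutive splits on x
  expect_gte(sum(td$merged_multiway), 1)
})

test_that("low-accuracy flags partition the table at the threshold", {
  set.seed(17)
  tab <- tibble::tibble(id = as.character(1:400),
                        x = rep(c(0, 1), 200),
                        accuracy = rep(c(0.8, 0.99), 200) +
                          rnorm(400, 0, 0.005))
  tr <- fit_accuracy_tree(tab)
  fl <- predict_low_accuracy(tr, tab, threshold = 0.95)
  expect_equal(nrow(fl), 400L)
  expect_true(all(fl$flag == (fl$predicted < 0.95)))
  expect_true(all(fl$flag[tab$x == 0]))
  expect_false(any(fl$flag[tab$x == 1]))
})

test_that("cross-validation metrics are exact for clean predictors", {
  set.seed(19)
  ## perfect predictor: sensitivity and specificity both 1
  tab <- tibble::tibble(id = as.character(1:400),
                        x = rep(c(0, 1), 200),
                        accuracy = rep(c(0.7, 0.99), 200) +
                          rnorm(400, 0, 0.004))
  cv <- crossvalidate_low_accuracy(tab, k = 10, seed = 1)
  expect_equal(cv$sensitivity, 1.0)
  expect_equal(cv$specificity, 1.0)
  ## constant predictor with mostly-high accuracy: nobody flagged
  tab2 <- tibble::tibble(id = as.character(1:300), x = 1,
                         accuracy = c(rep(0.99, 280), rep(0.5, 20)))
  cv2 <- crossvalidate_low_accuracy(tab2, k = 5, seed = 1)
  expect_equal(cv2$sensitivity, 0)
  expect_equal(cv2$specificity, 1)
  ## confusion arithmetic on constructed counts
  cs <- confusion_stats(tp = 33, fn = 17, tn = 190, fp = 10)
  expect_equal(cs$sensitivity, 0.66)
  expect_equal(cs$specificity, 0.95)
  ## band table covers the stated accuracy bands
  expect_setequal(as.character(cv$by_band$band),
                  c("0-0.5", "0.5-0.75", "0.75-0.85", "0.85-0.9",
                    "0.9-0.95"))
})

test_that("the linear screen finds real factors and stays calibrated", {
  set.seed(23)
  n <- 1000
  x <- rnorm(n); z <- rnorm(n)
  tab <- tibble::tibble(id = as.character(1:n), x = x, z = z,
                        accuracy = 0.5 * x + rnorm(n, 0, 0.05))
  sc <- linear_screen(tab)
  expect_lt(sc$p_value[sc$factor == "x"], 1e-6)
  expect_gt(sc$p_value[sc$factor == "z"], 1e-4)
  ## null p-values roughly uniform across replicates (KS at alpha 0.01)
  ps <- replicate(200, {
    y <- rnorm(120)
    tb <- tibble::tibble(id = as.character(1:120), w = rnorm(120),
                         accuracy = y)
    linear_screen(tb)$p_value[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  ## no usable factor columns
  expect_error(linear_screen(tibble::tibble(id = "a", accuracy = 1)),
               "factor|rows")
})
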
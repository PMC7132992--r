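#' Individual-level explanatory factor table
#'
#' One row per individual with the 23 factors used to explain
#' individual-wise imputation accuracy: population size, own genotyping
#' status, counts of relatives genotyped at each density (4 relationship
#' levels x 3 statuses = 12), counts and cumulative coverage of sequenced
#' relatives (4 levels x 2 = 8), and connectedness (sum of relationship
#' coefficients to the rest of the pedigree).
#'
#' @param ped Pedigree tibble.
#' @param status Named genotyping-status vector (`none`/`LD`/`HD`).
#' @param plan [build_plan()] tibble (sequencing coverage assignments).
#' @return Tibble with `id` plus 23 factor columns.
#' @export
build_individual_factors <- function(ped, status, plan) {
  n <- nrow(ped)
  pi <- ped_indices(ped)
  prog <- ped_progeny(ped)
  cov <- stats::setNames(rep(0, n), ped$id)
  if (!is.null(plan) && nrow(plan)) cov[plan$id] <- plan$coverage
  st <- stats::setNames(rep("none", n), ped$id)
  st[names(status)] <- status

  rel_idx <- function(i) {
    par <- c(pi$sire[i], pi$dam[i]); par <- par[!is.na(par)]
    gpar <- unlist(lapply(par, function(p) c(pi$sire[p], pi$dam[p])))
    gpar <- unique(gpar[!is.na(gpar)])
    pr <- prog[[i]]
    gpr <- unique(unlist(lapply(pr, function(p) prog[[p]])))
    list(gpar = gpar, par = par, prog = pr, gprog = gpr)
  }
  count_status <- function(ix, s) sum(st[ix] == s)

  lv <- c("gpar", "par", "prog", "gprog")
  lv_lab <- c("GPar", "Par", "Prog", "GProg")
  rows <- matrix(0, n, 20)
  for (i in seq_len(n)) {
    r <- rel_idx(i)
    k <- 0
    for (j in seq_along(lv)) {
      ix <- r[[lv[j]]]
      rows[i, k + 1] <- count_status(ix, "none")
      rows[i, k + 2] <- count_status(ix, "LD")
      rows[i, k + 3] <- count_status(ix, "HD")
      k <- k + 3
    }
    for (j in seq_along(lv)) {
      ix <- r[[lv[j]]]
      rows[i, 12 + 2 * j - 1] <- sum(cov[ix] > 0)
      rows[i, 12 + 2 * j] <- sum(cov[ix])
    }
  }
  colnames(rows) <- c(
    paste0("n", rep(lv_lab, each = 3), c("None", "LD", "HD")),
    paste0(rep(c("n", "cov"), 4), rep(lv_lab, each = 2), "Seq")
  )
  conn <- connectedness(ped)
  tibble::tibble(id = ped$id, popSize = n,
                 status = factor(st, levels = c("none", "LD", "HD"))) |>
    dplyr::bind_cols(tibble::as_tibble(rows)) |>
    dplyr::mutate(connectedness = conn$connectedness)
}

#' Variant-level explanatory factor table
#'
#' One row per variant with the 6 variant-level factors: population size,
#' MAF, relative position within the chromosome, distance to the nearest
#' marker-panel variant (0 if on the panel), cumulative sequencing coverage
#' and the number of individuals with at least one read at the site.
#'
#' @param pop `sim_pop` dataset.
#' @param variants Variant ids to include (default all).
#' @return Tibble with `variant` plus 6 factor columns.
#' @export
build_variant_factors <- function(pop, variants = NULL) {
  map <- pop$map
  if (is.null(variants)) variants <- map$variant
  mv <- map[match(variants, map$variant), ]
  true_freq <- colMeans(true_genotypes(pop$truth)[, variants, drop = FALSE]) / 2
  rel_pos <- vapply(seq_len(nrow(mv)), function(k) {
    chr <- map[map$chrom == mv$chrom[k], ]
    (mv$pos_cm[k] - min(chr$pos_cm)) / (max(chr$pos_cm) - min(chr$pos_cm))
  }, numeric(1))
  dist_panel <- vapply(seq_len(nrow(mv)), function(k) {
    if (mv$variant[k] %in% pop$panels$hd) return(0)
    ppos <- map$pos_cm[map$chrom == mv$chrom[k] &
                         map$variant %in% pop$panels$hd]
    if (!length(ppos)) return(NA_real_)
    min(abs(ppos - mv$pos_cm[k]))
  }, numeric(1))
  rd <- pop$reads[pop$reads$variant %in% variants, ]
  n_reads <- table(factor(rd$variant, levels = variants))
  cum_cov <- tapply(rd$refReads + rd$altReads,
                    factor(rd$variant, levels = variants), sum, default = 0)
  tibble::tibble(variant = variants,
                 popSize = nrow(pop$ped),
                 maf = unname(pmin(true_freq, 1 - true_freq)),
                 relPosition = rel_pos,
                 distToPanel = dist_panel,
                 cumCoverage = as.numeric(cum_cov[variants]),
                 nIndSeq = as.integer(n_reads[variants]))
}

#' Fit a regression tree of imputation accuracy on explanatory factors
#'
#' Recursive binary partitioning (rpart, anova method) keeping a split only
#' if it increases the overall model R-squared by at least `min_gain`.
#' Consecutive splits on the same variable are reported merged as
#' multi-way partitions by [tidy.accuracy_tree()].
#'
#' @param table Factor table joined with a response column.
#' @param response Response column name (default `"accuracy"`).
#' @param min_gain Minimum R-squared gain per split (default 0.005).
#' @param min_leaf Minimum observations per leaf.
#' @return Object of class `accuracy_tree` wrapping the rpart fit.
#' @export
fit_accuracy_tree <- function(table, response = "accuracy",
                              min_gain = 0.005, min_leaf = 20) {
  stopifnot(nrow(table) >= 20)
  dat <- as.data.frame(table)
  dat <- dat[!is.na(dat[[response]]), ]
  drop <- intersect(c("id", "variant"), names(dat))
  preds <- setdiff(names(dat), c(response, drop))
  fml <- stats::as.formula(paste(response, "~",
                                 paste(preds, collapse = " + ")))
  ctrl <- rpart::rpart.control(cp = min_gain, minbucket = min_leaf,
                               maxsurrogate = 0, maxcompete = 0, xval = 0)
  if (stats::var(dat[[response]]) == 0) {
    ## constant response: force a root-only tree (zero deviance makes any
    ## split pass rpart's relative-improvement rule vacuously)
    ctrl$maxdepth <- 1
    ctrl$minsplit <- nrow(dat) + 1
  }
  fit <- rpart::rpart(fml, data = dat, method = "anova", control = ctrl)
  structure(list(fit = fit, response = response, min_gain = min_gain,
                 n = nrow(dat)),
            class = "accuracy_tree")
}

#' First partitioning variable of an accuracy tree
#' @param tree `accuracy_tree` object.
#' @return Variable name, or `NA` for a root-only tree.
#' @export
first_split <- function(tree) {
  v <- as.character(tree$fit$frame$var[1])
  if (identical(v, "<leaf>")) NA_character_ else v
}

#' Tidy an accuracy tree into a node table
#'
#' One row per node with the split variable, node size, mean response and
#' the R-squared gain of the split; consecutive child splits on the parent's
#' variable are flagged `merged_multiway`.
#'
#' @param x `accuracy_tree` object.
#' @param ... Unused.
#' @export
tidy.accuracy_tree <- function(x, ...) {
  fr <- x$fit$frame
  node <- as.integer(rownames(fr))
  dev_root <- fr$dev[1]
  gain <- vapply(seq_len(nrow(fr)), function(k) {
    if (fr$var[k] == "<leaf>") return(NA_real_)
    kids <- match(c(2 * node[k], 2 * node[k] + 1), node)
    (fr$dev[k] - sum(fr$dev[kids])) / dev_root
  }, numeric(1))
  parent_var <- as.character(fr$var[match(node %/% 2, node)])
  tibble::tibble(node = node,
                 var = as.character(fr$var),
                 n = fr$n,
                 mean_response = fr$yval,
                 r2_gain = gain,
                 is_leaf = fr$var == "<leaf>",
                 merged_multiway = !is.na(parent_var) &
                   as.character(fr$var) == parent_var &
                   fr$var != "<leaf>")
}

#' @export
#' @rdname tidy.accuracy_tree
#' @param x `accuracy_tree` object.
glance.accuracy_tree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n = x$n,
                 n_splits = sum(!td$is_leaf),
                 n_leaves = sum(td$is_leaf),
                 r_squared = sum(td$r2_gain, na.rm = TRUE),
                 first_split = first_split(x))
}

#' @export
print.accuracy_tree <- function(x, ...) {
  cat("<accuracy_tree> n =", x$n, ", first split:", first_split(x), "\n")
  print(x$fit)
  invisible(x)
}

#' Flag individuals predicted to have low imputation accuracy
#'
#' @param tree `accuracy_tree` fitted on an individual factor table.
#' @param table Factor table to predict for.
#' @param threshold Low-accuracy threshold (default 0.95).
#' @return Tibble with `id` (or `variant`), `predicted`, `flag`.
#' @export
predict_low_accuracy <- function(tree, table, threshold = 0.95) {
  pred <- unname(stats::predict(tree$fit, newdata = as.data.frame(table)))
  key <- intersect(c("id", "variant"), names(table))[1]
  tibble::tibble(!!key := table[[key]], predicted = pred,
                 flag = pred < threshold)
}

#' Sensitivity and specificity from a confusion table
#' @param tp,fn,tn,fp Confusion counts (positives = truly low accuracy).
#' @return Tibble with `sensitivity`, `specificity`.
#' @export
confusion_stats <- function(tp, fn, tn, fp) {
  tibble::tibble(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp))
}

#' Cross-validate the low-accuracy prediction
#'
#' Stratified k-fold cross-validation of the regression-tree flag for
#' individuals below the accuracy threshold. Reports overall sensitivity
#' and specificity plus sensitivity within observed-accuracy bands
#' (0-0.5, 0.5-0.75, 0.75-0.85, 0.85-0.9, 0.9-0.95).
#'
#' @param table Factor table with the response column.
#' @param response Response column name.
#' @param threshold Low-accuracy threshold (default 0.95).
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param min_gain,min_leaf Tree-fitting controls.
#' @return List with `sensitivity`, `specificity`, `by_band` tibble and
#'   `confusion` counts.
#' @export
crossvalidate_low_accuracy <- function(table, response = "accuracy",
                                       threshold = 0.95, k = 10, seed = 1,
                                       min_gain = 0.005, min_leaf = 20) {
  stopifnot(k >= 2)
  set.seed(seed)
  dat <- table[!is.na(table[[response]]), ]
  y_low <- dat[[response]] < threshold
  fold <- integer(nrow(dat))
  fold[y_low] <- sample(rep_len(seq_len(k), sum(y_low)))
  fold[!y_low] <- sample(rep_len(seq_len(k), sum(!y_low)))
  pred_flag <- logical(nrow(dat))
  for (f in seq_len(k)) {
    test <- fold == f
    tree <- fit_accuracy_tree(dat[!test, ], response, min_gain, min_leaf)
    pred_flag[test] <- predict_low_accuracy(tree, dat[test, ],
                                            threshold)$flag
  }
  tp <- sum(pred_flag & y_low); fn <- sum(!pred_flag & y_low)
  tn <- sum(!pred_flag & !y_low); fp <- sum(pred_flag & !y_low)
  bands <- cut(dat[[response]],
               breaks = c(-Inf, 0.5, 0.75, 0.85, 0.9, 0.95),
               labels = c("0-0.5", "0.5-0.75", "0.75-0.85", "0.85-0.9",
                          "0.9-0.95"))
  by_band <- tibble::tibble(band = bands[y_low],
                            flagged = pred_flag[y_low]) |>
    dplyr::group_by(.data$band, .drop = FALSE) |>
    dplyr::summarise(sensitivity = ifelse(dplyr::n() > 0,
                                          mean(.data$flagged), NA_real_),
                     n = dplyr::n(), .groups = "drop")
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       by_band = by_band,
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Linear-model screen of accuracy factors
#'
#' Ordinary least squares of accuracy on all factors jointly, reporting the
#' per-coefficient t-test p-values. Rank-deficient (aliased) columns are
#' dropped with a warning.
#'
#' @param table Factor table with the response column.
#' @param response Response column name.
#' @return Tibble with `factor`, `estimate`, `p_value`.
#' @export
linear_screen <- function(table, response = "accuracy") {
  dat <- as.data.frame(table)
  dat <- dat[!is.na(dat[[response]]), ]
  drop <- intersect(c("id", "variant"), names(dat))
  preds <- setdiff(names(dat), c(response, drop))
  ## drop constant columns up front
  const <- vapply(preds, function(p) length(unique(dat[[p]])) < 2, logical(1))
  preds <- preds[!const]
  if (!length(preds)) stop("no non-constant factor columns")
  if (nrow(dat) <= length(preds) + 1) stop("more factors than rows")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(preds, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    warning("aliased factor(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  tibble::tibble(factor = rownames(sm),
                 estimate = sm[, "Estimate"],
                 p_value = sm[, "Pr(>|t|)"])
}
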
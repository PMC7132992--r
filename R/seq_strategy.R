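#' Rank sires and dams by genotyped progeny
#'
#' The first step of the sequencing strategy targets the parents that
#' contributed most genotyped progeny ("top sires and dams"). Ties are
#' broken by earlier pedigree position, then id.
#'
#' @param ped Pedigree tibble.
#' @param genotyped Character vector of genotyped individual ids.
#' @return List with tibbles `sires` and `dams` (`id`,
#'   `n_genotyped_progeny`), ranked best-first.
#' @export
rank_top_parents <- function(ped, genotyped) {
  gset <- ped$id %in% genotyped
  rank_one <- function(parent_col) {
    par <- parent_col[gset]
    cnt <- table(par[!is.na(par)])
    if (!length(cnt)) {
      return(tibble::tibble(id = character(0),
                            n_genotyped_progeny = integer(0)))
    }
    tb <- tibble::tibble(id = names(cnt),
                         n_genotyped_progeny = as.integer(cnt))
    pos <- match(tb$id, ped$id)
    tb[order(-tb$n_genotyped_progeny, pos, tb$id), ]
  }
  list(sires = rank_one(ped$sire), dams = rank_one(ped$dam))
}

## descendant indicator matrix (rows: individual; TRUE where column is a
## descendant); exact under inbreeding. Desk-scale pedigrees only.
descendant_matrix <- function(ped) {
  n <- nrow(ped)
  prog <- ped_progeny(ped)
  D <- matrix(FALSE, n, n)
  for (i in rev(seq_len(n))) {
    kids <- prog[[i]]
    if (length(kids)) {
      row <- D[i, ]
      for (k in kids) {
        row <- row | D[k, ]
        row[k] <- TRUE
      }
      D[i, ] <- row
    }
  }
  D
}

#' Select focal individuals for high-coverage sequencing
#'
#' Greedy pedigree-based proxy for haplotype-representation optimization:
#' repeatedly picks the individual with the most pedigree descendants not
#' yet covered by a previous pick, assigns it high coverage (30x for the
#' first pick, 15x after, falling back to lower menu coverages when the
#' remaining slice is smaller), and gives 5x to its not-yet-sequenced
#' parents while budget remains.
#'
#' @param ped Pedigree tibble.
#' @param budget_slice Budget for this step, in x-equivalents.
#' @param current Named coverage vector of already-sequenced individuals
#'   (skipped by this step).
#' @param menu High-coverage menu, descending preference.
#' @param parent_cov Coverage for the focal individuals' parents.
#' @return Named numeric vector id -> coverage for the new assignments.
#' @export
select_focal <- function(ped, budget_slice, current = numeric(0),
                         menu = c(30, 15, 5), parent_cov = 5) {
  assign <- numeric(0)
  if (budget_slice < min(c(menu, 1))) return(assign)
  D <- descendant_matrix(ped)
  covered <- rep(FALSE, nrow(ped))
  pi <- ped_indices(ped)
  remaining <- budget_slice
  first <- TRUE
  repeat {
    affordable <- menu[menu <= remaining]
    if (!length(affordable)) break
    scores <- as.integer(D %*% (!covered))
    scores[match(names(current), ped$id)] <- 0L
    scores[match(names(assign), ped$id)] <- 0L
    best <- which.max(scores)  # ties: earliest pedigree position
    if (scores[best] == 0L) break
    cov <- if (first) affordable[1] else {
      aff2 <- affordable[affordable <= 15]
      if (length(aff2)) aff2[1] else affordable[length(affordable)]
    }
    assign[ped$id[best]] <- cov
    remaining <- remaining - cov
    covered <- covered | D[best, ]
    for (p in c(pi$sire[best], pi$dam[best])) {
      if (!is.na(p) && remaining >= parent_cov &&
          !(ped$id[p] %in% c(names(assign), names(current)))) {
        assign[ped$id[p]] <- parent_cov
        remaining <- remaining - parent_cov
      }
    }
    first <- FALSE
  }
  assign
}

#' Top-up under-sequenced pedigree branches with 1x
#'
#' Distributes 1x units to unsequenced individuals whose ancestors (up to
#' two generations) carry a cumulative assigned coverage below
#' `threshold`, most deficient first.
#'
#' @param ped Pedigree tibble.
#' @param current Named coverage vector of prior assignments.
#' @param budget_slice Budget for this step (x-equivalents).
#' @param threshold Cumulative-coverage deficiency threshold (default 10x).
#' @return Named numeric vector of the new 1x assignments.
#' @export
topup_undersequenced <- function(ped, current, budget_slice, threshold = 10) {
  units <- floor(budget_slice)
  if (units < 1) return(numeric(0))
  cov <- stats::setNames(rep(0, nrow(ped)), ped$id)
  cov[names(current)] <- current
  pi <- ped_indices(ped)
  anc_cov <- vapply(seq_len(nrow(ped)), function(i) {
    par <- c(pi$sire[i], pi$dam[i]); par <- par[!is.na(par)]
    gpar <- unlist(lapply(par, function(p) c(pi$sire[p], pi$dam[p])))
    gpar <- gpar[!is.na(gpar)]
    sum(cov[c(par, gpar)])
  }, numeric(1))
  elig <- which(cov == 0 & anc_cov < threshold)
  elig <- elig[order(anc_cov[elig], elig)]
  take <- utils::head(elig, units)
  stats::setNames(rep(1, length(take)), ped$id[take])
}

#' Build a sequencing budget plan
#'
#' Composes the three-step strategy: top sires at 2x, top dams at 1x, focal
#' individuals (and their parents) at high coverage, and a 1x top-up of
#' under-sequenced branches. The default budget equals sequencing 2 percent of the
#' population at 2x. Unspent focal budget rolls into the top-up slice so
#' total assigned coverage stays within one 1x unit of the budget.
#'
#' @param ped Pedigree tibble.
#' @param genotyped Ids with marker-array data (used to rank top parents).
#' @param total_budget Total budget in x-equivalents.
#' @param fractions Split over c(sires, dams, focal, topup); sums to 1.
#' @return Tibble of class `budget_plan` (`id`, `coverage`, `step`) with
#'   attributes `total_budget` and `fractions`.
#' @export
build_plan <- function(ped, genotyped,
                       total_budget = 0.02 * nrow(ped) * 2,
                       fractions = c(sires = 0.30, dams = 0.15,
                                     focal = 0.25, topup = 0.30)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  if (total_budget < 1) stop("budget smaller than one 1x unit")
  ranked <- rank_top_parents(ped, genotyped)
  n_sires <- floor(fractions[[1]] * total_budget / 2)
  n_dams <- floor(fractions[[2]] * total_budget / 1)
  sires <- utils::head(ranked$sires$id, n_sires)
  assign <- stats::setNames(rep(2, length(sires)), sires)
  dams <- utils::head(setdiff(ranked$dams$id, names(assign)), n_dams)
  assign <- c(assign, stats::setNames(rep(1, length(dams)), dams))
  step <- stats::setNames(c(rep("top_sire", length(sires)),
                            rep("top_dam", length(dams))), names(assign))

  focal <- select_focal(ped, fractions[[3]] * total_budget, current = assign)
  assign <- c(assign, focal)
  step[names(focal)] <- "focal"

  ## unspent budget from earlier steps rolls into the top-up spread,
  ## unless the top-up step is disabled outright
  topup_slice <- if (fractions[[4]] > 0) total_budget - sum(assign) else 0
  topup <- topup_undersequenced(ped, assign, topup_slice)
  assign <- c(assign, topup)
  step[names(topup)] <- "topup"

  plan <- tibble::tibble(id = names(assign),
                         coverage = unname(assign),
                         step = unname(step[names(assign)]))
  plan <- plan[match(intersect(ped$id, plan$id), plan$id), ]
  structure(plan, class = c("budget_plan", class(plan)),
            total_budget = total_budget, fractions = fractions)
}

#' Coverage histogram of a budget plan
#'
#' Table-1-style summary: counts of sequenced individuals in the 1x, 2x,
#' 5x and 15-30x coverage bands plus the total assigned coverage.
#'
#' @param plan [build_plan()] tibble.
#' @return One-row tibble.
#' @export
coverage_histogram <- function(plan) {
  tibble::tibble(
    n_sequenced = nrow(plan),
    n_1x = sum(plan$coverage == 1),
    n_2x = sum(plan$coverage == 2),
    n_5x = sum(plan$coverage == 5),
    n_15_30x = sum(plan$coverage >= 15),
    total_coverage = sum(plan$coverage)
  )
}
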
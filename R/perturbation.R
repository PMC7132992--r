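#' Build seeded perturbation scenarios
#'
#' For each target (by design the individuals sequenced at high coverage)
#' and error type, draws a donor from the eligible pool: sequence
#' misassignment draws from the other high-coverage individuals, array
#' misassignment from HD-genotyped individuals, pedigree misassignment from
#' high-coverage individuals with progeny (whose progeny are reassigned to
#' the target). The removal control needs no donor.
#'
#' @param pop `sim_pop` dataset.
#' @param targets Target individual ids.
#' @param types Subset of `c("removal_control", "seq_misassign",
#'   "array_misassign", "pedigree_misassign")`.
#' @param seed Donor-draw seed.
#' @return Tibble with `type`, `target`, `donor`.
#' @export
make_scenarios <- function(pop, targets,
                           types = c("removal_control", "seq_misassign",
                                     "array_misassign",
                                     "pedigree_misassign"),
                           seed = 1) {
  set.seed(seed)
  cov <- attr(pop$reads, "coverage")
  high <- names(cov)[cov >= 15]
  hd <- names(pop$status)[pop$status == "HD"]
  has_prog <- unique(c(pop$ped$sire, pop$ped$dam))
  rows <- list()
  for (ty in types) {
    for (tg in targets) {
      pool <- switch(ty,
        removal_control = NA_character_,
        seq_misassign = setdiff(high, tg),
        array_misassign = setdiff(hd, tg),
        pedigree_misassign = setdiff(intersect(high, has_prog), tg))
      if (ty != "removal_control" && !length(pool)) {
        stop("empty eligible donor pool for ", ty)
      }
      donor <- if (ty == "removal_control") NA_character_
               else sample(pool, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(type = ty, target = tg,
                                                 donor = donor)
    }
  }
  dplyr::bind_rows(rows)
}

#' Inject one data-misassignment or pedigree error
#'
#' Perturbations are surgical: only the stated records change.
#' `seq_misassign` replaces the target's read rows by the donor's (the
#' donor keeps its own data); `array_misassign` replaces the target's array
#' genotypes by the donor's HD row; `pedigree_misassign` reassigns the
#' donor's progeny to the target (the target replaces the donor in their
#' sire/dam fields); `removal_control` deletes the target's reads.
#'
#' @param pop `sim_pop` dataset.
#' @param scenario One-row tibble (or list) with `type`, `target`, `donor`.
#' @return Modified copy of `pop`; for pedigree errors the element
#'   `misassigned_progeny` lists the reassigned ids.
#' @export
perturb_inject <- function(pop, scenario) {
  type <- scenario$type; target <- scenario$target; donor <- scenario$donor
  if (!is.na(donor) && identical(donor, target)) stop("donor == target")
  out <- pop
  if (type == "removal_control") {
    out$reads <- pop$reads[pop$reads$id != target, ]
  } else if (type == "seq_misassign") {
    donated <- pop$reads[pop$reads$id == donor, ]
    donated$id <- target
    out$reads <- dplyr::bind_rows(pop$reads[pop$reads$id != target, ],
                                  donated)
  } else if (type == "array_misassign") {
    out$genotypes[target, ] <- pop$genotypes[donor, ]
  } else if (type == "pedigree_misassign") {
    prog <- pop$ped$id[(!is.na(pop$ped$sire) & pop$ped$sire == donor) |
                         (!is.na(pop$ped$dam) & pop$ped$dam == donor)]
    ## a reassigned progeny must not be the target or one of its
    ## ancestors, which would create cyclic ancestry
    anc <- character(0)
    queue <- target
    pi <- ped_indices(pop$ped)
    while (length(queue)) {
      i <- match(queue[1], pop$ped$id); queue <- queue[-1]
      for (p in c(pi$sire[i], pi$dam[i])) {
        if (!is.na(p) && !(pop$ped$id[p] %in% anc)) {
          anc <- c(anc, pop$ped$id[p])
          queue <- c(queue, pop$ped$id[p])
        }
      }
    }
    prog <- setdiff(prog, c(target, anc))
    if (!length(prog)) stop("donor has no progeny to misassign")
    ped <- pop$ped
    rows <- match(prog, ped$id)
    for (r in rows) {
      if (identical(ped$sire[r], donor)) ped$sire[r] <- target
      if (identical(ped$dam[r], donor)) ped$dam[r] <- target
    }
    out$ped <- as_pedigree(as.data.frame(ped)[, c("id", "sire", "dam",
                                                  "sex")], quiet = TRUE)
    out$misassigned_progeny <- prog
  } else stop("unknown scenario type: ", type)
  ## preserve read-count attributes lost by row filtering
  attr(out$reads, "coverage") <- attr(pop$reads, "coverage")
  out$reads <- as_read_counts(out$reads)
  out
}

#' Impact of a perturbation on the target and its relatives
#'
#' For the target individual and each relative class, the mean
#' individual-wise MAF-corrected dosage correlation between reference
#' (correct-data) and perturbed dosages over the assessed variants, with
#' allele frequencies taken from the reference run. Without the correction
#' the between-variant allele-frequency spread dominates and even drastic
#' errors correlate near 1.
#'
#' @param ref_dosages,pert_dosages Dosage matrices from the reference and
#'   perturbed runs (identical variant sets).
#' @param ped Pedigree tibble (the *unperturbed* pedigree).
#' @param target Target id.
#' @param misassigned_progeny Ids of reassigned progeny (pedigree errors);
#'   kept disjoint from the true-progeny class.
#' @param vars Variant ids to correlate over (default all columns).
#' @return Tibble with `class`, `mean_correlation`, `n`.
#' @export
perturb_impact <- function(ref_dosages, pert_dosages, ped, target,
                           misassigned_progeny = NULL, vars = NULL) {
  if (is.null(vars)) vars <- colnames(ref_dosages)
  rel <- ped_relatives(ped, target)
  classes <- list(
    ind = target,
    grandparents = rel$grandparents,
    parents = rel$parents,
    progeny = setdiff(rel$progeny, misassigned_progeny),
    grandprogeny = setdiff(rel$grandprogeny, misassigned_progeny)
  )
  if (!is.null(misassigned_progeny)) {
    prog_lists <- ped_progeny(ped)
    mis_gprog <- unique(unlist(lapply(match(misassigned_progeny, ped$id),
                                      function(i) prog_lists[[i]])))
    classes$misassigned_progeny <- misassigned_progeny
    classes$misassigned_grandprogeny <- ped$id[mis_gprog]
  }
  rows <- purrr::imap_dfr(classes, function(ids, cls) {
    ids <- intersect(ids, rownames(ref_dosages))
    if (!length(ids)) {
      return(tibble::tibble(class = cls, mean_correlation = NA_real_,
                            n = 0L))
    }
    freqs <- colMeans(ref_dosages[, vars, drop = FALSE]) / 2
    cors <- vapply(ids, function(i) {
      maf_corrected_correlation(ref_dosages[i, vars],
                                pert_dosages[i, vars], freqs)
    }, numeric(1))
    tibble::tibble(class = cls,
                   mean_correlation = mean(cors, na.rm = TRUE),
                   n = length(ids))
  })
  rows
}

#' Run the error-injection stress study
#'
#' For each scenario: inject the error, re-run hybrid peeling on the
#' perturbed data, and measure the dosage correlation between the correct
#' and erroneous runs for the target and each relative class.
#'
#' @param pop `sim_pop` dataset.
#' @param targets Target ids (high-coverage individuals).
#' @param types Scenario types (see [make_scenarios()]).
#' @param seed Seed for donor draws and the variant subsample.
#' @param subsample Number of variants the impact correlations use.
#' @param settings [peel_settings()].
#' @param reference Optional precomputed full-data [hybrid_peel()] result.
#' @param replicates Donor redraws per (type, target) pair.
#' @return Tibble of class `perturb_study`: `type`, `target`, `donor`,
#'   `replicate`, `class`, `mean_correlation`, `n`.
#' @export
run_perturbation_study <- function(pop, targets,
                                   types = c("removal_control",
                                             "seq_misassign",
                                             "array_misassign",
                                             "pedigree_misassign"),
                                   seed = 1, subsample = 1000,
                                   settings = peel_settings(),
                                   reference = NULL, replicates = 1) {
  if (is.null(reference)) {
    reference <- hybrid_peel(pop$ped, pop$genotypes, pop$reads, pop$map,
                             pop$panels, settings)
  }
  set.seed(seed)
  all_vars <- colnames(reference$dosages)
  vars <- all_vars[sort(sample(seq_along(all_vars),
                               min(subsample, length(all_vars))))]
  out <- list()
  for (rep_i in seq_len(replicates)) {
    scen <- make_scenarios(pop, targets, types, seed = seed + 1000 * rep_i)
    for (r in seq_len(nrow(scen))) {
      sc <- scen[r, ]
      pp <- perturb_inject(pop, sc)
      res <- hybrid_peel(pp$ped, pp$genotypes, pp$reads, pp$map, pp$panels,
                         settings)
      imp <- perturb_impact(reference$dosages, res$dosages, pop$ped,
                            sc$target, pp$misassigned_progeny, vars)
      imp$type <- sc$type; imp$target <- sc$target; imp$donor <- sc$donor
      imp$replicate <- rep_i
      out[[length(out) + 1]] <- imp
    }
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::select("type", "target", "donor", "replicate", "class",
                  "mean_correlation", "n")
  class(res) <- c("perturb_study", class(res))
  res
}

#' Aggregate a perturbation study by scenario type and relative class
#' @param study [run_perturbation_study()] tibble.
#' @return Tibble with per-(type, class) mean and SD of the correlations.
#' @export
perturbation_summary <- function(study) {
  study |>
    dplyr::group_by(.data$type, .data$class) |>
    dplyr::summarise(mean_correlation = mean(.data$mean_correlation,
                                             na.rm = TRUE),
                     sd_correlation = stats::sd(.data$mean_correlation,
                                                na.rm = TRUE),
                     n_scenarios = dplyr::n(), .groups = "drop")
}

#' Simulated stress-test population for the error-injection study
#'
#' A compact population with a Table-1-shaped coverage ladder: a handful of
#' key sires at 15-30x plus a broad 2x/1x spread. The read field is denser
#' per individual than under the 2-percent-at-2x budget so that the
#' background imputation is saturated and the effect of a single injected
#' error is isolated, which is the regime of a full-scale population where
#' one animal's reads are a negligible share of the total.
#'
#' @param seed Integer seed.
#' @param n2x,n1x Numbers of individuals sequenced at 2x and 1x.
#' @return A `sim_pop` dataset whose `plan` carries the fixture coverage.
#' @export
sim_perturb_fixture <- function(seed = 1, n2x = 40, n1x = 60) {
  params <- sim_params(n_founders = 40, n_generations = 4, gen_size = 140,
                       n_chr = 1, var_per_chr = 500, hd_per_chr = 80,
                       ld_per_chr = 20)
  pop <- sim_population(params, seed = seed)
  set.seed(seed + 7)
  ranked <- rank_top_parents(pop$ped, names(pop$status)[pop$status != "none"])
  high <- utils::head(ranked$sires$id, 6)
  cov <- stats::setNames(c(30, 30, 15, 15, 15, 15)[seq_along(high)], high)
  pool <- setdiff(pop$ped$id[pop$ped$gen >= 1], names(cov))
  lows <- sample(pool, n2x)
  cov <- c(cov, stats::setNames(rep(2, n2x), lows))
  spread <- sample(setdiff(pool, lows), n1x)
  cov <- c(cov, stats::setNames(rep(1, n1x), spread))
  pop$plan <- tibble::tibble(id = names(cov), coverage = unname(cov),
                             step = "fixture")
  pop$reads <- simulate_reads(pop$truth, cov, params)
  pop
}
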
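#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config accepted by [run_pipeline()].
#' Values not set in a user config fall back to these defaults, which
#' reproduce the package's default desk-scale study population.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    population = list(n_founders = 20, n_generations = 10,
                      gen_size = NULL, gen_sizes = NULL,
                      litter_mean = 6, sire_frac = 0.05, dam_frac = 0.5,
                      hd_frac = 0.25, ungenotyped_gens = 2,
                      rollout_frac = 0.5, geno_frac = 1),
    genome = list(n_chr = 2, length_cm = 100, var_per_chr = 5000,
                  hd_per_chr = 100, ld_per_chr = 25),
    sequencing = list(budget_x = NULL, gamma_shape = 4, seq_error = 1e-3,
                      fractions = c(0.30, 0.15, 0.25, 0.30)),
    peeling = list(maxit = 20, tol = 1e-4, geno_error = 1e-4,
                   seq_error = 1e-3, multi_maxit = 15, multi_tol = 1e-3),
    evaluation = list(subsample = 2000),
    factors = list(threshold = 0.95, min_gain = 0.005, cv_folds = 10),
    perturbation = list(enabled = FALSE, n_targets = 5, replicates = 1,
                        subsample = 1000),
    output = list(write_full_dosages = FALSE)
  )
}

#' Read a pipeline configuration file
#'
#' YAML file with the structure of [default_config()]; missing entries are
#' filled from the defaults.
#'
#' @param path YAML file path.
#' @return Merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]])) {
        merge_cfg(def[[k]], usr[[k]])
      } else usr[[k]]
    }
    def
  }
  cfg <- merge_cfg(default_config(), user)
  fr <- unlist(cfg$sequencing$fractions)
  if (abs(sum(fr) - 1) > 1e-8) stop("config: budget fractions must sum to 1")
  if (is.null(cfg$seed)) stop("config: seed is required")
  cfg
}

cfg_params <- function(cfg) {
  sim_params(
    n_founders = cfg$population$n_founders,
    n_generations = cfg$population$n_generations,
    gen_size = cfg$population$gen_size,
    gen_sizes = cfg$population$gen_sizes,
    ungenotyped_gens = cfg$population$ungenotyped_gens,
    rollout_frac = cfg$population$rollout_frac,
    geno_frac = cfg$population$geno_frac,
    litter_mean = cfg$population$litter_mean,
    sire_frac = cfg$population$sire_frac,
    dam_frac = cfg$population$dam_frac,
    hd_frac = cfg$population$hd_frac,
    n_chr = cfg$genome$n_chr, length_cm = cfg$genome$length_cm,
    var_per_chr = cfg$genome$var_per_chr,
    hd_per_chr = cfg$genome$hd_per_chr,
    ld_per_chr = cfg$genome$ld_per_chr,
    gamma_shape = cfg$sequencing$gamma_shape,
    seq_error = cfg$sequencing$seq_error,
    budget_x = cfg$sequencing$budget_x,
    fractions = stats::setNames(unlist(cfg$sequencing$fractions),
                                c("sires", "dams", "focal", "topup"))
  )
}

cfg_settings <- function(cfg) {
  p <- cfg$peeling
  peel_settings(maxit = p$maxit, tol = p$tol, geno_error = p$geno_error,
                seq_error = p$seq_error, multi_maxit = p$multi_maxit,
                multi_tol = p$multi_tol)
}

#' Run the full pipeline
#'
#' Chains simulation, sequencing-budget allocation, hybrid peeling,
#' accuracy evaluation, factor analysis and (optionally) the perturbation
#' study, writing all reports plus a machine-readable JSON log (seed,
#' config hash, package version) to `out_dir`. Deterministic given
#' (config, seed).
#'
#' @param config Configuration list ([default_config()] shape) or path to
#'   a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @return Invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempdir()) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- cfg_params(cfg)
  settings <- cfg_settings(cfg)

  pop <- sim_population(params, seed = cfg$seed)
  write_pedigree(pop$ped, file.path(out_dir, "pedigree.tsv"))
  readr::write_csv(pop$plan, file.path(out_dir, "sequencing_plan.csv"))
  readr::write_csv(coverage_histogram(pop$plan),
                   file.path(out_dir, "coverage_histogram.csv"))

  result <- hybrid_peel(pop$ped, pop$genotypes, pop$reads, pop$map,
                        pop$panels, settings)
  report <- evaluate_accuracy(pop, result,
                              subsample = cfg$evaluation$subsample,
                              seed = cfg$seed)
  readr::write_csv(report$individuals,
                   file.path(out_dir, "accuracy_individuals.csv"))
  readr::write_csv(report$variants,
                   file.path(out_dir, "accuracy_variants.csv"))
  readr::write_csv(accuracy_by_maf(report),
                   file.path(out_dir, "accuracy_by_maf.csv"))
  if (isTRUE(cfg$output$write_full_dosages)) {
    write_dosages(result$dosages, file.path(out_dir, "dosages.tsv"))
  } else {
    write_dosages(result$dosages[, report$variants_used, drop = FALSE],
                  file.path(out_dir, "dosages_subsample.tsv"))
  }

  itab <- build_individual_factors(pop$ped, pop$status, pop$plan) |>
    dplyr::left_join(report$individuals[, c("id", "accuracy")], by = "id")
  itree <- fit_accuracy_tree(itab, min_gain = cfg$factors$min_gain)
  vtab <- build_variant_factors(pop, report$variants_used) |>
    dplyr::left_join(report$variants[, c("variant", "accuracy")],
                     by = "variant")
  vtree <- fit_accuracy_tree(vtab, min_gain = cfg$factors$min_gain)
  cv <- crossvalidate_low_accuracy(itab, threshold = cfg$factors$threshold,
                                   k = cfg$factors$cv_folds,
                                   seed = cfg$seed,
                                   min_gain = cfg$factors$min_gain)
  screen <- linear_screen(itab)
  readr::write_csv(tidy(itree), file.path(out_dir, "tree_individual.csv"))
  readr::write_csv(tidy(vtree), file.path(out_dir, "tree_variant.csv"))
  readr::write_csv(cv$by_band, file.path(out_dir, "cv_sensitivity_bands.csv"))
  readr::write_csv(tibble::tibble(sensitivity = cv$sensitivity,
                                  specificity = cv$specificity),
                   file.path(out_dir, "cv_metrics.csv"))
  readr::write_csv(screen, file.path(out_dir, "linear_screen.csv"))

  perturb <- NULL
  if (isTRUE(cfg$perturbation$enabled)) {
    cov <- attr(pop$reads, "coverage")
    targets <- names(sort(cov, decreasing = TRUE))
    targets <- utils::head(targets[cov[targets] >= 15],
                           cfg$perturbation$n_targets)
    if (length(targets)) {
      perturb <- run_perturbation_study(
        pop, targets, seed = cfg$seed,
        subsample = cfg$perturbation$subsample, settings = settings,
        reference = result, replicates = cfg$perturbation$replicates)
      readr::write_csv(perturb, file.path(out_dir, "perturbation.csv"))
      readr::write_csv(perturbation_summary(perturb),
                       file.path(out_dir, "perturbation_summary.csv"))
    }
  }

  log <- list(seed = cfg$seed,
              config_hash = rlang::hash(cfg),
              package_version = as.character(utils::packageVersion("hybridpeel")),
              n_individuals = nrow(pop$ped),
              n_variants = nrow(pop$map),
              outputs = list.files(out_dir))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pop = pop, result = result, report = report,
                 individual_tree = itree, variant_tree = vtree, cv = cv,
                 linear_screen = screen, perturbation = perturb,
                 config = cfg))
}
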
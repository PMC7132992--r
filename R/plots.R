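#' Plot individual-wise accuracy against pedigree position
#'
#' Mirrors the classic accuracy-by-generation pattern: individuals early in
#' the (parents-first) pedigree tend to impute worse because neither they
#' nor their ancestors carry marker data.
#'
#' @param report [evaluate_accuracy()] result.
#' @return A ggplot object.
#' @export
plot_accuracy_by_position <- function(report) {
  ggplot2::ggplot(report$individuals,
                  ggplot2::aes(x = .data$position_fraction,
                               y = .data$accuracy,
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "relative position in pedigree",
                  y = "MAF-corrected dosage correlation",
                  colour = "array") +
    ggplot2::theme_minimal()
}

#' Plot variant-wise accuracy across the MAF spectrum
#'
#' @param report [evaluate_accuracy()] result.
#' @return A ggplot object.
#' @export
plot_accuracy_by_maf <- function(report) {
  v <- report$variants
  v$maf_bin <- cut(v$maf, breaks = c(-Inf, 0.001, 0.005, 0.023, Inf),
                   labels = c("<=0.001", "0.001-0.005", "0.005-0.023",
                              ">0.023"))
  ggplot2::ggplot(v[!is.na(v$accuracy), ],
                  ggplot2::aes(x = .data$maf_bin, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "minor allele frequency",
                  y = "variant-wise dosage correlation") +
    ggplot2::theme_minimal()
}

#' Plot perturbation impact by scenario type and relative class
#'
#' @param study [run_perturbation_study()] tibble.
#' @return A ggplot object.
#' @export
plot_perturbation <- function(study) {
  lev <- c("ind", "grandparents", "parents", "progeny", "grandprogeny",
           "misassigned_progeny", "misassigned_grandprogeny")
  study$class <- factor(study$class, levels = lev)
  ggplot2::ggplot(study[!is.na(study$mean_correlation), ],
                  ggplot2::aes(x = .data$class,
                               y = .data$mean_correlation)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~type) +
    ggplot2::geom_vline(xintercept = 1.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "dosage correlation (correct vs erroneous)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.accuracy_report <- function(object, ...) {
  plot_accuracy_by_position(object)
}
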
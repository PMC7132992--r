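#' Genetic maps
#'
#' A genetic map is a tibble with columns `chrom`, `variant` and `pos_cm`
#' (strictly increasing within a chromosome). Recombination fractions
#' between positions follow Haldane's mapping function
#' `0.5 * (1 - exp(-2 * d))` with `d` in Morgans, giving fractions in
#' `[0, 0.5)`.
#'
#' @param df Data frame with `chrom`, `variant`, `pos_cm`.
#' @return Tibble of class `gmap_df`.
#' @export
as_genetic_map <- function(df) {
  stopifnot(all(c("chrom", "variant", "pos_cm") %in% names(df)))
  df <- tibble::as_tibble(df)
  df$chrom <- as.character(df$chrom)
  df$variant <- as.character(df$variant)
  df$pos_cm <- as.numeric(df$pos_cm)
  if (anyDuplicated(df$variant)) stop("duplicate variant id(s) in map")
  bad <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos_cm, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("positions not strictly increasing on chromosome(s): ",
         paste(bad$chrom, collapse = ", "))
  }
  class(df) <- c("gmap_df", class(df))
  df
}

#' Build an evenly spaced genetic map
#'
#' @param n_chr Number of chromosomes.
#' @param length_cm Chromosome length in centimorgans.
#' @param n_var Variants per chromosome, evenly spaced over `(0, length_cm)`.
#' @return A [as_genetic_map()] tibble.
#' @export
sim_genetic_map <- function(n_chr = 2, length_cm = 100, n_var = 5000) {
  pos <- length_cm * (seq_len(n_var) - 0.5) / n_var
  df <- tidyr::expand_grid(chrom = as.character(seq_len(n_chr)),
                           i = seq_len(n_var)) |>
    dplyr::mutate(variant = paste0("c", .data$chrom, "_v", .data$i),
                  pos_cm = pos[.data$i]) |>
    dplyr::select("chrom", "variant", "pos_cm")
  as_genetic_map(df)
}

#' Haldane recombination fraction
#'
#' @param d_cm Map distance in centimorgans (vectorized).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cm) {
  r <- 0.5 * (1 - exp(-2 * d_cm / 100))
  ## mathematically r < 0.5 for finite distance; keep that under rounding
  pmin(r, 0.5 - 1e-9)
}

#' Read / write a map TSV (`chrom  variant  pos_cm`)
#' @param path File path.
#' @export
read_genetic_map <- function(path) {
  as_genetic_map(utils::read.table(path, header = TRUE,
                                   stringsAsFactors = FALSE))
}

#' @rdname read_genetic_map
#' @param map Map tibble.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Nested marker panels
#'
#' Selects evenly spaced high-density (HD) panel variants per chromosome,
#' preferring intermediate allele frequencies (MAF >= 0.05 where possible),
#' and a low-density (LD) panel as an evenly spaced subset of HD, mirroring
#' commercial nested arrays.
#'
#' @param map Genetic map.
#' @param hd_per_chr,ld_per_chr Panel sizes per chromosome
#'   (`ld_per_chr <= hd_per_chr`).
#' @param freqs Optional named vector of alt-allele frequencies per variant,
#'   used for the MAF preference; without it selection is purely positional.
#' @param min_maf MAF preference threshold.
#' @return List with character vectors `sequence`, `hd`, `ld`
#'   (`ld` nested in `hd`, `hd` in `sequence`), class `panel_set`.
#' @export
make_panels <- function(map, hd_per_chr, ld_per_chr, freqs = NULL,
                        min_maf = 0.05) {
  stopifnot(ld_per_chr <= hd_per_chr)
  hd <- character(0)
  for (ch in unique(map$chrom)) {
    mv <- map[map$chrom == ch, ]
    if (hd_per_chr > nrow(mv)) stop("not enough variants on chromosome ", ch)
    eligible <- rep(TRUE, nrow(mv))
    if (!is.null(freqs)) {
      p <- freqs[mv$variant]
      maf <- pmin(p, 1 - p)
      eligible <- !is.na(maf) & maf >= min_maf
      if (sum(eligible) < hd_per_chr) eligible <- rep(TRUE, nrow(mv))
    }
    ## target positions evenly spaced; take nearest eligible variant
    targets <- min(mv$pos_cm) +
      (max(mv$pos_cm) - min(mv$pos_cm)) * (seq_len(hd_per_chr) - 0.5) / hd_per_chr
    pool <- which(eligible)
    picked <- integer(0)
    for (t in targets) {
      j <- pool[which.min(abs(mv$pos_cm[pool] - t))]
      picked <- c(picked, j)
      pool <- setdiff(pool, j)
      if (!length(pool)) pool <- setdiff(seq_len(nrow(mv)), picked)
    }
    hd <- c(hd, mv$variant[sort(unique(picked))])
  }
  ## LD: evenly spaced subset of HD within each chromosome
  ld <- character(0)
  for (ch in unique(map$chrom)) {
    hv <- hd[hd %in% map$variant[map$chrom == ch]]
    take <- unique(round(seq(1, length(hv), length.out = ld_per_chr)))
    ld <- c(ld, hv[take])
  }
  structure(list(sequence = map$variant, hd = hd, ld = ld),
            class = "panel_set")
}
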
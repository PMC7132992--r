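#' Mendelian conflicts between parent-progeny pairs
#'
#' For every parent-progeny pair, counts the loci observed in both
#' (comparable) and the opposing homozygotes (one scored 0 and the other 2),
#' and reports the percentage `100 * opposing / comparable`.
#'
#' @param genotypes Genotype matrix (individuals x shared panel loci,
#'   0/1/2/`NA`).
#' @param ped Pedigree tibble.
#' @return Tibble with `parent`, `progeny`, `n_comparable`, `n_opposing`,
#'   `pct_opposing`.
#' @export
mendelian_conflicts <- function(genotypes, ped) {
  pairs <- dplyr::bind_rows(
    tibble::tibble(parent = ped$sire, progeny = ped$id),
    tibble::tibble(parent = ped$dam, progeny = ped$id)
  ) |>
    dplyr::filter(!is.na(.data$parent))
  have <- rownames(genotypes)
  pairs <- pairs[pairs$parent %in% have & pairs$progeny %in% have, ]
  res <- purrr::pmap_dfr(pairs, function(parent, progeny) {
    gp <- genotypes[parent, ]; gc <- genotypes[progeny, ]
    cmp <- !is.na(gp) & !is.na(gc)
    opp <- cmp & ((gp == 0 & gc == 2) | (gp == 2 & gc == 0))
    tibble::tibble(parent = parent, progeny = progeny,
                   n_comparable = sum(cmp), n_opposing = sum(opp),
                   pct_opposing = ifelse(sum(cmp) > 0,
                                         100 * sum(opp) / sum(cmp), NA_real_))
  })
  if (!nrow(res)) {
    res <- tibble::tibble(parent = character(0), progeny = character(0),
                          n_comparable = integer(0), n_opposing = integer(0),
                          pct_opposing = numeric(0))
  }
  res
}

flag_pairs <- function(conf, threshold, min_comparable) {
  conf$flag <- !is.na(conf$pct_opposing) &
    conf$pct_opposing > threshold & conf$n_comparable >= min_comparable
  conf
}

#' Apply pedigree/data quality-control repair rules
#'
#' Three repair rules driven by Mendelian conflicts, applied in order with a
#' single recomputation afterwards:
#' 1. an individual whose genotype data conflicts with *all* its available
#'    parents and progeny has its array and sequence data removed (likely
#'    sample misassignment);
#' 2. a conflict confined to a single parent-progeny pair (both members
#'    compatible with their other relatives) cuts that pedigree link;
#' 3. a full-sib litter that conflicts only with one shared parent gets a
#'    new dummy parent (id `DUM<N>`, no data), preserving the full-sib
#'    relationship.
#'
#' A pair is deemed incompatible when its opposing-homozygote percentage
#' exceeds `threshold` and at least `min_comparable` loci are comparable.
#'
#' @param ped Pedigree tibble.
#' @param genotypes Genotype matrix (individuals x panel loci).
#' @param reads `read_counts` tibble (may be `NULL`).
#' @param threshold Conflict percentage threshold (default 2).
#' @param min_comparable Minimum comparable loci per pair (default 50).
#' @return List with repaired `ped`, `genotypes`, `reads`, the `log` tibble
#'   of actions (`rule`, `id`, `detail`), and conflict reports
#'   `conflicts_before` / `conflicts_after`.
#' @export
apply_qc_rules <- function(ped, genotypes, reads = NULL, threshold = 2,
                           min_comparable = 50) {
  conf0 <- flag_pairs(mendelian_conflicts(genotypes, ped),
                      threshold, min_comparable)
  conf <- conf0
  log <- tibble::tibble(rule = character(0), id = character(0),
                        detail = character(0))
  handled <- character(0)

  ## rule 1: conflict with ALL available parents and progeny. Requires at
  ## least two pairs (a single conflicting pair cannot be attributed to
  ## either member) and handles the most-conflicted individual first, so
  ## relatives whose only conflicts involve an already-removed sample are
  ## not swept up as collateral.
  repeat {
    inds <- unique(c(conf$parent, conf$progeny))
    cand <- Filter(function(i) {
      mine <- conf[conf$parent == i | conf$progeny == i, ]
      nrow(mine) >= 2 && all(mine$flag)
    }, inds)
    if (!length(cand)) break
    npairs <- vapply(cand, function(i) {
      sum(conf$parent == i | conf$progeny == i)
    }, numeric(1))
    i <- cand[which.max(npairs)]
    genotypes[i, ] <- NA_integer_
    if (!is.null(reads)) reads <- reads[reads$id != i, ]
    handled <- c(handled, i)
    log <- dplyr::add_row(log, rule = "1_remove_data", id = i,
                          detail = paste0("conflicted with all ",
                                          max(npairs), " pairs"))
    conf <- conf[!(conf$parent == i | conf$progeny == i), ]
  }

  ## rule 2: isolated bad link
  flagged <- conf[conf$flag, ]
  cut <- character(0)
  for (r in seq_len(nrow(flagged))) {
    p <- flagged$parent[r]; c <- flagged$progeny[r]
    others_p <- conf[(conf$parent == p | conf$progeny == p) &
                       !(conf$parent == p & conf$progeny == c), ]
    others_c <- conf[(conf$parent == c | conf$progeny == c) &
                       !(conf$parent == p & conf$progeny == c), ]
    if ((nrow(others_p) == 0 || !any(others_p$flag)) &&
        (nrow(others_c) == 0 || !any(others_c$flag))) {
      row <- match(c, ped$id)
      side <- if (identical(ped$sire[row], p)) "sire" else "dam"
      ped[[side]][row] <- NA_character_
      cut <- c(cut, paste(p, c))
      log <- dplyr::add_row(log, rule = "2_cut_link", id = c,
                            detail = paste0("removed ", side, " link to ", p))
    }
  }
  conf <- conf[!(paste(conf$parent, conf$progeny) %in% cut), ]

  ## rule 3: full-sib litter conflicting with one shared parent
  flagged <- conf[conf$flag, ]
  if (nrow(flagged)) {
    ndum <- 0L
    for (p in unique(flagged$parent)) {
      kids <- flagged$progeny[flagged$parent == p]
      rows <- match(kids, ped$id)
      full_sibs <- length(unique(ped$sire[rows])) == 1 &&
        length(unique(ped$dam[rows])) == 1
      other_pairs_ok <- all(!conf$flag[!(conf$parent == p &
                                           conf$progeny %in% kids)])
      if (full_sibs && other_pairs_ok && length(kids) >= 2) {
        ndum <- ndum + 1L
        dum <- paste0("DUM", ndum)
        side <- if (identical(ped$sire[rows[1]], p)) "sire" else "dam"
        ped <- dplyr::add_row(ped, id = dum, sire = NA_character_,
                              dam = NA_character_,
                              sex = if (side == "sire") "M" else "F",
                              gen = 0L, .before = 1)
        rows <- match(kids, ped$id)
        ped[[side]][rows] <- dum
        log <- dplyr::add_row(log, rule = "3_dummy_parent", id = p,
                              detail = paste0("litter ",
                                              paste(kids, collapse = ","),
                                              " reassigned to ", dum))
      }
    }
  }
  ped <- as_pedigree(as.data.frame(ped)[, c("id", "sire", "dam", "sex")],
                     quiet = TRUE)
  conf_after <- flag_pairs(mendelian_conflicts(genotypes, ped),
                           threshold, min_comparable)
  list(ped = ped, genotypes = genotypes, reads = reads, log = log,
       conflicts_before = conf0, conflicts_after = conf_after)
}

#' Read-depth variant filter for repetitive regions
#'
#' Flags variants whose mean read depth across sequenced individuals
#' exceeds `factor` times the overall mean realized depth (indicative of
#' collapsed repeats attracting excess reads).
#'
#' @param reads `read_counts` tibble.
#' @param variants All variant ids (variants without reads count as depth
#'   0).
#' @param factor Exclusion multiplier (default 3).
#' @return Named logical vector, `TRUE` = variant excluded.
#' @export
depth_filter <- function(reads, variants, factor = 3) {
  stopifnot(factor > 1)
  n_seq <- length(unique(reads$id))
  if (n_seq == 0) stop("no sequenced individuals")
  depth <- stats::setNames(rep(0, length(variants)), variants)
  agg <- reads |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(d = sum(.data$refReads + .data$altReads))
  depth[agg$variant] <- agg$d / n_seq
  overall <- mean(depth)
  stats::setNames(depth > factor * overall, variants)
}
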
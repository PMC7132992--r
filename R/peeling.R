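#' Peeling settings
#'
#' @param maxit Maximum single-locus peeling iterations (each iteration is a
#'   down sweep plus an up sweep over all families).
#' @param tol Convergence tolerance on the maximum absolute dosage change.
#' @param geno_error Marker-array genotype observation error `eps_g`.
#' @param seq_error Sequencing error rate `e` used in the read likelihood.
#' @param multi_maxit Maximum outer iterations of multi-locus peeling (each
#'   couples a genotype-peeling sweep per locus with a forward-backward pass
#'   over segregation states).
#' @param multi_tol Convergence tolerance on the maximum segregation
#'   probability change.
#' @param inner_sweeps Genotype-peeling sweeps per locus per outer iteration.
#' @return List of class `peel_settings`.
#' @export
peel_settings <- function(maxit = 20, tol = 1e-4, geno_error = 1e-4,
                          seq_error = 1e-3, multi_maxit = 15,
                          multi_tol = 1e-3, inner_sweeps = 1) {
  stopifnot(maxit >= 1, tol > 0, multi_maxit >= 1)
  structure(list(maxit = as.integer(maxit), tol = tol,
                 geno_error = geno_error, seq_error = seq_error,
                 multi_maxit = as.integer(multi_maxit),
                 multi_tol = multi_tol,
                 inner_sweeps = as.integer(inner_sweeps)),
            class = "peel_settings")
}

## family structure for the C++ kernels (all indices 0-based)
ped_families <- function(ped) {
  pi <- ped_indices(ped)
  n <- nrow(ped)
  s <- ifelse(is.na(pi$sire), -1L, pi$sire - 1L)
  d <- ifelse(is.na(pi$dam), -1L, pi$dam - 1L)
  has_fam <- which(s >= 0L | d >= 0L)
  key <- paste(s[has_fam], d[has_fam])
  fam_id <- match(key, unique(key))
  nfam <- max(c(fam_id, 0L))
  fs <- integer(nfam); fd <- integer(nfam)
  fs[fam_id] <- s[has_fam]; fd[fam_id] <- d[has_fam]
  ## order families by earliest child (parents precede progeny, so this
  ## processes the pedigree top-down)
  first_child <- vapply(seq_len(nfam),
                        function(f) min(has_fam[fam_id == f]), integer(1))
  ord <- order(first_child)
  remap <- match(seq_len(nfam), ord)
  fam_id <- remap[fam_id]
  fs <- fs[ord]; fd <- fd[ord]
  child_fam <- rep(-1L, n)
  child_fam[has_fam] <- fam_id - 1L
  o <- order(fam_id, has_fam)
  fam_child <- has_fam[o] - 1L
  fam_ptr <- c(0L, cumsum(tabulate(fam_id, nbins = nfam)))
  list(fs = fs, fd = fd, fam_ptr = as.integer(fam_ptr),
       fam_child = as.integer(fam_child), child_fam = child_fam)
}

#' Penetrance: likelihood of observed data given ordered genotypes
#'
#' Combines marker-array genotypes (exact match up to observation error
#' `eps_g`: matching ordered states get `1 - eps_g`, the rest `eps_g / 2`)
#' and sequencing reads (binomial likelihood of the alt read count with
#' alt-read probability `e`, `0.5`, `0.5`, `1 - e` for the four ordered
#' genotypes). Contributions multiply; entries with no data are 1.
#'
#' @param genotypes Integer matrix individuals x loci (0/1/2/`NA`), or
#'   `NULL`.
#' @param reads `read_counts` tibble (rows at other loci are ignored), or
#'   `NULL`.
#' @param ids Individual ids (row order of the result).
#' @param loci Locus (variant) ids, defining columns.
#' @param settings [peel_settings()].
#' @return Numeric array `c(4, length(ids), length(loci))`; `pen[, i, l]`
#'   is the unnormalized likelihood 4-vector of individual `i` at locus `l`
#'   over (aa, aA, Aa, AA).
#' @export
penetrance <- function(genotypes = NULL, reads = NULL, ids, loci,
                       settings = peel_settings()) {
  n <- length(ids); L <- length(loci)
  pen <- array(1, dim = c(4, n, L))
  eps <- settings$geno_error
  if (!is.null(genotypes)) {
    M <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
    sr <- intersect(rownames(genotypes), ids)
    sc <- intersect(colnames(genotypes), loci)
    if (length(sr) && length(sc)) {
      M[sr, sc] <- genotypes[sr, sc]
      obs <- !is.na(M)
      fac_for <- function(gval) {
        f <- matrix(1, n, L)
        f[obs] <- ifelse(M[obs] == gval, 1 - eps, eps / 2)
        f
      }
      pen[1, , ] <- pen[1, , ] * fac_for(0L)
      f_het <- fac_for(1L)
      pen[2, , ] <- pen[2, , ] * f_het
      pen[3, , ] <- pen[3, , ] * f_het
      pen[4, , ] <- pen[4, , ] * fac_for(2L)
    }
  }
  if (!is.null(reads)) {
    e <- settings$seq_error
    rr <- reads[reads$variant %in% loci & reads$id %in% ids, ]
    if (nrow(rr)) {
      i <- match(rr$id, ids); l <- match(rr$variant, loci)
      nr <- rr$refReads; na <- rr$altReads
      fac <- rbind(e^na * (1 - e)^nr,
                   0.5^(na + nr),
                   0.5^(na + nr),
                   (1 - e)^na * e^nr)
      for (k in seq_along(i)) {
        pen[, i[k], l[k]] <- pen[, i[k], l[k]] * fac[, k]
      }
    }
  }
  dimnames(pen) <- list(NULL, ids, loci)
  pen
}

#' Single-locus iterative peeling
#'
#' Estimates each individual's posterior over ordered genotypes at one
#' locus by iterative peeling: posterior proportional to anterior (from
#' parents through the segregation-weighted transmission kernel) times
#' penetrance times the product of family posterior terms (from progeny).
#' Exact on loop-free pedigrees at convergence; a loopy approximation under
#' inbreeding.
#'
#' @param ped Pedigree tibble.
#' @param pen Penetrance matrix, individuals x 4 (rows align with `ped`),
#'   or the `[, , l]` slice of [penetrance()] transposed.
#' @param seg Optional segregation probability matrix individuals x 4
#'   (states pp, pm, mp, mm); uniform when `NULL`.
#' @param p Founder alt-allele prior frequency.
#' @param settings [peel_settings()].
#' @return List with `prob` (individuals x 4 matrix over (aa, aA, Aa, AA)),
#'   `dosage`, `iterations`.
#' @export
single_locus_peel <- function(ped, pen, seg = NULL, p = 0.5,
                              settings = peel_settings()) {
  fam <- ped_families(ped)
  stopifnot(nrow(pen) == nrow(ped), ncol(pen) == 4)
  segv <- if (!is.null(seg)) {
    stopifnot(nrow(seg) == nrow(ped), ncol(seg) == 4)
    as.numeric(t(seg))
  } else NULL
  res <- .peel_single_cpp(fam, as.numeric(t(pen)), segv, p,
                          settings$maxit, settings$tol)
  prob <- t(matrix(res$prob, nrow = 4))
  dimnames(prob) <- list(ped$id, c("aa", "aA", "Aa", "AA"))
  list(prob = prob, dosage = stats::setNames(res$dosage, ped$id),
       iterations = res$iterations)
}

#' Multi-locus iterative peeling
#'
#' Jointly iterates genotype peeling at each locus with a forward-backward
#' pass over each individual's segregation states along the chromosome.
#' Transitions between adjacent loci factorize into independent
#' paternal/maternal indicator switches with Haldane recombination
#' fractions. Founders keep the uniform segregation distribution.
#'
#' @param ped Pedigree tibble.
#' @param pen Penetrance array `c(4, n, L)` from [penetrance()].
#' @param pos_cm Locus positions in cM (strictly increasing; one
#'   chromosome).
#' @param freqs Per-locus founder alt-allele frequencies (length L); when
#'   `NULL`, estimated from the penetrance of informative individuals.
#' @param settings [peel_settings()].
#' @return List with arrays `seg` and `prob`, both `c(4, n, L)`.
#' @export
multi_locus_peel <- function(ped, pen, pos_cm, freqs = NULL,
                             settings = peel_settings()) {
  if (is.unsorted(pos_cm, strictly = TRUE)) stop("loci must be ordered by map position")
  n <- nrow(ped); L <- length(pos_cm)
  stopifnot(identical(dim(pen), c(4L, n, L)))
  if (is.null(freqs)) {
    freqs <- vapply(seq_len(L), function(l) {
      m <- pen[, , l]
      tot <- colSums(m)
      informative <- tot > 0 & apply(m, 2, function(v) max(v) - min(v) > 0)
      if (!any(informative)) return(0.5)
      pm <- sweep(m[, informative, drop = FALSE], 2,
                  tot[informative], "/")
      mean((pm[2, ] + pm[3, ] + 2 * pm[4, ]) / 2)
    }, numeric(1))
  }
  fam <- ped_families(ped)
  res <- .peel_multi_cpp(fam, as.numeric(pen), pos_cm, freqs,
                         settings$multi_maxit, settings$multi_tol,
                         settings$inner_sweeps)
  dimnames(res$seg) <- list(c("pp", "pm", "mp", "mm"), ped$id, NULL)
  dimnames(res$prob) <- list(c("aa", "aA", "Aa", "AA"), ped$id, NULL)
  res
}

#' Interpolate segregation probabilities to off-panel positions
#'
#' Between flanking panel loci each inheritance indicator (paternal,
#' maternal) is bridged by a two-state Markov chain with Haldane
#' recombination fractions to each flank; beyond terminal panel loci the
#' nearest posterior is carried over with decay toward uniform. At a panel
#' position the panel posterior is returned unchanged.
#'
#' @param seg Array `c(4, n, L)` of panel segregation posteriors.
#' @param panel_pos Panel locus positions (cM).
#' @param target_pos Positions to interpolate to (cM).
#' @return Array `c(4, n, length(target_pos))`.
#' @export
interpolate_segregation <- function(seg, panel_pos, target_pos) {
  if (!length(panel_pos)) stop("empty panel on chromosome")
  n <- dim(seg)[2]
  out <- array(0.25, dim = c(4, n, length(target_pos)))
  pu <- matrix(seg[1, , ] + seg[2, , ], nrow = n)
  pv <- matrix(seg[1, , ] + seg[3, , ], nrow = n)
  for (t in seq_along(target_pos)) {
    x <- target_pos[t]
    hit <- which(abs(panel_pos - x) < 1e-9)
    if (length(hit)) {
      out[, , t] <- seg[, , hit[1]]
      next
    }
    lo <- findInterval(x, panel_pos)
    hi <- lo + 1
    bridge <- function(q, lo, hi) {
      mL <- if (lo >= 1) {
        r <- haldane(x - panel_pos[lo]); q[, lo] * (1 - r) + (1 - q[, lo]) * r
      } else rep(0.5, n)
      mR <- if (hi <= length(panel_pos)) {
        r <- haldane(panel_pos[hi] - x); q[, hi] * (1 - r) + (1 - q[, hi]) * r
      } else rep(0.5, n)
      num <- mL * mR
      num / (num + (1 - mL) * (1 - mR))
    }
    qu <- bridge(pu, lo, hi); qv <- bridge(pv, lo, hi)
    out[1, , t] <- qu * qv
    out[2, , t] <- qu * (1 - qv)
    out[3, , t] <- (1 - qu) * qv
    out[4, , t] <- (1 - qu) * (1 - qv)
  }
  dimnames(out) <- list(c("pp", "pm", "mp", "mm"), dimnames(seg)[[2]], NULL)
  out
}

#' Estimate per-variant alt-allele frequencies from observed data
#'
#' Pools array genotypes (as `g/2`) and per-individual read fractions
#' (`alt / (alt + ref)`), each with unit weight; the estimate is floored at
#' `1/(2N)` and capped at `1 - 1/(2N)`. Variants with no data get 0.5.
#'
#' @param genotypes Array genotype matrix (individuals x panel variants).
#' @param reads `read_counts` tibble.
#' @param n_ind Population size (for the frequency floor).
#' @param variants Variant ids defining the output order.
#' @return Named numeric vector of frequencies.
#' @export
estimate_allele_freqs <- function(genotypes, reads, n_ind, variants) {
  num <- stats::setNames(rep(0, length(variants)), variants)
  den <- num
  if (!is.null(genotypes)) {
    cols <- intersect(colnames(genotypes), variants)
    if (length(cols)) {
      cnt <- colSums(!is.na(genotypes[, cols, drop = FALSE]))
      s <- colSums(genotypes[, cols, drop = FALSE], na.rm = TRUE) / 2
      num[cols] <- num[cols] + s
      den[cols] <- den[cols] + cnt
    }
  }
  if (!is.null(reads) && nrow(reads)) {
    rr <- reads[reads$variant %in% variants, ]
    if (nrow(rr)) {
      agg <- rr |>
        dplyr::mutate(frac = .data$altReads /
                        (.data$altReads + .data$refReads)) |>
        dplyr::group_by(.data$variant) |>
        dplyr::summarise(s = sum(.data$frac), n = dplyr::n())
      num[agg$variant] <- num[agg$variant] + agg$s
      den[agg$variant] <- den[agg$variant] + agg$n
    }
  }
  p <- ifelse(den > 0, num / pmax(den, 1), 0.5)
  lo <- 1 / (2 * n_ind)
  pmin(pmax(p, lo), 1 - lo)
}

#' Hybrid peeling: impute whole-genome dosages
#'
#' Two-step hybrid peeling. Step 1 runs multi-locus iterative peeling on
#' the marker-panel loci (all array data as observed; LD individuals are
#' not pre-imputed to HD) to estimate per-individual segregation
#' probabilities. Step 2 interpolates the segregation probabilities to
#' every variant and runs segregation-aware single-locus peeling there,
#' using allele frequencies estimated from the data as founder priors.
#'
#' @param ped Pedigree tibble.
#' @param genotypes Array genotype matrix (individuals x HD-panel variants,
#'   `NA` at unobserved entries). Rows are matched to `ped$id`; missing
#'   rows are treated as ungenotyped.
#' @param reads `read_counts` tibble.
#' @param map Genetic map covering all variants to impute.
#' @param panels [make_panels()] result (`hd` defines the multi-locus
#'   panel).
#' @param settings [peel_settings()].
#' @param return_probs Also return full genotype-probability arrays (only
#'   sensible for small problems).
#' @param freqs Optional per-variant founder-prior allele frequencies
#'   (named by variant), e.g. dosage-derived estimates from an earlier
#'   pass; when `NULL` they are estimated from the array and read data.
#' @return Object of class `hybrid_peel`: list with `dosages` (individuals
#'   x variants matrix), `seg_panel` (per-chromosome arrays `c(4, n, L)`),
#'   `freqs`, `map`, `panels`, `settings` and optionally `probs`.
#' @export
hybrid_peel <- function(ped, genotypes, reads, map, panels,
                        settings = peel_settings(), return_probs = FALSE,
                        freqs = NULL) {
  n <- nrow(ped)
  if (is.null(reads)) stop("read-count table is required (may have 0 rows)")
  ## align genotype rows with the pedigree
  G <- matrix(NA_integer_, n, length(intersect(panels$hd, map$variant)),
              dimnames = list(ped$id,
                              intersect(map$variant, panels$hd)))
  if (!is.null(genotypes)) {
    shared_r <- intersect(rownames(genotypes), ped$id)
    shared_c <- intersect(colnames(genotypes), colnames(G))
    G[shared_r, shared_c] <- genotypes[shared_r, shared_c]
  }
  if (is.null(freqs)) {
    freqs <- estimate_allele_freqs(G, reads, n, map$variant)
  } else {
    stopifnot(all(map$variant %in% names(freqs)))
    lo <- 1 / (2 * n)
    freqs <- pmin(pmax(freqs[map$variant], lo), 1 - lo)
  }
  fam <- ped_families(ped)
  dos <- matrix(NA_real_, n, nrow(map), dimnames = list(ped$id, map$variant))
  seg_panel <- list()
  probs <- if (return_probs) array(NA_real_, c(4, n, nrow(map))) else NULL
  for (ch in unique(map$chrom)) {
    mv <- map[map$chrom == ch, ]
    pvars <- mv$variant[mv$variant %in% panels$hd]
    if (!length(pvars)) stop("empty panel on chromosome ", ch)
    ppos <- mv$pos_cm[match(pvars, mv$variant)]
    pen_panel <- penetrance(G, reads, ids = ped$id, loci = pvars,
                            settings = settings)
    ## sparse read counts in CSC order over this chromosome's variants
    rr <- reads[reads$variant %in% mv$variant & reads$id %in% ped$id, ]
    vi <- match(rr$variant, mv$variant)
    o <- order(vi)
    rc_ptr <- c(0L, cumsum(tabulate(vi, nbins = nrow(mv))))
    rc_ind <- match(rr$id, ped$id)[o] - 1L
    panel_col <- match(mv$variant, pvars)
    panel_col <- ifelse(is.na(panel_col), -1L, panel_col - 1L)
    res <- .hybrid_chr_cpp(fam, as.numeric(pen_panel), ppos,
                           unname(freqs[pvars]), mv$pos_cm,
                           unname(freqs[mv$variant]),
                           as.integer(panel_col),
                           as.integer(rc_ptr), as.integer(rc_ind),
                           as.integer(rr$refReads[o]),
                           as.integer(rr$altReads[o]),
                           settings$seq_error, settings$multi_maxit,
                           settings$multi_tol, settings$inner_sweeps,
                           settings$maxit, settings$tol, return_probs)
    dos[, mv$variant] <- res$dosage
    dimnames(res$seg_panel) <- list(c("pp", "pm", "mp", "mm"), ped$id, pvars)
    seg_panel[[as.character(ch)]] <- res$seg_panel
    if (return_probs) probs[, , match(mv$variant, map$variant)] <- res$prob
  }
  out <- list(dosages = dos, seg_panel = seg_panel, freqs = freqs,
              map = map, panels = panels, settings = settings)
  if (return_probs) {
    dimnames(probs) <- list(c("aa", "aA", "Aa", "AA"), ped$id, map$variant)
    out$probs <- probs
  }
  structure(out, class = "hybrid_peel")
}

#' @export
print.hybrid_peel <- function(x, ...) {
  cat("<hybrid_peel> dosages:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}

#' Tidy a hybrid peeling result into a long dosage tibble
#' @param x `hybrid_peel` object.
#' @param ... Unused.
#' @export
#' @importFrom generics tidy
tidy.hybrid_peel <- function(x, ...) {
  tibble::tibble(id = rep(rownames(x$dosages), times = ncol(x$dosages)),
                 variant = rep(colnames(x$dosages), each = nrow(x$dosages)),
                 dosage = as.vector(x$dosages))
}

#' One-row summary of a hybrid peeling result
#' @param x `hybrid_peel` object.
#' @param ... Unused.
#' @export
#' @importFrom generics glance
glance.hybrid_peel <- function(x, ...) {
  tibble::tibble(n_individuals = nrow(x$dosages),
                 n_variants = ncol(x$dosages),
                 mean_dosage = mean(x$dosages),
                 mean_maf = mean(pmin(x$freqs, 1 - x$freqs)))
}
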
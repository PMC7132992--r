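#' Pedigree tables
#'
#' A pedigree is a tibble with columns `id`, `sire`, `dam` (character;
#' `NA` = unknown parent), `sex` (`"M"`/`"F"`/`NA`) and `gen` (integer
#' generation index, 0 for founders). Rows are ordered so that every named
#' parent appears before its progeny; this ordering is what the peeling
#' sweeps and the gene-dropping simulator rely on.
#'
#' @param df A data frame with at least `id`, `sire`, `dam`.
#' @param quiet Suppress re-sort/auto-founder warnings.
#' @return A tibble of class `ped_df`, topologically sorted.
#' @export
as_pedigree <- function(df, quiet = FALSE) {
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  df <- tibble::as_tibble(df)
  df$id   <- as.character(df$id)
  df$sire <- clean_parent(df$sire)
  df$dam  <- clean_parent(df$dam)
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df$sex <- toupper(as.character(df$sex))
  df$sex[!df$sex %in% c("M", "F")] <- NA_character_

  if (anyDuplicated(df$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }

  ## parents referenced but never defined become founder records
  refs <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(refs)) {
    if (!quiet) {
      warning(length(refs), " parent(s) referenced but not defined; ",
              "added as founders: ", paste(utils::head(refs, 5), collapse = ", "),
              if (length(refs) > 5) ", ..." else "")
    }
    df <- dplyr::bind_rows(
      tibble::tibble(id = refs, sire = NA_character_, dam = NA_character_,
                     sex = NA_character_),
      df
    )
  }

  ord <- ped_toposort(df$id, df$sire, df$dam)
  if (is.null(ord)) stop("cyclic ancestry: an individual is its own ancestor")
  if (!identical(ord, seq_len(nrow(df)))) {
    if (!quiet) warning("pedigree re-sorted so parents precede progeny")
    df$.orig_order <- seq_len(nrow(df))
    df <- df[ord, ]
  }

  df$gen <- ped_generation(df)
  class(df) <- c("ped_df", class(df))
  df
}

clean_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", ".", "", "NA")] <- NA_character_
  x
}

## Kahn topological sort, stable in input order; NULL on cycle.
ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  si <- unname(idx[sire]); di <- unname(idx[dam])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  ## stable queue: process candidates in input order
  out <- integer(0)
  avail <- which(indeg == 0L)
  done <- logical(n)
  while (length(avail)) {
    i <- avail[1]; avail <- avail[-1]
    out <- c(out, i); done[i] <- TRUE
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- sort(c(avail, k))
    }
  }
  if (length(out) < n) return(NULL)
  out
}

ped_generation <- function(df) {
  idx <- stats::setNames(seq_len(nrow(df)), df$id)
  si <- unname(idx[df$sire]); di <- unname(idx[df$dam])
  g <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    pg <- c(if (!is.na(si[i])) g[si[i]], if (!is.na(di[i])) g[di[i]])
    g[i] <- if (length(pg)) max(pg) + 1L else 0L
  }
  g
}

#' Read a pedigree file
#'
#' Tab- or space-delimited with header `id sire dam [sex]`; `"0"` or `"."`
#' marks an unknown parent. Rows are re-sorted parents-first if needed (with
#' a warning) and parents that never appear as individuals are auto-created
#' as founders.
#'
#' @param path File path.
#' @param quiet Suppress warnings.
#' @return A [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path, quiet = FALSE) {
  df <- utils::read.table(path, header = TRUE, colClasses = "character",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  as_pedigree(df, quiet = quiet)
}

#' Write a pedigree file
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ifelse(is.na(ped$sex), "NA", ped$sex))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## integer parent indices (NA for unknown), aligned to pedigree order
ped_indices <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  list(sire = unname(idx[ped$sire]), dam = unname(idx[ped$dam]), id = idx)
}

## list of progeny row-indices per individual
ped_progeny <- function(ped) {
  pi <- ped_indices(ped)
  n <- nrow(ped)
  prog <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(pi$sire[i], pi$dam[i])) {
      if (!is.na(p)) prog[[p]] <- c(prog[[p]], i)
    }
  }
  prog
}

#' Relatives of an individual by relationship level
#'
#' Resolves grandparents, parents, progeny and grandprogeny strictly through
#' pedigree links.
#'
#' @param ped Pedigree tibble.
#' @param id Individual id.
#' @return Named list of character vectors:
#'   `grandparents`, `parents`, `progeny`, `grandprogeny`.
#' @export
ped_relatives <- function(ped, id) {
  pi <- ped_indices(ped)
  prog <- ped_progeny(ped)
  i <- pi$id[[id]]
  par <- c(pi$sire[i], pi$dam[i]); par <- par[!is.na(par)]
  gpar <- unique(unlist(lapply(par, function(p) {
    g <- c(pi$sire[p], pi$dam[p]); g[!is.na(g)]
  })))
  pr <- prog[[i]]
  gpr <- unique(unlist(lapply(pr, function(p) prog[[p]])))
  list(grandparents = ped$id[gpar], parents = ped$id[par],
       progeny = ped$id[pr], grandprogeny = ped$id[gpr])
}

#' Additive (numerator) relationship matrix, tabular method
#'
#' Dense recursion `A[i,j] = (A[j,sire(i)] + A[j,dam(i)]) / 2`,
#' `A[i,i] = 1 + A[sire(i),dam(i)] / 2`. Intended for small pedigrees
#' (tests, toy examples); [connectedness()] handles large pedigrees without
#' materializing `A`.
#'
#' @param ped Pedigree tibble.
#' @return Dense numeric matrix with id dimnames.
#' @export
additive_relationship <- function(ped) {
  pi <- ped_indices(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        a <- 0
        if (!is.na(s)) a <- a + A[j, s]
        if (!is.na(d)) a <- a + A[j, d]
        A[i, j] <- A[j, i] <- a / 2
      }
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  A
}

#' Connectedness to the rest of the pedigree
#'
#' Sum of additive relationship coefficients between each individual and all
#' other pedigree members, `sum_j A[i,j] - A[i,i]`. Computed without
#' materializing `A` via the decomposition `A = T D T'`: `A 1 = T D (T' 1)`
#' with `T' 1` from a single reverse sweep, `D` from inbreeding coefficients
#' (Meuwissen-Luo recursion), and `T w` from a forward sweep.
#'
#' @param ped Pedigree tibble.
#' @return Tibble with `id`, `inbreeding`, `connectedness`.
#' @export
connectedness <- function(ped) {
  pi <- ped_indices(ped)
  s <- ifelse(is.na(pi$sire), 0L, pi$sire)
  d <- ifelse(is.na(pi$dam), 0L, pi$dam)
  res <- .ped_connectedness_cpp(s, d)
  tibble::tibble(id = ped$id,
                 inbreeding = res$f,
                 connectedness = res$connect)
}
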
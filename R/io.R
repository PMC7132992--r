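#' Genotype / dosage / read-count file formats
#'
#' Genotypes travel as a PLINK-RAW-style table: one row per individual,
#' first column `id`, one column per variant with entries 0/1/2 (alt-allele
#' count) or `NA`. Dosages use the same layout with floats in `[0, 2]`.
#' Read counts use a long TSV `id  variant  refReads  altReads` holding only
#' (individual, variant) pairs with at least one read. All writers round-trip
#' losslessly through the matching reader.
#'
#' @name hybridpeel-io
NULL

#' @rdname hybridpeel-io
#' @param mat Integer matrix (individuals x variants), dimnames required.
#' @param path File path.
#' @export
write_genotypes <- function(mat, path) {
  check_geno(mat)
  write_id_matrix(mat, path)
}

#' @rdname hybridpeel-io
#' @export
read_genotypes <- function(path) {
  mat <- read_id_matrix(path, integer = TRUE)
  check_geno(mat)
  mat
}

#' @rdname hybridpeel-io
#' @export
write_dosages <- function(mat, path) {
  check_dosage(mat)
  write_id_matrix(mat, path)
}

#' @rdname hybridpeel-io
#' @export
read_dosages <- function(path) {
  mat <- read_id_matrix(path, integer = FALSE)
  check_dosage(mat)
  mat
}

#' @rdname hybridpeel-io
#' @param rc Read-count tibble (`id`, `variant`, `refReads`, `altReads`).
#' @export
write_read_counts <- function(rc, path) {
  rc <- as_read_counts(rc)
  utils::write.table(as.data.frame(rc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname hybridpeel-io
#' @export
read_read_counts <- function(path) {
  as_read_counts(utils::read.table(path, header = TRUE,
                                   stringsAsFactors = FALSE))
}

#' Read-count table constructor
#'
#' @param df Data frame with `id`, `variant`, `refReads`, `altReads`
#'   (non-negative integers); rows with zero total reads are dropped.
#' @return Tibble of class `read_counts`.
#' @export
as_read_counts <- function(df) {
  stopifnot(all(c("id", "variant", "refReads", "altReads") %in% names(df)))
  df <- tibble::as_tibble(df)
  df$id <- as.character(df$id)
  df$variant <- as.character(df$variant)
  df$refReads <- as.integer(df$refReads)
  df$altReads <- as.integer(df$altReads)
  if (any(df$refReads < 0 | df$altReads < 0, na.rm = TRUE)) {
    stop("negative read count")
  }
  df <- df[df$refReads + df$altReads > 0, ]
  if (!inherits(df, "read_counts")) class(df) <- c("read_counts", class(df))
  df
}

check_geno <- function(mat) {
  v <- mat[!is.na(mat)]
  if (length(v) && !all(v %in% 0:2)) stop("genotype outside {0, 1, 2, NA}")
  invisible(mat)
}

check_dosage <- function(mat) {
  v <- mat[!is.na(mat)]
  if (length(v) && (min(v) < 0 || max(v) > 2)) stop("dosage outside [0, 2]")
  invisible(mat)
}

write_id_matrix <- function(mat, path) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_id_matrix <- function(path, integer = FALSE) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- if (integer) "integer" else "double"
  rownames(mat) <- as.character(df$id)
  mat
}
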
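#' Genotype dosage matrix with a variant map
#'
#' The central genotype container: an `n_samples x n_variants` matrix of
#' allele dosages (expected alternate-allele counts in `[0, 2]`) together
#' with a variant map describing each column. Variants are kept sorted by
#' `(chrom, pos)`; sample ids must be unique. Only biallelic variants are
#' representable (`ref` and `alt` are single allele strings).
#'
#' @param dosage numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids; missing values are allowed and are
#'   mean-imputed per variant.
#' @param map data frame with columns `chrom`, `pos` (1-based integer),
#'   `id`, `ref`, `alt`; one row per dosage column, in column order.
#' @param samples optional character vector of sample ids overriding
#'   `rownames(dosage)`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (the matrix, dimnames set to samples x variant ids) and `map`.
#' @export
geno_matrix <- function(dosage, map, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (!is.null(samples)) rownames(dosage) <- samples
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("sample%04d", seq_len(nrow(dosage)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols))
    stop("variant map lacks column(s): ", paste(missing_cols, collapse = ", "))
  map <- map[required]
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$id <- as.character(map$id)
  if (nrow(map) != ncol(dosage))
    stop("map has ", nrow(map), " rows but dosage has ", ncol(dosage), " columns")
  if (any(map$pos < 1L)) stop("variant positions must be >= 1")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids in genotype matrix")
  if (anyDuplicated(map$id)) stop("duplicate variant ids in map")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(map) <- NULL
  n_imputed <- 0L
  if (anyNA(dosage)) {
    for (j in which(colSums(is.na(dosage)) > 0L)) {
      nas <- is.na(dosage[, j])
      if (all(nas)) stop("variant ", map$id[j], " has no non-missing dosage")
      dosage[nas, j] <- mean(dosage[!nas, j])
      n_imputed <- n_imputed + sum(nas)
    }
  }
  if (any(dosage < -1e-8 | dosage > 2 + 1e-8))
    stop("dosages must lie in [0, 2]")
  dosage[dosage < 0] <- 0
  dosage[dosage > 2] <- 2
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map, n_imputed = n_imputed),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  cat("chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  if (x$n_imputed > 0L) cat("mean-imputed dosages:", x$n_imputed, "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param g a `geno_matrix`.
#' @return character vector of sample ids.
#' @export
geno_samples <- function(g) rownames(g$dosage)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @param samples sample ids or indices to keep (default all).
#' @param variants variant ids or column indices to keep (default all).
#' @return a `geno_matrix` restricted to the requested rows/columns.
#' @export
geno_subset <- function(g, samples = NULL, variants = NULL) {
  dos <- g$dosage
  map <- g$map
  if (!is.null(variants)) {
    idx <- if (is.character(variants)) match(variants, map$id) else as.integer(variants)
    if (anyNA(idx)) stop("unknown variant id(s) in subset")
    dos <- dos[, idx, drop = FALSE]
    map <- map[idx, , drop = FALSE]
  }
  if (!is.null(samples)) {
    sidx <- if (is.character(samples)) match(samples, rownames(dos)) else as.integer(samples)
    if (anyNA(sidx)) stop("unknown sample id(s) in subset")
    dos <- dos[sidx, , drop = FALSE]
  }
  geno_matrix(dos, map)
}

#' Dosage vector for one variant
#' @param g a `geno_matrix`.
#' @param id variant id.
#' @return named numeric vector of per-sample dosages.
#' @export
geno_dosage <- function(g, id) {
  j <- match(id, g$map$id)
  if (is.na(j)) stop("variant ", id, " not present")
  g$dosage[, j]
}
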
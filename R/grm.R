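#' Genomic relationship matrix from dosages
#'
#' VanRaden-style GRM on dosages with per-variant standardization: each
#' variant column is centered at `2p` and scaled by `sqrt(2p(1-p))` (with
#' `p` the alternate allele frequency), and the GRM is the cross-product of
#' the standardized matrix divided by the number of variants used. This is
#' the default GRM of standard mixed-model GWAS software. Monomorphic
#' variants carry no information and are excluded from the sum.
#'
#' @param g a [geno_matrix()].
#' @param variant_subset optional character vector of variant ids to build
#'   from (default: all variants).
#' @return an object of class `grm`: list with `K` (n x n symmetric matrix,
#'   dimnames = sample ids), `samples`, and `n_variants` actually used.
#' @export
build_grm <- function(g, variant_subset = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  dos <- g$dosage
  if (!is.null(variant_subset)) {
    keep <- intersect(variant_subset, g$map$id)
    if (!length(keep)) stop("variant subset is empty after intersection with the map")
    dos <- dos[, match(keep, g$map$id), drop = FALSE]
  }
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants to build a GRM from")
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(dos, 2, 2 * p, `-`)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(z) / ncol(z)
  K <- (K + t(K)) / 2
  structure(list(K = K, samples = rownames(dos), n_variants = ncol(z)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$samples), "samples, built from", x$n_variants, "variants\n")
  cat("mean diagonal:", round(mean(diag(x$K)), 4), "\n")
  invisible(x)
}

#' Remove all variants flanking lead SNPs
#'
#' Drops every variant on the same chromosome within `flank_bp` of any lead
#' position (boundary inclusive), including the leads themselves. Used to
#' build the "rest of genome" GRM for two-component variance partitioning.
#'
#' @param g a [geno_matrix()].
#' @param leads data frame with columns `chrom` and `pos` (e.g. the lead-SNP
#'   table from [iterative_scan()]), or a character vector of variant ids.
#' @param flank_bp flank size in base pairs (default 2,500,000).
#' @return a `geno_matrix` without the flanking variants.
#' @export
exclude_flank <- function(g, leads, flank_bp = 2.5e6) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.character(leads)) {
    idx <- match(leads, g$map$id)
    if (anyNA(idx)) stop("lead id(s) not found in genotype map")
    leads <- g$map[idx, c("chrom", "pos")]
  }
  if (!nrow(leads)) stop("no leads supplied")
  drop <- rep(FALSE, nrow(g$map))
  for (k in seq_len(nrow(leads))) {
    drop <- drop | (g$map$chrom == leads$chrom[k] &
                      abs(g$map$pos - leads$pos[k]) <= flank_bp)
  }
  if (all(drop)) stop("flank exclusion removed every variant")
  geno_subset(g, variants = which(!drop))
}

#' Write a GRM as a long-format TSV
#'
#' Lower triangle (including diagonal) as `sample_i<TAB>sample_j<TAB>value`,
#' plus a companion `.samples` file listing the sample order.
#'
#' @param grm a [build_grm()] result.
#' @param path output TSV path.
#' @return invisibly, the paths written.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  idx <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(sample_i = grm$samples[idx[, 1]],
                    sample_j = grm$samples[idx[, 2]],
                    value = grm$K[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- paste0(path, ".samples")
  writeLines(grm$samples, spath)
  invisible(c(path, spath))
}

#' Read a GRM written by [write_grm()]
#' @param path TSV path (with `paste0(path, ".samples")` alongside).
#' @param n_variants variant count to record (default `NA`).
#' @return a `grm` object.
#' @export
read_grm <- function(path, n_variants = NA_integer_) {
  samples <- readLines(paste0(path, ".samples"))
  dat <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  n <- length(samples)
  K <- matrix(0, n, n, dimnames = list(samples, samples))
  i <- match(dat$sample_i, samples)
  j <- match(dat$sample_j, samples)
  K[cbind(i, j)] <- dat$value
  K[cbind(j, i)] <- dat$value
  structure(list(K = K, samples = samples, n_variants = n_variants),
            class = "grm")
}
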
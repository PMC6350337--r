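#' Pairwise LD (r-squared) between a focal variant and others
#'
#' Genotype-based linkage disequilibrium: the squared Pearson correlation of
#' dosage vectors (the `--r2` of common GWAS toolkits on imputed dosages).
#' Monomorphic partners have undefined correlation and are omitted with a
#' warning.
#'
#' @param g a [geno_matrix()].
#' @param focal id of the focal (e.g. lead) variant.
#' @param others character vector of partner ids (default: every other
#'   variant on the focal variant's chromosome).
#' @return data frame with `id`, `chrom`, `pos`, `r2`, sorted by position.
#' @export
pairwise_r2 <- function(g, focal, others = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  fi <- match(focal, g$map$id)
  if (is.na(fi)) stop("focal variant ", focal, " not in genotype map")
  if (is.null(others))
    others <- setdiff(g$map$id[g$map$chrom == g$map$chrom[fi]], focal)
  oi <- match(others, g$map$id)
  if (anyNA(oi)) stop("partner variant(s) missing from genotype map")
  x <- g$dosage[, fi]
  if (stats::sd(x) < 1e-12) stop("focal variant is monomorphic; r2 undefined")
  M <- g$dosage[, oi, drop = FALSE]
  sds <- apply(M, 2, stats::sd)
  mono <- sds < 1e-12
  if (any(mono)) {
    warning(sum(mono), " monomorphic partner(s) omitted from r2 computation")
    M <- M[, !mono, drop = FALSE]
    oi <- oi[!mono]
  }
  r <- suppressWarnings(as.vector(stats::cor(x, M)))
  out <- data.frame(id = g$map$id[oi], chrom = g$map$chrom[oi],
                    pos = g$map$pos[oi], r2 = r^2, stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LD region around a lead SNP
#'
#' The region spans from the outermost variant upstream of the lead with
#' `r2 > r2_min` through the outermost such variant downstream; qualifying
#' variants need not be contiguous (the boundary is the *last* SNP above the
#' cutoff on each side). With no qualifying partner the region degenerates
#' to the lead position itself.
#'
#' @param pairs a [pairwise_r2()] result for one chromosome.
#' @param lead_pos position of the lead variant.
#' @param r2_min LD cutoff (default 0.2, exclusive).
#' @return list with `start`, `end` (1-based inclusive).
#' @export
ld_region <- function(pairs, lead_pos, r2_min = 0.2) {
  qual <- pairs$pos[!is.na(pairs$r2) & pairs$r2 > r2_min]
  list(start = as.integer(min(c(qual, lead_pos))),
       end = as.integer(max(c(qual, lead_pos))))
}
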
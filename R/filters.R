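#' Minor allele frequency from a dosage column
#'
#' The allele frequency is `p = mean(dosage) / 2`; the MAF is `min(p, 1 - p)`,
#' so it is invariant under allele relabeling (`d -> 2 - d`).
#'
#' @param dosage_column numeric vector of per-sample dosages in `[0, 2]`;
#'   missing values are dropped.
#' @return MAF, a value in `[0, 0.5]`.
#' @export
compute_maf <- function(dosage_column) {
  x <- dosage_column[!is.na(dosage_column)]
  if (!length(x)) stop("all dosages missing; MAF undefined")
  p <- mean(x) / 2
  min(p, 1 - p)
}

#' Hardy-Weinberg goodness-of-fit test from genotype counts
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the proportions expected under Hardy-Weinberg equilibrium. Dosages should
#' be rounded to the nearest hard genotype (0/1/2) before counting.
#'
#' @param genotype_counts integer vector `c(n_AA, n_Aa, n_aa)` of genotype
#'   counts (AA = dosage 0, Aa = 1, aa = 2).
#' @param exact logical; if `TRUE`, use the exact conditional test
#'   (enumeration over heterozygote counts) instead of the chi-square.
#' @return p-value in `(0, 1]`. Monomorphic input returns 1 by convention.
#' @export
hwe_test <- function(genotype_counts, exact = FALSE) {
  if (length(genotype_counts) != 3L || any(genotype_counts < 0))
    stop("genotype_counts must be three non-negative counts (n_AA, n_Aa, n_aa)")
  n <- sum(genotype_counts)
  if (n == 0) stop("no genotypes to test")
  n_aa2 <- genotype_counts[3]
  n_het <- genotype_counts[2]
  p <- (2 * genotype_counts[1] + n_het) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  if (exact) return(hwe_exact_p(genotype_counts))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((genotype_counts - expected)^2 / expected)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# Exact HWE test (Wigginton et al. style): probability of the observed
# heterozygote count conditional on allele counts, summed over outcomes no
# more probable than observed.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_a <- 2 * counts[1] + counts[2]   # minor-or-major, symmetry below
  n_b <- 2 * n - n_a
  rare <- min(n_a, n_b)
  het_obs <- counts[2]
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == het_obs)
  min(1, sum(prob[prob <= prob[obs] + 1e-12]))
}

#' Filter variants on MAF and Hardy-Weinberg deviation
#'
#' Removes variants with minor allele frequency below `maf_min` or with a
#' Hardy-Weinberg goodness-of-fit p-value below `hwe_p_min` (dosages rounded
#' to the nearest genotype for the HWE count). Variants failing both filters
#' are counted against the MAF filter, so the report reconciles exactly.
#'
#' @param g a [geno_matrix()].
#' @param maf_min minimum minor allele frequency retained (default 0.01).
#' @param hwe_p_min minimum HWE p-value retained (default 1e-6).
#' @return list with `geno` (the filtered `geno_matrix`) and `report`, a
#'   one-row data frame with counts `n_input`, `n_removed_maf`,
#'   `n_removed_hwe`, `n_retained`.
#' @export
filter_variants <- function(g, maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "geno_matrix"))
  maf <- apply(g$dosage, 2, compute_maf)
  fail_maf <- maf < maf_min
  hwe_p <- hwe_p_column(g$dosage)
  fail_hwe <- hwe_p < hwe_p_min & !fail_maf
  keep <- !fail_maf & !fail_hwe
  report <- data.frame(
    n_input = ncol(g$dosage),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_retained = sum(keep)
  )
  out <- if (any(keep)) geno_subset(g, variants = which(keep)) else {
    gm <- g
    gm$dosage <- g$dosage[, 0, drop = FALSE]
    gm$map <- g$map[0, , drop = FALSE]
    gm
  }
  list(geno = out, report = report)
}

hwe_p_column <- function(dosage) {
  hard <- round(dosage)
  apply(hard, 2, function(x) {
    counts <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    hwe_test(counts)
  })
}
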
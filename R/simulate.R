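#' Configuration of the haplotype-mosaic simulator and spike-in experiment
#'
#' Defaults define the study conditions of the type-I-error experiment:
#' a single-chromosome panel of 2,000 samples by 5,000 variants with
#' cattle-like long-range LD, a polygenic base phenotype standing in for a
#' de-regressed proof, 100 replicates, QTN minor allele frequency in
#' [0.05, 0.10] under Hardy-Weinberg equilibrium, allele-substitution
#' effects drawn from Normal(0.2 * SD(y), variance 0.01 * Var(y)), and ten
#' LD partners in the r-squared bins 0.9-1, 0.8-0.9, ..., 0.2-0.3 plus two
#' below 0.2.
#'
#' @param n_samples samples in the panel (default 2000).
#' @param n_variants variants on the chromosome (default 5000).
#' @param chrom chromosome label (default "1").
#' @param chrom_length_bp chromosome length (default 10 Mb).
#' @param mosaic_segment_mean_bp mean founder-segment length of the mosaic;
#'   longer segments mean slower LD decay (default 500 kb).
#' @param n_founder_haplotypes founder haplotypes the mosaics copy from
#'   (default 30).
#' @param n_recomb_sites number of candidate recombination sites shared by
#'   all haplotypes (default 500), emulating the finite set of ancestral
#'   breakpoints of a real genealogy: variants between consecutive sites
#'   that carry the same founder pattern are exact LD duplicates, as
#'   imputed sequence variants in perfect LD are.
#' @param founder_maf_range allele-frequency range of fresh founder allele
#'   patterns (default `c(0.05, 0.5)`).
#' @param pattern_toggle_prob per-variant probability that the founder
#'   allele pattern mutates by toggling one founder, grading LD downward
#'   along the chromosome (default 0.008).
#' @param pattern_fresh_prob per-variant probability of an entirely new
#'   founder pattern (default 0.002).
#' @param h2_polygenic variance fraction of the polygenic term in the base
#'   phenotype (default 0.8, emulating a de-regressed proof whose variance
#'   is mostly additive-genetic).
#' @param seed base random seed.
#' @param n_replicates spike-in replicates (default 100).
#' @param qtn_maf_range MAF window for QTN eligibility (default
#'   `c(0.05, 0.10)`).
#' @param qtn_hwe_p_min minimum HWE p-value for QTN eligibility (default
#'   0.05).
#' @param effect_mean_frac mean of the allele-substitution effect as a
#'   fraction of SD(y) (default 0.20).
#' @param effect_var_frac variance of the effect distribution as a fraction
#'   of Var(y) (default 0.01).
#' @param effect_mode `"distribution"` draws the effect from the Normal law
#'   above (the literal protocol); `"fixed_var"` instead sizes the effect so
#'   the QTN explains `effect_var_frac` of the phenotypic variance.
#' @param r2_bins data frame `lo`, `hi`, `count` defining the partner bins.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_variants = 5000, chrom = "1",
                       chrom_length_bp = 10e6,
                       mosaic_segment_mean_bp = 5e5,
                       n_founder_haplotypes = 30,
                       n_recomb_sites = 500,
                       founder_maf_range = c(0.05, 0.5),
                       pattern_toggle_prob = 0.008,
                       pattern_fresh_prob = 0.002,
                       h2_polygenic = 0.8, seed = 1, n_replicates = 100,
                       qtn_maf_range = c(0.05, 0.10), qtn_hwe_p_min = 0.05,
                       effect_mean_frac = 0.20, effect_var_frac = 0.01,
                       effect_mode = c("distribution", "fixed_var"),
                       r2_bins = default_r2_bins()) {
  stopifnot(n_samples >= 1, n_variants >= 2, chrom_length_bp > n_variants,
            mosaic_segment_mean_bp > 0, n_founder_haplotypes >= 2,
            n_recomb_sites >= 1, h2_polygenic >= 0, h2_polygenic < 1,
            n_replicates >= 1)
  structure(list(
    n_samples = n_samples, n_variants = n_variants, chrom = chrom,
    chrom_length_bp = chrom_length_bp,
    mosaic_segment_mean_bp = mosaic_segment_mean_bp,
    n_founder_haplotypes = n_founder_haplotypes,
    n_recomb_sites = n_recomb_sites,
    founder_maf_range = founder_maf_range,
    pattern_toggle_prob = pattern_toggle_prob,
    pattern_fresh_prob = pattern_fresh_prob,
    h2_polygenic = h2_polygenic, seed = seed, n_replicates = n_replicates,
    qtn_maf_range = qtn_maf_range, qtn_hwe_p_min = qtn_hwe_p_min,
    effect_mean_frac = effect_mean_frac, effect_var_frac = effect_var_frac,
    effect_mode = match.arg(effect_mode), r2_bins = r2_bins
  ), class = "sim_config")
}

#' Default LD partner bins of the spike-in protocol
#'
#' Eight one-partner bins from 0.9-1 down to 0.2-0.3 plus one two-partner
#' bin below 0.2.
#'
#' @return data frame with columns `lo`, `hi`, `count`.
#' @export
default_r2_bins <- function() {
  data.frame(lo = c(seq(0.9, 0.2, by = -0.1), 0),
             hi = c(seq(1.0, 0.3, by = -0.1), 0.2),
             count = c(rep(1L, 8), 2L))
}

#' Simulate genotypes as mosaics of founder haplotypes
#'
#' Each sample carries two haplotypes built as mosaics of a small founder
#' panel. Recombination is restricted to a finite set of candidate sites
#' shared by all haplotypes (as the breakpoints of a real genealogy are);
#' at each site a haplotype switches to a uniformly drawn founder with
#' probability `1 - exp(-spacing / mosaic_segment_mean_bp)`, so founder
#' segments have mean length `mosaic_segment_mean_bp`. Founder allele
#' patterns mutate slowly along the chromosome (single-founder toggles,
#' occasional fresh patterns), which together with the segment decay yields
#' block LD spanning the whole r-squared range: variants with the same
#' pattern and no intervening recombination site are exact LD duplicates,
#' and correlation decays with distance beyond that. Dosage is the
#' haplotype sum; output is deterministic given `(cfg, seed)`.
#'
#' @param cfg a [sim_config()].
#' @param seed random seed (default `cfg$seed`).
#' @return a [geno_matrix()] of 0/1/2 dosages.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  m <- cfg$n_variants
  n <- cfg$n_samples
  K <- cfg$n_founder_haplotypes
  L <- cfg$chrom_length_bp
  pos <- sort(sample.int(L - 1L, m))

  # founder allele patterns, mutating slowly along the chromosome
  F <- matrix(FALSE, K, m)
  fresh_pattern <- function() {
    u <- stats::runif(1, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
    nc <- min(max(1L, round(u * K)), K - 1L)
    pat <- rep(FALSE, K)
    pat[sample.int(K, nc)] <- TRUE
    pat
  }
  pat <- fresh_pattern()
  F[, 1] <- pat
  for (j in 2:m) {
    u <- stats::runif(1)
    if (u < cfg$pattern_fresh_prob) {
      pat <- fresh_pattern()
    } else if (u < cfg$pattern_fresh_prob + cfg$pattern_toggle_prob) {
      flip <- sample.int(K, 1)
      pat[flip] <- !pat[flip]
      if (!any(pat) || all(pat)) pat <- fresh_pattern()
    }
    F[, j] <- pat
  }

  # shared candidate recombination sites and per-site switch probabilities
  B <- cfg$n_recomb_sites
  sites <- sort(stats::runif(B, 1, L))
  spacing <- diff(c(0, sites))
  p_switch <- 1 - exp(-spacing / cfg$mosaic_segment_mean_bp)
  interval_of_variant <- findInterval(pos, sites) + 1L  # 1 .. B+1

  dosage <- matrix(0, n, m)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    acc <- integer(m)
    for (h in 1:2) {
      switches <- stats::runif(B) < p_switch
      seg_of_interval <- cumsum(c(1L, switches))       # length B + 1
      founder_of_seg <- sample.int(K, seg_of_interval[B + 1L], replace = TRUE)
      fid <- founder_of_seg[seg_of_interval[interval_of_variant]]
      acc <- acc + F[cbind(fid, cols)]
    }
    dosage[i, ] <- acc
  }
  map <- data.frame(chrom = cfg$chrom, pos = pos,
                    id = sprintf("v%05d", seq_len(m)),
                    ref = "A", alt = "B", stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("s%04d", seq_len(n))
  geno_matrix(dosage, map)
}

#' Polygenic base phenotype
#'
#' `y = polygenic + residual`: the polygenic term is a sum of small effects
#' over all (centered, unit-scaled) variants, so its covariance across
#' samples is proportional to the VanRaden relationship matrix of `g`; it
#' is rescaled so its realized variance is exactly
#' `h2_polygenic * var_target`. The residual is Gaussian with variance
#' `(1 - h2_polygenic) * var_target`. With `h2_polygenic = 0` the phenotype
#' is pure noise. Deterministic given `(g, h2, seed)`.
#'
#' @param g a [geno_matrix()].
#' @param h2_polygenic polygenic variance fraction in `[0, 1)`.
#' @param seed random seed.
#' @param var_target total phenotypic variance aimed for (default 1).
#' @return named numeric phenotype vector over the samples of `g`.
#' @export
base_phenotype <- function(g, h2_polygenic, seed, var_target = 1) {
  stopifnot(inherits(g, "geno_matrix"), h2_polygenic >= 0, h2_polygenic < 1)
  set.seed(seed)
  n <- nrow(g$dosage)
  e <- stats::rnorm(n, 0, sqrt((1 - h2_polygenic) * var_target))
  y <- e
  if (h2_polygenic > 0) {
    u <- stats::rnorm(ncol(g$dosage))
    ctr <- sweep(g$dosage, 2, colMeans(g$dosage), `-`)
    csd <- sqrt(colMeans(ctr^2))
    ok <- csd > 1e-9
    poly <- as.vector(sweep(ctr[, ok, drop = FALSE], 2, csd[ok], `/`) %*% u[ok])
    poly_sd <- stats::sd(poly)
    if (poly_sd > 0)
      y <- y + poly / poly_sd * sqrt(h2_polygenic * var_target)
  }
  names(y) <- geno_samples(g)
  y
}

#' Select a QTN and its ten LD partners
#'
#' Draws the QTN uniformly from variants with MAF inside `qtn_maf_range`
#' and HWE p-value at least `qtn_hwe_p_min`, then fills each r-squared bin
#' of `cfg$r2_bins` with partners drawn from the variants whose LD with the
#' QTN falls in the bin. When a candidate QTN cannot fill every bin another
#' QTN is drawn, up to `max_tries`; exhaustion raises an error naming the
#' first unfillable bin.
#'
#' @param g a [geno_matrix()] (one chromosome).
#' @param cfg a [sim_config()].
#' @param seed random seed.
#' @param maf,hwe_p optional precomputed per-variant MAF and HWE p vectors
#'   (in map order), to avoid recomputation across replicates.
#' @param max_tries QTN candidates attempted before failing (default 50).
#' @return list with `qtn` (one-row map entry plus `maf`) and `partners`
#'   (data frame `id`, `pos`, `r2`, `bin_lo`, `bin_hi`).
#' @export
select_qtn_and_partners <- function(g, cfg, seed, maf = NULL, hwe_p = NULL,
                                    max_tries = 50) {
  stopifnot(inherits(g, "geno_matrix"))
  set.seed(seed)
  if (is.null(maf)) maf <- apply(g$dosage, 2, compute_maf)
  if (is.null(hwe_p)) hwe_p <- hwe_p_column(g$dosage)
  eligible <- which(maf >= cfg$qtn_maf_range[1] & maf <= cfg$qtn_maf_range[2] &
                      hwe_p >= cfg$qtn_hwe_p_min)
  if (!length(eligible))
    stop("no variant satisfies the QTN MAF/HWE eligibility window")
  bins <- cfg$r2_bins
  first_failure <- NULL
  for (try in seq_len(max_tries)) {
    qi <- sample(eligible, 1)
    x <- g$dosage[, qi]
    r2 <- suppressWarnings(as.vector(stats::cor(x, g$dosage))^2)
    r2[qi] <- NA
    chosen <- integer(0)
    failed_bin <- NULL
    for (b in seq_len(nrow(bins))) {
      in_bin <- which(!is.na(r2) & r2 >= bins$lo[b] &
                        (r2 < bins$hi[b] | bins$hi[b] >= 1))
      in_bin <- setdiff(in_bin, chosen)
      if (length(in_bin) < bins$count[b]) {
        failed_bin <- sprintf("[%.1f, %.1f)", bins$lo[b], bins$hi[b])
        break
      }
      pick <- if (length(in_bin) == 1L) in_bin else sample(in_bin, bins$count[b])
      chosen <- c(chosen, pick)
    }
    if (is.null(failed_bin)) {
      qtn <- g$map[qi, , drop = FALSE]
      qtn$maf <- maf[qi]
      rownames(qtn) <- NULL
      bin_idx <- rep(seq_len(nrow(bins)), bins$count)
      partners <- data.frame(id = g$map$id[chosen], pos = g$map$pos[chosen],
                             r2 = r2[chosen], bin_lo = bins$lo[bin_idx],
                             bin_hi = bins$hi[bin_idx],
                             stringsAsFactors = FALSE)
      return(list(qtn = qtn, partners = partners))
    }
    if (is.null(first_failure)) first_failure <- failed_bin
  }
  stop("could not fill LD partner bin ", first_failure, " after ", max_tries,
       " candidate QTNs")
}

#' Spike a QTN effect into a phenotype
#'
#' Samples the allele-substitution effect
#' `b ~ Normal(effect_mean_frac * SD(y), effect_var_frac * Var(y))` (or, in
#' `"fixed_var"` mode, sizes `b` so the QTN contributes
#' `effect_var_frac * Var(y)`), and returns `y + dosage * b`.
#'
#' @param y named numeric base phenotype.
#' @param qtn_dosage per-sample dosage vector of the QTN, aligned to `y`.
#' @param cfg a [sim_config()].
#' @param seed random seed.
#' @param b optional forced effect (e.g. 0 for a null run); skips sampling.
#' @return list with `y` (spiked phenotype) and `b` (effect used).
#' @export
spike_phenotype <- function(y, qtn_dosage, cfg, seed, b = NULL) {
  stopifnot(length(y) == length(qtn_dosage))
  if (is.null(b)) {
    set.seed(seed)
    sdy <- stats::sd(y)
    b <- if (cfg$effect_mode == "fixed_var") {
      sqrt(cfg$effect_var_frac) * sdy / stats::sd(qtn_dosage)
    } else {
      stats::rnorm(1, mean = cfg$effect_mean_frac * sdy,
                   sd = sqrt(cfg$effect_var_frac) * sdy)
    }
  }
  list(y = y + qtn_dosage * b, b = b)
}
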
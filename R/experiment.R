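#' QTN spike-in type-I-error experiment
#'
#' The simulation protocol probing whether iterative conditioning inflates
#' the false-positive rate. Per replicate: draw a fresh polygenic base
#' phenotype, select a QTN (MAF in the eligibility window, under HWE) and
#' its ten LD partners, spike `dosage * b` into the phenotype, run the
#' conditional scan at the experiment's Bonferroni threshold (recomputed
#' for the simulated variant count), and record (a) whether the QTN attains
#' the maximum -log10(P) of the unconditional round-1 scan and (b) how many
#' LD partners remain significant after the QTN itself is fixed as a
#' covariate (false positives). By default one genotype panel, its GRM and
#' its eigendecomposition are reused across replicates; a replicate whose
#' partner bins cannot be filled is resampled with a new seed and logged.
#'
#' The polygenic background is simulated from a second, unlinked chromosome
#' panel, which also builds the relationship matrix for the scan
#' (leave-one-chromosome-out): the random effect then absorbs the polygenic
#' variance, as a genome-wide GRM does for a real multi-chromosome dataset,
#' without absorbing the focal chromosome's QTN signal.
#'
#' @param cfg a [sim_config()].
#' @param reuse_panel reuse one simulated genotype panel across replicates
#'   (default `TRUE`); `FALSE` resimulates per replicate.
#' @param seed overrides `cfg$seed`.
#' @param progress print one line per 10 replicates.
#' @return list with `n_qtn_lead` (replicates where the QTN tops round 1),
#'   `n_false_positive_partners` (partner-significant count summed over
#'   replicates, after conditioning on the QTN), `n_replicates`,
#'   `threshold`, `n_variants`, and `log` (per-replicate data frame).
#' @export
type1_error_experiment <- function(cfg = sim_config(), reuse_panel = TRUE,
                                   seed = cfg$seed, progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1000L, cfg$n_replicates)

  prepare_panel <- function(panel_seed) {
    g <- simulate_genotypes(cfg, seed = panel_seed)
    g <- filter_variants(g)$geno
    bg_cfg <- cfg
    bg_cfg$chrom <- paste0(cfg$chrom, "_bg")
    g_bg <- simulate_genotypes(bg_cfg, seed = panel_seed + 17L)
    g_bg <- filter_variants(g_bg)$geno
    grm <- build_grm(g_bg)   # leave-one-chromosome-out relationship matrix
    cache <- scan_cache(grm, g)
    list(g = g, g_bg = g_bg, cache = cache,
         maf = apply(g$dosage, 2, compute_maf),
         hwe_p = hwe_p_column(g$dosage))
  }

  panel <- if (reuse_panel) prepare_panel(seed) else NULL
  logs <- vector("list", cfg$n_replicates)

  for (i in seq_len(cfg$n_replicates)) {
    if (!reuse_panel) panel <- prepare_panel(rep_seeds[i])
    g <- panel$g
    m <- ncol(g$dosage)
    threshold <- bonferroni_threshold(m)
    scfg <- scan_config(threshold_neg_log10p = threshold)

    sel <- NULL
    sel_seed <- rep_seeds[i] + 1L
    resampled <- 0L
    while (is.null(sel)) {
      sel <- tryCatch(
        select_qtn_and_partners(g, cfg, seed = sel_seed, maf = panel$maf,
                                hwe_p = panel$hwe_p),
        error = function(e) NULL)
      if (is.null(sel)) {
        resampled <- resampled + 1L
        sel_seed <- sel_seed + 7919L
        if (resampled > 20L) stop("replicate ", i,
                                  ": LD partner bins repeatedly unfillable")
      }
    }
    y0 <- base_phenotype(panel$g_bg, cfg$h2_polygenic, seed = rep_seeds[i] + 2L)
    sp <- spike_phenotype(y0, geno_dosage(g, sel$qtn$id), cfg,
                          seed = rep_seeds[i] + 3L)

    leads <- iterative_scan(g, sp$y, grm = NULL, cfg = scfg,
                            cache = panel$cache)
    rounds <- attr(leads, "rounds")
    r1 <- rounds[[1]]
    tested <- !r1$skipped & !is.na(r1$neg_log10_p)
    max_p <- max(r1$neg_log10_p[tested])
    qtn_p <- r1$neg_log10_p[match(sel$qtn$id, r1$id)]
    qtn_top <- !is.na(qtn_p) && qtn_p >= max_p - 1e-9

    # partner false positives: condition on the true QTN and rescan
    lead1 <- if (nrow(leads)) leads$id[leads$round == 1][1] else NA_character_
    cond <- if (identical(lead1, sel$qtn$id) && length(rounds) >= 2) {
      rounds[[2]]
    } else {
      scan_chromosome(g, sp$y, cache = panel$cache,
                      covariates = covariate_set(g, sel$qtn$id))
    }
    pp <- cond$neg_log10_p[match(sel$partners$id, cond$id)]
    n_fp <- sum(!is.na(pp) & pp > threshold)

    logs[[i]] <- data.frame(
      replicate = i, qtn_id = sel$qtn$id, qtn_maf = sel$qtn$maf, b = sp$b,
      qtn_neg_log10_p = qtn_p, max_neg_log10_p = max_p, qtn_top = qtn_top,
      round1_lead = lead1, n_leads = nrow(leads),
      n_false_positive_partners = n_fp, partner_max_r2 = max(sel$partners$r2),
      bins_resampled = resampled, stringsAsFactors = FALSE)
    if (progress && i %% 10 == 0)
      message("replicate ", i, "/", cfg$n_replicates)
  }
  log_df <- do.call(rbind, logs)
  list(n_qtn_lead = sum(log_df$qtn_top),
       n_false_positive_partners = sum(log_df$n_false_positive_partners),
       n_replicates = cfg$n_replicates,
       threshold = bonferroni_threshold(ncol(panel$g$dosage)),
       n_variants = ncol(panel$g$dosage), log = log_df)
}

#' Null calibration of the chromosome scan
#'
#' With no spiked QTN the per-variant p-values should be uniform: simulates
#' `n_sims` fresh panels with polygenic base phenotypes (polygenic term and
#' relationship matrix from an unlinked background panel, as in
#' [type1_error_experiment()]), scans each, and pools the empirical
#' fraction of tested variants with `p < alpha`.
#'
#' @param cfg a [sim_config()] (panel dimensions are taken from it).
#' @param n_sims number of independent null scans (default 10).
#' @param alpha nominal level checked (default 0.05).
#' @param seed overrides `cfg$seed`.
#' @return list with `fraction` (pooled empirical P(p < alpha)), `n_tests`,
#'   and `per_sim` fractions.
#' @export
null_calibration <- function(cfg, n_sims = 10, alpha = 0.05, seed = cfg$seed) {
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1000L, n_sims)
  hits <- 0L
  total <- 0L
  per_sim <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    g <- simulate_genotypes(cfg, seed = sim_seeds[s])
    g <- filter_variants(g)$geno
    bg_cfg <- cfg
    bg_cfg$chrom <- paste0(cfg$chrom, "_bg")
    g_bg <- filter_variants(simulate_genotypes(bg_cfg, seed = sim_seeds[s] + 17L))$geno
    grm <- build_grm(g_bg)
    y <- base_phenotype(g_bg, cfg$h2_polygenic, seed = sim_seeds[s] + 1L)
    res <- scan_chromosome(g, y, grm = grm)
    p <- 10^(-res$neg_log10_p[!res$skipped])
    per_sim[s] <- mean(p < alpha)
    hits <- hits + sum(p < alpha)
    total <- total + length(p)
  }
  list(fraction = hits / total, n_tests = total, per_sim = per_sim)
}

#' Two linked QTL separation experiment
#'
#' Spikes two QTNs a fixed distance apart (each sized to explain
#' `effect_var_frac` of the phenotypic variance, mutually near-independent
#' in LD) and checks that the iterative conditional scan separates them:
#' success requires at least two reported leads and each true QTN falling
#' inside the LD (r-squared > `r2_min`) region of some lead.
#'
#' @param cfg a [sim_config()].
#' @param spacing_bp distance between the two QTNs (default 2 Mb).
#' @param n_replicates replicates (default 50).
#' @param r2_min LD-region cutoff (default 0.2).
#' @param max_qtn_r2 maximum allowed LD between the two QTNs (default 0.1).
#' @param seed overrides `cfg$seed`.
#' @return list with `n_success`, `n_replicates`, and a per-replicate `log`.
#' @export
linked_qtl_experiment <- function(cfg = sim_config(), spacing_bp = 2e6,
                                  n_replicates = 50, r2_min = 0.2,
                                  max_qtn_r2 = 0.1, seed = cfg$seed) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1000L, n_replicates)
  g <- filter_variants(simulate_genotypes(cfg, seed = seed))$geno
  bg_cfg <- cfg
  bg_cfg$chrom <- paste0(cfg$chrom, "_bg")
  g_bg <- filter_variants(simulate_genotypes(bg_cfg, seed = seed + 17L))$geno
  grm <- build_grm(g_bg)
  cache <- scan_cache(grm, g)
  maf <- apply(g$dosage, 2, compute_maf)
  eligible <- which(maf >= 0.05)
  m <- ncol(g$dosage)
  threshold <- bonferroni_threshold(m)
  scfg <- scan_config(threshold_neg_log10p = threshold)
  fv_cfg <- cfg
  fv_cfg$effect_mode <- "fixed_var"

  logs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(rep_seeds[i])
    pair <- NULL
    for (try in seq_len(100)) {
      a <- sample(eligible, 1)
      target <- g$map$pos[a] + spacing_bp
      cand <- eligible[abs(g$map$pos[eligible] - target) <= 0.25e6]
      cand <- setdiff(cand, a)
      if (!length(cand)) next
      bpos <- cand[which.min(abs(g$map$pos[cand] - target))]
      r2ab <- stats::cor(g$dosage[, a], g$dosage[, bpos])^2
      if (!is.na(r2ab) && r2ab <= max_qtn_r2) {
        pair <- c(a, bpos)
        break
      }
    }
    if (is.null(pair)) stop("replicate ", i,
                            ": no eligible QTN pair at the requested spacing")
    y0 <- base_phenotype(g_bg, cfg$h2_polygenic, seed = rep_seeds[i] + 1L)
    s1 <- spike_phenotype(y0, g$dosage[, pair[1]], fv_cfg,
                          seed = rep_seeds[i] + 2L)
    s2 <- spike_phenotype(s1$y, g$dosage[, pair[2]], fv_cfg,
                          seed = rep_seeds[i] + 3L)
    leads <- iterative_scan(g, s2$y, grm = NULL, cfg = scfg, cache = cache)

    covered <- c(FALSE, FALSE)
    if (nrow(leads) >= 1) {
      for (k in seq_len(nrow(leads))) {
        pr <- pairwise_r2(g, leads$id[k])
        reg <- ld_region(pr, leads$pos[k], r2_min = r2_min)
        inside <- g$map$pos[pair] >= reg$start & g$map$pos[pair] <= reg$end
        covered <- covered | inside
      }
    }
    success <- nrow(leads) >= 2 && all(covered)
    logs[[i]] <- data.frame(
      replicate = i, qtn_a = g$map$id[pair[1]], qtn_b = g$map$id[pair[2]],
      qtn_r2 = stats::cor(g$dosage[, pair[1]], g$dosage[, pair[2]])^2,
      n_leads = nrow(leads), covered_a = covered[1], covered_b = covered[2],
      success = success, stringsAsFactors = FALSE)
  }
  log_df <- do.call(rbind, logs)
  list(n_success = sum(log_df$success), n_replicates = n_replicates,
       threshold = threshold, log = log_df)
}
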
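test_that("the Bonferroni threshold reproduces its landmark values", {
  expect_equal(round(bonferroni_threshold(15512960), 1), 8.5)
  expect_equal(bonferroni_threshold(15512960), 8.4917, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(1), 1.30103, tolerance = 1e-5)
  expect_equal(bonferroni_threshold(1e6), 7.30103, tolerance = 1e-5)
})

test_that("solo significant SNPs are removed; supported ones survive", {
  cfg <- scan_config(threshold_neg_log10p = 5)
  # a single significant variant on the chromosome is removed
  res <- make_results(pos = c(1e6, 3e6, 8e6), logp = c(2, 6, 1))
  out <- remove_solo_snps(res, cfg)
  expect_true(out$solo[2])
  # two significant variants 0.5 Mb apart are both kept
  res2 <- make_results(pos = c(1e6, 1.5e6), logp = c(7, 6.2))
  out2 <- remove_solo_snps(res2, cfg)
  expect_false(any(out2$solo))
  # non-significant variants pass through untouched
  expect_false(any(out$solo[c(1, 3)]))
})

test_that("solo-SNP survivors match the pairwise-distance oracle", {
  set.seed(91)
  for (rep in 1:5) {
    pos <- sort(sample.int(2e7, 50))
    logp <- runif(50, 5.5, 12)           # all significant
    res <- make_results(pos = pos, logp = logp)
    out <- remove_solo_snps(res, scan_config(threshold_neg_log10p = 5))
    expect_equal(!out$solo, oracle_solo_survivors(pos, 1e6))
  }
})

test_that("QTL boundaries follow the drop-and-distance rule with its fallback and clipping", {
  cfg <- scan_config(threshold_neg_log10p = 5)
  # drop > 3 units at 0.40 Mb downstream marks the boundary
  res <- make_results(pos = c(4.8e6, 5.0e6, 5.2e6, 5.4e6, 5.8e6),
                      logp = c(11, 12, 10.5, 8.5, 8.4))
  res$id[2] <- "lead"
  reg <- define_qtl_region(res, "lead", cfg, chrom_length = 1e7)
  expect_equal(reg$end, 5400000L)
  expect_equal(reg$start, 4750000L)      # no upstream qualifier: fallback
  # flat profile: both sides fall back to +/- 0.25 Mb
  res2 <- make_results(pos = c(4.6e6, 5.0e6, 5.4e6), logp = c(10, 12, 11))
  res2$id[2] <- "lead"
  reg2 <- define_qtl_region(res2, "lead", cfg, chrom_length = 1e7)
  expect_equal(c(reg2$start, reg2$end), c(4750000L, 5250000L))
  # near the chromosome start the region clips to 1
  res3 <- make_results(pos = c(1e5, 2e5), logp = c(12, 11))
  res3$id[1] <- "lead"
  reg3 <- define_qtl_region(res3, "lead", cfg, chrom_length = 1e7)
  expect_equal(reg3$start, 1L)
  # a qualifying drop nearer than 0.25 Mb does not terminate the walk
  res4 <- make_results(pos = c(5.0e6, 5.1e6, 5.6e6), logp = c(12, 8, 8.2))
  res4$id[1] <- "lead"
  reg4 <- define_qtl_region(res4, "lead", cfg, chrom_length = 1e7)
  expect_equal(reg4$end, 5600000L)
})

test_that("QTL boundaries match the brute-force oracle on random profiles", {
  set.seed(93)
  cfg <- scan_config(threshold_neg_log10p = 5)
  for (rep in 1:10) {
    pos <- sort(sample.int(1e7, 80))
    logp <- runif(80, 4, 12)
    res <- make_results(pos = pos, logp = logp)
    li <- sample(80, 1)
    expected <- oracle_region(pos, logp, pos[li], logp[li], 1e6, 3, 250000)
    expected <- pmin(pmax(expected, 1), 2e7)   # chromosome bounds
    reg <- define_qtl_region(res, res$id[li], cfg, chrom_length = 2e7)
    expect_equal(c(reg$start, reg$end), as.integer(expected))
  }
})

test_that("a scan with nothing significant returns no leads after one round", {
  g <- make_geno(120, 60, seed = 95)
  set.seed(96)
  y <- rnorm(120); names(y) <- geno_samples(g)
  leads <- iterative_scan(g, y, grm = NULL,
                          cfg = scan_config(threshold_neg_log10p = 6))
  expect_equal(nrow(leads), 0L)
  expect_length(attr(leads, "rounds"), 1L)
})

test_that("the iterative scan separates two strong linked QTL across rounds", {
  cfg <- sim_config(n_samples = 800, n_variants = 1500, chrom_length_bp = 6e6,
                    seed = 97)
  g <- filter_variants(simulate_genotypes(cfg))$geno
  bg_cfg <- cfg; bg_cfg$chrom <- "bg"
  g_bg <- filter_variants(simulate_genotypes(bg_cfg, seed = 98))$geno
  grm <- build_grm(g_bg)
  y <- base_phenotype(g_bg, 0.8, seed = 99)
  maf <- apply(g$dosage, 2, compute_maf)
  elig <- which(maf >= 0.2)
  a <- elig[1]
  target <- g$map$pos[a] + 2.5e6
  b <- elig[which.min(abs(g$map$pos[elig] - target))]
  for (j in c(a, b)) {
    x <- g$dosage[, j]
    y <- y + 0.2 * sd(y) / sd(x) * x   # each ~4% of variance
  }
  scfg <- scan_config(n_tests = ncol(g$dosage))
  leads <- iterative_scan(g, y, grm = grm, cfg = scfg)
  expect_gte(nrow(leads), 2L)
  thr <- attr(leads, "threshold")
  # every lead is significant in its discovery round ...
  expect_true(all(leads$neg_log10_p > thr))
  # ... and later-round leads were already significant in round 1
  rounds <- attr(leads, "rounds")
  r1 <- rounds[[1]]
  later <- leads[leads$round >= 2, ]
  if (nrow(later)) {
    r1p <- r1$neg_log10_p[match(later$id, r1$id)]
    expect_true(all(r1p > thr))
  }
  # regions bracket their leads
  expect_true(all(leads$region_start <= leads$pos &
                    leads$pos <= leads$region_end))
  # the loop reached its fixed point: conditioning on all leads leaves no
  # eligible candidate above the threshold
  final <- scan_chromosome(g, y, grm = grm,
                           covariates = covariate_set(g, leads$id))
  r1p_all <- r1$neg_log10_p[match(final$id, r1$id)]
  final <- remove_solo_snps(final, scfg, threshold = thr)
  eligible <- !final$skipped & !is.na(final$neg_log10_p) & !final$solo &
    final$neg_log10_p > thr & !(final$id %in% leads$id) &
    !is.na(r1p_all) & r1p_all > thr
  expect_false(any(eligible))
})
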
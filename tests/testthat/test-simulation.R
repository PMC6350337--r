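small_cfg <- function(...) {
  sim_config(n_samples = 300, n_variants = 600, chrom_length_bp = 2e6,
             seed = 7, ...)
}

test_that("genotype simulation is deterministic and shape-correct", {
  cfg <- small_cfg()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  expect_equal(dim(g1), c(300L, 600L))
  # a single sample is a valid 1 x m matrix
  g3 <- simulate_genotypes(sim_config(n_samples = 1, n_variants = 50,
                                      chrom_length_bp = 1e6, seed = 3))
  expect_equal(dim(g3), c(1L, 50L))
  expect_true(all(g3$dosage %in% 0:2))
})

test_that("LD decays with distance: adjacent variants correlate more than distant ones", {
  g <- simulate_genotypes(small_cfg())
  d <- g$dosage
  sds <- apply(d, 2, sd)
  ok <- which(sds[-600] > 0 & sds[-1] > 0)
  adj <- sapply(ok[ok <= 300], function(j) cor(d[, j], d[, j + 1])^2)
  far <- sapply(ok[ok <= 300], function(j) cor(d[, j], d[, j + 300])^2)
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("simulated panels pass the association-study variant filters almost entirely", {
  g <- simulate_genotypes(small_cfg())
  rep <- filter_variants(g)$report
  expect_gte(rep$n_retained / rep$n_input, 0.99)
})

test_that("the base phenotype respects its variance budget", {
  cfg <- sim_config(n_samples = 2000, n_variants = 1000,
                    chrom_length_bp = 4e6, seed = 17)
  g <- simulate_genotypes(cfg)
  # pure-noise case
  y0 <- base_phenotype(g, 0, seed = 21)
  expect_lt(abs(var(y0) - 1), 0.1)
  # realized polygenic fraction close to its target
  y <- base_phenotype(g, 0.5, seed = 22)
  set.seed(22)
  e <- rnorm(2000, 0, sqrt(0.5))     # reconstruct the residual stream
  poly <- y - e
  expect_lt(abs(var(poly) / var(y) - 0.5), 0.05)
  # determinism
  expect_identical(y, base_phenotype(g, 0.5, seed = 22))
})

test_that("QTN selection respects MAF, HWE and the LD bin assignments", {
  cfg <- sim_config(seed = 7, n_samples = 800, n_variants = 2000,
                    chrom_length_bp = 4e6)
  g <- filter_variants(simulate_genotypes(cfg))$geno
  sel <- select_qtn_and_partners(g, cfg, seed = 5)
  expect_gte(sel$qtn$maf, 0.05)
  expect_lte(sel$qtn$maf, 0.10)
  expect_equal(nrow(sel$partners), 10L)
  x <- geno_dosage(g, sel$qtn$id)
  # realized r2 of each partner lies in its assigned bin, and agrees with a
  # direct correlation computation
  for (k in seq_len(10)) {
    r2 <- cor(x, geno_dosage(g, sel$partners$id[k]))^2
    expect_equal(r2, sel$partners$r2[k], tolerance = 1e-12)
    expect_gte(r2, sel$partners$bin_lo[k])
    expect_lte(r2, max(sel$partners$bin_hi[k], sel$partners$bin_lo[k] + 1e-12))
  }
  # the top bin partner really is a high-LD proxy
  expect_gte(sel$partners$r2[1], 0.9)
  # bin assignment matches a brute-force classification of the chromosome
  r2_all <- as.vector(cor(x, g$dosage))^2
  for (k in seq_len(8)) {
    in_bin <- which(r2_all >= sel$partners$bin_lo[k] &
                      r2_all < sel$partners$bin_hi[k])
    expect_true(match(sel$partners$id[k], g$map$id) %in% in_bin)
  }
})

test_that("effect spiking follows the prescribed distribution", {
  set.seed(33)
  y <- rnorm(500, 0, 1.7)
  names(y) <- sprintf("s%03d", 1:500)
  x <- rbinom(500, 2, 0.08)
  cfg <- small_cfg()
  # forced-zero effect leaves the phenotype untouched
  sp0 <- spike_phenotype(y, x, cfg, seed = 1, b = 0)
  expect_identical(sp0$y, y)
  # the sampled effects have the requested mean and variance
  bs <- vapply(1:1000, function(s) spike_phenotype(y, x, cfg, seed = s)$b,
               numeric(1))
  expect_lt(abs(mean(bs) / sd(y) - 0.20), 0.01)
  expect_lt(abs(var(bs) / var(y) - 0.01), 0.002)
  # added variance follows the exact decomposition var(y + xb) - var(y)
  sp <- spike_phenotype(y, x, cfg, seed = 9)
  expect_equal(var(sp$y) - var(y),
               sp$b^2 * var(x) + 2 * sp$b * cov(y, x), tolerance = 1e-12)
  # fixed-variance mode sizes the QTN contribution exactly
  cfg_fv <- small_cfg(effect_mode = "fixed_var")
  spf <- spike_phenotype(y, x, cfg_fv, seed = 2)
  expect_equal(spf$b^2 * var(x) / var(y), 0.01, tolerance = 1e-12)
})

test_that("the spike-in experiment is reproducible and null effects yield no leads", {
  cfg <- sim_config(n_samples = 400, n_variants = 800, chrom_length_bp = 2e6,
                    seed = 19, n_replicates = 2)
  r1 <- type1_error_experiment(cfg)
  r2 <- type1_error_experiment(cfg)
  expect_identical(r1$log, r2$log)
  expect_equal(r1$n_replicates, 2L)
  # with the effect forced to zero nothing reaches the Bonferroni threshold
  g <- filter_variants(simulate_genotypes(cfg))$geno
  bg_cfg <- cfg; bg_cfg$chrom <- "bg"
  g_bg <- filter_variants(simulate_genotypes(bg_cfg, seed = 36))$geno
  y <- base_phenotype(g_bg, cfg$h2_polygenic, seed = 20)
  leads <- iterative_scan(g, y, grm = build_grm(g_bg),
                          cfg = scan_config(n_tests = ncol(g$dosage)))
  expect_equal(nrow(leads), 0L)
})

test_that("power to top the scan does not fall when the panel doubles", {
  base <- list(n_variants = 1000, chrom_length_bp = 3e6, seed = 23,
               n_replicates = 6)
  small <- do.call(sim_config, c(base, list(n_samples = 500)))
  large <- do.call(sim_config, c(base, list(n_samples = 1000)))
  rs <- type1_error_experiment(small)
  rl <- type1_error_experiment(large)
  # matched seeds; allow one replicate of Monte-Carlo slack
  expect_gte(rl$n_qtn_lead, rs$n_qtn_lead - 1L)
})
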
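test_that("r2 is 1 for identical and allele-flipped partners and matches the correlation oracle", {
  g <- make_geno(100, 40, seed = 101)
  g$dosage[, 2] <- g$dosage[, 1]
  g$dosage[, 3] <- 2 - g$dosage[, 1]
  pr <- pairwise_r2(g, g$map$id[1])
  expect_equal(pr$r2[match(g$map$id[2], pr$id)], 1)
  expect_equal(pr$r2[match(g$map$id[3], pr$id)], 1)
  for (j in sample(4:40, 10)) {
    expect_equal(pr$r2[match(g$map$id[j], pr$id)],
                 oracle_r2(g$dosage[, 1], g$dosage[, j]), tolerance = 1e-10)
  }
  expect_true(all(pr$r2 >= 0 & pr$r2 <= 1 + 1e-12))
})

test_that("monomorphic partners are omitted with a warning", {
  g <- make_geno(50, 5, seed = 103)
  g$dosage[, 4] <- 2
  expect_warning(pr <- pairwise_r2(g, g$map$id[1]), "monomorphic")
  expect_false(g$map$id[4] %in% pr$id)
})

test_that("the LD region spans the outermost qualifying SNPs, across gaps", {
  pairs <- data.frame(id = c("a", "b", "c"), chrom = "1",
                      pos = c(1e6, 2e6, 3e6), r2 = c(0.5, 0.1, 0.3))
  reg <- ld_region(pairs, lead_pos = 1.5e6)
  expect_equal(c(reg$start, reg$end), c(1000000L, 3000000L))
  # nothing above the cutoff: degenerate region at the lead
  pairs$r2 <- c(0.1, 0.2, 0.15)
  reg2 <- ld_region(pairs, lead_pos = 1.5e6)
  expect_equal(c(reg2$start, reg2$end), c(1500000L, 1500000L))
})

test_that("LD regions match the min/max oracle on random inputs", {
  set.seed(105)
  for (rep in 1:10) {
    pos <- sort(sample.int(1e7, 60))
    r2 <- runif(60)
    pairs <- data.frame(id = sprintf("p%02d", 1:60), chrom = "1",
                        pos = pos, r2 = r2)
    lead_pos <- sample(pos, 1)
    reg <- ld_region(pairs, lead_pos)
    qual <- pos[r2 > 0.2]
    expect_equal(reg$start, as.integer(min(c(qual, lead_pos))))
    expect_equal(reg$end, as.integer(max(c(qual, lead_pos))))
  }
})

test_that("the closest gene is found, inside-gene leads report distance zero", {
  genes <- small_gene_table()
  hit <- closest_gene(list(chrom = "14", pos = 1802265), genes)
  expect_equal(hit$symbol, "DGAT1")
  expect_equal(hit$relation, "within")
  expect_equal(hit$distance, 0)
  # equidistant leads resolve to the lower-start gene
  genes2 <- data.frame(symbol = c("G1", "G2"), chrom = "1",
                       start = c(100L, 300L), end = c(150L, 350L))
  tie <- closest_gene(list(chrom = "1", pos = 225), genes2)
  expect_equal(tie$symbol, "G1")
  expect_warning(out <- closest_gene(list(chrom = "9", pos = 10), genes),
                 "no gene")
  expect_equal(nrow(out), 0L)
})

test_that("closest-gene search matches the distance-minimization oracle", {
  set.seed(107)
  starts <- sort(sample.int(1e7, 50))
  genes <- data.frame(symbol = sprintf("g%02d", 1:50), chrom = "1",
                      start = starts,
                      end = starts + sample.int(5e4, 50))
  for (pos in sample.int(1e7, 20)) {
    got <- closest_gene(list(chrom = "1", pos = pos), genes)
    want <- oracle_closest_gene("1", pos, genes)
    expect_equal(got$symbol, want$symbol)
    expect_equal(got$distance, want$distance)
  }
})

test_that("gene-region overlap is closed-interval and matches the oracle", {
  genes <- data.frame(symbol = c("touch_left", "inside", "outside"),
                      chrom = "1",
                      start = c(5e5, 1.2e6, 3e6), end = c(1e6, 1.4e6, 4e6))
  regions <- data.frame(chrom = "1", start = 1e6, end = 2e6)
  out <- genes_in_ld_regions(regions, genes)
  expect_setequal(out$symbol, c("touch_left", "inside"))
  set.seed(109)
  for (rep in 1:5) {
    genes_r <- data.frame(symbol = sprintf("r%02d", 1:30), chrom = "1",
                          start = s <- sample.int(1e7, 30),
                          end = s + sample.int(2e5, 30))
    regions_r <- data.frame(chrom = "1", start = rs <- sample.int(1e7, 3),
                            end = rs + sample.int(1e6, 3))
    expect_setequal(genes_in_ld_regions(regions_r, genes_r)$symbol,
                    oracle_overlap(regions_r, genes_r))
    # monotonicity: enlarging a region never loses a gene
    bigger <- regions_r
    bigger$end <- bigger$end + 5e5
    expect_true(all(genes_in_ld_regions(regions_r, genes_r)$symbol %in%
                      genes_in_ld_regions(bigger, genes_r)$symbol))
  }
})

test_that("phenotype-term matching hits verbatim terms and Fisher p matches enumeration", {
  tt <- list(ELF5 = c("abnormal mammary gland development"),
             DGAT1 = c("abnormal milk composition", "obesity"),
             OTHER = c("kinked tail"))
  mt <- match_phenotype_terms(c("DGAT1", "OTHER"), tt)
  expect_named(mt$hits, "DGAT1")
  expect_equal(mt$hits$DGAT1, "abnormal milk composition")
  # case folding
  mt2 <- match_phenotype_terms("DGAT1", tt, terms = "ABNORMAL MILK COMPOSITION")
  expect_named(mt2$hits, "DGAT1")
  # the 2x2 enrichment p equals hypergeometric enumeration
  expect_equal(fisher.test(matrix(c(3, 7, 10, 80), 2, byrow = TRUE))$p.value,
               oracle_fisher(3, 7, 10, 80), tolerance = 1e-10)
  # no annotated candidate: empty hits, p well-defined
  mt3 <- match_phenotype_terms("OTHER", tt, terms = "abnormal milk composition")
  expect_length(mt3$hits, 0)
  expect_true(is.na(mt3$fisher_p) || mt3$fisher_p >= 0.05)
})

test_that("variant screening ranks impact, then SIFT class, then SIFT score", {
  rec <- data.frame(
    id = c("syn", "mis_tol", "mis_del", "stop", "inter", "mis_del2"),
    consequence = c("synonymous_variant", "missense_variant",
                    "missense_variant", "stop_gained", "intergenic_variant",
                    "missense_variant"),
    sift_class = c(NA, "tolerated", "deleterious", NA, NA, "deleterious"),
    sift_score = c(NA, 0.4, 0.02, NA, NA, 0.01),
    stringsAsFactors = FALSE)
  out <- screen_vep(rec, rec$id)
  expect_equal(out$id[1], "stop")                      # HIGH impact first
  expect_equal(out$id[2:3], c("mis_del2", "mis_del"))  # deleterious by score
  expect_equal(out$id[4], "mis_tol")
  expect_lt(which(out$id == "syn"), which(out$id == "inter"))
  expect_equal(out$id[6], "inter")                     # modifier last
  # restriction to in-LD ids
  out2 <- screen_vep(rec, c("syn", "stop"))
  expect_setequal(out2$id, c("syn", "stop"))
  # unknown consequence terms are binned as MODIFIER with a warning
  rec2 <- data.frame(id = "x", consequence = "mystery_variant",
                     sift_class = NA, sift_score = NA)
  expect_warning(out3 <- screen_vep(rec2, "x"), "mystery_variant")
  expect_equal(as.character(out3$impact), "MODIFIER")
  # stable total order: re-screening a shuffled table gives the same order
  set.seed(111)
  out4 <- screen_vep(rec[sample(nrow(rec)), ], rec$id)
  expect_equal(out4$id, out$id)
})

test_that("gene annotation files parse through the GFF3 reader", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "14\ttest\tgene\t1795351\t1804562\t.\t+\t.\tID=gene:1;Name=DGAT1",
    "14\ttest\texon\t1795351\t1796000\t.\t+\t.\tID=exon:1;Parent=gene:1",
    "14\ttest\tgene\t2000000\t2100000\t.\t-\t.\tID=gene:2;Name=OTHER"
  ), path)
  genes <- read_genes(path)
  expect_equal(nrow(genes), 2L)
  expect_setequal(genes$symbol, c("DGAT1", "OTHER"))
  expect_equal(genes$start[genes$symbol == "DGAT1"], 1795351)
})

test_that("VEP tables parse combined SIFT annotations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tconsequence\tsift",
               "rs1\tmissense_variant\tdeleterious(0.02)",
               "rs2\tsynonymous_variant\t-"), path)
  v <- read_vep_table(path)
  expect_equal(v$sift_class[1], "deleterious")
  expect_equal(v$sift_score[1], 0.02)
  expect_true(is.na(v$sift_class[2]))
})
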
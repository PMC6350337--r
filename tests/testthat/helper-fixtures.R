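# Small programmatic fixtures shared across test files.

# iid binomial genotypes (no LD) with random frequencies
make_geno <- function(n, m, seed = 1, chrom = "1", maf = NULL,
                      pos = NULL) {
  set.seed(seed)
  p <- if (is.null(maf)) stats::runif(m, 0.1, 0.5) else rep(maf, m)
  dos <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  if (n == 1) dos <- matrix(dos, nrow = 1)
  if (is.null(pos)) pos <- sort(sample.int(1e7, m))
  map <- data.frame(chrom = chrom, pos = pos,
                    id = sprintf("v%04d", seq_len(m)), ref = "A", alt = "B",
                    stringsAsFactors = FALSE)
  geno_matrix(dos, map)
}

# association results table for rule-based tests (no model fitting)
make_results <- function(pos, logp, chrom = "1", skipped = FALSE) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = sprintf("m%04d", seq_along(pos)), beta = 0.1, se = 0.05,
             neg_log10_p = logp, n_used = 100,
             skipped = rep_len(skipped, length(pos)),
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcow1",
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/1"
  ), path)
  path
}

small_gene_table <- function() {
  data.frame(
    symbol = c("DGAT1", "LEFT", "RIGHT"),
    chrom = c("14", "14", "14"),
    start = c(1795351L, 1500000L, 1900000L),
    end = c(1804562L, 1600000L, 2000000L),
    stringsAsFactors = FALSE)
}
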
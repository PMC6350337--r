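# Independent brute-force oracles used to cross-check the package's
# algebraic and combinatorial operations. These are deliberately naive
# (double loops, direct enumeration) and share no code with the package.

oracle_maf <- function(dosage) {
  x <- round(dosage[!is.na(dosage)])
  alt <- sum(x)
  total <- 2 * length(x)
  p <- alt / total
  min(p, 1 - p)
}

oracle_grm <- function(dosage) {
  p <- colMeans(dosage) / 2
  keep <- p > 0 & p < 1
  dosage <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(dosage)
  m <- ncol(dosage)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) {
      s <- s + (dosage[i, k] - 2 * p[k]) * (dosage[j, k] - 2 * p[k]) /
        (2 * p[k] * (1 - p[k]))
    }
    K[i, j] <- s / m
  }
  K
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  (sxy / sqrt(sxx * syy))^2
}

# which significant positions survive the solo rule (pairwise distances)
oracle_solo_survivors <- function(sig_pos, window) {
  keep <- logical(length(sig_pos))
  for (i in seq_along(sig_pos)) {
    keep[i] <- any(abs(sig_pos[-i] - sig_pos[i]) <= window)
  }
  keep
}

# brute-force QTL boundary: all variants within the scan window qualifying
# on (drop, distance); nearest qualifier per side, else the fallback
oracle_region <- function(pos, logp, lead_pos, lead_logp, scan_bp, drop_units,
                          min_bp) {
  one_side <- function(sign) {
    d <- (pos - lead_pos) * sign
    ok <- d > 0 & d <= scan_bp & !is.na(logp) &
      (lead_logp - logp) > drop_units & d > min_bp
    if (any(ok)) pos[ok][which.min(d[ok])] else lead_pos + sign * min_bp
  }
  c(one_side(-1), one_side(1))
}

oracle_overlap <- function(regions, genes) {
  hit <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(regions))) {
      if (genes$chrom[i] == regions$chrom[j] &&
          max(genes$start[i], regions$start[j]) <=
            min(genes$end[i], regions$end[j])) {
        hit <- c(hit, genes$symbol[i])
        break
      }
    }
  }
  unique(hit)
}

oracle_closest_gene <- function(chrom, pos, genes) {
  best <- NULL
  best_d <- Inf
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    d <- if (pos >= genes$start[i] && pos <= genes$end[i]) 0 else
      min(abs(pos - genes$start[i]), abs(pos - genes$end[i]))
    if (d < best_d || (d == best_d && genes$start[i] < genes$start[best])) {
      best <- i
      best_d <- d
    }
  }
  list(symbol = genes$symbol[best], distance = best_d)
}

# two-sided Fisher's exact p for table matrix(c(a, b, c, d), 2, byrow):
# enumeration over the hypergeometric support
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

oracle_ols_neglog10p <- function(y, x, covariates = NULL) {
  dat <- if (is.null(covariates)) data.frame(y = y, x = x)
  else cbind(data.frame(y = y, x = x), as.data.frame(covariates))
  fit <- stats::lm(y ~ ., data = dat)
  -log10(summary(fit)$coefficients["x", 4])
}
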
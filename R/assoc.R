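#' Precompute the eigen-rotation for repeated chromosome scans
#'
#' Eigendecomposes the GRM once and (optionally) rotates the full dosage
#' matrix into the eigenbasis, so that many scans over the same panel (e.g.
#' the rounds of an iterative conditional analysis, or the replicates of a
#' simulation experiment) reuse the expensive linear algebra.
#'
#' @param grm a [build_grm()] object, or `NULL` for an identity relationship
#'   matrix (reduces every scan to ordinary least squares).
#' @param g optional [geno_matrix()] whose dosages are rotated and cached.
#' @return an object of class `scan_cache`.
#' @export
scan_cache <- function(grm, g = NULL) {
  if (is.null(grm)) {
    samples <- if (!is.null(g)) geno_samples(g) else
      stop("need a GRM or a genotype matrix to define the sample set")
    U <- NULL
    d <- rep(1, length(samples))
  } else {
    stopifnot(inherits(grm, "grm"))
    samples <- grm$samples
    eig <- eigen(grm$K, symmetric = TRUE)
    U <- eig$vectors
    d <- pmax(eig$values, 0)
  }
  Gs <- NULL
  map <- NULL
  raw_sd <- raw_scaled <- NULL
  if (!is.null(g)) {
    stopifnot(inherits(g, "geno_matrix"))
    if (!all(samples %in% geno_samples(g)))
      stop("genotype matrix lacks samples present in the GRM")
    dos <- g$dosage[samples, , drop = FALSE]
    centered <- sweep(dos, 2, colMeans(dos), `-`)
    raw_sd <- sqrt(colSums(centered^2))
    raw_scaled <- sweep(centered, 2, pmax(raw_sd, 1e-12), `/`)
    Gs <- if (is.null(U)) dos else crossprod(U, dos)
    map <- g$map
  }
  structure(list(samples = samples, U = U, d = d, Gs = Gs, map = map,
                 raw_scaled = raw_scaled, raw_sd = raw_sd),
            class = "scan_cache")
}

rotate_cols <- function(cache, M) {
  if (is.null(cache$U)) M else crossprod(cache$U, M)
}

# Assemble the rotated design matrix (intercept + covariates), dropping
# rank-deficient columns with a warning.
build_design <- function(cache, covariates) {
  n <- length(cache$samples)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  if (!is.null(covariates) && ncol(covariates) > 0) {
    cov <- covariates[cache$samples, , drop = FALSE]
    X <- cbind(X, cov)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    warning("dropping rank-deficient covariate column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  list(X = X, Xs = rotate_cols(cache, X))
}

#' Restricted-likelihood fit of the covariates-only mixed model
#'
#' Profiles the restricted likelihood of `y = X beta + g + e`,
#' `cov(g) = v_g * K`, over the variance ratio `lambda = v_e / v_g` in the
#' eigenbasis of `K`, by one-dimensional search on `log10(lambda)` in
#' `[-6, 6]`. The returned object carries the rotation and fitted ratio used
#' by [scan_chromosome()] for fast fixed-lambda per-variant tests. When the
#' genetic variance is estimated at its boundary the fit degenerates to
#' ordinary least squares (`ols` flag).
#'
#' @param y named numeric phenotype vector covering the cache/GRM samples.
#' @param grm a [build_grm()] object (ignored when `cache` is given).
#' @param covariates optional numeric matrix of per-sample covariates (rows
#'   named by sample, e.g. from [covariate_set()]).
#' @param cache optional [scan_cache()] to reuse.
#' @return list of class `null_fit`: `lambda`, `h2` (`v_g / (v_g + v_e)`),
#'   `v_g`, `v_e`, `loglik`, `ols`, plus internals used by the scan.
#' @export
reml_null_fit <- function(y, grm = NULL, covariates = NULL, cache = NULL) {
  if (is.null(cache)) cache <- scan_cache(grm)
  if (!all(cache$samples %in% names(y)))
    stop("phenotype lacks values for some GRM samples")
  n <- length(cache$samples)
  if (n < 30) stop("need at least 30 samples for the mixed-model fit")
  yv <- as.numeric(y[cache$samples])
  ys <- as.vector(rotate_cols(cache, matrix(yv, ncol = 1)))
  des <- build_design(cache, covariates)
  Xs <- des$Xs
  c_rank <- ncol(Xs)
  d <- cache$d

  neg_restricted_ll <- function(log10_lambda) {
    lambda <- 10^log10_lambda
    w <- 1 / (d + lambda)
    sw <- sqrt(w)
    A <- Xs * sw
    qa <- qr(A)
    yt <- ys * sw
    res <- qr.resid(qa, yt)
    rss <- sum(res^2)
    ldet_xwx <- 2 * sum(log(abs(diag(qr.R(qa)))))
    0.5 * ((n - c_rank) * log(rss) + sum(log(d + lambda)) + ldet_xwx)
  }

  opt <- stats::optimize(neg_restricted_ll, interval = c(-6, 6), tol = 1e-6)
  # guard against a local dip: compare with the boundaries
  cand <- c(opt$minimum, -6, 6)
  vals <- c(opt$objective, neg_restricted_ll(-6), neg_restricted_ll(6))
  best <- cand[which.min(vals)]
  lambda <- 10^best
  w <- 1 / (d + lambda)
  sw <- sqrt(w)
  qa <- qr(Xs * sw)
  res <- qr.resid(qa, ys * sw)
  v_g <- sum(res^2) / (n - c_rank)
  v_e <- lambda * v_g
  ols <- best >= 6 - 1e-3
  structure(list(lambda = lambda, h2 = 1 / (1 + lambda), v_g = v_g, v_e = v_e,
                 loglik = -min(vals), ols = ols, cache = cache, ys = ys,
                 Xs = Xs, X = des$X, yv = yv, covariates = covariates),
            class = "null_fit")
}

#' Dosage covariate matrix for conditional analysis
#'
#' Extracts the dosage columns of the given variant ids as a sample-by-id
#' matrix suitable for the `covariates` argument of [reml_null_fit()],
#' [scan_chromosome()] and [iterative_scan()].
#'
#' @param g a [geno_matrix()].
#' @param ids character vector of variant ids (duplicates rejected).
#' @return numeric matrix with row names = sample ids, column names = `ids`.
#' @export
covariate_set <- function(g, ids) {
  if (anyDuplicated(ids)) stop("duplicate variant ids in covariate set")
  idx <- match(ids, g$map$id)
  if (anyNA(idx)) stop("covariate variant(s) missing from genotype map")
  m <- g$dosage[, idx, drop = FALSE]
  colnames(m) <- ids
  m
}

#' Mixed-model association scan of one chromosome
#'
#' Wald test of each variant's dosage term given the fixed covariates, at
#' the variance ratio fitted by [reml_null_fit()] (the standard single-fit
#' approximation of mixed-model association software). The per-variant
#' residual variance is re-estimated and the test referred to a
#' t-distribution, so with an identity relationship matrix the scan is
#' exactly ordinary least-squares regression. Variants nearly collinear
#' with a covariate (|r| above `collinearity_r`) or monomorphic are skipped
#' with a reason rather than tested; p-values are carried on the -log10
#' scale so extreme signals do not underflow.
#'
#' @param g a [geno_matrix()] (one chromosome).
#' @param y named numeric phenotype vector.
#' @param grm a [build_grm()] object, or `NULL` for plain regression.
#' @param covariates optional covariate matrix (see [covariate_set()]).
#' @param cache optional [scan_cache()] built with this `g` (reused across
#'   rounds/replicates).
#' @param null_fit optional [reml_null_fit()] result for these covariates.
#' @param collinearity_r absolute dosage correlation with any covariate
#'   above which a variant is skipped (default 0.995).
#' @return data frame of class `assoc_result`, one row per variant:
#'   `chrom`, `pos`, `id`, `beta`, `se`, `neg_log10_p`, `n_used`,
#'   `skipped`, `skip_reason`.
#' @export
scan_chromosome <- function(g, y, grm = NULL, covariates = NULL, cache = NULL,
                            null_fit = NULL, collinearity_r = 0.995) {
  if (is.null(cache)) {
    cache <- if (!is.null(null_fit)) null_fit$cache else scan_cache(grm, g)
    if (is.null(cache$Gs)) cache <- scan_cache(grm, g)
  }
  if (is.null(cache$Gs)) stop("scan cache was built without genotype dosages")
  if (is.null(null_fit))
    null_fit <- reml_null_fit(y, covariates = covariates, cache = cache)
  n <- length(cache$samples)
  lambda <- null_fit$lambda
  w <- 1 / (cache$d + lambda)
  sw <- sqrt(w)
  Xs <- null_fit$Xs
  c_rank <- ncol(Xs)
  qa <- qr(Xs * sw)
  y_r <- qr.resid(qa, null_fit$ys * sw)
  rss0 <- sum(y_r^2)
  Gw <- cache$Gs * sw
  G_r <- qr.resid(qa, Gw)
  xx <- colSums(G_r^2)
  xy <- as.vector(crossprod(G_r, y_r))
  df <- n - c_rank - 1L

  beta <- xy / xx
  rss <- pmax(rss0 - xy^2 / xx, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / xx)
  tstat <- beta / se
  neg_log10_p <- -(stats::pt(-abs(tstat), df, log.p = TRUE) + log(2)) / log(10)

  skip_reason <- rep(NA_character_, ncol(Gw))
  mono <- cache$raw_sd < 1e-9
  skip_reason[mono] <- "monomorphic"
  cov_cols <- setdiff(colnames(null_fit$X), "(intercept)")
  if (length(cov_cols)) {
    covm <- null_fit$X[, cov_cols, drop = FALSE]
    cs <- sweep(covm, 2, colMeans(covm), `-`)
    csd <- sqrt(colSums(cs^2))
    ok <- csd > 1e-12
    if (any(ok)) {
      cs <- sweep(cs[, ok, drop = FALSE], 2, csd[ok], `/`)
      rmax <- apply(abs(crossprod(cache$raw_scaled, cs)), 1, max)
      skip_reason[is.na(skip_reason) & rmax > collinearity_r] <- "collinear"
    }
  }
  skip_reason[is.na(skip_reason) & xx < 1e-10 * max(xx)] <- "collinear"
  skipped <- !is.na(skip_reason)
  beta[skipped] <- NA_real_
  se[skipped] <- NA_real_
  neg_log10_p[skipped] <- NA_real_

  out <- data.frame(chrom = cache$map$chrom, pos = cache$map$pos,
                    id = cache$map$id, beta = beta, se = se,
                    neg_log10_p = neg_log10_p, n_used = n,
                    skipped = skipped, skip_reason = skip_reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", class(out))
  out
}
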
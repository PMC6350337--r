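#' Two-component REML variance partitioning
#'
#' Fits `y = mu + g1 + g2 + e` with `cov(g_k) = v_gk * GRM_k` and
#' `cov(e) = v_e * I` by restricted maximum likelihood, and reports each
#' component's share of the phenotypic variance `vp = v_g1 + v_g2 + v_e`.
#' The optimizer runs expectation-maximization steps first (guaranteed
#' likelihood ascent) and then switches to average-information updates with
#' step halving; estimates are constrained to be non-negative, a component
#' pinned at zero being dropped from subsequent updates.
#'
#' @param y named numeric phenotype vector.
#' @param grm1,grm2 [build_grm()] objects over (at least) the samples of `y`.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param max_iter maximum iterations (default 200). Non-convergence is
#'   flagged in the result, not raised.
#' @param n_em number of initial EM iterations before AI updates (default 3;
#'   set `n_em = max_iter` for pure EM).
#' @return list of class `var_components`: `v_g1`, `v_g2`, `v_e`, `vp`,
#'   `ratio_g1`, `ratio_g2` (components over `vp`), `log_likelihood`,
#'   `loglik_trace`, `converged`, `n_iter`, `n_samples`.
#' @export
partition_variance <- function(y, grm1, grm2, tol = 1e-6, max_iter = 200,
                               n_em = 3) {
  stopifnot(inherits(grm1, "grm"), inherits(grm2, "grm"))
  common <- Reduce(intersect, list(names(y), grm1$samples, grm2$samples))
  if (length(common) < 30)
    stop("need at least 30 samples shared by phenotype and both GRMs")
  yv <- as.numeric(y[common])
  K1 <- grm1$K[common, common]
  K2 <- grm2$K[common, common]
  fit <- reml_multi(yv, list(K1, K2), tol = tol, max_iter = max_iter,
                    n_em = n_em)
  vp <- sum(fit$theta)
  structure(list(
    v_g1 = fit$theta[1], v_g2 = fit$theta[2], v_e = fit$theta[3], vp = vp,
    ratio_g1 = fit$theta[1] / vp, ratio_g2 = fit$theta[2] / vp,
    log_likelihood = fit$loglik, loglik_trace = fit$trace,
    converged = fit$converged, n_iter = fit$n_iter,
    n_samples = length(common)
  ), class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf("REML variance components (n = %d, %s after %d iterations)\n",
              x$n_samples, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  cat(sprintf("  V(G1) = %.4f  (%.2f%% of Vp)\n", x$v_g1, 100 * x$ratio_g1))
  cat(sprintf("  V(G2) = %.4f  (%.2f%% of Vp)\n", x$v_g2, 100 * x$ratio_g2))
  cat(sprintf("  V(e)  = %.4f\n  logL  = %.4f\n", x$v_e, x$log_likelihood))
  invisible(x)
}

# REML for y = 1*mu + sum_k g_k + e, random covariances theta_k * K_k plus
# theta_resid * I. K_list holds the genetic kernels; the residual identity is
# appended internally as the last component.
reml_multi <- function(y, K_list, tol = 1e-6, max_iter = 200, n_em = 3) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Ks <- c(K_list, list(diag(n)))
  m <- length(Ks)
  vp0 <- stats::var(y)
  theta <- rep(vp0 / m, m)
  floor_val <- vp0 * 1e-8
  active <- rep(TRUE, m)

  reml_parts <- function(theta) {
    V <- matrix(0, n, n)
    for (k in seq_len(m)) V <- V + theta[k] * Ks[[k]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(R))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll))
  }

  parts <- reml_parts(theta)
  if (is.null(parts)) stop("initial variance matrix not positive definite")
  ll <- parts$ll
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- parts$P
    Py <- parts$Py
    KPy <- lapply(Ks, function(K) K %*% Py)
    grad <- vapply(seq_len(m), function(k) {
      0.5 * (sum(Py * KPy[[k]]) - sum(P * Ks[[k]]))
    }, numeric(1))
    if (iter <= n_em) {
      theta_new <- theta + theta^2 * (2 * grad) / n
    } else {
      idx <- which(active)
      AI <- matrix(0, length(idx), length(idx))
      PKPy <- lapply(KPy[idx], function(v) P %*% v)
      for (a in seq_along(idx)) for (b in seq_len(a)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[idx[a]]] * PKPy[[b]])
      }
      step <- tryCatch(solve(AI, grad[idx]), error = function(e) NULL)
      theta_new <- theta
      if (is.null(step)) {
        theta_new <- theta + theta^2 * (2 * grad) / n
      } else {
        theta_new[idx] <- theta[idx] + step
      }
    }
    theta_new[theta_new < floor_val] <- floor_val
    active <- theta_new > floor_val * 1.01 | seq_len(m) == m
    parts_new <- reml_parts(theta_new)
    halvings <- 0L
    while ((is.null(parts_new) || parts_new$ll < ll - 1e-10) && halvings < 20L) {
      theta_new <- (theta + theta_new) / 2
      parts_new <- reml_parts(theta_new)
      halvings <- halvings + 1L
    }
    if (is.null(parts_new)) break
    delta <- parts_new$ll - ll
    theta <- theta_new
    parts <- parts_new
    ll <- parts$ll
    trace <- c(trace, ll)
    if (abs(delta) < tol && iter > n_em) {
      converged <- TRUE
      break
    }
  }
  theta[theta <= floor_val * 1.01] <- 0
  list(theta = theta, loglik = ll, trace = trace, converged = converged,
       n_iter = iter)
}
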
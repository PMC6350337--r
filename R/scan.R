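#' Genome-wide Bonferroni significance threshold on the -log10 scale
#'
#' `-log10(alpha / n_tests)`: the per-test significance level controlling
#' the experiment-wise type-I error at `alpha` across `n_tests` simultaneous
#' tests, expressed on the -log10(P) scale used throughout the scan.
#'
#' @param n_tests number of simultaneous tests (>= 1).
#' @param alpha experiment-wise type-I error rate (default 0.05).
#' @return the -log10(P) threshold.
#' @examples
#' bonferroni_threshold(15512960)   # ~8.49, the whole-genome-sequence scale
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  log10(n_tests / alpha)
}

#' Configuration of the iterative conditional scan
#'
#' Bundles the constants of the multi-QTL detection loop: the significance
#' threshold (computed by [bonferroni_threshold()] from `n_tests` when not
#' given explicitly), the solo-SNP window, the peak boundary rules, and the
#' round cap.
#'
#' @param threshold_neg_log10p significance threshold on the -log10(P)
#'   scale; if `NULL`, derived from the number of variants scanned.
#' @param n_tests optional test count used to derive the threshold.
#' @param alpha experiment-wise error rate for the derived threshold.
#' @param solo_window_bp a significant SNP with no other significant SNP
#'   within this distance is removed as unsupported (default 1 Mb).
#' @param boundary_scan_bp how far up/downstream of a lead the boundary walk
#'   extends (default 1 Mb).
#' @param boundary_drop_units -log10(P) drop relative to the lead that marks
#'   a boundary SNP (default 3).
#' @param boundary_min_bp minimum half-width of a QTL region; also the
#'   fallback half-width when no SNP qualifies (default 250 kb).
#' @param max_rounds cap on conditional rounds per chromosome (default 10).
#' @param collinearity_r skip threshold passed to [scan_chromosome()].
#' @return list of class `scan_config`.
#' @export
scan_config <- function(threshold_neg_log10p = NULL, n_tests = NULL,
                        alpha = 0.05, solo_window_bp = 1e6,
                        boundary_scan_bp = 1e6, boundary_drop_units = 3,
                        boundary_min_bp = 250000, max_rounds = 10,
                        collinearity_r = 0.995) {
  if (is.null(threshold_neg_log10p) && !is.null(n_tests))
    threshold_neg_log10p <- bonferroni_threshold(n_tests, alpha)
  stopifnot(solo_window_bp > 0, boundary_scan_bp > 0,
            boundary_drop_units > 0, boundary_min_bp > 0, max_rounds >= 1)
  structure(list(threshold_neg_log10p = threshold_neg_log10p, alpha = alpha,
                 solo_window_bp = solo_window_bp,
                 boundary_scan_bp = boundary_scan_bp,
                 boundary_drop_units = boundary_drop_units,
                 boundary_min_bp = boundary_min_bp, max_rounds = max_rounds,
                 collinearity_r = collinearity_r),
            class = "scan_config")
}

cfg_threshold <- function(cfg, n_tests) {
  if (!is.null(cfg$threshold_neg_log10p)) cfg$threshold_neg_log10p
  else bonferroni_threshold(n_tests, cfg$alpha)
}

#' Flag solo significant SNPs
#'
#' A significant variant survives only if at least one other significant
#' variant lies within `solo_window_bp` of it on the same chromosome;
#' isolated ("solo") significants are treated as unsupported. Non-significant
#' variants pass through untouched.
#'
#' @param results an [scan_chromosome()] result (position-sorted, one
#'   chromosome).
#' @param cfg a [scan_config()].
#' @param threshold significance threshold; defaults to the one in `cfg`.
#' @return `results` with an added logical column `solo`, `TRUE` for
#'   significant variants removed by the rule.
#' @export
remove_solo_snps <- function(results, cfg = scan_config(), threshold = NULL) {
  threshold <- threshold %||% cfg_threshold(cfg, nrow(results))
  sig <- !results$skipped & !is.na(results$neg_log10_p) &
    results$neg_log10_p > threshold
  solo <- rep(FALSE, nrow(results))
  for (ch in unique(results$chrom[sig])) {
    idx <- which(sig & results$chrom == ch)
    if (length(idx) == 1L) {
      solo[idx] <- TRUE
    } else if (length(idx) > 1L) {
      pos <- results$pos[idx]
      gap_prev <- c(Inf, diff(pos))
      gap_next <- c(diff(pos), Inf)
      solo[idx] <- gap_prev > cfg$solo_window_bp & gap_next > cfg$solo_window_bp
    }
  }
  results$solo <- solo
  results
}

#' QTL peak boundary around a lead SNP
#'
#' Walks outward from the lead on each side independently, over variants
#' within `boundary_scan_bp`, in increasing distance order. The first
#' variant whose -log10(P) has dropped by more than `boundary_drop_units`
#' relative to the lead *and* that lies more than `boundary_min_bp` away
#' becomes the boundary; if no variant qualifies the boundary falls back to
#' `lead pos +/- boundary_min_bp`. The region is clipped to
#' `[1, chrom_length]`.
#'
#' @param results a position-sorted [scan_chromosome()] result for the
#'   lead's chromosome.
#' @param lead_id id of the lead variant (must be present and tested).
#' @param cfg a [scan_config()].
#' @param chrom_length chromosome length in bp (default: last variant
#'   position).
#' @return list with `chrom`, `start`, `end`.
#' @export
define_qtl_region <- function(results, lead_id, cfg = scan_config(),
                              chrom_length = NULL) {
  li <- match(lead_id, results$id)
  if (is.na(li)) stop("lead variant ", lead_id, " not in results")
  chrom <- results$chrom[li]
  sub <- results[results$chrom == chrom, , drop = FALSE]
  li <- match(lead_id, sub$id)
  lead_pos <- sub$pos[li]
  lead_p <- sub$neg_log10_p[li]
  if (is.na(lead_p)) stop("lead variant was skipped; no profile to walk")
  chrom_length <- chrom_length %||% max(sub$pos)

  side_boundary <- function(direction) {
    dist <- (sub$pos - lead_pos) * direction
    ok <- dist > 0 & dist <= cfg$boundary_scan_bp
    cand <- sub[ok, , drop = FALSE]
    cand <- cand[order(abs(cand$pos - lead_pos)), , drop = FALSE]
    qual <- !cand$skipped & !is.na(cand$neg_log10_p) &
      (lead_p - cand$neg_log10_p) > cfg$boundary_drop_units &
      abs(cand$pos - lead_pos) > cfg$boundary_min_bp
    if (any(qual)) cand$pos[which(qual)[1]]
    else lead_pos + direction * cfg$boundary_min_bp
  }

  start <- max(1, side_boundary(-1))
  end <- min(chrom_length, side_boundary(+1))
  list(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

#' Iterative conditional multi-QTL scan
#'
#' The core detection loop, run independently per chromosome. Round 1 is an
#' unconditional mixed-model scan; solo significants are flagged; if the top
#' surviving variant exceeds the threshold it is recorded as a lead SNP and
#' its dosage is fixed as a covariate for the next round. From round 2 on, a
#' candidate lead must exceed the threshold in the current round *and* have
#' exceeded it in round 1 (the guard against conditioning-induced false
#' positives). The loop stops when no candidate remains or `max_rounds` is
#' reached. When several variants tie at the maximum -log10(P), all tied
#' ids are reported but only the lowest-position one is fixed as the
#' covariate. Each lead's peak region is taken from its discovery round's
#' profile via [define_qtl_region()].
#'
#' @param g a [geno_matrix()] (may span several chromosomes).
#' @param y named numeric phenotype vector.
#' @param grm a [build_grm()] object (by default includes the scanned
#'   chromosome, as in standard mixed-model association).
#' @param cfg a [scan_config()]; a `NULL` threshold is derived from the
#'   total variant count of `g`.
#' @param cache optional single-chromosome [scan_cache()] for `g` (reused
#'   across rounds; only valid when `g` holds one chromosome).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data frame of class `lead_snps`: one row per lead with `chrom`,
#'   `pos`, `id`, `round`, `beta`, `se`, `neg_log10_p`, `region_start`,
#'   `region_end`, `n_tied`, `tied_ids`. Attributes: `rounds` (per-round,
#'   per-chromosome association results), `solo_removed` (significant
#'   variants deleted by the solo rule), `threshold`, `diagnostics`.
#' @export
iterative_scan <- function(g, y, grm, cfg = scan_config(), cache = NULL,
                           chrom_lengths = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  threshold <- cfg_threshold(cfg, ncol(g$dosage))
  chroms <- unique(g$map$chrom)
  if (!is.null(cache) && length(chroms) > 1L)
    stop("a prebuilt cache is only valid for a single-chromosome matrix")
  leads <- list()
  rounds_log <- list()
  solo_log <- list()
  diagnostics <- character(0)

  for (ch in chroms) {
    g_c <- if (length(chroms) == 1L) g else
      geno_subset(g, variants = which(g$map$chrom == ch))
    cache_c <- cache %||% scan_cache(grm, g_c)
    chrom_len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(g_c$map$pos)
    cov_ids <- character(0)
    round1 <- NULL
    for (round in seq_len(cfg$max_rounds)) {
      covs <- if (length(cov_ids)) covariate_set(g_c, cov_ids) else NULL
      res <- tryCatch(
        scan_chromosome(g_c, y, cache = cache_c, covariates = covs,
                        collinearity_r = cfg$collinearity_r),
        error = function(e) e)
      if (inherits(res, "error")) {
        diagnostics <- c(diagnostics, sprintf(
          "chromosome %s round %d aborted: %s", ch, round, conditionMessage(res)))
        break
      }
      res <- remove_solo_snps(res, cfg, threshold = threshold)
      res$round <- round
      rounds_log[[paste(ch, round, sep = "_r")]] <- res
      if (round == 1L) round1 <- res
      removed <- res[res$solo, , drop = FALSE]
      if (nrow(removed)) solo_log[[paste(ch, round, sep = "_r")]] <- removed

      eligible <- !res$skipped & !is.na(res$neg_log10_p) & !res$solo &
        res$neg_log10_p > threshold & !(res$id %in% cov_ids)
      if (round >= 2L) {
        r1p <- round1$neg_log10_p[match(res$id, round1$id)]
        eligible <- eligible & !is.na(r1p) & r1p > threshold
      }
      if (!any(eligible)) break
      top_p <- max(res$neg_log10_p[eligible])
      tied <- which(eligible & res$neg_log10_p >= top_p - 1e-9)
      tied <- tied[order(res$pos[tied])]
      li <- tied[1]
      region <- define_qtl_region(res, res$id[li], cfg, chrom_len)
      leads[[length(leads) + 1L]] <- data.frame(
        chrom = ch, pos = res$pos[li], id = res$id[li], round = round,
        beta = res$beta[li], se = res$se[li],
        neg_log10_p = res$neg_log10_p[li],
        region_start = region$start, region_end = region$end,
        n_tied = length(tied),
        tied_ids = paste(res$id[tied], collapse = ","),
        stringsAsFactors = FALSE)
      cov_ids <- c(cov_ids, res$id[li])
    }
  }
  out <- if (length(leads)) do.call(rbind, leads) else
    data.frame(chrom = character(0), pos = integer(0), id = character(0),
               round = integer(0), beta = numeric(0), se = numeric(0),
               neg_log10_p = numeric(0), region_start = integer(0),
               region_end = integer(0), n_tied = integer(0),
               tied_ids = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("lead_snps", class(out))
  attr(out, "rounds") <- rounds_log
  attr(out, "solo_removed") <- solo_log
  attr(out, "threshold") <- threshold
  attr(out, "diagnostics") <- diagnostics
  out
}
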
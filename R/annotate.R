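#' Closest gene to a lead SNP
#'
#' Returns the gene minimizing the distance to the lead position on the
#' lead's chromosome: distance 0 ("within") when the position falls inside
#' the gene's `[start, end]`, otherwise the distance to the nearer gene edge
#' ("near"). Ties are broken toward the lower start position.
#'
#' @param lead list or one-row data frame with `chrom` and `pos`.
#' @param genes gene table as returned by [read_genes()] (`symbol`, `chrom`,
#'   `start`, `end`).
#' @return one-row data frame `symbol`, `chrom`, `start`, `end`, `relation`
#'   (`"within"`/`"near"`), `distance`; zero rows (with a warning) when the
#'   chromosome has no genes.
#' @export
closest_gene <- function(lead, genes) {
  sub <- genes[genes$chrom == lead$chrom, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no gene on chromosome ", lead$chrom)
    return(cbind(genes[0, , drop = FALSE],
                 data.frame(relation = character(0), distance = numeric(0))))
  }
  dist <- pmax(sub$start - lead$pos, lead$pos - sub$end, 0)
  best <- which(dist == min(dist))
  best <- best[order(sub$start[best])][1]
  out <- sub[best, , drop = FALSE]
  out$relation <- if (dist[best] == 0) "within" else "near"
  out$distance <- dist[best]
  rownames(out) <- NULL
  out
}

#' Genes overlapping the LD regions of lead SNPs
#'
#' Closed-interval intersection: a gene is returned when its `[start, end]`
#' shares at least one base with any lead's LD region (a gene ending exactly
#' at a region start, or starting at its end, is included).
#'
#' @param regions data frame with `chrom`, `start`, `end` (one row per lead
#'   LD region).
#' @param genes gene table (`symbol`, `chrom`, `start`, `end`).
#' @return the overlapping subset of `genes` (unique rows).
#' @export
genes_in_ld_regions <- function(regions, genes) {
  hit <- rep(FALSE, nrow(genes))
  for (k in seq_len(nrow(regions))) {
    hit <- hit | (genes$chrom == regions$chrom[k] &
                    genes$start <= regions$end[k] &
                    genes$end >= regions$start[k])
  }
  out <- genes[hit, , drop = FALSE]
  out <- out[!duplicated(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default milk-trait phenotype query terms
#'
#' The mammary/milk phenotype descriptions used to prioritize candidate
#' genes, including the common wording variants ("abnormal mammary gland
#' development" / "abnormal in mammary gland development", "abnormal milk
#' composition" / "abnormal in milk production").
#'
#' @return character vector of query terms.
#' @export
milk_phenotype_terms <- function() {
  c("abnormal mammary gland development",
    "abnormal in mammary gland development",
    "abnormal milk composition",
    "abnormal in milk production")
}

#' Match candidate genes against phenotype terms, with enrichment test
#'
#' A gene is a hit when at least one of its phenotype annotations equals one
#' of the query terms (case-folded exact match). Enrichment of hits among
#' the candidate genes is assessed by a two-sided Fisher's exact test on the
#' 2x2 table (candidate vs rest of universe) x (term-annotated vs not); the
#' universe defaults to every gene of the term table.
#'
#' @param genes character vector of candidate gene symbols (or a data frame
#'   with a `symbol` column), e.g. from [genes_in_ld_regions()].
#' @param term_table named list, gene symbol -> character vector of
#'   phenotype terms (see [read_term_table()]).
#' @param terms query terms (default [milk_phenotype_terms()]).
#' @param universe background gene symbols for the enrichment table
#'   (default: all genes in `term_table`).
#' @return list with `hits` (named list: hit gene -> matched terms),
#'   `fisher_p` (two-sided p, `NA` when the universe is empty), and `table`
#'   (the 2x2 matrix).
#' @export
match_phenotype_terms <- function(genes, term_table,
                                  terms = milk_phenotype_terms(),
                                  universe = NULL) {
  if (is.data.frame(genes)) genes <- genes$symbol
  genes <- unique(as.character(genes))
  if (!length(terms)) stop("no query terms supplied")
  terms_cf <- tolower(trimws(terms))
  annotated <- vapply(term_table, function(tt)
    any(tolower(trimws(tt)) %in% terms_cf), logical(1))
  hit_genes <- intersect(genes, names(term_table)[annotated])
  hits <- lapply(hit_genes, function(gn) {
    tt <- term_table[[gn]]
    tt[tolower(trimws(tt)) %in% terms_cf]
  })
  names(hits) <- hit_genes
  universe <- universe %||% names(term_table)
  universe <- unique(union(universe, genes))
  in_set <- universe %in% genes
  is_annot <- universe %in% names(term_table)[annotated]
  tab <- matrix(c(sum(in_set & is_annot), sum(in_set & !is_annot),
                  sum(!in_set & is_annot), sum(!in_set & !is_annot)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "background"),
                                c("annotated", "not_annotated")))
  fisher_p <- if (length(universe) == 0 || all(!in_set) || all(in_set))
    NA_real_ else stats::fisher.test(tab)$p.value
  list(hits = hits, fisher_p = fisher_p, table = tab)
}

# Sequence-ontology consequence -> VEP impact class.
.impact_map <- c(
  transcript_ablation = "HIGH", splice_acceptor_variant = "HIGH",
  splice_donor_variant = "HIGH", stop_gained = "HIGH",
  frameshift_variant = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  transcript_amplification = "HIGH",
  inframe_insertion = "MODERATE", inframe_deletion = "MODERATE",
  missense_variant = "MODERATE", protein_altering_variant = "MODERATE",
  splice_region_variant = "LOW", incomplete_terminal_codon_variant = "LOW",
  start_retained_variant = "LOW", stop_retained_variant = "LOW",
  synonymous_variant = "LOW",
  coding_sequence_variant = "MODIFIER", mature_miRNA_variant = "MODIFIER",
  `5_prime_UTR_variant` = "MODIFIER", `3_prime_UTR_variant` = "MODIFIER",
  non_coding_transcript_exon_variant = "MODIFIER",
  intron_variant = "MODIFIER", non_coding_transcript_variant = "MODIFIER",
  upstream_gene_variant = "MODIFIER", downstream_gene_variant = "MODIFIER",
  TF_binding_site_variant = "MODIFIER", regulatory_region_variant = "MODIFIER",
  intergenic_variant = "MODIFIER")

#' Prioritize VEP-annotated variants within LD regions
#'
#' Restricts a variant-consequence table to the variants in LD with lead
#' SNPs and ranks them as candidate causative mutations: impact class
#' (HIGH > MODERATE > LOW > MODIFIER, derived from the consequence term when
#' not supplied), then SIFT "deleterious" before "tolerated", then ascending
#' SIFT score; remaining ties fall back to variant id, making the order
#' total and stable. Consequence terms outside the standard sequence
#' ontology are binned as MODIFIER with a warning.
#'
#' @param records data frame from [read_vep_table()] (`id`, `consequence`,
#'   optionally `impact`, `sift_class`, `sift_score`).
#' @param in_ld_variant_ids ids of variants inside lead LD regions.
#' @return the restricted, ranked data frame with an added `impact` column;
#'   attribute `consequence_counts` tabulates consequences among the
#'   retained variants.
#' @export
screen_vep <- function(records, in_ld_variant_ids) {
  out <- records[records$id %in% in_ld_variant_ids, , drop = FALSE]
  first_cons <- sub(",.*$", "", out$consequence)
  derived <- unname(.impact_map[first_cons])
  unknown <- is.na(derived)
  if (any(unknown)) {
    warning("unknown consequence term(s) binned as MODIFIER: ",
            paste(unique(first_cons[unknown]), collapse = ", "))
    derived[unknown] <- "MODIFIER"
  }
  impact <- if ("impact" %in% names(out)) ifelse(is.na(out$impact), derived,
                                                 out$impact) else derived
  out$impact <- factor(impact, levels = c("HIGH", "MODERATE", "LOW", "MODIFIER"))
  sift_rank <- match(tolower(out$sift_class %||% rep(NA, nrow(out))),
                     c("deleterious", "deleterious_low_confidence",
                       "tolerated_low_confidence", "tolerated"))
  sift_rank[is.na(sift_rank)] <- 5L
  score <- out$sift_score
  score[is.na(score)] <- Inf
  ord <- order(as.integer(out$impact), sift_rank, score, out$id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "consequence_counts") <-
    sort(table(sub(",.*$", "", out$consequence)), decreasing = TRUE)
  out
}
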
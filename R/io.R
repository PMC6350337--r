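#' Read genotype dosages from VCF or plain matrix format
#'
#' VCF input is parsed with \pkg{vcfR}. The per-sample dosage field (default
#' `DS`) is used when present; otherwise hard `GT` genotypes are converted to
#' alternate-allele counts 0/1/2. Multi-allelic records are skipped with a
#' warning. Matrix input is the package's own tab-separated layout: a header
#' row of variant ids, one sample per row (first column the sample id), with
#' a companion variant map TSV (`chrom pos id ref alt`).
#'
#' @param path input file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"matrix"`.
#' @param dosage_field VCF FORMAT key holding dosages (default `"DS"`).
#' @param map_path path to the variant map TSV for matrix input; defaults to
#'   `paste0(path, ".map")`.
#' @return a [geno_matrix()], variants sorted by position, missing dosages
#'   mean-imputed per variant (count recorded in the `n_imputed` element).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           dosage_field = "DS", map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "vcf") read_genotypes_vcf(path, dosage_field)
  else read_genotypes_matrix(path, map_path %||% paste0(path, ".map"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_genotypes_vcf <- function(path, dosage_field) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in ", path)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (dosage_field %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = dosage_field, as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, gt_to_dosage)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  geno_matrix(t(ds), map)
}

gt_to_dosage <- function(gt) {
  alleles <- strsplit(sub(":.*$", "", gt), "[/|]")
  vapply(alleles, function(a) {
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a)) NA_real_ else sum(a > 0)
  }, numeric(1))
}

read_genotypes_matrix <- function(path, map_path) {
  if (!file.exists(map_path)) stop("variant map file not found: ", map_path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(dat) != length(header))
    stop("malformed matrix file ", path, ": header/body column mismatch at line 2")
  samples <- as.character(dat[[1]])
  raw <- dat[, -1, drop = FALSE]
  dos <- vapply(raw, function(col) suppressWarnings(as.numeric(as.character(col))),
                numeric(nrow(raw)))
  if (nrow(raw) == 1L) dos <- matrix(dos, nrow = 1)
  colnames(dos) <- names(raw)
  mangled <- is.na(dos) & !vapply(raw, function(col)
    is.na(col) | as.character(col) %in% c("NA", ""), logical(nrow(raw)))
  if (nrow(raw) == 1L) mangled <- matrix(mangled, nrow = 1)
  if (any(mangled)) {
    bad <- which(apply(mangled, 1, any))
    stop("malformed dosage value(s) in ", path, " at line ", bad[1] + 1L)
  }
  map <- utils::read.table(map_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  mis <- setdiff(colnames(dos), map$id)
  if (length(mis)) stop("variant(s) absent from map: ", paste(mis, collapse = ", "))
  map <- map[match(colnames(dos), map$id), , drop = FALSE]
  geno_matrix(dos, map, samples = samples)
}

#' Write genotype dosages in the plain matrix format
#'
#' Writes the tab-separated dosage matrix (fixed 6-decimal precision, so a
#' write/read round trip is exact at that precision) and the companion
#' variant map at `paste0(path, ".map")`.
#'
#' @param g a [geno_matrix()].
#' @param path output path for the matrix file.
#' @param digits decimal places stored (default 6).
#' @return invisibly, the two paths written.
#' @export
write_genotypes <- function(g, path, digits = 6) {
  stopifnot(inherits(g, "geno_matrix"))
  dos <- formatC(g$dosage, format = "f", digits = digits)
  out <- cbind(sample_id = rownames(g$dosage), dos)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map_path <- paste0(path, ".map")
  utils::write.table(g$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' Write genotype dosages as a VCF
#'
#' Minimal VCF 4.2 writer: emits `GT:DS` per sample, `GT` from the rounded
#' dosage and `DS` at fixed precision. Readable by any VCF parser, including
#' [read_genotypes()].
#'
#' @param g a [geno_matrix()].
#' @param path output `.vcf` path.
#' @param digits decimal places for the DS field (default 6).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(g, path, digits = 6) {
  stopifnot(inherits(g, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=qtldissect",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$dosage)), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, j]
    cells <- paste0(gt_codes[pmin(pmax(round(d), 0), 2) + 1L], ":",
                    formatC(d, format = "f", digits = digits))
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$id[j],
                       g$map$ref[j], g$map$alt[j], ".", "PASS", ".",
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column tab-separated file, `sample_id<TAB>value`, with an optional
#' header (detected when the second field of the first line is not numeric).
#'
#' @param path input TSV path.
#' @return named numeric vector, one value per sample.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  dat <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 2) stop("phenotype file must have two tab-separated columns")
  y <- as.numeric(dat[[2]])
  names(y) <- as.character(dat[[1]])
  if (anyDuplicated(names(y))) stop("duplicate sample ids in phenotype file")
  y
}

#' Write a phenotype table
#' @param y named numeric vector.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(y, path) {
  utils::write.table(data.frame(sample_id = names(y), value = y), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene features from GFF3 or BED
#'
#' GFF3/BED parsing is delegated to \pkg{rtracklayer}; for GFF3, rows with
#' `type == "gene"` are kept (all rows if none are typed "gene"). The symbol
#' is taken from the first available of `Name`, `gene_name`, `gene_id`, `ID`
#' (GFF3) or the BED name column.
#'
#' @param path `.gff3`/`.gff` or `.bed` file.
#' @return data frame with columns `symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene annotation file not found: ", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3/BED requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  symbol <- rep(NA_character_, nrow(df))
  for (col in c("Name", "gene_name", "gene_id", "ID", "name")) {
    if (col %in% names(df)) {
      val <- as.character(df[[col]])
      symbol <- ifelse(is.na(symbol) | symbol == "", val, symbol)
    }
  }
  symbol[is.na(symbol) | symbol == ""] <-
    paste0("feature_", which(is.na(symbol) | symbol == ""))
  out <- data.frame(symbol = symbol, chrom = as.character(df$seqnames),
                    start = df$start, end = df$end, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a gene-to-phenotype-term table
#'
#' TSV with columns `symbol<TAB>term`, one row per (gene, term) pair, in the
#' style of a Mammalian Phenotype database export.
#'
#' @param path input TSV path.
#' @return named list: gene symbol -> character vector of terms.
#' @export
read_term_table <- function(path) {
  if (!file.exists(path)) stop("term table not found: ", path)
  dat <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(dat) < 2) stop("term table must have columns symbol<TAB>term")
  split(as.character(dat[[2]]), as.character(dat[[1]]))
}

#' Read a VEP-style variant annotation table
#'
#' Tab-separated table with at least a variant id and a consequence column.
#' Recognized column names (case-insensitive): `id`/`variant`/
#' `uploaded_variation`, `consequence`, `impact`, `sift`. A combined VEP
#' `SIFT` field like `deleterious(0.02)` is split into class and score.
#'
#' @param path input TSV path.
#' @return data frame with columns `id`, `consequence`, `impact`,
#'   `sift_class`, `sift_score`.
#' @export
read_vep_table <- function(path) {
  if (!file.exists(path)) stop("VEP table not found: ", path)
  dat <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  nm <- tolower(gsub("^#", "", names(dat)))
  names(dat) <- nm
  idc <- intersect(c("id", "variant", "uploaded_variation"), nm)[1]
  if (is.na(idc) || !("consequence" %in% nm))
    stop("VEP table needs a variant id column and a consequence column")
  out <- data.frame(id = as.character(dat[[idc]]),
                    consequence = as.character(dat$consequence),
                    stringsAsFactors = FALSE)
  out$impact <- if ("impact" %in% nm) toupper(dat$impact) else NA_character_
  if ("sift" %in% nm) {
    sift <- as.character(dat$sift)
    out$sift_class <- sub("\\(.*$", "", sift)
    score <- suppressWarnings(as.numeric(sub("^.*\\(([0-9.]+)\\)$", "\\1", sift)))
    out$sift_score <- score
  } else {
    out$sift_class <- if ("sift_class" %in% nm) as.character(dat$sift_class) else NA_character_
    out$sift_score <- if ("sift_score" %in% nm) as.numeric(dat$sift_score) else NA_real_
  }
  out$sift_class[out$sift_class %in% c("", "-", "NA")] <- NA_character_
  out
}
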
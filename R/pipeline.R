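#' Run the full QTL dissection pipeline
#'
#' Orchestrates filter -> GRM -> iterative conditional scan -> LD regions ->
#' closest genes -> phenotype-term matching -> variant-annotation screen ->
#' two-GRM variance partition, writing every stage's table and a
#' machine-readable run manifest into `out_dir`. Inputs may be files or the
#' built-in simulator; every output TSV carries a header comment with the
#' seed, the significance threshold and a hash of the configuration, and a
#' rerun with the same configuration and seed reproduces the outputs
#' byte-identically.
#'
#' @param config a configuration list or the path of a YAML file. Top-level
#'   keys (all optional unless noted): `seed`; `out_dir` (required unless
#'   given as argument); `genotypes` (`path`+`format`+`dosage_field`, or
#'   `simulate: yes` with [sim_config()] fields); `phenotypes` (`path`, or
#'   simulated when the genotypes are); `filter` (`maf_min`, `hwe_p_min`);
#'   `scan` ([scan_config()] fields; `threshold: auto` derives the
#'   Bonferroni threshold from the variant count); `ld` (`r2_min`);
#'   `genes` (`path`); `terms` (`path`, `query`); `vep` (`path`);
#'   `varexp` (`enabled`, `flank_bp`).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, the manifest list. Stage failure raises an error after
#'   the manifest (with the failed stage recorded) is written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  cfg_hash <- config_hash(config)

  manifest <- list(seed = seed, config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("qtldissect")),
                   stages = list())
  state <- new.env(parent = emptyenv())

  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "completed")
    res
  }
  header <- function() {
    c(sprintf("# seed=%s", seed),
      sprintf("# threshold=%s",
              if (!is.null(state$threshold)) format(state$threshold) else "NA"),
      sprintf("# config_hash=%s", cfg_hash))
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(header(), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }

  run_stage("load_inputs", function() {
    gcfg <- config$genotypes %||% list(simulate = TRUE)
    if (isTRUE(gcfg$simulate)) {
      sim_args <- gcfg[intersect(names(gcfg), names(formals(sim_config)))]
      state$sim_cfg <- do.call(sim_config, c(sim_args, list(seed = seed)))
      state$geno <- simulate_genotypes(state$sim_cfg)
      h2 <- config$phenotypes$h2_polygenic %||% state$sim_cfg$h2_polygenic
      state$pheno <- base_phenotype(state$geno, h2, seed = seed + 1L)
      write_genotypes(state$geno, file.path(out_dir, "genotypes.tsv"))
      write_phenotypes(state$pheno, file.path(out_dir, "phenotypes.tsv"))
    } else {
      state$geno <- read_genotypes(gcfg$path, format = gcfg$format %||% "auto",
                                   dosage_field = gcfg$dosage_field %||% "DS",
                                   map_path = gcfg$map_path)
      if (is.null(config$phenotypes$path))
        stop("phenotype path missing from configuration")
      state$pheno <- read_phenotypes(config$phenotypes$path)
    }
    common <- intersect(geno_samples(state$geno), names(state$pheno))
    if (length(common) < 30) stop("fewer than 30 samples shared by genotypes and phenotypes")
    state$geno <- geno_subset(state$geno, samples = common)
    state$pheno <- state$pheno[common]
    invisible(NULL)
  })

  run_stage("filter", function() {
    f <- filter_variants(state$geno,
                         maf_min = config$filter$maf_min %||% 0.01,
                         hwe_p_min = config$filter$hwe_p_min %||% 1e-6)
    state$geno <- f$geno
    emit(f$report, "filter_report.tsv")
  })

  run_stage("grm", function() {
    state$grm <- build_grm(state$geno)
    write_grm(state$grm, file.path(out_dir, "grm.tsv"))
  })

  run_stage("scan", function() {
    sc <- config$scan %||% list()
    thr <- sc$threshold %||% "auto"
    scan_args <- sc[intersect(names(sc), names(formals(scan_config)))]
    if (!identical(thr, "auto"))
      scan_args$threshold_neg_log10p <- as.numeric(thr)
    cfg_s <- do.call(scan_config, scan_args)
    state$threshold <- cfg_threshold(cfg_s, ncol(state$geno$dosage))
    leads <- iterative_scan(state$geno, state$pheno, state$grm, cfg_s)
    state$leads <- leads
    for (nm in names(attr(leads, "rounds")))
      emit(attr(leads, "rounds")[[nm]], sprintf("assoc_%s.tsv", nm))
    invisible(NULL)
  })

  run_stage("ld_regions", function() {
    leads <- state$leads
    r2_min <- config$ld$r2_min %||% 0.2
    regions <- lapply(seq_len(nrow(leads)), function(k) {
      pr <- pairwise_r2(state$geno, leads$id[k])
      reg <- ld_region(pr, leads$pos[k], r2_min = r2_min)
      in_ld <- pr$id[!is.na(pr$r2) & pr$r2 > r2_min]
      data.frame(id = leads$id[k], chrom = leads$chrom[k],
                 start = reg$start, end = reg$end,
                 n_in_ld = length(in_ld),
                 in_ld_ids = paste(in_ld, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    state$ld_regions <- if (length(regions)) do.call(rbind, regions) else
      data.frame(id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0),
                 n_in_ld = integer(0), in_ld_ids = character(0))
    emit(state$ld_regions, "ld_regions.tsv")
  })

  run_stage("candidate_genes", function() {
    if (is.null(config$genes$path)) return(invisible(NULL))
    genes <- read_genes(config$genes$path)
    leads <- state$leads
    closest <- lapply(seq_len(nrow(leads)), function(k) {
      cg <- closest_gene(leads[k, ], genes)
      if (!nrow(cg)) return(NULL)
      cbind(lead = leads$id[k], cg)
    })
    closest <- do.call(rbind, closest)
    leads$closest_gene <- if (!is.null(closest))
      closest$symbol[match(leads$id, closest$lead)] else NA_character_
    state$leads <- leads
    state$region_genes <- genes_in_ld_regions(state$ld_regions, genes)
    emit(state$region_genes, "genes_in_ld_regions.tsv")
    invisible(NULL)
  })

  run_stage("phenotype_terms", function() {
    if (is.null(config$terms$path) || is.null(state$region_genes))
      return(invisible(NULL))
    tt <- read_term_table(config$terms$path)
    query <- config$terms$query %||% milk_phenotype_terms()
    mt <- match_phenotype_terms(state$region_genes, tt, terms = query)
    hits <- data.frame(
      symbol = names(mt$hits),
      terms = vapply(mt$hits, paste, character(1), collapse = "; "))
    emit(hits, "term_hits.tsv")
    manifest$fisher_p <<- mt$fisher_p
    invisible(NULL)
  })

  run_stage("vep_screen", function() {
    if (is.null(config$vep$path)) return(invisible(NULL))
    vep <- read_vep_table(config$vep$path)
    in_ld <- unique(c(state$leads$id,
                      unlist(strsplit(state$ld_regions$in_ld_ids, ","))))
    emit(screen_vep(vep, in_ld), "vep_screen.tsv")
    invisible(NULL)
  })

  run_stage("variance_partition", function() {
    if (identical(config$varexp$enabled, FALSE)) return(invisible(NULL))
    leads <- state$leads
    if (!nrow(leads)) return(invisible(NULL))
    grm1 <- build_grm(state$geno, variant_subset = leads$id)
    rest <- exclude_flank(state$geno, leads,
                          flank_bp = config$varexp$flank_bp %||% 2.5e6)
    grm2 <- build_grm(rest)
    vc <- partition_variance(state$pheno, grm1, grm2)
    emit(data.frame(component = c("V(G1)", "V(G2)", "V(e)"),
                    variance = c(vc$v_g1, vc$v_g2, vc$v_e),
                    pct_of_vp = 100 * c(vc$ratio_g1, vc$ratio_g2,
                                        vc$v_e / vc$vp),
                    converged = vc$converged), "varexp.tsv")
    invisible(NULL)
  })

  # final lead table (after optional closest-gene annotation)
  emit(state$leads, "leads.tsv")
  manifest$threshold <- state$threshold
  manifest$n_leads <- nrow(state$leads)
  finish()
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
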
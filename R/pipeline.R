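# End-to-end orchestration: QC -> LD pruning -> per-SNP association ->
# risk-allele orientation -> GRS construction (all scopes x weightings x
# phenotypes) -> GRS models over covariate sets -> risk groups -> sex
# strata, with optional plain-text artifacts and a manifest.

#' Run the full pathway-GRS analysis
#'
#' @param genotypes Panel dosage matrix (individuals x SNPs).
#' @param phenotypes Phenotype data frame (`individual_id`, `age`, `sex`,
#'   `bmi`, `tg`, `hdl`).
#' @param panel A `snp_panel`.
#' @param aims Optional AIMs dosage matrix for ancestry PCs.
#' @param phenos Phenotypes to analyze.
#' @param hwe_alpha Hardy-Weinberg exclusion level.
#' @param min_call_rate Minimum per-SNP call rate.
#' @param dprime_threshold High-LD threshold for tag-SNP pruning.
#' @param top_hits_alpha Inclusion threshold for the top-hits score.
#' @param n_pcs Number of ancestry PCs when `aims` is given.
#' @param scan_snp_interactions Run the pairwise interaction scan?
#' @param out_dir Optional directory for TSV/CSV/JSON artifacts and a
#'   manifest with file checksums.
#' @return A `grs_report` list: `qc`, `ld`, `pcs`, per-phenotype results
#'   (`assoc`, `interactions`, `pruning`, `retained`, `definitions`,
#'   `scores`, `models`, `model_table`, `risk_groups`, `comparisons`,
#'   `stratified`), and `manifest`.
#' @export
run_pipeline <- function(genotypes, phenotypes, panel = load_snp_panel(),
                         aims = NULL, phenos = c("TG", "HDL"),
                         hwe_alpha = 0.05, min_call_rate = 0.9,
                         dprime_threshold = 0.8, top_hits_alpha = 0.10,
                         n_pcs = 2, scan_snp_interactions = FALSE,
                         out_dir = NULL) {
  panel_snps <- intersect(panel$snp_id, colnames(genotypes))
  if (length(panel_snps) == 0) stop("stage qc: no panel SNPs in genotypes")
  genotypes <- genotypes[, panel_snps, drop = FALSE]

  qc <- qc_report(genotypes, hwe_alpha = hwe_alpha,
                  min_call_rate = min_call_rate)
  retained_qc <- apply_qc_filters(qc)
  ld <- ld_table(genotypes, panel, snp_ids = retained_qc)

  pcs <- NULL
  if (!is.null(aims)) {
    pcs <- compute_ancestry_pcs(aims, n_components = n_pcs)$scores
  }

  # pairs partitioned between phenotypes rather than pruned
  ps <- panel$pheno_specific
  spec_snps <- panel$snp_id[!is.na(ps) & ps != ""]
  exempt <- NULL
  if (length(spec_snps) >= 2) {
    cmb <- t(utils::combn(spec_snps, 2))
    exempt <- data.frame(snp_1 = cmb[, 1], snp_2 = cmb[, 2],
                         stringsAsFactors = FALSE)
  }

  maf <- compute_maf(genotypes)
  maf_vec <- stats::setNames(maf$maf, maf$snp_id)

  results <- list()
  for (ph in phenos) {
    transform <- prepare_phenotype(
      phenotypes[[phenotype_column(ph)]])$transform
    assoc <- snp_association_table(phenotypes, genotypes, panel, ph,
                                   covariates = c("age", "sex"),
                                   snp_ids = retained_qc,
                                   transform = transform)
    if (is.null(assoc$summary)) stop("stage assoc: no estimable SNPs")
    ve <- stats::setNames(assoc$summary$partial_r2, assoc$summary$snp_id)
    pruning <- prune_ld_groups(ld, ve, maf = maf_vec,
                               dprime_threshold = dprime_threshold,
                               exempt_pairs = exempt)
    retained <- pruning$retained
    idx <- match(retained, panel$snp_id)
    keep <- is.na(panel$pheno_specific[idx]) |
      panel$pheno_specific[idx] == "" | panel$pheno_specific[idx] == ph
    retained <- retained[keep]

    definitions <- list()
    for (w in c("additive", "weighted")) {
      for (scope in c("RCT", "CLU", "LPF", "TOTAL")) {
        key <- paste(scope, w, sep = "_")
        definitions[[key]] <- tryCatch(
          build_pathway_definition(assoc$summary, scope, retained, w),
          error = function(e) NULL)
      }
      th <- withCallingHandlers(
        build_top_hits_definition(assoc$summary, retained,
                                  alpha = top_hits_alpha, weighting = w),
        warning = function(wn) invokeRestart("muffleWarning"))
      definitions[[paste("TOP_HITS", w, sep = "_")]] <- th
    }
    definitions <- Filter(Negate(is.null), definitions)

    scores <- lapply(definitions, function(d) {
      assign_risk_groups(build_grs(genotypes, d, panel))
    })

    covariate_sets <- list(base = c("age", "sex"),
                           bmi = c("age", "sex", "bmi"))
    models <- list()
    for (key in names(scores)) {
      for (cs in names(covariate_sets)) {
        models[[paste(key, cs, sep = ".")]] <-
          fit_grs_model(phenotypes, scores[[key]], ph,
                        covariates = covariate_sets[[cs]],
                        transform = transform)
      }
      if (!is.null(pcs)) {
        models[[paste(key, "pcs", sep = ".")]] <-
          fit_grs_model(phenotypes, scores[[key]], ph,
                        covariates = c("age", "sex"), pcs = pcs,
                        transform = transform)
      }
    }

    comparisons <- lapply(
      scores[grepl("additive", names(scores))],
      function(sc) compare_risk_groups(phenotypes, sc, ph,
                                       transform = transform))

    stratified <- lapply(scores, function(sc) {
      withCallingHandlers(
        stratify_by_sex(phenotypes, sc, ph, covariates = c("age", "sex"),
                        transform = transform),
        warning = function(wn) invokeRestart("muffleWarning"))
    })

    interactions <- NULL
    if (scan_snp_interactions) {
      interactions <- scan_interactions(phenotypes, genotypes, ph,
                                        covariates = c("age", "sex"),
                                        snp_ids = retained,
                                        transform = transform)
    }

    results[[ph]] <- list(transform = transform, assoc = assoc,
                          interactions = interactions, pruning = pruning,
                          retained = retained, definitions = definitions,
                          scores = scores, models = models,
                          model_table = format_grs_table(models),
                          comparisons = comparisons,
                          stratified = stratified)
  }

  manifest <- list(
    n_individuals = nrow(genotypes),
    n_snps_input = length(panel_snps),
    n_snps_qc_pass = length(retained_qc),
    thresholds = list(hwe_alpha = hwe_alpha,
                      min_call_rate = min_call_rate,
                      dprime_threshold = dprime_threshold,
                      top_hits_alpha = top_hits_alpha),
    n_pcs = if (is.null(pcs)) 0 else ncol(pcs),
    package_version = as.character(utils::packageVersion("pathgrs")))

  report <- list(qc = qc, ld = ld, pcs = pcs, results = results,
                 manifest = manifest)
  class(report) <- "grs_report"
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Writes the QC and LD tables, per-phenotype association and model
#' tables, GRS definitions and scores, and a `manifest.json` carrying the
#' run settings and an md5 checksum per artifact.
#'
#' @param report A `grs_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write_report_tsv(df, p)
    paths <<- c(paths, p)
  }
  wr(as.data.frame(report$qc), "qc_report.tsv")
  wr(report$ld, "ld_table.tsv")
  if (!is.null(report$pcs)) {
    p <- file.path(out_dir, "ancestry_pcs.csv")
    utils::write.csv(data.frame(individual_id = rownames(report$pcs),
                                report$pcs, check.names = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  for (ph in names(report$results)) {
    res <- report$results[[ph]]
    wr(res$assoc$summary, sprintf("assoc_%s.tsv", ph))
    wr(res$model_table, sprintf("grs_models_%s.tsv", ph))
    if (!is.null(res$interactions)) {
      wr(res$interactions, sprintf("interactions_%s.tsv", ph))
    }
    for (key in names(res$definitions)) {
      p <- file.path(out_dir, sprintf("grs_def_%s_%s.json", ph, key))
      write_grs_definition(res$definitions[[key]], p)
      paths <- c(paths, p)
      sc <- res$scores[[key]]
      p2 <- file.path(out_dir, sprintf("grs_scores_%s_%s.csv", ph, key))
      utils::write.csv(as.data.frame(sc), p2, row.names = FALSE,
                       quote = FALSE, na = "NA")
      paths <- c(paths, p2)
    }
  }
  manifest <- report$manifest
  manifest$files <- lapply(stats::setNames(paths, basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
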
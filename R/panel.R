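#' Load the packaged lipid-metabolism SNP panel
#'
#' Reads the annotated SNP panel shipped with the package: 19 variants in
#' genes of three lipoprotein-metabolism pathways — reverse cholesterol
#' transport (RCT), cellular lipid uptake (CLU) and lipoprotein formation
#' (LPF) — with reference allele frequencies (1000 Genomes global, the MXL
#' subpopulation, and the genotyped cohort). The `counted_allele` is the
#' allele the 0/1/2 dosage code counts; `maf_cohort` is its cohort
#' frequency. One CD36 variant (rs3173798) is flagged in `note` as a
#' reported Hardy-Weinberg failure and carries a synthetic placeholder
#' frequency; it is excluded from score construction by
#' [reported_grs_members()]. The two ABCA1 variants carry a
#' `pheno_specific` tag (rs4149310 contributes to triglyceride scores,
#' rs9282541 to HDL-C scores).
#'
#' The non-counted allele letters are a reconstruction for simulation
#' purposes; only the counted allele and its frequency enter any
#' computation.
#'
#' @param path Optional path to an alternative panel CSV with the same
#'   columns.
#' @return A `snp_panel` data frame with columns `snp_id`, `gene`,
#'   `chromosome`, `pathway`, `allele_a`, `allele_b`, `counted_allele`,
#'   `maf_global`, `maf_mxl`, `maf_cohort`, `pheno_specific`, `note`.
#' @export
#' @examples
#' panel <- load_snp_panel()
#' table(panel$pathway)
load_snp_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snp_panel.csv", package = "pathgrs",
                        mustWork = TRUE)
  }
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  panel$chromosome <- as.character(panel$chromosome)
  validate_snp_panel(panel)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Validate a SNP panel data frame
#'
#' @param panel A data frame with the columns documented in
#'   [load_snp_panel()].
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_snp_panel <- function(panel) {
  required <- c("snp_id", "gene", "chromosome", "pathway", "allele_a",
                "allele_b", "counted_allele", "maf_cohort")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$snp_id)) {
    stop("panel snp_ids are not unique")
  }
  if (!all(panel$pathway %in% c("RCT", "CLU", "LPF"))) {
    stop("panel pathways must be one of RCT, CLU, LPF")
  }
  ok <- panel$counted_allele == panel$allele_a |
    panel$counted_allele == panel$allele_b
  if (!all(ok)) {
    stop("counted_allele must be one of allele_a/allele_b for: ",
         paste(panel$snp_id[!ok], collapse = ", "))
  }
  mafs <- panel$maf_cohort[!is.na(panel$maf_cohort)]
  if (any(mafs <= 0 | mafs >= 1)) {
    stop("maf_cohort must lie in (0, 1)")
  }
  invisible(panel)
}

#' Other (non-counted) allele for each panel SNP
#' @param panel A `snp_panel`.
#' @return Named character vector of the allele not counted by the dosage
#'   code, named by `snp_id`.
#' @export
other_allele <- function(panel) {
  out <- ifelse(panel$counted_allele == panel$allele_a,
                panel$allele_b, panel$allele_a)
  stats::setNames(out, panel$snp_id)
}

#' Panel members entering each phenotype's risk score after the reported
#' exclusions
#'
#' Applies to the packaged panel the quality-control outcome reported for
#' the genotyped cohort: the Hardy-Weinberg-failing CD36 variant is
#' dropped; the ANGPTL4 trio collapses to its tag SNP rs2278236 and the
#' CD36 pair to rs10499859; and the two ABCA1 variants are assigned
#' phenotype-specifically (rs4149310 to TG, rs9282541 to HDL). The result
#' is the 14-SNP membership per phenotype from which the published scores
#' are built. The data-driven pipeline ([run_pipeline()]) recomputes these
#' decisions from genotypes; this function encodes the reported outcome as
#' a fixture for panel bookkeeping.
#'
#' @param panel A `snp_panel` (defaults to the packaged panel).
#' @param phenotype `"TG"` or `"HDL"`.
#' @param hwe_exclude SNP ids excluded for Hardy-Weinberg failure.
#' @param ld_drop SNP ids dropped during LD pruning (non-tag members).
#' @return Character vector of member SNP ids.
#' @export
#' @examples
#' length(reported_grs_members(phenotype = "TG"))   # 14
#' length(reported_grs_members(phenotype = "HDL"))  # 14
reported_grs_members <- function(panel = load_snp_panel(),
                                 phenotype = c("TG", "HDL"),
                                 hwe_exclude = "rs3173798",
                                 ld_drop = c("rs1044250", "rs7255436",
                                             "rs1527483")) {
  phenotype <- match.arg(phenotype)
  keep <- !(panel$snp_id %in% c(hwe_exclude, ld_drop))
  ps <- panel$pheno_specific
  keep <- keep & (is.na(ps) | ps == "" | ps == phenotype)
  panel$snp_id[keep]
}
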
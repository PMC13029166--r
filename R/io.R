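# Readers and writers for the plain-text interchange formats: genotype /
# AIMs CSV (rows = individuals, columns = SNP ids, codes 0/1/2/NA),
# phenotype CSV, report TSV, and a minimal biallelic VCF reader with
# allele harmonization against the panel.

#' Write a dosage matrix to CSV
#' @param genotypes Integer 0/1/2/NA matrix with individual ids as row
#'   names.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_genotype_csv <- function(genotypes, path) {
  df <- data.frame(individual_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a dosage matrix from CSV
#'
#' Expects the dialect written by [write_genotype_csv()]: an
#' `individual_id` column followed by one column per SNP with codes 0, 1,
#' 2 or NA.
#'
#' @param path CSV file.
#' @param panel Optional `snp_panel`; when given, file columns must be a
#'   subset check of the panel's SNP ids.
#' @return Integer dosage matrix.
#' @export
read_genotype_csv <- function(path, panel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "NA")
  if (!"individual_id" %in% names(df)) {
    stop("genotype CSV must have an individual_id column")
  }
  ids <- as.character(df$individual_id)
  mat <- as.matrix(df[, setdiff(names(df), "individual_id"),
                      drop = FALSE])
  bad <- !is.na(mat) & !(mat %in% c(0, 1, 2))
  if (any(bad)) {
    rows <- unique(which(bad, arr.ind = TRUE)[, 1])
    stop("invalid genotype codes at data line(s): ",
         paste(utils::head(rows, 5), collapse = ", "))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  if (!is.null(panel)) {
    unknown <- setdiff(colnames(mat), panel$snp_id)
    if (length(unknown) > 0) {
      stop("genotype columns not in panel: ",
           paste(unknown, collapse = ", "))
    }
  }
  mat
}

#' Read a phenotype table from CSV
#' @param path CSV with columns `individual_id`, `age`, `sex`, `bmi`,
#'   `tg`, `hdl`.
#' @return Data frame.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "age", "sex", "bmi", "tg", "hdl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("phenotype CSV missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$tg <= 0, na.rm = TRUE) || any(df$hdl <= 0, na.rm = TRUE)) {
    stop("tg and hdl must be positive")
  }
  df$individual_id <- as.character(df$individual_id)
  df
}

#' Read panel genotypes from a biallelic VCF
#'
#' Minimal reader for the GT field of biallelic records. Dosages are
#' harmonized against the panel: when the ALT allele is the counted
#' allele the ALT count is used directly; when REF and ALT are swapped
#' relative to the panel the dosage is complemented with a notice; records
#' whose alleles do not match the panel's pair raise an error.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param panel A `snp_panel`; records are matched by the VCF ID column.
#' @return Integer dosage matrix (individuals x matched SNPs) of
#'   counted-allele copies.
#' @export
read_vcf_genotypes <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  keep <- fix[, "ID"] %in% panel$snp_id & !grepl(",", fix[, "ALT"])
  if (!any(keep)) stop("no biallelic panel records found in VCF")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  oth <- other_allele(panel)
  out <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), fix[, "ID"]))
  mismatch <- character()
  for (i in seq_len(nrow(fix))) {
    id <- fix[i, "ID"]
    counted <- panel$counted_allele[panel$snp_id == id]
    pair <- c(counted, oth[[id]])
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (!setequal(c(ref, alt), pair)) {
      mismatch <- c(mismatch, id)
      next
    }
    alt_dose <- alt_allele_count(gt[i, ])
    if (alt == counted) {
      out[, id] <- alt_dose
    } else {
      message("REF/ALT swapped relative to panel for ", id,
              "; dosage complemented")
      out[, id] <- 2L - alt_dose
    }
  }
  if (length(mismatch) > 0) {
    stop("VCF alleles do not match the panel for: ",
         paste(mismatch, collapse = ", "))
  }
  out
}

alt_allele_count <- function(gt) {
  vapply(gt, function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(as.integer(alleles) > 0)
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a data frame as a TSV report
#' @param df Data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
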
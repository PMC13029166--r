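# Per-SNP quality control: counted-allele/minor allele frequencies, call
# rate, and the 1-df Pearson chi-square test of Hardy-Weinberg equilibrium.

#' Allele frequencies from a dosage matrix
#'
#' @param genotypes Integer matrix of 0/1/2 counted-allele dosages with
#'   `NA` for missing entries (individuals x SNPs).
#' @return Data frame with one row per SNP: `snp_id`, `n_called`,
#'   `call_rate`, `freq_counted` (unfolded counted-allele frequency),
#'   `maf` (folded, <= 0.5), `monomorphic`, `all_missing`.
#' @export
compute_maf <- function(genotypes) {
  stopifnot(is.matrix(genotypes))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  n_called <- colSums(!is.na(genotypes))
  freq <- colSums(genotypes, na.rm = TRUE) / (2 * pmax(n_called, 1))
  freq[n_called == 0] <- NA_real_
  data.frame(
    snp_id = colnames(genotypes),
    n_called = n_called,
    call_rate = n_called / nrow(genotypes),
    freq_counted = freq,
    maf = pmin(freq, 1 - freq),
    monomorphic = !is.na(freq) & (freq == 0 | freq == 1),
    all_missing = n_called == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts `(n0, n1, n2)` with the counts
#' expected at the estimated allele frequency under random mating
#' (`p^2, 2pq, q^2`), as a 1-df chi-square statistic without continuity
#' correction. Monomorphic samples are not testable.
#'
#' @param n0,n1,n2 Counts of the 0/1/2 dosage classes.
#' @return List with `chi2`, `p`, `testable` and the estimated
#'   counted-allele frequency `freq`.
#' @export
#' @examples
#' test_hwe(25, 50, 25)  # exact HWE proportions: chi2 = 0, p = 1
#' test_hwe(50, 0, 50)   # maximal heterozygote deficit: chi2 = 100
test_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) stop("need at least one genotype")
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = NA_real_, p = NA_real_, testable = FALSE, freq = p))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n0, n1, n2) - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       testable = TRUE, freq = p)
}

#' Per-SNP quality-control report
#'
#' Combines allele frequencies, call rate and the Hardy-Weinberg test into
#' one table with pass/fail flags. All-missing SNPs are excluded from the
#' report and listed in the `excluded` attribute with a reason.
#'
#' @param genotypes Dosage matrix.
#' @param hwe_alpha Hardy-Weinberg exclusion threshold on the chi-square
#'   p-value.
#' @param min_call_rate Minimum fraction of non-missing genotypes.
#' @param min_maf Minimum folded minor allele frequency; the default 0
#'   excludes only monomorphic SNPs.
#' @return A `qc_report` data frame: per SNP `maf`, `freq_counted`,
#'   `call_rate`, `hwe_chi2`, `hwe_p`, `pass`, `reason`.
#' @export
qc_report <- function(genotypes, hwe_alpha = 0.05, min_call_rate = 0.9,
                      min_maf = 0) {
  maf <- compute_maf(genotypes)
  excluded <- maf[maf$all_missing, "snp_id"]
  rep <- maf[!maf$all_missing, , drop = FALSE]
  hwe <- lapply(rep$snp_id, function(j) {
    g <- genotypes[, j]
    test_hwe(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 2, na.rm = TRUE))
  })
  rep$hwe_chi2 <- vapply(hwe, `[[`, numeric(1), "chi2")
  rep$hwe_p <- vapply(hwe, `[[`, numeric(1), "p")
  reason <- character(nrow(rep))
  add_reason <- function(which, msg) {
    ifelse(which, ifelse(reason == "", msg, paste(reason, msg, sep = ";")),
           reason)
  }
  reason <- add_reason(rep$monomorphic, "monomorphic")
  reason <- add_reason(!rep$monomorphic & rep$maf < min_maf, "low MAF")
  reason <- add_reason(rep$call_rate < min_call_rate, "low call rate")
  reason <- add_reason(!is.na(rep$hwe_p) & rep$hwe_p < hwe_alpha,
                       "HWE failure")
  rep$pass <- reason == ""
  rep$reason <- reason
  rep$all_missing <- NULL
  attr(rep, "excluded") <- excluded
  attr(rep, "thresholds") <- list(hwe_alpha = hwe_alpha,
                                  min_call_rate = min_call_rate,
                                  min_maf = min_maf)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Retained SNPs after quality-control filtering
#'
#' @param report A `qc_report`.
#' @return Character vector of passing SNP ids; errors if none pass.
#' @export
apply_qc_filters <- function(report) {
  retained <- report$snp_id[report$pass]
  if (length(retained) == 0) {
    stop("no SNPs pass quality control; check thresholds and genotypes")
  }
  retained
}
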
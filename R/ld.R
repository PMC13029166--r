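# Linkage disequilibrium from unphased genotypes: composite r-squared from
# dosage correlation, and |D'| from EM-estimated two-locus haplotype
# frequencies. Tag-SNP pruning collapses connected high-LD groups to the
# member explaining the most phenotype variance.

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Standard expectation-maximisation over the four haplotypes of a
#' biallelic SNP pair: all genotype combinations resolve haplotypes
#' unambiguously except the double heterozygote, whose cis/trans split is
#' re-estimated each iteration.
#'
#' @param tab 3x3 table of genotype counts (rows: SNP1 dosage 0/1/2,
#'   columns: SNP2 dosage 0/1/2).
#' @param tol Convergence tolerance on haplotype frequencies.
#' @param max_iter Iteration cap.
#' @return List with `h` (frequencies of haplotypes 11, 10, 01, 00 where 1
#'   is the counted allele), `converged`, `iterations`.
#' @export
em_haplotype_freqs <- function(tab, tol = 1e-8, max_iter = 1000) {
  stopifnot(all(dim(tab) == c(3, 3)))
  n <- sum(tab)
  p1 <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p2 <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  h <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  n_dh <- tab[2, 2]
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- h[1] * h[4] + h[2] * h[3]
    pc <- if (denom > 0) h[1] * h[4] / denom else 0.5
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + n_dh * pc
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + n_dh * (1 - pc)
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + n_dh * (1 - pc)
    c00 <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2] + n_dh * pc
    h_new <- c(c11, c10, c01, c00) / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(h = h, converged = converged, iterations = iter)
}

#' Pairwise linkage disequilibrium for one SNP pair
#'
#' `r2` is the squared Pearson correlation of the dosage codes (the
#' composite estimator appropriate for unphased data); `d_prime` is
#' `|D| / D_max` from EM-estimated haplotype frequencies.
#'
#' @param g1,g2 Dosage vectors for the two SNPs over the same individuals.
#' @param min_n Minimum pairwise-complete individuals (default 20).
#' @param tol,max_iter Passed to [em_haplotype_freqs()].
#' @return An `ld_estimate` list: `d_prime`, `r2`, `d`, `haplotype_freqs`,
#'   `em_converged`, `em_iterations`, `n_used`.
#' @export
#' @examples
#' g <- rbinom(100, 2, 0.4)
#' estimate_ld(g, g)$d_prime  # 1: identical dosages
estimate_ld <- function(g1, g2, min_n = 20, tol = 1e-8, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < min_n) {
    stop("need at least ", min_n, " pairwise-complete genotypes")
  }
  if (stats::var(g1) == 0 || stats::var(g2) == 0) {
    stop("both SNPs must be polymorphic in the pairwise-complete sample")
  }
  r2 <- stats::cor(g1, g2)^2
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  em <- em_haplotype_freqs(tab, tol = tol, max_iter = max_iter)
  if (!em$converged) {
    warning("EM for haplotype frequencies did not converge; D' approximate")
  }
  h <- em$h
  p1 <- h[1] + h[2]
  p2 <- h[1] + h[3]
  d <- h[1] - p1 * p2
  d_max <- if (d >= 0) {
    min(p1 * (1 - p2), (1 - p1) * p2)
  } else {
    min(p1 * p2, (1 - p1) * (1 - p2))
  }
  d_prime <- if (d_max > 0) abs(d) / d_max else 0
  structure(list(d_prime = min(d_prime, 1), r2 = r2, d = d,
                 haplotype_freqs = stats::setNames(h, c("11", "10", "01",
                                                        "00")),
                 em_converged = em$converged, em_iterations = em$iterations,
                 n_used = length(g1)),
            class = "ld_estimate")
}

#' Pairwise LD table for panel SNPs within a gene or chromosome
#'
#' Mirrors the analysis convention of assessing LD only among variants in
#' the same gene or on the same chromosome.
#'
#' @param genotypes Dosage matrix.
#' @param panel A `snp_panel` covering the matrix columns.
#' @param snp_ids Subset of SNPs to consider (default: all panel SNPs
#'   present in the matrix).
#' @param within `"gene_or_chromosome"` (default), `"gene"`, or `"all"`.
#' @param min_n Passed to [estimate_ld()].
#' @return Data frame with one row per tested pair: `snp_1`, `snp_2`,
#'   `gene_1`, `gene_2`, `d_prime`, `r2`, `em_converged`, `n_used`.
#' @export
ld_table <- function(genotypes, panel, snp_ids = NULL,
                     within = c("gene_or_chromosome", "gene", "all"),
                     min_n = 20) {
  within <- match.arg(within)
  if (is.null(snp_ids)) {
    snp_ids <- intersect(panel$snp_id, colnames(genotypes))
  }
  meta <- panel[match(snp_ids, panel$snp_id), ]
  rows <- list()
  if (length(snp_ids) >= 2) {
    for (i in seq_len(length(snp_ids) - 1)) {
      for (j in seq(i + 1, length(snp_ids))) {
        test <- switch(within,
          all = TRUE,
          gene = meta$gene[i] == meta$gene[j],
          gene_or_chromosome = meta$gene[i] == meta$gene[j] |
            meta$chromosome[i] == meta$chromosome[j])
        if (!isTRUE(test)) next
        est <- tryCatch(
          estimate_ld(genotypes[, snp_ids[i]], genotypes[, snp_ids[j]],
                      min_n = min_n),
          error = function(e) NULL)
        if (is.null(est)) next
        rows[[length(rows) + 1]] <- data.frame(
          snp_1 = snp_ids[i], snp_2 = snp_ids[j],
          gene_1 = meta$gene[i], gene_2 = meta$gene[j],
          d_prime = est$d_prime, r2 = est$r2,
          em_converged = est$em_converged, n_used = est$n_used,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(snp_1 = character(), snp_2 = character(),
                      gene_1 = character(), gene_2 = character(),
                      d_prime = numeric(), r2 = numeric(),
                      em_converged = logical(), n_used = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Collapse high-LD groups to tag SNPs
#'
#' Builds the graph of SNP pairs with `d_prime >= dprime_threshold`,
#' takes its connected components as LD groups, and keeps from each group
#' the member with the greatest phenotype variance explained (partial
#' R-squared from the per-SNP model). Ties are broken by larger minor
#' allele frequency, then lexicographic SNP id. Pairs whose two members
#' both carry a phenotype-specific panel assignment are exempt from
#' grouping (they are partitioned between phenotypes, not pruned).
#'
#' @param ld An [ld_table()] result.
#' @param variance_explained Named per-SNP partial R-squared for the
#'   target phenotype.
#' @param maf Named per-SNP folded MAF (tie-break); optional.
#' @param dprime_threshold High-LD threshold on D' (default 0.8).
#' @param exempt_pairs Data frame with columns `snp_1`, `snp_2` of pairs
#'   never grouped, or `NULL`.
#' @return List with `retained` (tag SNPs plus ungrouped SNPs present in
#'   `variance_explained`), `dropped`, and `groups` (list of data frames
#'   logging each group and the choice).
#' @export
prune_ld_groups <- function(ld, variance_explained, maf = NULL,
                            dprime_threshold = 0.8, exempt_pairs = NULL) {
  snps <- names(variance_explained)
  high <- ld[ld$d_prime >= dprime_threshold &
               ld$snp_1 %in% snps & ld$snp_2 %in% snps, , drop = FALSE]
  if (!is.null(exempt_pairs) && nrow(high) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    high <- high[!(key(high$snp_1, high$snp_2) %in%
                     key(exempt_pairs$snp_1, exempt_pairs$snp_2)), ,
                 drop = FALSE]
  }
  parent <- stats::setNames(seq_along(snps), snps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(high))) {
    a <- find(which(snps == high$snp_1[k]))
    b <- find(which(snps == high$snp_2[k]))
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(snps), find, integer(1))
  retained <- character()
  dropped <- character()
  groups <- list()
  for (cid in unique(comp)) {
    members <- snps[comp == cid]
    if (length(members) == 1) {
      retained <- c(retained, members)
      next
    }
    ve <- variance_explained[members]
    mf <- if (is.null(maf)) rep(0, length(members)) else maf[members]
    ord <- order(-ve, -mf, members)
    tag <- members[ord[1]]
    retained <- c(retained, tag)
    dropped <- c(dropped, setdiff(members, tag))
    groups[[length(groups) + 1]] <- data.frame(
      snp_id = members[ord], variance_explained = ve[ord],
      maf = mf[ord], tag = members[ord] == tag,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(retained = sort(retained), dropped = sort(dropped), groups = groups)
}
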
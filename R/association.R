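# Per-SNP general linear models: additive dosage fit for the effect size
# and its partial R-squared, a parallel genotype-as-category fit for
# least-squares means with Tukey-Kramer pairwise comparisons, risk-allele
# determination from the effect direction, and a SNP-SNP interaction scan.

#' Assess normality and transform a phenotype for analysis
#'
#' Shapiro-Wilk at `alpha`; if normality is rejected the natural log is
#' applied and recorded so reported means can be back-transformed
#' (geometric means).
#'
#' @param values Positive phenotype values (positivity required only when
#'   the log is applied).
#' @param transform Force `"log"` or `"identity"` instead of testing.
#' @param alpha Shapiro-Wilk rejection level.
#' @return List with `values` (analysis scale), `transform`, and
#'   `shapiro_p` (NA when forced).
#' @export
prepare_phenotype <- function(values, transform = NULL, alpha = 0.05) {
  shapiro_p <- NA_real_
  if (is.null(transform)) {
    x <- values[!is.na(values)]
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    shapiro_p <- stats::shapiro.test(x)$p.value
    transform <- if (shapiro_p < alpha) "log" else "identity"
  }
  transform <- match.arg(transform, c("log", "identity"))
  if (transform == "log") {
    if (any(values <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive values")
    }
    values <- log(values)
  }
  list(values = values, transform = transform, shapiro_p = shapiro_p)
}

#' Back-transform an analysis-scale mean
#' @param x Mean on the analysis scale.
#' @param transform `"log"` or `"identity"`.
#' @return Mean on the reporting scale (geometric mean for log fits).
#' @export
back_transform <- function(x, transform) {
  if (transform == "log") exp(x) else x
}

phenotype_column <- function(phenotype) {
  switch(phenotype, TG = "tg", HDL = "hdl")
}

model_frame <- function(phenotypes, genotypes, snp_ids, phenotype,
                        covariates, pcs = NULL, transform = NULL) {
  pcol <- phenotype_column(phenotype)
  df <- phenotypes[, c("individual_id", pcol, covariates), drop = FALSE]
  prep <- prepare_phenotype(df[[pcol]], transform = transform)
  df$y <- prep$values
  idx <- match(df$individual_id, rownames(genotypes))
  for (s in snp_ids) df[[s]] <- genotypes[idx, s]
  if (!is.null(pcs)) {
    pidx <- match(df$individual_id, rownames(pcs))
    for (k in seq_len(ncol(pcs))) df[[colnames(pcs)[k]]] <- pcs[pidx, k]
    covariates <- c(covariates, colnames(pcs))
  }
  df <- df[stats::complete.cases(df[, c("y", covariates, snp_ids)]), ,
           drop = FALSE]
  list(data = df, covariates = covariates, transform = prep$transform)
}

rhs_formula <- function(terms) {
  if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
}

# Partial R-squared of `term` as the Type-III sum of squares of the term
# over the corrected total SS, identical to the Delta-R-squared of the
# nested model pair.
partial_r2_term <- function(fit_full, fit_reduced, y) {
  ss_total <- sum((y - mean(y))^2)
  (sum(stats::resid(fit_reduced)^2) - sum(stats::resid(fit_full)^2)) /
    ss_total
}

#' Per-SNP general linear model
#'
#' Ordinary least squares of the (transformed) phenotype on the additive
#' dosage code plus covariates, on complete cases. The effect size, its
#' Wald p-value and partial R-squared come from the dosage fit; a parallel
#' fit with genotype as a 3-level factor provides least-squares means per
#' genotype class at covariate means and Tukey-Kramer-adjusted pairwise
#' comparisons.
#'
#' @param phenotypes Phenotype data frame with `individual_id`, the lipid
#'   columns `tg`/`hdl` (mg/dL) and all covariates.
#' @param genotypes Dosage matrix with individual ids as row names.
#' @param snp_id SNP to model (a column of `genotypes`).
#' @param phenotype `"TG"` or `"HDL"`.
#' @param covariates Covariate column names (default age and sex).
#' @param pcs Optional ancestry PC matrix (rownames = individual ids).
#' @param transform Force the phenotype transform; `NULL` tests normality.
#' @param ls_means Compute the categorical-genotype fit with LS means and
#'   Tukey-Kramer comparisons (default `TRUE`; disable for bulk
#'   simulation where only the dosage fit is needed).
#' @return A `snp_assoc` object: `beta_per_allele`, `se`, `p_value`,
#'   `ci` (normal-approximation 95%), `partial_r2`, `model_r2`,
#'   `ls_means` (per genotype class, analysis and response scale),
#'   `pairwise_p` (Tukey-Kramer), `freq_counted`, `n_used`, `transform`,
#'   `estimable`.
#' @export
fit_snp_model <- function(phenotypes, genotypes, snp_id,
                          phenotype = c("TG", "HDL"),
                          covariates = c("age", "sex"), pcs = NULL,
                          transform = NULL, ls_means = TRUE) {
  phenotype <- match.arg(phenotype)
  mf <- model_frame(phenotypes, genotypes, snp_id, phenotype, covariates,
                    pcs, transform)
  df <- mf$data
  out <- list(snp_id = snp_id, phenotype = phenotype,
              transform = mf$transform, n_used = nrow(df),
              estimable = FALSE)
  class(out) <- "snp_assoc"
  g <- df[[snp_id]]
  if (nrow(df) < length(mf$covariates) + 3 || length(unique(g)) < 2) {
    out$reason <- "monomorphic or insufficient data"
    return(out)
  }
  out$freq_counted <- mean(g) / 2
  fit <- stats::lm(stats::as.formula(
    paste("y ~", rhs_formula(c(snp_id, mf$covariates)))), data = df)
  fit0 <- stats::lm(stats::as.formula(
    paste("y ~", rhs_formula(mf$covariates))), data = df)
  sm <- summary(fit)
  co <- sm$coefficients[snp_id, ]
  out$estimable <- TRUE
  out$beta_per_allele <- unname(co["Estimate"])
  out$se <- unname(co["Std. Error"])
  out$p_value <- unname(co["Pr(>|t|)"])
  out$ci <- out$beta_per_allele +
    c(-1, 1) * stats::qnorm(0.975) * out$se
  out$model_r2 <- sm$r.squared
  out$partial_r2 <- partial_r2_term(fit, fit0, df$y)

  if (!ls_means) return(out)
  df$.geno <- factor(g, levels = sort(unique(g)))
  cfit <- stats::lm(stats::as.formula(
    paste("y ~ .geno +", rhs_formula(mf$covariates))), data = df)
  emm <- emmeans::emmeans(cfit, ".geno")
  es <- as.data.frame(summary(emm))
  out$ls_means <- data.frame(
    genotype = as.integer(as.character(es$.geno)),
    n = as.integer(table(df$.geno)),
    lsmean = es$emmean, se = es$SE,
    response = back_transform(es$emmean, mf$transform),
    stringsAsFactors = FALSE)
  pw <- summary(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "tukey"))
  out$pairwise_p <- data.frame(contrast = as.character(pw$contrast),
                               estimate = pw$estimate,
                               p_tukey = pw$p.value,
                               stringsAsFactors = FALSE)
  out
}

#' Determine the phenotype-specific risk allele
#'
#' For triglycerides the risk allele is the one whose higher dosage class
#' has the higher adjusted mean (equivalently, the counted allele when the
#' additive effect is positive); for HDL-C it is the allele associated
#' with the lower adjusted mean. A zero effect is flagged ambiguous and
#' the minor allele is assigned with a warning.
#'
#' @param assoc A fitted `snp_assoc`.
#' @param counted_allele,other The SNP's counted and non-counted allele
#'   codes.
#' @return The `snp_assoc` with `risk_allele`, `risk_is_counted`, and
#'   `risk_ambiguous` filled in.
#' @export
determine_risk_allele <- function(assoc, counted_allele, other) {
  stopifnot(inherits(assoc, "snp_assoc"), assoc$estimable)
  b <- assoc$beta_per_allele
  if (b == 0) {
    warning("effect exactly zero for ", assoc$snp_id,
            "; assigning minor allele as risk allele")
    assoc$risk_ambiguous <- TRUE
    assoc$risk_is_counted <- assoc$freq_counted <= 0.5
  } else {
    assoc$risk_ambiguous <- FALSE
    assoc$risk_is_counted <- if (assoc$phenotype == "TG") b > 0 else b < 0
  }
  assoc$risk_allele <- if (assoc$risk_is_counted) counted_allele else other
  assoc
}

#' Fit per-SNP models for a set of SNPs
#'
#' @param phenotypes,genotypes,phenotype,covariates,pcs,transform As in
#'   [fit_snp_model()].
#' @param panel A `snp_panel` providing alleles and pathway annotation.
#' @param snp_ids SNPs to fit (default: panel SNPs present in the matrix).
#' @return List with `fits` (named `snp_assoc` list) and `summary` (one
#'   row per estimable SNP: effect, p, partial R-squared, risk allele).
#' @export
snp_association_table <- function(phenotypes, genotypes, panel,
                                  phenotype = c("TG", "HDL"),
                                  covariates = c("age", "sex"),
                                  snp_ids = NULL, pcs = NULL,
                                  transform = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(snp_ids)) {
    snp_ids <- intersect(panel$snp_id, colnames(genotypes))
  }
  oth <- other_allele(panel)
  fits <- list()
  rows <- list()
  for (s in snp_ids) {
    a <- fit_snp_model(phenotypes, genotypes, s, phenotype, covariates,
                       pcs, transform)
    if (a$estimable) {
      meta <- panel[panel$snp_id == s, ]
      a <- determine_risk_allele(a, meta$counted_allele, oth[[s]])
      rows[[s]] <- data.frame(
        snp_id = s, gene = meta$gene, pathway = meta$pathway,
        phenotype = phenotype, transform = a$transform,
        beta_per_allele = a$beta_per_allele, se = a$se,
        p_value = a$p_value, partial_r2 = a$partial_r2,
        risk_allele = a$risk_allele, risk_is_counted = a$risk_is_counted,
        n_used = a$n_used, stringsAsFactors = FALSE)
    }
    fits[[s]] <- a
  }
  summary <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else NULL
  list(fits = fits, summary = summary)
}

#' SNP-SNP interaction scan
#'
#' For each pair, fits the phenotype on both dosage main effects plus
#' their product (with covariates) and reports the Wald p-value of the
#' product term. Pairs whose dosage correlation exceeds the collinearity
#' bound are flagged and skipped.
#'
#' @param phenotypes,genotypes,phenotype,covariates,transform As in
#'   [fit_snp_model()].
#' @param pairs Two-column matrix or data frame of SNP id pairs; default
#'   all pairs of `snp_ids`.
#' @param snp_ids SNPs entering the default pair set.
#' @param r2_collinear Dosage r-squared above which a pair is skipped.
#' @return Data frame: `snp_1`, `snp_2`, `interaction_beta`,
#'   `interaction_p`, `n_used`, `skipped`, `reason`.
#' @export
scan_interactions <- function(phenotypes, genotypes,
                              phenotype = c("TG", "HDL"),
                              covariates = c("age", "sex"),
                              pairs = NULL, snp_ids = NULL,
                              r2_collinear = 0.9, transform = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(pairs)) {
    if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
    pairs <- t(utils::combn(snp_ids, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    s1 <- pairs[k, 1]; s2 <- pairs[k, 2]
    mf <- model_frame(phenotypes, genotypes, c(s1, s2), phenotype,
                      covariates, transform = transform)
    df <- mf$data
    row <- data.frame(snp_1 = s1, snp_2 = s2,
                      interaction_beta = NA_real_,
                      interaction_p = NA_real_, n_used = nrow(df),
                      skipped = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    r2 <- if (stats::var(df[[s1]]) > 0 && stats::var(df[[s2]]) > 0) {
      stats::cor(df[[s1]], df[[s2]])^2
    } else 1
    if (r2 >= r2_collinear) {
      row$skipped <- TRUE
      row$reason <- "collinear"
    } else {
      fml <- stats::as.formula(paste(
        "y ~", s1, "*", s2, "+", rhs_formula(mf$covariates)))
      fit <- stats::lm(fml, data = df)
      term <- paste0(s1, ":", s2)
      sm <- summary(fit)$coefficients
      if (term %in% rownames(sm) && !is.na(sm[term, "Estimate"])) {
        row$interaction_beta <- sm[term, "Estimate"]
        row$interaction_p <- sm[term, "Pr(>|t|)"]
      } else {
        row$skipped <- TRUE
        row$reason <- "interaction not estimable"
      }
    }
    rows[[k]] <- row
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
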
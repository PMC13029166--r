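# GRS-phenotype models: OLS with covariate sets, model and GRS-term
# variance decomposition, the "not calculated" reporting convention,
# high/low risk-group t-tests, sex stratification, and triglyceride
# category classification.

#' GRS-phenotype general linear model
#'
#' Ordinary least squares of the (transformed) phenotype on the score plus
#' covariates, on complete cases. Reports the overall model F-test p-value
#' and R-squared, the score term's Wald p-value, its effect per unit score
#' with a normal-approximation 95% CI, and the partial R-squared of the
#' score (the increment over the covariate-only model, identical to the
#' Type-III SS of the score over the corrected total SS). Percent
#' variability explained is `100 * R2`; the GRS percent is reported only
#' when the score term is significant at `nc_alpha` (the "not calculated"
#' convention) — the raw partial R-squared is always present.
#'
#' @param phenotypes Phenotype data frame.
#' @param grs A `grs_vector` (or data frame with `individual_id`, `score`).
#' @param phenotype `"TG"` or `"HDL"`.
#' @param covariates Covariate column names.
#' @param pcs Optional ancestry PC matrix (rownames = individual ids).
#' @param transform Force the phenotype transform; `NULL` tests normality.
#' @param nc_alpha Significance level gating the reported GRS percent.
#' @return A `grs_assoc` object.
#' @export
fit_grs_model <- function(phenotypes, grs, phenotype = c("TG", "HDL"),
                          covariates = c("age", "sex"), pcs = NULL,
                          transform = NULL, nc_alpha = 0.05) {
  phenotype <- match.arg(phenotype)
  pcol <- phenotype_column(phenotype)
  df <- phenotypes[, c("individual_id", pcol, covariates), drop = FALSE]
  prep <- prepare_phenotype(df[[pcol]], transform = transform)
  df$y <- prep$values
  df$score <- grs$score[match(df$individual_id, grs$individual_id)]
  if (!is.null(pcs)) {
    pidx <- match(df$individual_id, rownames(pcs))
    for (k in seq_len(ncol(pcs))) df[[colnames(pcs)[k]]] <- pcs[pidx, k]
    covariates <- c(covariates, colnames(pcs))
  }
  df <- df[stats::complete.cases(df[, c("y", "score", covariates)]), ,
           drop = FALSE]
  if (nrow(df) < length(covariates) + 3) stop("too few complete cases")
  if (stats::var(df$score) == 0) stop("constant score")
  fit <- stats::lm(stats::as.formula(
    paste("y ~ score +", rhs_formula(covariates))), data = df)
  fit0 <- stats::lm(stats::as.formula(
    paste("y ~", rhs_formula(covariates))), data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  co <- sm$coefficients["score", ]
  grs_p <- unname(co["Pr(>|t|)"])
  partial <- partial_r2_term(fit, fit0, df$y)
  out <- list(
    definition = attr(grs, "definition"),
    phenotype = phenotype, transform = prep$transform,
    covariates = covariates,
    model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    model_r2 = sm$r.squared,
    beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
    ci = unname(co["Estimate"]) +
      c(-1, 1) * stats::qnorm(0.975) * unname(co["Std. Error"]),
    grs_p = grs_p,
    grs_partial_r2 = partial,
    pct_model = 100 * sm$r.squared,
    pct_grs = if (grs_p < nc_alpha) 100 * partial else NA_real_,
    n_used = nrow(df))
  class(out) <- "grs_assoc"
  out
}

#' @export
print.grs_assoc <- function(x, ...) {
  def <- x$definition
  scope <- if (is.null(def)) "?" else paste(def$scope, def$weighting)
  cat(sprintf("GRS model: %s ~ %s [%s]\n", x$phenotype, scope,
              paste(x$covariates, collapse = "+")))
  cat(sprintf("  model p = %.4g, model R2 = %.4f\n", x$model_p, x$model_r2))
  cat(sprintf("  GRS beta = %.4g (95%% CI %.4g, %.4g), p = %.4g\n",
              x$beta, x$ci[1], x$ci[2], x$grs_p))
  cat(sprintf("  %% variability explained by GRS = %s\n",
              if (is.na(x$pct_grs)) "NC" else sprintf("%.2f", x$pct_grs)))
  invisible(x)
}

#' Compare phenotype concentrations between risk groups
#'
#' Two-sample Student's t-test on the analysis (possibly log) scale; group
#' means and standard errors are back-transformed for log phenotypes
#' (geometric means, delta-method SEs).
#'
#' @param phenotypes Phenotype data frame.
#' @param grs A `grs_vector` with a `risk_group` column (see
#'   [assign_risk_groups()]).
#' @param phenotype `"TG"` or `"HDL"`.
#' @param transform Force the phenotype transform; `NULL` tests normality.
#' @return A `risk_group_comparison` list: per-group `n`, `mean`, `se`
#'   (reporting scale), the analysis-scale mean difference, and `t_p`.
#' @export
compare_risk_groups <- function(phenotypes, grs,
                                phenotype = c("TG", "HDL"),
                                transform = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(grs$risk_group)) stop("assign risk groups first")
  pcol <- phenotype_column(phenotype)
  prep <- prepare_phenotype(phenotypes[[pcol]], transform = transform)
  y <- prep$values
  grp <- grs$risk_group[match(phenotypes$individual_id,
                              grs$individual_id)]
  ok <- !is.na(y) & !is.na(grp)
  y <- y[ok]; grp <- grp[ok]
  tab <- table(factor(grp, levels = c("high", "low")))
  if (any(tab < 2)) stop("each risk group needs at least 2 members")
  tt <- stats::t.test(y[grp == "high"], y[grp == "low"], var.equal = TRUE)
  summarize <- function(v) {
    m <- mean(v); se <- stats::sd(v) / sqrt(length(v))
    if (prep$transform == "log") {
      c(mean = exp(m), se = exp(m) * se)
    } else c(mean = m, se = se)
  }
  hi <- summarize(y[grp == "high"])
  lo <- summarize(y[grp == "low"])
  structure(list(
    phenotype = phenotype, transform = prep$transform,
    groups = data.frame(
      risk_group = c("high", "low"),
      n = c(sum(grp == "high"), sum(grp == "low")),
      mean = c(hi["mean"], lo["mean"]),
      se = c(hi["se"], lo["se"]), row.names = NULL),
    diff_analysis_scale = unname(diff(rev(tt$estimate))),
    t_p = tt$p.value), class = "risk_group_comparison")
}

#' Sex-stratified GRS models
#'
#' Refits the GRS model within each sex stratum with sex dropped from the
#' covariates. Strata below `min_n` individuals are skipped with a
#' warning.
#'
#' @param phenotypes,grs,phenotype,covariates,pcs,transform As in
#'   [fit_grs_model()].
#' @param sex_column Name of the binary sex indicator column.
#' @param min_n Minimum stratum size.
#' @return Named list (`"0"`, `"1"`) of `grs_assoc` objects (absent
#'   strata skipped).
#' @export
stratify_by_sex <- function(phenotypes, grs, phenotype = c("TG", "HDL"),
                            covariates = c("age", "sex"), pcs = NULL,
                            transform = NULL, sex_column = "sex",
                            min_n = 30) {
  phenotype <- match.arg(phenotype)
  covariates <- setdiff(covariates, sex_column)
  if (length(covariates) == 0) stop("no covariates left after dropping sex")
  out <- list()
  for (s in sort(unique(phenotypes[[sex_column]]))) {
    sub <- phenotypes[phenotypes[[sex_column]] == s, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("sex stratum ", s, " below n = ", min_n, "; skipped")
      next
    }
    out[[as.character(s)]] <-
      fit_grs_model(sub, grs, phenotype, covariates, pcs, transform)
  }
  out
}

#' Classify triglyceride concentration into metabolic-risk categories
#'
#' Half-open guideline bands: below 90 mg/dL "Optimal"; 90 to below 130
#' "Early metabolic risk"; 130 to below 150 "Borderline metabolic risk";
#' 150 and above "Clinical hypertriglyceridemia".
#'
#' @param tg Triglyceride concentrations in mg/dL (all > 0).
#' @return Factor with the four ordered category labels.
#' @export
#' @examples
#' classify_tg_category(c(89.9, 90, 129.9, 130, 150))
classify_tg_category <- function(tg) {
  if (any(is.na(tg)) || any(tg <= 0)) {
    stop("triglyceride values must be positive and non-missing")
  }
  cut(tg, breaks = c(0, 90, 130, 150, Inf), right = FALSE,
      labels = c("Optimal", "Early metabolic risk",
                 "Borderline metabolic risk",
                 "Clinical hypertriglyceridemia"))
}

#' Tabulate GRS model results in the report layout
#'
#' One row per scope x phenotype x weighting x covariate set, with the
#' "NC" convention applied to the GRS percent column.
#'
#' @param models List of `grs_assoc` objects.
#' @return Data frame with character `pct_grs` (`"NC"` when suppressed).
#' @export
format_grs_table <- function(models) {
  rows <- lapply(models, function(m) {
    def <- m$definition
    data.frame(
      scope = if (is.null(def)) NA_character_ else def$scope,
      weighting = if (is.null(def)) NA_character_ else def$weighting,
      phenotype = m$phenotype,
      covariates = paste(m$covariates, collapse = "+"),
      model_p = m$model_p,
      pct_model = round(m$pct_model, 2),
      grs_p = m$grs_p,
      pct_grs = if (is.na(m$pct_grs)) "NC" else
        sprintf("%.2f", m$pct_grs),
      beta = m$beta, ci_low = m$ci[1], ci_high = m$ci[2],
      n_used = m$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
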
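cohort_total_grs <- function(cohort, phenotype = "TG") {
  panel <- load_snp_panel()
  tab <- snp_association_table(cohort$phenotypes, cohort$genotypes,
                               panel, phenotype,
                               transform = if (phenotype == "TG") "log"
                               else "identity")
  members <- reported_grs_members(panel, phenotype)
  def <- build_pathway_definition(tab$summary, "TOTAL", members,
                                  "additive")
  assign_risk_groups(build_grs(cohort$genotypes, def, panel))
}

test_that("GRS model decomposes variance consistently with the nested-model oracle", {
  cohort <- default_cohort()
  grs <- cohort_total_grs(cohort, "TG")
  m <- fit_grs_model(cohort$phenotypes, grs, "TG", transform = "log")
  df <- cohort$phenotypes
  df$y <- log(df$tg)
  df$score <- grs$score[match(df$individual_id, grs$individual_id)]
  df <- df[stats::complete.cases(df[, c("y", "score", "age", "sex")]), ]
  expect_equal(m$grs_partial_r2,
               delta_r2_oracle(df, "y", "score", c("age", "sex")),
               tolerance = 1e-10)
  expect_lte(m$grs_partial_r2, m$model_r2)
  expect_true(m$ci[1] < m$beta && m$beta < m$ci[2])
  expect_equal(m$n_used, nrow(df))

  # adding BMI cannot reduce the model R2 on the same sample
  m_bmi <- fit_grs_model(cohort$phenotypes, grs, "TG",
                         covariates = c("age", "sex", "bmi"),
                         transform = "log")
  expect_gte(m_bmi$model_r2, m$model_r2 - 1e-12)
})

test_that("the NC convention suppresses the GRS percent for non-significant scores", {
  cohort <- default_cohort()
  set.seed(55)
  null_grs <- structure(
    data.frame(individual_id = cohort$phenotypes$individual_id,
               score = rnorm(nrow(cohort$phenotypes)),
               n_missing_members = 0L),
    class = c("grs_vector", "data.frame"))
  m <- fit_grs_model(cohort$phenotypes, null_grs, "TG",
                     transform = "log")
  # a pure-noise score is (almost surely for this seed) non-significant
  expect_gt(m$grs_p, 0.05)
  expect_true(is.na(m$pct_grs))
  tab <- format_grs_table(list(m))
  expect_identical(tab$pct_grs, "NC")

  const <- null_grs
  const$score <- 1
  expect_error(fit_grs_model(cohort$phenotypes, const, "TG",
                             transform = "log"), "constant score")
})

test_that("risk-group t-test equals the indicator regression", {
  cohort <- default_cohort()
  grs <- cohort_total_grs(cohort, "TG")
  cmp <- compare_risk_groups(cohort$phenotypes, grs, "TG",
                             transform = "log")
  df <- cohort$phenotypes
  df$y <- log(df$tg)
  df$grp <- grs$risk_group[match(df$individual_id, grs$individual_id)]
  df <- df[!is.na(df$grp), ]
  lm_p <- summary(stats::lm(y ~ grp, data = df))$coefficients[2, 4]
  expect_equal(cmp$t_p, lm_p, tolerance = 1e-10)
  # groups are disjoint and exhaustive over analyzed individuals
  expect_equal(sum(cmp$groups$n), nrow(df))
  # geometric means on the reporting scale
  gm_high <- exp(mean(df$y[df$grp == "high"]))
  expect_equal(cmp$groups$mean[cmp$groups$risk_group == "high"], gm_high,
               tolerance = 1e-10)
  expect_error(
    compare_risk_groups(cohort$phenotypes,
                        data.frame(individual_id = "I0001", score = 1),
                        "TG"),
    "assign risk groups")
})

test_that("sex strata partition the sample and drop the sex covariate", {
  cohort <- default_cohort()
  grs <- cohort_total_grs(cohort, "TG")
  strata <- stratify_by_sex(cohort$phenotypes, grs, "TG",
                            transform = "log")
  expect_named(strata, c("0", "1"))
  pooled <- fit_grs_model(cohort$phenotypes, grs, "TG",
                          transform = "log")
  expect_equal(strata[["0"]]$n_used + strata[["1"]]$n_used,
               pooled$n_used)
  expect_false(any(vapply(strata, function(m) "sex" %in% m$covariates,
                          logical(1))))
  # homogeneous effect: both strata agree with the pooled fit within 2 SE
  for (m in strata) {
    expect_lt(abs(m$beta - pooled$beta), 2 * (m$se + pooled$se))
  }
  small <- cohort$phenotypes
  small <- small[c(which(small$sex == 0)[1:5], which(small$sex == 1)), ]
  expect_warning(stratify_by_sex(small, grs, "TG", transform = "log"),
                 "skipped")
})

test_that("triglyceride categories use half-open guideline bands", {
  got <- classify_tg_category(c(89.9, 90, 129.9, 130, 149.9, 150, 300))
  expect_equal(as.character(got),
               c("Optimal", "Early metabolic risk",
                 "Early metabolic risk", "Borderline metabolic risk",
                 "Borderline metabolic risk",
                 "Clinical hypertriglyceridemia",
                 "Clinical hypertriglyceridemia"))
  expect_error(classify_tg_category(c(100, 0)), "positive")
  expect_error(classify_tg_category(c(100, NA)), "positive")
})
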
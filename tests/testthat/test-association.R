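test_that("phenotype preparation detects and records the transform", {
  set.seed(10)
  ln <- exp(rnorm(400, 4.6, 0.4))
  nm <- rnorm(400, 50, 10)
  expect_identical(prepare_phenotype(ln)$transform, "log")
  expect_identical(prepare_phenotype(nm)$transform, "identity")
  expect_error(prepare_phenotype(c(-1, 2, 3), transform = "log"),
               "positive")
  # back-transform of a log-scale mean of constants is the constant
  prep <- prepare_phenotype(rep(100, 10), transform = "log")
  expect_equal(back_transform(mean(prep$values), "log"), 100)
})

test_that("per-SNP model recovers a simulated effect and its partial R2 equals the nested-model oracle", {
  cohort <- default_cohort()
  fit <- fit_snp_model(cohort$phenotypes, cohort$genotypes, "rs2286276",
                       phenotype = "TG", transform = "log")
  expect_true(fit$estimable)
  truth <- default_snp_effects()$log_tg[["rs2286276"]]
  expect_lt(abs(fit$beta_per_allele - truth), 2 * fit$se)
  expect_true(fit$ci[1] < fit$beta_per_allele &&
                fit$beta_per_allele < fit$ci[2])

  df <- oracle_frame(cohort, "rs2286276", "TG")
  expect_equal(fit$partial_r2,
               delta_r2_oracle(df, "y", "g", c("age", "sex")),
               tolerance = 1e-10)
  expect_equal(fit$n_used, nrow(df))
})

test_that("LS means reduce to raw class means without covariates and back-transform to geometric means", {
  cohort <- default_cohort()
  fit <- fit_snp_model(cohort$phenotypes, cohort$genotypes, "rs1532624",
                       phenotype = "TG", covariates = character(0),
                       transform = "log")
  df <- oracle_frame(cohort, "rs1532624", "TG")
  raw <- as.vector(tapply(df$y, df$g, mean))
  expect_equal(fit$ls_means$lsmean, raw, tolerance = 1e-10)
  expect_equal(fit$ls_means$response, exp(raw), tolerance = 1e-10)
  expect_equal(nrow(fit$pairwise_p), choose(nrow(fit$ls_means), 2))
  expect_true(all(fit$pairwise_p$p_tukey >= 0 &
                    fit$pairwise_p$p_tukey <= 1))
})

test_that("risk alleles follow the phenotype-specific direction rule", {
  cohort <- default_cohort()
  panel <- load_snp_panel()
  oth <- other_allele(panel)

  # TG: positive effect per counted allele means counted allele is risk
  fit_tg <- fit_snp_model(cohort$phenotypes, cohort$genotypes,
                          "rs2286276", "TG", transform = "log")
  fit_tg <- determine_risk_allele(
    fit_tg, panel$counted_allele[panel$snp_id == "rs2286276"],
    oth[["rs2286276"]])
  expect_true(fit_tg$risk_is_counted)
  expect_identical(fit_tg$risk_allele, "G")

  # HDL: negative effect per counted allele means counted allele is risk
  fit_hdl <- fit_snp_model(cohort$phenotypes, cohort$genotypes,
                           "rs9282541", "HDL", transform = "identity")
  fit_hdl <- determine_risk_allele(
    fit_hdl, panel$counted_allele[panel$snp_id == "rs9282541"],
    oth[["rs9282541"]])
  expect_true(fit_hdl$risk_is_counted)

  # direction reversal: a positive HDL effect makes the OTHER allele risk
  flipped <- fit_hdl
  flipped$beta_per_allele <- abs(flipped$beta_per_allele)
  flipped <- determine_risk_allele(flipped, "T", "C")
  expect_false(flipped$risk_is_counted)
  expect_identical(flipped$risk_allele, "C")

  # exact zero effect: ambiguous, minor allele assigned with warning
  zero <- fit_hdl
  zero$beta_per_allele <- 0
  expect_warning(zero <- determine_risk_allele(zero, "T", "C"),
                 "minor allele")
  expect_true(zero$risk_ambiguous)
})

test_that("allele recoding flips the sign but not inference", {
  cohort <- default_cohort()
  g <- cohort$genotypes
  g2 <- g
  g2[, "rs2286276"] <- 2L - g2[, "rs2286276"]
  f1 <- fit_snp_model(cohort$phenotypes, g, "rs2286276", "TG",
                      transform = "log")
  f2 <- fit_snp_model(cohort$phenotypes, g2, "rs2286276", "TG",
                      transform = "log")
  expect_equal(f2$beta_per_allele, -f1$beta_per_allele, tolerance = 1e-10)
  expect_equal(f2$se, f1$se, tolerance = 1e-10)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-10)
  expect_equal(f2$partial_r2, f1$partial_r2, tolerance = 1e-10)
  # risk allele identity is unchanged once the coding is accounted for
  f1 <- determine_risk_allele(f1, "G", "C")
  f2 <- determine_risk_allele(f2, "C", "G")  # counted allele now C
  expect_identical(f1$risk_allele, f2$risk_allele)
})

test_that("null per-SNP p-values are uniform", {
  n <- 250
  set.seed(314)
  freqs <- stats::setNames(runif(400, 0.1, 0.5), sprintf("n%03d", 1:400))
  cfg <- cohort_config(n = n, seed = 314, allele_freqs = freqs,
                       ld_blocks = list(), snp_effects = list(),
                       missing_rate = 0)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  pvals <- vapply(colnames(g), function(s) {
    fit_snp_model(ph, g, s, "TG", transform = "log",
                  ls_means = FALSE)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("association table assembles per-SNP results with pathway annotation", {
  cohort <- default_cohort()
  panel <- load_snp_panel()
  tab <- snp_association_table(cohort$phenotypes, cohort$genotypes,
                               panel, "TG", transform = "log")
  expect_equal(sort(tab$summary$snp_id),
               sort(intersect(panel$snp_id, colnames(cohort$genotypes))))
  expect_true(all(tab$summary$partial_r2 >= 0))
  expect_true(all(tab$summary$risk_allele %in%
                    c(panel$allele_a, panel$allele_b)))
})

test_that("interaction scan flags collinear pairs and detects a product effect", {
  cohort <- default_cohort()
  g <- cohort$genotypes[, c("rs1532624", "rs5882")]
  g <- cbind(g, dup = g[, "rs1532624"])
  res <- scan_interactions(cohort$phenotypes, g, "TG",
                           pairs = rbind(c("rs1532624", "dup"),
                                         c("rs1532624", "rs5882")),
                           transform = "log")
  expect_true(res$skipped[1])
  expect_identical(res$reason[1], "collinear")
  expect_false(res$skipped[2])

  # planted product effect on log TG
  set.seed(99)
  n <- 500
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  ids <- sprintf("I%04d", 1:n)
  gm <- cbind(a = g1, b = g2)
  rownames(gm) <- ids
  ph <- data.frame(individual_id = ids, age = rnorm(n, 19, 1),
                   sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 23, 4),
                   tg = exp(4.6 + 0.15 * g1 * g2 + rnorm(n, 0, 0.4)),
                   hdl = rnorm(n, 50, 10))
  res2 <- scan_interactions(ph, gm, "TG", pairs = cbind("a", "b"),
                            transform = "log")
  expect_lt(res2$interaction_p, 0.05)
  expect_gt(res2$interaction_beta, 0)
})
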
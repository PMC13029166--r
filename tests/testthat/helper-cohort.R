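# Shared fixtures: one default synthetic cohort reused across test files,
# and an independent Delta-R-squared oracle built from two explicit lm fits.

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(cohort_config(n = 400,
                                                         seed = 2024))
  }
  .fixture_env$cohort
}

# R-squared increment of `term` over the covariate-only model, computed
# from scratch with two lm fits (independent of the package's internal
# partial R-squared route).
delta_r2_oracle <- function(data, response, term, covariates) {
  rhs0 <- if (length(covariates)) covariates else "1"
  f1 <- stats::lm(stats::reformulate(c(term, covariates), response),
                  data = data)
  f0 <- stats::lm(stats::reformulate(rhs0, response), data = data)
  summary(f1)$r.squared - summary(f0)$r.squared
}

# assemble a phenotype frame joined with one SNP's dosages, on the
# analysis (log for TG) scale, for oracle fits
oracle_frame <- function(cohort, snp_id, phenotype = "TG") {
  ph <- cohort$phenotypes
  ph$y <- if (phenotype == "TG") log(ph$tg) else ph$hdl
  ph$g <- cohort$genotypes[match(ph$individual_id,
                                 rownames(cohort$genotypes)), snp_id]
  ph[stats::complete.cases(ph[, c("y", "g", "age", "sex")]), ]
}
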
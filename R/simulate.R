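# Synthetic cohort generator: genotypes at panel frequencies (with optional
# LD blocks and two-way admixture), AIMs genotypes, and lipid phenotypes
# with configurable additive SNP effects. The generator realizes the model
# the analysis fits, so parameter recovery and calibration are testable.

#' Default LD blocks emulating the panel's reported haplotype structure
#'
#' Three blocks with one absent recombinant haplotype each (|D'| = 1 between
#' every within-block pair): the ANGPTL4 trio, the CD36 pair, and the ABCA1
#' pair. Haplotype frequencies are chosen so marginal counted-allele
#' frequencies match the cohort column of the packaged panel; the ABCA1
#' block places the two counted alleles on opposite haplotypes so that
#' D' = 1 coexists with a small r-squared, as observed for that pair.
#'
#' @param panel A `snp_panel`.
#' @return List of blocks, each `list(snp_ids, haplotypes, freqs)` where
#'   `haplotypes` is a 0/1 matrix (rows = haplotypes, columns = SNPs,
#'   1 = counted allele).
#' @export
default_ld_blocks <- function(panel = load_snp_panel()) {
  list(
    list(snp_ids = c("rs1044250", "rs2278236", "rs7255436"),
         haplotypes = rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)),
         freqs = c(0.40, 0.08, 0.01, 0.51)),
    list(snp_ids = c("rs10499859", "rs1527483"),
         haplotypes = rbind(c(1, 1), c(1, 0), c(0, 0)),
         freqs = c(0.12, 0.36, 0.52)),
    list(snp_ids = c("rs4149310", "rs9282541"),
         haplotypes = rbind(c(1, 0), c(0, 1), c(0, 0)),
         freqs = c(0.38, 0.10, 0.52))
  )
}

#' Default per-SNP phenotype effects for the synthetic cohort
#'
#' Additive effects per copy of the counted (risk) allele. Triglyceride
#' effects act on the natural-log scale; HDL-C effects on mg/dL. The
#' defaults concentrate TG signal in CETP/MLXIPL variants and HDL-C signal
#' in ABCA1-rs9282541, mirroring the association pattern the pipeline is
#' designed to detect; magnitudes are plausible small effects for common
#' lipid variants, not published estimates.
#'
#' @return List with named numeric vectors `log_tg` and `hdl`.
#' @export
default_snp_effects <- function() {
  list(
    log_tg = c(rs1532624 = 0.06, rs5882 = 0.04, rs2286276 = 0.07,
               rs1800588 = 0.03, rs12639162 = 0.03, rs4149310 = 0.04),
    hdl = c(rs9282541 = -4.0, rs289714 = -1.2, rs1800588 = -1.0,
            rs12678919 = -1.5)
  )
}

#' Default covariate effects for the synthetic cohort
#' @return List with vectors `log_tg` and `hdl`, each giving `age`, `sex`
#'   (indicator, 1 = female) and `bmi` slopes.
#' @export
default_covariate_effects <- function() {
  list(
    log_tg = c(age = 0.005, sex = -0.04, bmi = 0.018),
    hdl = c(age = -0.1, sex = 4.0, bmi = -0.45)
  )
}

#' Default ancestry-informative-marker design
#'
#' 64 AIMs with strongly differentiated frequencies between two ancestral
#' populations, and a Beta(3, 2) distribution of individual admixture
#' proportions. The frequency pairs are design constants generated once
#' from a fixed stream so the marker set does not vary with the cohort
#' seed.
#'
#' @param n_aims Number of markers (>= 2).
#' @return List with `n_aims`, `p1`, `p2` (per-AIM ancestral frequencies)
#'   and `beta_shape` (admixture Beta parameters).
#' @export
default_admixture <- function(n_aims = 64) {
  if (n_aims < 2) stop("n_aims must be >= 2")
  rs <- local({
    set.seed(104729)
    list(p1 = stats::runif(n_aims, 0.75, 0.95),
         p2 = stats::runif(n_aims, 0.05, 0.25))
  })
  list(n_aims = n_aims, p1 = rs$p1, p2 = rs$p2, beta_shape = c(3, 2))
}

#' Configuration for the synthetic cohort
#'
#' Collects every tunable of the generator with defaults set to the study
#' conditions the package emulates: n = 580 individuals, counted-allele
#' frequencies from the cohort column of the packaged panel, the reported
#' LD-block structure, 54% female, age ~ Normal(18.9, 0.9) truncated to
#' [18, 25], BMI ~ Normal(23.6, 4.0) truncated positive, log-normal TG and
#' normal HDL-C residuals.
#'
#' One global `seed` governs all draws through a fixed stream-splitting
#' rule: genotypes use `seed + 1`, AIMs `seed + 2`, phenotypes `seed + 3`,
#' admixture proportions `seed + 4`, and missingness `seed + 5`.
#'
#' @param n Number of individuals.
#' @param panel A `snp_panel`.
#' @param allele_freqs Named counted-allele frequencies in (0, 1); defaults
#'   to the panel's `maf_cohort`.
#' @param ld_blocks List of LD blocks (see [default_ld_blocks()]); use
#'   `list()` for fully independent SNPs.
#' @param snp_effects List with `log_tg`/`hdl` named effect vectors.
#' @param covariate_effects List with `log_tg`/`hdl` covariate slopes.
#' @param intercepts Named vector `c(log_tg=, hdl=)`.
#' @param noise_sd Named residual SDs `c(log_tg=, hdl=)`, both > 0.
#' @param female_prevalence Probability an individual is female.
#' @param age_mean,age_sd,age_range Truncated-normal age parameters.
#' @param bmi_mean,bmi_sd Truncated-normal (positive) BMI parameters.
#' @param admixture AIMs design from [default_admixture()].
#' @param confounding `NULL`, or `list(freq_delta=, pheno_shift=c(log_tg=,
#'   hdl=))`: panel allele frequencies become ancestry-dependent
#'   (`freq +/- freq_delta/2` in the two ancestral populations) and the
#'   phenotype means shift linearly in the admixture proportion, creating
#'   population-stratification confounding for type-I-error experiments.
#' @param missing_rate Per-entry genotype missingness probability in [0, 1).
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 580,
                          panel = load_snp_panel(),
                          allele_freqs = NULL,
                          ld_blocks = default_ld_blocks(panel),
                          snp_effects = default_snp_effects(),
                          covariate_effects = default_covariate_effects(),
                          intercepts = c(log_tg = 3.88, hdl = 62.5),
                          noise_sd = c(log_tg = 0.42, hdl = 10),
                          female_prevalence = 315 / 580,
                          age_mean = 18.9, age_sd = 0.9,
                          age_range = c(18, 25),
                          bmi_mean = 23.6, bmi_sd = 4.0,
                          admixture = default_admixture(),
                          confounding = NULL,
                          missing_rate = 0.01,
                          seed = 1L) {
  if (n < 1) stop("n must be positive")
  if (is.null(allele_freqs)) {
    allele_freqs <- stats::setNames(panel$maf_cohort, panel$snp_id)
  }
  if (any(is.na(allele_freqs)) ||
      any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stop("allele_freqs must lie strictly in (0, 1)")
  }
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  block_snps <- unlist(lapply(ld_blocks, `[[`, "snp_ids"))
  if (anyDuplicated(block_snps)) stop("ld_blocks overlap")
  for (b in ld_blocks) {
    if (abs(sum(b$freqs) - 1) > 1e-9) {
      stop("haplotype frequencies in an ld_block must sum to 1")
    }
    if (!all(b$snp_ids %in% names(allele_freqs))) {
      stop("ld_block references SNPs without allele frequencies")
    }
  }
  cfg <- list(n = as.integer(n), panel = panel, allele_freqs = allele_freqs,
              ld_blocks = ld_blocks, snp_effects = snp_effects,
              covariate_effects = covariate_effects,
              intercepts = intercepts, noise_sd = noise_sd,
              female_prevalence = female_prevalence,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              admixture = admixture, confounding = confounding,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

individual_ids <- function(n) sprintf("I%04d", seq_len(n))

#' Draw admixture proportions for a configured cohort
#' @param config A `cohort_config`.
#' @return Numeric vector of length `config$n` in (0, 1).
#' @export
simulate_admixture <- function(config) {
  set.seed(config$seed + 4L)
  sh <- config$admixture$beta_shape
  stats::rbeta(config$n, sh[1], sh[2])
}

#' Simulate panel genotypes
#'
#' Independent SNPs are drawn as two Bernoulli(freq) copies (so they are in
#' Hardy-Weinberg equilibrium by construction); SNPs inside an LD block are
#' derived from two haplotypes sampled per individual at the block's
#' haplotype frequencies. Under a confounded configuration, each
#' individual's allele frequency at independent SNPs interpolates between
#' two ancestral frequencies according to the admixture proportion `q`.
#' Missingness is applied uniformly at random at `missing_rate`.
#'
#' @param config A `cohort_config`.
#' @param q Optional admixture proportions (drawn via
#'   [simulate_admixture()] when needed and not supplied).
#' @param apply_missing Mask entries at `missing_rate`? Set `FALSE` to get
#'   the complete matrix used for phenotype generation.
#' @return Integer matrix (individuals x SNPs) of 0/1/2 counted-allele
#'   dosages, with `NA` for missing entries.
#' @export
simulate_genotypes <- function(config, q = NULL, apply_missing = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  freqs <- config$allele_freqs
  snp_ids <- names(freqs)
  confounded <- !is.null(config$confounding)
  if (confounded && is.null(q)) q <- simulate_admixture(config)
  set.seed(config$seed + 1L)
  geno <- matrix(NA_integer_, n, length(snp_ids),
                 dimnames = list(individual_ids(n), snp_ids))
  block_snps <- unlist(lapply(config$ld_blocks, `[[`, "snp_ids"))
  for (j in setdiff(snp_ids, block_snps)) {
    f <- freqs[[j]]
    if (confounded) {
      d <- config$confounding$freq_delta
      f1 <- pmin(pmax(f + d / 2, 0.01), 0.99)
      f2 <- pmin(pmax(f - d / 2, 0.01), 0.99)
      f <- q * f1 + (1 - q) * f2
    }
    geno[, j] <- stats::rbinom(n, 2L, f)
  }
  for (b in config$ld_blocks) {
    k <- length(b$freqs)
    h1 <- sample.int(k, n, replace = TRUE, prob = b$freqs)
    h2 <- sample.int(k, n, replace = TRUE, prob = b$freqs)
    geno[, b$snp_ids] <- b$haplotypes[h1, , drop = FALSE] +
      b$haplotypes[h2, , drop = FALSE]
  }
  storage.mode(geno) <- "integer"
  if (apply_missing && config$missing_rate > 0) {
    geno <- mask_missing(geno, config$missing_rate, config$seed + 5L)
  }
  geno
}

#' Mask genotype entries completely at random
#' @param genotypes Integer dosage matrix.
#' @param rate Missingness probability per entry, in [0, 1).
#' @param seed Integer seed for the mask.
#' @return The matrix with masked entries set to `NA`.
#' @export
mask_missing <- function(genotypes, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  set.seed(seed)
  mask <- stats::runif(length(genotypes)) < rate
  genotypes[mask] <- NA_integer_
  genotypes
}

#' Simulate ancestry-informative-marker genotypes
#'
#' Individual `i`'s allele frequency at AIM `m` is
#' `q_i * p1_m + (1 - q_i) * p2_m` under a two-way admixture model; the
#' genotype is the sum of two Bernoulli draws at that frequency.
#'
#' @param config A `cohort_config`.
#' @param q Optional admixture proportions; drawn via
#'   [simulate_admixture()] if `NULL`.
#' @return Integer matrix (individuals x AIMs) with the true admixture
#'   proportions attached as attribute `"admixture"`.
#' @export
simulate_aims <- function(config, q = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  adm <- config$admixture
  if (adm$n_aims < 2) stop("need at least 2 AIMs")
  if (is.null(q)) q <- simulate_admixture(config)
  set.seed(config$seed + 2L)
  n <- config$n
  p <- outer(q, adm$p1) + outer(1 - q, adm$p2)  # n x m individual freqs
  aims <- matrix(stats::rbinom(length(p), 2L, p), nrow = n,
                 dimnames = list(individual_ids(n),
                                 sprintf("AIM%03d", seq_len(adm$n_aims))))
  attr(aims, "admixture") <- q
  aims
}

#' Simulate lipid phenotypes from genotypes
#'
#' Realizes the model the analysis fits: `log(TG) = intercept + sum(beta_j
#' g_j) + age/sex/BMI terms + Normal(0, sd)` with `TG = exp(log TG)`, and
#' HDL-C generated analogously on the natural scale. Missing dosages for
#' effect SNPs are replaced by the SNP's mean dosage so the genetic
#' component is defined for every individual (pass the complete matrix for
#' exact effects).
#'
#' @param genotypes Dosage matrix including every SNP named in
#'   `config$snp_effects`.
#' @param config A `cohort_config`.
#' @param q Optional admixture proportions, required only under a
#'   confounded configuration (drawn if `NULL`).
#' @return Data frame `individual_id`, `age`, `sex` (1 = female), `bmi`,
#'   `tg`, `hdl`.
#' @export
simulate_phenotypes <- function(genotypes, config, q = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(genotypes)
  eff <- config$snp_effects
  for (ph in names(eff)) {
    absent <- setdiff(names(eff[[ph]]), colnames(genotypes))
    if (length(absent) > 0) {
      stop("snp_effects reference SNPs absent from genotypes: ",
           paste(absent, collapse = ", "))
    }
  }
  confounded <- !is.null(config$confounding)
  if (confounded && is.null(q)) q <- simulate_admixture(config)
  set.seed(config$seed + 3L)
  sex <- stats::rbinom(n, 1L, config$female_prevalence)
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, 12, Inf)

  genetic <- function(betas) {
    if (length(betas) == 0) return(rep(0, n))
    g <- genotypes[, names(betas), drop = FALSE]
    for (j in seq_len(ncol(g))) {
      nas <- is.na(g[, j])
      if (any(nas)) g[nas, j] <- mean(g[, j], na.rm = TRUE)
    }
    as.numeric(g %*% betas)
  }
  cov_term <- function(ce) ce["age"] * age + ce["sex"] * sex + ce["bmi"] * bmi
  shift <- function(ph) {
    if (!confounded) return(0)
    s <- config$confounding$pheno_shift[[ph]]
    if (is.null(s)) 0 else s * (q - mean(q))
  }
  log_tg <- config$intercepts[["log_tg"]] + genetic(eff$log_tg) +
    cov_term(config$covariate_effects$log_tg) + shift("log_tg") +
    stats::rnorm(n, 0, config$noise_sd[["log_tg"]])
  hdl <- config$intercepts[["hdl"]] + genetic(eff$hdl) +
    cov_term(config$covariate_effects$hdl) + shift("hdl") +
    stats::rnorm(n, 0, config$noise_sd[["hdl"]])
  hdl <- pmax(hdl, 5)  # physiological floor, essentially never binds
  data.frame(individual_id = rownames(genotypes),
             age = age, sex = sex, bmi = bmi,
             tg = exp(log_tg), hdl = hdl,
             stringsAsFactors = FALSE)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate a complete cohort
#'
#' Draws admixture proportions once and threads them through genotypes,
#' AIMs and phenotypes; phenotypes are generated from the complete
#' genotype matrix before missingness is applied.
#'
#' @param config A `cohort_config`.
#' @return List with `genotypes` (missingness applied), `aims`,
#'   `phenotypes`, `admixture` (true proportions) and `truth` (the
#'   generating parameters, for recovery tests).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 100, seed = 7))
#' dim(cohort$genotypes)
simulate_cohort <- function(config) {
  q <- simulate_admixture(config)
  complete <- simulate_genotypes(config, q = q, apply_missing = FALSE)
  phen <- simulate_phenotypes(complete, config, q = q)
  geno <- if (config$missing_rate > 0) {
    mask_missing(complete, config$missing_rate, config$seed + 5L)
  } else complete
  aims <- simulate_aims(config, q = q)
  truth <- list(snp_effects = lapply(config$snp_effects, as.list),
                covariate_effects = lapply(config$covariate_effects,
                                           as.list),
                intercepts = as.list(config$intercepts),
                noise_sd = as.list(config$noise_sd),
                allele_freqs = as.list(config$allele_freqs),
                seed = config$seed)
  list(genotypes = geno, aims = aims, phenotypes = phen,
       admixture = q, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `genotypes.csv`, `aims.csv`, `phenotypes.csv` and a
#' `truth.json` sidecar with the generating parameters.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.csv"),
             aims = file.path(dir, "aims.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.json"))
  write_genotype_csv(cohort$genotypes, paths[["genotypes"]])
  write_genotype_csv(cohort$aims, paths[["aims"]])
  utils::write.csv(cohort$phenotypes, paths[["phenotypes"]],
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
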
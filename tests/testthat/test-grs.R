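toy_panel <- function() {
  p <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4", "s5"),
    gene = "G", chromosome = "1", pathway = "RCT",
    allele_a = "A", allele_b = "C", counted_allele = "C",
    maf_global = 0.3, maf_mxl = 0.3, maf_cohort = 0.3,
    pheno_specific = NA_character_, note = NA_character_,
    stringsAsFactors = FALSE)
  class(p) <- c("snp_panel", "data.frame")
  p
}

toy_definition <- function(risk = rep("C", 5), weight = rep(1, 5),
                           weighting = "additive") {
  grs_definition("TG", "RCT",
                 data.frame(snp_id = paste0("s", 1:5), risk_allele = risk,
                            weight = weight, stringsAsFactors = FALSE),
                 weighting)
}

toy_genotypes <- function(rows) {
  g <- do.call(rbind, rows)
  dimnames(g) <- list(sprintf("I%02d", seq_len(nrow(g))),
                      paste0("s", seq_len(ncol(g))))
  g
}

test_that("dosage orientation counts risk alleles", {
  panel <- toy_panel()
  g <- toy_genotypes(list(c(2L, 2L, 0L, 1L, NA)))
  # risk == counted for s1..s4, flipped for s5
  def <- toy_definition(risk = c("C", "C", "C", "C", "A"))
  o <- orient_dosages(g, def, panel)
  expect_equal(unname(o[1, 1:4]), c(2, 2, 0, 1))
  expect_true(is.na(o[1, 5]))  # missing propagates
  # flipped homozygote: dosage 2 of counted allele = 0 risk alleles
  g2 <- toy_genotypes(list(c(2L, 2L, 2L, 2L, 2L)))
  expect_equal(unname(orient_dosages(g2, def, panel)[1, 5]), 0)
  # absent member names the SNP
  bad <- toy_definition()
  bad$members$snp_id[1] <- "zz"
  expect_error(orient_dosages(g, bad, panel), "zz")
})

test_that("additive scores are risk-allele counts with complete-case exclusion", {
  panel <- toy_panel()
  def <- toy_definition()
  g <- toy_genotypes(list(c(0L, 1L, 2L, 2L, 1L),
                          c(2L, 2L, 2L, 2L, 2L),
                          c(0L, 0L, 0L, 0L, 0L),
                          c(1L, NA, 1L, 1L, 1L)))
  grs <- build_additive_grs(g, def, panel)
  expect_equal(grs$score[1], 6)
  expect_equal(grs$score[2], 10)   # homozygous risk attains 2m
  expect_equal(grs$score[3], 0)
  expect_true(is.na(grs$score[4]))
  expect_equal(grs$n_missing_members[4], 1)
  expect_true(all(grs$score >= 0 & grs$score <= 10, na.rm = TRUE))
})

test_that("weighted scores generalize additive scores", {
  panel <- toy_panel()
  g <- toy_genotypes(list(c(2L, 1L, 0L, 1L, 2L),
                          c(1L, 1L, 1L, 1L, 1L)))
  add <- build_additive_grs(g, toy_definition(), panel)
  w1 <- build_weighted_grs(g, toy_definition(weight = rep(1, 5),
                                             weighting = "weighted"),
                           panel)
  expect_identical(w1$score, add$score)

  # hand arithmetic: weights (0.5, -0.2) on counts (2, 1)
  p2 <- toy_panel()[1:2, ]
  d2 <- grs_definition("TG", "RCT",
                       data.frame(snp_id = c("s1", "s2"),
                                  risk_allele = "C",
                                  weight = c(0.5, -0.2)), "weighted")
  g2 <- toy_genotypes(list(c(2L, 1L)))[, 1:2, drop = FALSE]
  expect_equal(build_weighted_grs(g2, d2, p2)$score, 0.8)

  # member order never matters
  d_rev <- toy_definition(weight = c(0.1, 0.2, 0.3, 0.4, 0.5),
                          weighting = "weighted")
  d_perm <- d_rev
  d_perm$members <- d_perm$members[5:1, ]
  s1 <- build_weighted_grs(g, d_rev, panel)$score
  s2 <- build_weighted_grs(g, d_perm, panel)$score
  expect_equal(s1, s2)
})

test_that("definition construction is validated", {
  expect_error(grs_definition("TG", "RCT",
                              data.frame(snp_id = character(),
                                         risk_allele = character(),
                                         weight = numeric())),
               "at least one")
  expect_error(toy_definition(weight = c(2, 1, 1, 1, 1)), "unit weights")
  m <- data.frame(snp_id = c("a", "a"), risk_allele = "C", weight = 1)
  expect_error(grs_definition("TG", "RCT", m), "duplicate")
})

test_that("top-hits membership follows the p-value threshold monotonically", {
  summ <- data.frame(
    snp_id = paste0("s", 1:5), pathway = "RCT", phenotype = "TG",
    beta_per_allele = c(0.2, 0.1, 0.05, 0.01, 0.3),
    p_value = c(0.01, 0.04, 0.08, 0.5, 0.09),
    risk_allele = "C", risk_is_counted = TRUE,
    stringsAsFactors = FALSE)
  strict <- build_top_hits_definition(summ, summ$snp_id, alpha = 0.05)
  loose <- build_top_hits_definition(summ, summ$snp_id, alpha = 0.10)
  expect_equal(nrow(strict$members), 2)
  expect_equal(nrow(loose$members), 4)
  expect_true(all(strict$members$snp_id %in% loose$members$snp_id))
  expect_warning(
    none <- build_top_hits_definition(summ, summ$snp_id, alpha = 0.001),
    "skipped")
  expect_null(none)
  # weighted top-hits carries risk-oriented signed weights
  w <- build_top_hits_definition(summ, summ$snp_id, alpha = 0.05,
                                 weighting = "weighted")
  expect_equal(w$members$weight, c(0.2, 0.1))
})

test_that("median split sends ties to the low-risk group", {
  mk <- function(scores) {
    structure(data.frame(individual_id = seq_along(scores),
                         score = scores, n_missing_members = 0L),
              class = c("grs_vector", "data.frame"))
  }
  g1 <- assign_risk_groups(mk(c(1, 2, 3, 4, 5)))
  expect_equal(g1$risk_group, c("low", "low", "low", "high", "high"))
  g2 <- assign_risk_groups(mk(c(1, 1, 2, 2)))
  expect_equal(g2$risk_group, c("low", "low", "high", "high"))
  expect_equal(attr(g2, "median"), 1.5)
  expect_error(assign_risk_groups(mk(rep(3, 10))), "degenerate")
  # partition invariant under adding a constant to all scores
  g3 <- assign_risk_groups(mk(c(1, 2, 3, 4, 5) + 100))
  expect_identical(g3$risk_group, g1$risk_group)
  # NA scores have no group
  g4 <- assign_risk_groups(mk(c(1, 2, NA, 4)))
  expect_true(is.na(g4$risk_group[3]))
})

test_that("key-SNP removal is exact and reversible", {
  def <- toy_definition()
  d2 <- remove_key_snp(def, "s3")
  expect_equal(nrow(d2$members), 4)
  expect_false("s3" %in% d2$members$snp_id)
  expect_error(remove_key_snp(def, "nope"), "not a member")
  # re-adding restores the original member set
  d3 <- d2
  d3$members <- rbind(d3$members,
                      def$members[def$members$snp_id == "s3", ])
  expect_setequal(d3$members$snp_id, def$members$snp_id)
})

test_that("GRS definitions round-trip through JSON", {
  def <- toy_definition(weight = c(0.1, -0.2, 0.3, 0.4, 0.5),
                        weighting = "weighted")
  path <- withr::local_tempfile(fileext = ".json")
  write_grs_definition(def, path)
  back <- read_grs_definition(path)
  expect_equal(back$members$weight, def$members$weight)
  expect_identical(back$scope, def$scope)
  expect_identical(back$weighting, def$weighting)
})
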
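# Genetic risk score construction: risk-allele orientation of dosages,
# additive (allele-count) and beta-weighted scores per pathway / total /
# top-hits SNP sets, median-split risk groups, and key-SNP removal.

#' Define a genetic risk score
#'
#' @param phenotype `"TG"` or `"HDL"`.
#' @param scope One of `"RCT"`, `"CLU"`, `"LPF"`, `"TOTAL"`, `"TOP_HITS"`.
#' @param members Data frame with columns `snp_id`, `risk_allele`, and
#'   `weight` (all 1 for an additive score; signed per-risk-allele effect
#'   estimates for a weighted score).
#' @param weighting `"additive"` or `"weighted"`.
#' @return A `grs_definition`.
#' @export
grs_definition <- function(phenotype = c("TG", "HDL"),
                           scope = c("RCT", "CLU", "LPF", "TOTAL",
                                     "TOP_HITS"),
                           members,
                           weighting = c("additive", "weighted")) {
  phenotype <- match.arg(phenotype)
  scope <- match.arg(scope)
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(members),
            all(c("snp_id", "risk_allele", "weight") %in% names(members)))
  if (nrow(members) == 0) stop("a GRS needs at least one member SNP")
  if (anyDuplicated(members$snp_id)) stop("duplicate member snp_ids")
  if (weighting == "additive" && !all(members$weight == 1)) {
    stop("additive scores require unit weights")
  }
  structure(list(phenotype = phenotype, scope = scope,
                 members = members[, c("snp_id", "risk_allele", "weight")],
                 weighting = weighting),
            class = "grs_definition")
}

#' Orient dosages to risk-allele counts
#'
#' For each member SNP the risk-allele count is the dosage itself when the
#' counted allele is the risk allele, and `2 - dosage` otherwise; missing
#' dosages propagate.
#'
#' @param genotypes Dosage matrix (counted-allele codes).
#' @param definition A `grs_definition`.
#' @param panel A `snp_panel` giving each member's counted allele.
#' @return Matrix of risk-allele counts (individuals x members).
#' @export
orient_dosages <- function(genotypes, definition, panel) {
  m <- definition$members
  absent <- setdiff(m$snp_id, colnames(genotypes))
  if (length(absent) > 0) {
    stop("member SNPs absent from genotypes: ",
         paste(absent, collapse = ", "))
  }
  idx <- match(m$snp_id, panel$snp_id)
  if (anyNA(idx)) {
    stop("member SNPs absent from panel: ",
         paste(m$snp_id[is.na(idx)], collapse = ", "))
  }
  counted <- panel$counted_allele[idx]
  oriented <- genotypes[, m$snp_id, drop = FALSE]
  flip <- counted != m$risk_allele
  if (any(flip)) {
    oriented[, flip] <- 2L - oriented[, flip, drop = FALSE]
  }
  oriented
}

#' Build a genetic risk score vector
#'
#' Computes per-individual scores as the weighted sum of risk-allele
#' counts over the definition's members (the plain count for an additive
#' definition). Individuals missing any member genotype receive `NA`
#' (complete-case scoring); their missing-member counts are recorded.
#'
#' @param genotypes Dosage matrix.
#' @param definition A `grs_definition`.
#' @param panel A `snp_panel`.
#' @return A `grs_vector` data frame: `individual_id`, `score`,
#'   `n_missing_members`; the definition is attached as an attribute.
#' @export
build_grs <- function(genotypes, definition, panel) {
  oriented <- orient_dosages(genotypes, definition, panel)
  w <- definition$members$weight
  n_missing <- rowSums(is.na(oriented))
  score <- as.numeric(oriented %*% w)
  score[n_missing > 0] <- NA_real_
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  out <- data.frame(individual_id = ids,
                    score = score,
                    n_missing_members = n_missing,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "definition") <- definition
  class(out) <- c("grs_vector", "data.frame")
  out
}

#' @rdname build_grs
#' @export
build_additive_grs <- function(genotypes, definition, panel) {
  stopifnot(definition$weighting == "additive")
  build_grs(genotypes, definition, panel)
}

#' @rdname build_grs
#' @export
build_weighted_grs <- function(genotypes, definition, panel) {
  stopifnot(definition$weighting == "weighted")
  if (anyNA(definition$members$weight)) {
    stop("missing weight for members: ",
         paste(definition$members$snp_id[is.na(definition$members$weight)],
               collapse = ", "))
  }
  build_grs(genotypes, definition, panel)
}

#' Construct GRS definitions from per-SNP association results
#'
#' Builds the member list for a pathway scope (or `TOTAL`, the union of
#' the three pathways) from the retained SNPs, using each SNP's
#' phenotype-specific risk allele and, for weighted scores, its effect
#' estimate oriented per risk-allele copy (`beta` when the risk allele is
#' the counted allele, `-beta` otherwise), so that weights point in the
#' adverse direction convention: positive for TG, typically negative for
#' HDL-C.
#'
#' @param assoc_summary The `summary` component of
#'   [snp_association_table()] for the target phenotype.
#' @param scope `"RCT"`, `"CLU"`, `"LPF"` or `"TOTAL"`.
#' @param retained SNP ids surviving QC and LD pruning for this phenotype.
#' @param weighting `"additive"` or `"weighted"`.
#' @return A `grs_definition`.
#' @export
build_pathway_definition <- function(assoc_summary, scope, retained,
                                     weighting = c("additive", "weighted")) {
  weighting <- match.arg(weighting)
  rows <- assoc_summary[assoc_summary$snp_id %in% retained, , drop = FALSE]
  if (scope != "TOTAL") rows <- rows[rows$pathway == scope, , drop = FALSE]
  if (nrow(rows) == 0) stop("no member SNPs for scope ", scope)
  weight <- if (weighting == "additive") {
    rep(1, nrow(rows))
  } else {
    ifelse(rows$risk_is_counted, rows$beta_per_allele,
           -rows$beta_per_allele)
  }
  grs_definition(phenotype = rows$phenotype[1], scope = scope,
                 members = data.frame(snp_id = rows$snp_id,
                                      risk_allele = rows$risk_allele,
                                      weight = weight,
                                      stringsAsFactors = FALSE),
                 weighting = weighting)
}

#' Top-hits GRS definition
#'
#' Restricts the member list to SNPs individually associated with the
#' phenotype below a p-value threshold. Both the strict (0.05) and loose
#' (0.10, the default) sets are constructible.
#'
#' @param assoc_summary As in [build_pathway_definition()].
#' @param retained SNP ids surviving QC and LD pruning.
#' @param alpha Inclusion threshold on the per-SNP p-value (default 0.10).
#' @param weighting `"additive"` or `"weighted"`.
#' @return A `grs_definition` with scope `"TOP_HITS"`, or `NULL` (with a
#'   warning) when no SNP qualifies.
#' @export
build_top_hits_definition <- function(assoc_summary, retained,
                                      alpha = 0.10,
                                      weighting = c("additive",
                                                    "weighted")) {
  weighting <- match.arg(weighting)
  rows <- assoc_summary[assoc_summary$snp_id %in% retained &
                          assoc_summary$p_value < alpha, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no SNP below p < ", alpha, "; top-hits GRS skipped")
    return(NULL)
  }
  weight <- if (weighting == "additive") {
    rep(1, nrow(rows))
  } else {
    ifelse(rows$risk_is_counted, rows$beta_per_allele,
           -rows$beta_per_allele)
  }
  grs_definition(phenotype = rows$phenotype[1], scope = "TOP_HITS",
                 members = data.frame(snp_id = rows$snp_id,
                                      risk_allele = rows$risk_allele,
                                      weight = weight,
                                      stringsAsFactors = FALSE),
                 weighting = weighting)
}

#' Median-split high/low genetic-risk groups
#'
#' High risk is a score strictly greater than the sample median of
#' complete-case scores; ties go to the low-risk group. The median is
#' recorded as an attribute.
#'
#' @param grs A `grs_vector`.
#' @return The `grs_vector` with a `risk_group` column (`"high"`/`"low"`,
#'   `NA` for incomplete individuals) and attribute `"median"`.
#' @export
assign_risk_groups <- function(grs) {
  sc <- grs$score[!is.na(grs$score)]
  if (length(unique(sc)) < 2) {
    stop("degenerate score distribution: all scores identical")
  }
  med <- stats::median(sc)
  grs$risk_group <- ifelse(is.na(grs$score), NA_character_,
                           ifelse(grs$score > med, "high", "low"))
  attr(grs, "median") <- med
  grs
}

#' Remove a key SNP from a GRS definition
#'
#' Supports the sensitivity analysis in which the score is reconstructed
#' without its most strongly associated member.
#'
#' @param definition A `grs_definition`.
#' @param snp_id Member to remove.
#' @return The definition without that member.
#' @export
remove_key_snp <- function(definition, snp_id) {
  if (!snp_id %in% definition$members$snp_id) {
    stop(snp_id, " is not a member of this definition")
  }
  definition$members <-
    definition$members[definition$members$snp_id != snp_id, , drop = FALSE]
  if (nrow(definition$members) == 0) {
    stop("removing ", snp_id, " leaves an empty definition")
  }
  definition
}

#' Serialize a GRS definition to JSON
#' @param definition A `grs_definition`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_grs_definition <- function(definition, path) {
  jsonlite::write_json(
    list(phenotype = definition$phenotype, scope = definition$scope,
         weighting = definition$weighting, members = definition$members),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a GRS definition from JSON
#' @param path JSON file written by [write_grs_definition()].
#' @return A `grs_definition`.
#' @export
read_grs_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grs_definition(phenotype = x$phenotype, scope = x$scope,
                 members = x$members, weighting = x$weighting)
}
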
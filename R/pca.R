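# Ancestry principal components from AIMs genotypes, used as admixture
# covariates in association models.

#' Principal components from ancestry-informative markers
#'
#' Missing AIM genotypes are mean-imputed; dosages are centered by twice
#' the estimated allele frequency and scaled by the binomial standard
#' deviation `sqrt(2 p (1 - p))` (frequency-scaled centering); scores are
#' the leading left singular vectors scaled by their singular values,
#' equivalent to an eigen-decomposition of the individual-by-individual
#' covariance. Monomorphic AIMs are dropped with a warning. The sign of
#' each component is fixed so that its largest-magnitude marker loading is
#' positive.
#'
#' @param aims Dosage matrix (individuals x AIMs), 0/1/2 with `NA`
#'   allowed.
#' @param n_components Number of components to return (default 2).
#' @return An `ancestry_scores` list: `scores` (matrix, columns
#'   `PC1`, ...), `variance_explained` (fraction per returned component,
#'   non-increasing), `loadings`, `n_aims_used`.
#' @export
compute_ancestry_pcs <- function(aims, n_components = 2) {
  stopifnot(is.matrix(aims))
  freq <- colMeans(aims, na.rm = TRUE) / 2
  poly <- !is.na(freq) & freq > 0 & freq < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic or empty AIMs dropped")
  }
  if (sum(poly) < 2) stop("need at least 2 polymorphic AIMs")
  x <- aims[, poly, drop = FALSE]
  freq <- freq[poly]
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- 2 * freq[j]
  }
  z <- sweep(x, 2, 2 * freq)
  z <- sweep(z, 2, sqrt(2 * freq * (1 - freq)), "/")
  n_components <- min(n_components, ncol(z), nrow(z) - 1)
  sv <- svd(z, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  for (k in seq_len(n_components)) {
    top <- which.max(abs(loadings[, k]))
    if (loadings[top, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(aims),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(x),
                             paste0("PC", seq_len(n_components)))
  structure(list(
    scores = scores,
    variance_explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2),
    loadings = loadings,
    n_aims_used = ncol(x)), class = "ancestry_scores")
}
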
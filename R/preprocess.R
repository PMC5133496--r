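# ---------------------------------------------------------------------------
# Covariate adjustment, missing-value policy, heritability filtering and
# per-family dataset assembly.
# ---------------------------------------------------------------------------

#' Regress covariates out of traits or expression
#'
#' Replaces each variable by its OLS residuals on an intercept plus the
#' supplied covariates (e.g. age and sex), so downstream correlations and
#' association tests are free of these nuisance effects. For a matrix,
#' rows are variables (probes) and columns are samples matching the
#' covariate rows. The operation is idempotent and the output is orthogonal
#' to the covariate columns.
#'
#' @param values Numeric vector (length n) or variables x samples matrix
#'   (n columns).
#' @param covariates n x q matrix or data frame of covariates (no intercept
#'   column; one is added).
#' @return Residualised object of the same shape and dimnames.
#' @export
regress_out_covariates <- function(values, covariates) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  M <- cbind(`(Intercept)` = 1, covariates)
  if (qr(M)$rank < ncol(M)) stop("covariate matrix is rank deficient")
  qrM <- qr(M)
  if (is.matrix(values)) {
    if (ncol(values) != nrow(M))
      stop("columns of values must match covariate rows")
    res <- t(qr.resid(qrM, t(values)))
    dimnames(res) <- dimnames(values)
    res
  } else {
    if (length(values) != nrow(M))
      stop("length of values must match covariate rows")
    stats::setNames(as.numeric(qr.resid(qrM, as.numeric(values))),
                    names(values))
  }
}

#' Impute sparse missing expression values
#'
#' Probes with more than \code{max_missing} missing fraction are dropped;
#' remaining missing values are replaced by the probe mean, since the
#' correlation step requires complete vectors.
#'
#' @param expr Probes x samples matrix.
#' @param max_missing Maximum tolerated missing fraction per probe
#'   (default 0.1).
#' @return Imputed matrix (possibly fewer rows).
#' @export
impute_expression <- function(expr, max_missing = 0.1) {
  frac <- rowMeans(is.na(expr))
  drop <- frac > max_missing
  if (any(drop))
    warning(sum(drop), " probe(s) dropped for >",
            round(100 * max_missing), "% missing values")
  x <- expr[!drop, , drop = FALSE]
  if (anyNA(x)) {
    mu <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 1]]
  }
  x
}

#' Keep the most heritable probes
#'
#' Estimates per-probe heritability with the intercept-only kinship mixed
#' model and keeps the \code{ceiling(top_fraction * P)} probes with the
#' highest \eqn{h^2}; ties at the cutoff are broken by probe id so the
#' subset is deterministic. Probes whose fit fails (e.g. constant probes)
#' get missing \eqn{h^2} and are never kept.
#'
#' @param expr Probes x samples matrix.
#' @param ped Pedigree; \code{K} kinship matrix.
#' @param K Kinship matrix.
#' @param top_fraction Fraction in (0, 1] of probes to keep (default 0.25).
#' @param polish Passed to [heritability_scan()].
#' @return List: \code{expr} (the kept subset, original probe order),
#'   \code{h2} (data frame for all probes).
#' @export
filter_heritable <- function(expr, ped, K, top_fraction = 0.25,
                             polish = TRUE) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  h2 <- heritability_scan(expr, ped, K, polish = polish)
  n_keep <- ceiling(top_fraction * nrow(expr))
  ok <- !is.na(h2$h2)
  ord <- order(-h2$h2[ok], h2$probe_id[ok])
  kept_ids <- h2$probe_id[ok][ord][seq_len(min(n_keep, sum(ok)))]
  list(expr = expr[rownames(expr) %in% kept_ids, , drop = FALSE], h2 = h2)
}

#' Split an expression matrix by family
#'
#' @param expr Probes x samples matrix.
#' @param ped Pedigree resolving each sample to exactly one family.
#' @return Named list family id -> probes x members matrix; column sets are
#'   disjoint and their union is the input columns, probe order preserved.
#' @export
split_by_family <- function(expr, ped) {
  fid <- family_of(colnames(expr), ped)
  lapply(split(seq_len(ncol(expr)), fid),
         function(ix) expr[, ix, drop = FALSE])
}
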
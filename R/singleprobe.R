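# ---------------------------------------------------------------------------
# Per-probe mixed-model association scan, the non-network comparator.
# ---------------------------------------------------------------------------

#' Single-probe mixed-model association scan
#'
#' For each probe fits \eqn{Y_{ij} = \mu + u_{ij} + v_i + \beta X_{ij} +
#' \epsilon_{ij}} with genetic (2K), shared-family and residual components
#' and records the Wald test of \eqn{\beta}. Variance components are
#' re-estimated for every probe by default, matching the model as written;
#' \code{reuse_null = TRUE} estimates them once under the probe-free null
#' and reuses them for a fast generalised-least-squares scan.
#'
#' @param expr Probes x samples matrix.
#' @param pheno Phenotype data frame with \code{sample_id}.
#' @param trait Trait column name.
#' @param K Kinship matrix; \code{ped} the pedigree.
#' @param ped Pedigree.
#' @param alpha Nominal level for the Bonferroni flag (default 0.05).
#' @param reuse_null Reuse null-model variance components (default
#'   \code{FALSE}).
#' @return Data frame: probe_id, beta, se, p, p_bonferroni, significant;
#'   Bonferroni uses the probe count (failed fits become NA rows and stay
#'   in the count).
#' @export
single_probe_scan <- function(expr, pheno, trait, K, ped, alpha = 0.05,
                              reuse_null = FALSE) {
  ids <- colnames(expr)
  idx <- match(ids, pheno$sample_id)
  if (anyNA(idx)) stop("expression samples missing from the phenotype table")
  y <- pheno[[trait]][idx]
  P <- nrow(expr)
  beta <- se <- p <- rep(NA_real_, P)
  if (reuse_null) {
    null_fit <- fit_lmm(y, NULL, ped = ped, K = K, ids = ids,
                        kernels = c("genetic", "family"))
    lg <- null_fit$sigma2["g"] / null_fit$sigma2["e"]
    lv <- null_fit$sigma2["v"] / null_fit$sigma2["e"]
    blocks <- lmm_family_blocks(ids, ped, K)
    for (j in seq_len(P)) {
      X <- cbind(1, expr[j, ])
      ev <- reml_eval(y, X, blocks, lg, lv, want_extras = FALSE)
      if (is.null(ev)) next
      vb <- ev$s2e * chol2inv(chol(ev$XtWiX))
      beta[j] <- ev$beta[2]; se[j] <- sqrt(vb[2, 2])
      p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    }
  } else {
    for (j in seq_len(P)) {
      X <- cbind(`(Intercept)` = 1, probe = expr[j, ])
      fit <- tryCatch(fit_lmm(y, X, ped = ped, K = K, ids = ids,
                              kernels = c("genetic", "family")),
                      error = function(e) NULL)
      if (is.null(fit)) next
      w <- wald_test(fit, "probe")
      beta[j] <- w$beta; se[j] <- w$se; p[j] <- w$p
    }
  }
  if (anyNA(p))
    warning(sum(is.na(p)), " probe fit(s) failed; rows kept as NA")
  data.frame(probe_id = rownames(expr), beta = beta, se = se, p = p,
             p_bonferroni = pmin(1, p * P),
             significant = !is.na(p) & p <= alpha / P,
             stringsAsFactors = FALSE)
}
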
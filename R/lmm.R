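# ---------------------------------------------------------------------------
# Variance-components REML engine.
#
# Model: y = X beta + u + v + e with
#   u ~ N(0, sigma_g^2 * 2K)   additive genetic effect (K = kinship),
#   v ~ N(0, sigma_v^2 * Z)    shared-family effect (Z block of ones),
#   e ~ N(0, sigma_e^2 * I).
# Both non-identity kernels are block-diagonal by family, so every
# likelihood evaluation factors into per-family Cholesky solves of
# W = I + lg * 2K + lv * J, where (lg, lv) are variance ratios relative to
# sigma_e^2.  sigma_e^2 and beta are profiled out analytically; the
# restricted likelihood is maximised over log variance ratios, and the
# non-negativity boundary is handled exactly by also fitting every kernel
# subset (g+v, g only, v only, none) and keeping the best.
# ---------------------------------------------------------------------------

# Per-family data blocks: list of (idx, G = 2*K block) in sample order.
lmm_family_blocks <- function(ids, ped, K) {
  fid <- family_of(ids, ped)
  kidx <- match(ids, rownames(K))
  if (anyNA(kidx))
    stop("sample ids absent from kinship matrix: ",
         paste(utils::head(ids[is.na(kidx)], 5), collapse = ", "))
  lapply(split(seq_along(ids), fid), function(ix) {
    list(idx = ix, G = 2 * K[kidx[ix], kidx[ix], drop = FALSE])
  })
}

# Profiled REML objective and GLS byproducts at fixed ratios (lg, lv).
# Returns loglik (restricted, up to an additive constant), beta, cov_beta
# (unit sigma_e^2 scale), sigma_e^2, and W^{-1} r needed for residuals.
reml_eval <- function(y, X, blocks, lg, lv, want_extras = FALSE) {
  n <- length(y); p <- ncol(X)
  logdetW <- 0
  XtWiX <- matrix(0, p, p); XtWiy <- numeric(p); ytWiy <- 0
  chols <- if (want_extras) vector("list", length(blocks)) else NULL
  for (b in seq_along(blocks)) {
    ix <- blocks[[b]]$idx
    m <- length(ix)
    W <- diag(m)
    if (lg > 0) W <- W + lg * blocks[[b]]$G
    if (lv > 0) W <- W + lv
    R <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdetW <- logdetW + 2 * sum(log(diag(R)))
    Zy <- forwardsolve(R, y[ix], transpose = TRUE, upper.tri = TRUE)
    ZX <- forwardsolve(R, X[ix, , drop = FALSE], transpose = TRUE,
                       upper.tri = TRUE)
    XtWiX <- XtWiX + crossprod(ZX)
    XtWiy <- XtWiy + crossprod(ZX, Zy)[, 1]
    ytWiy <- ytWiy + sum(Zy^2)
    if (want_extras) chols[[b]] <- R
  }
  cX <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(cX, XtWiy, transpose = TRUE,
                                     upper.tri = TRUE))
  rss <- ytWiy - sum(XtWiy * beta)
  rss <- max(rss, 1e-300)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(s2e) + logdetW + 2 * sum(log(diag(cX))) +
                  (n - p))
  out <- list(loglik = ll, beta = beta, s2e = s2e, XtWiX = XtWiX)
  if (want_extras) {
    r <- y - X %*% beta
    Wir <- numeric(n)
    for (b in seq_along(blocks)) {
      ix <- blocks[[b]]$idx
      R <- chols[[b]]
      Wir[ix] <- backsolve(R, forwardsolve(R, r[ix], transpose = TRUE,
                                           upper.tri = TRUE))
    }
    out$marginal <- as.numeric(r)
    out$Wir <- Wir
  }
  out
}

#' Fit a kinship-aware variance-components mixed model by REML
#'
#' Fits \eqn{y = X\beta + u + v + e} with an additive genetic random effect
#' (covariance \eqn{2K\sigma_g^2}), an optional shared-family random effect
#' (\eqn{\sigma_v^2} on a block-of-ones kernel) and an i.i.d. residual.
#' Variance components are estimated by REML with the fixed effects and the
#' residual scale profiled out; the non-negativity constraint is enforced
#' exactly by comparing all kernel subsets, so a component estimated at the
#' boundary is reported as 0. With both non-identity kernels absent the fit
#' collapses to ordinary least squares.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (include the intercept column); a
#'   vector is treated as a single column. If \code{NULL}, intercept only.
#' @param ped Pedigree (\code{fam_pedigree}) resolving sample ids to families.
#' @param K Kinship matrix (dimnames = individual ids). May be \code{NULL}
#'   when \code{kernels} excludes \code{"genetic"}.
#' @param ids Sample ids aligning \code{y} to \code{ped}/\code{K}; defaults
#'   to \code{names(y)}.
#' @param kernels Character subset of \code{c("genetic", "family")}; the
#'   identity residual kernel is always present.
#' @return A \code{famnet_lmm} list: \code{sigma2} (named g, v, e),
#'   \code{beta}, \code{se}, \code{vcov}, \code{reml_loglik},
#'   \code{residuals_marginal} (y minus fixed part) and
#'   \code{residuals_conditional} (y minus fixed part minus random-effect
#'   BLUPs), \code{n}, \code{ids}.
#' @export
fit_lmm <- function(y, X = NULL, ped, K = NULL, ids = names(y),
                    kernels = c("genetic", "family")) {
  ids <- if (is.null(ids)) names(y) else ids
  y <- as.numeric(unlist(y))
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  if (n < ncol(X) + 2) stop("need n >= number of fixed effects + 2")
  use_g <- "genetic" %in% kernels
  use_v <- "family" %in% kernels
  if (use_g && is.null(K)) stop("genetic kernel requested but K is NULL")
  if ((use_g || use_v) && is.null(ids))
    stop("sample ids are required to resolve families/kinship")

  blocks <- if (use_g || use_v) {
    if (use_g) lmm_family_blocks(ids, ped, K)
    else lapply(split(seq_len(n), family_of(ids, ped)),
                function(ix) list(idx = ix, G = NULL))
  } else list(list(idx = seq_len(n), G = NULL))
  if (use_g) {
    bad <- vapply(blocks, function(b) any(!is.finite(b$G)), TRUE)
    if (any(bad)) stop("kinship kernel contains non-finite entries")
  }

  obj <- function(par, use_g. = FALSE, use_v. = FALSE) {
    lg <- if (use_g.) exp(par[1]) else 0
    lv <- if (use_v.) exp(par[if (use_g.) 2 else 1]) else 0
    ev <- reml_eval(y, X, blocks, lg, lv)
    if (is.null(ev)) return(1e10)
    -ev$loglik
  }

  fits <- list(list(lg = 0, lv = 0, nll = obj(numeric(0))))
  lo <- -14; hi <- 14
  if (use_g) {
    og <- stats::optimize(function(t) obj(t, use_g. = TRUE), c(lo, hi),
                          tol = 1e-7)
    fits <- c(fits, list(list(lg = exp(og$minimum), lv = 0,
                              nll = og$objective)))
  }
  if (use_v) {
    ov <- stats::optimize(function(t) obj(t, use_v. = TRUE), c(lo, hi),
                          tol = 1e-7)
    fits <- c(fits, list(list(lg = 0, lv = exp(ov$minimum),
                              nll = ov$objective)))
  }
  if (use_g && use_v) {
    starts <- list(c(0, 0))
    starts <- c(starts, list(c(log(fits[[2]]$lg + 1e-6), -3),
                             c(-3, log(fits[[3]]$lv + 1e-6))))
    for (st in starts) {
      o2 <- stats::optim(st, obj, use_g. = TRUE, use_v. = TRUE,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 500))
      fits <- c(fits, list(list(lg = exp(o2$par[1]), lv = exp(o2$par[2]),
                                nll = o2$value)))
    }
  }
  nlls <- vapply(fits, `[[`, 0, "nll")
  best <- fits[[which.min(nlls)]]
  # ratios driven to the lower search bound are boundary zeros
  if (best$lg > 0 && best$lg < 2 * exp(lo)) best$lg <- 0
  if (best$lv > 0 && best$lv < 2 * exp(lo)) best$lv <- 0

  ev <- reml_eval(y, X, blocks, best$lg, best$lv, want_extras = TRUE)
  s2e <- ev$s2e
  sigma2 <- c(g = best$lg * s2e, v = best$lv * s2e, e = s2e)
  vcov_beta <- s2e * chol2inv(chol(ev$XtWiX))
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  # conditional residuals: y - X beta - BLUPs = sigma_e^2 V^{-1} r = W^{-1} r
  cond <- ev$Wir
  fit <- list(sigma2 = sigma2,
              beta = stats::setNames(as.numeric(ev$beta), colnames(X)),
              se = sqrt(pmax(diag(vcov_beta), 0)),
              vcov = vcov_beta,
              reml_loglik = ev$loglik,
              residuals_marginal = ev$marginal,
              residuals_conditional = as.numeric(cond),
              kernels = kernels,
              n = n, rank = ncol(X), ids = ids)
  class(fit) <- "famnet_lmm"
  fit
}

#' @export
print.famnet_lmm <- function(x, ...) {
  cat("Variance-components mixed model (REML)\n")
  cat(sprintf("  n = %d, kernels: %s + identity\n", x$n,
              paste(x$kernels, collapse = " + ")))
  cat(sprintf("  sigma2: g = %.4g, v = %.4g, e = %.4g\n",
              x$sigma2["g"], x$sigma2["v"], x$sigma2["e"]))
  est <- cbind(beta = x$beta, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' Wald test of a fixed effect
#'
#' Two-sided test of a fixed-effect coefficient against a standard normal
#' reference, the usual choice in kinship mixed models.
#'
#' @param fit A \code{famnet_lmm}.
#' @param column Index or name of the fixed-effect column; the intercept is
#'   not a testable effect.
#' @return List with \code{beta}, \code{se}, \code{z}, \code{p}.
#' @export
wald_test <- function(fit, column) {
  if (is.character(column)) column <- match(column, names(fit$beta))
  if (is.na(column) || column < 1 || column > length(fit$beta))
    stop("column does not index a fixed effect")
  if (names(fit$beta)[column] == "(Intercept)")
    stop("the intercept is not a testable effect")
  b <- fit$beta[[column]]; s <- fit$se[[column]]
  z <- if (s > 0) b / s else 0
  list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Heritability from a fitted mixed model
#'
#' Narrow-sense heritability of the modelled variable:
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_v^2 + \sigma_e^2)}.
#'
#' @param fit A \code{famnet_lmm} fitted with the genetic kernel.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
heritability <- function(fit) {
  s <- fit$sigma2
  tot <- sum(s)
  if (tot <= 0) stop("heritability undefined: all variance components are zero")
  unname(s["g"] / tot)
}

# ---------------------------------------------------------------------------
# Batch per-probe intercept-only REML: vectorised grid over variance ratios
# (shared Cholesky factors across probes) plus optional per-probe polish.
# Used by decorrelate() and heritability filtering, where thousands of
# probes share the same kernels.
# ---------------------------------------------------------------------------

reml_ratio_grid <- function() {
  lg <- c(0, exp(seq(log(0.03), log(60), length.out = 12)))
  lv <- c(0, exp(seq(log(0.03), log(30), length.out = 8)))
  expand.grid(lg = lg, lv = lv)
}

# expr: probes x samples matrix. Returns per-probe (lg, lv, s2e, loglik) and,
# when residuals = TRUE, the conditional/marginal residual matrices.
reml_batch_intercept <- function(expr, blocks, polish = TRUE,
                                 residuals = FALSE) {
  Y <- t(expr)                       # samples x probes
  n <- nrow(Y); P <- ncol(Y)
  grid <- reml_ratio_grid()
  bestll <- rep(-Inf, P); besti <- rep(1L, P)
  stats_at <- function(lg, lv) {
    logdetW <- 0
    otWio <- 0; otWiY <- numeric(P); YtWiY <- numeric(P)
    for (b in blocks) {
      m <- length(b$idx)
      W <- diag(m)
      if (lg > 0) W <- W + lg * b$G
      if (lv > 0) W <- W + lv
      R <- chol(W)
      logdetW <- logdetW + 2 * sum(log(diag(R)))
      Zy <- forwardsolve(R, Y[b$idx, , drop = FALSE], transpose = TRUE,
                         upper.tri = TRUE)
      Zo <- forwardsolve(R, rep(1, m), transpose = TRUE, upper.tri = TRUE)
      otWio <- otWio + sum(Zo^2)
      otWiY <- otWiY + colSums(Zo * Zy)
      YtWiY <- YtWiY + colSums(Zy^2)
    }
    rss <- pmax(YtWiY - otWiY^2 / otWio, 1e-300)
    s2e <- rss / (n - 1)
    list(ll = -0.5 * ((n - 1) * log(s2e) + logdetW + log(otWio) + (n - 1)),
         mu = otWiY / otWio, s2e = s2e)
  }
  for (gi in seq_len(nrow(grid))) {
    st <- stats_at(grid$lg[gi], grid$lv[gi])
    upd <- st$ll > bestll
    bestll[upd] <- st$ll[upd]
    besti[upd] <- gi
  }
  lg <- grid$lg[besti]; lv <- grid$lv[besti]
  if (polish) {
    for (j in seq_len(P)) {
      yj <- Y[, j]
      f <- function(par) {
        ev <- reml_eval(yj, matrix(1, n, 1), blocks, exp(par[1]), exp(par[2]))
        if (is.null(ev)) 1e10 else -ev$loglik
      }
      st <- c(log(max(lg[j], 1e-4)), log(max(lv[j], 1e-4)))
      o <- stats::optim(st, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 120))
      if (-o$value > bestll[j]) {
        bestll[j] <- -o$value
        lg[j] <- exp(o$par[1]); lv[j] <- exp(o$par[2])
      }
      if (lg[j] < 1e-5) lg[j] <- 0
      if (lv[j] < 1e-5) lv[j] <- 0
    }
  }
  # recompute profiled quantities at final ratios, grouped to reuse Cholesky
  s2e <- numeric(P); mu <- numeric(P)
  cond <- if (residuals) matrix(0, n, P) else NULL
  marg <- if (residuals) matrix(0, n, P) else NULL
  key <- paste(signif(lg, 10), signif(lv, 10))
  for (k in unique(key)) {
    jj <- which(key == k)
    st <- stats_at(lg[jj[1]], lv[jj[1]])
    s2e[jj] <- st$s2e[jj]; mu[jj] <- st$mu[jj]
    if (residuals) {
      r <- Y[, jj, drop = FALSE] - rep(1, n) %o% st$mu[jj]
      marg[, jj] <- r
      for (b in blocks) {
        m <- length(b$idx)
        W <- diag(m)
        if (lg[jj[1]] > 0) W <- W + lg[jj[1]] * b$G
        if (lv[jj[1]] > 0) W <- W + lv[jj[1]]
        R <- chol(W)
        cond[b$idx, jj] <- backsolve(R, forwardsolve(
          R, r[b$idx, , drop = FALSE], transpose = TRUE, upper.tri = TRUE))
      }
    }
  }
  out <- list(lg = lg, lv = lv, s2e = s2e, mu = mu, loglik = bestll,
              sigma2_g = lg * s2e, sigma2_v = lv * s2e, sigma2_e = s2e)
  out$h2 <- out$sigma2_g / (out$sigma2_g + out$sigma2_v + out$sigma2_e)
  if (residuals) {
    out$conditional <- cond
    out$marginal <- marg
  }
  out
}

#' Per-probe heritability scan
#'
#' Fits the intercept-only mixed model (genetic + shared-family + residual)
#' to every probe and returns the REML variance components and heritability
#' \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_v^2+\sigma_e^2)}.
#'
#' @param expr Probes x samples expression matrix (dimnames required).
#' @param ped Pedigree; \code{K} kinship matrix.
#' @param K Kinship matrix.
#' @param polish Refine each probe's grid estimate with a short Nelder-Mead
#'   polish (default \code{TRUE}).
#' @return Data frame: probe_id, sigma2_g, sigma2_v, sigma2_e, h2. Probes
#'   with zero variance get \code{NA} heritability.
#' @export
heritability_scan <- function(expr, ped, K, polish = TRUE) {
  blocks <- lmm_family_blocks(colnames(expr), ped, K)
  sdv <- apply(expr, 1, stats::sd)
  ok <- is.finite(sdv) & sdv > 0
  res <- data.frame(probe_id = rownames(expr), sigma2_g = NA_real_,
                    sigma2_v = NA_real_, sigma2_e = NA_real_, h2 = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    b <- reml_batch_intercept(expr[ok, , drop = FALSE], blocks,
                              polish = polish)
    res$sigma2_g[ok] <- b$sigma2_g
    res$sigma2_v[ok] <- b$sigma2_v
    res$sigma2_e[ok] <- b$sigma2_e
    res$h2[ok] <- b$h2
  }
  if (any(!ok))
    warning(sum(!ok), " constant probe(s): heritability set to NA")
  res
}

#' Decorrelate expression for family structure
#'
#' Removes the family-induced covariance from each probe by fitting the
#' intercept-only mixed model with genetic (2K), shared-family and residual
#' components and replacing the probe by its residuals. Conditional
#' residuals (response minus fixed part minus random-effect BLUPs) are the
#' default: marginal residuals would retain the very covariance the step is
#' meant to remove.
#'
#' @inheritParams heritability_scan
#' @param residual_type \code{"conditional"} (default) or \code{"marginal"}.
#' @return Matrix of the same shape and dimnames as \code{expr}. Probes with
#'   zero variance become all-zero rows with a warning.
#' @export
decorrelate <- function(expr, ped, K,
                        residual_type = c("conditional", "marginal"),
                        polish = TRUE) {
  residual_type <- match.arg(residual_type)
  blocks <- lmm_family_blocks(colnames(expr), ped, K)
  sdv <- apply(expr, 1, stats::sd)
  ok <- is.finite(sdv) & sdv > 0
  out <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  if (any(ok)) {
    b <- reml_batch_intercept(expr[ok, , drop = FALSE], blocks,
                              polish = polish, residuals = TRUE)
    out[ok, ] <- t(if (residual_type == "conditional") b$conditional
                   else b$marginal)
  }
  if (any(!ok))
    warning(sum(!ok), " constant probe(s) decorrelated to all-zero residuals")
  out
}
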
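# ---------------------------------------------------------------------------
# Signed weighted coexpression networks: biweight midcorrelation, signed
# soft-threshold adjacency, topological overlap, module detection by
# average-linkage clustering with a validated tree cut, module eigengenes.
# ---------------------------------------------------------------------------

#' Biweight midcorrelation matrix
#'
#' Robust correlation between all probe pairs. Per probe,
#' \eqn{u_i = (x_i - med(x)) / (9 \cdot mad(x))} with the unscaled median
#' absolute deviation; Tukey biweights \eqn{w_i = (1 - u_i^2)^2} for
#' \eqn{|u_i| < 1} and 0 otherwise downweight points beyond 9 MADs, and the
#' Pearson correlation of the weighted median-centred vectors is returned;
#' on well-behaved data it closely tracks the Pearson correlation while
#' staying stable under gross outliers. Pairs involving a probe with zero
#' MAD are computed as plain Pearson correlation of the raw vectors, with
#' a warning.
#'
#' @param expr Probes x samples numeric matrix; at least 4 samples, no
#'   missing values.
#' @return Symmetric probes x probes matrix in \eqn{[-1, 1]}, unit diagonal.
#' @export
bicor_matrix <- function(expr) {
  x <- as.matrix(expr)
  if (ncol(x) < 4) stop("biweight midcorrelation needs at least 4 samples")
  if (anyNA(x)) stop("expression matrix contains missing values; impute first")
  med <- apply(x, 1, stats::median)
  madv <- apply(x, 1, function(r) stats::mad(r, constant = 1))
  xc <- x - med
  zero <- madv <= 0
  if (any(zero)) {
    warning(sum(zero), " probe(s) with zero MAD: Pearson fallback for their pairs")
  }
  u <- xc / (9 * pmax(madv, .Machine$double.eps))
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (xc * w)
  xt <- xt - rowMeans(xt)
  nrm <- sqrt(rowSums(xt^2))
  nrm[nrm <= 0] <- 1  # all-zero weighted vector: correlations become 0
  xn <- xt / nrm
  C <- tcrossprod(xn)
  if (any(zero)) {
    # plain Pearson rows for zero-MAD probes, on raw vectors both sides
    z <- x - rowMeans(x)
    znrm <- sqrt(rowSums(z^2))
    znrm[znrm <= 0] <- 1
    z <- z / znrm
    Cz <- tcrossprod(z[zero, , drop = FALSE], z)
    C[zero, ] <- Cz
    C[, zero] <- t(Cz)
  }
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(rownames(x), rownames(x))
  C
}

#' Signed soft-threshold adjacency
#'
#' \eqn{a_{lk} = |0.5 + 0.5\,cor(x_l, x_k)|^\gamma}: correlation \code{+1}
#' maps to adjacency 1, \code{-1} to 0, and the exponent \eqn{\gamma}
#' suppresses weak edges without a hard cutoff.
#'
#' @param cor Symmetric correlation matrix in \eqn{[-1, 1]}.
#' @param gamma Positive soft-threshold exponent (default 6).
#' @return Adjacency matrix in \eqn{[0, 1]} with unit diagonal and attribute
#'   \code{gamma}.
#' @export
signed_adjacency <- function(cor, gamma = 6) {
  stopifnot(gamma > 0)
  A <- abs(0.5 + 0.5 * cor)^gamma
  diag(A) <- 1
  attr(A, "gamma") <- gamma
  A
}

#' Choose a soft-threshold exponent by scale-free topology fit
#'
#' For each candidate exponent, computes the connectivity distribution of
#' the resulting adjacency and the signed \eqn{R^2} of the regression of
#' log frequency on log binned connectivity. Returns the smallest candidate
#' whose fit reaches \code{rsq_cut}; if none qualifies, the candidate with
#' the best fit.
#'
#' @param cor Correlation matrix.
#' @param candidates Candidate exponents (default \code{seq(2, 20, 2)}).
#' @param rsq_cut Required signed scale-free fit (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return Chosen exponent, with attribute \code{fit_table} (gamma, rsq,
#'   mean_k).
#' @export
pick_soft_threshold <- function(cor, candidates = seq(2, 20, 2),
                                rsq_cut = 0.8, n_bins = 10) {
  if (length(candidates) < 1) stop("need at least one candidate exponent")
  fit <- data.frame(gamma = candidates, rsq = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    A <- signed_adjacency(cor, candidates[i])
    k <- rowSums(A) - 1
    fit$mean_k[i] <- mean(k)
    if (stats::sd(k) == 0)
      stop("degenerate connectivity: all nodes identical")
    # equal-width connectivity bins: frequency decay over k is the signature
    bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
    pk <- as.numeric(table(bin)) / length(k)
    mk <- tapply(k, bin, mean)
    keep <- !is.na(mk) & pk > 0 & mk > 0
    if (sum(keep) < 3) { fit$rsq[i] <- 0; next }
    m <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
    r2 <- suppressWarnings(summary(m)$r.squared)
    fit$rsq[i] <- r2 * -sign(stats::coef(m)[2])
  }
  ok <- which(fit$rsq >= rsq_cut)
  gamma <- if (length(ok)) fit$gamma[min(ok)] else fit$gamma[which.max(fit$rsq)]
  attr(gamma, "fit_table") <- fit
  gamma
}

#' Topological overlap similarity
#'
#' \eqn{TOM_{lk} = (\sum_m a_{lm} a_{mk} + a_{lk}) / (\min(k_l, k_k) + 1 -
#' a_{lk})} with \eqn{k_l = \sum_{m \ne l} a_{lm}}; shared neighbours raise
#' the similarity of a pair beyond their direct adjacency. Diagonal is 1.
#'
#' @param adj Adjacency matrix in \eqn{[0, 1]} with unit diagonal.
#' @return Symmetric matrix in \eqn{[0, 1]}.
#' @export
tom_similarity <- function(adj) {
  A <- as.matrix(adj)
  diag(A) <- 0
  k <- rowSums(A)
  L <- tcrossprod(A)           # sum_m a_lm a_mk (diag of A zeroed)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect coexpression modules from a network dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity (1 - TOM by
#' convention) followed by a separation-validated branch selection, a
#' dynamic cut in the spirit of the hybrid tree-cut algorithms. Every
#' dendrogram branch gets a separation score: the relative amount by which
#' the mean dissimilarity from its members to the rest of the network
#' exceeds its mean internal dissimilarity (for average linkage both are
#' computed exactly from the merge heights in linear time). Walking the
#' merge tree bottom-up, a branch becomes a module candidate when it has at
#' least \code{min_module_size} probes and separation at least
#' \code{min_separation}; an ancestor branch absorbs the candidates below
#' it only when they cover at least \code{coverage} of it and none of them
#' is markedly better separated (by more than the relative \code{margin}),
#' so tight cores grow to whole modules but loose super-clusters cannot
#' swallow distinct modules or drag in background probes. Unstructured
#' data admits no candidate at any level and comes back all grey. Modules
#' are labelled \code{"module1"}, \code{"module2"}, ... by decreasing size;
#' unassigned probes get \code{"grey"}.
#'
#' @param dissim Square symmetric dissimilarity matrix (e.g.
#'   \code{1 - tom_similarity(adj)}).
#' @param min_module_size Minimum probes per module (default 30).
#' @param min_separation Minimum relative drop of within-module vs
#'   to-background dissimilarity (default 0.05).
#' @param margin Relative separation advantage a sub-branch must hold to
#'   resist absorption by its ancestor (default 0.10).
#' @param coverage Minimum fraction of an ancestor covered by its
#'   candidates for absorption (default 0.8).
#' @return Named character vector probe -> module label, with attribute
#'   \code{dendrogram} (the \code{hclust} object).
#' @export
detect_modules <- function(dissim, min_module_size = 30,
                           min_separation = 0.05, margin = 0.10,
                           coverage = 0.8) {
  D <- as.matrix(dissim)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(D)))
  n <- nrow(D)
  labels <- stats::setNames(rep("grey", n), ids)
  if (n < min_module_size) {
    warning("fewer probes than min_module_size: all probes grey")
    return(labels)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  M <- hc$merge
  h <- hc$height
  rs_leaf <- rowSums(D)
  size <- sumin <- rsum <- sep <- numeric(n - 1)
  node <- function(k) if (k < 0) c(1, 0, rs_leaf[-k])
  else c(size[k], sumin[k], rsum[k])
  res <- vector("list", n - 1)       # surviving candidate nodes below each
  bestsep <- rep(-Inf, n - 1)        # best separation along absorbed chain
  for (i in seq_len(n - 1)) {
    a <- node(M[i, 1]); b <- node(M[i, 2])
    size[i] <- a[1] + b[1]
    # average linkage: cross-branch dissimilarity sum = height * |a| * |b|
    sumin[i] <- a[2] + b[2] + h[i] * a[1] * b[1]
    rsum[i] <- a[3] + b[3]
    m <- size[i]
    sep[i] <- if (m < n) {
      d_in <- 2 * sumin[i] / (m * (m - 1))
      d_out <- (rsum[i] - 2 * sumin[i]) / (m * (n - m))
      (d_out - d_in) / d_out
    } else -Inf
    cand <- c(if (M[i, 1] > 0) res[[M[i, 1]]],
              if (M[i, 2] > 0) res[[M[i, 2]]])
    valid <- m >= min_module_size && m < n &&
      is.finite(sep[i]) && sep[i] >= min_separation
    best_below <- if (length(cand)) max(bestsep[cand]) else -Inf
    absorb <- valid && (!length(cand) ||
                          (best_below <= sep[i] * (1 + margin) &&
                             (sum(size[cand]) / m >= coverage ||
                                sep[i] >= best_below - 1e-6)))
    if (absorb) {
      res[[i]] <- i
      bestsep[i] <- max(sep[i], if (length(cand)) bestsep[cand] else -Inf)
    } else res[i] <- list(cand)
  }
  mods <- res[[n - 1]]
  if (length(mods)) {
    mods <- mods[order(size[mods], decreasing = TRUE)]
    for (j in seq_along(mods)) {
      stack <- mods[j]
      while (length(stack)) {        # decode leaves without deep recursion
        k <- stack[1]; stack <- stack[-1]
        kids <- M[k, ]
        labels[-kids[kids < 0]] <- paste0("module", j)
        stack <- c(kids[kids > 0], stack)
      }
    }
  }
  attr(labels, "dendrogram") <- hc
  labels
}

#' Module eigengene
#'
#' First principal component of a module: probes are standardised to mean 0
#' and sd 1 across samples, the leading left singular vector of the samples
#' x genes block gives the per-sample scores (scaled to unit variance), and
#' the leading eigenvalue share gives the variance explained. The sign is
#' fixed so the scores correlate positively with the module's mean
#' standardised expression.
#'
#' @param expr Probes x samples matrix containing the module's probes.
#' @param gene_set Probe ids of the module (at least 2).
#' @return List of class \code{fam_eigengene}: \code{genes}, \code{scores}
#'   (named per-sample, unit variance), \code{var_explained}.
#' @export
module_eigengene <- function(expr, gene_set) {
  gene_set <- intersect(gene_set, rownames(expr))
  if (length(gene_set) < 2) stop("gene set must contain at least 2 probes of expr")
  x <- expr[gene_set, , drop = FALSE]
  sdv <- apply(x, 1, stats::sd)
  drop <- sdv <= 0 | !is.finite(sdv)
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) dropped from the module")
    x <- x[!drop, , drop = FALSE]
    if (nrow(x) < 2) stop("module collapsed below 2 genes after dropping")
  }
  z <- t(scale(t(x)))                     # standardise probes
  sv <- svd(t(z), nu = 1, nv = 0)         # samples x genes
  scores <- sv$u[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  if (stats::sd(scores) > 0) scores <- scores / stats::sd(scores)
  avg <- colMeans(z)
  if (sum(scores * (avg - mean(avg))) < 0) scores <- -scores
  structure(list(genes = rownames(x),
                 scores = stats::setNames(scores, colnames(expr)),
                 var_explained = ve),
            class = "fam_eigengene")
}

#' @export
print.fam_eigengene <- function(x, ...) {
  cat(sprintf("Module eigengene: %d genes, %d samples, %.1f%% variance explained\n",
              length(x$genes), length(x$scores), 100 * x$var_explained))
  invisible(x)
}

#' Build one signed coexpression network and its modules
#'
#' Convenience wrapper chaining [bicor_matrix()], [signed_adjacency()],
#' [tom_similarity()] (or 1 - adjacency), [detect_modules()] and
#' [module_eigengene()] for every non-grey module.
#'
#' @param expr Probes x samples matrix.
#' @param gamma Soft threshold; \code{"auto"} runs [pick_soft_threshold()].
#' @param min_module_size Minimum module size (default 30).
#' @param dissimilarity \code{"tom"} (default) or \code{"adjacency"}.
#' @param min_separation,margin,coverage Passed to [detect_modules()].
#' @return List of class \code{fam_network}: \code{partition} (probe ->
#'   label), \code{eigengenes} (named list of \code{fam_eigengene}),
#'   \code{gamma}, \code{module_sizes}.
#' @export
build_network <- function(expr, gamma = 6, min_module_size = 30,
                          dissimilarity = c("tom", "adjacency"),
                          min_separation = 0.05, margin = 0.10,
                          coverage = 0.8) {
  dissimilarity <- match.arg(dissimilarity)
  C <- bicor_matrix(expr)
  if (identical(gamma, "auto")) gamma <- as.numeric(pick_soft_threshold(C))
  A <- signed_adjacency(C, gamma)
  D <- if (dissimilarity == "tom") 1 - tom_similarity(A) else 1 - A
  part <- detect_modules(D, min_module_size = min_module_size,
                         min_separation = min_separation,
                         margin = margin, coverage = coverage)
  mods <- setdiff(unique(part), "grey")
  mods <- mods[order(as.integer(sub("module", "", mods)))]
  eg <- lapply(mods, function(m) module_eigengene(expr, names(part)[part == m]))
  names(eg) <- mods
  structure(list(partition = part, eigengenes = eg, gamma = gamma,
                 module_sizes = vapply(mods, function(m) sum(part == m), 0L)),
            class = "fam_network")
}

#' @export
print.fam_network <- function(x, ...) {
  nm <- length(x$eigengenes)
  cat(sprintf("Signed coexpression network (gamma = %g): %d module(s), %d/%d probes grey\n",
              x$gamma, nm, sum(x$partition == "grey"), length(x$partition)))
  if (nm) print(x$module_sizes)
  invisible(x)
}
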
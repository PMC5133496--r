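# ---------------------------------------------------------------------------
# Family-based network meta-analysis: per-family module-trait testing,
# top-module selection, overlap matching across families, common gene sets
# by intersection/union, the pooled family eigengene E_F, the joint test,
# Bonferroni control, and the two naive whole-sample baselines.
# ---------------------------------------------------------------------------

#' Build family-specific networks
#'
#' Runs [build_network()] on each family's expression subset, the first
#' step of the family-based approach. Eigengenes are therefore computed on
#' family-restricted samples.
#'
#' @param expr_by_family Named list family id -> probes x members matrix
#'   (see [split_by_family()]); all over the same probe universe.
#' @param ... Passed to [build_network()] (gamma, min_module_size, ...).
#' @return Named list family id -> \code{fam_network}.
#' @export
family_networks <- function(expr_by_family, ...) {
  lapply(expr_by_family, build_network, ...)
}

assoc_row <- function(unit_id, family_id, w, n) {
  data.frame(unit_id = unit_id, family_id = family_id, beta = w$beta,
             se = w$se, p = w$p, n = n, stringsAsFactors = FALSE)
}

#' Test every family module against a trait
#'
#' For each family and each non-grey module, fits the within-family mixed
#' model \eqn{Y_j = \mu + u_j + \beta\,eigengene_j + \epsilon_j} with the
#' family's own kinship as genetic kernel (a family-constant effect is
#' confounded with the intercept inside one family, so no shared-family
#' component) and records the Wald test of \eqn{\beta}.
#'
#' @param nets Named list family id -> \code{fam_network} (see
#'   [family_networks()]).
#' @param pheno Phenotype data frame with a \code{sample_id} column.
#' @param trait Name of the trait column.
#' @param K Kinship matrix; \code{ped} the pedigree.
#' @param ped Pedigree.
#' @param min_family_size Families smaller than this are skipped with a
#'   warning (default 10).
#' @return Data frame of association results: unit_id (module), family_id,
#'   beta, se, p, n.
#' @export
test_family_modules <- function(nets, pheno, trait, K, ped,
                                min_family_size = 10) {
  if (!trait %in% names(pheno)) stop("trait column not found: ", trait)
  out <- list()
  for (f in names(nets)) {
    eg <- nets[[f]]$eigengenes
    if (!length(eg)) next
    ids <- names(eg[[1]]$scores)
    if (length(ids) < min_family_size) {
      warning("family ", f, " has fewer than ", min_family_size,
              " samples: skipped")
      next
    }
    y <- pheno[[trait]][match(ids, pheno$sample_id)]
    if (anyNA(y)) stop("phenotype missing for samples of family ", f)
    for (m in names(eg)) {
      X <- cbind(`(Intercept)` = 1, eigengene = eg[[m]]$scores)
      fit <- fit_lmm(y, X, ped = ped, K = K, ids = ids, kernels = "genetic")
      out[[length(out) + 1]] <- assoc_row(m, f, wald_test(fit, "eigengene"),
                                          length(ids))
    }
  }
  if (!length(out)) return(data.frame(unit_id = character(), family_id = character(),
                                      beta = numeric(), se = numeric(),
                                      p = numeric(), n = integer()))
  do.call(rbind, out)
}

#' Select the overall top family module
#'
#' Within each family, the module with the smallest p-value is that
#' family's candidate; across families the overall smallest p wins. Ties
#' are broken by the larger |beta|/se, then lexicographic module id, so
#' selection is deterministic and order-invariant.
#'
#' @param results Association data frame from [test_family_modules()].
#' @return List: \code{family_id}, \code{unit_id}, \code{per_family} (one
#'   best row per family), \code{best} (the winning row).
#' @export
select_top_module <- function(results) {
  res <- results[is.finite(results$p), , drop = FALSE]
  if (!nrow(res)) stop("no usable association results to select from")
  stat <- abs(res$beta) / res$se
  ord <- order(res$p, -stat, res$unit_id)
  res <- res[ord, , drop = FALSE]
  per_family <- res[!duplicated(res$family_id), , drop = FALSE]
  best <- per_family[1, , drop = FALSE]
  list(family_id = best$family_id, unit_id = best$unit_id,
       per_family = per_family[order(per_family$family_id), , drop = FALSE],
       best = best)
}

#' Match modules across families by highest overlap
#'
#' For each family, picks the non-grey module sharing the most genes with
#' the reference set (the top module's genes). Ties go to the higher
#' Jaccard index, then the smaller module, then the lexicographically
#' smaller id. The reference family maps to the reference set itself. A
#' family with zero overlap everywhere maps to the empty set with a
#' warning (its intersection contribution empties the common set).
#'
#' @param reference Character vector of reference gene ids (non-empty).
#' @param nets Named list family id -> \code{fam_network}.
#' @param reference_family Family id owning the reference module, or
#'   \code{NULL} to match every family against the reference.
#' @return Named list family id -> matched gene set, with attribute
#'   \code{overlap} (named integer vector).
#' @export
match_modules_by_overlap <- function(reference, nets,
                                     reference_family = NULL) {
  if (!length(reference)) stop("reference gene set is empty")
  matched <- list()
  ov <- integer(0)
  for (f in names(nets)) {
    if (!is.null(reference_family) && f == reference_family) {
      matched[[f]] <- reference
      ov[f] <- length(reference)
      next
    }
    part <- nets[[f]]$partition
    mods <- setdiff(unique(part), "grey")
    if (!length(mods)) {
      warning("family ", f, " has no modules: matched to empty set")
      matched[[f]] <- character(0); ov[f] <- 0L
      next
    }
    sets <- lapply(mods, function(m) names(part)[part == m])
    inter <- vapply(sets, function(s) length(intersect(s, reference)), 0L)
    if (max(inter) == 0L) {
      warning("family ", f, " has no module overlapping the reference: ",
              "matched to empty set")
      matched[[f]] <- character(0); ov[f] <- 0L
      next
    }
    jac <- vapply(sets, function(s)
      length(intersect(s, reference)) / length(union(s, reference)), 0)
    sizes <- lengths(sets)
    pick <- order(-inter, -jac, sizes, mods)[1]
    matched[[f]] <- sets[[pick]]
    ov[f] <- inter[pick]
  }
  attr(matched, "overlap") <- ov
  matched
}

#' Intersection and union common gene sets
#'
#' @param matched Named list family id -> matched gene set (at least 2
#'   families), as from [match_modules_by_overlap()].
#' @return List of class \code{fam_common_sets}: \code{matched},
#'   \code{intersection}, \code{union}.
#' @export
build_common_sets <- function(matched) {
  if (length(matched) < 2) stop("need matched modules from at least 2 families")
  inter <- Reduce(intersect, matched)
  uni <- sort(unique(unlist(matched)))
  if (!length(inter))
    warning("intersection of matched modules is empty; only the union set is usable")
  structure(list(matched = matched, intersection = sort(inter), union = uni),
            class = "fam_common_sets")
}

#' @export
print.fam_common_sets <- function(x, ...) {
  cat(sprintf("Common gene sets over %d families: intersection %d, union %d\n",
              length(x$matched), length(x$intersection), length(x$union)))
  invisible(x)
}

#' Family eigengene E_F from the common sets
#'
#' Computes, for both candidate sets (intersection and union), a per-family
#' eigengene on the candidate's genes, summarises each candidate by its
#' minimum variance explained across families (a worst-case criterion: the
#' chosen set should summarise every family well), keeps the better
#' candidate, and concatenates the per-family score vectors into one
#' eigengene across all samples.
#'
#' @param expr_by_family Named list family id -> probes x members matrix.
#' @param sets A \code{fam_common_sets}.
#' @return List: \code{scores} (named per-sample vector over all families),
#'   \code{chosen_set} ("intersection" or "union"), \code{genes},
#'   \code{var_explained} (per family, chosen candidate),
#'   \code{candidate_var_explained} (per family, both candidates).
#' @export
family_eigengene <- function(expr_by_family, sets) {
  cand <- list(intersection = sets$intersection, union = sets$union)
  cand <- cand[lengths(cand) >= 2]
  if (!length(cand)) stop("both candidate gene sets are empty or too small")
  per_fam <- lapply(cand, function(genes)
    lapply(expr_by_family, module_eigengene, gene_set = genes))
  ve <- lapply(per_fam, function(l) vapply(l, `[[`, 0, "var_explained"))
  summary_ve <- vapply(ve, min, 0)
  chosen <- names(which.max(summary_ve))
  scores <- unlist(lapply(per_fam[[chosen]], `[[`, "scores"))
  names(scores) <- unlist(lapply(per_fam[[chosen]],
                                 function(e) names(e$scores)))
  list(scores = scores, chosen_set = chosen, genes = cand[[chosen]],
       var_explained = ve[[chosen]], candidate_var_explained = ve)
}

#' Joint mixed-model test of an eigengene across all families
#'
#' Fits \eqn{Y_{ij} = \mu + u_{ij} + v_i + \beta\,eigengene_{ij} +
#' \epsilon_{ij}} over all samples with genetic (2K), shared-family and
#' residual components, and returns the Wald test of \eqn{\beta}.
#'
#' @param scores Named per-sample eigengene vector.
#' @param pheno Phenotype data frame with \code{sample_id}.
#' @param trait Trait column name.
#' @param K Kinship matrix; \code{ped} the pedigree.
#' @param ped Pedigree.
#' @param unit_id Label recorded in the result row.
#' @return One-row association data frame (family_id = "all").
#' @export
test_joint <- function(scores, pheno, trait, K, ped, unit_id = "E_F") {
  ids <- names(scores)
  if (is.null(ids)) stop("eigengene scores must be named by sample id")
  idx <- match(ids, pheno$sample_id)
  if (anyNA(idx))
    stop("eigengene samples missing from the phenotype table: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  y <- pheno[[trait]][idx]
  X <- cbind(`(Intercept)` = 1, eigengene = as.numeric(scores))
  fit <- fit_lmm(y, X, ped = ped, K = K, ids = ids,
                 kernels = c("genetic", "family"))
  assoc_row(unit_id, "all", wald_test(fit, "eigengene"), length(ids))
}

#' Bonferroni adjustment of association results
#'
#' @param results Association data frame.
#' @param n_tests Number of tests in the family (e.g. the module count of
#'   the relevant network); defaults to \code{nrow(results)}.
#' @param alpha Nominal level (default 0.05).
#' @return \code{results} with \code{p_bonferroni} (capped at 1) and
#'   \code{significant} columns.
#' @export
bonferroni <- function(results, n_tests = nrow(results), alpha = 0.05) {
  if (is.null(n_tests) || n_tests <= 0) stop("n_tests must be positive")
  results$p_bonferroni <- pmin(1, results$p * n_tests)
  results$significant <- results$p <= alpha / n_tests
  results
}

#' The full family-based meta-analysis
#'
#' Chains the family-approach stages: per-family module tests (within-family
#' mixed model), selection of the top module M_F^M, highest-overlap
#' matching across families, intersection/union common sets, the pooled
#' family eigengene E_F (candidate chosen by worst-case variance
#' explained), and the joint kinship mixed-model test of E_F, with
#' Bonferroni control over all per-family module tests.
#'
#' @param expr_by_family Named list family id -> probes x members matrix.
#' @param pheno,trait,K,ped As in [test_joint()].
#' @param nets Pre-built [family_networks()] result, or \code{NULL} to
#'   build here.
#' @param alpha Nominal level.
#' @param ... Passed to [build_network()] when \code{nets} is \code{NULL}.
#' @return List of class \code{fam_meta}: \code{module_tests} (Bonferroni-
#'   adjusted), \code{top}, \code{matched} (with overlaps),
#'   \code{common_sets}, \code{eigengene}, \code{joint_test}, \code{nets}.
#' @export
family_meta_analysis <- function(expr_by_family, pheno, trait, K, ped,
                                 nets = NULL, alpha = 0.05, ...) {
  if (is.null(nets)) nets <- family_networks(expr_by_family, ...)
  tests <- test_family_modules(nets, pheno, trait, K, ped)
  if (!nrow(tests)) stop("no family produced testable modules")
  tests <- bonferroni(tests, n_tests = nrow(tests), alpha = alpha)
  top <- select_top_module(tests)
  ref_genes <- nets[[top$family_id]]$eigengenes[[top$unit_id]]$genes
  matched <- match_modules_by_overlap(ref_genes, nets,
                                      reference_family = top$family_id)
  sets <- build_common_sets(matched)
  eg <- family_eigengene(expr_by_family, sets)
  joint <- test_joint(eg$scores, pheno, trait, K, ped, unit_id = "E_F")
  joint <- bonferroni(joint, n_tests = 1, alpha = alpha)
  structure(list(module_tests = tests, top = top, matched = matched,
                 common_sets = sets, eigengene = eg, joint_test = joint,
                 nets = nets, trait = trait, alpha = alpha),
            class = "fam_meta")
}

#' @export
print.fam_meta <- function(x, ...) {
  cat("Family-based coexpression meta-analysis\n")
  cat(sprintf("  trait: %s; families: %d; module tests: %d\n", x$trait,
              length(x$nets), nrow(x$module_tests)))
  cat(sprintf("  top module: %s in family %s (p = %.3g)\n", x$top$unit_id,
              x$top$family_id, x$top$best$p))
  cat(sprintf("  common sets: intersection %d, union %d; E_F uses the %s\n",
              length(x$common_sets$intersection), length(x$common_sets$union),
              x$eigengene$chosen_set))
  cat(sprintf("  joint E_F test: beta = %.3g (se %.3g), p = %.3g\n",
              x$joint_test$beta, x$joint_test$se, x$joint_test$p))
  invisible(x)
}

#' Naive whole-sample network baselines
#'
#' The two comparison tracks: a single network over all samples built from
#' the raw (covariate-adjusted) expression, and one built from the
#' decorrelated expression. Every module eigengene of each track is tested
#' with the joint kinship mixed model, and Bonferroni control uses the
#' track's module count.
#'
#' @param expr Probes x samples matrix (raw track).
#' @param expr_star Decorrelated matrix over the same probes and samples
#'   (see [decorrelate()]); \code{NULL} skips that track.
#' @param pheno,trait,K,ped As in [test_joint()].
#' @param alpha Nominal level.
#' @param ... Passed to [build_network()].
#' @return Named list of tracks (\code{naive}, \code{naive_decorrelated}),
#'   each \code{list(network, tests)} with Bonferroni-adjusted tests.
#' @export
naive_pipelines <- function(expr, expr_star = NULL, pheno, trait, K, ped,
                            alpha = 0.05, ...) {
  run_track <- function(mat) {
    net <- build_network(mat, ...)
    if (!length(net$eigengenes))
      return(list(network = net,
                  tests = bonferroni(data.frame(unit_id = character(),
                                                family_id = character(),
                                                beta = numeric(), se = numeric(),
                                                p = numeric(), n = integer()),
                                     n_tests = 1, alpha = alpha)))
    tests <- do.call(rbind, lapply(names(net$eigengenes), function(m)
      test_joint(net$eigengenes[[m]]$scores, pheno, trait, K, ped,
                 unit_id = m)))
    list(network = net,
         tests = bonferroni(tests, n_tests = length(net$eigengenes),
                            alpha = alpha))
  }
  out <- list(naive = run_track(expr))
  if (!is.null(expr_star)) {
    if (!identical(dimnames(expr), dimnames(expr_star)))
      stop("expr and expr_star must share probes and samples")
    out$naive_decorrelated <- run_track(expr_star)
  }
  out
}
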
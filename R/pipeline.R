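# ---------------------------------------------------------------------------
# Top-level pipeline: covariate adjustment -> (optional) heritability
# filter -> decorrelation -> family / naive / single-probe tracks -> files.
# ---------------------------------------------------------------------------

#' Run the full family-network analysis
#'
#' Orchestrates every analysis track on one dataset: covariates are
#' regressed out of the trait and all probes, probes are optionally
#' restricted to the most heritable fraction, the family approach builds
#' one network per family and meta-analyses the modules, the two naive
#' baselines build whole-sample networks on raw and decorrelated
#' expression, and the single-probe scan tests each probe directly. Any
#' subset of tracks can be selected.
#'
#' @param expr Probes x samples matrix, or a TSV path for
#'   [read_expression()].
#' @param ped A \code{fam_pedigree} or PED file path.
#' @param pheno Phenotype data frame or TSV path (needs \code{sample_id},
#'   the trait, and the covariate columns).
#' @param trait Trait column name.
#' @param covariates Covariate column names regressed out of trait and
#'   probes (default \code{c("age", "sex")}; use \code{character(0)} to
#'   skip).
#' @param mode One of \code{"family"}, \code{"naive"}, \code{"naive-decor"},
#'   \code{"single-probe"}, \code{"all"}.
#' @param gamma Soft threshold (number or \code{"auto"}).
#' @param min_module_size Minimum module size.
#' @param heritable_top Fraction of most-heritable probes to keep, or
#'   \code{NULL}/\code{"off"} to analyse all probes.
#' @param dissimilarity \code{"tom"} or \code{"adjacency"}.
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Integer seed (fixes any stochastic step; the pipeline itself
#'   is deterministic given inputs).
#' @param out Output directory for [write_results()], or \code{NULL} to
#'   skip writing.
#' @return List of class \code{fam_run}: \code{family} (a
#'   \code{fam_meta}), \code{naive}, \code{naive_decorrelated},
#'   \code{single_probe}, \code{h2}, \code{config}; tracks not run are
#'   absent.
#' @export
famnet_run <- function(expr, ped, pheno, trait,
                       covariates = c("age", "sex"),
                       mode = c("all", "family", "naive", "naive-decor",
                                "single-probe"),
                       gamma = 6, min_module_size = 30,
                       heritable_top = NULL, dissimilarity = "tom",
                       alpha = 0.05, seed = 1, out = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  set.seed(seed)
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(ped)) ped <- parse_pedigree(ped)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno, required = trait)
  if (!trait %in% names(pheno)) stop("trait column not found: ", trait)
  miss_cov <- setdiff(covariates, names(pheno))
  if (length(miss_cov))
    stop("covariate column(s) missing: ", paste(miss_cov, collapse = ", "))
  idx <- match(colnames(expr), pheno$sample_id)
  if (anyNA(idx)) stop("expression samples missing from the phenotype table")
  pheno <- pheno[idx, , drop = FALSE]

  K <- kinship_matrix(ped)
  expr <- impute_expression(expr)

  # covariate adjustment of trait and probes precedes everything else
  if (length(covariates)) {
    cv <- as.matrix(pheno[, covariates, drop = FALSE])
    expr <- regress_out_covariates(expr, cv)
    pheno[[trait]] <- regress_out_covariates(pheno[[trait]], cv)
  }

  h2 <- NULL
  if (!is.null(heritable_top) && !identical(heritable_top, "off")) {
    fh <- filter_heritable(expr, ped, K, top_fraction = heritable_top)
    expr <- fh$expr
    h2 <- fh$h2
  }

  res <- list(config = list(trait = trait, covariates = covariates,
                            mode = mode, gamma = gamma,
                            min_module_size = min_module_size,
                            heritable_top = heritable_top,
                            dissimilarity = dissimilarity, alpha = alpha,
                            seed = seed, n_probes = nrow(expr),
                            n_samples = ncol(expr)))
  res$h2 <- h2
  errors <- character(0)
  need_decor <- mode %in% c("all", "naive-decor")
  expr_star <- if (need_decor) decorrelate(expr, ped, K) else NULL

  if (mode %in% c("all", "family")) {
    ebf <- split_by_family(expr, ped)
    res$family <- tryCatch(
      family_meta_analysis(ebf, pheno, trait, K, ped, alpha = alpha,
                           gamma = gamma, min_module_size = min_module_size,
                           dissimilarity = dissimilarity),
      error = function(e) {
        errors <<- c(errors, paste("family track:", conditionMessage(e)))
        NULL
      })
  }
  if (mode %in% c("all", "naive", "naive-decor")) {
    raw_track <- mode != "naive-decor"
    nv <- tryCatch(
      naive_pipelines(if (raw_track) expr else expr_star,
                      expr_star = if (mode == "all") expr_star else NULL,
                      pheno = pheno, trait = trait, K = K, ped = ped,
                      alpha = alpha, gamma = gamma,
                      min_module_size = min_module_size,
                      dissimilarity = dissimilarity),
      error = function(e) {
        errors <<- c(errors, paste("naive track:", conditionMessage(e)))
        NULL
      })
    if (!is.null(nv)) {
      if (mode == "naive-decor") res$naive_decorrelated <- nv$naive
      else {
        res$naive <- nv$naive
        res$naive_decorrelated <- nv$naive_decorrelated
      }
    }
  }
  if (mode %in% c("all", "single-probe")) {
    res$single_probe <- tryCatch(
      single_probe_scan(expr, pheno, trait, K, ped, alpha = alpha),
      error = function(e) {
        errors <<- c(errors, paste("single-probe track:", conditionMessage(e)))
        NULL
      })
  }
  res$errors <- errors
  class(res) <- "fam_run"

  if (!is.null(out)) {
    artifacts <- list()
    if (!is.null(res$family)) {
      artifacts$associations_family <- res$family$module_tests
      artifacts$associations_family_joint <- res$family$joint_test
      artifacts$eigengenes_family <- data.frame(
        sample_id = names(res$family$eigengene$scores),
        E_F = as.numeric(res$family$eigengene$scores))
      for (f in names(res$family$nets))
        artifacts[[paste0("modules_family_", f)]] <-
          partition_df(res$family$nets[[f]]$partition)
      artifacts$common_sets <- list(
        intersection = res$family$common_sets$intersection,
        union = res$family$common_sets$union)
    }
    for (tr in c("naive", "naive_decorrelated")) {
      if (is.null(res[[tr]])) next
      artifacts[[paste0("modules_", tr)]] <-
        partition_df(res[[tr]]$network$partition)
      artifacts[[paste0("associations_", tr)]] <- res[[tr]]$tests
      artifacts[[paste0("eigengenes_", tr)]] <- eigengene_df(res[[tr]]$network)
    }
    if (!is.null(res$single_probe))
      artifacts$associations_single_probe <- res$single_probe
    if (!is.null(h2)) artifacts$heritability <- h2
    write_results(out, artifacts, config = res$config, seed = seed,
                  errors = errors)
  }
  res
}

partition_df <- function(partition) {
  data.frame(probe_id = names(partition),
             module_label = as.character(partition),
             stringsAsFactors = FALSE)
}

eigengene_df <- function(net) {
  if (!length(net$eigengenes))
    return(data.frame(sample_id = character(0)))
  df <- data.frame(sample_id = names(net$eigengenes[[1]]$scores),
                   stringsAsFactors = FALSE)
  for (m in names(net$eigengenes))
    df[[m]] <- as.numeric(net$eigengenes[[m]]$scores)
  df
}

#' @export
print.fam_run <- function(x, ...) {
  cat("famnet analysis run (mode =", x$config$mode, ")\n")
  cat(sprintf("  %d probes x %d samples, trait %s\n", x$config$n_probes,
              x$config$n_samples, x$config$trait))
  if (!is.null(x$family)) print(x$family)
  for (tr in c("naive", "naive_decorrelated")) {
    if (is.null(x[[tr]])) next
    t <- x[[tr]]$tests
    if (nrow(t)) {
      b <- t[which.min(t$p), ]
      cat(sprintf("  %s track: %d modules; best %s beta = %.3g, p = %.3g%s\n",
                  tr, nrow(t), b$unit_id, b$beta, b$p,
                  if (b$significant) " (significant)" else ""))
    } else cat(sprintf("  %s track: no modules\n", tr))
  }
  if (!is.null(x$single_probe)) {
    sp <- x$single_probe
    b <- sp[which.min(sp$p), ]
    cat(sprintf("  single-probe scan: %d probes; best %s p = %.3g, %d significant\n",
                nrow(sp), b$probe_id, b$p, sum(sp$significant, na.rm = TRUE)))
  }
  if (length(x$errors)) cat("  errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}
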
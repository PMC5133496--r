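# ---------------------------------------------------------------------------
# Synthetic multi-family study generator: pedigrees, family-structured
# expression with planted latent-factor modules, and causal/null traits.
# Emulates the design of a 5-family expression study (65/55/45/62/49
# members, 276 samples) with an SBP-like causal trait and a Q1-like null
# trait, so every pipeline stage is testable without restricted data.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults mirror the 5-family
#' design the package targets: 276 individuals in families of 65, 55, 45,
#' 62 and 49 members; 2,000 probes carrying 6 latent-factor coexpression
#' modules (the trait-associated one shared by all families); per-probe
#' variance components (sigma_g^2, sigma_v^2, sigma_e^2) = (1, 0.5, 1); a
#' causal trait loading on 15 genes (one per module plus background genes,
#' effect 0.3 each) with its own polygenic and residual variance, and a
#' null trait built from the same nuisance components but independent of
#' all probes. Age (years) and sex enter both probes and traits.
#'
#' @param family_sizes Integer vector of family sizes.
#' @param n_probes Total probe count.
#' @param modules Data frame with columns \code{size}, \code{loading}
#'   (latent-factor loading in \eqn{[0, 1]}) and \code{shared} (logical: module
#'   present in all families or in one family only).
#' @param sigma2_g,sigma2_v,sigma2_e Per-probe variance components.
#' @param n_causal Number of causal genes for the trait.
#' @param causal_effect Trait effect per causal gene expression unit.
#' @param trait_sigma2_g,trait_sigma2_v,trait_sigma2_e Trait nuisance
#'   variances (polygenic, shared family, residual).
#' @param age_range Age range (years); \code{age_effect} per-year effect on
#'   probes and traits; \code{sex_effect} male-female offset.
#' @param seed Mandatory integer seed.
#' @return List of class \code{fam_sim_config}.
#' @export
sim_config <- function(family_sizes = c(65, 55, 45, 62, 49),
                       n_probes = 2000,
                       modules = default_module_spec(),
                       sigma2_g = 1, sigma2_v = 0.5, sigma2_e = 1,
                       n_causal = 15, causal_effect = 0.3,
                       trait_sigma2_g = 1, trait_sigma2_v = 0.5,
                       trait_sigma2_e = 1,
                       age_range = c(20, 80), age_effect = 0.02,
                       sex_effect = 0.5, seed = 1) {
  stopifnot(all(family_sizes >= 3), n_probes >= 1,
            sum(modules$size) <= n_probes,
            all(modules$loading >= 0 & modules$loading <= 1),
            sigma2_g >= 0, sigma2_v >= 0, sigma2_e >= 0,
            length(seed) == 1, is.finite(seed))
  structure(list(family_sizes = family_sizes, n_probes = n_probes,
                 modules = modules, sigma2_g = sigma2_g, sigma2_v = sigma2_v,
                 sigma2_e = sigma2_e, n_causal = n_causal,
                 causal_effect = causal_effect,
                 trait_sigma2_g = trait_sigma2_g,
                 trait_sigma2_v = trait_sigma2_v,
                 trait_sigma2_e = trait_sigma2_e,
                 age_range = age_range, age_effect = age_effect,
                 sex_effect = sex_effect, seed = as.integer(seed)),
            class = "fam_sim_config")
}

#' @rdname sim_config
#' @export
default_module_spec <- function() {
  data.frame(size = c(150, 120, 100, 90, 80, 60),
             loading = rep(0.8, 6),
             shared = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
}

#' Read / write a simulation configuration as JSON
#' @param path JSON path.
#' @return For the reader, a \code{fam_sim_config}.
#' @export
read_sim_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$modules <- as.data.frame(j$modules)
  do.call(sim_config, j)
}

#' @rdname read_sim_config
#' @param config A \code{fam_sim_config}.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a multi-family pedigree
#'
#' Grows each family to its exact target size over 3-4 generations: a
#' founder couple starts the family, and one individual is added per step —
#' either a child of an existing couple or a founder spouse married into
#' the family, which opens a new couple. Deterministic under the config
#' seed.
#'
#' @param config A \code{fam_sim_config} (only \code{family_sizes} and
#'   \code{seed} are used), or an integer vector of family sizes with
#'   \code{seed} given separately.
#' @param seed Overrides the config seed when supplied.
#' @return A \code{fam_pedigree}.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "fam_sim_config"))
    config <- sim_config(family_sizes = config,
                         seed = if (is.null(seed)) 1 else seed)
  set.seed(if (is.null(seed)) config$seed else seed)
  rows <- list()
  for (f in seq_along(config$family_sizes)) {
    target <- config$family_sizes[f]
    fid <- paste0("F", f)
    iid <- function(k) sprintf("%s_I%03d", fid, k)
    # each row: iid, father, mother, sex, generation, married
    tab <- data.frame(iid = c(iid(1), iid(2)),
                      father = NA_character_, mother = NA_character_,
                      sex = c(1L, 2L), gen = 0L, married = c(TRUE, TRUE),
                      stringsAsFactors = FALSE)
    couples <- list(c(1L, 2L))
    n_children <- c(0L)
    k <- 2L
    while (nrow(tab) < target) {
      k <- k + 1L
      singles <- which(!tab$married & !is.na(tab$father) & tab$gen < 3L)
      open <- which(vapply(couples, function(cp) tab$gen[cp[1]] < 3L ||
                             tab$gen[cp[2]] < 3L, TRUE) & n_children < 6L)
      marry <- length(singles) > 0 && (length(open) == 0 ||
                                         stats::runif(1) < 0.35)
      if (marry) {
        s <- singles[sample.int(length(singles), 1)]
        spouse_sex <- if (tab$sex[s] == 1L) 2L else 1L
        tab <- rbind(tab, data.frame(iid = iid(k), father = NA_character_,
                                     mother = NA_character_, sex = spouse_sex,
                                     gen = tab$gen[s], married = TRUE,
                                     stringsAsFactors = FALSE))
        tab$married[s] <- TRUE
        cp <- if (tab$sex[s] == 1L) c(s, nrow(tab)) else c(nrow(tab), s)
        couples[[length(couples) + 1]] <- cp
        n_children <- c(n_children, 0L)
      } else {
        ci <- open[sample.int(length(open), 1)]
        cp <- couples[[ci]]
        gen <- max(tab$gen[cp]) + 1L
        tab <- rbind(tab, data.frame(iid = iid(k),
                                     father = tab$iid[cp[1]],
                                     mother = tab$iid[cp[2]],
                                     sex = sample(1:2, 1), gen = gen,
                                     married = FALSE, stringsAsFactors = FALSE))
        n_children[ci] <- n_children[ci] + 1L
      }
    }
    rows[[f]] <- data.frame(fid = fid, iid = tab$iid, father = tab$father,
                            mother = tab$mother, sex = tab$sex,
                            stringsAsFactors = FALSE)
  }
  as_pedigree(do.call(rbind, rows))
}

# Gene-drop additive effects: founders ~ N(0, s2), child = midparent +
# N(0, s2/2). Vectorised over n_draws independent replicates (probes or
# drops). Returns individuals x n_draws matrix; empirical covariance across
# draws converges to 2 K s2.
gene_drop_effects <- function(ped, s2, n_draws) {
  n <- nrow(ped)
  ord <- pedigree_order_or_null(ped)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  g <- matrix(0, n, n_draws)
  sd_f <- sqrt(s2); sd_m <- sqrt(s2 / 2)
  for (i in ord) {
    g[i, ] <- if (is.na(fa[i])) stats::rnorm(n_draws, 0, sd_f)
    else 0.5 * (g[fa[i], ] + g[mo[i], ]) + stats::rnorm(n_draws, 0, sd_m)
  }
  rownames(g) <- ped$iid
  g
}

#' Simulate family-structured expression with planted modules
#'
#' Per probe, \eqn{X = \lambda\,\sigma_{tot} F + \sqrt{1-\lambda^2}(g + v +
#' e) + covariate\ effects}: F is the probe's module latent factor
#' (per-sample standard normal; zero outside the module's family when the
#' module is not shared), g an additive polygenic effect generated by gene
#' dropping down the pedigree (so its covariance converges to
#' \eqn{2K\sigma_g^2}), v a family-constant draw and e i.i.d. noise, with
#' \eqn{\sigma_{tot}^2 = \sigma_g^2+\sigma_v^2+\sigma_e^2}. The loading
#' \eqn{\lambda} is thus the probe-factor correlation and the expected
#' within-module correlation is \eqn{\lambda^2}; module probes keep total
#' variance \eqn{\sigma_{tot}^2} but trade a \eqn{\lambda^2} share of
#' their polygenic/family/residual variance for factor variance.
#' Covariates (age, sex) are returned alongside so the same draws feed
#' [simulate_traits()].
#'
#' @param ped A \code{fam_pedigree}.
#' @param config A \code{fam_sim_config}.
#' @param seed Overrides the config seed when supplied.
#' @return List: \code{expr} (probes x samples), \code{truth} (module
#'   assignment per probe, module table with assigned family for non-shared
#'   modules, variance components), \code{covariates} (data frame with
#'   sample_id, age, sex).
#' @export
simulate_expression <- function(ped, config = sim_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  n <- nrow(ped)
  P <- config$n_probes
  fam <- factor(ped$fid, levels = unique(ped$fid))
  probe_ids <- sprintf("probe%05d", seq_len(P))
  mods <- config$modules
  mod_label <- rep("grey", P)
  pos <- 1L
  mod_family <- rep(NA_character_, nrow(mods))
  F_mat <- matrix(0, n, max(nrow(mods), 1))
  for (m in seq_len(nrow(mods))) {
    idx <- seq.int(pos, pos + mods$size[m] - 1L)
    mod_label[idx] <- paste0("sim_module", m)
    pos <- pos + mods$size[m]
    f <- stats::rnorm(n)
    if (!mods$shared[m]) {
      mod_family[m] <- levels(fam)[1L + (m %% nlevels(fam))]
      f[fam != mod_family[m]] <- 0
    }
    F_mat[, m] <- f
  }
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ped$sex
  sex[is.na(sex)] <- 1L
  g <- gene_drop_effects(ped, config$sigma2_g, P)          # n x P
  v <- matrix(stats::rnorm(nlevels(fam) * P, 0, sqrt(config$sigma2_v)),
              nlevels(fam), P)[as.integer(fam), , drop = FALSE]
  e <- matrix(stats::rnorm(n * P, 0, sqrt(config$sigma2_e)), n, P)
  X <- g + v + e
  s_tot <- sqrt(config$sigma2_g + config$sigma2_v + config$sigma2_e)
  for (m in seq_len(nrow(mods))) {
    idx <- which(mod_label == paste0("sim_module", m))
    lam <- mods$loading[m]
    X[, idx] <- sqrt(1 - lam^2) * X[, idx] + lam * s_tot * F_mat[, m]
  }
  X <- X + config$age_effect * (age - mean(age)) +
    config$sex_effect * (sex == 1L)
  expr <- t(X)
  dimnames(expr) <- list(probe_ids, ped$iid)
  mod_table <- mods
  mod_table$family <- mod_family
  mod_table$label <- paste0("sim_module", seq_len(max(nrow(mods), 0)))[
    seq_len(nrow(mods))]
  truth <- list(module = stats::setNames(mod_label, probe_ids),
                modules = mod_table,
                sigma2 = c(g = config$sigma2_g, v = config$sigma2_v,
                           e = config$sigma2_e))
  covariates <- data.frame(sample_id = ped$iid, age = age, sex = sex,
                           stringsAsFactors = FALSE)
  list(expr = expr, truth = truth, covariates = covariates)
}

#' Simulate causal and null quantitative traits
#'
#' The causal trait (SBP analogue) is a linear combination of the causal
#' genes' expression plus a gene-dropped polygenic effect, a shared-family
#' effect, covariate effects and noise. The null trait (Q1 analogue) is
#' built from independent draws of the same nuisance components and is
#' independent of every probe. By default causal genes are spread widely,
#' echoing a simulation model whose genes sit in different pathways: three
#' land in the first shared module (making it the trait-associated module
#' every family can recover), one in each remaining module, and the rest
#' in background probes.
#'
#' @param expr Probes x samples matrix from [simulate_expression()].
#' @param ped A \code{fam_pedigree}.
#' @param config A \code{fam_sim_config}.
#' @param covariates Data frame from [simulate_expression()] (sample_id,
#'   age, sex); regenerated if missing.
#' @param truth Truth list from [simulate_expression()]; used to place the
#'   causal genes. If \code{NULL}, causal genes are the first
#'   \code{n_causal} probes.
#' @param causal_genes Explicit causal probe ids, overriding the default
#'   placement.
#' @param seed Overrides the config seed when supplied.
#' @return List: \code{pheno} (data frame sample_id, trait_causal,
#'   trait_null, age, sex), \code{causal_genes}.
#' @export
simulate_traits <- function(expr, ped, config = sim_config(),
                            covariates = NULL, truth = NULL,
                            causal_genes = NULL, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  n <- ncol(expr)
  fam <- factor(ped$fid, levels = unique(ped$fid))
  if (is.null(covariates)) {
    covariates <- data.frame(sample_id = colnames(expr),
                             age = stats::runif(n, config$age_range[1],
                                                config$age_range[2]),
                             sex = ifelse(is.na(ped$sex), 1L, ped$sex))
  }
  causal <- if (!is.null(causal_genes)) causal_genes
  else if (!is.null(truth) && nrow(truth$modules)) {
    mt <- truth$modules
    lead <- c(mt$label[mt$shared], mt$label)[1]   # prefer a shared module
    in_mod <- function(l, k) utils::head(
      names(truth$module)[truth$module == l], k)
    picks <- in_mod(lead, min(3, config$n_causal))
    for (l in setdiff(mt$label, lead))
      if (length(picks) < config$n_causal)
        picks <- c(picks, in_mod(l, 1))
    bg <- names(truth$module)[truth$module == "grey"]
    c(picks, utils::head(bg, max(0, config$n_causal - length(picks))))
  } else utils::head(rownames(expr), config$n_causal)
  causal <- unname(causal[!is.na(causal)])
  if (!all(causal %in% rownames(expr)))
    stop("causal gene ids missing from the expression matrix")
  nuisance <- function() {
    as.numeric(gene_drop_effects(ped, config$trait_sigma2_g, 1)) +
      stats::rnorm(nlevels(fam), 0, sqrt(config$trait_sigma2_v))[
        as.integer(fam)] +
      stats::rnorm(n, 0, sqrt(config$trait_sigma2_e))
  }
  cov_part <- config$age_effect * (covariates$age - mean(covariates$age)) +
    config$sex_effect * (covariates$sex == 1L)
  y_causal <- config$causal_effect *
    colSums(expr[causal, , drop = FALSE]) + nuisance() + cov_part
  y_null <- nuisance() + cov_part
  pheno <- data.frame(sample_id = colnames(expr),
                      trait_causal = as.numeric(y_causal),
                      trait_null = as.numeric(y_null),
                      age = covariates$age, sex = covariates$sex,
                      stringsAsFactors = FALSE)
  list(pheno = pheno, causal_genes = causal)
}

#' Simulate a complete study
#'
#' Pedigree, expression and traits in one call; the one-stop generator used
#' by the tests and the command-line `simulate` subcommand.
#'
#' @param config A \code{fam_sim_config}.
#' @return List: \code{ped}, \code{expr}, \code{pheno}, \code{truth}
#'   (planted modules, causal genes, variance components).
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  ex <- simulate_expression(ped, config)
  tr <- simulate_traits(ex$expr, ped, config, covariates = ex$covariates,
                        truth = ex$truth)
  truth <- ex$truth
  truth$causal_genes <- tr$causal_genes
  list(ped = ped, expr = ex$expr, pheno = tr$pheno, truth = truth)
}
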
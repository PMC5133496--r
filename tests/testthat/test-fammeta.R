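# Small fam_network stand-ins let the matching/selection logic be tested
# without building real networks.
fake_net <- function(partition, samples = NULL) {
  structure(list(partition = partition, eigengenes = list()),
            class = "fam_network")
}

test_that("top-module selection is deterministic and tie-ruled", {
  res <- data.frame(
    unit_id = c("module1", "module2", "module1", "module3"),
    family_id = c("F1", "F1", "F2", "F2"),
    beta = c(1, 2, 0.5, 2.5), se = c(0.5, 0.5, 0.5, 0.4),
    p = c(0.04, 0.001, 0.2, 0.001), n = 20)
  top <- select_top_module(res)
  # equal smallest p; |beta|/se = 6.25 beats 4
  expect_equal(top$family_id, "F2")
  expect_equal(top$unit_id, "module3")
  expect_equal(nrow(top$per_family), 2)

  # invariant to row order
  for (i in 1:5) {
    top2 <- select_top_module(res[sample(nrow(res)), ])
    expect_equal(top2$unit_id, top$unit_id)
    expect_equal(top2$family_id, top$family_id)
  }
  expect_error(select_top_module(res[0, ]), "no usable")
})

test_that("overlap matching picks the largest shared-gene module", {
  p1 <- setNames(c(rep("module1", 5), rep("module2", 4), "grey"),
                 paste0("g", 1:10))
  p2 <- setNames(c(rep("module1", 3), rep("module2", 6), "grey"),
                 paste0("g", c(1:3, 6:12)))
  nets <- list(F1 = fake_net(p1), F2 = fake_net(p2))
  ref <- paste0("g", 1:5)            # F1's module1
  matched <- match_modules_by_overlap(ref, nets, reference_family = "F1")
  expect_equal(matched$F1, ref)      # self-match returns the reference
  expect_equal(attr(matched, "overlap")[["F1"]], 5L)
  expect_equal(matched$F2, paste0("g", 1:3))   # overlap 3 beats 0
  expect_equal(attr(matched, "overlap")[["F2"]], 3L)

  # grey is never matchable; zero overlap yields the empty set
  p3 <- setNames(c(rep("module1", 4), rep("grey", 6)), paste0("h", 1:10))
  expect_warning(
    m3 <- match_modules_by_overlap(ref, list(F3 = fake_net(p3))),
    "no module overlapping")
  expect_equal(m3$F3, character(0))
})

test_that("common sets honour intersection/union algebra", {
  matched <- list(F1 = c("a", "b", "c"), F2 = c("b", "c", "d"),
                  F3 = c("b", "c", "e"))
  cs <- build_common_sets(matched)
  expect_equal(cs$intersection, c("b", "c"))
  expect_equal(cs$union, c("a", "b", "c", "d", "e"))
  expect_true(all(cs$intersection %in% cs$union))

  same <- list(F1 = c("x", "y"), F2 = c("x", "y"))
  cs2 <- build_common_sets(same)
  expect_equal(cs2$intersection, cs2$union)

  expect_warning(cs3 <- build_common_sets(list(F1 = "a", F2 = "b")),
                 "empty")
  expect_equal(cs3$intersection, character(0))
  expect_equal(cs3$union, c("a", "b"))
  expect_error(build_common_sets(list(F1 = "a")), "at least 2")
})

test_that("family eigengene picks the candidate with the best worst-case fit", {
  # two families; intersection genes share a strong factor, union adds
  # independent genes that dilute the leading component
  set.seed(14)
  make_fam <- function(n) {
    f <- rnorm(n)
    core <- t(replicate(6, 0.95 * f + sqrt(1 - 0.95^2) * rnorm(n)))
    extra <- matrix(rnorm(8 * n), 8, n)
    x <- rbind(core, extra)
    rownames(x) <- paste0("g", 1:14)
    x
  }
  ebf <- list(F1 = make_fam(40), F2 = make_fam(35))
  colnames(ebf$F1) <- paste0("a", 1:40)
  colnames(ebf$F2) <- paste0("b", 1:35)
  sets <- build_common_sets(list(F1 = paste0("g", 1:6),
                                 F2 = paste0("g", 1:14)))
  eg <- family_eigengene(ebf, sets)
  expect_equal(eg$chosen_set, "intersection")
  expect_equal(length(eg$scores), 75)
  expect_equal(names(eg$var_explained), c("F1", "F2"))
  expect_true(min(eg$var_explained) >
                min(eg$candidate_var_explained$union))

  # single family: reduces to the plain module eigengene
  eg1 <- family_eigengene(ebf["F1"],
                          structure(list(intersection = paste0("g", 1:6),
                                         union = character(0)),
                                    class = "fam_common_sets"))
  direct <- module_eigengene(ebf$F1, paste0("g", 1:6))
  expect_equal(unname(eg1$scores), unname(direct$scores))
})

test_that("per-family module tests find a planted trait-module link", {
  st <- small_study(n_probes = 100, seed = 31,
                    modules = data.frame(size = 40, loading = 0.85,
                                         shared = TRUE))
  K <- kinship_matrix(st$ped)
  ebf <- split_by_family(st$expr, st$ped)
  nets <- family_networks(ebf, gamma = 6, min_module_size = 15)
  # trait built directly on the planted module's factor, per family
  module_genes <- names(st$truth$module)[st$truth$module == "sim_module1"]
  set.seed(32)
  eg_truth <- unlist(lapply(ebf, function(m)
    module_eigengene(m, module_genes)$scores))
  pheno <- data.frame(sample_id = unlist(lapply(ebf, colnames)),
                      y = eg_truth + rnorm(length(eg_truth), 0, 0.5))
  res <- test_family_modules(nets, pheno, "y", K, st$ped)
  expect_true(all(c("unit_id", "family_id", "beta", "se", "p") %in%
                    names(res)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  top <- select_top_module(res)
  top_genes <- nets[[top$family_id]]$eigengenes[[top$unit_id]]$genes
  expect_gt(mean(top_genes %in% module_genes), 0.8)

  # small families are skipped with a warning
  w <- capture_warnings(
    test_family_modules(nets, pheno, "y", K, st$ped,
                        min_family_size = 100))
  expect_true(all(grepl("fewer than", w)))
  expect_equal(length(w), length(nets))
})

test_that("joint eigengene test is wired through the kinship mixed model", {
  st <- small_study(n_probes = 60, seed = 33)
  K <- kinship_matrix(st$ped)
  scores <- setNames(rnorm(ncol(st$expr)), colnames(st$expr))
  out <- test_joint(scores, st$pheno, "trait_null", K, st$ped)
  expect_equal(out$family_id, "all")
  expect_true(out$p > 0 && out$p <= 1)
  expect_gt(out$se, 0)

  bad <- setNames(rnorm(5), paste0("ghost", 1:5))
  expect_error(test_joint(bad, st$pheno, "trait_null", K, st$ped),
               "missing from the phenotype")
})

test_that("Bonferroni control follows the stated arithmetic", {
  res <- data.frame(unit_id = "m", family_id = "all",
                    beta = 1, se = 1, p = c(0.01, 1e-4, 0.2), n = 10)
  adj <- bonferroni(res, n_tests = 50)
  expect_equal(adj$p_bonferroni, c(0.5, 0.005, 1))
  expect_equal(adj$significant, c(FALSE, TRUE, FALSE))
  adj45 <- bonferroni(res[2, ], n_tests = 45)
  expect_equal(adj45$p_bonferroni, 4.5e-3)
  expect_true(adj45$significant)
  expect_equal(bonferroni(res, n_tests = 1)$p_bonferroni, res$p)
  expect_error(bonferroni(res, n_tests = 0), "positive")
})

test_that("the full meta-analysis recovers a shared planted module", {
  st <- small_study(
    n_probes = 150, seed = 35,
    family_sizes = c(24, 20, 18),
    modules = data.frame(size = c(45, 35), loading = c(0.85, 0.8),
                         shared = TRUE))
  K <- kinship_matrix(st$ped)
  cv <- as.matrix(st$pheno[match(colnames(st$expr), st$pheno$sample_id),
                           c("age", "sex")])
  ex <- regress_out_covariates(st$expr, cv)
  ph <- st$pheno
  ph$trait_causal <- regress_out_covariates(ph$trait_causal, cv)
  ebf <- split_by_family(ex, st$ped)
  fm <- family_meta_analysis(ebf, ph, "trait_causal", K, st$ped,
                             gamma = 6, min_module_size = 15)
  expect_s3_class(fm, "fam_meta")
  planted <- names(st$truth$module)[st$truth$module != "grey"]
  expect_gt(mean(fm$common_sets$union %in% planted), 0.8)
  expect_true(all(fm$common_sets$intersection %in% fm$common_sets$union))
  expect_equal(sort(names(fm$matched)), sort(names(ebf)))
  expect_true(fm$eigengene$chosen_set %in% c("intersection", "union"))
})

test_that("naive tracks agree when there is no family structure", {
  # without genetic or family variance, decorrelation is a no-op up to
  # centering, so both whole-sample networks see the same signal
  ped <- simulate_pedigree(sim_config(family_sizes = c(20, 16, 14),
                                      seed = 36))
  K <- kinship_matrix(ped)
  cfg <- sim_config(family_sizes = c(20, 16, 14), n_probes = 120,
                    modules = data.frame(size = c(40, 30), loading = 0.85,
                                         shared = TRUE),
                    sigma2_g = 0, sigma2_v = 0, sigma2_e = 1,
                    age_effect = 0, sex_effect = 0, seed = 37)
  ex <- simulate_expression(ped, cfg)
  tr <- simulate_traits(ex$expr, ped, cfg, covariates = ex$covariates,
                        truth = ex$truth)
  star <- decorrelate(ex$expr, ped, K)
  nv <- naive_pipelines(ex$expr, star, tr$pheno, "trait_causal", K, ped,
                        gamma = 6, min_module_size = 15)
  expect_named(nv, c("naive", "naive_decorrelated"))
  expect_gt(adjusted_rand(nv$naive$network$partition,
                          nv$naive_decorrelated$network$partition), 0.9)
  expect_equal(sort(unique(nv$naive$tests$unit_id)),
               sort(names(nv$naive$network$eigengenes)))
})
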
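# Shared test utilities: partition agreement, planted-module expression,
# and a Monte-Carlo gene-dropping kinship oracle independent of the
# recursive implementation.

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  si <- sc(tab); sa <- sc(rowSums(tab)); sb <- sc(colSums(tab))
  ex <- sa * sb / choose(n, 2)
  (si - ex) / ((sa + sb) / 2 - ex)
}

# Probes x samples matrix with planted latent-factor modules at pairwise
# within-module correlation r, plus independent background probes.
# Truth labels: 0 = background, 1..n_mod = modules.
plant_modules <- function(n_mod = 4, size = 60, n_noise = 260, n = 100,
                          r = 0.6, seed = 1) {
  set.seed(seed)
  lam <- sqrt(r)
  X <- NULL; lab <- integer(0)
  for (m in seq_len(n_mod)) {
    f <- rnorm(n)
    X <- rbind(X, t(replicate(size, lam * f + sqrt(1 - lam^2) * rnorm(n))))
    lab <- c(lab, rep(m, size))
  }
  if (n_noise > 0) {
    X <- rbind(X, matrix(rnorm(n_noise * n), n_noise, n))
    lab <- c(lab, rep(0L, n_noise))
  }
  rownames(X) <- sprintf("p%04d", seq_len(nrow(X)))
  list(expr = X, labels = lab)
}

# Monte-Carlo kinship by dropping founder alleles down the pedigree and
# scoring identity by descent; oracle for the recursive computation.
gene_drop_kinship <- function(ped, n_drops = 20000) {
  n <- nrow(ped)
  ord <- famnet:::pedigree_order_or_null(ped)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  A1 <- matrix(0L, n, n_drops)
  A2 <- matrix(0L, n, n_drops)
  for (i in ord) {
    if (is.na(fa[i])) {
      A1[i, ] <- 2L * i - 1L
      A2[i, ] <- 2L * i
    } else {
      pick <- runif(n_drops) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa[i], ], A2[fa[i], ])
      pick <- runif(n_drops) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo[i], ], A2[mo[i], ])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (i in seq_len(n)) for (j in i:n) {
    phi <- mean((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
                  (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
    K[i, j] <- K[j, i] <- phi
  }
  K
}

# Write a small PED file and return its path.
write_ped_file <- function(ped_df, header = FALSE) {
  path <- tempfile(fileext = ".ped")
  df <- ped_df
  df$father[is.na(df$father)] <- "0"
  df$mother[is.na(df$mother)] <- "0"
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = header)
  path
}

# A trio pedigree data frame.
trio_df <- function() {
  data.frame(fid = "1", iid = c("dad", "mum", "kid"),
             father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
             sex = c(1, 2, 1), stringsAsFactors = FALSE)
}

# Small multi-family study used across tests: 3 families, quick to fit.
small_study <- function(n_probes = 120, seed = 42,
                        family_sizes = c(20, 16, 14),
                        modules = data.frame(size = min(40, n_probes %/% 3),
                                             loading = 0.8, shared = TRUE),
                        ...) {
  simulate_study(sim_config(family_sizes = family_sizes,
                            n_probes = n_probes, modules = modules,
                            seed = seed, ...))
}
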
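test_that("EV pruning keeps the higher-priority member of a correlated pair", {
  tab <- data.frame(population_id = paste0("P", 1:8),
                    evA = 1:8, evB = (1:8) * 2 + 0.0, evC = c(8:1) %% 3)
  kept <- prune_evs(tab, threshold = 0.8)
  expect_true("evA" %in% kept)
  expect_false("evB" %in% kept)          # |r| = 1 with evA
  kept2 <- prune_evs(tab, threshold = 0.8, priority = c("evB", "evA", "evC"))
  expect_true("evB" %in% kept2)
  expect_false("evA" %in% kept2)
})

test_that("orthogonal EVs all survive pruning", {
  set.seed(14)
  tab <- data.frame(population_id = paste0("P", 1:40),
                    a = rnorm(40), b = rnorm(40), c = rnorm(40))
  expect_setequal(prune_evs(tab, threshold = 0.8), c("a", "b", "c"))
})

test_that("pruning a planted correlation structure matches the greedy oracle", {
  set.seed(15)
  n <- 30
  base <- rnorm(n)
  tab <- data.frame(population_id = paste0("P", 1:n),
                    e1 = base,
                    e2 = base + rnorm(n, 0, 0.1),     # ~0.99 with e1
                    e3 = rnorm(n),
                    e4 = base + rnorm(n, 0, 1.5),     # moderate with e1
                    e5 = -base + rnorm(n, 0, 0.2))    # ~ -0.98 with e1
  pri <- c("e1", "e2", "e3", "e4", "e5")
  expect_identical(prune_evs(tab, threshold = 0.8, priority = pri),
                   oracle_greedy_prune(tab, 0.8, pri))
})

test_that("latent factors recover planted group structure", {
  b <- default_bundle()
  U <- fit_latent_factors(b$genotypes, 3)
  grp <- b$samples$group_id[match(b$genotypes$samples,
                                  b$samples$sample_id)]
  cent <- apply(U, 2, function(u) tapply(u, grp, mean))
  assign <- apply(U, 1, function(u)
    rownames(cent)[which.min(colSums((t(cent) - u)^2))])
  expect_gte(mean(assign == grp), 0.95)
  gram <- crossprod(U)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  U0 <- fit_latent_factors(b$genotypes, 0)
  expect_equal(ncol(U0), 0L)
})

test_that("the K = 0 scan z equals the textbook OLS t statistic", {
  set.seed(16)
  n <- 50
  g <- flat_gm(n, 30, seed = 16)
  env <- env_frame(data.frame(population_id = paste0("P", 1:n),
                              evA = rnorm(n)))
  sf <- data.frame(sample_id = g$samples,
                   population_id = paste0("P", 1:n))
  sc <- lfmm_scan(g, env, sf, fit_latent_factors(g, 0), evs = "evA")
  e <- env$current$evA
  for (j in sample(30, 10)) {
    expect_equal(sc$z[j], oracle_ols_t(g$dosage[, j], e),
                 tolerance = 1e-10)
  }
})

test_that("the scan is invariant to locus order and EV affine rescaling", {
  b <- default_bundle()
  g <- gm_subset(b$genotypes, loci = 1:400)
  U <- fit_latent_factors(b$genotypes, 3)
  sc1 <- lfmm_scan(g, b$env, b$samples, U, evs = "bio1")
  env2 <- b$env
  env2$current$bio1 <- env2$current$bio1 * 100 - 7
  sc2 <- lfmm_scan(g, env2, b$samples, U, evs = "bio1")
  expect_equal(sc1$z, sc2$z, tolerance = 1e-8)
  expect_equal(sc1$effect, sc2$effect * 100, tolerance = 1e-8)
})

test_that("BH q-values are monotone in calibrated p within each EV", {
  b <- default_bundle()
  U <- fit_latent_factors(b$genotypes, 3)
  sc <- lfmm_scan(b$genotypes, b$env, b$samples, U,
                  evs = c("bio1", "bio13"))
  for (ev in c("bio1", "bio13")) {
    s <- sc[sc$ev == ev, ]
    ord <- order(s$p_adj)
    expect_true(all(diff(s$q[ord]) >= -1e-12))
  }
})

test_that("key-EAL sets shrink as thresholds tighten", {
  b <- default_bundle()
  U <- fit_latent_factors(b$genotypes, 3)
  loose <- lfmm_scan(b$genotypes, b$env, b$samples, U, evs = "bio1",
                     z_min = 2, p_max = 1e-2)
  mid <- lfmm_scan(b$genotypes, b$env, b$samples, U, evs = "bio1",
                   z_min = 4, p_max = 1e-5)
  tight <- lfmm_scan(b$genotypes, b$env, b$samples, U, evs = "bio1",
                     z_min = 6, p_max = 1e-8)
  expect_true(all(mid$id[mid$key] %in% loose$id[loose$key]))
  expect_true(all(tight$id[tight$key] %in% mid$id[mid$key]))
})

test_that("a collinear EV/latent-factor design is reported per EV", {
  tg <- two_group_gm(n_per = 20, L = 300, f = 0.4, seed = 18)
  g <- tg$g
  U <- fit_latent_factors(g, 1)
  # an EV that is exactly the first latent factor (each sample its own
  # population) leaves no identifiable environmental effect
  env <- env_frame(data.frame(population_id = paste0("P", 1:40),
                              evA = as.numeric(U[, 1])))
  sf <- data.frame(sample_id = g$samples,
                   population_id = paste0("P", 1:40))
  expect_error(lfmm_scan(g, env, sf, U, evs = "evA"), "collinear|reduce K")
})

test_that("the F_ST-outlier prescreen keeps the expected top fraction", {
  b <- default_bundle()
  keep_all <- fst_outlier_prescreen(b$genotypes, b$samples, q = 1)
  site <- wc_fst(b$genotypes,
                 split(b$samples$sample_id, b$samples$population_id),
                 per_site = TRUE)
  expect_equal(sum(keep_all), sum(!is.na(site$fst)))
  keep <- fst_outlier_prescreen(b$genotypes, b$samples, q = 0.01)
  expect_lte(sum(keep), 0.01 * sum(!is.na(site$fst)) + 1)
  # planted sweep loci carry extreme divergence: strongly enriched
  cls <- b$truth$loci$class[match(b$genotypes$loci$id, b$truth$loci$id)]
  expect_gt(mean(cls[keep] != "neutral"), mean(cls != "neutral") * 3)
})

test_that("two-proportion tests match the closed-form oracle", {
  res <- eal_annotation_classes(c(rep("ns", 30), rep("syn", 370)),
                                c(rep("ns", 15), rep("syn", 585)))
  ns <- res[res$class == "ns", ]
  orc <- oracle_two_prop(30, 400, 15, 600)
  expect_equal(ns$z, orc$z, tolerance = 1e-10)
  expect_equal(ns$p, orc$p, tolerance = 1e-10)
  # swapping the groups flips the sign, keeps the p-value
  res2 <- eal_annotation_classes(c(rep("ns", 15), rep("syn", 585)),
                                 c(rep("ns", 30), rep("syn", 370)))
  ns2 <- res2[res2$class == "ns", ]
  expect_equal(ns2$z, -ns$z, tolerance = 1e-12)
  expect_equal(ns2$p, ns$p, tolerance = 1e-12)
})

test_that("equal proportions give z = 0, p = 1; zero classes are flagged", {
  res <- eal_annotation_classes(c(rep("a", 10), rep("b", 10)),
                                c(rep("a", 50), rep("b", 50)))
  expect_equal(res$z[res$class == "a"], 0)
  expect_equal(res$p[res$class == "a"], 1)
  res2 <- eal_annotation_classes(rep("a", 10),
                                 c(rep("a", 5), rep("b", 5)))
  expect_true(res2$exact_flag[res2$class == "b"])
})
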
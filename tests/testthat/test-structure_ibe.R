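test_that("PC1 separates two Balding-Nichols groups perfectly", {
  tg <- two_group_gm(n_per = 30, L = 500, f = 0.3)
  pc <- genotype_pca(tg$g, K = 2)
  s1 <- pc$scores[tg$groups$A, 1]
  s2 <- pc$scores[tg$groups$B, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("explained fractions are complete at K = n - 1 and decreasing", {
  g <- flat_gm(15, 200, seed = 21)
  pc <- genotype_pca(g, K = 14)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-12))
  gram <- crossprod(pc$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("duplicating every sample preserves PC1 loadings up to scale", {
  tg <- two_group_gm(n_per = 15, L = 300, f = 0.3, seed = 8)
  g <- tg$g
  d2 <- rbind(g$dosage, g$dosage)
  rownames(d2) <- c(g$samples, paste0(g$samples, "_dup"))
  g2 <- genotype_matrix(d2, g$loci)
  l1 <- genotype_pca(g, K = 1)$loadings[, 1]
  l2 <- genotype_pca(g2, K = 1)$loadings[, 1]
  expect_gt(abs(cor(l1, l2)), 1 - 1e-6)
})

test_that("PCA scores are invariant to locus order", {
  tg <- two_group_gm(n_per = 10, L = 200, f = 0.3, seed = 9)
  g <- tg$g
  set.seed(1)
  perm <- sample(ncol(g$dosage))
  g2 <- genotype_matrix(g$dosage[, perm], g$loci[perm, ])
  expect_equal(abs(genotype_pca(g, K = 2)$scores),
               abs(genotype_pca(g2, K = 2)$scores), tolerance = 1e-8)
})

test_that("haversine distances honor identity, symmetry and antipodes", {
  sf <- data.frame(sample_id = c("a", "b", "c"),
                   population_id = c("P1", "P2", "P3"),
                   latitude = c(10, 10, 0), longitude = c(20, 20, 0))
  m <- geographic_distance_km(sf)
  expect_equal(m["P1", "P2"], 0)
  sf2 <- data.frame(sample_id = c("a", "b"),
                    population_id = c("P1", "P2"),
                    latitude = c(0, 0), longitude = c(0, 180))
  m2 <- geographic_distance_km(sf2)
  expect_equal(m2["P1", "P2"], 20015, tolerance = 1 / 20015)
  set.seed(2)
  sf3 <- data.frame(sample_id = letters[1:6],
                    population_id = paste0("P", 1:6),
                    latitude = runif(6, -80, 80),
                    longitude = runif(6, -170, 170))
  m3 <- geographic_distance_km(sf3)
  expect_equal(m3, t(m3))
  expect_true(all(diag(m3) == 0))
})

test_that("environmental distance is the Euclidean metric on z-scores", {
  env <- env_frame(data.frame(population_id = c("P1", "P2", "P3"),
                              evA = c(-1, 0, 1), evB = c(5, 5, 5)))
  expect_warning(m <- env_distance(env), "zero-variance")
  expect_equal(m["P1", "P2"] * 2, m["P1", "P3"])
  # z-scoring makes the matrix unit-invariant
  env2 <- env_frame(data.frame(population_id = c("P1", "P2", "P3"),
                               evA = c(-1000, 0, 1000)))
  m2 <- env_distance(env2)
  expect_equal(unclass(m2)[1:3, 1:3],
               unclass(suppressWarnings(env_distance(env)))[1:3, 1:3])
  env3 <- env_frame(data.frame(population_id = c("P1", "P2"),
                               evA = c(3, 3)))
  expect_error(suppressWarnings(env_distance(env3)), "no EVs")
})

test_that("identical environments give zero distance", {
  env <- env_frame(data.frame(population_id = c("P1", "P2", "P3"),
                              evA = c(2, 2, 7), evB = c(1, 1, 3)))
  m <- env_distance(env)
  expect_equal(m["P1", "P2"], 0)
})

test_that("linearized F_ST is consistent with the raw genome-wide value", {
  b <- default_bundle()
  sf <- b$samples
  keep_pops <- c("NW1", "SW1", "TH1", "NC1")
  sfk <- sf[sf$population_id %in% keep_pops, ]
  m <- fst_linearized(b$genotypes, sfk)
  # recompute one pair directly and apply x/(1-x)
  pr <- split(sfk$sample_id, sfk$population_id)[c("NW1", "SW1")]
  site <- wc_fst(b$genotypes, pr, per_site = TRUE)
  fst <- max(0, sum(site$a, na.rm = TRUE) /
               sum(site$a + site$b + site$c, na.rm = TRUE))
  expect_equal(m["NW1", "SW1"], fst / (1 - fst), tolerance = 1e-12)
  expect_true(all(m >= 0))
  expect_equal(unclass(m), t(unclass(m)))
})

test_that("identical populations have near-zero linearized F_ST", {
  set.seed(31)
  p <- runif(1200, 0.2, 0.8)
  d <- matrix(rbinom(24 * 1200, 2, rep(p, each = 24)), 24, 1200)
  rownames(d) <- paste0("s", 1:24)
  g <- genotype_matrix(d, data.frame(chrom = "chr1",
                                     pos = seq_len(1200) * 50L,
                                     id = paste0("v", 1:1200), ref = "A",
                                     alt = "T"))
  sf <- data.frame(sample_id = g$samples,
                   population_id = rep(c("P1", "P2"), each = 12))
  m <- fst_linearized(g, sf)
  expect_lt(m["P1", "P2"], 0.01)
})

test_that("Mantel test is exact on self-comparison and argument-symmetric", {
  A <- rand_dist(10, seed = 1)
  m <- mantel_test(A, A, n_perm = 999, seed = 3)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 1000)
  B <- rand_dist(10, seed = 2)
  m1 <- mantel_test(A, B, n_perm = 499, seed = 4)
  m2 <- mantel_test(B, A, n_perm = 499, seed = 4)
  expect_identical(m1, m2)
  expect_gte(m1$p, 1 / 500)
  expect_error(mantel_test(A, B, n_perm = 50), "99")
  C <- A * 0
  expect_error(mantel_test(C, B, n_perm = 99), "constant")
})

test_that("Mantel statistic agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  A <- rand_dist(12, seed = 5)
  B <- rand_dist(12, seed = 6)
  m <- mantel_test(A, B, n_perm = 99, seed = 1)
  vm <- vegan::mantel(A, B, permutations = 99)
  expect_equal(m$r, unname(vm$statistic), tolerance = 1e-12)
})

test_that("planted geographic drift gradient yields significant IBD", {
  b <- default_bundle()
  geo <- geographic_distance_km(b$samples)
  fst <- fst_linearized(b$genotypes, b$samples)
  m <- mantel_test(fst, geo, n_perm = 999, seed = 7)
  expect_gt(m$r, 0)
  expect_lte(m$p, 0.01)
})

test_that("greedy LD pruning removes high-r^2 neighbours", {
  b <- default_bundle()
  g <- b$genotypes
  keep <- ld_prune(g, r2_max = 0.2, window_bp = 50000)
  expect_true(any(!keep))
  gk <- gm_subset(g, loci = keep)
  # verify the constraint on one chromosome slice
  li <- which(gk$loci$chrom == "chr1")[1:50]
  d <- gk$dosage[, li]
  pos <- gk$loci$pos[li]
  for (i in 2:50) {
    close <- which(pos[1:(i - 1)] >= pos[i] - 50000)
    if (length(close)) {
      r2 <- suppressWarnings(
        cor(d[, i], d[, close, drop = FALSE],
            use = "pairwise.complete.obs"))^2
      expect_true(all(r2 <= 0.2 + 1e-12, na.rm = TRUE))
    }
  }
})
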
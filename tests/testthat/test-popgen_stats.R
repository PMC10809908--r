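test_that("allele frequencies count called alleles only", {
  d <- rbind(c(0L, NA), c(1L, NA), c(1L, NA), c(2L, NA))
  rownames(d) <- paste0("s", 1:4)
  g <- genotype_matrix(d, data.frame(chrom = "chr1", pos = c(10L, 20L),
                                     id = c("a", "b"), ref = "A",
                                     alt = "T"))
  af <- allele_frequencies(g)
  expect_equal(af$freq[1], 0.5)        # 4 ALT / 8 called alleles
  expect_true(is.na(af$freq[2]))       # all missing: undefined, not 0
  expect_equal(af$n_called, c(8L, 0L))
  expect_error(allele_frequencies(g, samples = "nope"), "unknown")
})

test_that("single-SNP window pi matches the hand computation", {
  d <- matrix(c(0L, 1L, 1L, 2L), ncol = 1)
  rownames(d) <- paste0("s", 1:4)
  g <- genotype_matrix(d, data.frame(chrom = "chr1", pos = 5000L, id = "a",
                                     ref = "A", alt = "T"))
  tr <- windowed_pi(g, length_bp = 10000, step_bp = 10000)
  # 4 ALT among 8 alleles: 4*4 differing pairs of C(8,2)=28
  expect_equal(tr$value[1], (16 / 28) / 10000, tolerance = 1e-15)
})

test_that("monomorphic windows have pi exactly zero", {
  d <- matrix(2L, nrow = 4, ncol = 3)
  rownames(d) <- paste0("s", 1:4)
  g <- genotype_matrix(d, data.frame(chrom = "chr1",
                                     pos = c(100L, 200L, 300L),
                                     id = letters[1:3], ref = "A",
                                     alt = "T"))
  expect_true(all(windowed_pi(g, length_bp = 1000)$value == 0))
})

test_that("windowed pi equals the brute-force pairwise oracle", {
  b <- default_bundle()
  g <- b$genotypes
  sub <- gm_subset(g, samples = sample(g$samples, 20))
  tr <- windowed_pi(sub, length_bp = 50000, step_bp = 50000)
  sp_pi <- vapply(seq_len(ncol(sub$dosage)),
                  function(j) oracle_pi_site(sub$dosage[, j]), 1)
  sp_pi[is.na(sp_pi)] <- 0
  set.seed(3)
  for (k in sample(nrow(tr), 50)) {
    idx <- sub$loci$chrom == tr$chrom[k] & sub$loci$pos >= tr$start[k] &
      sub$loci$pos <= tr$end[k]
    expect_equal(tr$value[k], sum(sp_pi[idx]) / 50000, tolerance = 1e-12)
  }
})

test_that("non-overlapping window pi counts tile the genome total", {
  b <- default_bundle()
  g <- gm_subset(b$genotypes, samples = b$genotypes$samples[1:15])
  tr <- windowed_pi(g, length_bp = 100000, step_bp = 100000)
  total_windows <- sum(tr$value) * 100000
  sp_pi <- vapply(seq_len(ncol(g$dosage)),
                  function(j) oracle_pi_site(g$dosage[, j]), 1)
  expect_equal(total_windows, sum(sp_pi, na.rm = TRUE),
               tolerance = 1e-10)
})

test_that("fixed allele difference between groups gives site F_ST of 1", {
  d <- rbind(matrix(0L, 10, 1), matrix(2L, 10, 1))
  rownames(d) <- paste0("s", 1:20)
  g <- genotype_matrix(d, data.frame(chrom = "chr1", pos = 50L, id = "a",
                                     ref = "A", alt = "T"))
  site <- wc_fst(g, list(A = paste0("s", 1:10), B = paste0("s", 11:20)),
                 per_site = TRUE)
  expect_equal(site$fst, 1)
})

test_that("identical genotype distributions give non-positive site F_ST", {
  gts <- c(rep(0L, 4), rep(1L, 4), rep(2L, 2))
  d <- matrix(c(gts, gts), ncol = 1)
  rownames(d) <- paste0("s", 1:20)
  g <- genotype_matrix(d, data.frame(chrom = "chr1", pos = 50L, id = "a",
                                     ref = "A", alt = "T"))
  site <- wc_fst(g, list(A = paste0("s", 1:10), B = paste0("s", 11:20)),
                 per_site = TRUE)
  expect_lte(site$fst, 0)
  expect_equal(site$fst,
               oracle_wc_site(list(d[1:10, 1], d[11:20, 1])),
               tolerance = 1e-14)
})

test_that("site F_ST matches the clean-room Weir-Cockerham oracle", {
  b <- default_bundle()
  g <- b$genotypes
  pops <- split(b$samples$sample_id, b$samples$population_id)
  site <- wc_fst(g, pops, per_site = TRUE)
  set.seed(11)
  for (j in sample(nrow(site), 200)) {
    geno <- lapply(pops, function(ids)
      g$dosage[match(ids, g$samples), j])
    expect_equal(site$fst[j], oracle_wc_site(geno), tolerance = 1e-12)
  }
})

test_that("splitting one group at random gives mean F_ST near zero", {
  # one panmictic pool with heterogeneous per-locus frequencies
  set.seed(13)
  p <- runif(1500, 0.1, 0.9)
  d <- matrix(rbinom(40 * 1500, 2, rep(p, each = 40)), 40, 1500)
  rownames(d) <- paste0("s", 1:40)
  g <- genotype_matrix(d, data.frame(chrom = "chr1",
                                     pos = seq_len(1500) * 100L,
                                     id = paste0("v", 1:1500), ref = "A",
                                     alt = "T"))
  split_a <- paste0("s", 1:20)
  site <- wc_fst(g, list(A = split_a, B = setdiff(g$samples, split_a)),
                 per_site = TRUE)
  expect_lt(abs(mean(site$fst, na.rm = TRUE)), 0.01)
})

test_that("windowed F_ST is the ratio of summed variance components", {
  b <- default_bundle()
  g <- b$genotypes
  groups <- split(b$samples$sample_id, b$samples$group_id)
  tr <- wc_fst(g, groups, length_bp = 100000, step_bp = 100000)
  site <- wc_fst(g, groups, per_site = TRUE)
  k <- which.max(tr$n_sites)
  idx <- site$chrom == tr$chrom[k] & site$pos >= tr$start[k] &
    site$pos <= tr$end[k] & !is.na(site$a)
  expect_equal(tr$value[k],
               sum(site$a[idx]) / sum(site$a[idx] + site$b[idx] +
                                        site$c[idx]),
               tolerance = 1e-12)
  expect_true(all(tr$value <= 1, na.rm = TRUE))
})

test_that("pi and F_ST tracks are invariant to sample order", {
  b <- default_bundle()
  g <- b$genotypes
  set.seed(5)
  perm <- sample(g$samples)
  gp <- gm_subset(g, samples = perm)
  sub <- g$samples[1:30]
  expect_equal(windowed_pi(g, samples = sub)$value,
               windowed_pi(gp, samples = sub)$value)
  groups <- split(b$samples$sample_id, b$samples$group_id)
  expect_equal(wc_fst(g, groups)$value, wc_fst(gp, groups)$value)
})

test_that("constructed window with theta_pi == theta_W has D exactly 0", {
  # 10 sites with 2 diploids called (x=1, site pi = 1/2) plus 1 site with
  # a single called diploid (x=1, site pi = 1): theta_pi = 6; S = 11;
  # modal m = 4 so a1 = 11/6 and theta_W = 11/a1 = 6
  dos <- matrix(NA_integer_, 3, 11)
  dos[2, 1:10] <- 1L
  dos[3, 1:10] <- 0L
  dos[2, 11] <- 1L
  g <- genotype_matrix(dos, data.frame(chrom = "chr1", pos = (1:11) * 10L,
                                       id = paste0("s", 1:11), ref = "A",
                                       alt = "T"),
                       samples = c("a", "b", "c"))
  td <- tajimas_d(g, length_bp = 1000)
  expect_identical(td$value[1], 0)
})

test_that("windowed Tajima's D matches the constants-from-scratch oracle", {
  b <- default_bundle()
  g <- gm_subset(b$genotypes, samples = b$genotypes$samples[1:25])
  td <- tajimas_d(g, length_bp = 100000)
  for (k in which(!is.na(td$value))[1:15]) {
    idx <- g$loci$chrom == td$chrom[k] & g$loci$pos >= td$start[k] &
      g$loci$pos <= td$end[k]
    expect_equal(td$value[k],
                 oracle_tajima_window(g$dosage[, idx, drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("windows below the minimum call count are undefined with warning", {
  dos <- matrix(c(0L, 1L), 1, 2)          # single diploid: m = 2 < 4
  g <- genotype_matrix(dos, data.frame(chrom = "chr1", pos = c(10L, 20L),
                                       id = c("a", "b"), ref = "A",
                                       alt = "T"), samples = "s1")
  expect_warning(td <- tajimas_d(g, length_bp = 1000), "modal")
  expect_true(all(is.na(td$value)))
})

test_that("mean windowed D is near zero on a neutral panmictic fixture", {
  cfg <- sim_config(n_groups = 1, pops_per_group = 1, inds_per_pop = 60,
                    n_chrom = 2, chrom_length_bp = 5e6,
                    n_neutral_loci = 20000, n_adaptive_loci = 0,
                    fst_between_groups = 0.005, fst_within_group = 0.001,
                    sweep_regions = list(), n_junk_sites = 0,
                    missing_rate = 0, maf_floor = 0,
                    ancestral_spectrum = "neutral", seed = 13)
  b <- simulate_dataset(cfg)
  td <- tajimas_d(b$genotypes, length_bp = 100000)
  expect_gte(sum(!is.na(td$value)), 100)
  expect_lt(abs(mean(td$value, na.rm = TRUE)), 0.5)
})

test_that("duplicated loci have r^2 of 1 in their distance bin", {
  set.seed(9)
  col <- rbinom(30, 2, 0.5)
  d <- cbind(col, col, rbinom(30, 2, 0.5))
  rownames(d) <- paste0("s", 1:30)
  g <- genotype_matrix(d, data.frame(chrom = "chr1",
                                     pos = c(100L, 4100L, 90000L),
                                     id = c("a", "b", "c"), ref = "A",
                                     alt = "T"))
  curve <- ld_decay(g, max_dist = 100000, bin_width = 5000)
  expect_equal(curve$bins$mean_r2[1], 1)   # the duplicate pair at 4 kb
})

test_that("independent loci have mean r^2 near the 1/n sampling floor", {
  g <- flat_gm(100, 800, p = 0.5, seed = 17)
  curve <- ld_decay(g, max_dist = 500000, bin_width = 100000)
  overall <- sum(curve$bins$mean_r2 * curve$bins$n_pairs, na.rm = TRUE) /
    sum(curve$bins$n_pairs)
  expect_lt(overall, 3 / 100)
  expect_gt(overall, 1 / (3 * 100))
})

test_that("pairs with too few jointly called samples are skipped", {
  d <- cbind(c(0L, 1L, NA, NA, NA, NA), c(NA, NA, 0L, 1L, 2L, 0L))
  rownames(d) <- paste0("s", 1:6)
  g <- genotype_matrix(d, data.frame(chrom = "chr1", pos = c(10L, 500L),
                                     id = c("a", "b"), ref = "A",
                                     alt = "T"))
  curve <- ld_decay(g, max_dist = 10000, bin_width = 1000)
  expect_equal(sum(curve$bins$n_pairs), 0L)
})
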
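test_that("population retention honors the more-than-six-individuals rule", {
  set.seed(61)
  d <- matrix(rbinom(13 * 50, 2, 0.4), 13, 50)
  rownames(d) <- paste0("s", 1:13)
  g <- genotype_matrix(d, data.frame(chrom = "chr1",
                                     pos = seq_len(50) * 100L,
                                     id = paste0("v", 1:50), ref = "A",
                                     alt = "T"))
  sf <- data.frame(sample_id = g$samples,
                   population_id = c(rep("P6", 6), rep("P7", 7)))
  expect_message(fq <- pop_allele_freqs(g, sf, min_inds = 7), "dropped")
  expect_equal(rownames(fq), "P7")
  expect_error(pop_allele_freqs(g, sf, min_inds = 20), "below")
})

test_that("retained-population count matches the generator's cohort", {
  b <- default_bundle()
  fq <- suppressMessages(pop_allele_freqs(b$genotypes, b$samples,
                                          min_inds = 7))
  sizes <- table(b$samples$population_id)
  expect_equal(nrow(fq), sum(sizes >= 7))
  # frequencies are computed over called alleles
  p1 <- rownames(fq)[1]
  ids <- b$samples$sample_id[b$samples$population_id == p1]
  sub <- b$genotypes$dosage[match(ids, b$genotypes$samples), 1]
  expect_equal(fq[1, 1], sum(sub, na.rm = TRUE) /
                 (2 * sum(!is.na(sub))))
})

test_that("a noiseless linear cline recovers the textbook example", {
  # f = 0.1 + 0.02 * EV across populations (R^2 = 1); a population at
  # EV 10 (f = 0.30) facing future EV 15 requires 0.40: RONA = 0.10
  ev <- c(P1 = 0, P2 = 5, P3 = 10, P4 = 2.5, P5 = 7.5)
  fq <- matrix(0.1 + 0.02 * ev, ncol = 1,
               dimnames = list(names(ev), "locus1"))
  fut <- ev + 5
  res <- rona_per_population(fq, ev, fut)
  expect_equal(res$rona[res$population == "P3"], 0.10, tolerance = 1e-12)
  expect_equal(res$rona, rep(0.10, 5), tolerance = 1e-12)
})

test_that("required frequencies are clamped to [0, 1] before distances", {
  ev <- c(P1 = 0, P2 = 5, P3 = 10)
  fq <- matrix(0.2 + 0.07 * ev, ncol = 1,
               dimnames = list(names(ev), "L1"))   # 0.2, 0.55, 0.9
  fut <- ev + 10                                    # prediction 0.9..1.6
  res <- rona_per_population(fq, ev, fut)
  expect_equal(res$rona[3], 1.0 - 0.9, tolerance = 1e-12)   # clamped
  expect_gt(res$rona_unclamped[3], res$rona[3])             # diagnostic
})

test_that("zero-weight loci do not move the weighted average", {
  set.seed(62)
  ev <- setNames(seq(0, 10, length.out = 8), paste0("P", 1:8))
  f1 <- 0.1 + 0.05 * ev                 # informative cline
  f2 <- rep(0.4, 8)                     # constant: R^2 = 0
  fq1 <- matrix(f1, ncol = 1, dimnames = list(names(ev), "La"))
  fq12 <- cbind(fq1, Lb = f2)
  r1 <- rona_per_population(fq1, ev, ev + 3)
  r12 <- rona_per_population(fq12, ev, ev + 3)
  expect_equal(r1$rona, r12$rona, tolerance = 1e-12)
})

test_that("RONA is invariant to affine rescaling of the EV", {
  set.seed(63)
  ev <- setNames(runif(10, 0, 20), paste0("P", 1:10))
  fq <- matrix(runif(10 * 6, 0.1, 0.9), 10, 6,
               dimnames = list(names(ev), paste0("L", 1:6)))
  r1 <- rona_per_population(fq, ev, ev + 4)
  ev2 <- ev * 9 / 5 + 32
  r2 <- rona_per_population(fq, ev2, ev2 + 4 * 9 / 5)
  expect_equal(r1$rona, r2$rona, tolerance = 1e-10)
})

test_that("degenerate inputs fail loudly or warn", {
  ev <- c(P1 = 1, P2 = 1, P3 = 1)
  fq <- matrix(runif(3), 3, 1, dimnames = list(names(ev), "L1"))
  expect_error(rona_per_population(fq, ev, ev + 1), "constant")
  ev2 <- c(P1 = 1, P2 = 2, P3 = 3)
  expect_warning(r <- rona_per_population(fq[, 0, drop = FALSE], ev2,
                                          ev2 + 1), "empty")
  expect_true(all(is.na(r$rona)))
  expect_error(rona_per_population(fq[1:2, , drop = FALSE], ev2[1:2],
                                   ev2[1:2]), ">= 3")
})

test_that("model aggregation computes mean, SE and scenario contrast", {
  cells <- expand.grid(population = c("P1", "P2"), ev = "bio1",
                       scenario = c("SSP126", "SSP585"),
                       model = c("m1", "m2", "m3"),
                       stringsAsFactors = FALSE)
  cells$rona <- ifelse(cells$scenario == "SSP585", 0.2, 0.1)
  cells$rona[cells$population == "P1" & cells$scenario == "SSP126"] <-
    c(0.1, 0.2, 0.3)
  agg <- aggregate_models(cells)
  p1lo <- agg$summary[agg$summary$population == "P1" &
                        agg$summary$scenario == "SSP126", ]
  expect_equal(p1lo$mean, 0.2)
  expect_equal(p1lo$se, sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  ident <- agg$summary[agg$summary$population == "P2" &
                         agg$summary$scenario == "SSP585", ]
  expect_equal(ident$se, 0)
  expect_equal(agg$contrast$delta[agg$contrast$population == "P2"], 0.1)
  expect_warning(aggregate_models(cells[cells$model == "m1", ]),
                 "single-model")
})

test_that("larger planted EV shifts produce larger maladaptation risk", {
  b <- default_bundle()
  fq <- suppressMessages(pop_allele_freqs(b$genotypes, b$samples,
                                          min_inds = 7))
  sc <- lfmm_scan(b$genotypes, b$env, b$samples,
                  fit_latent_factors(b$genotypes, 3), evs = "bio1")
  loc <- intersect(unique(sc$id[sc$p_adj < 1e-3]), colnames(fq))
  skip_if(length(loc) < 3, "too few associated loci in fixture")
  ev <- setNames(b$env$current$bio1, b$env$current$population_id)
  shifts <- c(0.5, 1, 2, 4)
  means <- vapply(shifts, function(dl)
    mean(rona_per_population(fq[, loc], ev, ev + dl)$rona), 1)
  expect_true(all(diff(means) > 0))
  # across-model correlation mirrors similar-shift models
  r1 <- rona_per_population(fq[, loc], ev, ev + 1.8)$rona
  r2 <- rona_per_population(fq[, loc], ev, ev + 2.0)$rona
  expect_gt(cor(r1, r2, method = "spearman"), 0.9)
})
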
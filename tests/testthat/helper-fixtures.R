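# Shared small fixtures, built once per test run.

# mid-sized hierarchical bundle with planted signal of every kind
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(
        n_neutral_loci = 3000, n_adaptive_loci = 30, n_chrom = 2,
        chrom_length_bp = 1500000,
        sweep_regions = list(list(group = "NW", chrom = "chr1",
                                  start = 500001, end = 600000,
                                  diversity_reduction_factor = 0.15,
                                  divergence_boost = 3)),
        seed = 4242))
    }
    cache
  }
})

# plain genotype matrix without structure: n diploids, iid Binomial(2, p)
flat_gm <- function(n, L, p = 0.4, seed = 1, chrom = "chr1",
                    spacing = 1000L) {
  set.seed(seed)
  d <- matrix(rbinom(n * L, 2, p), n, L)
  rownames(d) <- paste0("s", seq_len(n))
  loci <- data.frame(chrom = chrom, pos = seq_len(L) * spacing,
                     id = paste0("v", seq_len(L)),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(d, loci)
}

# two Balding-Nichols groups (no geography), for structure tests
two_group_gm <- function(n_per = 30, L = 500, f = 0.3, seed = 2) {
  set.seed(seed)
  p0 <- runif(L, 0.2, 0.8)
  p1 <- rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  p2 <- rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  d <- rbind(
    matrix(rbinom(n_per * L, 2, rep(p1, each = n_per)), n_per, L),
    matrix(rbinom(n_per * L, 2, rep(p2, each = n_per)), n_per, L))
  rownames(d) <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  loci <- data.frame(chrom = "chr1", pos = seq_len(L) * 997L,
                     id = paste0("v", seq_len(L)), ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  list(g = genotype_matrix(d, loci),
       groups = list(A = paste0("a", seq_len(n_per)),
                     B = paste0("b", seq_len(n_per))))
}

# labeled symmetric random distance matrix
rand_dist <- function(n = 10, seed = 1, labels = paste0("p", seq_len(n))) {
  set.seed(seed)
  m <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(m) <- list(labels, labels)
  m
}
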
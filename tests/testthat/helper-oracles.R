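# Independent clean-room oracles.  These re-derive each statistic from its
# published definition with scalar arithmetic and a different
# parameterization than the package implementation, so agreement is
# evidence of correctness rather than shared code.

# Weir & Cockerham (1984) variance components for one site, from raw
# dosage vectors per population.  Populations with fewer than two called
# individuals at the site are excluded (matching the analysis rule).
oracle_wc_site <- function(geno_by_pop) {
  gs <- lapply(geno_by_pop, function(g) g[!is.na(g)])
  gs <- gs[vapply(gs, length, 1L) >= 2L]
  r <- length(gs)
  if (r < 2) return(NA_real_)
  n <- vapply(gs, length, 1)
  p <- vapply(gs, function(g) sum(g) / (2 * length(g)), 1)
  h <- vapply(gs, function(g) sum(g == 1) / length(g), 1)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  ssq <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (ssq - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Brute-force per-site pairwise diversity: expand the called genotypes into
# haploid alleles and count differing pairs over all C(m, 2) pairs.
oracle_pi_site <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  alleles <- unlist(lapply(d, function(x) c(rep(1L, x), rep(0L, 2 - x))))
  m <- length(alleles)
  if (m < 2) return(NA_real_)
  diff_pairs <- 0L
  for (i in seq_len(m - 1)) {
    diff_pairs <- diff_pairs + sum(alleles[i] != alleles[(i + 1):m])
  }
  diff_pairs / (m * (m - 1) / 2)
}

# Tajima (1989) D for one window, constants derived from scratch; takes the
# per-site dosage matrix of the window.  `m` convention: modal called
# allele count across the window's sites.
oracle_tajima_window <- function(dosage_window) {
  m_site <- 2 * colSums(!is.na(dosage_window))
  x_site <- colSums(dosage_window, na.rm = TRUE)
  seg <- x_site > 0 & x_site < m_site
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  tab <- table(m_site[m_site >= 2])
  m <- as.integer(names(tab)[which.max(tab)])
  if (m < 4) return(NA_real_)
  theta_pi <- 0
  for (j in seq_len(ncol(dosage_window))) {
    v <- oracle_pi_site(dosage_window[, j])
    if (!is.na(v)) theta_pi <- theta_pi + v
  }
  a1 <- 0; a2 <- 0
  for (i in 1:(m - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Textbook simple-regression t statistic.
oracle_ols_t <- function(y, x) {
  n <- length(y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  b / se
}

# Pooled two-proportion Z and two-sided normal p.
oracle_two_prop <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Greedy EV pruning re-derived independently.
oracle_greedy_prune <- function(tab, threshold, priority) {
  kept <- character(0)
  for (ev in priority) {
    drop <- FALSE
    for (k in kept) {
      if (abs(cor(tab[[ev]], tab[[k]])) > threshold) drop <- TRUE
    }
    if (!drop) kept <- c(kept, ev)
  }
  kept
}
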
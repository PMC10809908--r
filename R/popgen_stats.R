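#' Per-locus ALT allele frequencies
#'
#' @param g a `genotype_matrix`.
#' @param samples optional sample subset (IDs or index).
#' @return data.frame with `chrom`, `pos`, `id`, `freq` (ALT alleles /
#'   called alleles; `NA` when no allele is called) and `n_called` (called
#'   allele count, i.e. twice the genotyped diploids).
#' @export
allele_frequencies <- function(g, samples = NULL) {
  if (!is.null(samples)) g <- gm_subset(g, samples = samples)
  if (length(g$samples) == 0) stop("empty sample subset")
  d <- g$dosage
  n_called <- 2L * colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  freq <- ifelse(n_called > 0, alt / n_called, NA_real_)
  data.frame(chrom = g$loci$chrom, pos = g$loci$pos, id = g$loci$id,
             freq = freq, n_called = n_called, row.names = NULL)
}

# ---- window machinery ------------------------------------------------------

.make_windows <- function(loci, length_bp, step_bp) {
  stopifnot(length_bp >= step_bp, step_bp >= 1)
  chroms <- sort(unique(loci$chrom))
  out <- lapply(chroms, function(ch) {
    maxpos <- max(loci$pos[loci$chrom == ch])
    starts <- seq.int(1L, maxpos, by = step_bp)
    data.frame(chrom = ch, start = starts,
               end = starts + length_bp - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sum `values` (and count defined sites) over windows; loci sorted by pos
# within chrom.  Returns list(sum, n) aligned with `windows`.
.window_sums <- function(loci, windows, values) {
  s <- numeric(nrow(windows))
  n <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    li <- which(loci$chrom == ch)
    wi <- which(windows$chrom == ch)
    pos <- loci$pos[li]
    v <- values[li]
    def <- !is.na(v)
    v[!def] <- 0
    cs <- c(0, cumsum(v))
    cn <- c(0L, cumsum(def))
    hi <- findInterval(windows$end[wi], pos)
    lo <- findInterval(windows$start[wi] - 1L, pos)
    s[wi] <- cs[hi + 1L] - cs[lo + 1L]
    n[wi] <- cn[hi + 1L] - cn[lo + 1L]
  }
  list(sum = s, n = n)
}

.site_index_by_window <- function(loci, windows) {
  # list of integer vectors: locus indices per window
  idx <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    li <- which(loci$chrom == ch)
    wi <- which(windows$chrom == ch)
    pos <- loci$pos[li]
    hi <- findInterval(windows$end[wi], pos)
    lo <- findInterval(windows$start[wi] - 1L, pos)
    for (k in seq_along(wi)) {
      if (hi[k] > lo[k]) idx[[wi[k]]] <- li[(lo[k] + 1L):hi[k]]
    }
  }
  idx
}

.stat_track <- function(windows, value, n_sites, statistic, ...) {
  df <- data.frame(chrom = windows$chrom, start = windows$start,
                   end = windows$end, n_sites = n_sites, value = value,
                   stringsAsFactors = FALSE)
  attr(df, "statistic") <- statistic
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("stat_track", "data.frame")
  df
}

.same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

# ---- nucleotide diversity --------------------------------------------------

# per-site pairwise diversity: x ALT among m called alleles ->
# fraction of differing haploid pairs x(m-x)/C(m,2) == 2*p*q*m/(m-1)
.site_pi <- function(g, samples = NULL) {
  if (!is.null(samples)) g <- gm_subset(g, samples = samples)
  d <- g$dosage
  m <- 2 * colSums(!is.na(d))
  x <- colSums(d, na.rm = TRUE)
  pi <- ifelse(m >= 2, x * (m - x) / (m * (m - 1) / 2), NA_real_)
  list(pi = pi, m = m, x = x, loci = g$loci)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is the fraction of differing haploid allele pairs among called
#' alleles, `2*p*q*m/(m-1)` with `m` the called allele count.  The window
#' value divides the summed site pi by the physical window length (the
#' VCFtools `--window-pi` convention); `denominator = "sites"` divides by the
#' number of polymorphic+monomorphic SNP records in the window instead.
#'
#' @param g a `genotype_matrix`.
#' @param samples optional sample subset.
#' @param length_bp,step_bp window size and step in bp.
#' @param denominator `"window"` (per-bp over window length, default) or
#'   `"sites"` (per analyzed site).
#' @return a `stat_track` data.frame (`chrom`, `start`, `end`, `n_sites`,
#'   `value`).
#' @export
windowed_pi <- function(g, samples = NULL, length_bp = 100000,
                        step_bp = 1000, denominator = c("window", "sites")) {
  denominator <- match.arg(denominator)
  sp <- .site_pi(g, samples)
  w <- .make_windows(sp$loci, length_bp, step_bp)
  ws <- .window_sums(sp$loci, w, sp$pi)
  value <- if (denominator == "window") ws$sum / length_bp else
    ifelse(ws$n > 0, ws$sum / ws$n, 0)
  .stat_track(w, value, ws$n, "pi",
              window_spec = c(length_bp = length_bp, step_bp = step_bp),
              denominator = denominator)
}

# ---- Weir-Cockerham F_ST ---------------------------------------------------

.group_list <- function(g, groups) {
  if (is.list(groups)) {
    gl <- groups
  } else if (!is.null(names(groups))) {
    gl <- split(names(groups), as.character(groups))
  } else stop("groups must be a named list of sample IDs or a named vector")
  if (length(gl) < 2) stop("need at least two groups")
  for (nm in names(gl)) {
    unk <- setdiff(gl[[nm]], g$samples)
    if (length(unk))
      stop("unknown sample IDs in group ", nm, ": ",
           paste(unk, collapse = ", "))
  }
  gl
}

# Per-site Weir & Cockerham (1984) variance components for diploid data,
# from genotype counts (uses observed heterozygote frequencies).  Groups
# with fewer than 2 called individuals at a site are excluded at that site;
# sites retaining < 2 groups are undefined.
.wc_components <- function(g, gl) {
  d <- g$dosage
  r <- length(gl)
  L <- ncol(d)
  N <- P <- H <- matrix(0, nrow = r, ncol = L)
  for (i in seq_len(r)) {
    sub <- d[match(gl[[i]], g$samples), , drop = FALSE]
    ni <- colSums(!is.na(sub))
    N[i, ] <- ni
    P[i, ] <- ifelse(ni > 0, colSums(sub, na.rm = TRUE) / (2 * ni), 0)
    H[i, ] <- ifelse(ni > 0, colSums(sub == 1L, na.rm = TRUE) / ni, 0)
  }
  if (any(apply(N, 1, max) < 2))
    stop("group(s) with fewer than 2 called individuals at every site: ",
         paste(names(gl)[apply(N, 1, max) < 2], collapse = ", "))
  incl <- N >= 2
  Nm <- N * incl
  Pm <- P * incl
  Hm <- H * incl
  r_s <- colSums(incl)
  sumN <- colSums(Nm)
  valid <- r_s >= 2
  nbar <- sumN / r_s
  nc <- (sumN - colSums(Nm^2) / sumN) / (r_s - 1)
  pbar <- colSums(Nm * Pm) / sumN
  hbar <- colSums(Nm * Hm) / sumN
  s2 <- colSums(Nm * (Pm - rep(pbar, each = r))^2 * incl) /
    ((r_s - 1) * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r_s - 1) / r_s * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r_s - 1) / r_s * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  undef <- !valid | !is.finite(tot) | tot == 0
  a[undef] <- NA_real_
  b[undef] <- NA_real_
  cc[undef] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST, per site or in sliding windows
#'
#' The Weir & Cockerham (1984) variance-components estimator for diploid
#' genotype data.  Site F_ST is `a / (a + b + c)` (undefined at monomorphic
#' sites; negative estimates retained).  The windowed value is the "weighted"
#' ratio-of-sums `sum(a) / sum(a + b + c)` over sites in the window (as in
#' VCFtools); `estimator = "mean"` returns the mean of per-site ratios
#' instead.
#'
#' @param g a `genotype_matrix`.
#' @param groups named list of sample-ID vectors (two or more groups), or a
#'   character vector of group labels named by sample ID.
#' @param length_bp,step_bp window size and step in bp.
#' @param per_site if `TRUE` return per-site values instead of windows.
#' @param estimator `"weighted"` (ratio of sums, default) or `"mean"`.
#' @return a `stat_track`; for `per_site = TRUE` a data.frame with `chrom`,
#'   `pos`, `fst` (plus components `a`, `b`, `c`).
#' @export
wc_fst <- function(g, groups, length_bp = 100000, step_bp = 1000,
                   per_site = FALSE, estimator = c("weighted", "mean")) {
  estimator <- match.arg(estimator)
  gl <- .group_list(g, groups)
  comp <- .wc_components(g, gl)
  tot <- comp$a + comp$b + comp$c
  site_f <- comp$a / tot
  if (per_site) {
    return(data.frame(chrom = g$loci$chrom, pos = g$loci$pos,
                      id = g$loci$id, fst = site_f, a = comp$a, b = comp$b,
                      c = comp$c, row.names = NULL))
  }
  w <- .make_windows(g$loci, length_bp, step_bp)
  if (estimator == "weighted") {
    sa <- .window_sums(g$loci, w, comp$a)
    st <- .window_sums(g$loci, w, tot)
    value <- ifelse(st$n > 0 & st$sum != 0, sa$sum / st$sum, NA_real_)
    n <- st$n
  } else {
    sr <- .window_sums(g$loci, w, site_f)
    value <- ifelse(sr$n > 0, sr$sum / sr$n, NA_real_)
    n <- sr$n
  }
  .stat_track(w, value, n, "fst",
              window_spec = c(length_bp = length_bp, step_bp = step_bp),
              groups = names(gl), estimator = estimator)
}

# ---- Tajima's D ------------------------------------------------------------

.tajima_constants <- function(m) {
  i <- seq_len(m - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard Tajima (1989) D per window: `(theta_pi - S/a1) /
#' sqrt(e1*S + e2*S*(S-1))`, with `S` the number of segregating sites and
#' `theta_pi` the summed per-site pairwise diversity on the count scale.
#' Because the called allele count can vary across sites, the normalizing
#' constants use the modal per-site called-allele count `m` of the window;
#' each site's pairwise term uses its own call count.  Undefined (NA) when
#' `S = 0` or `m < 4`.
#'
#' @param g a `genotype_matrix`.
#' @param samples optional sample subset.
#' @param length_bp,step_bp window size and step in bp (non-overlapping by
#'   default, as in VCFtools' Tajima's D bins).
#' @return a `stat_track`.
#' @export
tajimas_d <- function(g, samples = NULL, length_bp = 100000,
                      step_bp = length_bp) {
  sp <- .site_pi(g, samples)
  w <- .make_windows(sp$loci, length_bp, step_bp)
  seg <- sp$x > 0 & sp$x < sp$m
  idx <- .site_index_by_window(sp$loci, w)
  value <- rep(NA_real_, nrow(w))
  n_sites <- integer(nrow(w))
  warned <- FALSE
  for (k in seq_along(idx)) {
    li <- idx[[k]]
    n_sites[k] <- length(li)
    if (!length(li)) next
    S <- sum(seg[li])
    if (S == 0) next
    mm <- sp$m[li]
    mm <- mm[mm >= 2]
    if (!length(mm)) next
    tb <- table(mm)
    m_modal <- as.integer(names(tb)[which.max(tb)])
    if (m_modal < 4) {
      warned <- TRUE
      next
    }
    kc <- .tajima_constants(m_modal)
    theta_pi <- sum(sp$pi[li], na.rm = TRUE)
    theta_w <- S / kc$a1
    denom <- sqrt(kc$e1 * S + kc$e2 * S * (S - 1))
    value[k] <- (theta_pi - theta_w) / denom
  }
  if (warned)
    warning("windows with modal called-allele count < 4 left undefined")
  .stat_track(w, value, n_sites, "tajima_d",
              window_spec = c(length_bp = length_bp, step_bp = step_bp))
}

# ---- LD decay --------------------------------------------------------------

#' Linkage-disequilibrium decay curve
#'
#' r^2 is the squared Pearson correlation of genotype dosages over jointly
#' called samples (composite LD on unphased data, as in PopLDdecay's genotype
#' mode).  Pairs of loci up to `max_dist` apart on the same chromosome are
#' binned by physical distance; if the number of pairs exceeds `max_pairs`
#' the loci are thinned deterministically (every k-th locus) first.
#'
#' @param g a `genotype_matrix`.
#' @param samples optional sample subset.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance-bin width in bp.
#' @param max_pairs pair-count budget before deterministic thinning.
#' @param min_joint minimum jointly called samples; pairs below are skipped.
#' @return an `ld_decay_curve`: list with `bins` (data.frame `mid`,
#'   `mean_r2`, `n_pairs`) and `smoothed` (monotone non-increasing fit).
#' @export
ld_decay <- function(g, samples = NULL, max_dist = 500000, bin_width = 5000,
                     max_pairs = 200000, min_joint = 3) {
  if (!is.null(samples)) g <- gm_subset(g, samples = samples)
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  nb <- length(breaks) - 1
  acc_sum <- numeric(nb)
  acc_n <- integer(nb)
  for (ch in unique(g$loci$chrom)) {
    li <- which(g$loci$chrom == ch)
    if (length(li) < 2) next
    pos <- g$loci$pos[li]
    hi <- findInterval(pos + max_dist, pos)
    total_pairs <- sum(hi - seq_along(pos))
    stride <- max(1L, ceiling(sqrt(total_pairs / max_pairs)))
    keep <- seq(1L, length(li), by = stride)
    pos <- pos[keep]
    X <- g$dosage[, li[keep], drop = FALSE]
    storage.mode(X) <- "double"
    called <- !is.na(X)
    hi <- findInterval(pos + max_dist, pos)
    for (i in seq_along(pos)) {
      if (hi[i] <= i) next
      j <- (i + 1L):hi[i]
      joint <- colSums(called[, j, drop = FALSE] & called[, i])
      ok <- joint >= min_joint
      if (!any(ok)) next
      j <- j[ok]
      r <- suppressWarnings(
        stats::cor(X[, i], X[, j, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      dist <- pos[j] - pos[i]
      good <- is.finite(r2)
      if (!any(good)) next
      b <- pmin(pmax(ceiling(dist[good] / bin_width), 1L), nb)
      rs <- rowsum(r2[good], b)
      bi <- as.integer(rownames(rs))
      acc_sum[bi] <- acc_sum[bi] + rs[, 1]
      acc_n <- acc_n + tabulate(b, nbins = nb)
    }
  }
  mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
  mean_r2 <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  def <- !is.na(mean_r2)
  smoothed <- rep(NA_real_, nb)
  if (sum(def) >= 2) {
    iso <- stats::isoreg(mid[def], -mean_r2[def])
    smoothed[def] <- -iso$yf
  } else smoothed[def] <- mean_r2[def]
  structure(list(bins = data.frame(mid = mid, mean_r2 = mean_r2,
                                   n_pairs = acc_n),
                 smoothed = smoothed),
            class = "ld_decay_curve")
}

#' Distance at which smoothed LD decays below a threshold
#'
#' @param curve an `ld_decay_curve` from [ld_decay()].
#' @param threshold r^2 threshold (default 0.2).
#' @return bp (midpoint of the first bin whose monotone-smoothed mean r^2 is
#'   at or below `threshold`), or `NA` if never reached.
#' @export
decay_distance_at <- function(curve, threshold = 0.2) {
  s <- curve$smoothed
  i <- which(!is.na(s) & s <= threshold)
  if (!length(i)) return(NA_real_)
  curve$bins$mid[min(i)]
}
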
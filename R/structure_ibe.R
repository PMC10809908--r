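#' Genotype PCA (GCTA-style genetic relationship matrix)
#'
#' Dosages are mean-imputed per locus, centered by `2*p` and scaled by
#' `sqrt(2*p*(1-p))` (the Patterson / GCTA GRM convention); principal
#' components come from the eigen-decomposition of the sample-by-sample
#' kernel.  Monomorphic loci are dropped (count reported via message).  Sign
#' convention: for each component the largest-|loading| locus entry is made
#' positive, so results are deterministic.
#'
#' @param g a `genotype_matrix`.
#' @param samples optional sample subset.
#' @param K number of components, `K < min(n_samples, n_loci)`.
#' @return a `pca_result` list: `scores` (samples x K, eigenvector *
#'   sqrt(eigenvalue)), `explained` (variance fractions), `loadings`
#'   (loci x K), `dropped_monomorphic`.
#' @export
genotype_pca <- function(g, samples = NULL, K) {
  if (!is.null(samples)) g <- gm_subset(g, samples = samples)
  d <- g$dosage
  n <- nrow(d)
  if (K >= min(n, ncol(d))) stop("K must be < min(n_samples, n_loci)")
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  n_mono <- sum(mono)
  if (n_mono) message(n_mono, " monomorphic loci dropped from PCA")
  d <- d[, !mono, drop = FALSE]
  p <- p[!mono]
  X <- sweep(d, 2, 2 * p)
  X[is.na(X)] <- 0                       # mean imputation after centering
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  Kmat <- tcrossprod(X) / ncol(X)
  e <- eigen(Kmat, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(K)]), K)
  loadings <- crossprod(X, e$vectors[, seq_len(K), drop = FALSE])
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- g$samples
  structure(list(scores = scores,
                 explained = lam[seq_len(K)] / sum(lam),
                 loadings = loadings, eigenvalues = lam,
                 dropped_monomorphic = n_mono),
            class = "pca_result")
}

.dist_matrix <- function(m, labels, kind) {
  dimnames(m) <- list(labels, labels)
  attr(m, "kind") <- kind
  class(m) <- c("distance_matrix", "matrix")
  m
}

#' Great-circle distances between populations, in km
#'
#' Haversine distance with Earth radius 6371.0088 km.  Population
#' coordinates are the centroids of member samples.
#'
#' @param samples sample table (`sample_id`, `population_id`, `latitude`,
#'   `longitude`).
#' @param level `"population"` (default) or `"sample"`.
#' @return a symmetric `distance_matrix` (km) with zero diagonal.
#' @export
geographic_distance_km <- function(samples, level = c("population",
                                                      "sample")) {
  level <- match.arg(level)
  if (level == "population") {
    lat <- tapply(samples$latitude, samples$population_id, mean)
    lon <- tapply(samples$longitude, samples$population_id, mean)
    labels <- names(lat)
  } else {
    lat <- samples$latitude
    lon <- samples$longitude
    labels <- samples$sample_id
  }
  m <- geosphere::distm(cbind(as.numeric(lon), as.numeric(lat)),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371008.8))
  .dist_matrix(m / 1000, labels, "geographic_km")
}

#' Euclidean environmental distance between populations
#'
#' Each EV is z-scored across populations first, so the matrix is invariant
#' to each variable's raw units.  Zero-variance EVs are dropped with a
#' warning.
#'
#' @param env an [env_frame()].
#' @param evs EV subset (default: all current EVs).
#' @return a `distance_matrix`.
#' @export
env_distance <- function(env, evs = NULL) {
  if (is.null(evs)) evs <- env$evs
  miss <- setdiff(evs, env$evs)
  if (length(miss)) stop("EVs not in env frame: ", paste(miss, collapse = ", "))
  X <- as.matrix(env$current[, evs, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance EV(s) dropped: ",
            paste(evs[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!ncol(X)) stop("no EVs with variance")
  X <- scale(X)
  .dist_matrix(as.matrix(stats::dist(X)), env$current$population_id,
               "env_euclidean")
}

#' Linearized pairwise F_ST distance matrix
#'
#' Pairwise genome-wide weighted Weir-Cockerham F_ST between populations
#' (ratio of summed variance components over all sites), transformed to
#' `F_ST / (1 - F_ST)`.  Negative genome-wide estimates are floored at 0
#' before the transform so the matrix stays non-negative.
#'
#' @param g a `genotype_matrix`.
#' @param samples sample table (`sample_id`, `population_id`).
#' @param loci optional locus index (e.g. adaptive or LD-pruned neutral
#'   subsets) to restrict the computation.
#' @return a `distance_matrix` of kind `fst_linearized`.
#' @export
fst_linearized <- function(g, samples, loci = NULL) {
  if (!is.null(loci)) g <- gm_subset(g, loci = loci)
  pops <- split(samples$sample_id, samples$population_id)
  pops <- lapply(pops, intersect, g$samples)
  sizes <- lengths(pops)
  if (any(sizes < 2))
    stop("populations with < 2 samples: ",
         paste(names(pops)[sizes < 2], collapse = ", "))
  P <- length(pops)
  if (P < 2) stop("need >= 2 populations")
  m <- matrix(0, P, P)
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      sub <- gm_subset(g, samples = c(pops[[i]], pops[[j]]))
      comp <- .wc_components(sub, pops[c(i, j)])
      tot <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
      if (!sum(!is.na(comp$a)))
        stop("no overlapping called sites for populations ",
             names(pops)[i], " and ", names(pops)[j])
      fst <- sum(comp$a, na.rm = TRUE) / tot
      fst <- max(fst, 0)
      m[i, j] <- m[j, i] <- fst / (1 - fst)
    }
  }
  .dist_matrix(m, names(pops), "fst_linearized")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' (positive-association) permutation p-value
#' `(1 + #[r_perm >= r_obs]) / (n_perm + 1)` obtained by jointly permuting
#' rows and columns.  To make the result invariant to argument order for a
#' given seed, permutations are applied to a canonically chosen matrix (the
#' one with the smaller total entry sum; correlation itself is symmetric).
#'
#' @param a,b `distance_matrix` objects (or plain labeled symmetric
#'   matrices) with matching labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  la <- rownames(a)
  lb <- rownames(b)
  if (is.null(la) || is.null(lb) || !setequal(la, lb))
    stop("matrices must share labels")
  b <- b[la, la]
  n <- nrow(a)
  ut <- upper.tri(a)
  va <- a[ut]
  vb <- b[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- stats::cor(va, vb)
  # canonical permutation target: invariant under argument swap
  target_a <- sum(a) <= sum(b)
  M <- if (target_a) unclass(a) else unclass(b)
  other <- if (target_a) vb else va
  set.seed(seed)
  r_perm <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    s <- sample.int(n)
    r_perm[k] <- stats::cor(M[s, s][ut], other)
  }
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm)
}

#' Greedy LD pruning
#'
#' Scans loci in coordinate order and keeps a locus only if its dosage r^2
#' with every already-kept locus within `window_bp` upstream is at or below
#' `r2_max`.  Used to build the neutral-variant set for the
#' isolation-by-environment contrast.
#'
#' @param g a `genotype_matrix`.
#' @param r2_max r^2 threshold (default 0.2).
#' @param window_bp window in bp (default 50000).
#' @return logical vector over loci (`TRUE` = kept).
#' @export
ld_prune <- function(g, r2_max = 0.2, window_bp = 50000) {
  keep <- logical(nrow(g$loci))
  d <- g$dosage
  storage.mode(d) <- "double"
  for (ch in unique(g$loci$chrom)) {
    li <- which(g$loci$chrom == ch)
    pos <- g$loci$pos[li]
    kept_local <- integer(0)
    for (k in seq_along(li)) {
      inwin <- kept_local[pos[kept_local] >= pos[k] - window_bp]
      ok <- TRUE
      if (length(inwin)) {
        r <- suppressWarnings(
          stats::cor(d[, li[k]], d[, li[inwin], drop = FALSE],
                     use = "pairwise.complete.obs"))
        if (any(r^2 > r2_max, na.rm = TRUE)) ok <- FALSE
      }
      if (ok) {
        kept_local <- c(kept_local, k)
        keep[li[k]] <- TRUE
      }
    }
  }
  keep
}
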
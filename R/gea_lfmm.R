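#' Greedy correlation pruning of environmental variables
#'
#' Iterates EVs in priority order and keeps an EV only if its absolute
#' Pearson correlation with every already-kept EV is at or below
#' `threshold`.
#'
#' @param env an [env_frame()] or a population x EV data.frame.
#' @param threshold correlation threshold (default 0.8).
#' @param priority EV evaluation order (default: column order).
#' @return character vector of retained EV names.
#' @export
prune_evs <- function(env, threshold = 0.8, priority = NULL) {
  tab <- if (inherits(env, "env_frame")) env$current else env
  evs <- setdiff(names(tab), "population_id")
  if (nrow(tab) < 2) stop("need >= 2 populations")
  if (is.null(priority)) priority <- evs
  stopifnot(all(priority %in% evs))
  kept <- character(0)
  for (ev in priority) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(stats::cor(tab[[ev]], tab[[k]]))
      if (!is.na(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, ev)
  }
  if (!length(kept)) stop("no EVs survive pruning")
  kept
}

#' Latent factors for structure correction
#'
#' Top-`K` genotype PCA score columns, used as fixed covariates in the
#' association scan (the standard two-stage latent-factor approximation of
#' an LFMM: structure is estimated genome-wide first, then conditioned on
#' per locus).
#'
#' @param g a `genotype_matrix`.
#' @param K number of latent factors (`K = 0` gives an empty matrix and the
#'   scan reduces to simple regression).
#' @param samples optional sample subset.
#' @return samples x K numeric matrix with orthogonal columns.
#' @export
fit_latent_factors <- function(g, K, samples = NULL) {
  if (!is.null(samples)) g <- gm_subset(g, samples = samples)
  if (K == 0) {
    U <- matrix(numeric(0), nrow = length(g$samples), ncol = 0)
    rownames(U) <- g$samples
    return(U)
  }
  genotype_pca(g, K = K)$scores
}

#' Scree-gap heuristic for the number of latent factors
#'
#' @param g a `genotype_matrix`.
#' @param k_max largest K considered.
#' @return suggested K (position of the largest relative eigenvalue drop).
#' @export
suggest_k <- function(g, k_max = 10) {
  pc <- genotype_pca(g, K = min(k_max + 1, length(g$samples) - 1))
  lam <- pc$eigenvalues[seq_len(min(k_max + 1, length(pc$eigenvalues)))]
  drops <- lam[-length(lam)] / lam[-1]
  which.max(drops)
}

#' Latent-factor genotype-environment association scan
#'
#' For each (locus, EV) pair, ordinary least squares of the (mean-imputed)
#' dosage on `[intercept, EV, U]`, where `U` are latent structure factors.
#' The z-score is effect/SE; p-values are calibrated with the genomic
#' inflation factor `lambda = median(z^2) / 0.4549364` (median of a 1-df
#' chi-square) and recomputed as the upper tail of chi-square(1) at
#' `z^2 / lambda`.  Benjamini-Hochberg q-values are computed over loci
#' within each EV.  Key environment-association loci (EALs) satisfy
#' `|z| >= z_min` and calibrated `p <= p_max` (defaults 4 and 1e-5).
#'
#' @param g a `genotype_matrix`.
#' @param env an [env_frame()] with population-level EV values, broadcast to
#'   samples via their population.
#' @param samples sample table (`sample_id`, `population_id`).
#' @param U latent-factor matrix from [fit_latent_factors()] (rows aligned
#'   with `g$samples`).
#' @param evs EVs to scan (default: all current EVs).
#' @param loci optional locus subset (e.g. from
#'   [fst_outlier_prescreen()]); default scans all loci.
#' @param z_min,p_max key-EAL thresholds.
#' @return data.frame of class `eal_records`: `chrom`, `pos`, `id`, `ev`,
#'   `effect`, `z`, `p_raw`, `p_adj`, `q`, `key`; attribute `lambda` holds
#'   the per-EV genomic inflation factors.
#' @export
lfmm_scan <- function(g, env, samples, U, evs = NULL, loci = NULL,
                      z_min = 4, p_max = 1e-5) {
  if (is.null(evs)) evs <- env$evs
  if (!is.null(loci)) g <- gm_subset(g, loci = loci)
  d <- g$dosage
  storage.mode(d) <- "double"
  cm <- colMeans(d, na.rm = TRUE)
  na <- which(is.na(d))
  if (length(na)) d[na] <- cm[(na - 1) %/% nrow(d) + 1]
  n <- nrow(d)
  pop_of <- samples$population_id[match(g$samples, samples$sample_id)]
  if (anyNA(pop_of)) stop("samples missing from sample table")
  if (nrow(U) != n) stop("U rows must match samples")
  lambdas <- numeric(length(evs))
  names(lambdas) <- evs
  out <- vector("list", length(evs))
  for (ei in seq_along(evs)) {
    ev <- evs[ei]
    e_pop <- stats::setNames(env$current[[ev]], env$current$population_id)
    e <- as.numeric(e_pop[pop_of])
    sd_e <- stats::sd(e)
    if (sd_e == 0) stop("EV '", ev, "' is constant across samples")
    es <- (e - mean(e)) / sd_e          # standardized internally; the
    D <- cbind(1, es, U)                # effect is rescaled back below
    DtD <- crossprod(D)
    if (kappa(DtD, exact = TRUE) > 1e10)
      stop("collinear design for EV '", ev,
           "' (EV lies in the span of the latent factors); reduce K")
    DtDi <- solve(DtD)
    B <- DtDi %*% crossprod(D, d)
    res <- d - D %*% B
    df <- n - ncol(D)
    sigma2 <- colSums(res^2) / df
    se <- sqrt(sigma2 * DtDi[2, 2]) / sd_e
    effect <- B[2, ] / sd_e
    z <- effect / se
    lam <- stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    lambdas[ei] <- lam
    # z is a t-statistic with `df` residual degrees of freedom; at a few
    # hundred samples the usual normal/chi-square tail is anti-conservative
    # by 2-3x at |z| ~ 4-5, so the exact Student-t null is used.  As in
    # standard genomic control, lambda rescales z^2 only when > 1:
    # apparent deflation is never converted into extra significance
    lam_cal <- max(lam, 1)
    p_raw <- 2 * stats::pt(-abs(z), df)
    p_adj <- 2 * stats::pt(-sqrt(pmax(z^2 / lam_cal, 0)), df)
    q <- stats::p.adjust(p_adj, method = "BH")
    out[[ei]] <- data.frame(chrom = g$loci$chrom, pos = g$loci$pos,
                            id = g$loci$id, ev = ev, effect = effect,
                            z = z, p_raw = p_raw, p_adj = p_adj, q = q,
                            key = !is.na(z) & abs(z) >= z_min &
                              p_adj <= p_max,
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "lambda") <- lambdas
  attr(res, "thresholds") <- c(z_min = z_min, p_max = p_max)
  class(res) <- c("eal_records", "data.frame")
  res
}

#' Empirical F_ST-outlier prescreen
#'
#' Per-site multi-population Weir-Cockerham F_ST; keeps the top `q` fraction
#' of defined sites (strictly above the `(1 - q)` type-7 quantile).  An
#' empirical stand-in for a Bayesian F_ST outlier scan when only a
#' candidate-enrichment prescreen is needed; with `q = 1` all defined sites
#' are kept.
#'
#' @param g a `genotype_matrix`.
#' @param samples sample table (`sample_id`, `population_id`).
#' @param q upper tail fraction (default 0.01).
#' @return logical vector over loci (`TRUE` = kept).
#' @export
fst_outlier_prescreen <- function(g, samples, q = 0.01) {
  pops <- split(samples$sample_id, samples$population_id)
  pops <- lapply(pops, intersect, g$samples)
  site <- wc_fst(g, pops, per_site = TRUE)
  f <- site$fst
  def <- !is.na(f)
  if (q >= 1) return(def)
  thr <- stats::quantile(f[def], 1 - q, type = 7, names = FALSE)
  def & f > thr
}

#' Annotation-category enrichment of EALs (two-proportion Z-test)
#'
#' Compares the proportion of each functional class (non-synonymous,
#' synonymous, UTRs, ...) among EALs with the background set, using the
#' pooled two-proportion Z statistic
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` and a two-sided normal
#' p-value.  Classes with a zero pooled count get `exact_flag = TRUE`
#' (the normal approximation is unreliable; use an exact test).
#'
#' @param eal_classes character vector of class labels for the EAL set.
#' @param background_classes class labels for the background set.
#' @return data.frame: `class`, `n_eal`, `n_background`, `prop_eal`,
#'   `prop_background`, `z`, `p`, `exact_flag`.
#' @export
eal_annotation_classes <- function(eal_classes, background_classes) {
  n1 <- length(eal_classes)
  n2 <- length(background_classes)
  if (n1 == 0 || n2 == 0) stop("empty class vectors")
  classes <- sort(unique(c(eal_classes, background_classes)))
  out <- lapply(classes, function(cl) {
    x1 <- sum(eal_classes == cl)
    x2 <- sum(background_classes == cl)
    p1 <- x1 / n1
    p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    degenerate <- pp == 0 || pp == 1
    z <- if (degenerate) NA_real_ else
      (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    data.frame(class = cl, n_eal = x1, n_background = x2, prop_eal = p1,
               prop_background = p2, z = z,
               p = if (degenerate) NA_real_ else
                 2 * stats::pnorm(-abs(z)),
               exact_flag = degenerate || x1 == 0 || x2 == 0)
  })
  do.call(rbind, out)
}
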
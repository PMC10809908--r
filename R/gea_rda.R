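#' Partial redundancy analysis of candidate loci on environment
#'
#' Classic partial RDA: the (mean-imputed, column-centered) dosage response
#' `Y` and the z-scored EV matrix `X` are residualized on `[1, Z]` (the
#' conditioning matrix, typically longitude/latitude), the multivariate
#' least-squares fit of the residualized response on the residualized
#' predictors is decomposed by SVD, and constrained axes are reported with
#' SNP loadings and EV biplot scores.  Loadings follow the vegan species-
#' score convention (`t(Y_perp) %*% u`, i.e. covariance-type); per-locus
#' correlations with the axes are returned alongside.  Sign convention:
#' each axis's largest-|loading| entry is positive.
#'
#' @param Y samples x loci dosage matrix (may contain NA; mean-imputed).
#' @param X samples x EVs matrix or data.frame.
#' @param Z optional conditioning matrix (e.g. cbind(lon, lat)); `NULL`
#'   for an unconditioned RDA.
#' @return an `rda_result` list: `scores` (samples x A), `snp_loadings`,
#'   `snp_loading_cor`, `ev_biplot` (EV x A correlations with the axes),
#'   `explained` (per-axis fraction of *total* variance), `varfrac`
#'   (`conditioned`, `constrained`, `residual` fractions summing to 1),
#'   `singular_values`, `rank`.
#' @export
partial_rda_fit <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n || (!is.null(Z) && nrow(as.matrix(Z)) != n))
    stop("rows of Y, X, Z must align")
  cmY <- colMeans(Y, na.rm = TRUE)
  na <- which(is.na(Y))
  if (length(na)) Y[na] <- cmY[(na - 1) %/% n + 1]
  Yc <- sweep(Y, 2, colMeans(Y))
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0))
    stop("constant EV column(s): ",
         paste(colnames(X)[sdx == 0], collapse = ", "))
  Xs <- scale(X)
  cond <- cbind(rep(1, n), if (!is.null(Z)) as.matrix(Z))
  qrZ <- qr(cond)
  Yp <- qr.resid(qrZ, Yc)
  Xp <- qr.resid(qrZ, Xs)
  # EVs annihilated by the conditioning variables (e.g. an EV that is a
  # linear function of lon/lat) carry no conditional information: drop
  # them rather than fit floating-point noise
  xnorm <- sqrt(colSums(Xp^2)) / sqrt(n - 1)
  ann <- xnorm < 1e-7
  if (all(ann)) {
    warning("all EVs annihilated by the conditioning matrix; ",
            "constrained variance is zero")
    A <- 1
    scores <- matrix(0, n, 1)
    tot <- sum(Yc^2)
    conditioned <- tot - sum(Yp^2)
    out <- structure(list(
      scores = scores,
      snp_loadings = matrix(0, ncol(Y), 1,
                            dimnames = list(colnames(Y), NULL)),
      snp_loading_cor = matrix(0, ncol(Y), 1,
                               dimnames = list(colnames(Y), NULL)),
      ev_biplot = matrix(0, ncol(X), 1,
                         dimnames = list(colnames(X), NULL)),
      explained = 0,
      varfrac = c(conditioned = conditioned / tot, constrained = 0,
                  residual = sum(Yp^2) / tot),
      singular_values = 0, rank = 0, n = n, qrZ = qrZ, qrX = qr(Xp)),
      class = "rda_result")
    return(out)
  }
  if (any(ann)) {
    warning("EV(s) annihilated by the conditioning matrix dropped: ",
            paste(colnames(Xs)[ann], collapse = ", "))
    Xp <- Xp[, !ann, drop = FALSE]
    Xs <- Xs[, !ann, drop = FALSE]
  }
  qrX <- qr(Xp)
  rk <- qrX$rank
  if (rk < ncol(Xp)) {
    drop_cols <- colnames(Xs)[qrX$pivot[(rk + 1):ncol(Xp)]]
    stop("EV matrix rank-deficient after conditioning; collinear EVs: ",
         paste(drop_cols, collapse = ", "))
  }
  if (n <= qrZ$rank + rk)
    stop("too few samples for the requested model")
  Yhat <- qr.fitted(qrX, Yp)
  sv <- svd(Yhat, nu = min(n, ncol(Y)), nv = 0)
  tol <- max(sv$d) * 1e-8
  A <- max(1L, min(rk, sum(sv$d > tol)))
  u <- sv$u[, seq_len(A), drop = FALSE]
  d <- sv$d[seq_len(A)]
  scores <- u %*% diag(d, A)
  loadings <- crossprod(Yp, u)
  sdY <- sqrt(colSums(Yp^2))
  load_cor <- loadings / outer(sdY, sqrt(colSums(u^2)))
  ev_biplot <- suppressWarnings(stats::cor(Xp, scores))
  for (k in seq_len(A)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      load_cor[, k] <- -load_cor[, k]
      scores[, k] <- -scores[, k]
      ev_biplot[, k] <- -ev_biplot[, k]
    }
  }
  tot <- sum(Yc^2)
  conditioned <- tot - sum(Yp^2)
  constrained <- sum(sv$d^2)
  residual <- tot - conditioned - constrained
  rownames(loadings) <- rownames(load_cor) <- colnames(Y)
  rownames(ev_biplot) <- colnames(X)
  structure(list(scores = scores, snp_loadings = loadings,
                 snp_loading_cor = load_cor, ev_biplot = ev_biplot,
                 explained = d^2 / tot,
                 varfrac = c(conditioned = conditioned / tot,
                             constrained = constrained / tot,
                             residual = residual / tot),
                 singular_values = d, rank = rk, n = n,
                 qrZ = qrZ, qrX = qrX),
            class = "rda_result")
}

#' Tail-loading RDA outliers on the leading axes
#'
#' Per axis, a locus is an outlier when its loading lies outside
#' `mean +/- cutoff_sd * SD` of that axis's loading distribution (the
#' default 1.959964 SD corresponds to two-sided 95\% normal tails; 3 SD is
#' the other common landscape-genomics convention).  The outlier set is the
#' union over the requested axes; each outlier is attributed to its
#' max-|loading| axis and to the EV with the largest |biplot correlation|
#' on that axis.
#'
#' @param fit an `rda_result`.
#' @param axes axes to scan (default 1:3, truncated to those available).
#' @param cutoff_sd tail cutoff in SD units.
#' @return data.frame: `locus`, `axis`, `ev`, `loading` for each outlier.
#' @export
rda_outliers <- function(fit, axes = 1:3, cutoff_sd = 1.959964) {
  axes <- axes[axes <= ncol(fit$snp_loadings)]
  if (!length(axes)) stop("no axes available")
  L <- fit$snp_loadings[, axes, drop = FALSE]
  sds <- apply(L, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate (constant) loadings on some axis")
  mus <- colMeans(L)
  out_mask <- abs(sweep(L, 2, mus)) > sweep(matrix(1, nrow(L),
                                                   length(axes)), 2,
                                            cutoff_sd * sds, "*")
  hit <- which(rowSums(out_mask) > 0)
  per_axis_n <- stats::setNames(colSums(out_mask), paste0("axis", axes))
  if (!length(hit)) {
    out <- data.frame(locus = character(), axis = integer(),
                      ev = character(), loading = numeric())
    attr(out, "per_axis_n") <- per_axis_n
    return(out)
  }
  best_axis <- axes[apply(abs(L[hit, , drop = FALSE]), 1, which.max)]
  ev_names <- rownames(fit$ev_biplot)
  best_ev <- vapply(best_axis, function(a)
    ev_names[which.max(abs(fit$ev_biplot[, a]))], "")
  out <- data.frame(locus = rownames(L)[hit], axis = best_axis,
                    ev = best_ev,
                    loading = L[cbind(hit, match(best_axis, axes))],
                    row.names = NULL)
  attr(out, "per_axis_n") <- per_axis_n
  out
}

#' Permutation significance of a (partial) RDA
#'
#' Model-level pseudo-F = (constrained variance / rank(X_perp)) /
#' (residual variance / df_resid), with a null distribution built by
#' permuting rows of the residualized response (the standard scheme for
#' partial models); `p = (1 + #[F* >= F]) / (n_perm + 1)`.  Per-axis
#' marginal tests remove the preceding axes from the response and test the
#' leading singular value of the re-fitted constrained space.
#'
#' @param Y,X,Z as in [partial_rda_fit()].
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @param by_axis also compute per-axis p-values (slower).
#' @param max_axes number of axes tested when `by_axis = TRUE`.
#' @return list with `F`, `p`, and (optionally) `axis_p`.
#' @export
rda_significance <- function(Y, X, Z = NULL, n_perm = 999, seed = 1,
                             by_axis = FALSE, max_axes = 3) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  fit <- partial_rda_fit(Y, X, Z)
  n <- fit$n
  qrZ <- fit$qrZ
  qrX <- fit$qrX
  # rebuild the residualized response exactly as in the fit
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  cmY <- colMeans(Y, na.rm = TRUE)
  na <- which(is.na(Y))
  if (length(na)) Y[na] <- cmY[(na - 1) %/% n + 1]
  Yc <- sweep(Y, 2, colMeans(Y))
  Yp <- qr.resid(qrZ, Yc)
  rk <- fit$rank
  df_res <- n - qrZ$rank - rk
  if (df_res <= 0) stop("no residual degrees of freedom")
  tot_p <- sum(Yp^2)
  constr <- sum(fit$singular_values^2)
  F_obs <- (constr / rk) / ((tot_p - constr) / df_res)
  set.seed(seed)
  F_perm <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    s <- sample.int(n)
    # permuted rows are no longer orthogonal to the conditioning
    # variables: residualize again before projecting onto X_perp
    Ys <- qr.resid(qrZ, Yp[s, , drop = FALSE])
    c_k <- sum(qr.fitted(qrX, Ys)^2)
    F_perm[k] <- (c_k / rk) / ((sum(Ys^2) - c_k) / df_res)
  }
  p <- (1 + sum(F_perm >= F_obs)) / (n_perm + 1)
  out <- list(F = F_obs, p = p, n_perm = n_perm)
  if (by_axis) {
    A <- min(max_axes, length(fit$singular_values))
    axis_p <- numeric(A)
    Yk <- Yp
    for (a in seq_len(A)) {
      d2_obs <- fit$singular_values[a]^2
      F_a <- d2_obs / ((tot_p - constr) / df_res)
      cnt <- 0L
      for (k in seq_len(n_perm)) {
        s <- sample.int(n)
        Ys <- qr.resid(qrZ, Yk[s, , drop = FALSE])
        fitted_k <- qr.fitted(qrX, Ys)
        d1 <- svd(fitted_k, nu = 0, nv = 0)$d[1]
        F_k <- d1^2 / ((tot_p - constr) / df_res)
        if (F_k >= F_a) cnt <- cnt + 1L
      }
      axis_p[a] <- (1 + cnt) / (n_perm + 1)
      # remove this axis from the response before testing the next
      u <- fit$scores[, a, drop = FALSE] / fit$singular_values[a]
      Yk <- Yk - u %*% crossprod(u, Yk)
    }
    out$axis_p <- axis_p
  }
  out
}
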
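#' Population allele-frequency table for RONA
#'
#' Frequencies over called alleles per population; populations with fewer
#' than `min_inds` individuals are dropped (with a message) to avoid
#' unstable frequency estimates ("more than six individuals" retained by
#' default, i.e. `min_inds = 7`).
#'
#' @param g a `genotype_matrix`.
#' @param samples sample table (`sample_id`, `population_id`).
#' @param min_inds minimum individuals per retained population.
#' @return populations x loci numeric matrix of ALT frequencies (NA where a
#'   population has no called allele at a locus); attribute `n_inds` holds
#'   the per-population sample sizes.
#' @export
pop_allele_freqs <- function(g, samples, min_inds = 7) {
  pops <- split(samples$sample_id, samples$population_id)
  pops <- lapply(pops, intersect, g$samples)
  sizes <- lengths(pops)
  drop <- sizes < min_inds
  if (all(drop)) stop("all populations below min_inds = ", min_inds)
  if (any(drop))
    message(sum(drop), " population(s) dropped (fewer than ", min_inds,
            " individuals): ", paste(names(pops)[drop], collapse = ", "))
  pops <- pops[!drop]
  Fq <- t(vapply(pops, function(ids) {
    sub <- g$dosage[match(ids, g$samples), , drop = FALSE]
    nc <- 2 * colSums(!is.na(sub))
    ifelse(nc > 0, colSums(sub, na.rm = TRUE) / nc, NA_real_)
  }, numeric(ncol(g$dosage))))
  colnames(Fq) <- g$loci$id
  attr(Fq, "n_inds") <- sizes[!drop]
  Fq
}

#' Risk of non-adaptedness for one EV and one future scenario/model
#'
#' Per locus, an OLS regression of population allele frequency on the
#' current EV across populations gives `(a, b, R^2)`; the frequency a
#' population would need under the future EV is `clamp(a + b * EV_future,
#' 0, 1)`, and the per-locus distance is the absolute difference between
#' that requirement and the population's current observed frequency (or the
#' regression-fitted value with `current = "fitted"`).  RONA is the
#' R^2-weighted mean distance over loci (`weight_by_r2 = FALSE` for the
#' unweighted mean).  Loci with an undefined regression are excluded.
#'
#' @param freqs populations x loci matrix from [pop_allele_freqs()],
#'   already restricted to the EAL set for this EV.
#' @param ev_current,ev_future named numeric vectors (population -> EV
#'   value); names must cover the rows of `freqs`.
#' @param weight_by_r2 weight loci by regression R^2 (default TRUE).
#' @param current `"observed"` (default) or `"fitted"` baseline frequency.
#' @return data.frame: `population`, `rona`, `rona_unclamped` (diagnostic,
#'   without the [0,1] clamp), `n_loci`.
#' @export
rona_per_population <- function(freqs, ev_current, ev_future,
                                weight_by_r2 = TRUE,
                                current = c("observed", "fitted")) {
  current <- match.arg(current)
  pops <- rownames(freqs)
  if (is.null(pops)) stop("freqs must have population rownames")
  if (nrow(freqs) < 3) stop("need >= 3 retained populations")
  if (!all(pops %in% names(ev_current)) ||
      !all(pops %in% names(ev_future)))
    stop("EV vectors must cover all populations")
  x <- as.numeric(ev_current[pops])
  xf <- as.numeric(ev_future[pops])
  if (stats::sd(x) == 0) stop("constant current EV: regressions undefined")
  if (ncol(freqs) == 0) {
    warning("empty locus set: RONA undefined")
    return(data.frame(population = pops, rona = NA_real_,
                      rona_unclamped = NA_real_, n_loci = 0L))
  }
  xm <- mean(x)
  xc <- x - xm
  sxx <- sum(xc^2)
  # per-locus OLS across populations (NA frequencies excluded per locus)
  nl <- ncol(freqs)
  aa <- bb <- r2 <- rep(NA_real_, nl)
  for (l in seq_len(nl)) {
    y <- freqs[, l]
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) next
    xi <- x[ok]
    yi <- y[ok]
    b <- stats::cov(xi, yi) / stats::var(xi)
    a <- mean(yi) - b * mean(xi)
    syy <- sum((yi - mean(yi))^2)
    r2[l] <- if (syy == 0) 0 else b^2 * sum((xi - mean(xi))^2) / syy
    aa[l] <- a
    bb[l] <- b
  }
  usable <- !is.na(bb)
  if (!any(usable)) {
    warning("no usable locus regressions: RONA undefined")
    return(data.frame(population = pops, rona = NA_real_,
                      rona_unclamped = NA_real_, n_loci = 0L))
  }
  aa <- aa[usable]
  bb <- bb[usable]
  w <- if (weight_by_r2) r2[usable] else rep(1, sum(usable))
  fq <- freqs[, usable, drop = FALSE]
  rona <- rona_un <- numeric(length(pops))
  n_used <- integer(length(pops))
  for (j in seq_along(pops)) {
    pred <- aa + bb * xf[j]
    pred_cl <- pmin(pmax(pred, 0), 1)
    base <- if (current == "observed") fq[j, ] else
      pmin(pmax(aa + bb * x[j], 0), 1)
    ok <- !is.na(base)
    dist <- abs(pred_cl[ok] - base[ok])
    dist_un <- abs(pred[ok] - base[ok])
    wj <- w[ok]
    if (sum(wj) == 0) {
      # all weights zero (e.g. R^2 = 0 everywhere): fall back to unweighted
      wj <- rep(1, sum(ok))
    }
    rona[j] <- sum(wj * dist) / sum(wj)
    rona_un[j] <- sum(wj * dist_un) / sum(wj)
    n_used[j] <- sum(ok)
  }
  data.frame(population = pops, rona = rona, rona_unclamped = rona_un,
             n_loci = n_used, row.names = NULL)
}

#' Aggregate RONA across climate models
#'
#' Mean and standard error (`sd / sqrt(m)` over `m` models) per population
#' x EV x scenario, plus the SSP585 - SSP126 scenario contrast of the
#' means.
#'
#' @param cells data.frame with columns `population`, `ev`, `scenario`,
#'   `model`, `rona` (one row per model cell).
#' @return list with `summary` (population, ev, scenario, mean, se,
#'   n_models) and `contrast` (population, ev, delta = SSP585 - SSP126
#'   mean; only for population/EV pairs present in both scenarios).
#' @export
aggregate_models <- function(cells) {
  req <- c("population", "ev", "scenario", "model", "rona")
  stopifnot(all(req %in% names(cells)))
  key <- interaction(cells$population, cells$ev, cells$scenario,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(cells, key), function(s) {
    m <- nrow(s)
    data.frame(population = s$population[1], ev = s$ev[1],
               scenario = s$scenario[1], mean = mean(s$rona),
               se = if (m >= 2) stats::sd(s$rona) / sqrt(m) else NA_real_,
               n_models = m)
  }))
  rownames(agg) <- NULL
  if (any(agg$n_models < 2))
    warning("single-model cells: SE undefined there")
  contrast <- NULL
  sc <- unique(agg$scenario)
  if (all(c("SSP126", "SSP585") %in% sc)) {
    lo <- agg[agg$scenario == "SSP126", ]
    hi <- agg[agg$scenario == "SSP585", ]
    mm <- merge(hi[, c("population", "ev", "mean")],
                lo[, c("population", "ev", "mean")],
                by = c("population", "ev"), suffixes = c("_585", "_126"))
    contrast <- data.frame(population = mm$population, ev = mm$ev,
                           delta = mm$mean_585 - mm$mean_126)
  }
  list(summary = agg, contrast = contrast)
}

#' Closed-form consistency check for RONA on noiseless clines
#'
#' Builds exact linear clines `f = a + b * EV` across populations (no
#' sampling noise, R^2 = 1), applies a uniform future shift `delta_e`, runs
#' [rona_per_population()] and compares each population's RONA with the
#' analytic value `mean(|b|) * delta_e` (exact in the absence of clamping).
#' Intercepts and slopes are chosen so predictions stay inside [0, 1].
#'
#' @param b_values locus slopes per EV unit.
#' @param delta_e uniform EV shift.
#' @param n_pops number of populations.
#' @return list with `rona` (the table), `expected`, `max_abs_err`.
#' @export
rona_closed_form_check <- function(b_values = c(0.01, 0.02, 0.03),
                                   delta_e = 5, n_pops = 10) {
  ev <- seq(0, 10, length.out = n_pops)
  names(ev) <- paste0("P", seq_len(n_pops))
  a <- 0.2 - pmin(b_values, 0) * (max(ev) + delta_e)
  fq <- vapply(seq_along(b_values),
               function(l) a[l] + b_values[l] * ev, numeric(n_pops))
  rownames(fq) <- names(ev)
  stopifnot(all(fq >= 0 & fq <= 1),
            all(a + b_values * (max(ev) + delta_e) <= 1))
  res <- rona_per_population(fq, ev, ev + delta_e)
  expected <- mean(abs(b_values)) * delta_e
  list(rona = res, expected = expected,
       max_abs_err = max(abs(res$rona - expected)))
}
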
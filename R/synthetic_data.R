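#' Simulation configuration for synthetic landscape-genomics datasets
#'
#' Defines a hierarchically structured plant metapopulation: groups diverge
#' from a shared ancestor under the Balding-Nichols model (Beta-distributed
#' population allele frequencies parameterized by F_ST), populations drift
#' within groups, environmental variables follow geographic gradients, and
#' three kinds of signal are planted with recorded ground truth: adaptive
#' loci with clinal (logistic-in-EV) allele frequencies, selective-sweep
#' regions with locally collapsed diversity and boosted divergence in one
#' focal group, and filter-failing VCF records of every kind the ingestion
#' filters must remove.  Linkage disequilibrium is created by a Gaussian
#' AR(1) copula along each chromosome (marginal allele frequencies are
#' preserved exactly; latent correlation decays as `exp(-d /
#' ld_block_length_bp)`).  Adaptive loci are simulated unlinked from their
#' neighbours so that detection metrics against ground truth are
#' unambiguous.
#'
#' @param n_groups,pops_per_group,inds_per_pop cohort structure (defaults: 4
#'   groups x 3 populations x 10 individuals = 120 samples, a scaled-down
#'   analogue of a 438-sample range-wide collection).
#' @param n_chrom,chrom_length_bp genome layout.
#' @param n_neutral_loci,n_adaptive_loci locus counts (clean, filter-passing).
#' @param fst_between_groups Balding-Nichols divergence of each group from
#'   the ancestor (drives pairwise group F_ST of the same order).
#' @param fst_within_group additional drift of populations within groups.
#' @param adaptive_effects optional data.frame (`ev`, `a`, `b`) of logistic
#'   intercept/slope on the z-scored EV, one row per adaptive locus; `NULL`
#'   draws slopes `|b|` in `[4, 6]` (steep clines spanning most of the
#'   frequency range) with random sign and intercepts in `[-0.5, 0.5]`.
#' @param sweep_regions list of `list(group, chrom, start, end,
#'   diversity_reduction_factor, divergence_boost)`; `NULL` plants one
#'   100-kb sweep in each of the first two groups.
#' @param ld_block_length_bp latent-correlation decay scale in bp.
#' @param missing_rate per-genotype missingness.
#' @param maf_floor loci whose realized minor-allele frequency falls below
#'   this are reclassified as filter-failing sites.
#' @param env_gradient named list per EV: `list(intercept, lat, lon, alt,
#'   sd)` linear spatial trend coefficients plus noise SD; `NULL` uses nine
#'   built-in bioclimatic/radiation/vapour/altitude variables.
#' @param future_shift data.frame (`ev`, `scenario`, `model`, `delta`) of
#'   uniform additive EV changes for 2081-2100; `NULL` uses built-in
#'   SSP126/SSP585 shifts under three climate models for bio1, bio2, bio3,
#'   bio13, bio19.
#' @param n_junk_sites number of planted filter-failing VCF records.
#' @param ancestral_spectrum `"maf_filtered"` (default): ancestral
#'   frequencies with density proportional to `1/(p(1-p))` truncated to
#'   `[0.06, 0.94]`, emulating the site spectrum that survives a MAF >= 0.05
#'   filter; `"neutral"`: derived-allele density proportional to `1/p` on
#'   `[0.002, 0.98]` (the standard-neutral shape, for calibration fixtures
#'   that must not be MAF-truncated -- combine with `maf_floor = 0`).
#' @param seed mandatory integer seed; identical configs give byte-identical
#'   fixtures.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_groups = 4, pops_per_group = 3, inds_per_pop = 10,
                       n_chrom = 2, chrom_length_bp = 5e6,
                       n_neutral_loci = 20000, n_adaptive_loci = 60,
                       fst_between_groups = 0.25, fst_within_group = 0.01,
                       adaptive_effects = NULL, sweep_regions = NULL,
                       ld_block_length_bp = 10000, missing_rate = 0.03,
                       maf_floor = 0.05, env_gradient = NULL,
                       future_shift = NULL, n_junk_sites = 150,
                       ancestral_spectrum = c("maf_filtered", "neutral"),
                       seed) {
  ancestral_spectrum <- match.arg(ancestral_spectrum)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_groups >= 1, pops_per_group >= 1, inds_per_pop >= 1,
            n_chrom >= 1, chrom_length_bp >= 1,
            fst_between_groups > 0, fst_between_groups < 1,
            fst_within_group > 0, fst_within_group < 1,
            missing_rate >= 0, missing_rate < 1)
  groups <- if (n_groups <= 4) c("NW", "SW", "TH", "NC")[seq_len(n_groups)]
  else paste0("G", seq_len(n_groups))
  if (is.null(env_gradient)) env_gradient <- .default_env_gradient()
  if (is.null(future_shift)) future_shift <- .default_future_shift()
  if (is.null(sweep_regions)) {
    sweep_regions <- list()
    for (i in seq_len(min(2, n_groups))) {
      ch <- paste0("chr", min(i, n_chrom))
      sweep_regions[[i]] <- list(group = groups[i], chrom = ch,
                                 start = 1e6 * i + 1L,
                                 end = 1e6 * i + 100000L,
                                 diversity_reduction_factor = 0.15,
                                 divergence_boost = 3)
    }
  }
  for (sw in sweep_regions) {
    stopifnot(sw$diversity_reduction_factor > 0,
              sw$diversity_reduction_factor <= 1)
  }
  if (!is.null(adaptive_effects) &&
      nrow(adaptive_effects) != n_adaptive_loci)
    stop("infeasible config: adaptive_effects must have one row per ",
         "adaptive locus (", n_adaptive_loci, ")")
  if (n_adaptive_loci > 0 && n_neutral_loci == 0)
    stop("infeasible config: adaptive loci require a neutral background")
  structure(list(n_groups = n_groups, pops_per_group = pops_per_group,
                 inds_per_pop = inds_per_pop, n_chrom = n_chrom,
                 chrom_length_bp = chrom_length_bp,
                 n_neutral_loci = n_neutral_loci,
                 n_adaptive_loci = n_adaptive_loci,
                 fst_between_groups = fst_between_groups,
                 fst_within_group = fst_within_group,
                 adaptive_effects = adaptive_effects,
                 sweep_regions = sweep_regions,
                 ld_block_length_bp = ld_block_length_bp,
                 missing_rate = missing_rate, maf_floor = maf_floor,
                 env_gradient = env_gradient, future_shift = future_shift,
                 n_junk_sites = n_junk_sites,
                 ancestral_spectrum = ancestral_spectrum, groups = groups,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.default_env_gradient <- function() {
  # linear spatial trends (units: bio1/bio2 degC, bio3 %, bio13/bio19 mm,
  # srad kJ m-2 day-1, vapr kPa, altitude m); altitude is the coordinate
  # itself (sd = 0)
  # noise SDs represent microclimate/topography not captured by the linear
  # trend; they are sized so that a visible share of each EV's variance
  # lies within geographic groups
  list(
    bio1  = list(intercept = 28,    lat = -0.45, lon = 0,     alt = -0.004,
                 sd = 1.5),
    bio2  = list(intercept = -2,    lat = 0,     lon = 0.08,  alt = 0.001,
                 sd = 0.8),
    bio3  = list(intercept = 70,    lat = -0.5,  lon = 0,     alt = 0,
                 sd = 2.5),
    bio13 = list(intercept = 1100,  lat = -12,   lon = -4,    alt = 0,
                 sd = 25),
    bio19 = list(intercept = -35,   lat = 1.5,   lon = 0.3,   alt = 0.004,
                 sd = 8),
    srad6 = list(intercept = 14500, lat = 50,    lon = 0,     alt = 1.2,
                 sd = 600),
    srad12 = list(intercept = 11500, lat = -80,  lon = 0,     alt = 0.8,
                  sd = 450),
    vapr6 = list(intercept = 3.3,   lat = -0.03, lon = 0,     alt = -4e-4,
                 sd = 0.12),
    altitude = list(intercept = 0,  lat = 0,     lon = 0,     alt = 1,
                    sd = 0)
  )
}

.default_future_shift <- function() {
  models <- c("BCC-CSM2-MR", "ACCESS-CM2", "CMCC-ESM2")
  base <- rbind(
    data.frame(ev = "bio1",  scenario = "SSP126", delta = c(1.6, 2.0, 1.8)),
    data.frame(ev = "bio1",  scenario = "SSP585", delta = c(4.0, 5.0, 4.5)),
    data.frame(ev = "bio2",  scenario = "SSP126", delta = c(0.4, 0.6, 0.5)),
    data.frame(ev = "bio2",  scenario = "SSP585", delta = c(1.0, 1.4, 1.2)),
    data.frame(ev = "bio3",  scenario = "SSP126", delta = c(0.8, 1.2, 1.0)),
    data.frame(ev = "bio3",  scenario = "SSP585", delta = c(1.6, 2.4, 2.0)),
    data.frame(ev = "bio13", scenario = "SSP126", delta = c(12, 18, 15)),
    data.frame(ev = "bio13", scenario = "SSP585", delta = c(32, 48, 40)),
    data.frame(ev = "bio19", scenario = "SSP126", delta = c(4, 7, 5)),
    data.frame(ev = "bio19", scenario = "SSP585", delta = c(12, 18, 15)))
  base$model <- rep(models, length.out = nrow(base))
  base[, c("ev", "scenario", "model", "delta")]
}

.rbn <- function(n, p_anc, f) {
  # Balding-Nichols draw; (near-)fixed ancestral frequencies pass through
  # (rbeta with a zero shape parameter would warn and return NaN)
  p_anc <- rep_len(p_anc, n)
  eps <- 1e-12
  fixed <- p_anc <= eps | p_anc >= 1 - eps
  out <- p_anc
  if (any(!fixed)) {
    pa <- p_anc[!fixed]
    out[!fixed] <- stats::rbeta(sum(!fixed), pa * (1 - f) / f,
                                (1 - pa) * (1 - f) / f)
  }
  out
}

#' Simulate a ground-truth-annotated landscape-genomics dataset
#'
#' @param cfg a [sim_config()].
#' @return a `sim_bundle` list: `genotypes` (a [genotype_matrix()]),
#'   `samples` (sample table), `env` (an [env_frame()]), `genes` (gene
#'   models), `truth` (ground truth: per-locus class and effects, sweep
#'   spans, per-site filter pass/fail, genes inside sweeps), plus internal
#'   per-site QUAL/DP and planted failing VCF records used by
#'   [write_fixture()].
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  groups <- cfg$groups
  n_pops <- cfg$n_groups * cfg$pops_per_group
  n_ind <- n_pops * cfg$inds_per_pop

  ## --- geography -----------------------------------------------------------
  # group centers overlap climatically (adjacent montane provinces do);
  # most EV variance must not collapse onto the group axes, otherwise
  # structure correction would be confounded with every gradient
  centers <- data.frame(
    group = groups,
    lat = c(37, 31, 34, 38, 25 + 3 * seq_len(max(0, cfg$n_groups - 4)))[
      seq_len(cfg$n_groups)],
    lon = c(100, 101, 106, 111, 90 + 4 * seq_len(max(0, cfg$n_groups - 4)))[
      seq_len(cfg$n_groups)],
    alt = c(2400, 2800, 1800, 1200, rep(1500, max(0, cfg$n_groups - 4)))[
      seq_len(cfg$n_groups)])
  pops <- data.frame(
    population_id = paste0(rep(groups, each = cfg$pops_per_group),
                           rep(seq_len(cfg$pops_per_group), cfg$n_groups)),
    group_id = rep(groups, each = cfg$pops_per_group))
  ci <- match(pops$group_id, centers$group)
  # sampling locations within a region span several degrees and a wide
  # elevational band, as in range-wide montane collections; this keeps a
  # substantial share of each EV's variance within groups
  pops$latitude <- round(centers$lat[ci] + stats::runif(n_pops, -3, 3), 4)
  pops$longitude <- round(centers$lon[ci] + stats::runif(n_pops, -3, 3), 4)
  pops$altitude <- round(pmax(100, centers$alt[ci] +
                                stats::rnorm(n_pops, 0, 600)))
  samples <- data.frame(
    sample_id = paste0(rep(pops$population_id, each = cfg$inds_per_pop), "_",
                       rep(seq_len(cfg$inds_per_pop), n_pops)),
    population_id = rep(pops$population_id, each = cfg$inds_per_pop))
  samples <- merge(samples, pops, by = "population_id", sort = FALSE)
  samples <- samples[, c("sample_id", "population_id", "group_id",
                         "latitude", "longitude", "altitude")]

  ## --- environment ---------------------------------------------------------
  cur <- data.frame(population_id = pops$population_id)
  for (ev in names(cfg$env_gradient)) {
    gpar <- cfg$env_gradient[[ev]]
    cur[[ev]] <- gpar$intercept + gpar$lat * pops$latitude +
      gpar$lon * pops$longitude + gpar$alt * pops$altitude +
      stats::rnorm(n_pops, 0, gpar$sd)
    cur[[ev]] <- round(cur[[ev]], 4)
  }
  fs <- cfg$future_shift
  future <- NULL
  if (!is.null(fs) && nrow(fs)) {
    future <- do.call(rbind, lapply(seq_len(nrow(fs)), function(i) {
      data.frame(population_id = pops$population_id, ev = fs$ev[i],
                 scenario = fs$scenario[i], model = fs$model[i],
                 value = cur[[fs$ev[i]]] + fs$delta[i])
    }))
  }
  env <- env_frame(cur, future)

  ## --- locus layout --------------------------------------------------------
  n_loci <- cfg$n_neutral_loci + cfg$n_adaptive_loci
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  per_chrom <- diff(round(seq(0, n_loci, length.out = cfg$n_chrom + 1)))
  loci <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(k) {
    pos <- sort(sample.int(cfg$chrom_length_bp - 10L, per_chrom[k])) + 5L
    data.frame(chrom = chroms[k], pos = pos)
  }))
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, n_loci, replace = TRUE)
  loci$alt <- vapply(loci$ref,
                     function(r) sample(setdiff(bases, r), 1), "")
  loci$id <- paste0(loci$chrom, "_", loci$pos)
  cls <- rep("neutral", n_loci)
  in_sweep <- rep(FALSE, n_loci)
  for (sw in cfg$sweep_regions) {
    in_sweep <- in_sweep | (loci$chrom == sw$chrom & loci$pos >= sw$start &
                              loci$pos <= sw$end)
  }
  cls[in_sweep] <- "sweep_linked"
  eligible <- which(!in_sweep)
  adapt_idx <- sort(sample(eligible, cfg$n_adaptive_loci))
  cls[adapt_idx] <- "adaptive"

  ## --- adaptive effects ----------------------------------------------------
  evs <- names(cfg$env_gradient)
  eff <- cfg$adaptive_effects
  if (is.null(eff) && cfg$n_adaptive_loci > 0) {
    eff <- data.frame(
      ev = sample(evs, cfg$n_adaptive_loci, replace = TRUE),
      a = stats::runif(cfg$n_adaptive_loci, -0.5, 0.5),
      b = sample(c(-1, 1), cfg$n_adaptive_loci, TRUE) *
        stats::runif(cfg$n_adaptive_loci, 4, 6))
  }
  env_z <- vapply(evs, function(ev) {
    v <- cur[[ev]]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, n_pops) else (v - mean(v)) / s
  }, numeric(n_pops))

  ## --- population allele frequencies ---------------------------------------
  p0 <- if (cfg$ancestral_spectrum == "maf_filtered") {
    # density ~ 1/(p q) truncated: the spectrum surviving a MAF filter
    stats::plogis(stats::runif(n_loci, stats::qlogis(0.06),
                               stats::qlogis(0.94)))
  } else {
    # standard-neutral shape: derived-allele density ~ 1/p
    exp(stats::runif(n_loci, log(5e-4), log(0.9995)))
  }
  fb <- cfg$fst_between_groups
  fw <- cfg$fst_within_group
  pg <- matrix(0, cfg$n_groups, n_loci)  # group-level frequencies
  for (gi in seq_len(cfg$n_groups)) pg[gi, ] <- .rbn(n_loci, p0, fb)
  for (sw in cfg$sweep_regions) {
    gi <- match(sw$group, groups)
    si <- which(loci$chrom == sw$chrom & loci$pos >= sw$start &
                  loci$pos <= sw$end)
    if (!length(si)) next
    fboost <- min(0.95, fb * sw$divergence_boost)
    pgi <- .rbn(length(si), p0[si], fboost)
    drf <- sw$diversity_reduction_factor
    pg[gi, si] <- ifelse(pgi < 0.5, pgi * drf, 1 - (1 - pgi) * drf)
  }
  pp <- matrix(0, n_pops, n_loci)        # population-level frequencies
  for (pi in seq_len(n_pops)) {
    gi <- match(pops$group_id[pi], groups)
    pp[pi, ] <- .rbn(n_loci, pg[gi, ], fw)
  }
  sweep_pop <- matrix(FALSE, n_pops, n_loci)
  for (sw in cfg$sweep_regions) {
    si <- which(loci$chrom == sw$chrom & loci$pos >= sw$start &
                  loci$pos <= sw$end)
    pj <- which(pops$group_id == sw$group)
    if (!length(si)) next
    # focal-group populations share the collapsed sweep haplotype pool:
    # re-draw with strongly reduced within-group drift around the swept
    # frequency, keeping diversity low
    drf <- sw$diversity_reduction_factor
    gi <- match(sw$group, groups)
    for (p2 in pj) {
      pp[p2, si] <- .rbn(length(si), pg[gi, si], max(1e-4, fw * drf))
    }
  }
  if (cfg$n_adaptive_loci > 0) {
    for (k in seq_len(cfg$n_adaptive_loci)) {
      li <- adapt_idx[k]
      e <- env_z[, eff$ev[k]]
      pclin <- stats::plogis(eff$a[k] + eff$b[k] * e)
      pp[, li] <- .rbn(n_pops, pmin(pmax(pclin, 0.01), 0.99), fw)
    }
  }

  ## --- genotypes via AR(1) Gaussian copula ---------------------------------
  nh <- 2L * n_ind
  hap_pop <- rep(match(samples$population_id, pops$population_id), 2)
  dosage <- matrix(NA_integer_, n_ind, n_loci)
  for (k in seq_len(cfg$n_chrom)) {
    li <- which(loci$chrom == chroms[k])
    Lc <- length(li)
    phi <- c(0, exp(-diff(loci$pos[li]) / cfg$ld_block_length_bp))
    # adaptive loci segregate independently of their neighbours
    ai <- which(cls[li] == "adaptive")
    phi[ai] <- 0
    phi[ai[ai < Lc] + 1L] <- 0
    Z <- matrix(stats::rnorm(nh * Lc), nh, Lc)
    for (j in seq_len(Lc)[-1]) {
      if (phi[j] > 0)
        Z[, j] <- phi[j] * Z[, j - 1L] + sqrt(1 - phi[j]^2) * Z[, j]
    }
    TH <- stats::qnorm(pp[, li, drop = FALSE])   # n_pops x Lc thresholds
    AL <- Z < TH[hap_pop, , drop = FALSE]
    dosage[, li] <- AL[seq_len(n_ind), , drop = FALSE] +
      AL[n_ind + seq_len(n_ind), , drop = FALSE]
  }
  if (cfg$missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
  }

  ## --- realized-MAF floor --------------------------------------------------
  nc <- 2 * colSums(!is.na(dosage))
  p_real <- colSums(dosage, na.rm = TRUE) / pmax(nc, 1)
  maf <- pmin(p_real, 1 - p_real)
  drift_fail <- nc == 0 | maf < cfg$maf_floor
  qual <- round(stats::runif(n_loci, 60, 900), 1)
  dp <- matrix(stats::rpois(n_ind * n_loci, 20) + 3L, n_ind, n_loci)

  ## --- planted filter-failing records --------------------------------------
  junk <- .make_junk_sites(cfg, loci, n_ind, chroms)
  if (any(drift_fail)) {
    jf <- .vcf_lines(loci[drift_fail, , drop = FALSE],
                     dosage[, drift_fail, drop = FALSE],
                     qual[drift_fail], dp[, drift_fail, drop = FALSE])
    junk$lines <- c(junk$lines, jf)
    junk$table <- rbind(junk$table,
                        data.frame(chrom = loci$chrom[drift_fail],
                                   pos = loci$pos[drift_fail],
                                   reason = "maf_below_floor"))
  }
  keep <- !drift_fail
  gm <- genotype_matrix(dosage[, keep, drop = FALSE],
                        loci[keep, c("chrom", "pos", "id", "ref", "alt")],
                        samples = samples$sample_id)

  ## --- gene models ---------------------------------------------------------
  genes <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(k) {
    starts <- as.integer(seq(2001L, cfg$chrom_length_bp - 4000L,
                             by = 8000L))
    data.frame(gene_id = sprintf("g_%s_%05d", chroms[k],
                                 seq_along(starts)),
               chrom = chroms[k], start = starts, end = starts + 2999L,
               strand = rep(c("+", "-"), length.out = length(starts)),
               stringsAsFactors = FALSE)
  }))
  gis <- character(0)
  for (sw in cfg$sweep_regions) {
    ov <- genes$chrom == sw$chrom & genes$start <= sw$end &
      genes$end >= sw$start
    gis <- c(gis, genes$gene_id[ov])
  }

  ## --- ground truth --------------------------------------------------------
  truth_loci <- data.frame(chrom = loci$chrom[keep], pos = loci$pos[keep],
                           id = loci$id[keep], class = cls[keep],
                           ev = NA_character_, a = NA_real_, b = NA_real_,
                           stringsAsFactors = FALSE)
  if (cfg$n_adaptive_loci > 0) {
    ai_kept <- match(loci$id[adapt_idx][keep[adapt_idx]], truth_loci$id)
    src <- which(keep[adapt_idx])
    truth_loci$ev[ai_kept] <- eff$ev[src]
    truth_loci$a[ai_kept] <- eff$a[src]
    truth_loci$b[ai_kept] <- eff$b[src]
  }
  sweeps <- do.call(rbind, lapply(cfg$sweep_regions, function(sw) {
    data.frame(group = sw$group, chrom = sw$chrom, start = sw$start,
               end = sw$end, drf = sw$diversity_reduction_factor,
               boost = sw$divergence_boost, stringsAsFactors = FALSE)
  }))
  truth <- list(loci = truth_loci, junk = junk$table, sweeps = sweeps,
                genes_in_sweeps = sort(unique(gis)),
                pop_freq_true = pp[, keep, drop = FALSE],
                env_current = cur, env_future = future,
                n_pass = sum(keep),
                n_fail = nrow(junk$table))

  structure(list(genotypes = gm, samples = samples, env = env,
                 genes = genes, truth = truth, config = cfg,
                 qual = qual[keep], dp = dp[, keep, drop = FALSE],
                 junk_lines = junk$lines),
            class = "sim_bundle")
}

# format VCF body lines (GT:DP) for a block of sites
.vcf_lines <- function(loci, dosage, qual, dp) {
  if (!nrow(loci)) return(character(0))
  n <- nrow(dosage)
  gt_code <- c("0/0", "0/1", "1/1")
  gts <- matrix("./.", n, ncol(dosage))
  ok <- !is.na(dosage)
  gts[ok] <- gt_code[dosage[ok] + 1L]
  gts <- matrix(paste(gts, ifelse(is.na(dp), ".", dp), sep = ":"), n)
  do.call(paste, c(list(loci$chrom, loci$pos, loci$id, loci$ref, loci$alt,
                        format(qual, trim = TRUE), "PASS", ".", "GT:DP"),
                   lapply(seq_len(n), function(i) gts[i, ]),
                   list(sep = "\t")))
}

.make_junk_sites <- function(cfg, loci, n_ind, chroms) {
  n <- cfg$n_junk_sites
  if (n == 0)
    return(list(lines = character(0),
                table = data.frame(chrom = character(), pos = integer(),
                                   reason = character())))
  types <- rep(c("indel", "multiallelic", "low_maf", "low_callrate",
                 "low_qual", "low_dp"), length.out = n)
  used <- split(loci$pos, loci$chrom)
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- integer(n)
  for (k in seq_len(n)) {
    repeat {
      p <- sample.int(cfg$chrom_length_bp - 10L, 1) + 5L
      if (!p %in% used[[chrom[k]]]) break
    }
    pos[k] <- p
    used[[chrom[k]]] <- c(used[[chrom[k]]], p)
  }
  bases <- c("A", "C", "G", "T")
  lines <- character(n)
  for (k in seq_len(n)) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    qual <- round(stats::runif(1, 60, 900), 1)
    p <- stats::runif(1, 0.2, 0.8)
    dos <- stats::rbinom(n_ind, 2, p)
    dp <- stats::rpois(n_ind, 20) + 3L
    ty <- types[k]
    if (ty == "indel") ref <- paste0(ref, alt)
    if (ty == "multiallelic") alt <- paste(alt,
                                           sample(setdiff(bases, c(ref, alt)),
                                                  1), sep = ",")
    if (ty == "low_maf") {
      dos <- rep(0L, n_ind)
      dos[sample.int(n_ind, 2)] <- 1L   # MAF = 2 / (2 n) << floor
    }
    if (ty == "low_qual") qual <- round(stats::runif(1, 2, 25), 1)
    if (ty == "low_dp") dp <- sample(1:2, n_ind, replace = TRUE)
    dos_na <- dos
    if (ty == "low_callrate") {
      drop <- sample.int(n_ind, ceiling(0.9 * n_ind))
      dos_na[drop] <- NA_integer_
    }
    lt <- data.frame(chrom = chrom[k], pos = pos[k],
                     id = paste0(chrom[k], "_", pos[k]), ref = ref,
                     alt = alt, stringsAsFactors = FALSE)
    lines[k] <- .vcf_lines(lt, matrix(dos_na, ncol = 1), qual,
                           matrix(dp, ncol = 1))
  }
  list(lines = lines,
       table = data.frame(chrom = chrom, pos = pos, reason = types,
                          stringsAsFactors = FALSE))
}

#' Write a simulated bundle as an on-disk fixture
#'
#' Emits `data.vcf` (clean sites plus planted filter-failing records),
#' `samples.tsv`, `env.tsv`, `genes.gff3` and `truth.json`.  Re-reading the
#' VCF through [read_vcf_filtered()] with thresholds matching the config
#' reproduces the in-memory genotype matrix exactly.
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return data.frame manifest (`file`, `md5`, `bytes`), invisibly.
#' @export
write_fixture <- function(bundle, out_dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(out_dir, "data.vcf")
  body <- .vcf_lines(bundle$genotypes$loci, bundle$genotypes$dosage,
                     bundle$qual, bundle$dp)
  body <- c(body, bundle$junk_lines)
  key_chrom <- sub("\t.*", "", body)
  key_pos <- as.integer(vapply(strsplit(body, "\t", fixed = TRUE),
                               `[`, "", 2L))
  body <- body[order(key_chrom, key_pos)]
  hdr <- c("##fileformat=VCFv4.2", "##source=popclim-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", bundle$genotypes$samples),
                 collapse = "\t"))
  writeLines(c(hdr, body), vcf)
  write_tables(bundle$samples, bundle$env,
               file.path(out_dir, "samples.tsv"),
               file.path(out_dir, "env.tsv"))
  .write_gff3(bundle$genes, file.path(out_dir, "genes.gff3"))
  truth <- bundle$truth
  truth$pop_freq_true <- NULL   # large; kept in memory only
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", digits = 10, na = "null",
                       auto_unbox = TRUE)
  files <- c("data.vcf", "samples.tsv", "env.tsv", "genes.gff3",
             "truth.json")
  paths <- file.path(out_dir, files)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)),
                         bytes = file.size(paths))
  invisible(manifest)
}

.write_gff3 <- function(genes, path) {
  gene_lines <- paste(genes$chrom, "popclim", "gene", genes$start,
                      genes$end, ".", genes$strand, ".",
                      paste0("ID=", genes$gene_id), sep = "\t")
  mrna_lines <- paste(genes$chrom, "popclim", "mRNA", genes$start,
                      genes$end, ".", genes$strand, ".",
                      paste0("ID=", genes$gene_id, ".t1;Parent=",
                             genes$gene_id), sep = "\t")
  body <- character(2 * nrow(genes))
  body[c(TRUE, FALSE)] <- gene_lines
  body[c(FALSE, TRUE)] <- mrna_lines
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}
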
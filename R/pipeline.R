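#' Pipeline configuration
#'
#' Bundles the file paths, thresholds and master seed for a full run.  All
#' stage thresholds default to the conventional values for this kind of
#' landscape-genomics study: top 5\% joint sweep windows, key EALs at
#' `|z| >= 4` and calibrated `p <= 1e-5`, RDA tail cutoff at 1.96 SD on
#' axes 1-3, RONA loci at calibrated `p < 1e-3`, and populations with at
#' least 7 individuals retained for RONA.  Every stage derives its own RNG
#' substream from the master seed (stage index offsets), so adding a stage
#' never perturbs earlier stages' streams.
#'
#' @param vcf,samples,env,gff input file paths (`gff` optional).
#' @param outdir output directory.
#' @param filters a [filter_config()].
#' @param window_bp,step_bp window size/step for F_ST and pi tracks.
#' @param K latent factors (`NULL`: number of groups - 1).
#' @param sweep_q joint top-quantile for the sweep scan.
#' @param z_min,p_max key-EAL thresholds.
#' @param rda_cutoff_sd RDA tail-loading cutoff in SD units.
#' @param rona_p calibrated-p cutoff selecting RONA loci per EV.
#' @param min_inds minimum individuals per population retained for RONA.
#' @param n_perm permutations for Mantel and RDA significance.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, samples, env, gff = NULL, outdir,
                            filters = filter_config(), window_bp = 100000,
                            step_bp = 1000, K = NULL, sweep_q = 0.05,
                            z_min = 4, p_max = 1e-5,
                            rda_cutoff_sd = 1.959964, rona_p = 1e-3,
                            min_inds = 7, n_perm = 999, seed = 1) {
  structure(list(vcf = vcf, samples = samples, env = env, gff = gff,
                 outdir = outdir, filters = filters,
                 window_bp = window_bp, step_bp = step_bp, K = K,
                 sweep_q = sweep_q, z_min = z_min, p_max = p_max,
                 rda_cutoff_sd = rda_cutoff_sd, rona_p = rona_p,
                 min_inds = min_inds, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_seed <- function(cfg, stage) {
  offsets <- c(io = 1L, stats = 2L, structure = 3L, sweep = 4L,
               lfmm = 5L, rda = 6L, rona = 7L)
  (cfg$seed + 7919L * offsets[[stage]]) %% .Machine$integer.max
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 10, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.stage_manifest <- function(dir, stage, counts, seed, extra = list()) {
  m <- c(list(stage = stage, seed = seed, counts = counts), extra)
  jsonlite::write_json(m, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = 10)
  m
}

#' Run the full landscape-genomics pipeline
#'
#' Executes io -> stats -> structure -> sweep -> lfmm -> rda -> rona on the
#' configured inputs, writing TSV/BED outputs and a JSON manifest per stage
#' into `cfg$outdir`.  Reruns with the same config and seed produce
#' byte-identical numeric outputs.  A stage failure halts the run with the
#' stage name.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   output manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  od <- cfg$outdir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## io ----------------------------------------------------------------------
  res <- list()
  res$io <- stage("io", {
    g <- read_vcf_filtered(cfg$vcf, cfg$filters)
    tabs <- read_tables(cfg$samples, cfg$env)
    genes <- if (!is.null(cfg$gff)) read_gff_genes(cfg$gff) else NULL
    miss <- setdiff(g$samples, tabs$samples$sample_id)
    if (length(miss)) stop("VCF samples absent from sample table: ",
                           paste(miss, collapse = ", "))
    hashes <- tools::md5sum(c(cfg$vcf, cfg$samples, cfg$env,
                              if (!is.null(cfg$gff)) cfg$gff))
    names(hashes) <- basename(names(hashes))
    .stage_manifest(od, "io",
                    list(n_samples = length(g$samples),
                         n_loci = nrow(g$loci),
                         n_genes = if (is.null(genes)) 0 else nrow(genes)),
                    .stage_seed(cfg, "io"),
                    list(input_md5 = as.list(hashes)))
    list(g = g, samples = tabs$samples, env = tabs$env, genes = genes)
  })
  g <- res$io$g
  sf <- res$io$samples
  env <- res$io$env
  groups <- split(sf$sample_id, sf$group_id)

  ## stats -------------------------------------------------------------------
  res$stats <- stage("stats", {
    pi_group <- lapply(groups, function(ids)
      windowed_pi(g, samples = ids, length_bp = cfg$window_bp,
                  step_bp = cfg$window_bp))
    pi_mean <- vapply(pi_group, function(t) mean(t$value), 0)
    td <- tajimas_d(g, length_bp = cfg$window_bp)
    ld <- ld_decay(g)
    for (nm in names(pi_group))
      write_track_tsv(pi_group[[nm]], file.path(od, paste0("pi_", nm,
                                                           ".tsv")))
    write_track_tsv(td, file.path(od, "tajima_d.tsv"))
    .write_tsv(ld$bins, file.path(od, "ld_decay.tsv"))
    .stage_manifest(od, "stats",
                    list(pi_per_group = as.list(pi_mean),
                         ld_decay_bp_at_0.2 = decay_distance_at(ld, 0.2)),
                    .stage_seed(cfg, "stats"))
    list(pi_group = pi_group, pi_mean = pi_mean, tajima = td, ld = ld)
  })

  ## structure ---------------------------------------------------------------
  res$structure <- stage("structure", {
    K <- if (is.null(cfg$K)) max(1, length(groups) - 1) else cfg$K
    pca <- genotype_pca(g, K = K)
    geo <- geographic_distance_km(sf)
    fstlin <- fst_linearized(g, sf)
    ibd <- mantel_test(fstlin, geo, n_perm = cfg$n_perm,
                       seed = .stage_seed(cfg, "structure"))
    sc <- data.frame(sample = g$samples,
                     group = sf$group_id[match(g$samples, sf$sample_id)],
                     pca$scores)
    names(sc)[-(1:2)] <- paste0("PC", seq_len(K))
    .write_tsv(sc, file.path(od, "pca_scores.tsv"))
    .write_tsv(as.data.frame(as.matrix(fstlin)),
               file.path(od, "fst_linearized.tsv"))
    .stage_manifest(od, "structure",
                    list(K = K,
                         explained = as.list(round(pca$explained, 6)),
                         ibd_r = ibd$r, ibd_p = ibd$p),
                    .stage_seed(cfg, "structure"))
    list(pca = pca, geo = geo, fstlin = fstlin, ibd = ibd, K = K)
  })

  ## sweep -------------------------------------------------------------------
  res$sweep <- stage("sweep", {
    out <- list()
    for (gr in names(groups)) {
      focal <- groups[[gr]]
      ref <- setdiff(g$samples, focal)
      fst_tr <- wc_fst(g, list(focal = focal, reference = ref),
                       length_bp = cfg$window_bp, step_bp = cfg$step_bp)
      ratio_tr <- pi_ratio_scan(g, focal, ref, length_bp = cfg$window_bp,
                                step_bp = cfg$step_bp)
      reg <- joint_outlier_regions(fst_tr, ratio_tr, q = cfg$sweep_q)
      if (!is.null(res$io$genes)) reg <- annotate_regions(reg,
                                                          res$io$genes)
      out[[gr]] <- reg
      .write_tsv(reg, file.path(od, paste0("sweep_regions_", gr, ".tsv")))
      if (nrow(reg))
        write_bed(reg, file.path(od, paste0("sweep_regions_", gr,
                                            ".bed")))
    }
    .stage_manifest(od, "sweep",
                    list(n_regions = lapply(out, nrow), q = cfg$sweep_q),
                    .stage_seed(cfg, "sweep"))
    out
  })

  ## lfmm --------------------------------------------------------------------
  res$lfmm <- stage("lfmm", {
    evs <- prune_evs(env)
    U <- res$structure$pca$scores[, seq_len(res$structure$K),
                                  drop = FALSE]
    eals <- lfmm_scan(g, env, sf, U, evs = evs, z_min = cfg$z_min,
                      p_max = cfg$p_max)
    key_ids <- unique(eals$id[eals$key])
    # IBE contrast: adaptive (key-EAL) vs LD-pruned neutral variants
    envd <- env_distance(env, evs)
    ibe <- list()
    if (length(key_ids) >= 2) {
      adaptive_idx <- g$loci$id %in% key_ids
      ibe$adaptive <- mantel_test(fst_linearized(g, sf,
                                                 loci = adaptive_idx),
                                  envd, n_perm = cfg$n_perm,
                                  seed = .stage_seed(cfg, "lfmm"))
      neutral_idx <- !adaptive_idx & ld_prune(g)
      ibe$neutral <- mantel_test(fst_linearized(g, sf,
                                                loci = neutral_idx),
                                 envd, n_perm = cfg$n_perm,
                                 seed = .stage_seed(cfg, "lfmm"))
    }
    .write_tsv(as.data.frame(eals), file.path(od, "eal_records.tsv"))
    manh <- data.frame(chrom = eals$chrom, pos = eals$pos, ev = eals$ev,
                       neg_log10_p = -log10(pmax(eals$p_adj, 1e-300)))
    .write_tsv(manh, file.path(od, "manhattan.tsv"))
    .stage_manifest(od, "lfmm",
                    list(evs = evs, n_key_eals = length(key_ids),
                         lambda = as.list(round(attr(eals, "lambda"), 4)),
                         ibe_adaptive_r = if (length(ibe)) ibe$adaptive$r
                         else NA,
                         ibe_neutral_r = if (length(ibe)) ibe$neutral$r
                         else NA),
                    .stage_seed(cfg, "lfmm"))
    list(eals = eals, key_ids = key_ids, evs = evs, ibe = ibe, U = U)
  })

  ## rda ---------------------------------------------------------------------
  res$rda <- stage("rda", {
    key_ids <- res$lfmm$key_ids
    if (length(key_ids) < 4) {
      message("too few key EALs for RDA; skipping")
      return(NULL)
    }
    Y <- g$dosage[, g$loci$id %in% key_ids, drop = FALSE]
    pop_of <- sf$population_id[match(g$samples, sf$sample_id)]
    evs <- res$lfmm$evs
    Xev <- as.matrix(env$current[match(pop_of,
                                       env$current$population_id), evs])
    rownames(Xev) <- g$samples
    Z <- cbind(lon = sf$longitude[match(g$samples, sf$sample_id)],
               lat = sf$latitude[match(g$samples, sf$sample_id)])
    fit <- partial_rda_fit(Y, Xev, Z)
    outl <- rda_outliers(fit, axes = 1:3, cutoff_sd = cfg$rda_cutoff_sd)
    sig <- rda_significance(Y, Xev, Z, n_perm = cfg$n_perm,
                            seed = .stage_seed(cfg, "rda"))
    both <- intersect(outl$locus, key_ids)
    .write_tsv(outl, file.path(od, "rda_outliers.tsv"))
    vt <- data.frame(component = names(fit$varfrac),
                     fraction = as.numeric(fit$varfrac))
    .write_tsv(vt, file.path(od, "rda_variance.tsv"))
    .stage_manifest(od, "rda",
                    list(n_outliers = nrow(outl),
                         n_intersection_with_lfmm = length(both),
                         model_F = sig$F, model_p = sig$p,
                         varfrac = as.list(round(fit$varfrac, 6))),
                    .stage_seed(cfg, "rda"))
    list(fit = fit, outliers = outl, significance = sig)
  })

  ## rona --------------------------------------------------------------------
  res$rona <- stage("rona", {
    if (!nrow(env$future)) {
      message("no future EV data; skipping RONA")
      return(NULL)
    }
    fq <- suppressMessages(pop_allele_freqs(g, sf,
                                            min_inds = cfg$min_inds))
    eals <- res$lfmm$eals
    combos <- unique(env$future[, c("ev", "scenario", "model")])
    cells <- list()
    for (i in seq_len(nrow(combos))) {
      ev <- combos$ev[i]
      if (!ev %in% res$lfmm$evs) next
      loc <- unique(eals$id[eals$ev == ev & eals$p_adj < cfg$rona_p])
      loc <- intersect(loc, colnames(fq))
      if (length(loc) == 0) next
      cur <- stats::setNames(env$current[[ev]],
                             env$current$population_id)
      fut <- env_future_values(env, ev, combos$scenario[i],
                               combos$model[i])
      rr <- rona_per_population(fq[, loc, drop = FALSE], cur, fut)
      rr$ev <- ev
      rr$scenario <- combos$scenario[i]
      rr$model <- combos$model[i]
      cells[[length(cells) + 1L]] <- rr
    }
    if (!length(cells)) {
      message("no EV with qualifying loci and future data; RONA empty")
      return(NULL)
    }
    cells <- do.call(rbind, cells)
    agg <- aggregate_models(cells)
    .write_tsv(cells, file.path(od, "rona_cells.tsv"))
    .write_tsv(agg$summary, file.path(od, "rona_summary.tsv"))
    if (!is.null(agg$contrast))
      .write_tsv(agg$contrast, file.path(od, "rona_contrast.tsv"))
    .stage_manifest(od, "rona",
                    list(n_cells = nrow(cells),
                         mean_rona = mean(agg$summary$mean)),
                    .stage_seed(cfg, "rona"))
    list(cells = cells, aggregate = agg)
  })

  files <- sort(dir(od))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(od, files))))
  jsonlite::write_json(list(outputs = manifest, seed = cfg$seed),
                       file.path(od, "run_manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

#' Generate the default synthetic fixture and run the pipeline on it
#'
#' Simulates the default cohort (4 groups x 3 populations x 10
#' individuals), writes the fixture files, runs the full pipeline, and
#' scores the run against the recorded ground truth: sweep-region recall,
#' key-EAL precision/recall and neutral false-positive rate, and the
#' closed-form RONA consistency error.  The scorecard is written as
#' `scorecard.json`.
#'
#' @param outdir output directory (fixture under `fixture/`, results under
#'   `results/`).
#' @param seed master seed.
#' @param cfg optional [sim_config()] overriding the default (its seed is
#'   taken from `seed`).
#' @return (invisibly) list with `scorecard`, `pipeline` results and
#'   fixture paths.
#' @export
make_demo <- function(outdir, seed = 1, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  fixdir <- file.path(outdir, "fixture")
  resdir <- file.path(outdir, "results")
  bundle <- simulate_dataset(cfg)
  write_fixture(bundle, fixdir, overwrite = TRUE)
  pcfg <- pipeline_config(
    vcf = file.path(fixdir, "data.vcf"),
    samples = file.path(fixdir, "samples.tsv"),
    env = file.path(fixdir, "env.tsv"),
    gff = file.path(fixdir, "genes.gff3"),
    outdir = resdir,
    filters = filter_config(maf = cfg$maf_floor),
    seed = seed)
  run <- suppressMessages(run_pipeline(pcfg))

  truth <- bundle$truth
  ## sweep recall: fraction of planted spans overlapped by a detected
  ## region in the focal group's scan
  recall_sweep <- NA_real_
  if (!is.null(truth$sweeps) && nrow(truth$sweeps)) {
    hits <- vapply(seq_len(nrow(truth$sweeps)), function(i) {
      sw <- truth$sweeps[i, ]
      reg <- run$sweep[[sw$group]]
      any(reg$chrom == sw$chrom & reg$start <= sw$end &
            reg$end >= sw$start)
    }, TRUE)
    recall_sweep <- mean(hits)
  }
  ## key-EAL recovery
  eals <- run$lfmm$eals
  key_ids <- run$lfmm$key_ids
  adaptive_ids <- truth$loci$id[truth$loci$class == "adaptive"]
  neutral_ids <- truth$loci$id[truth$loci$class == "neutral"]
  eal_recall <- if (length(adaptive_ids))
    mean(adaptive_ids %in% key_ids) else NA_real_
  eal_fpr <- if (length(neutral_ids))
    mean(neutral_ids %in% key_ids) else NA_real_
  eal_precision <- if (length(key_ids))
    mean(key_ids %in% adaptive_ids) else NA_real_
  cf <- rona_closed_form_check()
  scorecard <- list(sweep_recall = recall_sweep, eal_recall = eal_recall,
                    eal_precision = eal_precision, eal_fpr = eal_fpr,
                    rona_closed_form_max_err = cf$max_abs_err,
                    n_key_eals = length(key_ids), seed = seed)
  jsonlite::write_json(scorecard, file.path(outdir, "scorecard.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(scorecard = scorecard, pipeline = run,
                 fixture = fixdir, results = resdir, bundle = bundle))
}
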
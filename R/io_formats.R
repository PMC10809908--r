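#' Construct a genotype matrix
#'
#' The central container of the package: a samples x loci matrix of ALT-allele
#' dosages (0, 1, 2 or `NA` for missing) for biallelic SNPs, together with the
#' locus table.  Loci are kept sorted by (chrom, pos) and internal coordinates
#' are 1-based throughout (VCF/GFF convention); conversion to 0-based
#' half-open happens only at BED export.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param samples character vector of sample IDs (defaults to
#'   `rownames(dosage)`).
#' @return object of class `genotype_matrix` with elements `dosage`, `loci`,
#'   `samples`.
#' @export
genotype_matrix <- function(dosage, loci, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) stop("sample IDs required (rownames or `samples`)")
  if (length(samples) != nrow(dosage))
    stop("length(samples) != nrow(dosage)")
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(loci))) {
    stop("loci table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loci) != ncol(dosage)) stop("nrow(loci) != ncol(dosage)")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (any(loci$pos < 1)) stop("positions are 1-based: pos >= 1 required")
  if (any(loci$ref == loci$alt)) stop("ref == alt at some locus")
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) loci")
  rownames(loci) <- NULL
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- samples
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci on %d chromosome(s)\n",
              length(x$samples), nrow(x$loci), length(unique(x$loci$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g a `genotype_matrix`.
#' @param samples sample IDs or logical/integer index; `NULL` keeps all.
#' @param loci logical/integer index over loci; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(g, samples = NULL, loci = NULL) {
  d <- g$dosage
  s <- g$samples
  if (!is.null(samples)) {
    if (is.character(samples)) {
      miss <- setdiff(samples, s)
      if (length(miss))
        stop("unknown sample IDs: ", paste(miss, collapse = ", "))
      idx <- match(samples, s)
    } else idx <- which(rep_len(TRUE, length(s)))[samples]
    d <- d[idx, , drop = FALSE]
    s <- s[idx]
  }
  lt <- g$loci
  if (!is.null(loci)) {
    d <- d[, loci, drop = FALSE]
    lt <- lt[loci, , drop = FALSE]
    rownames(lt) <- NULL
  }
  genotype_matrix(d, lt, s)
}

#' Site-filter settings for VCF ingestion
#'
#' Mirrors the usual VCFtools-style hard filters applied to population
#' resequencing data.  `max_missing` follows VCFtools semantics: it is the
#' minimum *call rate*, i.e. `max_missing = 0.2` keeps sites with at least
#' 20\% of genotypes called.  Depth/quality filters are applied only when the
#' corresponding fields are present in the VCF (otherwise skipped with a
#' warning), since in practice they are often applied upstream.
#'
#' @param maf minimum minor-allele frequency, computed on non-missing alleles
#'   over the full sample set at ingestion.
#' @param max_missing minimum call rate in `[0, 1]` (VCFtools convention).
#' @param min_mean_dp minimum site mean genotype depth; `NULL` disables.
#' @param min_qual minimum site QUAL; `NULL` disables.
#' @param biallelic_snp_only drop indels and multi-allelic records.
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf = 0.05, max_missing = 0.2, min_mean_dp = 3,
                          min_qual = 30, biallelic_snp_only = TRUE) {
  stopifnot(maf >= 0, maf <= 0.5, max_missing >= 0, max_missing <= 1)
  structure(list(maf = maf, max_missing = max_missing,
                 min_mean_dp = min_mean_dp, min_qual = min_qual,
                 biallelic_snp_only = biallelic_snp_only),
            class = "filter_config")
}

.gt_to_dosage <- function(gt) {
  # gt: character matrix loci x samples from vcfR::extract.gt
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  ok <- grepl("^[01.][/|][01.]$", u)
  if (!all(ok)) {
    bad <- u[!ok][1]
    stop("unsupported ploidy or allele code in GT field: '", bad,
         "' (diploid biallelic 0/0, 0/1, 1/1, ./., with / or |, expected)")
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  # half-calls (./1, 0/.) carry incomplete information and are set missing
  d <- ifelse(a1 == "." | a2 == ".", NA_integer_,
              (a1 == "1") + (a2 == "1"))
  d[is.na(gt)] <- NA_integer_
  matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a VCF and apply site-level filters
#'
#' Reads a (possibly gzipped) VCF 4.x with vcfR, keeps biallelic SNPs passing
#' QUAL, mean-depth, call-rate and MAF thresholds, and returns dosages.
#' Filters are applied in the order: biallelic-SNP, QUAL, mean DP, call rate,
#' MAF.  MAF is computed once here on the full sample set; downstream
#' analyses subset samples without re-filtering (use
#' `recompute_maf_on_subset()` if per-subset MAF filtering is wanted).
#'
#' @param path VCF file.
#' @param filters a [filter_config()].
#' @return a [genotype_matrix()] with filtered, coordinate-sorted loci.
#' @export
read_vcf_filtered <- function(path, filters = filter_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  keep <- rep(TRUE, nrow(fix))
  if (isTRUE(filters$biallelic_snp_only)) {
    snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." &
      fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
    keep <- keep & snp
  }
  if (!is.null(filters$min_qual)) {
    qual <- suppressWarnings(as.numeric(fix$QUAL))
    if (all(is.na(qual))) {
      warning("QUAL absent from VCF; skipping min_qual filter")
    } else {
      keep <- keep & !is.na(qual) & qual >= filters$min_qual
    }
  }
  v@fix <- v@fix[keep, , drop = FALSE]
  v@gt <- v@gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) stop("no sites survive fixed-field filters")

  gt <- vcfR::extract.gt(v, element = "GT")
  d <- .gt_to_dosage(gt)          # loci x samples
  if (!is.null(filters$min_mean_dp)) {
    fmt <- v@gt[, 1]
    if (any(grepl("(^|:)DP(:|$)", fmt))) {
      dp <- suppressWarnings(
        matrix(as.numeric(vcfR::extract.gt(v, element = "DP")),
               nrow = nrow(d)))
      mean_dp <- rowMeans(dp, na.rm = TRUE)
      mean_dp[is.nan(mean_dp)] <- NA
      pass_dp <- !is.na(mean_dp) & mean_dp >= filters$min_mean_dp
    } else {
      warning("DP absent from FORMAT; skipping min_mean_dp filter")
      pass_dp <- rep(TRUE, nrow(d))
    }
  } else pass_dp <- rep(TRUE, nrow(d))

  n_called <- rowSums(!is.na(d))
  call_rate <- n_called / ncol(d)
  pass_cr <- call_rate >= filters$max_missing
  alt <- rowSums(d, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA)
  maf <- pmin(p, 1 - p)
  pass_maf <- !is.na(maf) & maf >= filters$maf
  sel <- pass_dp & pass_cr & pass_maf
  if (!any(sel)) stop("no sites survive genotype-level filters")

  fix <- fix[sel, , drop = FALSE]
  d <- d[sel, , drop = FALSE]
  id <- fix$ID
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = id, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  genotype_matrix(t(d), loci, samples = colnames(d))
}

#' Recompute MAF on a sample subset and drop failing loci
#'
#' @param g a `genotype_matrix`.
#' @param samples sample subset.
#' @param maf minimum minor-allele frequency within the subset.
#' @return a `genotype_matrix` restricted to `samples`.
#' @export
recompute_maf_on_subset <- function(g, samples, maf = 0.05) {
  gs <- gm_subset(g, samples = samples)
  af <- allele_frequencies(gs)
  m <- pmin(af$freq, 1 - af$freq)
  gm_subset(gs, loci = !is.na(m) & m >= maf)
}

#' Write a genotype matrix to a VCF file
#'
#' Minimal deterministic VCF 4.2 writer (GT field, optional per-site QUAL and
#' per-genotype DP).  `write_vcf()` followed by [read_vcf_filtered()] with
#' no-op filters reproduces the genotype matrix exactly.
#'
#' @param g a `genotype_matrix`.
#' @param path output file.
#' @param qual numeric per-site QUAL values (default ".").
#' @param dp optional integer matrix (samples x loci) of genotype depths.
#' @param extra_lines optional pre-formatted VCF body lines to interleave
#'   (used by the fixture writer to plant filter-failing records); must carry
#'   their own sample columns.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, qual = NULL, dp = NULL, extra_lines = NULL) {
  n <- length(g$samples)
  L <- nrow(g$loci)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popclim",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fmt <- "GT"
  if (!is.null(dp)) {
    hdr <- c(hdr,
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
    fmt <- "GT:DP"
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", g$samples),
                      collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  gts <- matrix("./.", nrow = n, ncol = L)
  ok <- !is.na(g$dosage)
  gts[ok] <- gt_code[g$dosage[ok] + 1L]
  if (!is.null(dp)) {
    gts <- matrix(paste(gts, ifelse(is.na(dp), ".", dp), sep = ":"),
                  nrow = n)
  }
  qual_s <- if (is.null(qual)) rep(".", L) else format(qual, trim = TRUE)
  body <- do.call(paste, c(list(g$loci$chrom, g$loci$pos, g$loci$id,
                                g$loci$ref, g$loci$alt, qual_s, "PASS", ".",
                                fmt),
                           lapply(seq_len(n), function(i) gts[i, ]),
                           list(sep = "\t")))
  if (!is.null(extra_lines)) {
    body <- c(body, extra_lines)
    key_chrom <- sub("\t.*", "", body)
    key_pos <- as.integer(vapply(strsplit(body, "\t", fixed = TRUE),
                                 `[`, "", 2L))
    body <- body[order(key_chrom, key_pos)]
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps features of type `gene` only.  Coordinates stay 1-based inclusive as
#' in the file.  Records lacking an `ID` attribute get a synthesized stable
#' ID (`gene_<chrom>_<start>`) with a warning.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by (chrom, start).
#' @export
read_gff_genes <- function(path) {
  gff <- ape::read.gff(path, na.strings = c(".", "?"))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  id <- sub(".*(?:^|;)\\s*ID=([^;]+).*", "\\1", genes$attributes)
  noid <- !grepl("ID=", genes$attributes)
  if (any(noid)) {
    warning(sum(noid), " gene record(s) lack an ID attribute; IDs synthesized")
    id[noid] <- paste0("gene_", genes$seqid[noid], "_", genes$start[noid])
  }
  strand <- as.character(genes$strand)
  strand[is.na(strand)] <- "."
  out <- data.frame(gene_id = id, chrom = as.character(genes$seqid),
                    start = genes$start, end = genes$end, strand = strand,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.parse_env_columns <- function(nms) {
  parts <- strsplit(nms, ":", fixed = TRUE)
  n <- lengths(parts)
  if (any(!n %in% c(1L, 3L)))
    stop("environment columns must be 'EV' or 'EV:SCENARIO:MODEL'; got: ",
         paste(nms[!n %in% c(1L, 3L)], collapse = ", "))
  data.frame(column = nms,
             ev = vapply(parts, `[`, "", 1L),
             scenario = ifelse(n == 3L, vapply(parts, `[`, "", 2L), NA),
             model = ifelse(n == 3L, vapply(parts, `[`, "", 3L), NA),
             stringsAsFactors = FALSE)
}

#' Construct an environment frame
#'
#' Population-level environmental variables for the current period and for
#' (scenario x climate model) futures.
#'
#' @param current data.frame of current EV values, one row per population;
#'   must contain `population_id`.
#' @param future long data.frame with columns `population_id`, `ev`,
#'   `scenario`, `model`, `value` (may be empty).
#' @return an `env_frame` object.
#' @export
env_frame <- function(current, future = NULL) {
  stopifnot("population_id" %in% names(current))
  if (anyDuplicated(current$population_id))
    stop("duplicate population rows in environment table")
  evs <- setdiff(names(current), "population_id")
  if (is.null(future))
    future <- data.frame(population_id = character(), ev = character(),
                         scenario = character(), model = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  structure(list(populations = current$population_id, evs = evs,
                 current = current, future = future),
            class = "env_frame")
}

#' @export
#' @method print env_frame
print.env_frame <- function(x, ...) {
  cat(sprintf("env_frame: %d populations, %d EVs (%s)\n",
              length(x$populations), length(x$evs),
              paste(x$evs, collapse = ", ")))
  if (nrow(x$future)) {
    cat(sprintf("  futures: %s x %s\n",
                paste(unique(x$future$scenario), collapse = "/"),
                paste(unique(x$future$model), collapse = "/")))
  }
  invisible(x)
}

#' Future EV values for one scenario/model
#'
#' @param env an `env_frame`.
#' @param ev,scenario,model selection.
#' @return named numeric vector (population -> value).
#' @export
env_future_values <- function(env, ev, scenario, model) {
  f <- env$future
  f <- f[f$ev == ev & f$scenario == scenario & f$model == model, ]
  if (nrow(f) == 0)
    stop("no future values for ", ev, "/", scenario, "/", model)
  stats::setNames(f$value, f$population_id)[env$populations]
}

#' Read sample and environment tables
#'
#' Both tables are TSV (or CSV) with headers.  The sample table needs columns
#' `sample_id`, `population_id`, `group_id`, `latitude`, `longitude`,
#' `altitude`.  The environment table needs `population_id` plus EV columns;
#' future-scenario columns are tagged `EV:SCENARIO:MODEL`
#' (e.g. `bio1:SSP585:ACCESS-CM2`).
#'
#' @param sample_path,env_path file paths.
#' @return list with elements `samples` (data.frame) and `env`
#'   (an [env_frame()]).
#' @export
read_tables <- function(sample_path, env_path) {
  rd <- function(p) {
    first <- readLines(p, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "")
  }
  sf <- rd(sample_path)
  req <- c("sample_id", "population_id", "group_id", "latitude",
           "longitude", "altitude")
  if (!all(req %in% names(sf)))
    stop("sample table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(sf$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(sf$sample_id[duplicated(sf$sample_id)]), collapse = ", "))
  if (any(abs(sf$latitude) > 90) || any(abs(sf$longitude) > 180))
    stop("latitude/longitude out of range")
  ev <- rd(env_path)
  if (!"population_id" %in% names(ev))
    stop("environment table must have a population_id column")
  missing_pops <- setdiff(sf$population_id, ev$population_id)
  if (length(missing_pops))
    stop("populations missing from environment table: ",
         paste(missing_pops, collapse = ", "))
  cmap <- .parse_env_columns(setdiff(names(ev), "population_id"))
  cur_cols <- cmap$column[is.na(cmap$scenario)]
  fut_cols <- cmap$column[!is.na(cmap$scenario)]
  current <- ev[, c("population_id", cur_cols), drop = FALSE]
  future <- NULL
  if (length(fut_cols)) {
    future <- do.call(rbind, lapply(fut_cols, function(cl) {
      m <- cmap[cmap$column == cl, ]
      data.frame(population_id = ev$population_id, ev = m$ev,
                 scenario = m$scenario, model = m$model, value = ev[[cl]],
                 stringsAsFactors = FALSE)
    }))
  }
  list(samples = sf, env = env_frame(current, future))
}

#' Write sample and environment tables (fixture format)
#'
#' @param samples sample data.frame.
#' @param env an `env_frame`.
#' @param sample_path,env_path output paths.
#' @return invisible NULL.
#' @keywords internal
write_tables <- function(samples, env, sample_path, env_path) {
  wr <- function(df, p) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) format(x, digits = 10, trim = TRUE,
                                                  scientific = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(samples, sample_path)
  wide <- env$current
  if (nrow(env$future)) {
    f <- env$future
    keys <- unique(f[, c("ev", "scenario", "model")])
    keys <- keys[order(keys$ev, keys$scenario, keys$model), , drop = FALSE]
    for (i in seq_len(nrow(keys))) {
      cl <- paste(keys$ev[i], keys$scenario[i], keys$model[i], sep = ":")
      sub <- f[f$ev == keys$ev[i] & f$scenario == keys$scenario[i] &
                 f$model == keys$model[i], ]
      wide[[cl]] <- sub$value[match(wide$population_id, sub$population_id)]
    }
  }
  wr(wide, env_path)
  invisible(NULL)
}

#' Export regions or windows to BED
#'
#' Internal 1-based inclusive coordinates become 0-based half-open intervals.
#'
#' @param x data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`, `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) format(x$score, digits = 6) else "0"
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- paste(x$chrom, x$start - 1L, x$end, name, score, strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a windowed-statistic track to TSV
#'
#' @param track a `stat_track` data.frame (see [windowed_pi()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  df <- as.data.frame(track)
  df$value <- format(df$value, digits = 10, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
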
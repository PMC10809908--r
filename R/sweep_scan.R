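#' Windowed theta-pi ratio between a reference and a focal group
#'
#' Per window, `ratio = pi_reference / pi_focal`, so that a sweep (locally
#' reduced diversity) in the focal group lands in the top tail of the
#' distribution.  Windows where both diversities are 0 are undefined (NA);
#' `pi_focal = 0` with `pi_reference > 0` yields `Inf`, ranked above every
#' finite ratio when thresholding.  Set `orientation = "focal_over_ref"` to
#' invert.
#'
#' @param g a `genotype_matrix`.
#' @param focal,reference sample-ID vectors for the focal group and the
#'   reference group(s) (e.g. all remaining groups pooled).
#' @param length_bp,step_bp window size and step in bp.
#' @param orientation `"ref_over_focal"` (default) or `"focal_over_ref"`.
#' @return a `stat_track` with statistic `pi_ratio`; attributes carry the
#'   orientation and the two per-group pi tracks.
#' @export
pi_ratio_scan <- function(g, focal, reference, length_bp = 100000,
                          step_bp = 1000,
                          orientation = c("ref_over_focal",
                                          "focal_over_ref")) {
  orientation <- match.arg(orientation)
  if (length(focal) < 2 || length(reference) < 2)
    stop("both groups need >= 2 samples")
  pf <- windowed_pi(g, samples = focal, length_bp = length_bp,
                    step_bp = step_bp)
  pr <- windowed_pi(g, samples = reference, length_bp = length_bp,
                    step_bp = step_bp)
  stopifnot(.same_grid(pf, pr))
  num <- if (orientation == "ref_over_focal") pr$value else pf$value
  den <- if (orientation == "ref_over_focal") pf$value else pr$value
  ratio <- ifelse(num == 0 & den == 0, NA_real_, num / den)
  if (!any(!is.na(ratio))) stop("no defined windows in pi-ratio scan")
  out <- .stat_track(pf[, c("chrom", "start", "end")], ratio, pf$n_sites,
                     "pi_ratio",
                     window_spec = c(length_bp = length_bp, step_bp = step_bp),
                     orientation = orientation)
  attr(out, "pi_focal") <- pf$value
  attr(out, "pi_reference") <- pr$value
  out
}

#' Joint top-quantile F_ST x theta-pi-ratio sweep regions
#'
#' Thresholds are the empirical `(1 - q)` quantiles (type 7) of the defined,
#' finite window values of each track; selected windows lie strictly above
#' both thresholds (`Inf` ratios always pass the ratio cut).  Overlapping or
#' near-adjacent (within `merge_gap` bp) selected windows are merged into
#' regions.  With `q >= 1` every defined window is selected.
#'
#' @param fst_track,ratio_track `stat_track`s on the identical window grid.
#' @param q upper tail fraction (default 0.05, i.e. top 5\%).
#' @param merge_gap maximum bp gap between selected windows merged into one
#'   region.
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_fst`, `mean_ratio` (mean over finite window ratios; `Inf` when
#'   all member windows are infinite).
#' @export
joint_outlier_regions <- function(fst_track, ratio_track, q = 0.05,
                                  merge_gap = 0) {
  if (!.same_grid(fst_track, ratio_track))
    stop("window grids differ between tracks")
  f <- fst_track$value
  r <- ratio_track$value
  def_f <- !is.na(f)
  def_r <- !is.na(r)
  if (q >= 1) {
    sel <- def_f & def_r
  } else {
    thr_f <- stats::quantile(f[def_f], 1 - q, type = 7, names = FALSE)
    thr_r <- stats::quantile(r[def_r & is.finite(r)], 1 - q, type = 7,
                             names = FALSE)
    sel <- def_f & def_r & f > thr_f & (r > thr_r | is.infinite(r))
  }
  idx <- which(sel)
  if (!length(idx))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_fst = numeric(), mean_ratio = numeric()))
  w <- fst_track[idx, c("chrom", "start", "end")]
  ord <- order(w$chrom, w$start)
  w <- w[ord, ]
  idx <- idx[ord]
  regions <- list()
  cur <- list(chrom = w$chrom[1], start = w$start[1], end = w$end[1],
              members = idx[1])
  flush <- function(cur) {
    fin <- r[cur$members][is.finite(r[cur$members])]
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_windows = length(cur$members),
               mean_fst = mean(f[cur$members]),
               mean_ratio = if (length(fin)) mean(fin) else Inf)
  }
  for (k in seq_len(nrow(w))[-1]) {
    if (w$chrom[k] == cur$chrom && w$start[k] <= cur$end + merge_gap + 1L) {
      cur$end <- max(cur$end, w$end[k])
      cur$members <- c(cur$members, idx[k])
    } else {
      regions[[length(regions) + 1L]] <- flush(cur)
      cur <- list(chrom = w$chrom[k], start = w$start[k], end = w$end[k],
                  members = idx[k])
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene overlaps a region when their 1-based inclusive spans intersect by
#' at least 1 bp.  Gene lists are sorted by gene start.
#'
#' @param regions data.frame from [joint_outlier_regions()].
#' @param genes gene-model data.frame from [read_gff_genes()].
#' @return `regions` with added columns `n_genes` and `genes`
#'   (comma-separated gene IDs).
#' @export
annotate_regions <- function(regions, genes) {
  if (!nrow(regions)) {
    regions$n_genes <- integer(0)
    regions$genes <- character(0)
    return(regions)
  }
  glists <- vapply(seq_len(nrow(regions)), function(i) {
    ov <- genes$chrom == regions$chrom[i] &
      genes$start <= regions$end[i] & genes$end >= regions$start[i]
    g <- genes[ov, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    paste(g$gene_id, collapse = ",")
  }, "")
  regions$n_genes <- ifelse(glists == "", 0L,
                            lengths(strsplit(glists, ",", fixed = TRUE)))
  regions$genes <- glists
  regions
}
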
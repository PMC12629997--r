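#' Average modified z-score of a prophage region
#'
#' Robust outlier statistic for a candidate region against the host
#' background: the mean over the region's bins of
#' `0.6745 * (x_p - median(x_h)) / MAD`, where `MAD` is the median absolute
#' deviation of host-bin depths about their median. The constant 0.6745 makes
#' the MAD a consistent estimator of the standard deviation under normality.
#'
#' @param coverage A masked `binned_coverage` (see [mask_regions()]).
#' @param region_id Region label present in the coverage mask.
#'
#' @return The average modified z-score, or `NA_real_` when the host MAD is
#'   zero (flat host coverage), in which case the induction decision falls to
#'   the fold-change / Cohen's d clause.
#' @seealso [cohens_d()], [fold_change()], [call_induction()]
#' @export
zscore_ave <- function(coverage, region_id) {
  x_p <- phage_bins(coverage, region_id)
  x_h <- host_bins(coverage)
  if (length(x_p) < 1L) stop("no bins labelled ", region_id)
  if (length(x_h) < 2L) stop("cannot form host null: fewer than 2 host bins")
  med <- stats::median(x_h)
  mad_h <- stats::median(abs(x_h - med))
  if (mad_h == 0) return(NA_real_)
  mean(0.6745 * (x_p - med) / mad_h)
}

#' Cohen's d between host and prophage coverage
#'
#' Standardized mean difference
#' `(mean(x_h) - mean(x_p)) / sqrt((S_h^2 + S_p^2) / 2)` with `S` the sample
#' standard deviation of each group. The sign is negative for induced regions
#' (phage coverage exceeding host); the decision rule uses the magnitude.
#'
#' @inheritParams zscore_ave
#' @return Signed effect size, or `NA_real_` when both standard deviations
#'   are zero.
#' @export
cohens_d <- function(coverage, region_id) {
  x_p <- phage_bins(coverage, region_id)
  x_h <- host_bins(coverage)
  if (length(x_p) < 2L || length(x_h) < 2L)
    stop("cohens_d needs at least 2 bins on each side")
  pooled <- sqrt((stats::var(x_h) + stats::var(x_p)) / 2)
  if (pooled == 0) return(NA_real_)
  (mean(x_h) - mean(x_p)) / pooled
}

#' Coverage fold change of a prophage region
#'
#' Mean depth over the region's bins divided by the host baseline. The
#' baseline defaults to the median host-bin depth, which is robust to other
#' induced regions elsewhere on the genome; the host mean is available as an
#' alternative.
#'
#' @inheritParams zscore_ave
#' @param baseline `"median"` (default) or `"mean"` host-bin depth.
#' @return Fold change, or `NA_real_` when the baseline is zero.
#' @export
fold_change <- function(coverage, region_id, baseline = c("median", "mean")) {
  baseline <- match.arg(baseline)
  x_p <- phage_bins(coverage, region_id)
  x_h <- host_bins(coverage)
  if (length(x_p) < 1L) stop("no bins labelled ", region_id)
  if (length(x_h) < 1L) stop("no host bins")
  base <- if (baseline == "median") stats::median(x_h) else mean(x_h)
  if (base == 0) return(NA_real_)
  mean(x_p) / base
}

#' Induction decision rule
#'
#' A region is called induced when its average modified z-score reaches
#' `z_min`, or when it shows at least `fold_min`-fold coverage together with
#' a Cohen's d magnitude of at least `d_min`. An undefined (`NA`) statistic
#' fails only its own clause, so a flat host background (undefined z) can
#' still be rescued by the fold + effect-size clause.
#'
#' @param z_ave,cohens_d,fold Numeric vectors (recycled to common length).
#' @param z_min Minimum average modified z-score (default 3.5).
#' @param fold_min Minimum coverage fold change (default 2).
#' @param d_min Minimum `|d|` (default 0.7).
#' @return Logical vector of induction calls.
#' @export
call_induction <- function(z_ave, cohens_d, fold,
                           z_min = 3.5, fold_min = 2, d_min = 0.7) {
  n <- max(length(z_ave), length(cohens_d), length(fold))
  z_ave <- rep_len(z_ave, n)
  cohens_d <- rep_len(cohens_d, n)
  fold <- rep_len(fold, n)
  clause_z <- !is.na(z_ave) & z_ave >= z_min
  clause_fd <- !is.na(fold) & !is.na(cohens_d) &
    fold >= fold_min & abs(cohens_d) >= d_min
  clause_z | clause_fd
}

#' Induction statistics for every masked region
#'
#' Convenience wrapper computing [zscore_ave()], [cohens_d()],
#' [fold_change()] and the [call_induction()] decision for each region
#' labelled in the coverage mask. Regions with a single bin get `NA` for
#' Cohen's d (the effect size needs two bins per side).
#'
#' @param coverage A masked `binned_coverage`.
#' @param sample_id Identifier recorded in the output (default `NA`).
#' @param baseline Fold-change baseline, see [fold_change()].
#' @inheritParams call_induction
#' @return Data frame with one row per region: `sample_id`, `region_id`,
#'   `z_ave`, `cohens_d`, `fold_change`, `induced`.
#' @export
induction_stats <- function(coverage, sample_id = NA_character_,
                            baseline = "median",
                            z_min = 3.5, fold_min = 2, d_min = 0.7) {
  ids <- setdiff(unique(coverage$region_mask), "host")
  if (length(ids) == 0L)
    return(data.frame(sample_id = character(), region_id = character(),
                      z_ave = numeric(), cohens_d = numeric(),
                      fold_change = numeric(), induced = logical()))
  z <- vapply(ids, function(r) zscore_ave(coverage, r), numeric(1))
  d <- vapply(ids, function(r) {
    tryCatch(cohens_d(coverage, r), error = function(e) NA_real_)
  }, numeric(1))
  f <- vapply(ids, function(r) fold_change(coverage, r, baseline), numeric(1))
  data.frame(sample_id = sample_id, region_id = ids,
             z_ave = z, cohens_d = d, fold_change = f,
             induced = call_induction(z, d, f, z_min, fold_min, d_min),
             row.names = NULL)
}

#' Refine prophage region boundaries by coverage
#'
#' Trims flanking bins whose depth falls below a quarter of the region's
#' mean bin depth. The threshold is computed once from the initial region and
#' not updated during trimming; only flanking runs are removed, interior low
#' bins are kept. The result never extends beyond the input region.
#'
#' @param coverage A `binned_coverage` on the region's contig.
#' @param region One-row data frame with `start`, `end` (0-based half-open)
#'   and optionally other columns, which are carried through.
#' @param frac Fraction of the region's mean bin depth used as the trimming
#'   threshold (default 0.25).
#' @return The region with updated `start`/`end`, or a zero-row data frame
#'   (with a warning) when every bin is trimmed.
#' @export
refine_boundaries <- function(coverage, region, frac = 0.25) {
  stopifnot(inherits(coverage, "binned_coverage"), nrow(region) == 1L)
  bs <- coverage$bin_start
  be <- coverage$bin_start + coverage$bin_width
  idx <- which(bs < region$end & be > region$start)
  if (length(idx) == 0L) stop("region maps to no bins")
  d <- coverage$depth[idx]
  thr <- frac * mean(d)
  lo <- 1L
  hi <- length(d)
  while (lo <= hi && d[lo] < thr) lo <- lo + 1L
  while (hi >= lo && d[hi] < thr) hi <- hi - 1L
  if (lo > hi) {
    warning("all bins trimmed for region [", region$start, ",", region$end, ")")
    return(region[0L, , drop = FALSE])
  }
  region$start <- max(region$start, bs[idx[lo]])
  region$end <- min(region$end, be[idx[hi]])
  region
}

#' Merge overlapping prophage predictions
#'
#' Predictions overlapping by at least 1 bp on the same contig are merged
#' into a single region spanning their union; abutting half-open intervals
#' (end of one equal to start of the next) are kept separate. The merged
#' region's completeness is the maximum over its members and its quality is
#' recomputed from that completeness (> 50% is high).
#'
#' @param regions Data frame with `start`, `end` (0-based half-open) and
#'   optionally `contig`, `completeness` (percent), `source`.
#' @return Data frame of pairwise-disjoint regions, sorted by contig and
#'   start, with `region_id` renumbered.
#' @export
merge_overlapping <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(regions)
  if (!"contig" %in% names(regions)) regions$contig <- "contig_1"
  has_comp <- "completeness" %in% names(regions)
  has_src <- "source" %in% names(regions)
  out <- lapply(split(regions, regions$contig), function(tab) {
    ir <- IRanges::IRanges(start = tab$start + 1L, end = tab$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    res <- data.frame(contig = tab$contig[1L],
                      start = IRanges::start(red) - 1L,
                      end = IRanges::end(red))
    if (has_comp) {
      res$completeness <- vapply(revmap, function(m) {
        v <- tab$completeness[m]
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      }, numeric(1))
      res$quality <- ifelse(is.na(res$completeness), NA_character_,
                            ifelse(res$completeness > 50, "high", "low"))
    }
    if (has_src) {
      res$source <- vapply(revmap, function(m) {
        paste(unique(tab$source[m]), collapse = ";")
      }, character(1))
    }
    res
  })
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  res$region_id <- paste0("region_", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Published hallmark-gene length cut-offs (amino acids)
#'
#' Minimum protein lengths for counting a Caudoviricetes hallmark hit,
#' derived as half the mean length of the middle 80% of database
#' representatives of each gene class.
#' @format Named numeric vector.
#' @export
caudoviricetes_hallmark_cutoffs <- c(
  terminase_large = 265, portal = 245, major_head = 186)

#' Derive a hallmark-gene length cut-off
#'
#' Drops protein lengths below the 10th or above the 90th percentile (linear
#' interpolation convention) and returns half the mean of the remainder.
#'
#' @param lengths Numeric vector of protein lengths (>= 5 values).
#' @param probs Percentile window retained (default middle 80%).
#' @return Cut-off in amino acids.
#' @export
derive_length_cutoff <- function(lengths, probs = c(0.1, 0.9)) {
  stopifnot(length(lengths) >= 5L)
  q <- stats::quantile(lengths, probs, type = 7, names = FALSE)
  kept <- lengths[lengths >= q[1] & lengths <= q[2]]
  if (length(kept) == 0L) stop("no lengths left after percentile trimming")
  0.5 * mean(kept)
}

#' Retain contigs carrying a credible viral hallmark gene
#'
#' A hit counts only if its protein length reaches the cut-off for its gene
#' class; a contig is retained when it has at least one counting hit. Hits of
#' unknown gene class are ignored with a warning.
#'
#' @param hits Data frame with columns `contig_id`, `gene` and
#'   `protein_length`.
#' @param cutoffs Named vector of per-class minimum lengths (default
#'   [caudoviricetes_hallmark_cutoffs]).
#' @return Character vector of retained contig ids.
#' @export
filter_hallmarks <- function(hits, cutoffs = caudoviricetes_hallmark_cutoffs) {
  if (nrow(hits) == 0L) return(character())
  unknown <- !(hits$gene %in% names(cutoffs))
  if (any(unknown)) {
    warning("ignoring hits with unknown gene class: ",
            paste(unique(hits$gene[unknown]), collapse = ", "))
    hits <- hits[!unknown, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(character())
  ok <- hits$protein_length >= cutoffs[hits$gene]
  unique(hits$contig_id[ok])
}

#' Call induced prophage regions from a depth table
#'
#' End-to-end single-sample wrapper: bins the depth table, merges overlapping
#' predictions, masks the track, computes induction statistics, and refines
#' the boundaries of induced regions.
#'
#' @param depth_table samtools-depth style data frame (see [bin_depth()]).
#' @param regions Prediction data frame (`contig`, `start`, `end`, optional
#'   `completeness`).
#' @param bin_size Bin width in bp.
#' @param contig_length Optional named contig lengths.
#' @inheritParams induction_stats
#' @return List with `calls` (statistics per region per contig) and
#'   `refined` (refined intervals of induced regions).
#' @export
call_induced_regions <- function(depth_table, regions, bin_size = 100L,
                                 contig_length = NULL,
                                 sample_id = NA_character_,
                                 baseline = "median",
                                 z_min = 3.5, fold_min = 2, d_min = 0.7) {
  regions <- merge_overlapping(regions)
  cov <- bin_depth(depth_table, bin_size, contig_length)
  if (inherits(cov, "binned_coverage")) cov <- stats::setNames(list(cov), cov$contig_id)
  calls <- list()
  refined <- list()
  for (ctg in names(cov)) {
    cv <- mask_regions(cov[[ctg]], regions)
    st <- induction_stats(cv, sample_id, baseline, z_min, fold_min, d_min)
    if (nrow(st) == 0L) next
    st$contig <- ctg
    calls[[ctg]] <- st
    for (rid in st$region_id[st$induced]) {
      reg <- regions[regions$region_id == rid & regions$contig == ctg, , drop = FALSE]
      refined[[rid]] <- refine_boundaries(cv, reg)
    }
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       refined = do.call(rbind, c(refined, list(make.row.names = FALSE))))
}
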
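#' Binned coverage track
#'
#' Container for a per-contig coverage track summarised in fixed-width bins
#' (100 bp by default). Each bin carries the mean per-base depth over its
#' span; the last bin may be partial and then carries the mean over the
#' remaining bases. Bins are labelled either `"host"` or with the id of the
#' prophage region they overlap (see [mask_regions()]).
#'
#' @param contig_id Single contig name.
#' @param depth Numeric vector of per-bin mean depths (>= 0).
#' @param bin_size Bin width in bp.
#' @param contig_length Contig length in bp; defaults to a full tiling.
#' @param region_mask Character vector, one label per bin (`"host"` or a
#'   region id). Defaults to all-host.
#'
#' @return An object of class `binned_coverage`: a list with elements
#'   `contig_id`, `bin_size`, `contig_length`, `depth`, `bin_start`
#'   (0-based), `bin_width` and `region_mask`.
#' @export
binned_coverage <- function(contig_id, depth, bin_size = 100L,
                            contig_length = NULL,
                            region_mask = NULL) {
  depth <- as.numeric(depth)
  stopifnot(length(contig_id) == 1L, bin_size > 0, all(depth >= 0))
  n <- length(depth)
  if (is.null(contig_length)) contig_length <- n * bin_size
  if (contig_length <= (n - 1L) * bin_size || contig_length > n * bin_size)
    stop("contig_length inconsistent with number of bins")
  bin_start <- (seq_len(n) - 1L) * bin_size
  bin_width <- pmin(bin_size, contig_length - bin_start)
  if (is.null(region_mask)) region_mask <- rep("host", n)
  stopifnot(length(region_mask) == n)
  structure(
    list(contig_id = contig_id, bin_size = as.integer(bin_size),
         contig_length = as.numeric(contig_length),
         depth = depth, bin_start = bin_start, bin_width = bin_width,
         region_mask = as.character(region_mask)),
    class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  n_phage <- sum(x$region_mask != "host")
  cat(sprintf(
    "binned_coverage: %s (%d bp), %d bins of %d bp (%d phage-masked)\n",
    x$contig_id, x$contig_length, length(x$depth), x$bin_size, n_phage))
  invisible(x)
}

#' Bin a per-base depth table
#'
#' Converts a samtools-depth style table (contig, 1-based position, depth)
#' into mean depth per fixed-width bin. Positions absent from the table count
#' as depth 0; a trailing partial bin is retained with its per-base mean.
#'
#' @param depth_table Data frame with columns `contig`, `pos` (1-based) and
#'   `depth`, sorted by position within contig. Duplicated or unsorted
#'   positions are rejected.
#' @param bin_size Bin width in bp (default 100).
#' @param contig_length Optional named vector of contig lengths; when absent,
#'   each contig's length is taken as its maximum reported position.
#'
#' @return A `binned_coverage` for a single-contig table, otherwise a named
#'   list of `binned_coverage` objects.
#' @export
bin_depth <- function(depth_table, bin_size = 100L, contig_length = NULL) {
  stopifnot(all(c("contig", "pos", "depth") %in% names(depth_table)))
  split_tab <- split(depth_table, depth_table$contig)
  out <- lapply(names(split_tab), function(ctg) {
    tab <- split_tab[[ctg]]
    pos <- as.numeric(tab$pos)
    if (anyDuplicated(pos)) stop("duplicated positions on contig ", ctg)
    if (is.unsorted(pos, strictly = TRUE)) stop("unsorted positions on contig ", ctg)
    if (any(pos < 1)) stop("positions must be 1-based")
    len <- if (!is.null(contig_length) && ctg %in% names(contig_length))
      as.numeric(contig_length[[ctg]]) else max(pos)
    if (len < max(pos)) stop("contig_length smaller than max position on ", ctg)
    n_bins <- ceiling(len / bin_size)
    idx <- floor((pos - 1) / bin_size) + 1L
    sums <- numeric(n_bins)
    agg <- rowsum(as.numeric(tab$depth), idx)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
    width <- pmin(bin_size, len - (seq_len(n_bins) - 1L) * bin_size)
    binned_coverage(ctg, sums / width, bin_size = bin_size, contig_length = len)
  })
  names(out) <- names(split_tab)
  if (length(out) == 1L) out[[1L]] else out
}

#' Label coverage bins overlapping prophage regions
#'
#' Bins overlapping a region by at least 1 bp are labelled with the region's
#' id; all remaining bins are `"host"`. Host bins therefore exclude every
#' predicted region, not only the one under test, so that region statistics
#' are computed against an uncontaminated background.
#'
#' @param coverage A `binned_coverage`.
#' @param regions Data frame of regions with columns `start`, `end` (0-based,
#'   half-open) and optionally `region_id` and `contig`; rows on other
#'   contigs are ignored.
#'
#' @return The `binned_coverage` with an updated `region_mask`.
#' @export
mask_regions <- function(coverage, regions) {
  stopifnot(inherits(coverage, "binned_coverage"))
  mask <- rep("host", length(coverage$depth))
  if (is.null(regions) || nrow(regions) == 0L) {
    coverage$region_mask <- mask
    return(coverage)
  }
  if (!"region_id" %in% names(regions))
    regions$region_id <- paste0("region_", seq_len(nrow(regions)))
  if ("contig" %in% names(regions))
    regions <- regions[regions$contig == coverage$contig_id, , drop = FALSE]
  if (any(regions$start < 0 | regions$end > coverage$contig_length))
    stop("region outside contig bounds")
  bs <- coverage$bin_start
  be <- coverage$bin_start + coverage$bin_width
  for (i in seq_len(nrow(regions))) {
    hit <- bs < regions$end[i] & be > regions$start[i]
    mask[hit & mask == "host"] <- regions$region_id[i]
  }
  coverage$region_mask <- mask
  coverage
}

host_bins <- function(coverage) coverage$depth[coverage$region_mask == "host"]

phage_bins <- function(coverage, region_id) {
  coverage$depth[coverage$region_mask == region_id]
}
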
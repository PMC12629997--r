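#' Percent frequency change between prophage sets
#'
#' `100 * (f_cry - f_in) / f_in`, where `f_in` is a gene-category frequency
#' in the induced set and `f_cry` the frequency in the comparison
#' (putatively cryptic / predicted) set. Undefined (`NA`) when `f_in` is 0.
#'
#' @param f_in,f_cry Frequencies in \[0, 1\] (vectorized).
#' @return Percent change (positive when the category is more frequent in
#'   the comparison set).
#' @export
frequency_change <- function(f_in, f_cry) {
  stopifnot(all(f_in >= 0 & f_in <= 1, na.rm = TRUE),
            all(f_cry >= 0 & f_cry <= 1, na.rm = TRUE))
  ifelse(f_in == 0, NA_real_, 100 * (f_cry - f_in) / f_in)
}

category_counts <- function(annotations, mode) {
  if (mode == "total") {
    counts <- table(annotations$category)
    total <- nrow(annotations)
  } else {
    u <- unique(annotations[, c("genome", "category")])
    counts <- table(u$category)
    total <- length(unique(annotations$genome))
  }
  list(counts = counts, total = total)
}

#' Gene-category enrichment between induced and comparison prophages
#'
#' For each functional category (for example PHROG categories) a 2x2 table
#' (category vs all other genes, induced set vs comparison set) is tested
#' with a two-sided Fisher's exact test; p-values are adjusted with the
#' Hochberg method across categories. In `"total"` mode frequencies are
#' category genes over all annotated genes in the set; in `"presence"` mode
#' they are genomes containing the category over genomes in the set.
#' Degenerate tables with a zero margin give p = 1 and are flagged.
#'
#' @param annot_in,annot_cry Data frames with columns `genome`, `gene_id`,
#'   `category` for the induced and comparison sets.
#' @param mode `"total"` or `"presence"`.
#' @return Data frame per category: counts, frequencies `f_in`/`f_cry`,
#'   `freq_change` (percent), `p_value`, `p_adj`, `degenerate`.
#' @export
category_enrichment <- function(annot_in, annot_cry,
                                mode = c("total", "presence")) {
  mode <- match.arg(mode)
  stopifnot(nrow(annot_in) > 0L, nrow(annot_cry) > 0L)
  cin <- category_counts(annot_in, mode)
  ccr <- category_counts(annot_cry, mode)
  cats <- sort(union(names(cin$counts), names(ccr$counts)))
  get0n <- function(tab, x) if (x %in% names(tab)) as.integer(tab[[x]]) else 0L
  res <- lapply(cats, function(cat) {
    a <- get0n(cin$counts, cat)      # induced, in category
    b <- cin$total - a               # induced, rest
    c_ <- get0n(ccr$counts, cat)     # comparison, in category
    d <- ccr$total - c_              # comparison, rest
    m <- matrix(c(a, b, c_, d), nrow = 2)
    degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
    p <- if (degenerate) 1 else stats::fisher.test(m)$p.value
    f_in <- a / cin$total
    f_cry <- c_ / ccr$total
    data.frame(category = cat, n_in = a, total_in = cin$total,
               n_cry = c_, total_cry = ccr$total,
               f_in = f_in, f_cry = f_cry,
               freq_change = frequency_change(f_in, f_cry),
               p_value = p, degenerate = degenerate)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p_value, method = "hochberg")
  rownames(res) <- NULL
  res
}

#' Call HGT and insertion-deletion events between a prophage pair
#'
#' Scans the unaligned spans between adjacent collinear alignment blocks: a
#' span of at least `min_gap` bp on both genomes is an HGT (replacement)
#' event; a span of at least `min_gap` bp on exactly one genome is an
#' insertion-deletion event. Unaligned sequence before the first or after
#' the last block (gaps involving either genome's ends) is never counted.
#' Pairs whose blocks are not collinear on the subject after sorting by
#' query coordinate are excluded with a warning; blocks overlapping on
#' either genome are rejected.
#'
#' @param blocks Data frame of alignment blocks (`qstart`, `qend`, `sstart`,
#'   `send`, 1-based inclusive).
#' @param len_q,len_s Genome lengths in bp.
#' @param min_gap Minimum unaligned span in bp (default 50).
#' @return Data frame of events: `type` (`"HGT"`/`"indel"`), gap coordinates
#'   `qstart`, `qend`, `sstart`, `send` (1-based inclusive; `NA` on a side
#'   with no gap), `size_q`, `size_s`. Zero rows when no events (or when the
#'   pair was excluded, flagged by attribute `excluded = TRUE`).
#' @export
call_gap_events <- function(blocks, len_q, len_s, min_gap = 50) {
  empty <- data.frame(type = character(), qstart = numeric(),
                      qend = numeric(), sstart = numeric(), send = numeric(),
                      size_q = numeric(), size_s = numeric())
  if (is.null(blocks) || nrow(blocks) < 2L) return(empty)
  b <- blocks[order(blocks$qstart), , drop = FALSE]
  if (any(b$qstart > b$qend) || any(b$sstart > b$send) ||
      is.unsorted(b$sstart, strictly = TRUE)) {
    warning("blocks not collinear on subject; pair excluded from event calling")
    attr(empty, "excluded") <- TRUE
    return(empty)
  }
  n <- nrow(b)
  if (any(b$qstart[-1L] <= b$qend[-n]) || any(b$sstart[-1L] <= b$send[-n]))
    stop("overlapping alignment blocks")
  events <- list()
  for (i in seq_len(n - 1L)) {
    gap_q <- b$qstart[i + 1L] - b$qend[i] - 1
    gap_s <- b$sstart[i + 1L] - b$send[i] - 1
    if (gap_q >= min_gap && gap_s >= min_gap) {
      events[[length(events) + 1L]] <- data.frame(
        type = "HGT", qstart = b$qend[i] + 1, qend = b$qstart[i + 1L] - 1,
        sstart = b$send[i] + 1, send = b$sstart[i + 1L] - 1,
        size_q = gap_q, size_s = gap_s)
    } else if (gap_q >= min_gap) {
      events[[length(events) + 1L]] <- data.frame(
        type = "indel", qstart = b$qend[i] + 1, qend = b$qstart[i + 1L] - 1,
        sstart = NA_real_, send = NA_real_, size_q = gap_q, size_s = gap_s)
    } else if (gap_s >= min_gap) {
      events[[length(events) + 1L]] <- data.frame(
        type = "indel", qstart = NA_real_, qend = NA_real_,
        sstart = b$send[i] + 1, send = b$sstart[i + 1L] - 1,
        size_q = gap_q, size_s = gap_s)
    }
  }
  if (length(events) == 0L) return(empty)
  res <- do.call(rbind, events)
  rownames(res) <- NULL
  res
}

#' Tabulate gap-event counts for two sets of prophage pairs
#'
#' Summarises per-pair total, HGT and indel event counts for two pair sets
#' (for example induced/non-induced vs induced/induced pairs) and compares
#' the per-pair totals with a two-sided Wilcoxon rank-sum test.
#'
#' @param events_a,events_b Named lists of event data frames (one element
#'   per pair, as returned by [call_gap_events()]).
#' @param labels Length-2 character vector naming the two sets.
#' @return List with `summary` (per-pair counts, one row per pair) and
#'   `p_value` (rank-sum p on per-pair totals; `NA` when either set is
#'   empty).
#' @export
compare_event_counts <- function(events_a, events_b,
                                 labels = c("set_a", "set_b")) {
  tab <- function(evs, label) {
    if (length(evs) == 0L)
      return(data.frame(set = character(), pair_id = character(),
                        n_total = integer(), n_hgt = integer(),
                        n_indel = integer()))
    ids <- names(evs)
    if (is.null(ids)) ids <- paste0("pair_", seq_along(evs))
    do.call(rbind, lapply(seq_along(evs), function(i) {
      ev <- evs[[i]]
      data.frame(set = label, pair_id = ids[i], n_total = nrow(ev),
                 n_hgt = sum(ev$type == "HGT"),
                 n_indel = sum(ev$type == "indel"))
    }))
  }
  summary <- rbind(tab(events_a, labels[1L]), tab(events_b, labels[2L]))
  rownames(summary) <- NULL
  p <- if (length(events_a) && length(events_b)) {
    stats::wilcox.test(summary$n_total[summary$set == labels[1L]],
                       summary$n_total[summary$set == labels[2L]],
                       exact = FALSE)$p.value
  } else NA_real_
  list(summary = summary, p_value = p)
}
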
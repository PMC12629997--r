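#' ANI and alignment fraction from alignment blocks
#'
#' Resolves overlapping query intervals longest-first (later, shorter blocks
#' contribute only their not-yet-covered query span), then computes ANI as
#' the alignment-length-weighted mean percent identity and AF as the merged
#' aligned span divided by the shorter genome's length.
#'
#' @param blocks Data frame of local alignment blocks with columns `qstart`,
#'   `qend`, `sstart`, `send` (1-based inclusive) and `pident` (percent).
#' @param len_q,len_s Genome lengths in bp (> 0).
#' @return List with `ani` (percent; `NA` when there are no blocks) and `af`
#'   (percent of the shorter genome aligned).
#' @export
compute_ani_af <- function(blocks, len_q, len_s) {
  stopifnot(len_q > 0, len_s > 0)
  if (is.null(blocks) || nrow(blocks) == 0L)
    return(list(ani = NA_real_, af = 0))
  qs <- pmin(blocks$qstart, blocks$qend)
  qe <- pmax(blocks$qstart, blocks$qend)
  ord <- order(qe - qs, decreasing = TRUE)
  covered <- IRanges::IRanges()
  w_sum <- 0
  len_sum <- 0
  for (i in ord) {
    r <- IRanges::IRanges(qs[i], qe[i])
    ov <- sum(IRanges::width(IRanges::intersect(r, covered)))
    eff <- IRanges::width(r) - ov
    if (eff > 0) {
      w_sum <- w_sum + blocks$pident[i] * eff
      len_sum <- len_sum + eff
      covered <- IRanges::reduce(IRanges::union(covered, r))
    }
  }
  list(ani = w_sum / len_sum,
       af = 100 * sum(IRanges::width(covered)) / min(len_q, len_s))
}

#' Pairwise ANI/AF table from a BLAST-style block table
#'
#' Groups blocks by (query, subject) pair and applies [compute_ani_af()] to
#' each pair. Self-hits are dropped.
#'
#' @param blocks Data frame with `qid`, `sid`, `pident`, `qstart`, `qend`,
#'   `sstart`, `send`.
#' @param lengths Named numeric vector of genome lengths.
#' @return Data frame with `qid`, `sid`, `ani`, `af`.
#' @export
ani_af_table <- function(blocks, lengths) {
  blocks <- blocks[blocks$qid != blocks$sid, , drop = FALSE]
  if (nrow(blocks) == 0L)
    return(data.frame(qid = character(), sid = character(),
                      ani = numeric(), af = numeric()))
  missing <- setdiff(unique(c(blocks$qid, blocks$sid)), names(lengths))
  if (length(missing))
    stop("no length for genome(s): ", paste(missing, collapse = ", "))
  key <- paste(blocks$qid, blocks$sid, sep = "\r")
  out <- lapply(split(blocks, key), function(tab) {
    sim <- compute_ani_af(tab, lengths[[tab$qid[1L]]], lengths[[tab$sid[1L]]])
    data.frame(qid = tab$qid[1L], sid = tab$sid[1L],
               ani = sim$ani, af = sim$af)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greedy length-ranked dereplication of genomes
#'
#' Genomes are visited in order of decreasing length (ties broken
#' lexicographically by id); each genome joins the first existing cluster
#' whose representative it matches at or above both thresholds, otherwise it
#' founds a new cluster. Representatives are therefore the longest member of
#' each cluster. Comparison is against representatives only
#' (representative-linkage, matching anicalc/dRep-style tooling).
#'
#' @param pairs Data frame with `qid`, `sid`, `ani`, `af` (treated as
#'   symmetric: either orientation is looked up).
#' @param lengths Named numeric vector of genome lengths; its names define
#'   the genome universe.
#' @param ani_min,af_min Thresholds in percent (99/85 for dereplication,
#'   95/85 for species-level clustering).
#' @return Data frame with `genome`, `cluster_id`, `representative`,
#'   `is_representative`.
#' @export
cluster_dereplicate <- function(pairs, lengths, ani_min = 99, af_min = 85) {
  stopifnot(ani_min > 0, ani_min <= 100, af_min > 0, af_min <= 100)
  genomes <- names(lengths)
  ord <- genomes[order(-as.numeric(lengths), genomes)]
  sim <- new.env(parent = emptyenv())
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    for (i in seq_len(nrow(pairs))) {
      if (is.na(pairs$ani[i])) next
      ok <- pairs$ani[i] >= ani_min && pairs$af[i] >= af_min
      assign(paste(pairs$qid[i], pairs$sid[i], sep = "\r"), ok, envir = sim)
      assign(paste(pairs$sid[i], pairs$qid[i], sep = "\r"), ok, envir = sim)
    }
  }
  matches <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    exists(key, envir = sim) && get(key, envir = sim)
  }
  reps <- character(0)
  assign_to <- character(length(ord))
  names(assign_to) <- ord
  for (g in ord) {
    hit <- NA_character_
    for (r in reps) if (matches(g, r)) { hit <- r; break }
    if (is.na(hit)) {
      reps <- c(reps, g)
      assign_to[[g]] <- g
    } else {
      assign_to[[g]] <- hit
    }
  }
  cluster_id <- stats::setNames(paste0("cluster_", seq_along(reps)), reps)
  data.frame(genome = ord,
             cluster_id = unname(cluster_id[assign_to]),
             representative = unname(assign_to),
             is_representative = ord == assign_to,
             row.names = NULL)
}

#' Select comparable induced / non-induced prophage pairs
#'
#' Retains high-similarity pairs (default ANI >= 95 and AF >= 85) in which
#' the non-induced prophage's host was sequenced in at least one condition
#' under which the induced partner was actually induced — the rationale
#' being that highly similar prophages should respond to the same induction
#' triggers, so a failure to induce under a shared trigger marks the partner
#' as putatively cryptic.
#'
#' @param pairs Data frame with `induced_id`, `candidate_id`, `ani`, `af`.
#' @param induction_table Data frame with `region_id`, `condition`,
#'   `induced` (logical) recording where each induced prophage was induced.
#' @param condition_table Data frame with `genome_id`, `condition` listing
#'   the conditions in which each candidate's host was sequenced.
#' @param ani_min,af_min Similarity thresholds in percent.
#' @return The retained subset of `pairs`. Pairs with no condition records on
#'   either side are dropped with a warning.
#' @export
select_comparable_pairs <- function(pairs, induction_table, condition_table,
                                    ani_min = 95, af_min = 85) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(pairs)
  keep <- logical(nrow(pairs))
  dropped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    if (is.na(pairs$ani[i]) || pairs$ani[i] < ani_min || pairs$af[i] < af_min)
      next
    ind_cond <- induction_table$condition[
      induction_table$region_id == pairs$induced_id[i] & induction_table$induced]
    seq_cond <- condition_table$condition[
      condition_table$genome_id == pairs$candidate_id[i]]
    if (length(ind_cond) == 0L || length(seq_cond) == 0L) {
      dropped <- c(dropped, paste(pairs$induced_id[i], pairs$candidate_id[i]))
      next
    }
    keep[i] <- length(intersect(ind_cond, seq_cond)) > 0L
  }
  if (length(dropped))
    warning("dropping pair(s) with missing condition records: ",
            paste(dropped, collapse = "; "))
  pairs[keep, , drop = FALSE]
}
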
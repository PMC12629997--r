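#' Random DNA sequence with a given GC content
#'
#' Bases are drawn i.i.d.; no repeats are simulated.
#'
#' @param n Sequence length in bp.
#' @param gc GC fraction in \[0, 1\].
#' @return A single character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a lysogen genome with embedded prophages
#'
#' Builds a random host chromosome and inserts random prophage sequences at
#' the given host positions, returning the final genome together with a
#' truth table of the exact prophage coordinates (0-based, half-open) on the
#' assembled genome. Identical seeds yield byte-identical output.
#'
#' @param host_length Host chromosome length in bp (before insertion).
#' @param prophage_inserts Data frame with columns `position` (0-based offset
#'   on the host chromosome, strictly increasing), `phage_length` (bp) and
#'   optionally `label`. `NULL` for a prophage-free genome.
#' @param gc GC fraction of both host and phage sequence.
#' @param seed Integer seed.
#' @param contig_id Name of the emitted contig.
#' @return List with `genome` (character sequence), `truth` (data frame
#'   `region_id`, `contig`, `start`, `end`) and `contig_id`.
#' @export
gen_lysogen <- function(host_length, prophage_inserts = NULL, gc = 0.5,
                        seed = 1L, contig_id = "lysogen_1") {
  stopifnot(host_length > 0)
  if (!is.null(prophage_inserts) && nrow(prophage_inserts) > 0L) {
    ins <- prophage_inserts
    if (!"label" %in% names(ins))
      ins$label <- paste0("prophage_", seq_len(nrow(ins)))
    if (any(ins$position < 0 | ins$position > host_length))
      stop("insert position outside host chromosome")
    if (any(ins$phage_length <= 0)) stop("phage_length must be positive")
    if (anyDuplicated(ins$position) || is.unsorted(ins$position, strictly = TRUE))
      stop("overlapping inserts: positions must be strictly increasing")
  } else {
    ins <- data.frame(position = numeric(), phage_length = numeric(),
                      label = character())
  }
  set.seed(seed)
  host <- random_dna(host_length, gc)
  phages <- vapply(ins$phage_length, random_dna, character(1), gc = gc)
  pieces <- character(0)
  truth <- data.frame(region_id = character(), contig = character(),
                      start = numeric(), end = numeric())
  cur <- 0      # host bp consumed
  offset <- 0   # cumulative inserted bp
  for (i in seq_len(nrow(ins))) {
    p <- ins$position[i]
    pieces <- c(pieces, substr(host, cur + 1, p), phages[i])
    start <- p + offset
    truth <- rbind(truth, data.frame(
      region_id = ins$label[i], contig = contig_id,
      start = start, end = start + ins$phage_length[i]))
    cur <- p
    offset <- offset + ins$phage_length[i]
  }
  pieces <- c(pieces, substr(host, cur + 1, host_length))
  list(genome = paste(pieces, collapse = ""), truth = truth,
       contig_id = contig_id)
}

#' Simulate a binned coverage track with induced prophage regions
#'
#' Per-bin read bases are drawn from a negative binomial with mean
#' `base_depth * bin_width`, multiplied by `induction_fold` inside the truth
#' regions, and divided by the bin width to give a mean per-base depth. The
#' negative binomial `size` parameter (`dispersion`) controls overdispersion;
#' `dispersion = Inf` gives the Poisson limiting case. Bins overlapping a
#' truth region by at least 1 bp take the induced mean and are masked with
#' that region's id.
#'
#' @param genome_length Contig length in bp.
#' @param truth Data frame of prophage regions (`start`, `end` 0-based
#'   half-open, optional `region_id`); `NULL` or zero rows for none.
#' @param base_depth Mean per-base host depth (> 0).
#' @param induction_fold Multiplier on the mean inside prophage regions
#'   (>= 0).
#' @param dispersion Negative-binomial size per bin (> 0; `Inf` = Poisson).
#' @param bin_size Bin width in bp.
#' @param seed Integer seed.
#' @param contig_id Contig name.
#' @return A masked `binned_coverage`.
#' @export
simulate_coverage <- function(genome_length, truth = NULL, base_depth = 20,
                              induction_fold = 1, dispersion = 20,
                              bin_size = 100L, seed = 1L,
                              contig_id = "lysogen_1") {
  stopifnot(base_depth > 0, induction_fold >= 0, dispersion > 0, bin_size > 0)
  set.seed(seed)
  n_bins <- ceiling(genome_length / bin_size)
  bs <- (seq_len(n_bins) - 1L) * bin_size
  bw <- pmin(bin_size, genome_length - bs)
  mask <- rep("host", n_bins)
  if (!is.null(truth) && nrow(truth) > 0L) {
    if (!"region_id" %in% names(truth))
      truth$region_id <- paste0("region_", seq_len(nrow(truth)))
    for (i in seq_len(nrow(truth))) {
      hit <- bs < truth$end[i] & (bs + bw) > truth$start[i]
      mask[hit & mask == "host"] <- truth$region_id[i]
    }
  }
  mu <- base_depth * bw * ifelse(mask == "host", 1, induction_fold)
  counts <- if (is.infinite(dispersion)) stats::rpois(n_bins, mu)
            else stats::rnbinom(n_bins, size = dispersion, mu = mu)
  binned_coverage(contig_id, counts / bw, bin_size = bin_size,
                  contig_length = genome_length, region_mask = mask)
}

#' Simulate per-replicate community detection reports
#'
#' Emulates the per-genome report of a synthetic-community sequencing
#' experiment: one aggregated host row per isolate and one row per prophage,
#' across `n_replicates` replicates. Prophages listed in `induced_truth` are
#' drawn with breadth, depth fold, k-mer coverage and duplicity comfortably
#' above the calling thresholds in `n_pass` of the replicates (chosen at
#' random under the seed), and below them otherwise; all other prophages are
#' drawn below every threshold in every replicate.
#'
#' @param n_genomes Number of host isolates (each carrying one prophage).
#' @param n_replicates Number of replicates (default 5).
#' @param induced_truth Integer indices (in `1:n_genomes`) of truly induced
#'   prophages.
#' @param seed Integer seed.
#' @param n_pass Number of replicates in which an induced prophage exceeds
#'   the thresholds (default all).
#' @param host_depth Mean host depth around which host rows are drawn.
#' @return Data frame with columns `replicate`, `genome_id`, `host_id`,
#'   `kind`, `length`, `reads`, `breadth`, `mean_depth`, `unique_kmers`,
#'   `kmer_coverage`, `duplicity`.
#' @export
simulate_community_report <- function(n_genomes, n_replicates = 5L,
                                      induced_truth = integer(),
                                      seed = 1L, n_pass = n_replicates,
                                      host_depth = 20) {
  stopifnot(n_genomes >= 1, all(induced_truth %in% seq_len(n_genomes)),
            n_pass <= n_replicates)
  set.seed(seed)
  pass_reps <- lapply(seq_len(n_genomes), function(i) {
    if (i %in% induced_truth) sort(sample.int(n_replicates, n_pass)) else integer()
  })
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (g in seq_len(n_genomes)) {
      host_id <- sprintf("isolate_%02d", g)
      h_depth <- host_depth * stats::runif(1, 0.8, 1.2)
      h_dup <- stats::runif(1, 1.5, 2.5)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_i, genome_id = sprintf("host_%02d", g),
        host_id = host_id, kind = "host", length = 3e6,
        reads = round(stats::runif(1, 5e4, 2e5)), breadth = stats::runif(1, 0.97, 1),
        mean_depth = h_depth, unique_kmers = round(stats::runif(1, 5e4, 1e5)),
        kmer_coverage = stats::runif(1, 0.9, 1), duplicity = h_dup)
      passing <- rep_i %in% pass_reps[[g]]
      if (passing) {
        ph <- data.frame(
          replicate = rep_i, genome_id = sprintf("phage_%02d", g),
          host_id = host_id, kind = "phage", length = 5e4,
          reads = round(stats::runif(1, 2e3, 1e4)),
          breadth = stats::runif(1, 0.92, 0.99),
          mean_depth = h_depth * stats::runif(1, 3, 5),
          unique_kmers = round(stats::runif(1, 2e3, 5e3)),
          kmer_coverage = stats::runif(1, 0.6, 0.9),
          duplicity = h_dup * stats::runif(1, 3, 5))
      } else {
        ph <- data.frame(
          replicate = rep_i, genome_id = sprintf("phage_%02d", g),
          host_id = host_id, kind = "phage", length = 5e4,
          reads = round(stats::runif(1, 0, 5)),
          breadth = stats::runif(1, 0.1, 0.4),
          mean_depth = h_depth * stats::runif(1, 0.1, 0.5),
          unique_kmers = round(stats::runif(1, 0, 50)),
          kmer_coverage = stats::runif(1, 0.01, 0.1),
          duplicity = h_dup * stats::runif(1, 0.3, 0.8))
      }
      rows[[length(rows) + 1L]] <- ph
    }
  }
  do.call(rbind, rows)
}

#' Generate an alignment fixture with planted HGT and indel events
#'
#' Constructs two homologous sequences whose pairwise local alignment breaks
#' into collinear blocks around planted events: an HGT event replaces a
#' segment of A with unrelated sequence of the same length in B (unaligned
#' span on both sequences), while an indel event deletes a segment of A from
#' B (unaligned span on A only). Events must be at least 50 bp from either
#' sequence end and non-overlapping.
#'
#' @param length Length of sequence A in bp.
#' @param planted_hgt,planted_indel Data frames with columns `pos` (0-based
#'   start on A) and `size` (bp, >= 50), or `NULL`.
#' @param seed Integer seed.
#' @param min_margin Minimum distance of any event from either end (bp).
#' @return List with `seq_a`, `seq_b` (character), `len_a`, `len_b`,
#'   `blocks` (data frame `qid`, `sid`, `pident`, `qstart`, `qend`,
#'   `sstart`, `send`; 1-based inclusive) and `truth` (data frame `type`,
#'   `qstart`, `qend`, `sstart`, `send`, `size_q`, `size_s`).
#' @export
gen_alignment_fixture <- function(length, planted_hgt = NULL,
                                  planted_indel = NULL, seed = 1L,
                                  min_margin = 50L) {
  ev <- rbind(
    if (!is.null(planted_hgt) && nrow(planted_hgt) > 0L)
      data.frame(pos = planted_hgt$pos, size = planted_hgt$size, type = "HGT"),
    if (!is.null(planted_indel) && nrow(planted_indel) > 0L)
      data.frame(pos = planted_indel$pos, size = planted_indel$size, type = "indel"))
  if (is.null(ev)) ev <- data.frame(pos = numeric(), size = numeric(),
                                    type = character())
  if (nrow(ev) > 0L) {
    ev <- ev[order(ev$pos), , drop = FALSE]
    if (any(ev$size < 50)) stop("planted events must be at least 50 bp")
    if (any(ev$pos < min_margin | ev$pos + ev$size > length - min_margin))
      stop("planted events must lie at least ", min_margin,
           " bp from either end")
    if (nrow(ev) > 1L && any(ev$pos[-1L] < (ev$pos + ev$size)[-nrow(ev)]))
      stop("planted events overlap")
  }
  set.seed(seed)
  seq_a <- random_dna(length)
  a_parts <- character(0)  # pieces of B
  blocks <- list()
  truth <- list()
  a_cur <- 0   # 0-based cursor on A
  b_cur <- 0   # 0-based cursor on B
  for (i in seq_len(nrow(ev))) {
    pos <- ev$pos[i]; size <- ev$size[i]
    seg_len <- pos - a_cur
    a_parts <- c(a_parts, substr(seq_a, a_cur + 1, pos))
    blocks[[length(blocks) + 1L]] <- data.frame(
      qstart = a_cur + 1, qend = pos, sstart = b_cur + 1, send = b_cur + seg_len)
    b_cur <- b_cur + seg_len
    if (ev$type[i] == "HGT") {
      a_parts <- c(a_parts, random_dna(size))
      truth[[length(truth) + 1L]] <- data.frame(
        type = "HGT", qstart = pos + 1, qend = pos + size,
        sstart = b_cur + 1, send = b_cur + size, size_q = size, size_s = size)
      b_cur <- b_cur + size
    } else {
      truth[[length(truth) + 1L]] <- data.frame(
        type = "indel", qstart = pos + 1, qend = pos + size,
        sstart = NA_real_, send = NA_real_, size_q = size, size_s = 0)
    }
    a_cur <- pos + size
  }
  a_parts <- c(a_parts, substr(seq_a, a_cur + 1, length))
  blocks[[length(blocks) + 1L]] <- data.frame(
    qstart = a_cur + 1, qend = length,
    sstart = b_cur + 1, send = b_cur + (length - a_cur))
  seq_b <- paste(a_parts, collapse = "")
  blocks <- do.call(rbind, blocks)
  blocks <- data.frame(qid = "phage_A", sid = "phage_B", pident = 100,
                       blocks)
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(type = character(), qstart = numeric(),
                           qend = numeric(), sstart = numeric(),
                           send = numeric(), size_q = numeric(),
                           size_s = numeric())
  list(seq_a = seq_a, seq_b = seq_b, len_a = length, len_b = nchar(seq_b),
       blocks = blocks, truth = truth)
}
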
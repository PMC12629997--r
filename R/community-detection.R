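canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  unique(pmin(kmers, rc))
}

#' Count genome-unique canonical k-mers
#'
#' A k-mer is unique to a genome when its canonical form (lexicographic
#' minimum of the k-mer and its reverse complement) occurs in that genome and
#' in no other genome of the database. Windows containing characters outside
#' A/C/G/T (for example N) are skipped; contigs shorter than k contribute
#' nothing.
#'
#' @param genomes Named list: each element a character vector of contig
#'   sequences (or a single sequence) for one genome.
#' @param k Odd k-mer size >= 3 (default 21, so that no k-mer equals its own
#'   reverse complement).
#' @return Named integer vector of unique-k-mer counts per genome.
#' @export
count_unique_kmers <- function(genomes, k = 21L) {
  stopifnot(k >= 3L, k %% 2L == 1L, length(genomes) > 0L,
            !is.null(names(genomes)))
  sets <- lapply(genomes, function(seqs) {
    unique(unlist(lapply(as.character(seqs), canonical_kmers, k = k),
                  use.names = FALSE))
  })
  all_kmers <- unlist(sets, use.names = FALSE)
  occ <- table(all_kmers)
  vapply(sets, function(s) {
    if (length(s) == 0L) 0L else sum(occ[s] == 1L)
  }, integer(1))
}

#' Per-replicate genome detection from a community report row
#'
#' Phage genomes are detected when k-mer coverage, read count and unique
#' k-mer count all reach their cut-offs (defaults 0.25, 10 and 100); host
#' genomes when read count and unique k-mer count do (defaults 10 and
#' 18,000).
#'
#' @param reads,unique_kmers,kmer_coverage Numeric vectors (recycled).
#' @param kind `"phage"` or `"host"` (vectorized).
#' @param phage_kmer_cov_min,phage_reads_min,phage_kmers_min Phage cut-offs.
#' @param host_reads_min,host_kmers_min Host cut-offs.
#' @return Logical vector of detection calls.
#' @export
detect_genome <- function(reads, unique_kmers, kmer_coverage = NA_real_,
                          kind = "phage",
                          phage_kmer_cov_min = 0.25, phage_reads_min = 10,
                          phage_kmers_min = 100,
                          host_reads_min = 10, host_kmers_min = 18000) {
  n <- max(length(reads), length(unique_kmers), length(kmer_coverage),
           length(kind))
  reads <- rep_len(reads, n)
  unique_kmers <- rep_len(unique_kmers, n)
  kmer_coverage <- rep_len(kmer_coverage, n)
  kind <- rep_len(kind, n)
  ifelse(kind == "host",
         reads >= host_reads_min & unique_kmers >= host_kmers_min,
         !is.na(kmer_coverage) & kmer_coverage >= phage_kmer_cov_min &
           reads >= phage_reads_min & unique_kmers >= phage_kmers_min)
}

host_weighted <- function(tab, col) {
  stats::weighted.mean(tab[[col]], tab$length)
}

#' Read-mapping induction calls for a synthetic community
#'
#' A phage genome passes a replicate when it is covered over at least
#' `breadth_min` of its length with a mean depth of at least `fold_min`
#' times its host's genome-wide mean depth (host contig depths averaged with
#' length weights). A species is called induced when at least one member
#' genome passes in at least `quorum` replicates — the same member across
#' replicates, not passes pooled over members. A phage whose host is absent
#' from a replicate's report has an undefined fold there and fails that
#' replicate.
#'
#' @param report Community report data frame (see
#'   [simulate_community_report()] for the column contract).
#' @param species_clusters Optional data frame with `genome_id`, `species`;
#'   defaults to one species per phage genome.
#' @param breadth_min Minimum breadth (default 0.85).
#' @param fold_min Minimum depth fold over host (default 2).
#' @param quorum Minimum passing replicates (default 3).
#' @return List with `genomes` (per-genome `n_pass`, `induced`) and
#'   `species` (per-species `induced`).
#' @export
call_readmap_induction <- function(report, species_clusters = NULL,
                                   breadth_min = 0.85, fold_min = 2,
                                   quorum = 3L) {
  phage <- report[report$kind == "phage", , drop = FALSE]
  if (is.null(species_clusters))
    species_clusters <- data.frame(genome_id = unique(phage$genome_id),
                                   species = unique(phage$genome_id))
  pass <- vapply(seq_len(nrow(phage)), function(i) {
    hosts <- report[report$kind == "host" &
                      report$host_id == phage$host_id[i] &
                      report$replicate == phage$replicate[i], , drop = FALSE]
    if (nrow(hosts) == 0L) return(FALSE)
    host_mean <- host_weighted(hosts, "mean_depth")
    isTRUE(phage$breadth[i] >= breadth_min &&
             phage$mean_depth[i] >= fold_min * host_mean)
  }, logical(1))
  n_pass <- tapply(pass, phage$genome_id, sum)
  genomes <- data.frame(genome_id = names(n_pass),
                        n_pass = as.integer(n_pass),
                        induced = as.integer(n_pass) >= quorum,
                        row.names = NULL)
  genomes <- merge(genomes, species_clusters, by = "genome_id", all.x = TRUE)
  sp <- tapply(genomes$induced, genomes$species, any)
  list(genomes = genomes,
       species = data.frame(species = names(sp), induced = as.logical(sp),
                            row.names = NULL))
}

#' Unique-k-mer induction calls for a synthetic community
#'
#' Per replicate: when a phage's host genome is detected (read and unique
#' k-mer cut-offs on the length-weighted aggregate of its contigs), the
#' replicate counts towards induction if the phage is detected and its k-mer
#' duplicity is at least `fold_min` times the host's length-normalized
#' duplicity; when the host is undetected, the replicate counts whenever the
#' phage is detected. A phage is induced with at least `quorum` counting
#' replicates.
#'
#' @inheritParams call_readmap_induction
#' @param ... Detection cut-offs passed to [detect_genome()].
#' @return Data frame with `genome_id`, `host_id`, `n_pass`, `induced`.
#' @export
call_kmer_induction <- function(report, fold_min = 2, quorum = 3L, ...) {
  phage <- report[report$kind == "phage", , drop = FALSE]
  pass <- vapply(seq_len(nrow(phage)), function(i) {
    hosts <- report[report$kind == "host" &
                      report$host_id == phage$host_id[i] &
                      report$replicate == phage$replicate[i], , drop = FALSE]
    phage_det <- detect_genome(phage$reads[i], phage$unique_kmers[i],
                               phage$kmer_coverage[i], kind = "phage", ...)
    if (!phage_det) return(FALSE)
    if (nrow(hosts) == 0L) return(TRUE)
    host_det <- detect_genome(sum(hosts$reads), sum(hosts$unique_kmers),
                              kind = "host", ...)
    if (!host_det) return(TRUE)
    host_dup <- host_weighted(hosts, "duplicity")
    isTRUE(phage$duplicity[i] >= fold_min * host_dup)
  }, logical(1))
  n_pass <- tapply(pass, phage$genome_id, sum)
  host_of <- phage$host_id[match(names(n_pass), phage$genome_id)]
  data.frame(genome_id = names(n_pass), host_id = host_of,
             n_pass = as.integer(n_pass),
             induced = as.integer(n_pass) >= quorum,
             row.names = NULL)
}
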
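# Independent reference implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: explicit per-element
# loops, a hand-rolled reverse complement, and exhaustive enumeration.

naive_zscore_ave <- function(host, phage) {
  med <- stats::median(host)
  devs <- numeric(length(host))
  for (i in seq_along(host)) devs[i] <- abs(host[i] - med)
  mad_h <- stats::median(devs)
  total <- 0
  for (x in phage) total <- total + 0.6745 * (x - med) / mad_h
  total / length(phage)
}

naive_cohens_d <- function(host, phage) {
  mh <- sum(host) / length(host)
  mp <- sum(phage) / length(phage)
  vh <- sum((host - mh)^2) / (length(host) - 1)
  vp <- sum((phage - mp)^2) / (length(phage) - 1)
  (mh - mp) / sqrt((vh + vp) / 2)
}

revcomp_chr <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Dictionary-scan unique-k-mer counter: one environment entry per canonical
# k-mer holding the set of genomes it occurs in.
brute_unique_kmers <- function(genomes, k) {
  dict <- new.env(parent = emptyenv())
  for (g in names(genomes)) {
    for (seq in as.character(genomes[[g]])) {
      seq <- toupper(seq)
      if (nchar(seq) < k) next
      for (i in 1:(nchar(seq) - k + 1)) {
        km <- substr(seq, i, i + k - 1)
        if (grepl("[^ACGT]", km)) next
        rc <- revcomp_chr(km)
        canon <- if (km < rc) km else rc
        cur <- if (exists(canon, envir = dict)) get(canon, envir = dict)
               else character(0)
        assign(canon, union(cur, g), envir = dict)
      }
    }
  }
  counts <- stats::setNames(integer(length(genomes)), names(genomes))
  for (km in ls(dict)) {
    owners <- get(km, envir = dict)
    if (length(owners) == 1L) counts[owners] <- counts[owners] + 1L
  }
  counts
}

# Exhaustive two-sided Fisher p: sum of hypergeometric probabilities not
# exceeding the observed table's probability (with fisher.test's relative
# tolerance).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-built one-isolate community report: the phage exceeds the calling
# thresholds (breadth, depth fold, duplicity fold) in the first n_pass
# replicates and sits below them elsewhere.
make_report <- function(breadth, fold, dup_fold, n_pass, n_replicates = 5,
                        detected = TRUE, host_rows = TRUE) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    host <- data.frame(replicate = r, genome_id = "host_01",
                       host_id = "iso1", kind = "host", length = 3e6,
                       reads = 1e5, breadth = 0.99, mean_depth = 20,
                       unique_kmers = 5e4, kmer_coverage = 0.95,
                       duplicity = 2)
    passing <- r <= n_pass
    ph <- data.frame(replicate = r, genome_id = "phage_01",
                     host_id = "iso1", kind = "phage", length = 5e4,
                     reads = if (detected) 1000 else 5,
                     breadth = if (passing) breadth else 0.3,
                     mean_depth = if (passing) 20 * fold else 5,
                     unique_kmers = if (detected) 2000 else 50,
                     kmer_coverage = if (detected) 0.8 else 0.05,
                     duplicity = if (passing) 2 * dup_fold else 1)
    if (host_rows) rbind(host, ph) else ph
  })
  do.call(rbind, rows)
}

# Shared simulation setup for recovery/null experiments: one planted region
# in the middle of a host contig.
sim_region_track <- function(fold, base_depth = 20, dispersion = 20,
                             seed = 1, n_bins_region = 30,
                             genome_length = 60000, region_start = 20000) {
  truth <- data.frame(region_id = "p1", start = region_start,
                      end = region_start + n_bins_region * 100)
  cov <- simulate_coverage(genome_length, truth, base_depth = base_depth,
                           induction_fold = fold, dispersion = dispersion,
                           seed = seed)
  list(cov = cov, truth = truth)
}
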
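#' Fractional abundance of genomes within viromes
#'
#' Raw fractional abundance of a genome in a virome is its length-normalized
#' read count scaled by the virome's sequencing effort:
#' `(reads / length) / (total_reads / scale)` with `scale` = 50,000 by
#' convention. Raw values are then normalized to sum to 1 within each virome
#' (genomes with zero reads contribute zero and are excluded from the
#' denominator).
#'
#' @param mapping Data frame with columns `virome_id`, `genome_id`, `reads`,
#'   `length` and `total_reads` (per-virome total read count, repeated on
#'   each row of that virome).
#' @param scale Read-scaling constant (default 50,000).
#' @return The input with `raw_abundance` and `norm_abundance` columns
#'   added. When every genome in a virome has zero reads its normalized
#'   abundances are `NA` (with a warning).
#' @export
fractional_abundance <- function(mapping, scale = 50000) {
  stopifnot(all(c("virome_id", "genome_id", "reads", "length",
                  "total_reads") %in% names(mapping)),
            all(mapping$length > 0), all(mapping$total_reads > 0))
  mapping$raw_abundance <-
    (mapping$reads / mapping$length) / (mapping$total_reads / scale)
  norm <- unlist(lapply(split(mapping$raw_abundance, mapping$virome_id),
                        function(raw) {
    tot <- sum(raw[raw > 0])
    if (tot == 0) {
      warning("virome with no mapped reads: normalized abundance undefined")
      return(rep(NA_real_, length(raw)))
    }
    raw / tot
  }), use.names = FALSE)
  idx <- order(order(mapping$virome_id))  # undo split's grouping order
  mapping$norm_abundance <- norm[idx]
  mapping
}

#' Prevalence of genomes across viromes
#'
#' A genome counts as present in a virome when its breadth of coverage
#' reaches `breadth_min` (default 0.70). Genomes absent from a virome's rows
#' have breadth 0 and are absent. Frequency is the fraction of all viromes
#' in which the genome is present.
#'
#' @param mappings Data frame with `virome_id`, `genome_id`, `breadth`.
#' @param breadth_min Presence threshold on breadth (default 0.70).
#' @param n_viromes Total number of viromes surveyed; defaults to the number
#'   of distinct `virome_id` values.
#' @return Data frame with `genome_id`, `n_present`, `n_viromes`,
#'   `frequency`.
#' @export
prevalence <- function(mappings, breadth_min = 0.70, n_viromes = NULL) {
  stopifnot(all(c("virome_id", "genome_id", "breadth") %in% names(mappings)))
  if (is.null(n_viromes)) n_viromes <- length(unique(mappings$virome_id))
  present <- mappings$breadth >= breadth_min
  n_present <- tapply(present, mappings$genome_id, sum)
  data.frame(genome_id = names(n_present),
             n_present = as.integer(n_present),
             n_viromes = n_viromes,
             frequency = as.integer(n_present) / n_viromes,
             row.names = NULL)
}
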
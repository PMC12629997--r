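#' Write sequences to FASTA
#'
#' @param seqs Named character vector or list of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a samtools-depth style table
#'
#' Three tab-separated columns: contig, 1-based position, depth. No header.
#' @param path TSV file.
#' @return Data frame with columns `contig`, `pos`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("contig", "pos", "depth"),
                    colClasses = c("character", "numeric", "numeric"))
}

#' Write a samtools-depth style table
#' @param depth_table Data frame with `contig`, `pos`, `depth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth_table, path) {
  utils::write.table(depth_table[, c("contig", "pos", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read prophage regions from a BED-like TSV
#'
#' Columns: contig, start, end (0-based half-open), then optionally
#' region_id, completeness (percent), source. Quality is derived from
#' completeness (> 50% is high).
#' @param path BED/TSV file (no header).
#' @return Region data frame.
#' @export
read_regions_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("contig", "start", "end")
  extra <- c("region_id", "completeness", "source")
  if (ncol(tab) > 3L)
    names(tab)[4:ncol(tab)] <- extra[seq_len(ncol(tab) - 3L)]
  if ("completeness" %in% names(tab)) {
    tab$completeness <- as.numeric(tab$completeness)
    tab$quality <- ifelse(tab$completeness > 50, "high", "low")
  }
  tab
}

#' Write prophage regions as BED
#' @param regions Data frame with `contig`, `start`, `end` and optionally
#'   `region_id`, `completeness`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  cols <- intersect(c("contig", "start", "end", "region_id", "completeness"),
                    names(regions))
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6 style) block table
#'
#' Expects at least the columns qid, sid, pident, qstart, qend, sstart,
#' send; a full 12-column outfmt-6 file is accepted, extra columns are kept
#' under their standard names.
#' @param path TSV file (no header).
#' @return Data frame of alignment blocks.
#' @export
read_blast_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  std <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (ncol(tab) == 7L) {
    names(tab) <- c("qid", "sid", "pident", "qstart", "qend", "sstart", "send")
  } else {
    names(tab)[seq_len(min(ncol(tab), 12L))] <- std[seq_len(min(ncol(tab), 12L))]
  }
  tab
}

#' Read a community detection report
#' @param path TSV with header (columns as produced by
#'   [simulate_community_report()]).
#' @return Data frame.
#' @export
read_community_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a community detection report
#' @param report Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_community_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
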
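# Plain-text readers/writers for the native formats: truth tables, transcript
# models, sequences (FASTA), alignment records (gzip-transparent TSV), peak
# BED, site tables, PFMs and count tables.

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

write_tsv <- function(df, path) {
  con <- open_out(path); on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a truth annotation table
#'
#' TSV with header `transcript_id, position, mod_type, stoichiometry`;
#' positions 0-based.
#'
#' @param truth truth data.frame.
#' @param path file path.
#' @return the path (write) or the truth data.frame (read).
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "numeric"), stringsAsFactors = FALSE)
}

#' Write / read transcript models (TSV)
#'
#' Columns: transcript_id, gene_id, length, utr5_end, cds_end.
#' @param transcripts transcript model data.frame.
#' @param path file path.
#' @export
write_transcript_models <- function(transcripts, path)
  write_tsv(transcripts, path)

#' @rdname write_transcript_models
#' @export
read_transcript_models <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer"),
                    stringsAsFactors = FALSE)
}

#' Write / read transcript sequences as FASTA
#'
#' @param sequences named character vector (DNA alphabet) or DNAStringSet.
#' @param path FASTA path.
#' @export
write_sequences_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' @rdname write_sequences_fasta
#' @export
read_sequences_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write / read alignment records (native TSV dialect)
#'
#' Columns: library_role, transcript_id, start, end (0-based half-open).
#' Gzip-transparent in both directions.
#'
#' @param alignments alignment data.frame.
#' @param path file path (".gz" suffix compresses).
#' @export
write_alignments <- function(alignments, path) write_tsv(alignments, path)

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer"), stringsAsFactors = FALSE)
}

#' Export / import peaks as BED6+
#'
#' BED columns: transcript, start, end, name, score = round(100 x
#' fto_depletion), strand "+", then summit, enrichment, fto_depletion,
#' cap_proximal. Read back losslessly.
#'
#' @param peaks an `m6am_peaks` data.frame.
#' @param path file path.
#' @export
export_peaks_bed <- function(peaks, path) {
  score <- ifelse(is.na(peaks$fto_depletion), 0,
                  round(100 * peaks$fto_depletion))
  bed <- data.frame(chrom = peaks$transcript_id, start = peaks$start,
                    end = peaks$end,
                    name = sprintf("peak_%04d", seq_len(nrow(peaks))),
                    score = score, strand = "+",
                    summit = peaks$summit,
                    enrichment = peaks$enrichment,
                    fto_depletion = peaks$fto_depletion,
                    cap_proximal = peaks$cap_proximal,
                    stringsAsFactors = FALSE)
  con <- open_out(path); on.exit(close(con))
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname export_peaks_bed
#' @export
import_peaks_bed <- function(path) {
  if (file.size(path) == 0)
    return(empty_peaks())
  bed <- utils::read.table(path, sep = "\t",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "summit",
                                         "enrichment", "fto_depletion",
                                         "cap_proximal"),
                           stringsAsFactors = FALSE)
  p <- data.frame(transcript_id = bed$chrom, start = bed$start, end = bed$end,
                  summit = bed$summit, enrichment = bed$enrichment,
                  fto_depletion = bed$fto_depletion,
                  cap_proximal = as.logical(bed$cap_proximal),
                  stringsAsFactors = FALSE)
  class(p) <- c("m6am_peaks", "data.frame")
  p
}

#' Write / read a site-call table
#'
#' TSV with columns transcript_id, gene_id, position, base, m1, m2, score,
#' context.
#' @param sites an `m6am_sites` data.frame.
#' @param path file path.
#' @export
write_sites <- function(sites, path) write_tsv(sites, path)

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "integer",
                                        "character", "numeric", "numeric",
                                        "numeric", "character"),
                         stringsAsFactors = FALSE)
  class(s) <- c("m6am_sites", "data.frame")
  s
}

#' Write a position frequency matrix with its consensus
#'
#' Four tab-separated rows (A, C, G, T) under a `# consensus:` header line.
#' @param motif an `m6am_motif` object.
#' @param path file path.
#' @export
write_pfm <- function(motif, path) {
  con <- open_out(path); on.exit(close(con))
  writeLines(paste0("# consensus: ", motif$consensus), con)
  writeLines(paste0("# n_sites: ", motif$n_sites), con)
  for (b in rownames(motif$pfm))
    writeLines(paste(c(b, format(motif$pfm[b, ], digits = 6)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write site contexts as FASTA (input for external motif tools)
#'
#' @param sites an `m6am_sites` data.frame.
#' @param path FASTA path.
#' @export
write_contexts_fasta <- function(sites, path) {
  con <- open_out(path); on.exit(close(con))
  if (nrow(sites) > 0)
    writeLines(paste0(">", sites$transcript_id, "_", sites$position, "\n",
                      sites$context), con)
  invisible(path)
}

#' Read / write a gene-level count table (TSV: gene_id, count)
#'
#' @param path file path.
#' @export
read_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_counts
#' @param counts data.frame with gene_id and count.
#' @export
write_counts <- function(counts, path) write_tsv(counts, path)
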
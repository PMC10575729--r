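#' Per-transcript, per-library depth and read-start tracks
#'
#' Converts alignment records (0-based half-open intervals in transcript
#' coordinates) into integer coverage (`depth`) and 5'-end count
#' (`start_count`) vectors for every transcript and library. Transcripts with
#' no records get all-zero vectors. Depth is computed by difference arrays
#' (O(records + length)) and satisfies depth[p] == #\{records with
#' start <= p < end\}.
#'
#' @param alignments data.frame with columns `library_role`, `transcript_id`,
#'   `start`, `end`.
#' @param transcripts transcript model data.frame (`transcript_id`, `length`).
#' @return an object of class `m6am_tracks`: list with `transcript_id`,
#'   `length` (named), `roles`, `depth` and `start_count`
#'   (role -> transcript -> integer vector) and `library_sizes` (records per
#'   role across all transcripts).
#' @export
compute_tracks <- function(alignments, transcripts) {
  stopifnot(all(c("library_role", "transcript_id", "start", "end") %in%
                  names(alignments)))
  tid <- transcripts$transcript_id
  L <- as.integer(transcripts$length)
  names(L) <- tid

  if (nrow(alignments) > 0) {
    m <- match(alignments$transcript_id, tid)
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop("coordinate error: record ", bad, " (",
           alignments$transcript_id[bad], ") not in transcript set")
    }
    bad <- which(alignments$start < 0 | alignments$end > L[m] |
                   alignments$start >= alignments$end)
    if (length(bad) > 0) {
      b <- bad[1]
      stop("coordinate error: record ", b, " (", alignments$transcript_id[b],
           ", [", alignments$start[b], ",", alignments$end[b],
           ")) outside transcript bounds [0,", L[m[b]], ")")
    }
  }

  roles <- intersect(LIBRARY_ROLES, unique(as.character(alignments$library_role)))
  depth <- list(); start_count <- list()
  lib_sizes <- integer(length(roles)); names(lib_sizes) <- roles
  for (role in roles) {
    sub <- alignments[alignments$library_role == role, , drop = FALSE]
    lib_sizes[role] <- nrow(sub)
    idx <- split(seq_len(nrow(sub)), factor(sub$transcript_id, levels = tid))
    d <- vector("list", length(tid)); names(d) <- tid
    s <- d
    for (t in tid) {
      Lt <- L[[t]]
      rows <- idx[[t]]
      if (length(rows) == 0) {
        d[[t]] <- integer(Lt); s[[t]] <- integer(Lt)
      } else {
        st <- sub$start[rows]; en <- sub$end[rows]
        cov <- cumsum(tabulate(st + 1L, Lt) - tabulate(en + 1L, Lt))
        d[[t]] <- as.integer(cov)
        s[[t]] <- tabulate(st + 1L, Lt)
      }
    }
    depth[[role]] <- d
    start_count[[role]] <- s
  }
  structure(list(transcript_id = tid, length = L, roles = roles,
                 depth = depth, start_count = start_count,
                 library_sizes = lib_sizes),
            class = "m6am_tracks")
}

#' @export
print.m6am_tracks <- function(x, ...) {
  cat("m6am_tracks:", length(x$transcript_id), "transcripts,",
      length(x$roles), "libraries\n")
  for (r in x$roles)
    cat("  ", r, ": ", x$library_sizes[[r]], " records\n", sep = "")
  invisible(x)
}

require_roles <- function(tracks, roles) {
  miss <- setdiff(roles, tracks$roles)
  if (length(miss) > 0)
    stop("input error: tracks are missing required librar",
         if (length(miss) > 1) "ies: " else "y: ",
         paste(miss, collapse = ", "))
}

#' Normalize depth tracks
#'
#' @param tracks an `m6am_tracks` object.
#' @param library_role library to normalize.
#' @param mode `"cpm"` (depth x 1e6 / library size) or `"none"` (numeric cast).
#' @return named list of numeric vectors, one per transcript.
#' @export
normalize_depth <- function(tracks, library_role, mode = c("cpm", "none")) {
  mode <- match.arg(mode)
  require_roles(tracks, library_role)
  d <- tracks$depth[[library_role]]
  if (mode == "none") return(lapply(d, as.numeric))
  size <- tracks$library_sizes[[library_role]]
  if (size == 0)
    stop("normalization error: library ", library_role,
         " has zero records; cpm undefined")
  lapply(d, function(v) v * 1e6 / size)
}

#' Export a track as bedGraph
#'
#' Writes a 4-column bedGraph (transcript as chrom; 0-based half-open
#' intervals) with adjacent equal-value runs merged. Zero-valued runs are
#' omitted unless `keep_zero = TRUE`.
#'
#' @param tracks an `m6am_tracks` object.
#' @param library_role library to export.
#' @param path output file (".gz" suffix compresses).
#' @param what `"depth"` or `"start_count"`.
#' @param keep_zero keep zero-valued runs.
#' @export
export_bedgraph <- function(tracks, library_role, path,
                            what = c("depth", "start_count"),
                            keep_zero = FALSE) {
  what <- match.arg(what)
  require_roles(tracks, library_role)
  vecs <- tracks[[what]][[library_role]]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (t in tracks$transcript_id) {
    v <- vecs[[t]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    if (!any(keep)) next
    writeLines(paste(t, starts[keep], ends[keep], r$values[keep],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Import a bedGraph written by [export_bedgraph()]
#'
#' @param path bedGraph file.
#' @param transcripts transcript models giving vector lengths.
#' @return named list of numeric vectors (zero-filled outside recorded runs).
#' @export
import_bedgraph <- function(path, transcripts) {
  tid <- transcripts$transcript_id
  out <- lapply(stats::setNames(transcripts$length, tid), numeric)
  if (file.size(path) > 0 || grepl("\\.gz$", path)) {
    bg <- utils::read.table(path, sep = "\t", col.names =
                              c("chrom", "start", "end", "value"),
                            colClasses = c("character", "integer", "integer",
                                           "numeric"))
    for (i in seq_len(nrow(bg))) {
      t <- bg$chrom[i]
      if (!t %in% tid) stop("import error: unknown transcript ", t)
      out[[t]][(bg$start[i] + 1L):bg$end[i]] <- bg$value[i]
    }
  }
  out
}

#' Read alignments from a BAM file (optional ingestion path)
#'
#' Maps reference names to transcript ids and alignment start/end to 0-based
#' half-open transcript intervals; unmapped, secondary and supplementary
#' records are skipped. Requires the Rsamtools package.
#'
#' @param path BAM file.
#' @param library_role role label to assign to all records.
#' @return alignment data.frame in the native dialect.
#' @export
read_alignments_bam <- function(path, library_role) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("input error: BAM ingestion requires the Rsamtools package")
  library_role <- match.arg(library_role, LIBRARY_ROLES)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("rname", "pos", "qwidth", "cigar"))
  b <- Rsamtools::scanBam(path, param = par)[[1]]
  keep <- !is.na(b$pos)
  width <- GenomicAlignments_width(b$cigar[keep])
  data.frame(library_role = library_role,
             transcript_id = as.character(b$rname)[keep],
             start = b$pos[keep] - 1L,
             end = b$pos[keep] - 1L + width,
             stringsAsFactors = FALSE)
}

# Reference-consumed width from CIGAR (M/D/N/=/X), without a GenomicAlignments
# dependency.
GenomicAlignments_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
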
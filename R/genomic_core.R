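#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames sortSeqlevels
#' @importFrom stats median quantile sd mad rnorm rpois rnbinom runif setNames
#'   p.adjust pt wilcox.test t.test qnorm rlnorm rbinom var plogis
#' @importFrom utils read.table write.table head
NULL

# ---------------------------------------------------------------------------
# Domain types.
#
# A PeakSet is an S3 wrapper around a GRanges: coordinates are held 1-based
# closed internally (the Bioconductor convention) and converted from/to
# BED-style 0-based half-open at the I/O boundary, so a BED row
# "chr1 100 200" becomes GRanges chr1:101-200 and round-trips bit-exactly.
# ---------------------------------------------------------------------------

#' Construct a genomic interval
#'
#' Intervals follow the BED convention: 0-based start, exclusive end.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start (bp).
#' @param end Exclusive end (bp); must satisfy `end > start`.
#' @return A `genomic_interval` object (a named list).
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("invalid interval: need start >= 0 and end > start, got [",
         start, ", ", end, ")", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)\n", x$chrom, x$start, x$end))
  invisible(x)
}

#' Test whether two intervals overlap by at least `min_bp` bases
#'
#' Overlap length is `min(a$end, b$end) - max(a$start, b$start)` on the
#' half-open convention; adjacent intervals do not overlap.
#'
#' @param a,b `genomic_interval` objects (or lists with chrom/start/end).
#' @param min_bp Minimum overlap in bp (positive integer, default 1).
#' @return `TRUE` or `FALSE`.
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  if (a$chrom != b$chrom) return(FALSE)
  (min(a$end, b$end) - max(a$start, b$start)) >= min_bp
}

#' Build a PeakSet from vectors of coordinates
#'
#' @param factor Factor (antibody/protein) name, e.g. "BRG1".
#' @param chrom,start,end Coordinate vectors (BED convention, 0-based
#'   half-open).
#' @param name Peak identifiers; auto-generated as `<factor>_peak_<i>` when
#'   `NULL`.
#' @param signal Non-negative occupancy scores; default 0.
#' @param summit_offset Optional summit offsets from peak start (bp); `NA`
#'   where absent.
#' @return A `PeakSet` object.
#' @export
peak_set <- function(factor, chrom, start, end, name = NULL, signal = 0,
                     summit_offset = NA_integer_) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  if (any(start < 0) || any(end <= start))
    stop("invalid peak coordinates (need start >= 0, end > start)",
         call. = FALSE)
  signal <- rep_len(as.numeric(signal), n)
  if (any(signal < 0)) stop("peak signal must be nonnegative", call. = FALSE)
  summit_offset <- rep_len(as.integer(summit_offset), n)
  bad <- !is.na(summit_offset) &
    (summit_offset < 0 | summit_offset >= (end - start))
  if (any(bad)) stop("summit_offset out of [0, width)", call. = FALSE)
  if (is.null(name)) name <- sprintf("%s_peak_%d", factor, seq_len(n))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               name = as.character(name),
                               signal = signal,
                               summit_offset = summit_offset)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  # collapse duplicate identical intervals (keep first after sorting)
  dup <- duplicated(paste(as.character(seqnames(gr)),
                          GenomicRanges::start(gr), GenomicRanges::end(gr)))
  if (any(dup)) {
    warning(sum(dup), " duplicate interval(s) collapsed in ", factor,
            " peak set", call. = FALSE)
    gr <- gr[!dup]
  }
  if (anyDuplicated(mcols(gr)$name))
    stop("peak names must be unique within a set", call. = FALSE)
  structure(list(factor = factor, gr = gr), class = "PeakSet")
}

#' @export
length.PeakSet <- function(x) length(x$gr)

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peaks on %d sequence(s)\n", x$factor,
              length(x$gr),
              length(unique(as.character(seqnames(x$gr))))))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.PeakSet <- function(x, ...) {
  gr <- x$gr
  data.frame(chrom = as.character(seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = mcols(gr)$name,
             signal = mcols(gr)$signal,
             summit_offset = mcols(gr)$summit_offset,
             stringsAsFactors = FALSE)
}

#' Peak midpoints
#'
#' Midpoint of `[start, end)` computed as `floor((start + end) / 2)` in
#' 0-based coordinates.
#'
#' @param x A `PeakSet`.
#' @return Integer vector of 0-based midpoint positions, named by peak.
#' @export
peak_midpoints <- function(x) {
  df <- as.data.frame(x)
  setNames(floor((df$start + df$end) / 2), df$name)
}

# ---------------------------------------------------------------------------
# I/O
# ---------------------------------------------------------------------------

.parse_int <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) | (x != as.character(v))
  if (any(bad))
    stop(sprintf("%s: line %d: non-integer %s '%s'", path,
                 lineno[which(bad)[1]], what, x[which(bad)[1]]),
         call. = FALSE)
  v
}

#' Read peaks from a BED or narrowPeak file
#'
#' BED needs at least 3 tab-separated fields; signal is taken from column 5
#' when present (0 otherwise). narrowPeak is the 10-column ENCODE format:
#' signal from column 7, summit offset from column 10 (sentinel -1 means
#' no summit). Malformed lines raise an error naming the line number.
#'
#' @param path File path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param factor Factor name for the resulting set; defaults to the file
#'   base name.
#' @return A sorted `PeakSet`.
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"), factor = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(factor))
    factor <- sub("\\.(bed|narrowPeak)$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(peak_set(factor, character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_f <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < min_f))
    stop(sprintf("%s: line %d: expected >= %d tab-separated fields, got %d",
                 path, lineno[which(nf < min_f)[1]], min_f,
                 nf[which(nf < min_f)[1]]), call. = FALSE)
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- col(1)
  start <- .parse_int(col(2), path, lineno, "start")
  end <- .parse_int(col(3), path, lineno, "end")
  bad <- start < 0 | end <= start
  if (any(bad))
    stop(sprintf("%s: line %d: invalid interval [%d, %d)", path,
                 lineno[which(bad)[1]], start[which(bad)[1]],
                 end[which(bad)[1]]), call. = FALSE)
  name <- if (all(nf >= 4L)) col(4) else NULL
  if (!is.null(name) && (anyDuplicated(name) || any(name == ".")))
    name <- NULL
  if (format == "narrowPeak") {
    signal <- as.numeric(col(7))
    summit <- .parse_int(col(10), path, lineno, "summit")
    summit[summit < 0] <- NA_integer_
  } else {
    signal <- if (all(nf >= 5L)) suppressWarnings(as.numeric(col(5))) else 0
    signal[is.na(signal)] <- 0
    summit <- NA_integer_
  }
  peak_set(factor, chrom, start, end, name = name, signal = signal,
           summit_offset = summit)
}

#' Write a PeakSet to BED or narrowPeak
#'
#' @param x A `PeakSet`.
#' @param path Output path.
#' @param format `"bed"` (6 columns) or `"narrowPeak"` (10 columns;
#'   missing summits written as -1).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "bed") {
    out <- data.frame(df$chrom, df$start, df$end, df$name, df$signal, ".")
  } else {
    summit <- ifelse(is.na(df$summit_offset), -1L, df$summit_offset)
    out <- data.frame(df$chrom, df$start, df$end, df$name, 0L, ".",
                      df$signal, -1, -1, summit)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a chromHMM-style state segmentation
#'
#' @param path 4-column BED (chrom, start, end, state label).
#' @param genome_sizes Named numeric vector of chromosome lengths (bp), or a
#'   path to a 2-column chrom.sizes file.
#' @return A `StateSegmentation` object: `$gr` (GRanges with `state`),
#'   `$genome_sizes`.
#' @export
read_state_segmentation <- function(path, genome_sizes) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "state"),
                   colClasses = c("character", "integer", "integer",
                                  "character"))
  if (is.character(genome_sizes) && length(genome_sizes) == 1L &&
      file.exists(genome_sizes)) {
    gs <- read.table(genome_sizes, sep = "\t", header = FALSE)
    genome_sizes <- setNames(as.numeric(gs[[2]]), gs[[1]])
  }
  state_segmentation(df$chrom, df$start, df$end, df$state, genome_sizes)
}

#' Construct a state segmentation from vectors
#'
#' @param chrom,start,end Segment coordinates (BED convention).
#' @param state State labels.
#' @param genome_sizes Named numeric vector of chromosome lengths (bp).
#' @return A `StateSegmentation` object.
#' @export
state_segmentation <- function(chrom, start, end, state, genome_sizes) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                               state = as.character(state))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (any(GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L))
    stop("segments must be non-overlapping within a chromosome",
         call. = FALSE)
  for (ch in unique(as.character(seqnames(gr)))) {
    if (!ch %in% names(genome_sizes))
      stop("no genome size for chromosome ", ch, call. = FALSE)
    if (max(GenomicRanges::end(gr[seqnames(gr) == ch])) > genome_sizes[[ch]])
      stop("segment beyond chromosome end on ", ch, call. = FALSE)
  }
  structure(list(gr = gr, genome_sizes = genome_sizes),
            class = "StateSegmentation")
}

#' @export
print.StateSegmentation <- function(x, ...) {
  cat(sprintf("StateSegmentation: %d segments, %d states, %d chromosome(s)\n",
              length(x$gr), length(unique(mcols(x$gr)$state)),
              length(x$genome_sizes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Interval algebra
# ---------------------------------------------------------------------------

#' Map each peak in A to its overlapping peaks in B
#'
#' Equivalent to the exhaustive all-pairs comparison with
#' [interval_overlaps()]; implemented with an interval index.
#'
#' @param A,B `PeakSet` objects.
#' @param min_bp Minimum overlap (bp).
#' @return Named list: for each peak name in `A`, the character vector of
#'   overlapping peak names in `B` (possibly empty).
#' @export
intersect_sets <- function(A, B, min_bp = 1L) {
  stopifnot(inherits(A, "PeakSet"), inherits(B, "PeakSet"), min_bp >= 1)
  hits <- GenomicRanges::findOverlaps(A$gr, B$gr, minoverlap = min_bp,
                                      ignore.strand = TRUE)
  res <- rep(list(character(0)), length(A$gr))
  names(res) <- mcols(A$gr)$name
  if (length(hits)) {
    sp <- split(mcols(B$gr)$name[subjectHits(hits)],
                factor(queryHits(hits), levels = seq_along(A$gr)))
    res <- lapply(sp, as.character)
    names(res) <- mcols(A$gr)$name
  }
  res
}

#' Which peaks in A overlap any peak in B
#'
#' @inheritParams intersect_sets
#' @return Logical vector, one entry per peak of `A` (in sorted order),
#'   named by peak.
#' @export
overlaps_any <- function(A, B, min_bp = 1L) {
  hit <- GenomicRanges::countOverlaps(A$gr, B$gr, minoverlap = min_bp,
                                      ignore.strand = TRUE) > 0L
  setNames(hit, mcols(A$gr)$name)
}

#' Merge peaks closer than or equal to a gap
#'
#' Intervals whose gap is `<= max_gap` bp are merged; the merged signal is
#' the max over constituents; merged names join constituents with ";".
#'
#' @param A A `PeakSet`.
#' @param max_gap Non-negative gap (bp); 0 merges only touching/overlapping
#'   intervals (half-open: `[100,200)` and `[200,300)` touch).
#' @return A sorted, non-overlapping `PeakSet`.
#' @export
merge_peaks <- function(A, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  if (length(A$gr) == 0L) return(A)
  red <- GenomicRanges::reduce(A$gr, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  rm <- mcols(red)$revmap
  sig <- vapply(rm, function(i) max(mcols(A$gr)$signal[i]), numeric(1))
  nm <- vapply(rm, function(i) paste(mcols(A$gr)$name[i], collapse = ";"), "")
  peak_set(A$factor,
           as.character(seqnames(red)),
           GenomicRanges::start(red) - 1L,
           GenomicRanges::end(red),
           name = nm, signal = sig)
}

#' Subtract blacklist intervals from a peak set
#'
#' Drops any peak overlapping a blacklist interval by >= `min_bp`; an
#' optional pre-step mirroring ENCODE blacklist filtering (no blacklist is
#' bundled).
#'
#' @param A A `PeakSet`.
#' @param blacklist A `PeakSet` (or anything with a `$gr` GRanges).
#' @param min_bp Minimum overlap triggering removal.
#' @return Filtered `PeakSet`.
#' @export
subtract_blacklist <- function(A, blacklist, min_bp = 1L) {
  hit <- GenomicRanges::countOverlaps(A$gr, blacklist$gr,
                                      minoverlap = min_bp,
                                      ignore.strand = TRUE) > 0L
  out <- A
  out$gr <- A$gr[!hit]
  out
}
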
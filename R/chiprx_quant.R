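# Spike-in (ChIP-Rx) and in-peak normalization, quartile stratification
# and differential-occupancy analysis.
#
# RRPM scales per-peak counts per million exogenous (Drosophila) mapped
# reads, so occupancy is comparable across conditions with different IP
# efficiency; RPMPR scales per million reads falling in the union peak
# set, a within-library shape normalization.

#' Construct a spike-in count record for one library
#'
#' @param library_id Library identifier.
#' @param condition Condition label (e.g. sgScr, sgBRG1, ACBI1).
#' @param counts Named numeric vector of per-peak raw read counts.
#' @param human_mapped_total Total human-genome-mapped reads.
#' @param spike_mapped_total Total spike-genome-mapped reads (must be > 0
#'   for RRPM).
#' @return A `SpikeInCounts` object.
#' @export
spikein_counts <- function(library_id, condition, counts,
                           human_mapped_total, spike_mapped_total) {
  counts <- counts[order(names(counts))]
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) > human_mapped_total)
    stop("in-peak counts exceed human_mapped_total", call. = FALSE)
  structure(list(library_id = library_id, condition = condition,
                 counts = counts,
                 human_mapped_total = human_mapped_total,
                 spike_mapped_total = spike_mapped_total),
            class = "SpikeInCounts")
}

#' @export
print.SpikeInCounts <- function(x, ...) {
  cat(sprintf(
    "SpikeInCounts '%s' (%s): %d peaks, %g human / %g spike mapped reads\n",
    x$library_id, x$condition, length(x$counts), x$human_mapped_total,
    x$spike_mapped_total))
  invisible(x)
}

#' Read spike-in counts from TSV
#'
#' Format: header lines `#human_mapped_total=<int>` and
#' `#spike_mapped_total=<int>`, then `peak_name<TAB>count` rows.
#'
#' @param path File path.
#' @param library_id,condition Metadata; default to the file base name.
#' @return A `SpikeInCounts`.
#' @export
read_spikein_counts <- function(path, library_id = NULL, condition = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) != 1L) stop("missing header #", key, "= in ", path,
                              call. = FALSE)
    as.numeric(sub(paste0("^#", key, "="), "", m))
  }
  human <- get_hdr("human_mapped_total")
  spike <- get_hdr("spike_mapped_total")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  counts <- setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                     vapply(parts, `[`, "", 1L))
  if (is.null(library_id)) library_id <- sub("\\.tsv$", "", basename(path))
  if (is.null(condition)) condition <- library_id
  spikein_counts(library_id, condition, counts, human, spike)
}

#' Write spike-in counts to TSV
#' @param x A `SpikeInCounts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikein_counts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#human_mapped_total=%d",
                       as.integer(x$human_mapped_total)),
               sprintf("#spike_mapped_total=%d",
                       as.integer(x$spike_mapped_total))), con)
  write.table(data.frame(names(x$counts), x$counts), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Spike-in (RRPM) normalization
#'
#' `signal(p) = raw(p) * 1e6 / spike_mapped_total` — reference exogenous
#' reads per million mapped reads. Exactly linear in the raw counts and
#' inverse-linear in the spike total.
#'
#' @param x A `SpikeInCounts`.
#' @return Named numeric vector of RRPM signals with attribute
#'   `units = "RRPM"`.
#' @export
rrpm_normalize <- function(x) {
  if (is.na(x$spike_mapped_total) || x$spike_mapped_total <= 0)
    stop("spike_mapped_total must be > 0 for RRPM normalization",
         call. = FALSE)
  structure(x$counts * 1e6 / x$spike_mapped_total, units = "RRPM")
}

#' In-peak (RPMPR) normalization
#'
#' `signal(p) = raw(p) * 1e6 / sum(raw over the union peak set)` — reads
#' per million peak reads. Signals sum to 1e6 per library.
#'
#' @param x A `SpikeInCounts`.
#' @param union_peaks Optional `PeakSet` or character vector restricting /
#'   defining the union peak set; defaults to all peaks in `x`.
#' @return Named numeric vector of RPMPR signals with attribute
#'   `units = "RPMPR"`.
#' @export
rpmpr_normalize <- function(x, union_peaks = NULL) {
  counts <- x$counts
  if (!is.null(union_peaks)) {
    nm <- if (inherits(union_peaks, "PeakSet"))
      as.data.frame(union_peaks)$name else as.character(union_peaks)
    missing <- setdiff(nm, names(counts))
    if (length(missing))
      stop("no counts for union peak(s): ",
           paste(head(missing, 3), collapse = ", "), call. = FALSE)
    counts <- counts[nm]
  }
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero counts: RPMPR undefined", call. = FALSE)
  structure(counts * 1e6 / tot, units = "RPMPR")
}

#' Stratify a partner signal by quartiles of an anchor signal
#'
#' Anchor peaks are ranked by signal and split into four equal-size bins
#' (remainders go to the lower quartiles; ties broken by peak-name order);
#' the partner's signal on the same peaks (0 where absent) is summarized
#' per bin. Used to show, e.g., that BRG1 occupancy rises across MYCN peak
#' quartiles.
#'
#' @param anchor Named numeric vector of anchor signals (>= 8 peaks).
#' @param partner Named numeric vector of partner signals on (a subset of)
#'   the same peaks; peaks missing from `partner` count as 0.
#' @return A list with `$summary` (quartile, n, median, q25, q75,
#'   anchor_min, anchor_max) and `$values` (per-quartile partner vectors,
#'   Q1 = lowest anchor signal).
#' @export
quartile_stratify <- function(anchor, partner) {
  n <- length(anchor)
  stopifnot(n >= 8L)
  o <- order(anchor, names(anchor))
  anchor <- anchor[o]
  part <- partner[names(anchor)]
  part[is.na(part)] <- 0
  names(part) <- names(anchor)
  base <- n %/% 4L; rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= rem)  # remainder to lower bins
  bin <- rep(1:4, times = sizes)
  vals <- split(part, bin)
  names(vals) <- paste0("Q", 1:4)
  avals <- split(anchor, bin)
  summary <- do.call(rbind, lapply(1:4, function(q) {
    v <- vals[[q]]
    data.frame(quartile = paste0("Q", q), n = length(v),
               median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)),
               anchor_min = min(avals[[q]]), anchor_max = max(avals[[q]]))
  }))
  list(summary = summary, values = vals)
}

.paired_rrpm <- function(sites, control, treated, pseudocount) {
  stopifnot(pseudocount > 0)
  nm <- if (inherits(sites, "PeakSet")) as.data.frame(sites)$name
        else as.character(sites)
  for (lib in list(control, treated)) {
    missing <- setdiff(nm, names(lib$counts))
    if (length(missing))
      stop("site(s) missing from library ", lib$library_id, ": ",
           paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  ctl <- rrpm_normalize(control)[nm]
  trt <- rrpm_normalize(treated)[nm]
  # written as a difference of logs so a condition swap negates every
  # delta exactly, to the last bit
  delta <- log2(trt + pseudocount) - log2(ctl + pseudocount)
  data.frame(site = nm, rrpm_control = unname(ctl),
             rrpm_treated = unname(trt), delta = unname(delta),
             stringsAsFactors = FALSE)
}

#' Differential occupancy at co-occupied sites ("enhancer invasion")
#'
#' Per-site `delta = log2((RRPM_treated + pc) / (RRPM_control + pc))` at a
#' fixed set of sites (typically the BRG1-MYCN co-occupied set), with a
#' paired Wilcoxon signed-rank test across sites. A positive median delta
#' after loss of a competing factor is the invasion signature.
#'
#' @param sites `PeakSet` or character vector of site names; both
#'   libraries must carry counts for every site.
#' @param control,treated `SpikeInCounts` for the two conditions.
#' @param pseudocount Pseudocount on the RRPM scale (default 0.5).
#' @return An `InvasionResult`: `$per_site` data.frame (site, control and
#'   treated RRPM, delta), `$n_sites`, `$median_delta`,
#'   `$fraction_increased` (strict delta > 0), `$p_value`.
#' @export
invasion_analysis <- function(sites, control, treated, pseudocount = 0.5) {
  per <- .paired_rrpm(sites, control, treated, pseudocount)
  d <- per$delta
  p <- if (all(d == 0)) 1
       else suppressWarnings(
         wilcox.test(per$rrpm_treated + pseudocount,
                     per$rrpm_control + pseudocount,
                     paired = TRUE)$p.value)
  structure(list(per_site = per, n_sites = nrow(per),
                 median_delta = median(d),
                 fraction_increased = mean(d > 0),
                 p_value = p,
                 control = control$library_id,
                 treated = treated$library_id,
                 pseudocount = pseudocount),
            class = "InvasionResult")
}

#' @export
print.InvasionResult <- function(x, ...) {
  cat(sprintf(paste0(
    "InvasionResult: %d sites (%s vs %s)\n",
    "  median delta = %.3f log2, %.1f%% of sites increased, p = %.3g\n"),
    x$n_sites, x$treated, x$control, x$median_delta,
    100 * x$fraction_increased, x$p_value))
  invisible(x)
}

#' Per-peak spike-in-normalized delta table
#'
#' The same per-site log2 RRPM ratio as [invasion_analysis()], as a plain
#' table for arbitrary factors (e.g. BRG1-loss validation, H3K27ac gain).
#'
#' @inheritParams invasion_analysis
#' @param peaks `PeakSet` or character vector of peak names.
#' @param path Optional TSV path to write the table to.
#' @return Data.frame (site, rrpm_control, rrpm_treated, delta).
#' @export
signal_delta_track <- function(control, treated, peaks, pseudocount = 0.5,
                               path = NULL) {
  per <- .paired_rrpm(peaks, control, treated, pseudocount)
  if (!is.null(path))
    write.table(per, path, sep = "\t", quote = FALSE, row.names = FALSE)
  per
}
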
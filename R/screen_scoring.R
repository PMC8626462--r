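# Pooled CRISPR domain-screen scoring: depth normalization, per-guide
# log2 fold depletion between early and late timepoints, per-domain
# aggregation, and ranking by lineage-specific (RMS vs non-RMS) depletion.

#' Construct a screen count object
#'
#' @param counts Integer matrix, sgRNA x sample.
#' @param guide_info Data frame with rownames = sgRNA ids and columns
#'   `target` (domain name) and `is_control` (logical).
#' @param sample_info Data frame with rownames = sample ids and columns
#'   `cell_line`, `rms` (logical) and `timepoint` ("early"/"late").
#' @return A `ScreenCounts` object.
#' @export
screen_counts <- function(counts, guide_info, sample_info) {
  counts <- as.matrix(counts)
  stopifnot(all(rownames(counts) %in% rownames(guide_info)),
            all(colnames(counts) %in% rownames(sample_info)))
  guide_info <- guide_info[rownames(counts), , drop = FALSE]
  sample_info <- sample_info[colnames(counts), , drop = FALSE]
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(colSums(counts) <= 0))
    stop("every sample column must have positive total", call. = FALSE)
  stopifnot(all(sample_info$timepoint %in% c("early", "late")))
  for (cl in unique(sample_info$cell_line)) {
    tp <- sample_info$timepoint[sample_info$cell_line == cl]
    if (!all(c("early", "late") %in% tp))
      stop("cell line ", cl, " needs >= 1 early and >= 1 late sample",
           call. = FALSE)
  }
  structure(list(counts = counts, guide_info = guide_info,
                 sample_info = sample_info), class = "ScreenCounts")
}

#' @export
print.ScreenCounts <- function(x, ...) {
  cat(sprintf(
    "ScreenCounts: %d guides (%d targets, %d controls) x %d samples (%d cell lines)\n",
    nrow(x$counts), length(unique(x$guide_info$target[!x$guide_info$is_control])),
    sum(x$guide_info$is_control), ncol(x$counts),
    length(unique(x$sample_info$cell_line))))
  invisible(x)
}

#' Read screen counts from TSV files
#'
#' @param counts_path TSV: first column sgRNA id, second `target`, third
#'   `is_control` (TRUE/FALSE), remaining columns one per sample.
#' @param samples_path TSV: sample, cell_line, rms, timepoint.
#' @return A `ScreenCounts`.
#' @export
read_screen_counts <- function(counts_path, samples_path) {
  df <- read.table(counts_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  guide_info <- data.frame(target = df[[2]],
                           is_control = as.logical(df[[3]]),
                           row.names = df[[1]])
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(counts) <- df[[1]]
  ss <- read.table(samples_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  sample_info <- data.frame(cell_line = ss$cell_line,
                            rms = as.logical(ss$rms),
                            timepoint = ss$timepoint,
                            row.names = ss$sample)
  screen_counts(counts, guide_info, sample_info)
}

#' Normalize to total read depth per sample
#'
#' Each sample column is scaled to sum to one million (reads per million).
#'
#' @param x A `ScreenCounts` or a nonnegative matrix.
#' @return Matrix of RPM values, same dimensions.
#' @export
normalize_depth <- function(x) {
  m <- if (inherits(x, "ScreenCounts")) x$counts else as.matrix(x)
  tot <- colSums(m)
  if (any(tot <= 0)) stop("zero-total sample column", call. = FALSE)
  sweep(m, 2L, tot / 1e6, "/")
}

#' Per-guide log2 fold depletion per cell line
#'
#' Replicate RPM columns are averaged within each (cell line, timepoint)
#' pair and `LFC = log2((mean late RPM + pc) / (mean early RPM + pc))`.
#'
#' @param x A `ScreenCounts`.
#' @param pseudocount Pseudocount in RPM units (default 1).
#' @return Matrix guide x cell line of log2 fold depletions.
#' @export
fold_depletion <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "ScreenCounts"), pseudocount > 0)
  rpm <- normalize_depth(x)
  si <- x$sample_info
  lines <- unique(si$cell_line)
  out <- vapply(lines, function(cl) {
    early <- rownames(si)[si$cell_line == cl & si$timepoint == "early"]
    late <- rownames(si)[si$cell_line == cl & si$timepoint == "late"]
    e <- rowMeans(rpm[, early, drop = FALSE])
    l <- rowMeans(rpm[, late, drop = FALSE])
    log2((l + pseudocount) / (e + pseudocount))
  }, numeric(nrow(rpm)))
  # vapply drops to a plain vector for a single-guide screen
  matrix(out, nrow = nrow(rpm), dimnames = list(rownames(rpm), lines))
}

#' Rank targets by RMS-specific depletion
#'
#' Per target and cell line, guide LFCs are aggregated (mean by default);
#' the specificity score is the mean aggregate over RMS lines minus the
#' mean over non-RMS lines. Targets are ranked ascending: the most
#' negative score — strongest RMS-specific dropout — ranks 1. Negative-
#' control guides are summarized separately as an empirical null and used
#' for optional z-scores.
#'
#' @param x A `ScreenCounts`.
#' @param pseudocount Pseudocount in RPM units passed to
#'   [fold_depletion()].
#' @param aggregate `"mean"` (default) or `"median"` guide-to-target
#'   aggregation.
#' @return A `DepletionTable`: `$guide_lfc` (guide x line),
#'   `$target_lfc` (target x line), `$ranking` data.frame (target,
#'   rms_lfc, nonrms_lfc, specificity, z, rank), `$control_null`
#'   (per-control-guide specificity values).
#' @export
specificity_rank <- function(x, pseudocount = 1,
                             aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else median
  si <- x$sample_info
  rms_lines <- unique(si$cell_line[si$rms])
  non_lines <- unique(si$cell_line[!si$rms])
  stopifnot(length(rms_lines) >= 1L, length(non_lines) >= 1L)
  lfc <- fold_depletion(x, pseudocount)
  gi <- x$guide_info
  is_t <- !gi$is_control
  targets <- sort(unique(gi$target[is_t]))
  target_lfc <- t(vapply(targets, function(tg) {
    rows <- rownames(gi)[is_t & gi$target == tg]
    apply(lfc[rows, , drop = FALSE], 2L, agg)
  }, numeric(ncol(lfc))))
  rms_lfc <- rowMeans(target_lfc[, rms_lines, drop = FALSE])
  non_lfc <- rowMeans(target_lfc[, non_lines, drop = FALSE])
  spec <- rms_lfc - non_lfc
  # per-control-guide specificity: empirical null for z-scores
  ctl_rows <- rownames(gi)[gi$is_control]
  control_null <- if (length(ctl_rows)) {
    rowMeans(lfc[ctl_rows, rms_lines, drop = FALSE]) -
      rowMeans(lfc[ctl_rows, non_lines, drop = FALSE])
  } else numeric(0)
  z <- if (length(control_null) >= 2L)
    (spec - mean(control_null)) / sd(control_null) else rep(NA_real_, length(spec))
  o <- order(spec, targets)
  ranking <- data.frame(target = targets[o], rms_lfc = rms_lfc[o],
                        nonrms_lfc = non_lfc[o], specificity = spec[o],
                        z = z[o], rank = seq_along(o),
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  structure(list(guide_lfc = lfc, target_lfc = target_lfc,
                 ranking = ranking, control_null = control_null,
                 aggregate = aggregate),
            class = "DepletionTable")
}

#' @export
print.DepletionTable <- function(x, ...) {
  cat("DepletionTable:", nrow(x$ranking), "targets ranked by RMS-specific",
      "depletion\nTop 5:\n")
  print(head(x$ranking[, c("target", "specificity", "rank")], 5),
        row.names = FALSE)
  invisible(x)
}

#' Write the specificity ranking as TSV
#' @param x A `DepletionTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  write.table(x$ranking, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
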
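# qPCR and competition-assay arithmetic. Amplification efficiency is
# fixed at 2 (perfect doubling), so all quantities are powers of 2 of Ct
# differences.

#' ChIP-qPCR percent recovery
#'
#' `%recovery = 2^(Ct(input) - log2(X) - Ct(sample)) * 100`, where X is
#' the fold-dilution of the input aliquot.
#'
#' @param ct_input Input Ct (cycles).
#' @param X Input dilution factor (>= 1).
#' @param ct_sample IP sample Ct (cycles).
#' @return Percent of input recovered (vectorized).
#' @export
percent_recovery <- function(ct_input, X, ct_sample) {
  stopifnot(all(X >= 1))
  2^(ct_input - log2(X) - ct_sample) * 100
}

#' Spike-correct a sample Ct against exogenous control loci
#'
#' `Ct(sample)corr = Ct(sample) - (Ct(sample)Pgbs - Ct(control)Pgbs)`:
#' technical variation between ChIPs of the same antibody is removed using
#' Ct values from Drosophila-specific (Pgbs) primers on the spiked-in
#' chromatin.
#'
#' @param ct_sample Sample Ct at the locus of interest.
#' @param ct_sample_pgbs Sample Ct with the spike primer set.
#' @param ct_control_pgbs Control-condition Ct with the spike primer set.
#' @return Corrected Ct (vectorized).
#' @export
spike_correct_ct <- function(ct_sample, ct_sample_pgbs, ct_control_pgbs) {
  ct_sample - (ct_sample_pgbs - ct_control_pgbs)
}

#' dCt for ChIP-qPCR
#'
#' `dCt = Ct(input) - log2(X) - Ct(sample)`; the exponent of the percent-
#' recovery formula.
#'
#' @inheritParams percent_recovery
#' @return dCt (vectorized).
#' @export
chip_dct <- function(ct_input, X, ct_sample) {
  ct_input - log2(X) - ct_sample
}

#' Fold change from dCt values
#'
#' `ddCt = dCt(control) - dCt(sample)` and `FC = 2^(-ddCt)`.
#'
#' @param dct_control Control-condition dCt.
#' @param dct_sample Sample-condition dCt.
#' @return Fold change (vectorized).
#' @export
ddct_fold_change <- function(dct_control, dct_sample) {
  2^(-(dct_control - dct_sample))
}

# Iteratively drop the technical replicate farthest from the replicate
# median while SD > threshold and > 2 replicates remain.
.drop_ct_outliers <- function(ct, sd_threshold = 0.5) {
  ct <- ct[!is.na(ct)]
  while (length(ct) > 2L && sd(ct) > sd_threshold) {
    d <- abs(ct - median(ct))
    ct <- ct[-which.max(d)]
  }
  ct
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical-replicate Ct sets with SD > 0.5 cycles have the replicate
#' farthest from the replicate median removed, iterating until SD <= 0.5
#' or only two remain. Then, per biological replicate,
#' `dCt = mean Ct(target) - mean Ct(reference)` (reference typically
#' GAPDH), `ddCt = dCt(condition) - dCt(control)` pairing biological
#' replicates, and `expression = 2^(-ddCt)`. The reported value is the
#' mean over biological replicates, with upper and lower limits from the
#' per-replicate min and max of the back-transformed fold change.
#'
#' @param ct Data frame with columns `condition`, `replicate` (biological
#'   replicate id), `role` (`"target"` or `"reference"`) and `ct`;
#'   multiple rows per (condition, replicate, role) are technical
#'   replicates.
#' @param control_condition Name of the control condition.
#' @param sd_threshold Technical-replicate SD threshold (cycles, default
#'   0.5).
#' @return A list with `$summary` data.frame (condition, n_bio,
#'   expression, lower, upper, p_value) — `p_value` a paired two-tailed
#'   t-test on the per-replicate dCt values vs the control — and `$dct`
#'   the per-(condition, replicate) dCt table.
#' @export
relative_expression <- function(ct, control_condition, sd_threshold = 0.5) {
  stopifnot(all(c("condition", "replicate", "role", "ct") %in% names(ct)))
  if (!control_condition %in% ct$condition)
    stop("control condition '", control_condition, "' absent",
         call. = FALSE)
  dct_rows <- lapply(split(ct, interaction(ct$condition, ct$replicate,
                                           drop = TRUE)), function(g) {
    tc <- .drop_ct_outliers(g$ct[g$role == "target"], sd_threshold)
    rc <- .drop_ct_outliers(g$ct[g$role == "reference"], sd_threshold)
    if (length(tc) == 0L || length(rc) == 0L) return(NULL)
    data.frame(condition = g$condition[1], replicate = g$replicate[1],
               dct = mean(tc) - mean(rc), stringsAsFactors = FALSE)
  })
  dct <- do.call(rbind, dct_rows)
  rownames(dct) <- NULL
  ctl <- dct[dct$condition == control_condition, , drop = FALSE]
  ctl_d <- setNames(ctl$dct, ctl$replicate)
  conds <- unique(ct$condition)  # preserve input condition order
  summary <- do.call(rbind, lapply(conds, function(cond) {
    s <- dct[dct$condition == cond, , drop = FALSE]
    shared <- intersect(as.character(s$replicate), names(ctl_d))
    sd_ <- setNames(s$dct, s$replicate)[shared]
    ddct <- sd_ - ctl_d[shared]
    fc <- 2^(-ddct)
    p <- if (cond == control_condition || length(shared) < 2L) NA_real_
         else tryCatch(t.test(sd_, ctl_d[shared], paired = TRUE)$p.value,
                       error = function(e) NA_real_)  # constant dCts
    data.frame(condition = cond, n_bio = length(shared),
               expression = mean(fc), lower = min(fc), upper = max(fc),
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, dct = dct)
}

#' Read a Ct table
#'
#' @param path TSV with columns target, condition, replicate, role, ct and
#'   optionally X (input dilution).
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Normalize competition-assay trajectories to the day-2 baseline
#'
#' `value(day) = 100 * pct_rfp(day) / pct_rfp(day 2)`: the transduced
#' (reporter-positive) population share on each day as a percentage of its
#' starting share two days after transduction.
#'
#' @param records Data frame with columns `condition`, `day`, `pct_rfp`
#'   (percent reporter-positive cells, 0-100) and optionally `replicate`.
#' @param baseline_day Baseline day (default 2).
#' @return Data frame with an added `normalized` column (percent of
#'   baseline).
#' @export
competition_trajectory <- function(records, baseline_day = 2L) {
  stopifnot(all(c("condition", "day", "pct_rfp") %in% names(records)))
  if (any(records$pct_rfp < 0 | records$pct_rfp > 100))
    stop("pct_rfp must be within [0, 100]", call. = FALSE)
  if (!"replicate" %in% names(records)) records$replicate <- 1L
  grp <- interaction(records$condition, records$replicate, drop = TRUE)
  out <- lapply(split(records, grp), function(g) {
    b <- g$pct_rfp[g$day == baseline_day]
    if (length(b) != 1L || b <= 0)
      stop("condition ", g$condition[1],
           ": missing or nonpositive day-", baseline_day, " baseline",
           call. = FALSE)
    g$normalized <- 100 * g$pct_rfp / b
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$replicate, out$day), , drop = FALSE]
}
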
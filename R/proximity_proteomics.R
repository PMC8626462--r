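# Proximity-labeling (BioID) enrichment analysis: peptide/missingness
# filtering, per-sample robust z-score normalization on the log2 scale,
# group comparison with empirical-Bayes variance shrinkage, and a
# pseudo-fold-change route for proteins undetected in one condition.

#' Construct a protein intensity matrix
#'
#' @param intensities Numeric matrix, protein x sample, raw (positive)
#'   intensities with `NA` for missing entries.
#' @param n_peptides Named integer vector of peptide counts per protein.
#' @param groups Named character vector mapping each sample to its
#'   condition label (e.g. bait vs BirA-only control).
#' @return An `IntensityMatrix` object.
#' @export
intensity_matrix <- function(intensities, n_peptides, groups) {
  intensities <- as.matrix(intensities)
  stopifnot(all(rownames(intensities) %in% names(n_peptides)),
            all(colnames(intensities) %in% names(groups)))
  if (any(intensities <= 0, na.rm = TRUE))
    stop("intensities must be positive (use NA for missing)",
         call. = FALSE)
  structure(list(intensities = intensities,
                 n_peptides = n_peptides[rownames(intensities)],
                 groups = groups[colnames(intensities)]),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf(
    "IntensityMatrix: %d proteins x %d samples (%s), %.1f%% missing\n",
    nrow(x$intensities), ncol(x$intensities),
    paste(sprintf("%s n=%d", names(table(x$groups)), table(x$groups)),
          collapse = ", "),
    100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Read an intensity matrix from TSV
#'
#' @param path TSV: columns `protein`, `n_peptides`, then one column per
#'   sample; empty cells or `NA` are missing.
#' @param groups Named character vector sample -> condition, or a path to
#'   a 2-column TSV (sample, condition).
#' @return An `IntensityMatrix`.
#' @export
read_intensity_matrix <- function(path, groups) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("", "NA"))
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- read.table(groups, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    groups <- setNames(g[[2]], g[[1]])
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  intensity_matrix(m, setNames(as.integer(df[[2]]), df[[1]]), groups)
}

#' Filter proteins by peptide support and missingness
#'
#' Keeps proteins identified by at least `min_peptides` peptides with at
#' most `max_missing` missing entries across all samples.
#'
#' @param m An `IntensityMatrix`.
#' @param min_peptides Minimum peptide count (default 2).
#' @param max_missing Maximum missing entries per protein (default 4).
#' @return Filtered `IntensityMatrix`.
#' @export
filter_matrix <- function(m, min_peptides = 2L, max_missing = 4L) {
  keep <- m$n_peptides >= min_peptides &
    rowSums(is.na(m$intensities)) <= max_missing
  out <- m
  out$intensities <- m$intensities[keep, , drop = FALSE]
  out$n_peptides <- m$n_peptides[keep]
  out
}

#' Modified robust z-score normalization
#'
#' Per sample, log2 intensities are robust-z transformed,
#' `z = (x - median) / (1.4826 * MAD)`, then rescaled to the grand
#' location and scale — the median of the per-sample medians and the
#' median of the per-sample MADs — so values stay on a log2-intensity-
#' like scale while a location shift of any single sample is removed
#' entirely. Missing entries stay missing.
#'
#' @param m An `IntensityMatrix`.
#' @return Numeric matrix of normalized log2 intensities (protein x
#'   sample).
#' @export
robust_z_normalize <- function(m) {
  x <- log2(m$intensities)
  obs_per_sample <- colSums(!is.na(x))
  if (any(obs_per_sample < 3L))
    stop("need >= 3 observed values per sample", call. = FALSE)
  meds <- apply(x, 2L, median, na.rm = TRUE)
  mads <- vapply(seq_len(ncol(x)), function(j)
    median(abs(x[, j] - meds[j]), na.rm = TRUE), numeric(1))
  if (any(mads == 0))
    stop("sample '", colnames(x)[which(mads == 0)[1]],
         "' has zero MAD", call. = FALSE)
  grand_med <- median(meds)
  grand_mad <- median(mads)
  for (j in seq_len(ncol(x))) {
    z <- (x[, j] - meds[j]) / (1.4826 * mads[j])
    x[, j] <- z * (1.4826 * grand_mad) + grand_med
  }
  x
}

# Newton inversion of the trigamma function (for the prior df of the
# scaled-F variance model).
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Method-of-moments fit of s^2 ~ s0^2 * F(df, d0) on the log scale,
# allowing per-protein residual df. Returns prior df d0 (possibly Inf)
# and prior scale s0^2.
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s0 = mean(s2[df > 0])))
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0 = exp(mean(e))))
  d0 <- 2 * .trigamma_inverse(evar)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0 = s0)
}

#' Two-group comparison with empirical-Bayes variance shrinkage
#'
#' Per protein, `log2FC = mean(bait) - mean(control)` on the normalized
#' log2 scale. Per-protein pooled variances are shrunk toward a prior
#' estimated from the variance distribution by the method of moments
#' (scaled-F model on log variances); the moderated t statistic uses the
#' posterior variance and augmented degrees of freedom. P-values are
#' two-sided; Benjamini-Hochberg adjusted p-values are reported
#' alongside.
#'
#' @param m_norm Normalized log2 matrix from [robust_z_normalize()].
#' @param groups Named character vector sample -> condition.
#' @param bait,control Condition labels; default: `bait` is the first
#'   label alphabetically after removing `control`, `control` the label
#'   containing "control"/"BirA" if present, else the last label.
#' @return Data frame (protein, log2fc, t, df, p_value, adj_p,
#'   n_bait, n_control). Proteins with < 2 observations in either group
#'   get `NA` statistics (route those with a fully missing group to
#'   [pseudo_fold_change()]).
#' @export
group_compare <- function(m_norm, groups, bait = NULL, control = NULL) {
  labs <- unique(groups[colnames(m_norm)])
  if (is.null(control)) {
    hit <- grep("control|bira", labs, ignore.case = TRUE, value = TRUE)
    control <- if (length(hit)) hit[1] else labs[length(labs)]
  }
  if (is.null(bait)) bait <- setdiff(labs, control)[1]
  bcols <- colnames(m_norm)[groups[colnames(m_norm)] == bait]
  ccols <- colnames(m_norm)[groups[colnames(m_norm)] == control]
  stopifnot(length(bcols) >= 2L, length(ccols) >= 2L)
  bm <- m_norm[, bcols, drop = FALSE]
  cm <- m_norm[, ccols, drop = FALSE]
  nb <- rowSums(!is.na(bm)); nc <- rowSums(!is.na(cm))
  mb <- rowMeans(bm, na.rm = TRUE); mc <- rowMeans(cm, na.rm = TRUE)
  lfc <- mb - mc
  vb <- apply(bm, 1L, var, na.rm = TRUE)
  vc <- apply(cm, 1L, var, na.rm = TRUE)
  df_res <- nb + nc - 2L
  s2 <- (ifelse(nb > 1, (nb - 1) * vb, 0) +
         ifelse(nc > 1, (nc - 1) * vc, 0)) / pmax(df_res, 1L)
  testable <- nb >= 2L & nc >= 2L
  prior <- .fit_variance_prior(s2[testable], df_res[testable])
  d0 <- prior$d0; s0 <- prior$s0
  s2_post <- if (is.finite(d0)) (d0 * s0 + df_res * s2) / (d0 + df_res)
             else rep(s0, length(s2))
  se <- sqrt(s2_post * (1 / nb + 1 / nc))
  tstat <- lfc / se
  df_total <- df_res + (if (is.finite(d0)) d0 else Inf)
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[!testable] <- NA_real_
  tstat[!testable] <- NA_real_
  lfc[nb == 0 | nc == 0] <- NA_real_
  out <- data.frame(protein = rownames(m_norm), log2fc = unname(lfc),
                    t = unname(tstat),
                    df = unname(ifelse(testable, df_total, NA_real_)),
                    p_value = unname(p),
                    adj_p = NA_real_,
                    n_bait = unname(nb), n_control = unname(nc),
                    stringsAsFactors = FALSE)
  out$adj_p[testable] <- p.adjust(out$p_value[testable], "BH")
  attr(out, "prior") <- prior
  attr(out, "bait") <- bait
  attr(out, "control") <- control
  out
}

#' Pseudo fold change for proteins undetected in one condition
#'
#' When all measurements of a protein are missing in one condition, the
#' missing group average is replaced by the mean of the 10% smallest
#' observed intensity values in that condition (across all proteins;
#' ceiling of 0.1 x count, at least 1 value), and the log2 fold change is
#' computed against it.
#'
#' @param m_norm Normalized log2 matrix.
#' @param groups Named character vector sample -> condition.
#' @param bait,control Condition labels (as in [group_compare()]).
#' @return Data frame (protein, log2fc, pseudo_fc_flag) for proteins with
#'   exactly one group fully missing; proteins missing in both groups are
#'   dropped with a warning.
#' @export
pseudo_fold_change <- function(m_norm, groups, bait = NULL,
                               control = NULL) {
  labs <- unique(groups[colnames(m_norm)])
  if (is.null(control)) {
    hit <- grep("control|bira", labs, ignore.case = TRUE, value = TRUE)
    control <- if (length(hit)) hit[1] else labs[length(labs)]
  }
  if (is.null(bait)) bait <- setdiff(labs, control)[1]
  bcols <- colnames(m_norm)[groups[colnames(m_norm)] == bait]
  ccols <- colnames(m_norm)[groups[colnames(m_norm)] == control]
  bm <- m_norm[, bcols, drop = FALSE]
  cm <- m_norm[, ccols, drop = FALSE]
  nb <- rowSums(!is.na(bm)); nc <- rowSums(!is.na(cm))
  low_mean <- function(mat) {
    v <- sort(mat[!is.na(mat)])
    if (length(v) == 0L) return(NA_real_)
    mean(v[seq_len(max(1L, ceiling(0.1 * length(v))))])
  }
  both_missing <- nb == 0L & nc == 0L
  if (any(both_missing))
    warning(sum(both_missing),
            " protein(s) missing in both groups dropped", call. = FALSE)
  sel <- xor(nb == 0L, nc == 0L)
  if (!any(sel))
    return(data.frame(protein = character(0), log2fc = numeric(0),
                      pseudo_fc_flag = logical(0)))
  imput_b <- low_mean(bm); imput_c <- low_mean(cm)
  mb <- rowMeans(bm, na.rm = TRUE); mc <- rowMeans(cm, na.rm = TRUE)
  mb[nb == 0L] <- imput_b
  mc[nc == 0L] <- imput_c
  data.frame(protein = rownames(m_norm)[sel],
             log2fc = unname(mb[sel] - mc[sel]),
             pseudo_fc_flag = TRUE, stringsAsFactors = FALSE)
}

#' Full BioID enrichment analysis with hit calling
#'
#' Filters, normalizes, tests, routes all-missing-in-one-condition
#' proteins through the pseudo-fold-change rule, and flags hits by the
#' volcano-plot quadrant rule: `log2FC > fc_threshold` and (raw)
#' `p < p_threshold`. Pseudo-fold-change proteins have no p-value and are
#' hits on fold change alone when `hit_pseudo = TRUE`.
#'
#' @param m An `IntensityMatrix`.
#' @param bait,control Condition labels (see [group_compare()]).
#' @param min_peptides,max_missing Filter settings (see
#'   [filter_matrix()]).
#' @param fc_threshold log2 fold-change threshold (default 2.5).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param hit_pseudo Whether pseudo-fold-change proteins can be hits by
#'   fold change alone (default TRUE).
#' @return An `EnrichmentResult` data.frame: protein, log2fc, t, df,
#'   p_value, adj_p, n_bait, n_control, pseudo_fc_flag, hit.
#' @export
bioid_enrichment <- function(m, bait = NULL, control = NULL,
                             min_peptides = 2L, max_missing = 4L,
                             fc_threshold = 2.5, p_threshold = 0.05,
                             hit_pseudo = TRUE) {
  mf <- filter_matrix(m, min_peptides, max_missing)
  nm <- robust_z_normalize(mf)
  res <- group_compare(nm, mf$groups, bait, control)
  ps <- pseudo_fold_change(nm, mf$groups,
                           attr(res, "bait"), attr(res, "control"))
  res$pseudo_fc_flag <- FALSE
  if (nrow(ps)) {
    i <- match(ps$protein, res$protein)
    res$log2fc[i] <- ps$log2fc
    res$pseudo_fc_flag[i] <- TRUE
  }
  res$hit <- !is.na(res$log2fc) & res$log2fc > fc_threshold &
    ((!is.na(res$p_value) & res$p_value < p_threshold) |
       (res$pseudo_fc_flag & hit_pseudo))
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d proteins, %d hits (%d via pseudo-FC)\n",
              nrow(x), sum(x$hit), sum(x$hit & x$pseudo_fc_flag)))
  top <- x[order(-as.numeric(x$hit), x$p_value), , drop = FALSE]
  print(head(as.data.frame(top)[, c("protein", "log2fc", "p_value", "hit")],
             5), row.names = FALSE)
  invisible(x)
}
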
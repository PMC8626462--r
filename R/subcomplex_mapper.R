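# Subcomplex classification of ATPase-anchored sites and downstream
# occupancy summaries. BAF is marked by DPF2, PBAF by PBRM1 and ncBAF by
# BRD9; every class label is a pure function of the Boolean overlap triple
# at a BRG1 peak.

#' Subcomplex class labels
#'
#' The eight combination classes a BRG1 peak can take, ordered from
#' all-three to unassigned.
#' @export
subcomplex_classes <- function() {
  c("BAF+PBAF+ncBAF", "BAF+PBAF", "BAF+ncBAF", "PBAF+ncBAF",
    "BAF_only", "PBAF_only", "ncBAF_only", "BRG1_unassigned")
}

.triple_to_class <- function(has_dpf2, has_pbrm1, has_brd9) {
  key <- paste0(as.integer(has_dpf2), as.integer(has_pbrm1),
                as.integer(has_brd9))
  map <- c("111" = "BAF+PBAF+ncBAF", "110" = "BAF+PBAF",
           "101" = "BAF+ncBAF", "011" = "PBAF+ncBAF",
           "100" = "BAF_only", "010" = "PBAF_only",
           "001" = "ncBAF_only", "000" = "BRG1_unassigned")
  unname(map[key])
}

#' Classify BRG1 peaks into subcomplex combination classes
#'
#' Each BRG1 peak receives a Boolean triple (overlap with a DPF2, PBRM1 and
#' BRD9 peak, respectively) and the deterministic 8-way class label:
#' BAF = BRG1 & DPF2, PBAF = BRG1 & PBRM1, ncBAF = BRG1 & BRD9. PBRM1 peaks
#' with no BRG1 overlap are collected separately (PBAF-like binding away
#' from the shared ATPase anchor).
#'
#' @param brg1,dpf2,pbrm1,brd9 `PeakSet` objects.
#' @param min_bp Minimum overlap (bp) defining co-occupancy; default 1.
#' @return A `SubcomplexCalls` object: `$calls` data.frame (peak, chrom,
#'   start, end, has_dpf2, has_pbrm1, has_brd9, class), `$brg1` the input
#'   BRG1 `PeakSet`, `$pbrm1_without_brg1` the unanchored PBRM1 `PeakSet`.
#' @export
classify_subcomplexes <- function(brg1, dpf2, pbrm1, brd9, min_bp = 1L) {
  stopifnot(inherits(brg1, "PeakSet"))
  if (length(brg1) == 0L)
    warning("empty BRG1 peak set: no subcomplex calls", call. = FALSE)
  has_dpf2 <- overlaps_any(brg1, dpf2, min_bp)
  has_pbrm1 <- overlaps_any(brg1, pbrm1, min_bp)
  has_brd9 <- overlaps_any(brg1, brd9, min_bp)
  df <- as.data.frame(brg1)
  calls <- data.frame(peak = df$name, chrom = df$chrom, start = df$start,
                      end = df$end,
                      has_dpf2 = unname(has_dpf2),
                      has_pbrm1 = unname(has_pbrm1),
                      has_brd9 = unname(has_brd9),
                      class = factor(
                        .triple_to_class(has_dpf2, has_pbrm1, has_brd9),
                        levels = subcomplex_classes()),
                      stringsAsFactors = FALSE)
  orphan <- !overlaps_any(pbrm1, brg1, min_bp)
  pb <- pbrm1
  pb$gr <- pbrm1$gr[orphan]
  pb$factor <- "PBRM1_without_BRG1"
  structure(list(calls = calls, brg1 = brg1, pbrm1_without_brg1 = pb,
                 min_bp = min_bp),
            class = "SubcomplexCalls")
}

#' @export
print.SubcomplexCalls <- function(x, ...) {
  cat("SubcomplexCalls:", nrow(x$calls), "BRG1-anchored sites\n")
  print(table(x$calls$class))
  cat("PBRM1 without BRG1:", length(x$pbrm1_without_brg1), "peaks\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.SubcomplexCalls <- function(object, ...) {
  tab <- table(object$calls$class)
  data.frame(class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / max(1L, nrow(object$calls)))
}

#' Export per-class site lists as BED files
#'
#' One BED file per non-empty class, named `<prefix><class>.bed` (the "+"
#' separator is written as "_").
#'
#' @param calls A `SubcomplexCalls`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
export_class_beds <- function(calls, dir, prefix = "class_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in levels(calls$calls$class)) {
    sub <- calls$calls[calls$calls$class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) next
    p <- file.path(dir, paste0(prefix, gsub("\\+", "_", cl), ".bed"))
    ps <- peak_set(cl, sub$chrom, sub$start, sub$end, name = sub$peak)
    write_peaks(ps, p, "bed")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Co-occupancy of subcomplex classes with CRTF peaks
#'
#' For every class x factor pair, the fraction of class sites overlapped by
#' at least one factor peak, plus an "any_CRTF" column; also the reverse
#' view, the share of each factor's peaks that fall in each class (what
#' fraction of, e.g., all PAX3-FOXO1 peaks are BAF-only sites).
#'
#' @param calls A `SubcomplexCalls`.
#' @param crtfs Named list of `PeakSet` objects (e.g. P3F, MYOD1, MYCN).
#' @param min_bp Minimum overlap (bp).
#' @return A `CooccupancyTable`: `$fractions` and `$counts` (class x
#'   factor matrices; empty classes get `NA` fractions, not 0),
#'   `$class_sizes`, `$reverse` (factor x class share of factor peaks).
#' @export
cooccupancy_fractions <- function(calls, crtfs, min_bp = 1L) {
  stopifnot(inherits(calls, "SubcomplexCalls"), nrow(calls$calls) > 0L)
  if (is.null(names(crtfs)))
    names(crtfs) <- vapply(crtfs, function(p) p$factor, "")
  cls <- subcomplex_classes()
  site_class <- setNames(as.character(calls$calls$class), calls$calls$peak)
  # per-site overlap indicator for each factor (order = sorted brg1 peaks)
  ind <- vapply(crtfs, function(ps) overlaps_any(calls$brg1, ps, min_bp),
                logical(length(calls$brg1)))
  if (length(calls$brg1) == 1L) ind <- matrix(ind, nrow = 1L,
                                              dimnames = list(
                                                calls$calls$peak,
                                                names(crtfs)))
  any_ind <- apply(ind, 1L, any)
  cols <- c(names(crtfs), "any_CRTF")
  counts <- matrix(0L, length(cls), length(cols),
                   dimnames = list(cls, cols))
  fractions <- matrix(NA_real_, length(cls), length(cols),
                      dimnames = list(cls, cols))
  sizes <- setNames(integer(length(cls)), cls)
  site_cls <- site_class[rownames(ind)]
  for (cl in cls) {
    in_cl <- site_cls == cl
    sizes[cl] <- sum(in_cl)
    if (sizes[cl] == 0L) next  # fraction stays NA for empty classes
    counts[cl, names(crtfs)] <- colSums(ind[in_cl, , drop = FALSE])
    counts[cl, "any_CRTF"] <- sum(any_ind[in_cl])
    fractions[cl, ] <- counts[cl, ] / sizes[cl]
  }
  reverse <- t(vapply(names(crtfs), function(f) {
    hit <- overlaps_any(crtfs[[f]], calls$brg1, min_bp)
    ov <- intersect_sets(crtfs[[f]], calls$brg1, min_bp)
    cl_of_peak <- vapply(ov, function(nm) {
      if (length(nm) == 0L) return(NA_character_)
      site_class[nm[1]]
    }, "")
    n <- length(crtfs[[f]])
    vapply(cls, function(cl) sum(cl_of_peak == cl, na.rm = TRUE) / max(1L, n),
           numeric(1))
  }, numeric(length(cls))))
  structure(list(fractions = fractions, counts = counts,
                 class_sizes = sizes, reverse = reverse),
            class = "CooccupancyTable")
}

#' @export
print.CooccupancyTable <- function(x, ...) {
  cat("CooccupancyTable (fraction of class sites bound):\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Write a co-occupancy table as TSV
#' @param x A `CooccupancyTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cooccupancy <- function(x, path) {
  df <- data.frame(class = rownames(x$fractions),
                   n_sites = as.integer(x$class_sizes[rownames(x$fractions)]),
                   x$fractions, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chromatin-state enrichment of a peak category
#'
#' Each peak is assigned to exactly one state by its midpoint (so peak
#' fractions form a partition); for state s the enrichment is
#' `log2[(fraction of peaks in s) / (bp of s / total segmented bp)]`.
#' Peaks whose midpoints fall in unsegmented gaps are counted under a
#' `"none"` state whose genomic share is the gap's share of the genome.
#'
#' @param peaks A `PeakSet` (the binding category, e.g. PBRM1-alone sites).
#' @param seg A `StateSegmentation`.
#' @return Data frame (state, n_peaks, peak_fraction, genome_fraction,
#'   log2_enrichment), sorted by descending enrichment.
#' @export
state_enrichment <- function(peaks, seg) {
  stopifnot(inherits(seg, "StateSegmentation"), length(peaks) > 0L)
  mids <- peak_midpoints(peaks)
  df <- as.data.frame(peaks)
  midgr <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(mids + 1L, mids + 1L))
  hits <- GenomicRanges::findOverlaps(midgr, seg$gr, ignore.strand = TRUE)
  st <- rep("none", length(midgr))
  st[queryHits(hits)] <- mcols(seg$gr)$state[subjectHits(hits)]
  seg_bp <- tapply(GenomicRanges::width(seg$gr), mcols(seg$gr)$state, sum)
  total_seg <- sum(GenomicRanges::width(seg$gr))
  genome_bp <- sum(seg$genome_sizes)
  states <- names(seg_bp)
  zero <- seg_bp == 0
  if (any(zero)) {
    warning("state(s) with zero genomic bp excluded: ",
            paste(states[zero], collapse = ", "), call. = FALSE)
    states <- states[!zero]
  }
  n <- length(midgr)
  rows <- lapply(states, function(s) {
    pf <- sum(st == s) / n
    gf <- seg_bp[[s]] / total_seg
    data.frame(state = s, n_peaks = sum(st == s), peak_fraction = pf,
               genome_fraction = gf, log2_enrichment = log2(pf / gf))
  })
  gap_bp <- genome_bp - total_seg
  if (gap_bp > 0 || any(st == "none")) {
    pf <- sum(st == "none") / n
    gf <- if (genome_bp > 0) gap_bp / genome_bp else NA_real_
    rows <- c(rows, list(data.frame(
      state = "none", n_peaks = sum(st == "none"), peak_fraction = pf,
      genome_fraction = gf,
      log2_enrichment = if (!is.na(gf) && gf > 0) log2(pf / gf) else NA_real_)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$log2_enrichment, out$state), , drop = FALSE]
}

#' Rank chromatin states across several binding categories
#'
#' Convenience wrapper running [state_enrichment()] for each category and
#' assembling the state x category log2-enrichment matrix.
#'
#' @param categories Named list of `PeakSet` objects (e.g. PBRM1_alone,
#'   PBRM1_BRG1, BRG1_alone, P3F, MYCN, MYOD1).
#' @param seg A `StateSegmentation`.
#' @return Matrix of log2 enrichments, states x categories.
#' @export
state_enrichment_table <- function(categories, seg) {
  per <- lapply(categories, state_enrichment, seg = seg)
  states <- sort(unique(unlist(lapply(per, function(d) d$state))))
  out <- vapply(per, function(d) {
    setNames(d$log2_enrichment, d$state)[states]
  }, numeric(length(states)))
  rownames(out) <- states
  out
}

#' Read a TSS table
#'
#' @param path 4-column TSV: gene, chrom, tss position (1-based), strand.
#'   Strand is stored but unused.
#' @return Data frame (gene, chrom, tss, strand), `tss` converted to
#'   0-based.
#' @export
read_tss_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  names(df)[1:4] <- c("gene", "chrom", "tss", "strand")
  df$tss <- as.integer(df$tss) - 1L
  df
}

#' Assign peaks to genes by TSS proximity
#'
#' A gene is "bound" iff at least one peak midpoint lies within
#' `window_bp` of its TSS. Each peak is attributed to its nearest TSS
#' within the window (ties: smallest distance, then alphabetical gene
#' symbol); the gene inherits the occupancy class of its nearest assigned
#' peak when `calls` is supplied.
#'
#' @param peaks A `PeakSet`.
#' @param tss Data frame with columns gene, chrom, tss (0-based position).
#' @param window_bp Half-window around the TSS (bp); default 50000.
#' @param calls Optional `SubcomplexCalls` supplying per-peak classes.
#' @return Data frame, one row per bound gene: gene, n_peaks,
#'   assigned_peaks (";"-joined), nearest_peak, distance,
#'   occupancy_class (`NA` without `calls`).
#' @export
assign_peaks_to_genes <- function(peaks, tss, window_bp = 50000L,
                                  calls = NULL) {
  stopifnot(nrow(tss) > 0L)
  mids <- peak_midpoints(peaks)
  df <- as.data.frame(peaks)
  cls <- NULL
  if (!is.null(calls))
    cls <- setNames(as.character(calls$calls$class), calls$calls$peak)
  by_chrom <- split(tss, tss$chrom)
  recs <- vector("list", length(mids))
  for (i in seq_along(mids)) {
    cand <- by_chrom[[df$chrom[i]]]
    if (is.null(cand)) next
    d <- abs(cand$tss - mids[i])
    ok <- d <= window_bp
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    o <- order(d, cand$gene)
    recs[[i]] <- data.frame(gene = cand$gene[o[1]], peak = df$name[i],
                            distance = d[o[1]],
                            stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs)) {
    return(data.frame(gene = character(0), n_peaks = integer(0),
                      assigned_peaks = character(0),
                      nearest_peak = character(0), distance = numeric(0),
                      occupancy_class = character(0)))
  }
  out <- do.call(rbind, lapply(split(recs, recs$gene), function(g) {
    g <- g[order(g$distance, g$peak), , drop = FALSE]
    data.frame(gene = g$gene[1], n_peaks = nrow(g),
               assigned_peaks = paste(g$peak, collapse = ";"),
               nearest_peak = g$peak[1], distance = g$distance[1],
               occupancy_class = if (is.null(cls)) NA_character_
                                 else unname(cls[g$peak[1]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Summarize expression changes by occupancy group
#'
#' Partitions genes into occupancy groups and summarizes each group's log2
#' fold changes with the median and a seeded percentile-bootstrap 95% CI,
#' as used to compare, e.g., BRG1-only vs BRG1+MYCN-bound genes after BRG1
#' loss.
#'
#' @param deg Named numeric vector (or 2-column data.frame) of per-gene
#'   log2 fold changes.
#' @param groups Named list of character vectors of gene symbols, one per
#'   group.
#' @param B Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A list with `$summary` data.frame (group, n, median, ci_lo,
#'   ci_hi) and `$values` (per-group numeric vectors). Groups with n = 0
#'   get `NA` summaries.
#' @export
expression_by_occupancy <- function(deg, groups, B = 2000L, conf = 0.95,
                                    seed = 1L) {
  if (is.data.frame(deg)) deg <- setNames(deg[[2]], deg[[1]])
  alpha <- (1 - conf) / 2
  vals <- lapply(groups, function(g) unname(deg[intersect(g, names(deg))]))
  rows <- mapply(function(v, nm) {
    if (length(v) == 0L)
      return(data.frame(group = nm, n = 0L, median = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    meds <- local({
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      vapply(seq_len(B), function(b)
        median(sample(v, length(v), replace = TRUE)), numeric(1))
    })
    data.frame(group = nm, n = length(v), median = median(v),
               ci_lo = unname(quantile(meds, alpha)),
               ci_hi = unname(quantile(meds, 1 - alpha)))
  }, vals, names(groups), SIMPLIFY = FALSE)
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       values = vals)
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
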
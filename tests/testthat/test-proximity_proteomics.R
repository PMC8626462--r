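mk_matrix <- function(x, npep = NULL, groups = NULL) {
  if (is.null(colnames(x)))
    colnames(x) <- c(paste0("b", 1:(ncol(x) / 2)),
                     paste0("c", 1:(ncol(x) / 2)))
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  if (is.null(npep)) npep <- setNames(rep(3L, nrow(x)), rownames(x))
  if (is.null(groups))
    groups <- setNames(rep(c("bait", "control"), each = ncol(x) / 2),
                       colnames(x))
  intensity_matrix(x, npep, groups)
}

test_that("filtering drops low-peptide and high-missing proteins", {
  x <- matrix(2^rnorm(3 * 8, 20), 3, 8)
  x[2, 1:5] <- NA  # 5 of 8 missing
  m <- mk_matrix(x, npep = setNames(c(1L, 3L, 3L), paste0("P", 1:3)))
  mf <- filter_matrix(m)          # P1: 1 peptide; P2: 5 missing
  expect_equal(rownames(mf$intensities), "P3")
  # idempotent
  mff <- filter_matrix(mf)
  expect_identical(mff$intensities, mf$intensities)
})

test_that("robust z normalization removes per-sample location shifts", {
  set.seed(9)
  x <- 2^matrix(rnorm(200 * 4, 20, 2), 200, 4)
  m <- mk_matrix(x)
  n1 <- robust_z_normalize(m)
  # shifting the highest-median sample further up changes nothing: the
  # grand location (median of sample medians) and every MAD are untouched
  jmax <- which.max(apply(log2(x), 2, median))
  x2 <- x; x2[, jmax] <- x2[, jmax] * 2^3
  n2 <- robust_z_normalize(mk_matrix(x2))
  expect_equal(n1, n2, tolerance = 1e-12)
  # a sample already at the grand location/scale is a fixed point
  l <- log2(x)
  j_meds <- apply(l, 2, median)
  j_mads <- vapply(1:4, function(j) median(abs(l[, j] - j_meds[j])),
                   numeric(1))
  gm <- median(j_meds); gmad <- median(j_mads)
  fixed <- (l - matrix(j_meds, 200, 4, byrow = TRUE)) /
    matrix(j_mads, 200, 4, byrow = TRUE) * gmad + gm
  nf <- robust_z_normalize(mk_matrix(2^fixed))
  expect_equal(nf, fixed, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("robust z matches a hand-computed two-sample transform", {
  x <- rbind(c(10, 11), c(12, 15), c(14, 19), c(16, 23), c(18, 27))
  m <- mk_matrix(2^x)
  n <- robust_z_normalize(m)
  l <- x
  j_meds <- apply(l, 2, median)
  j_mads <- vapply(1:2, function(j) median(abs(l[, j] - j_meds[j])),
                   numeric(1))
  gm <- median(j_meds); gmad <- median(j_mads)
  for (j in 1:2) {
    expect_equal(unname(n[, j]),
                 (l[, j] - j_meds[j]) / (1.4826 * j_mads[j]) *
                   (1.4826 * gmad) + gm)
  }
  # zero-MAD sample is a hard error naming the sample
  bad <- mk_matrix(2^cbind(rep(10, 5), c(1, 2, 3, 4, 5)))
  expect_error(robust_z_normalize(bad), "b1")
})

test_that("group comparison returns exact fold changes", {
  base <- matrix(rep(seq(10, 19), 8), 10, 8,
                 dimnames = list(paste0("P", 1:10),
                                 c(paste0("b", 1:4), paste0("c", 1:4))))
  x <- base; x[, 1:4] <- x[, 1:4] + 3  # bait = control + 3, zero variance
  m <- mk_matrix(2^x)
  r <- group_compare(log2(m$intensities), m$groups, "bait", "control")
  expect_equal(r$log2fc, rep(3, 10))
  expect_true(all(r$p_value < 0.05))
  # identical groups give fold change 0
  m0 <- mk_matrix(2^base)
  r0 <- group_compare(log2(m0$intensities), m0$groups, "bait", "control")
  expect_equal(r0$log2fc, rep(0, 10))
  # monotone: raising every bait value raises the fold change
  x2 <- x; x2[3, 1:4] <- x2[3, 1:4] + 1
  r2 <- group_compare(x2, m$groups, "bait", "control")
  expect_gt(r2$log2fc[3], r$log2fc[3])
})

test_that("moderated statistics agree with limma on random data", {
  skip_if_not_installed("limma")
  set.seed(12)
  x <- matrix(rnorm(300 * 8, 20, 2), 300, 8)
  x[1:10, 1:4] <- x[1:10, 1:4] + 2
  m <- mk_matrix(2^x)
  r <- group_compare(log2(m$intensities), m$groups, "bait", "control")
  design <- cbind(1, rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(log2(m$intensities), design))
  expect_equal(r$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  expect_equal(attr(r, "prior")$d0, fit$df.prior, tolerance = 0.05)
  expect_equal(r$t, unname(fit$t[, 2]), tolerance = 0.01)
  expect_equal(r$p_value, unname(fit$p.value[, 2]), tolerance = 0.01)
})

test_that("pseudo fold change imputes the low-intensity mean", {
  # control condition fully missing for P1; observed control values for
  # the others are 10, 12, ..., 28 -> 10% smallest = {10}, imputed 10
  x <- matrix(NA_real_, 11, 4,
              dimnames = list(paste0("P", 1:11),
                              c("b1", "b2", "c1", "c2")))
  x[, c("b1", "b2")] <- 22
  x[2:11, "c1"] <- seq(10, 28, by = 2)
  x[2:11, "c2"] <- seq(10, 28, by = 2)
  groups <- setNames(c("bait", "bait", "control", "control"),
                     colnames(x))
  r <- pseudo_fold_change(x, groups, "bait", "control")
  expect_equal(r$protein, "P1")
  expect_equal(r$log2fc, 22 - 10)
  expect_true(r$pseudo_fc_flag)
  # raising all bait values by 1 raises the pseudo fold change by 1
  x2 <- x; x2[, c("b1", "b2")] <- x2[, c("b1", "b2")] + 1
  expect_equal(pseudo_fold_change(x2, groups, "bait", "control")$log2fc,
               r$log2fc + 1)
  # both groups missing: dropped with a warning
  x3 <- x; x3[1, ] <- NA
  expect_warning(r3 <- pseudo_fold_change(x3, groups, "bait", "control"),
                 "both groups")
  expect_equal(nrow(r3), 0)
})

test_that("hit calling reproduces the volcano quadrant rule", {
  cfg <- sim_config(seed = 44)
  pr <- simulate_proteomics(cfg)
  res <- bioid_enrichment(pr$matrix, bait = "bait", control = "control")
  manual <- !is.na(res$log2fc) & res$log2fc > 2.5 &
    ((!is.na(res$p_value) & res$p_value < 0.05) | res$pseudo_fc_flag)
  expect_equal(res$hit, manual)
  # pseudo-route proteins (those surviving the filter) are finite and
  # flagged
  forced <- pr$truth$protein[pr$truth$forced_missing_control]
  rows <- res[res$protein %in% forced, ]
  expect_gte(nrow(rows), 1L)
  expect_true(all(rows$pseudo_fc_flag))
  expect_true(all(is.finite(rows$log2fc)))
})

test_that("moderated test holds its size under the null", {
  fracs <- vapply(1:15, function(s) {
    pr <- simulate_proteomics(sim_config(
      seed = 7000 + s, proteomics = list(n_hits = 0L,
                                         n_forced_missing = 0L)))
    res <- bioid_enrichment(pr$matrix, bait = "bait", control = "control")
    mean(res$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(fracs), 0.03)
  expect_lt(mean(fracs), 0.07)
})

test_that("intensity matrix TSV round-trips with missing cells", {
  pr <- simulate_proteomics(sim_config(seed = 3))
  d <- tempfile(); dir.create(d)
  idf <- data.frame(protein = rownames(pr$matrix$intensities),
                    n_peptides = unname(pr$matrix$n_peptides),
                    pr$matrix$intensities, check.names = FALSE)
  write.table(idf, file.path(d, "i.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(pr$matrix$groups),
                         condition = unname(pr$matrix$groups)),
              file.path(d, "g.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- read_intensity_matrix(file.path(d, "i.tsv"), file.path(d, "g.tsv"))
  expect_equal(m$intensities, pr$matrix$intensities)
  expect_equal(m$groups, pr$matrix$groups)
})
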
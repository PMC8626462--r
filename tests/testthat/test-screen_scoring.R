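tiny_screen <- function(mat, targets, controls = NULL, rms, tps) {
  gi <- data.frame(
    target = c(targets, rep("control", length(controls %||% integer(0)))),
    is_control = c(rep(FALSE, length(targets)),
                   rep(TRUE, length(controls %||% integer(0)))),
    row.names = rownames(mat))
  si <- data.frame(cell_line = sub("_.*", "", colnames(mat)),
                   rms = rms, timepoint = tps, row.names = colnames(mat))
  screen_counts(mat, gi, si)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("depth normalization scales columns to one million", {
  m <- matrix(c(10, 30, 60, 200, 300, 500), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  n <- normalize_depth(m)
  expect_equal(colSums(n), c(s1 = 1e6, s2 = 1e6))
  expect_equal(n["g1", "s1"], 1e5)
  # a column already at 1e6 total is unchanged
  m2 <- matrix(c(4e5, 6e5), ncol = 1,
               dimnames = list(c("a", "b"), "s"))
  expect_equal(normalize_depth(m2), m2)
  # 50 of total 2e6 -> 25 RPM
  m3 <- matrix(c(50, 2e6 - 50), ncol = 1,
               dimnames = list(c("a", "b"), "s"))
  expect_equal(normalize_depth(m3)["a", "s"], 25)
  # proportional columns normalize identically
  m4 <- cbind(s1 = c(1, 2, 7), s2 = c(10, 20, 70))
  rownames(m4) <- paste0("g", 1:3)
  expect_equal(normalize_depth(m4)[, "s1"], normalize_depth(m4)[, "s2"])
  expect_error(normalize_depth(cbind(s = c(0, 0))), "zero")
})

test_that("fold depletion is log2 late/early after RPM averaging", {
  mat <- matrix(c(100, 900, 100, 900), nrow = 2,
                dimnames = list(c("g1", "g2"),
                                c("A_early", "A_late")))
  x <- tiny_screen(mat, c("T1", "T2"), rms = c(TRUE, TRUE),
                   tps = c("early", "late"))
  lfc <- fold_depletion(x, pseudocount = 1)
  expect_equal(unname(lfc[, "A"]), c(0, 0))
  # RPM 100 -> 25 at vanishing pseudocount approaches -2
  mat2 <- matrix(c(100, 900, 25, 975), nrow = 2,
                 dimnames = list(c("g1", "g2"),
                                 c("A_early", "A_late")))
  x2 <- tiny_screen(mat2, c("T1", "T2"), rms = c(TRUE, TRUE),
                    tps = c("early", "late"))
  lfc2 <- fold_depletion(x2, pseudocount = 1e-9)
  expect_equal(lfc2["g1", "A"], log2(25000 / 100000), tolerance = 1e-6)
  # guide absent at late: early 100 RPM, late 0, pc = 1
  mat3 <- matrix(c(100, 999900, 0, 1e6), nrow = 2,
                 dimnames = list(c("g1", "g2"),
                                 c("A_early", "A_late")))
  x3 <- tiny_screen(mat3, c("T1", "T2"), rms = c(TRUE, TRUE),
                    tps = c("early", "late"))
  expect_equal(fold_depletion(x3, 1)["g1", "A"], log2(1 / 101))
})

test_that("fold depletion is invariant to per-sample depth rescaling", {
  set.seed(4)
  mat <- matrix(rpois(40, 300), nrow = 10,
                dimnames = list(paste0("g", 1:10),
                                c("A_early", "A_late", "B_early",
                                  "B_late")))
  x <- tiny_screen(mat, paste0("T", 1:10), rms = rep(TRUE, 4),
                   tps = rep(c("early", "late"), 2))
  scaled <- mat %*% diag(c(3, 0.5, 10, 1))
  dimnames(scaled) <- dimnames(mat)
  xs <- tiny_screen(scaled, paste0("T", 1:10), rms = rep(TRUE, 4),
                    tps = rep(c("early", "late"), 2))
  expect_equal(fold_depletion(x), fold_depletion(xs))
})

test_that("specificity is RMS minus non-RMS depletion, rank 1 most specific", {
  # T1 depleted 4x in the RMS line only; T2 flat; a large flat guide
  # keeps the library composition (hence RPM) essentially constant
  mat <- matrix(c(400, 400, 1e6,   # R_early
                  100, 400, 1e6,   # R_late
                  400, 400, 1e6,   # N_early
                  400, 400, 1e6),  # N_late
                nrow = 3,
                dimnames = list(c("g1", "g2", "g3"),
                                c("R_early", "R_late", "N_early",
                                  "N_late")))
  x <- tiny_screen(mat, c("T1", "T2", "T3"),
                   rms = c(TRUE, TRUE, FALSE, FALSE),
                   tps = rep(c("early", "late"), 2))
  r <- specificity_rank(x, pseudocount = 1e-9)
  expect_equal(r$ranking$target[1], "T1")
  expect_equal(r$ranking$rank, 1:3)
  expect_equal(r$ranking$specificity[1], -2, tolerance = 0.01)
  expect_equal(r$ranking$specificity[r$ranking$target == "T2"], 0,
               tolerance = 0.01)
  # identical depletion in all lines gives specificity 0
  same <- tiny_screen(matrix(c(400, 100, 400, 100), nrow = 1,
                             dimnames = list("g1",
                                             c("R_early", "R_late",
                                               "N_early", "N_late"))),
                      "T1", rms = c(TRUE, TRUE, FALSE, FALSE),
                      tps = rep(c("early", "late"), 2))
  expect_equal(specificity_rank(same)$ranking$specificity, 0)
})

test_that("planted RMS-specific targets rank at the top", {
  cfg <- sim_config(seed = 19)
  scr <- simulate_screen(cfg)
  r <- specificity_rank(scr$counts)
  planted <- scr$truth$target[scr$truth$planted]
  top <- r$ranking$target[seq_along(planted)]
  expect_setequal(top, planted)
  # z-scores against the control-guide null flag planted targets
  z <- r$ranking$z[match(planted, r$ranking$target)]
  expect_true(all(z < -2))
})

test_that("control-guide null specificity is centred near zero", {
  # null generator: no planted dropout, so depth normalization adds no
  # composition bias to the control guides
  pooled <- unlist(lapply(1:20, function(s) {
    scr <- simulate_screen(sim_config(seed = 400 + s,
                                      screen = list(n_planted = 0L)))
    specificity_rank(scr$counts)$control_null
  }))
  expect_lt(abs(mean(pooled)), 0.1)
})

test_that("screen counts round-trip through TSV", {
  scr <- simulate_screen(sim_config(seed = 5))
  d <- tempfile(); dir.create(d)
  cdf <- data.frame(sgRNA = rownames(scr$counts$counts),
                    target = scr$counts$guide_info$target,
                    is_control = scr$counts$guide_info$is_control,
                    scr$counts$counts, check.names = FALSE)
  write.table(cdf, file.path(d, "c.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = rownames(scr$counts$sample_info),
                         scr$counts$sample_info),
              file.path(d, "s.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  x <- read_screen_counts(file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  expect_equal(x$counts, scr$counts$counts)
  expect_equal(x$sample_info$timepoint, scr$counts$sample_info$timepoint)
})
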
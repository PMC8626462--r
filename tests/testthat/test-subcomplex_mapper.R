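make_triple_calls <- function() {
  # 4 BRG1 peaks engineered to hit each definitional case
  brg1 <- ps("BRG1", c(100, 1000, 2000, 3000), c(700, 1600, 2600, 3600))
  dpf2 <- ps("DPF2", c(150, 2050), c(750, 2650))        # peaks 1 and 3
  pbrm1 <- ps("PBRM1", c(2100, 5000), c(2700, 5600))    # peak 3 + orphan
  brd9 <- ps("BRD9", 2000, 2600)                        # peak 3
  classify_subcomplexes(brg1, dpf2, pbrm1, brd9)
}

test_that("class labels follow the subunit-marker definitions", {
  cl <- make_triple_calls()
  expect_equal(as.character(cl$calls$class),
               c("BAF_only", "BRG1_unassigned", "BAF+PBAF+ncBAF",
                 "BRG1_unassigned"))
  expect_equal(length(cl$pbrm1_without_brg1), 1)
  # class counts always partition the BRG1 peaks
  expect_equal(sum(table(cl$calls$class)), 4)
})

test_that("classification is invariant under input record order", {
  brg1a <- ps("BRG1", c(3000, 100, 2000, 1000), c(3600, 700, 2600, 1600))
  cl1 <- make_triple_calls()
  cl2 <- classify_subcomplexes(brg1a,
                               ps("DPF2", c(2050, 150), c(2650, 750)),
                               ps("PBRM1", c(5000, 2100), c(5600, 2700)),
                               ps("BRD9", 2000, 2600))
  # calls come out coordinate-sorted, so intervals line up positionally
  expect_equal(cl1$calls[, c("chrom", "start", "end")],
               cl2$calls[, c("chrom", "start", "end")])
  expect_equal(cl1$calls$class, cl2$calls$class)
})

test_that("empty BRG1 set warns and returns empty calls", {
  empty <- peak_set("BRG1", character(0), integer(0), integer(0))
  expect_warning(
    cl <- classify_subcomplexes(empty, empty, empty, empty), "empty")
  expect_equal(nrow(cl$calls), 0)
})

test_that("classifier recovers a planted class multinomial within 3 SE", {
  probs <- c("BAF+PBAF+ncBAF" = 0.2, "BAF+PBAF" = 0.1, "BAF+ncBAF" = 0.1,
             "PBAF+ncBAF" = 0.05, "BAF_only" = 0.25, "PBAF_only" = 0.15,
             "ncBAF_only" = 0.05, "BRG1_unassigned" = 0.1)
  cfg <- sim_config(seed = 303, n_sites = 1000L, class_probs = probs)
  sim <- simulate_peaksets(cfg)
  cl <- classify_subcomplexes(sim$peaksets$BRG1, sim$peaksets$DPF2,
                              sim$peaksets$PBRM1, sim$peaksets$BRD9)
  est <- table(cl$calls$class) / 1000
  for (k in names(probs)) {
    se <- sqrt(probs[k] * (1 - probs[k]) / 1000)
    expect_lt(abs(est[[k]] - probs[k]), 3 * se + 1e-12)
  }
  # and the calls agree with the generator's per-site truth exactly
  truth <- setNames(sim$truth$class, sim$truth$site)
  expect_equal(as.character(cl$calls$class),
               unname(truth[cl$calls$peak]))
})

test_that("cooccupancy fractions hit the definitional endpoints", {
  cl <- make_triple_calls()
  none <- list(P3F = peak_set("P3F", character(0), integer(0), integer(0)))
  co0 <- cooccupancy_fractions(cl, none)
  expect_true(all(co0$fractions[!is.na(co0$fractions)] == 0))
  # empty classes report NA, not 0
  expect_true(is.na(co0$fractions["PBAF_only", "P3F"]))
  # a CRTF sitting exactly on the BAF_only site gives fraction 1
  baf_only <- cl$calls[cl$calls$class == "BAF_only", ]
  crtf <- list(P3F = ps("P3F", baf_only$start, baf_only$end))
  co1 <- cooccupancy_fractions(cl, crtf)
  expect_equal(co1$fractions["BAF_only", "P3F"], 1)
})

test_that("cooccupancy fractions are monotone in min_bp relaxation", {
  cfg <- sim_config(seed = 99, n_sites = 300L)
  sim <- simulate_peaksets(cfg)
  cl1 <- classify_subcomplexes(sim$peaksets$BRG1, sim$peaksets$DPF2,
                               sim$peaksets$PBRM1, sim$peaksets$BRD9,
                               min_bp = 1L)
  crtfs <- sim$peaksets[c("P3F", "MYOD1", "MYCN")]
  f1 <- cooccupancy_fractions(cl1, crtfs, min_bp = 1L)$fractions
  f200 <- cooccupancy_fractions(cl1, crtfs, min_bp = 200L)$fractions
  ok <- !is.na(f1) & !is.na(f200)
  expect_true(all(f1[ok] >= f200[ok]))
})

test_that("planted CRTF Bernoulli rates are recovered within 3 SE", {
  probs <- matrix(0.0, nrow = 8, ncol = 1,
                  dimnames = list(subcomplex_classes(), "P3F"))
  probs["BAF_only", ] <- 0.6
  probs["PBAF_only", ] <- 0.05
  cfg <- sim_config(seed = 77, n_sites = 2000L,
                    class_probs = c("BAF+PBAF+ncBAF" = 0, "BAF+PBAF" = 0,
                                    "BAF+ncBAF" = 0, "PBAF+ncBAF" = 0,
                                    "BAF_only" = 0.5, "PBAF_only" = 0.5,
                                    "ncBAF_only" = 0,
                                    "BRG1_unassigned" = 0),
                    crtf_probs = probs)
  sim <- simulate_peaksets(cfg)
  cl <- classify_subcomplexes(sim$peaksets$BRG1, sim$peaksets$DPF2,
                              sim$peaksets$PBRM1, sim$peaksets$BRD9)
  co <- cooccupancy_fractions(cl, sim$peaksets["P3F"])
  for (k in c("BAF_only", "PBAF_only")) {
    n <- co$class_sizes[[k]]
    p <- probs[k, 1]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(co$fractions[k, "P3F"] - p), 3 * se)
  }
})

test_that("state enrichment evaluates the log-ratio of partitions", {
  seg1 <- state_segmentation("chr1", 0, 1000, "all", c(chr1 = 1000))
  pk <- ps("A", c(100, 500), c(200, 600))
  e1 <- state_enrichment(pk, seg1)
  expect_equal(e1$log2_enrichment[e1$state == "all"], 0)
  # all peaks in a state covering 10% of the segmented genome
  seg2 <- state_segmentation("chr1", c(0, 100), c(100, 1000),
                             c("hot", "cold"), c(chr1 = 1000))
  pk2 <- ps("A", c(10, 40, 60), c(30, 55, 90))
  e2 <- state_enrichment(pk2, seg2)
  expect_equal(e2$log2_enrichment[e2$state == "hot"], log2(1 / 0.1))
  # enlarging a state's share with peaks fixed strictly lowers enrichment
  seg3 <- state_segmentation("chr1", c(0, 200), c(200, 1000),
                             c("hot", "cold"), c(chr1 = 1000))
  e3 <- state_enrichment(pk2, seg3)
  expect_lt(e3$log2_enrichment[e3$state == "hot"],
            e2$log2_enrichment[e2$state == "hot"])
})

test_that("uniform peaks give near-zero enrichment at scale", {
  set.seed(202)
  n <- 50000
  start <- sample.int(999000, n, replace = TRUE)
  pk <- suppressWarnings(peak_set("U", rep("chr1", n), start, start + 10))
  # 4 states of 25% each tiling the chromosome
  seg <- state_segmentation("chr1", c(0, 250000, 500000, 750000),
                            c(250000, 500000, 750000, 1000000),
                            c("s1", "s2", "s3", "s4"), c(chr1 = 1e6))
  e <- state_enrichment(pk, seg)
  expect_true(all(abs(e$log2_enrichment[e$state != "none"]) < 0.2))
})

test_that("gene assignment respects the window boundary", {
  tss <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                    tss = c(5000, 900000), strand = "+")
  # peak 1 midpoint exactly at G1 TSS; peak 2 midpoint at TSS+window+1
  pk <- ps("A", c(4950, 5000 + 50001 - 50), c(5050, 5000 + 50001 + 50))
  asn <- assign_peaks_to_genes(pk, tss, window_bp = 50000L)
  expect_equal(asn$gene, "G1")
  expect_equal(asn$n_peaks, 1L)
  expect_equal(asn$distance, 0)
})

test_that("noiseless planted binding is recovered exactly", {
  set.seed(15)
  n_genes <- 100
  tss <- data.frame(gene = sprintf("G%03d", 1:n_genes), chrom = "chr1",
                    tss = seq(2e5, by = 2e5, length.out = n_genes),
                    strand = "+")
  bound <- sort(sample(n_genes, 40))
  pk <- ps("A", tss$tss[bound] - 300, tss$tss[bound] + 300)
  asn <- assign_peaks_to_genes(pk, tss, window_bp = 50000L)
  expect_equal(asn$gene, tss$gene[bound])
})

test_that("expression summaries use median and bootstrap CI", {
  deg <- setNames(rep(0, 20), paste0("G", 1:20))
  r0 <- expression_by_occupancy(deg, list(all = names(deg)), B = 200)
  expect_equal(r0$summary$median, 0)
  expect_equal(r0$summary$ci_lo, 0)
  expect_equal(r0$summary$ci_hi, 0)
  deg2 <- setNames(c(1, 2, 3), c("a", "b", "c"))
  r2 <- expression_by_occupancy(deg2, list(g = c("a", "b", "c")), B = 100)
  expect_equal(r2$summary$median, 2)
  # empty group: n = 0, no summary
  re <- expression_by_occupancy(deg2, list(none = "zzz"), B = 10)
  expect_equal(re$summary$n, 0L)
  expect_true(is.na(re$summary$median))
})

test_that("a planted group shift is recovered by the group medians", {
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    deg <- setNames(c(rnorm(500, 0.8, 1), rnorm(500, 0, 1)),
                    sprintf("G%04d", 1:1000))
    r <- expression_by_occupancy(deg,
                                 list(shift = names(deg)[1:500],
                                      null = names(deg)[501:1000]),
                                 B = 50, seed = s)
    d <- r$summary$median[1] - r$summary$median[2]
    if (d >= 0.6 && d <= 1.0) hits <- hits + 1
  }
  expect_gte(hits, 28)
})
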
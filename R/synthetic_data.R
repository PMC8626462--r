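# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes, plus machine-readable ground truth, so the full
# pipeline runs and is validated without any external download.
#
# One root seed fans out deterministically to per-generator child seeds;
# the same seed and config give byte-identical outputs.

#' Deterministic child seed from a root seed and a stream name
#'
#' @param seed Root integer seed.
#' @param name Stream name (e.g. "peaksets").
#' @return Integer seed below 2^31.
#' @export
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Default simulation configuration
#'
#' Defaults describe a compact but structurally realistic FP-RMS-like
#' study: a 3 x 10 Mb toy genome; 600-bp BRG1-anchored sites with a fixed
#' subcomplex class multinomial; CRTF co-binding concentrated at
#' BAF-containing classes; lognormal occupancy; spike-in libraries at
#' mean depth 100 reads/site with 10% spike chromatin; a 60-domain screen
#' with 5 guides/target and 5 planted RMS-specific dependencies at
#' log2 effect -2 (negative-binomial dispersion 0.2); qPCR Ct noise of
#' 0.1 cycles; a 500-protein BioID matrix with 20 planted 8-fold
#' interactors and intensity-dependent missingness.
#'
#' @param seed Root seed (mandatory).
#' @param ... Overrides for any top-level field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = c(chrS1 = 1e7, chrS2 = 1e7, chrS3 = 1e7),
    n_sites = 2000L,
    site_width = 600L,
    jitter_bp = 100L,
    class_probs = c("BAF+PBAF+ncBAF" = 0.2, "BAF+PBAF" = 0.1,
                    "BAF+ncBAF" = 0.1, "PBAF+ncBAF" = 0.05,
                    "BAF_only" = 0.25, "PBAF_only" = 0.15,
                    "ncBAF_only" = 0.05, "BRG1_unassigned" = 0.1),
    crtf_probs = local({
      m <- matrix(0.05, nrow = 8, ncol = 3,
                  dimnames = list(subcomplex_classes(),
                                  c("P3F", "MYOD1", "MYCN")))
      m["BAF_only", ] <- c(0.6, 0.5, 0.4)
      m["BAF+PBAF+ncBAF", ] <- c(0.5, 0.5, 0.5)
      m["BAF+ncBAF", ] <- c(0.4, 0.4, 0.35)
      m["BAF+PBAF", ] <- c(0.3, 0.3, 0.3)
      m
    }),
    n_pbrm1_solo = 200L,
    signal_meanlog = 4, signal_sdlog = 0.8,
    copula_rho = 0.5,
    depth = 100,
    spike_fraction = 0.1,
    effect_log2 = 1.0,
    screen = list(n_targets = 60L, guides_per_target = 5L,
                  n_control_guides = 30L, n_planted = 5L, effect = -2,
                  dispersion = 0.2, depth = 500,
                  rms_lines = c("RH4", "RH30"),
                  nonrms_lines = c("HEK293T", "U2OS"),
                  reps_per_timepoint = 2L),
    qpcr = list(baseline_ct = 20, noise_sd = 0.1, n_bio = 3L, n_tech = 3L),
    proteomics = list(n_proteins = 500L, n_hits = 20L, effect_log2 = 3,
                      noise_sd = 0.5, baseline_mean = 20, baseline_sd = 2,
                      miss_slope = 1.2, miss_midpoint = 16,
                      n_samples_per_group = 4L, n_forced_missing = 5L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "sim_config")
}

# Non-overlapping site placement on a slotted genome: sites are assigned
# to disjoint slots wide enough that jittered subunit/CRTF peaks from
# neighbouring sites can never touch, then jittered within the slot.
.place_sites <- function(cfg, n, seed_name = "sites") {
  slot <- cfg$site_width + 4L * cfg$jitter_bp + 400L
  per_chr <- floor(cfg$genome / slot)
  total <- sum(per_chr)
  if (n > total)
    stop("genome too small for ", n, " sites; enlarge cfg$genome",
         call. = FALSE)
  .with_seed(child_seed(cfg$seed, seed_name), {
    idx <- sort(sample.int(total, n))
    chr_of <- rep(names(per_chr), per_chr)
    offset <- c(0, cumsum(per_chr))[-length(per_chr) - 1L]
    names(offset) <- names(per_chr)
    slot_in_chr <- idx - offset[chr_of[idx]]
    start <- (slot_in_chr - 1L) * slot + 2L * cfg$jitter_bp + 100L +
      sample.int(200L, n, replace = TRUE)
    data.frame(chrom = chr_of[idx], start = start,
               end = start + cfg$site_width, stringsAsFactors = FALSE)
  })
}

.jitter_interval <- function(df, jitter_bp) {
  sh <- sample.int(2L * jitter_bp + 1L, nrow(df), replace = TRUE) -
    jitter_bp - 1L
  data.frame(chrom = df$chrom, start = df$start + sh, end = df$end + sh)
}

#' Simulate subunit and CRTF peak sets with planted classes
#'
#' Each site draws a latent subcomplex class from `class_probs`; a BRG1
#' peak is placed at every site and DPF2/PBRM1/BRD9 peaks per the class's
#' Boolean triple (jittered by at most `jitter_bp`, preserving overlap);
#' CRTF peaks are placed per the class x factor Bernoulli matrix
#' `crtf_probs`. Standalone PBRM1 peaks (no BRG1) model PBAF-only
#' promoter binding.
#'
#' @param cfg A [sim_config()].
#' @return List: `$peaksets` (named list of `PeakSet`: BRG1, DPF2, PBRM1,
#'   BRD9 and one per CRTF), `$truth` data.frame (site = BRG1 peak name,
#'   class, one indicator column per CRTF).
#' @export
simulate_peaksets <- function(cfg) {
  sites <- .place_sites(cfg, cfg$n_sites + cfg$n_pbrm1_solo)
  .with_seed(child_seed(cfg$seed, "peaksets"), {
    take <- sort(sample.int(nrow(sites), cfg$n_sites))
    main <- sites[take, , drop = FALSE]
    solo <- sites[-take, , drop = FALSE]
    cls <- sample(names(cfg$class_probs), cfg$n_sites, replace = TRUE,
                  prob = cfg$class_probs)
    has_dpf2 <- cls %in% c("BAF+PBAF+ncBAF", "BAF+PBAF", "BAF+ncBAF",
                           "BAF_only")
    has_pbrm1 <- cls %in% c("BAF+PBAF+ncBAF", "BAF+PBAF", "PBAF+ncBAF",
                            "PBAF_only")
    has_brd9 <- cls %in% c("BAF+PBAF+ncBAF", "BAF+ncBAF", "PBAF+ncBAF",
                           "ncBAF_only")
    nm <- sprintf("site_%05d", seq_len(cfg$n_sites))
    sig <- function(n) rlnorm(n, cfg$signal_meanlog, cfg$signal_sdlog)
    brg1 <- peak_set("BRG1", main$chrom, main$start, main$end, name = nm,
                     signal = sig(cfg$n_sites))
    sub_ps <- function(fac, sel) {
      d <- .jitter_interval(main[sel, , drop = FALSE], cfg$jitter_bp)
      peak_set(fac, d$chrom, d$start, d$end,
               name = sprintf("%s_%s", fac, nm[sel]),
               signal = sig(sum(sel)))
    }
    dpf2 <- sub_ps("DPF2", has_dpf2)
    brd9 <- sub_ps("BRD9", has_brd9)
    # PBRM1: anchored peaks plus standalone sites
    pb_anchor <- .jitter_interval(main[has_pbrm1, , drop = FALSE],
                                  cfg$jitter_bp)
    pbrm1 <- peak_set("PBRM1",
                      c(pb_anchor$chrom, solo$chrom),
                      c(pb_anchor$start, solo$start),
                      c(pb_anchor$end, solo$end),
                      name = c(sprintf("PBRM1_%s", nm[has_pbrm1]),
                               sprintf("PBRM1_solo_%04d",
                                       seq_len(nrow(solo)))),
                      signal = sig(sum(has_pbrm1) + nrow(solo)))
    crtfs <- colnames(cfg$crtf_probs)
    truth <- data.frame(site = nm, class = cls,
                        stringsAsFactors = FALSE)
    crtf_sets <- list()
    for (f in crtfs) {
      p <- cfg$crtf_probs[cls, f]
      bound <- runif(cfg$n_sites) < p
      truth[[f]] <- bound
      crtf_sets[[f]] <- sub_ps(f, bound)
    }
    list(peaksets = c(list(BRG1 = brg1, DPF2 = dpf2, PBRM1 = pbrm1,
                           BRD9 = brd9), crtf_sets),
         truth = truth)
  })
}

#' Simulate spike-in ChIP libraries at a fixed site set
#'
#' Per-site weights are lognormal and shared across conditions; raw
#' counts are `Poisson(depth * weight * 2^effect)`. The spike-mapped
#' total reflects the constant chromatin input: it is derived from the
#' expected baseline (no-effect) library size as
#' `round(spike_fraction * baseline / (1 - spike_fraction))`, so a
#' genuine occupancy gain is not normalized away.
#'
#' @param cfg A [sim_config()].
#' @param sites Character vector of site names (or a `PeakSet`).
#' @param condition_effects Named list: condition -> either a single
#'   log2 effect applied to all sites, or a named per-site effect vector
#'   (unnamed sites get 0).
#' @return List: `$libraries` (named list of `SpikeInCounts`), `$truth`
#'   data.frame (site, weight, one effect column per condition).
#' @export
simulate_chiprx <- function(cfg, sites, condition_effects) {
  if (inherits(sites, "PeakSet")) sites <- as.data.frame(sites)$name
  stopifnot(length(sites) > 0L)
  .with_seed(child_seed(cfg$seed, "chiprx"), {
    n <- length(sites)
    w <- rlnorm(n, 0, 0.5)
    w <- w / mean(w)
    names(w) <- sites
    baseline <- cfg$depth * sum(w)
    truth <- data.frame(site = sites, weight = w,
                        stringsAsFactors = FALSE)
    libs <- list()
    for (cond in names(condition_effects)) {
      eff <- condition_effects[[cond]]
      evec <- setNames(numeric(n), sites)
      if (is.null(names(eff)) && length(eff) == 1L) evec[] <- eff
      else evec[names(eff)] <- eff
      mu <- cfg$depth * w * 2^evec
      raw <- rpois(n, mu)
      names(raw) <- sites
      if (cfg$spike_fraction <= 0) {
        spike <- 0
      } else {
        spike <- round(cfg$spike_fraction * baseline /
                         (1 - cfg$spike_fraction))
      }
      libs[[cond]] <- spikein_counts(
        library_id = cond, condition = cond, counts = raw,
        human_mapped_total = ceiling(sum(raw) * 1.25) + 1,
        spike_mapped_total = spike)
      truth[[paste0("effect_", cond)]] <- unname(evec)
    }
    list(libraries = libs, truth = truth)
  })
}

#' Draw coupled anchor/partner signals from a Gaussian copula
#'
#' Utility for quartile-stratification checks: two lognormal-margin
#' signal vectors with latent Gaussian correlation `copula_rho`.
#'
#' @param cfg A [sim_config()].
#' @param n Number of peaks.
#' @return List with named vectors `$anchor` and `$partner`.
#' @export
simulate_coupled_signals <- function(cfg, n = 2000L) {
  .with_seed(child_seed(cfg$seed, "copula"), {
    z1 <- rnorm(n)
    z2 <- cfg$copula_rho * z1 + sqrt(1 - cfg$copula_rho^2) * rnorm(n)
    nm <- sprintf("peak_%05d", seq_len(n))
    list(anchor = setNames(exp(cfg$signal_meanlog +
                                 cfg$signal_sdlog * z1), nm),
         partner = setNames(exp(cfg$signal_meanlog +
                                  cfg$signal_sdlog * z2), nm))
  })
}

#' Simulate a pooled CRISPR domain screen
#'
#' Early counts are negative binomial at the configured depth; late
#' counts multiply the mean by `2^LFC`, where LFC equals the planted
#' effect for planted targets in RMS lines and 0 otherwise (controls
#' always 0).
#'
#' @param cfg A [sim_config()].
#' @return List: `$counts` (`ScreenCounts`), `$truth` data.frame (target,
#'   planted, effect).
#' @export
simulate_screen <- function(cfg) {
  sc <- cfg$screen
  .with_seed(child_seed(cfg$seed, "screen"), {
    targets <- sprintf("DOM%03d", seq_len(sc$n_targets))
    planted <- sample(targets, sc$n_planted)
    guides <- c(
      sprintf("sg_%s_%d", rep(targets, each = sc$guides_per_target),
              seq_len(sc$guides_per_target)),
      sprintf("sg_CTRL_%d", seq_len(sc$n_control_guides)))
    gi <- data.frame(
      target = c(rep(targets, each = sc$guides_per_target),
                 rep("control", sc$n_control_guides)),
      is_control = c(rep(FALSE, sc$n_targets * sc$guides_per_target),
                     rep(TRUE, sc$n_control_guides)),
      row.names = guides)
    lines <- c(sc$rms_lines, sc$nonrms_lines)
    rms <- c(rep(TRUE, length(sc$rms_lines)),
             rep(FALSE, length(sc$nonrms_lines)))
    si_rows <- list()
    cols <- list()
    for (k in seq_along(lines)) {
      lfc <- ifelse(gi$target %in% planted & rms[k], sc$effect, 0)
      for (r in seq_len(sc$reps_per_timepoint)) {
        for (tp in c("early", "late")) {
          mu <- if (tp == "early") rep(sc$depth, nrow(gi))
                else sc$depth * 2^lfc
          id <- sprintf("%s_%s_r%d", lines[k], tp, r)
          cols[[id]] <- rnbinom(nrow(gi), size = 1 / sc$dispersion,
                                mu = mu)
          si_rows[[id]] <- data.frame(cell_line = lines[k], rms = rms[k],
                                      timepoint = tp, row.names = id)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- guides
    # guard against an all-zero guide column pathologies at tiny depth
    counts[counts < 0] <- 0L
    x <- screen_counts(counts, gi, do.call(rbind, si_rows))
    truth <- data.frame(target = targets,
                        planted = targets %in% planted,
                        effect = ifelse(targets %in% planted, sc$effect, 0))
    list(counts = x, truth = truth)
  })
}

#' Simulate qRT-PCR Ct tables from known fold changes
#'
#' `Ct = baseline_ct - log2(abundance) + N(0, noise_sd)`; the reference
#' assay has abundance 1 in every condition, the target's abundance in
#' each condition is its true fold change relative to the control.
#'
#' @param cfg A [sim_config()].
#' @param true_fold_changes Named numeric vector, condition -> fold
#'   change (> 0); must include the control at 1 (added if absent as
#'   `"control"`).
#' @return List: `$ct` data.frame in [relative_expression()] layout,
#'   `$truth` the fold-change vector.
#' @export
simulate_qpcr <- function(cfg, true_fold_changes) {
  stopifnot(all(true_fold_changes > 0))
  q <- cfg$qpcr
  if (!any(true_fold_changes == 1))
    true_fold_changes <- c(control = 1, true_fold_changes)
  .with_seed(child_seed(cfg$seed, "qpcr"), {
    rows <- list()
    for (cond in names(true_fold_changes)) {
      for (b in seq_len(q$n_bio)) {
        for (role in c("target", "reference")) {
          ab <- if (role == "target") true_fold_changes[[cond]] else 1
          ct <- q$baseline_ct - log2(ab) +
            rnorm(q$n_tech, 0, q$noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, replicate = b, role = role, ct = ct)
        }
      }
    }
    list(ct = do.call(rbind, rows), truth = true_fold_changes)
  })
}

#' Simulate a BioID intensity matrix with planted interactors
#'
#' Log2 intensities are `baseline + effect + N(0, noise_sd)` with the
#' planted effect added in the bait group for hit proteins; an entry is
#' missing with probability `plogis(-miss_slope * (x - miss_midpoint))`,
#' so low intensities are missing more often (missing not at random).
#' The first `n_forced_missing` hit proteins are forced fully missing in
#' the control group to exercise the pseudo-fold-change path.
#'
#' @param cfg A [sim_config()].
#' @return List: `$matrix` (`IntensityMatrix`), `$truth` data.frame
#'   (protein, hit, effect, forced_missing_control).
#' @export
simulate_proteomics <- function(cfg) {
  p <- cfg$proteomics
  .with_seed(child_seed(cfg$seed, "proteomics"), {
    prot <- sprintf("PROT%04d", seq_len(p$n_proteins))
    hits <- prot[seq_len(p$n_hits)]
    forced <- hits[seq_len(min(p$n_forced_missing, p$n_hits))]
    ns <- p$n_samples_per_group
    samples <- c(sprintf("bait_%d", seq_len(ns)),
                 sprintf("control_%d", seq_len(ns)))
    groups <- setNames(rep(c("bait", "control"), each = ns), samples)
    base <- rnorm(p$n_proteins, p$baseline_mean, p$baseline_sd)
    x <- matrix(NA_real_, p$n_proteins, 2L * ns,
                dimnames = list(prot, samples))
    for (j in seq_len(2L * ns)) {
      eff <- if (groups[samples[j]] == "bait")
        ifelse(prot %in% hits, p$effect_log2, 0) else 0
      v <- base + eff + rnorm(p$n_proteins, 0, p$noise_sd)
      miss <- runif(p$n_proteins) <
        plogis(-p$miss_slope * (v - p$miss_midpoint))
      v[miss] <- NA_real_
      x[, j] <- v
    }
    x[forced, groups[colnames(x)] == "control"] <- NA_real_
    m <- intensity_matrix(2^x, setNames(rep(3L, p$n_proteins), prot),
                          groups)
    truth <- data.frame(protein = prot, hit = prot %in% hits,
                        effect = ifelse(prot %in% hits, p$effect_log2, 0),
                        forced_missing_control = prot %in% forced)
    list(matrix = m, truth = truth)
  })
}
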
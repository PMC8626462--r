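# Orchestration: runs the stages in dependency order over a run
# directory, entirely from a config (YAML file or list). Every run writes
# a manifest capturing the config, package version and input/output
# checksums; identical config + inputs give byte-identical outputs.

.default_stages <- c("simulate", "classify", "cooccupy", "state-enrich",
                     "chiprx", "invade", "integrate-expression", "screen",
                     "qpcr", "bioid")

#' Default pipeline configuration
#'
#' @param seed Root seed.
#' @param ... Overrides (any [sim_config()] field, plus `min_bp`,
#'   `pseudocount`, `fc_threshold`, `p_threshold`, `window_bp`,
#'   `bootstrap_B`).
#' @return Config list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  dots <- list(...)
  params <- list(min_bp = 1L, pseudocount = 0.5, screen_pseudocount = 1,
                 fc_threshold = 2.5, p_threshold = 0.05,
                 window_bp = 50000L, bootstrap_B = 2000L)
  keep <- intersect(names(dots), names(params))
  params[keep] <- dots[keep]
  sim <- do.call(sim_config, c(list(seed = seed),
                               dots[setdiff(names(dots), names(params))]))
  c(list(seed = as.integer(seed)), params, list(sim = unclass(sim)))
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    base <- pipeline_config(seed = cfg$seed %||% 1L)
    for (nm in names(cfg)) {
      if (nm == "sim" && is.list(cfg$sim))
        base$sim[names(cfg$sim)] <- cfg$sim
      else base[[nm]] <- cfg[[nm]]
    }
    base
  } else config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.log_stage <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

# Simple uniform-state segmentation over the toy genome, for the
# state-enrichment stage of simulated runs.
.simulate_segmentation <- function(sim) {
  .with_seed(child_seed(sim$seed, "segmentation"), {
    states <- c("active_promoter", "bivalent_promoter", "enhancer",
                "transcribed", "quiescent")
    probs <- c(0.05, 0.03, 0.12, 0.3, 0.5)
    binw <- 5000L
    rows <- lapply(names(sim$genome), function(ch) {
      n <- floor(sim$genome[[ch]] / binw)
      data.frame(chrom = ch, start = (seq_len(n) - 1L) * binw,
                 end = seq_len(n) * binw,
                 state = sample(states, n, TRUE, probs))
    })
    do.call(rbind, rows)
  })
}

# Planted expression shifts keyed to peak-level truth: genes at
# MYCN-co-occupied BRG1 sites shift by -effect_log2 (repression after
# remodeler loss), others sit at 0.
.simulate_expression <- function(sim, truth, sites_df) {
  .with_seed(child_seed(sim$seed, "expression"), {
    n <- nrow(truth)
    gene <- sprintf("GENE%05d", seq_len(n))
    mid <- floor((sites_df$start + sites_df$end) / 2)
    shift <- ifelse(truth$MYCN, -sim$effect_log2, 0)
    data.frame(gene = gene, chrom = sites_df$chrom, tss = mid + 1L,
               strand = "+", site = truth$site,
               log2fc = shift + rnorm(n, 0, 0.5),
               stringsAsFactors = FALSE)
  })
}

#' Run the analysis pipeline
#'
#' Stages (in dependency order): `simulate` writes all synthetic inputs
#' and ground truth; `classify` calls subcomplex classes on the BRG1
#' anchor; `cooccupy` tabulates CRTF co-binding per class;
#' `state-enrich` ranks chromatin states per binding category; `chiprx`
#' writes RRPM/RPMPR tables; `invade` runs differential occupancy at
#' co-occupied sites; `integrate-expression` summarizes expression change
#' by occupancy group; `screen` ranks domains by RMS-specific depletion;
#' `qpcr` computes relative expression and competition trajectories;
#' `bioid` runs the proteomics enrichment.
#'
#' @param config A config list from [pipeline_config()] or a YAML file
#'   path.
#' @param outdir Run directory (created; outputs only under here).
#' @param stages Character vector of stages; default all.
#' @param verbose Log stage boundaries (default TRUE).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         outdir = "bafmap_run",
                         stages = .default_stages, verbose = TRUE) {
  cfg <- .read_config(config)
  sim <- do.call(sim_config, cfg$sim[!vapply(cfg$sim, is.null, TRUE)])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bad <- setdiff(stages, .default_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  pth <- function(...) file.path(outdir, ...)
  outputs <- character(0)
  rec <- function(p) { outputs <<- c(outputs, p); p }

  run_stage <- function(stage, fn) {
    .log_stage(verbose, stage, "start")
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .log_stage(verbose, stage, "done")
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    ps <- simulate_peaksets(sim)
    for (nm in names(ps$peaksets))
      rec(write_peaks(ps$peaksets[[nm]], pth(paste0(nm, ".bed")), "bed"))
    rec(.tsv(ps$truth, pth("truth_sites.tsv")))
    sites_df <- as.data.frame(ps$peaksets$BRG1)
    co <- ps$truth$site[ps$truth$MYCN]
    cx <- simulate_chiprx(sim, ps$truth$site,
                          list(control = 0,
                               treated = setNames(
                                 rep(sim$effect_log2, length(co)), co)))
    for (nm in names(cx$libraries))
      rec(write_spikein_counts(cx$libraries[[nm]],
                               pth(paste0("chiprx_", nm, ".tsv"))))
    rec(.tsv(cx$truth, pth("truth_chiprx.tsv")))
    seg <- .simulate_segmentation(sim)
    write.table(seg, pth("segmentation.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    rec(pth("segmentation.bed"))
    write.table(data.frame(names(sim$genome), unname(sim$genome)),
                pth("chrom.sizes"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    rec(pth("chrom.sizes"))
    scr <- simulate_screen(sim)
    cdf <- data.frame(sgRNA = rownames(scr$counts$counts),
                      target = scr$counts$guide_info$target,
                      is_control = scr$counts$guide_info$is_control,
                      scr$counts$counts, check.names = FALSE)
    rec(.tsv(cdf, pth("screen_counts.tsv")))
    rec(.tsv(data.frame(sample = rownames(scr$counts$sample_info),
                        scr$counts$sample_info),
             pth("screen_samples.tsv")))
    rec(.tsv(scr$truth, pth("truth_screen.tsv")))
    qp <- simulate_qpcr(sim, c(control = 1, sgBRG1 = 4, sgBRD9 = 0.5))
    rec(.tsv(qp$ct, pth("qpcr_ct.tsv")))
    traj <- data.frame(condition = rep(c("sgScr", "sgBRG1"), each = 4),
                       day = rep(c(2, 5, 7, 12), 2),
                       pct_rfp = c(40, 40, 41, 40, 40, 30, 18, 8))
    rec(.tsv(traj, pth("competition.tsv")))
    pr <- simulate_proteomics(sim)
    idf <- data.frame(protein = rownames(pr$matrix$intensities),
                      n_peptides = unname(pr$matrix$n_peptides),
                      pr$matrix$intensities, check.names = FALSE)
    rec(.tsv(idf, pth("bioid_intensities.tsv")))
    rec(.tsv(data.frame(sample = names(pr$matrix$groups),
                        condition = unname(pr$matrix$groups)),
             pth("bioid_groups.tsv")))
    rec(.tsv(pr$truth, pth("truth_bioid.tsv")))
    exp_df <- .simulate_expression(sim, ps$truth, sites_df)
    rec(.tsv(exp_df[, c("gene", "chrom", "tss", "strand")],
             pth("tss.tsv")))
    rec(.tsv(exp_df[, c("gene", "log2fc")], pth("deg.tsv")))
  })

  read_ps <- function(nm) read_peaks(pth(paste0(nm, ".bed")), "bed",
                                     factor = nm)

  calls <- NULL
  get_calls <- function() {
    if (is.null(calls))
      calls <<- classify_subcomplexes(read_ps("BRG1"), read_ps("DPF2"),
                                      read_ps("PBRM1"), read_ps("BRD9"),
                                      min_bp = cfg$min_bp)
    calls
  }

  if ("classify" %in% stages) run_stage("classify", function() {
    cl <- get_calls()
    rec(.tsv(cl$calls, pth("subcomplex_calls.tsv")))
    rec(.tsv(summary(cl), pth("subcomplex_summary.tsv")))
    invisible(lapply(export_class_beds(cl, pth("class_beds")), rec))
  })

  if ("cooccupy" %in% stages) run_stage("cooccupy", function() {
    cl <- get_calls()
    crtfs <- lapply(c("P3F", "MYOD1", "MYCN"), read_ps)
    names(crtfs) <- c("P3F", "MYOD1", "MYCN")
    co <- cooccupancy_fractions(cl, crtfs, min_bp = cfg$min_bp)
    rec(write_cooccupancy(co, pth("cooccupancy.tsv")))
    rec(.tsv(data.frame(factor = rownames(co$reverse), co$reverse,
                        check.names = FALSE),
             pth("cooccupancy_reverse.tsv")))
  })

  if ("state-enrich" %in% stages) run_stage("state-enrich", function() {
    seg <- read_state_segmentation(pth("segmentation.bed"),
                                   pth("chrom.sizes"))
    cl <- get_calls()
    brg1 <- read_ps("BRG1")
    cats <- list(
      PBRM1_alone = cl$pbrm1_without_brg1,
      BRG1_all = brg1,
      P3F = read_ps("P3F"), MYCN = read_ps("MYCN"),
      MYOD1 = read_ps("MYOD1"))
    cats <- Filter(function(p) length(p) > 0L, cats)
    tab <- state_enrichment_table(cats, seg)
    rec(.tsv(data.frame(state = rownames(tab), tab, check.names = FALSE),
             pth("state_enrichment.tsv")))
  })

  libs <- NULL
  get_libs <- function() {
    if (is.null(libs))
      libs <<- list(control = read_spikein_counts(pth("chiprx_control.tsv")),
                    treated = read_spikein_counts(pth("chiprx_treated.tsv")))
    libs
  }

  if ("chiprx" %in% stages) run_stage("chiprx", function() {
    lb <- get_libs()
    rr <- lapply(lb, rrpm_normalize)
    rp <- lapply(lb, rpmpr_normalize)
    rec(.tsv(data.frame(site = names(rr$control),
                        rrpm_control = unname(rr$control),
                        rrpm_treated = unname(rr$treated[names(rr$control)]),
                        rpmpr_control = unname(rp$control),
                        rpmpr_treated = unname(rp$treated[names(rr$control)])),
             pth("chiprx_normalized.tsv")))
  })

  if ("invade" %in% stages) run_stage("invade", function() {
    truth <- read.table(pth("truth_sites.tsv"), sep = "\t", header = TRUE)
    co_sites <- truth$site[truth$MYCN]
    lb <- get_libs()
    inv <- invasion_analysis(co_sites, lb$control, lb$treated,
                             pseudocount = cfg$pseudocount)
    rec(.tsv(inv$per_site, pth("invasion_per_site.tsv")))
    rec(.tsv(data.frame(n_sites = inv$n_sites,
                        median_delta = inv$median_delta,
                        fraction_increased = inv$fraction_increased,
                        p_value = inv$p_value),
             pth("invasion_summary.tsv")))
  })

  if ("integrate-expression" %in% stages)
    run_stage("integrate-expression", function() {
    cl <- get_calls()
    tss <- read_tss_table(pth("tss.tsv"))
    deg <- read.table(pth("deg.tsv"), sep = "\t", header = TRUE)
    mycn <- read_ps("MYCN")
    brg1 <- read_ps("BRG1")
    asn <- assign_peaks_to_genes(brg1, tss, window_bp = cfg$window_bp,
                                 calls = cl)
    with_mycn <- overlaps_any(brg1, mycn, cfg$min_bp)
    mycn_peaks <- names(with_mycn)[with_mycn]
    groups <- list(
      BRG1_only = asn$gene[!asn$nearest_peak %in% mycn_peaks],
      BRG1_MYCN = asn$gene[asn$nearest_peak %in% mycn_peaks])
    res <- expression_by_occupancy(deg, groups, B = cfg$bootstrap_B,
                                   seed = cfg$seed)
    rec(.tsv(res$summary, pth("expression_by_occupancy.tsv")))
    rec(.tsv(asn, pth("gene_assignments.tsv")))
  })

  if ("screen" %in% stages) run_stage("screen", function() {
    x <- read_screen_counts(pth("screen_counts.tsv"),
                            pth("screen_samples.tsv"))
    depl <- specificity_rank(x, pseudocount = cfg$screen_pseudocount)
    rec(write_ranking(depl, pth("screen_ranking.tsv")))
  })

  if ("qpcr" %in% stages) run_stage("qpcr", function() {
    ct <- read_ct_table(pth("qpcr_ct.tsv"))
    re <- relative_expression(ct, control_condition = "control")
    rec(.tsv(re$summary, pth("qpcr_expression.tsv")))
    traj <- read.table(pth("competition.tsv"), sep = "\t", header = TRUE)
    rec(.tsv(competition_trajectory(traj), pth("competition_normalized.tsv")))
  })

  if ("bioid" %in% stages) run_stage("bioid", function() {
    m <- read_intensity_matrix(pth("bioid_intensities.tsv"),
                               pth("bioid_groups.tsv"))
    res <- bioid_enrichment(m, bait = "bait", control = "control",
                            fc_threshold = cfg$fc_threshold,
                            p_threshold = cfg$p_threshold)
    rec(.tsv(as.data.frame(res), pth("bioid_enrichment.tsv")))
  })

  outputs <- sort(unique(outputs))
  sums <- tools::md5sum(outputs)
  # keyed by path relative to the run directory so manifests of identical
  # runs are byte-identical wherever the run directory lives
  pre <- paste0(outdir, .Platform$file.sep)
  names(sums) <- ifelse(startsWith(names(sums), pre),
                        substring(names(sums), nchar(pre) + 1L),
                        names(sums))
  manifest <- list(
    package = "bafmap",
    version = as.character(utils::packageVersion("bafmap")),
    stages = stages,
    config = cfg,
    checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
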
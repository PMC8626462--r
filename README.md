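# bafmap

Dissecting mSWI/SNF (BAF-family) subcomplex genomic occupancy and its
quantitative consequences in fusion-positive rhabdomyosarcoma (FP-RMS) and
similar core-regulatory-circuitry-driven cancers.

Mammalian SWI/SNF chromatin remodelers assemble into three subcomplexes that
share the BRG1/BRM ATPase but carry distinguishing subunits: canonical **BAF**
(DPF2), **PBAF** (PBRM1), and **ncBAF** (BRD9). Where each subcomplex sits on
the genome — and what happens to competing transcription factors such as MYCN
when the ATPase is removed — is read out by multi-subunit ChIP-seq,
spike-in-normalized ChIP (ChIP-Rx), domain-focused CRISPR screens, qPCR and
proximity proteomics. `bafmap` implements the computational core of that
tool-chain for analysts working downstream of alignment and peak calling:

- **Subcomplex deconvolution** — each BRG1-anchored peak receives the Boolean
  triple (DPF2, PBRM1, BRD9 overlap) and the derived 8-way class label
  (BAF = BRG1 ∧ DPF2, PBAF = BRG1 ∧ PBRM1, ncBAF = BRG1 ∧ BRD9), plus
  co-occupancy fractions with core-regulatory transcription factors (CRTFs:
  PAX3-FOXO1, MYOD1, MYCN), chromatin-state enrichment
  (log₂[peak fraction / genomic fraction] per chromHMM-style state), and
  expression stratified by occupancy class.
- **Spike-in quantification** — RRPM (reads per million exogenous-genome
  mapped reads; `signal = raw × 10⁶ / spike_total`) and RPMPR (reads per
  million peak reads; sums to 10⁶ per library), MYCN-quartile
  stratification, and differential occupancy
  `Δ = log₂((RRPM_treated + c) / (RRPM_control + c))` at co-occupied sites
  with a paired signed-rank test — the "enhancer invasion" readout.
- **Screen scoring** — per-sample depth normalization to RPM, per-guide
  `LFC = log₂((late + c)/(early + c))`, per-domain aggregation, and ranking
  by RMS-vs-non-RMS specificity with a control-guide empirical null.
- **Molecular quantification** — ChIP-qPCR
  `%recovery = 2^(Ct_input − log₂X − Ct_sample) × 100`, Drosophila-spike Ct
  correction, 2^(−ΔΔCt) fold changes with the SD > 0.5 technical-replicate
  outlier rule, and day-2-normalized competition trajectories.
- **Proximity proteomics** — peptide/missingness filtering, modified robust
  z-score normalization, empirical-Bayes moderated two-group tests,
  pseudo-fold-change imputation for proteins undetected in one condition,
  and volcano-rule hit calling (log₂FC > 2.5, p < 0.05).
- **Synthetic data** — seeded generators planting known subcomplex classes,
  co-binding rates, condition effects, guide depletion, Ct values and
  proteomic effects, so every stage is exercised and validated without any
  download.

## Worked example

```r
library(bafmap)

cfg  <- sim_config(seed = 7, n_sites = 2000)
sim  <- simulate_peaksets(cfg)
calls <- classify_subcomplexes(sim$peaksets$BRG1, sim$peaksets$DPF2,
                               sim$peaksets$PBRM1, sim$peaksets$BRD9)
calls
#> SubcomplexCalls: 2000 BRG1-anchored sites
#>
#>  BAF+PBAF+ncBAF        BAF+PBAF       BAF+ncBAF      PBAF+ncBAF        BAF_only
#>             407             202             200              88             520
#>       PBAF_only      ncBAF_only BRG1_unassigned
#>             291              73             219
#> PBRM1 without BRG1: 200 peaks

cooccupancy_fractions(calls, sim$peaksets[c("P3F", "MYOD1", "MYCN")])
#> CooccupancyTable (fraction of class sites bound):
#>                   P3F MYOD1  MYCN any_CRTF
#> BAF+PBAF+ncBAF  0.486 0.528 0.541    0.894
#> BAF+PBAF        0.252 0.312 0.342    0.634
#> BAF+ncBAF       0.405 0.395 0.370    0.770
#> PBAF+ncBAF      0.057 0.057 0.057    0.159
#> BAF_only        0.588 0.510 0.392    0.881
#> PBAF_only       0.038 0.038 0.055    0.127
#> ncBAF_only      0.110 0.041 0.068    0.219
#> BRG1_unassigned 0.032 0.050 0.032    0.114

# BRG1 loss with a planted +1 log2 MYCN gain at MYCN-co-occupied sites
co_sites <- sim$truth$site[sim$truth$MYCN]
cx <- simulate_chiprx(cfg, sim$truth$site,
                      list(sgScr  = 0,
                           sgBRG1 = setNames(rep(1, length(co_sites)),
                                             co_sites)))
invasion_analysis(co_sites, cx$libraries$sgScr, cx$libraries$sgBRG1)
#> InvasionResult: 600 sites (sgBRG1 vs sgScr)
#>   median delta = 1.000 log2, 99.8% of sites increased, p = 6.02e-100
```

The class table shows the planted subcomplex mixture recovered from peak
overlaps alone; the co-occupancy table shows CRTF binding concentrated at
BAF-containing classes, as planted; and the invasion analysis recovers the
planted +1 log₂ MYCN gain at co-occupied sites after BRG1 loss.

The full pipeline — simulation through classification, state enrichment,
ChIP-Rx, screen, qPCR and proteomics, with a manifest of checksums — runs as

```r
run_pipeline(pipeline_config(seed = 1), "my_run")
```

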
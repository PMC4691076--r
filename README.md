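# ampliqc

Quality control, simulation and variant triage for targeted amplicon
sequencing of critical oncology samples.

## The problem

Hotspot-panel sequencing of non-small-cell lung cancer material routinely has
to work with the worst DNA a lab sees: formalin-fixed paraffin-embedded
(FFPE) biopsies with heavily fragmented, chemically damaged template;
circulating free DNA (cfDNA) at sub-nanogram input that may need whole-genome
amplification (WGA) before library construction; and snap-frozen (SF) tissue
as the clean comparator. Getting a trustworthy variant list out of such
samples is as much a pre-analytic and post-analytic decision problem as a
sequencing one. `ampliqc` implements that decision workflow end to end for a
90-amplicon / 22-gene lung-and-colon hotspot panel:

* **Pre-analytic QC.** A multiplex-PCR assay amplifies 200, 300 and 400 bp
  GAPDH fragments from the sample and from an intact reference template. The
  **Average Yield Ratio** is the mean of the per-fragment yield ratios,

  `AYR = (1/3) * sum_L yield_sample(L) / yield_reference(L)`,  L in {200, 300, 400} bp,

  with degradation mapped as `(1 − AYR) · 100 %` (AYR 0.3 = 70 % degraded,
  the go/no-go boundary for library construction). Samples are routed to
  protocols: FFPE → 20 ng input, 22 + 5 PCR cycles; SF → 10 ng, 19 + 5;
  cfDNA < 1 ng → WGA then 10 ng, 19 + 5; cfDNA ≥ 1 ng → no WGA, 22 + 7.
  qPCR quantification against a log-linear standard curve
  (`Ct = intercept + slope · log10(q)`, efficiency `10^(−1/slope) − 1`) is
  included for cfDNA.

* **Simulation of the assay's failure modes** at pileup level: per-amplicon
  depth `Poisson(D · exp(−L/μ) · g(GC))`, where `μ` is the mean intact
  template length solved from the AYR, and `g` a piecewise-linear GC penalty;
  binomial allele counts with a uniform substitution error; and recurrent
  WGA insertion artifacts at homopolymer runs ≥ 5 bp.

* **Dual-caller triage.** Two desk-scale callers (a frequency-threshold
  caller and an exact-binomial caller with Phred 5/30 quality bands) feed a
  consensus cascade that filters on coverage (≥ 500×), limit of detection
  (allele fraction ≥ 5 %), WGA homopolymer-insertion artifacts and caller
  concordance, annotates against a COSMIC/dbSNP-style catalog, and routes
  discordant 5–20 % variants to pyrosequencing and > 20 % variants to Sanger
  sequencing.

* **Performance evaluation.** Confusion counts against a truth set;
  sensitivity, specificity and PPV with **Wilson score** 95 % confidence
  intervals (no continuity correction); and dilution-series limit-of-detection
  determination (smallest nominal allele fraction detected in a majority of
  replicates).

## Worked example

```r
library(ampliqc)
panel <- demo_panel()           # deterministic 90-amplicon demo panel
panel
#> amplicon_panel: 90 amplicons, 22 genes, reference 'ampliqc-demo-1'
#>   GC range 0.40-0.84; 5 homopolymer runs >= 5 bp

# pre-analytic QC of a degraded FFPE sample
ayr <- compute_ayr(yield_table(c(0.42, 0.30, 0.18), c(1, 1, 1)))
ayr
#> AYR 0.300 (pass at threshold 0.30), degradation 70.0%
library_plan("FFPE", ayr = ayr)
#> library_plan: FFPE, 20.0 ng input, 22 + 5 cycles

# simulate a 5% mutant at 1200x, call with both callers, triage
truth <- demo_dilution_truth(panel, af = 0.05)
res <- run_sample(panel, truth, sample_profile(mean_depth = 1200, seed = 3))
res$triaged[res$triaged$status == "confirmed",
            c("chrom", "pos", "ref", "alt", "af", "depth", "caller", "status")]
#>       chrom pos ref alt         af depth caller    status
#>  EGFR_locus 211   C   A 0.06124031  1290    A+B confirmed

# assay performance arithmetic: 24/25 recovered variants
wilson_interval(24, 25)
#> [1] 0.8045594 0.9929038
```

The confirmed row is the simulated p.Thr790Met-style variant: observed at
6.1 % allele fraction on 1290 reads, seen by both callers (`A+B`), above the
5 % LOD and the 500× coverage floor. The Wilson interval (80.5 %, 99.3 %) is
the 95 % CI on a 96 % sensitivity measured as 24 of 25.

A shell interface wrapping the same functions ships in `inst/cli/ampliqc`
(subcommands `qc`, `simulate`, `call`, `triage`, `coverage`, `evaluate`,
`lod`).

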
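---
title: "Models and design of the ampliqc workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the ampliqc workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliqc)
```

`ampliqc` implements a decision workflow for targeted amplicon sequencing of
degraded oncology samples: pre-analytic integrity scoring and routing, a
simulator of the assay's failure modes, two variant callers, a consensus
triage cascade, and assay performance evaluation. This vignette documents the
models, the tunable parameters, and the choices made where the design was
genuinely open.

## Pre-analytic integrity: the Average Yield Ratio

FFPE fixation fragments and cross-links DNA, so long amplifiable template is
depleted. The multiplex-PCR QC amplifies three GAPDH fragments (200, 300,
400 bp) from the sample and from an intact reference template; the Average
Yield Ratio is the arithmetic mean of the three sample/reference yield
ratios. The assay description speaks of a ratio "calculated for each
amplicon" and then works with a single number; the arithmetic mean is the
simplest reduction consistent with both statements and is what
`compute_ayr()` uses. Ratios above 1 are allowed (a warning is logged above
1.2) because capping would hide assay problems rather than flag them.

Degradation is reported as `(1 - AYR) * 100` percent, anchored by the
observation that AYR 0.3 corresponds to 70% degradation. AYR 0.3 is also the
library go/no-go boundary, and the boundary is inclusive: the 0.3 sample was
sequenced successfully while a heat-fragmented 0.2 sample failed, so
`ayr >= 0.3` passes.

Routing (`library_plan()`) follows the protocol table: FFPE 20 ng with
22 + 5 PCR cycles, snap-frozen 10 ng with 19 + 5, cfDNA below 1 ng routed
through whole-genome amplification (then 10 ng, 19 + 5), cfDNA at or above
1 ng enriched without WGA (22 + 7). The WGA boundary is strict ("less than
1 ng"), so exactly 1 ng does not trigger WGA. Spectrophotometric purity
(both 260/280 and 260/230 above 1.7) is a warning, never a blocker: the
decision criterion for degraded samples is the AYR alone.

qPCR quantification fits Ct against log10(quantity) by least squares;
efficiency is `10^(-1/slope) - 1` with an advisory band of [0.9, 1.1]
(logged, non-blocking — the source protocol is silent on acceptance).
Replicate Cts are averaged *before* interpolation, and a mean Ct more than 2
cycles outside the calibrated range produces an extrapolation warning but
still returns a value, since a concentration estimate is needed for routing
either way.

## The simulator

The simulator works at pileup level — per-site depth and allele counts —
because that is the unit the callers and the triage logic consume. Read-level
FASTQ/BAM emission, flow-space signal modeling, PCR duplicates and barcode
cross-talk are deliberately out of scope.

**Degradation-linked dropout.** Surviving template is modeled as
exponentially length-dependent: a fragment of length `L` is intact with
probability `exp(-L/mu)`. `mu` is solved from the AYR by bisection on the
defining equation `mean(exp(-L/mu)) = AYR` over the 200/300/400 bp ladder
(`mu_from_ayr()`, converged to well below 1e-6 in AYR; AYR 1 maps to
`mu = Inf`, i.e. no dropout). The functional form is this package's
construction — the source material states the correlation between
fragmentation and coverage only qualitatively — and the exponential is the
simplest single-parameter model consistent with the three-fragment ladder.

**GC penalty.** Coverage is scaled by `g(GC) = max(0, 1 - s*(GC - knee))`
with knee 0.60 and slope `s = 10/3`, chosen so that GC 0.75 halves coverage.
Per-amplicon depth is then `Poisson(mean_depth * exp(-L/mu) * g(GC))`.

**Allele counts.** At a truth-variant site the alternate count is
`Binomial(depth, af*(1-e) + (1-af)*e/3)`; every site receives error alleles
at `e/3` per non-reference base (`e` = 0.005 by default; the platform's true
error profile is not published, so a uniform substitution rate is used).
Counts are drawn as an exact multinomial via the chain rule, so allele counts
sum to depth at every site. All randomness flows through seeds carried in the
`sample_profile`, and the global RNG state is always restored.

**WGA artifacts.** Multiple-displacement amplification introduces recurrent
1-bp insertions in homopolymer runs of five or more bases. Eligible runs are
precomputed on the panel; each receives an artifact with probability
`wga_artifact_prob` (default 0.5 — no quantitative per-run rate is published,
so this free parameter is exposed in the profile) at an allele fraction
uniform on (0.01, 0.10), a range under which about 4/9 of artifacts fall
below the 5% LOD, matching the observed preponderance of sub-LOD artifacts.
Artifact *placement* is drawn from a panel-level stream (`artifact_seed`)
separate from the per-sample stream, so samples sharing an `artifact_seed`
show the same recurrent artifacts — the signature by which such artifacts
were recognized in practice. Insertions are left-aligned at creation
(anchored on the base preceding the run) and never overwrite a truth allele.

## The demo panel

The true commercial panel design is proprietary, so `demo_panel()` builds a
deterministic synthetic stand-in: 90 amplicons across the 22 lung/colon
genes, one mini-contig per gene, generated from a fixed internal seed so
coordinates never move. Two features are planted deliberately:

* The five recurrently under-covered amplicon identities (AKT1_1, FGFR3_2,
  NOTCH1_1, STK11_3, TP53_2) are modeled as long (250 bp), CpG-island-like
  targets with GC fixed at 0.836 (exact base counts, not expected values).
  Under the coverage model this makes them fully covered in intact samples
  but the first to fall below 500x as the AYR drops — the qualitative
  behavior reported for degraded FFPE — and makes amplicon-level uniformity
  respond to integrity (the test suite checks a Pearson correlation above
  0.8 across an AYR sweep of 0.2-0.9 at mean depth 6000, three seeds per
  step).
* Exactly five homopolymer runs of 5-7 bp sit in five other amplicons, so a
  WGA profile with artifact probability 1 yields exactly five recurrent
  insertion artifacts.

The remaining 85 amplicons are 100-160 bp with GC 0.40-0.55 and no runs of
five or more. `demo_catalog()` places COSMIC/dbSNP-style entries at fixed
offsets with reference alleles read off the generated reference, stored in
normalized form so keys always match normalized caller output. What the demo
panel does **not** emulate: real hotspot coordinates, primer chemistry,
strand effects, and inter-amplicon competition in multiplex PCR — so passing
tests demonstrate the decision logic, not concordance with any wet-lab run.

## Callers and normalization

The production pipelines behind the workflow are closed, so two desk-scale
stand-ins preserve their architecture (two algorithms, one consensus):

* **Caller A** (`call_threshold()`): calls any allele with at least 10
  supporting reads and at least 1% observed allele fraction. The floor sits
  deliberately *below* the assay LOD — triage, not calling, enforces 5%. Its
  quality score is a monotone heuristic that triage never consumes.
* **Caller B** (`call_binomial()`): exact binomial test of the allele count
  against the error null (`rate/3` per allele); Phred quality
  `-10 log10 P[X >= count]` capped at 99, call threshold Phred 5, and a
  "low" band for (5, 30]. The exact tail probability is carried in
  `p_value`, which survives the cap.

`normalize_variants()` left-aligns and parsimony-reduces indels against the
panel reference, verifies reference consistency, and annotates the
homopolymer context length (`hp_len`: the run containing or immediately
adjacent to the position). Normalization is idempotent, so both callers and
the truth set land on identical `(chrom, pos, ref, alt)` keys.

## The triage cascade

`triage()` merges the two call sets on normalized keys and applies rules in
a fixed order; the first match wins, so every variant carries exactly one
status and reason:

1. depth < 500x -> `insufficient_coverage`
2. WGA sample, insertion in a >= 5 bp homopolymer -> `wga_artifact`
3. allele fraction < 5% -> `below_LOD`
4. indel seen only by caller B -> `callerB_indel`
5. substitution in both callers -> confirmed
6. substitution in caller A only: 5-20% -> orthogonal validation by
   pyrosequencing; above 20% -> confirmed if catalog-pathogenic, otherwise
   orthogonal validation by Sanger
7. substitution in caller B only -> `callerB_only`
8. indel seen by caller A -> confirmed (caller A is authoritative for
   indels; rule 4 already removed B-only indels)

Two ordering decisions deserve a note. Coverage is checked first so that a
3% variant at 200x reads as a coverage problem, not an LOD problem. The WGA
artifact rule precedes the LOD rule: most WGA artifacts sit below the LOD,
and reporting them as `below_LOD` would hide the artifact mechanism — a
known artifact should be named as one. Rule 8 covers indels seen by caller A
*alone or with B*: an indel called by both is still confirmed on caller A's
authority (the enumerated concordance rules apply to substitutions; MNVs are
treated as substitutions throughout). Deletions in homopolymer context pass
with a logged warning — the artifact mechanism produces insertions.

Caller concordance compares presence only, never allele fraction: both
callers see the same pileups but may legitimately disagree on evidence
strength. Catalog annotation matches on the normalized key; rarity follows
the 1% global minor allele frequency convention (below 0.01 = rare).
`apply_validation_results()` folds orthogonal validation outcomes back in:
validated variants flip to confirmed, failures to
`failed_orthogonal_validation`; addressing a variant that is not pending is
a contract error.

## Performance evaluation

`confusion()` matches call and truth sets on normalized keys. True negatives
exist only when the caller supplies an assessable-negative count (e.g.
catalog positions screened and found wild-type); otherwise specificity is
reported absent — never as zero — because a tumor-only assay has no natural
negative denominator.

Confidence intervals are **Wilson score** intervals (no continuity
correction): the score-test inversion with center
`(p + z^2/2n) / (1 + z^2/n)`. The Wilson form was adopted because it is the
standard well-behaved interval for proportions at or near 0 and 1, the
regime of small validation panels (24/25, 25/25, 7/8, 8/8); the test suite
pins all four of those intervals to one decimal in percent and cross-checks
the closed form against a root-finding oracle on the score equation.

`determine_lod()` reports raw per-dilution detection rates (no monotone
smoothing) and the LOD as the smallest nominal allele fraction detected in
*more than half* of replicates. The majority rule generalizes a
single-replicate dilution design: with a hard >= 5% allele-fraction filter,
a true 5% variant at 1200x coverage is detected in about 58% of binomial
draws (the exact probability under the simulator's sampling distribution is
0.577), so majority detection places the LOD at 5% while any stricter
detection criterion would not. This also means a 50-replicate LOD experiment
is itself stochastic: at some seeds the 5% dilution falls just short of
majority. That knife-edge behavior is a property of the assay design, not of
the implementation, and is reported as observed.

## Problem sizes and numerical choices

The test and acceptance runs use the 90-amplicon demo panel throughout: 200
full pipeline replicates for the dilution-series LOD (50 per dilution at
mean depth 1200), 20 seeds for the artifact-filter completeness property, 30
runs for allele-fraction recovery (asserted against the 99% central binomial
band, with at least 95% of confirmed calls required inside it), and 24
coverage simulations for the AYR-uniformity sweep. Exact fractions (never
rounded values) are used in all threshold comparisons; allele fractions are
rounded to four decimals only for display and file output. Binomial tails
come from `pbinom` and are verified against direct summation to 1e-12 up to
depth 2000. Bisection for `mu` stops below 1e-9 in AYR. Zero-depth sites are
skipped with a log message rather than erroring, since a dropped amplicon is
an expected failure mode.

## Known limitations

* Pileup-level simulation cannot express alignment artifacts, strand bias,
  or context-dependent (flow-space) indel error, the very error mode that
  makes real homopolymer calling hard; the WGA artifact model injects the
  *consequence* (recurrent insertions) rather than the mechanism.
* The callers are stand-ins: results about their concordance characterize
  the triage logic, not any production caller pair.
* Uniformity is computed at amplicon granularity (share of amplicons at or
  above 0.2x the mean amplicon depth). Platform tools may compute it in base
  space; the two can differ on panels with heterogeneous amplicon lengths.
* The catalog is a packaged miniature; no external COSMIC/dbSNP download is
  performed, and identifiers are illustrative mappings onto the synthetic
  panel.
* Specificity depends entirely on the caller-supplied negative denominator;
  the package never invents one.
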
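# ---- end-to-end workflows ---------------------------------------------------

#' Run one sample through simulate -> call -> triage
#'
#' Convenience wrapper over the full desk-scale pipeline: simulate pileups
#' for a truth set under a profile (injecting WGA artifacts when the profile
#' says so), run both callers, normalize, and triage.
#'
#' @param panel an `amplicon_panel`.
#' @param truth truth-variant data.frame (or `NULL`).
#' @param profile a [sample_profile()].
#' @param config a [triage_config()]; its `wga_sample` flag is forced to the
#'   profile's `wga`.
#' @param catalog optional catalog for annotation.
#' @return list with `triaged`, `calls_a`, `calls_b`, `pileups`,
#'   `artifact_ledger`.
#' @export
run_sample <- function(panel, truth, profile, config = triage_config(),
                       catalog = NULL) {
  pileups <- simulate_pileups(panel, truth, profile)
  ledger <- NULL
  if (isTRUE(profile$wga)) {
    res <- inject_wga_artifacts(pileups, panel, profile)
    pileups <- res$pileups
    ledger <- res$ledger
  }
  calls_a <- normalize_variants(call_threshold(pileups), panel)
  calls_b <- normalize_variants(
    call_binomial(pileups, error_model(profile$error_rate)), panel)
  config$wga_sample <- isTRUE(profile$wga)
  triaged <- triage(calls_a, calls_b, config, panel = panel, catalog = catalog)
  list(triaged = triaged, calls_a = calls_a, calls_b = calls_b,
       pileups = pileups, artifact_ledger = ledger)
}

#' Simulated dilution-series limit-of-detection experiment
#'
#' Reproduces the workflow's LOD validation in silico: a single mutant
#' allele is simulated at each nominal allele fraction, the full
#' call-and-triage cascade runs on every replicate, and a dilution counts as
#' detected when the truth variant comes out `confirmed`. The LOD is the
#' smallest nominal AF detected in a majority of replicates
#' (see [determine_lod()]).
#'
#' @param panel an `amplicon_panel`.
#' @param nominal_afs dilution targets as allele fractions.
#' @param replicates replicates per dilution.
#' @param mean_depth mean amplicon coverage.
#' @param error_rate per-base substitution error.
#' @param seed base seed; each replicate draws a derived sub-seed.
#' @param config a [triage_config()].
#' @param truth_fn function(panel, af) giving the truth variant for one
#'   dilution (defaults to [demo_dilution_truth()]).
#' @return an `lod_result` (see [determine_lod()]) with attribute
#'   `n_runs` = total pipeline replicates executed.
#' @export
run_dilution_series <- function(panel, nominal_afs = c(0.50, 0.10, 0.05, 0.01),
                                replicates = 50L, mean_depth = 1200,
                                error_rate = 0.005, seed = 1L,
                                config = triage_config(),
                                truth_fn = demo_dilution_truth) {
  per_dilution <- lapply(seq_along(nominal_afs), function(d) {
    truth <- truth_fn(panel, af = nominal_afs[d])
    key <- variant_key(truth)
    vapply(seq_len(replicates), function(r) {
      profile <- sample_profile(
        sample_type = "SF", ayr = 1, mean_depth = mean_depth,
        error_rate = error_rate,
        seed = derive_seed(seed, d * 1000L + r)
      )
      res <- run_sample(panel, truth, profile, config)
      tr <- res$triaged
      any(variant_key(tr) == key & tr$status == "confirmed")
    }, logical(1))
  })
  names(per_dilution) <- as.character(nominal_afs)
  out <- determine_lod(per_dilution)
  attr(out, "n_runs") <- length(nominal_afs) * replicates
  out
}
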
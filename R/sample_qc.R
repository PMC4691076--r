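# ---- pre-analytic QC: multiplex-PCR yield ratio, purity, routing, qPCR -----

#' Construct a multiplex-PCR yield table
#'
#' The degradation assay amplifies three GAPDH fragments (200, 300, 400 bp by
#' default) from the test sample and from an intact reference template; the
#' per-fragment yield ratio sample/reference measures how much amplifiable
#' template of each length survives.
#'
#' @param sample_yields numeric yields for the test sample, one per fragment.
#' @param reference_yields numeric yields for the intact reference template
#'   (strictly positive).
#' @param fragment_lengths fragment sizes in bp.
#' @return a `yield_table` data.frame.
#' @export
yield_table <- function(sample_yields, reference_yields,
                        fragment_lengths = c(200L, 300L, 400L)) {
  if (length(sample_yields) != length(fragment_lengths) ||
      length(reference_yields) != length(fragment_lengths)) {
    stop("yield_table: the three columns must have equal length", call. = FALSE)
  }
  if (any(sample_yields < 0) || any(reference_yields < 0)) {
    stop("yield_table: yields must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(fragment_bp = as.integer(fragment_lengths),
               sample_yield = as.numeric(sample_yields),
               reference_yield = as.numeric(reference_yields)),
    class = c("yield_table", "data.frame")
  )
}

#' Average Yield Ratio (AYR) and degradation score
#'
#' The AYR is the arithmetic mean of the per-fragment sample/reference yield
#' ratios and serves as a quantitative indicator of FFPE DNA integrity
#' (1 = intact). Degradation is mapped as `(1 - AYR) * 100` percent, anchored
#' at AYR 0.3 corresponding to 70% degradation. The sample passes the
#' library-suitability gate when AYR is at or above `threshold`.
#'
#' @param yields a [yield_table()].
#' @param threshold minimum AYR for a pass decision (default 0.3).
#' @return an `ayr_result` list: `per_fragment_ratio`, `ayr`,
#'   `degradation_pct`, `decision` (`"pass"`/`"fail"`), `threshold`.
#' @examples
#' compute_ayr(yield_table(c(0.3, 0.3, 0.3), c(1, 1, 1)))
#' @export
compute_ayr <- function(yields, threshold = 0.3) {
  stopifnot(inherits(yields, "yield_table"))
  zero <- yields$reference_yield == 0
  if (any(zero)) {
    stop(sprintf("compute_ayr: reference yield is zero for the %d bp fragment",
                 yields$fragment_bp[which(zero)[1]]), call. = FALSE)
  }
  ratios <- yields$sample_yield / yields$reference_yield
  if (any(ratios > 1.2)) {
    warning("compute_ayr: per-fragment ratio above 1.2 (sample outperforms reference template)",
            call. = FALSE)
  }
  ayr <- mean(ratios)
  structure(list(
    per_fragment_ratio = ratios,
    ayr = ayr,
    degradation_pct = min(100, max(0, (1 - ayr) * 100)),
    decision = if (ayr >= threshold) "pass" else "fail",
    threshold = threshold
  ), class = "ayr_result")
}

#' @export
print.ayr_result <- function(x, ...) {
  cat(sprintf("AYR %.3f (%s at threshold %.2f), degradation %.1f%%\n",
              x$ayr, x$decision, x$threshold, x$degradation_pct))
  invisible(x)
}

#' Spectrophotometric purity gate
#'
#' Passes when both the 260/280 and 260/230 absorbance ratios exceed 1.7
#' (strict inequality). A failed purity check is a warning, not a blocker:
#' the go/no-go criterion for degraded samples is the AYR alone.
#'
#' @param a260_280,a260_230 absorbance ratios (positive).
#' @return list with `a260_280`, `a260_230` and `status` (`"pass"`/`"warn"`).
#' @export
assess_purity <- function(a260_280, a260_230) {
  if (a260_280 <= 0 || a260_230 <= 0) {
    stop("assess_purity: absorbance ratios must be positive", call. = FALSE)
  }
  list(a260_280 = a260_280, a260_230 = a260_230,
       status = if (a260_280 > 1.7 && a260_230 > 1.7) "pass" else "warn")
}

#' Route a sample to a library protocol
#'
#' Implements the routing table of the workflow:
#' \itemize{
#'   \item FFPE: requires an AYR at or above the threshold (default 0.3);
#'     20 ng input, 22 + 5 PCR cycles. Below threshold the sample is rejected
#'     (too fragmented to amplify).
#'   \item SF (snap-frozen): 10 ng input, 19 + 5 cycles.
#'   \item cfDNA with less than 1 ng available: whole-genome amplification
#'     first, then 10 ng input, 19 + 5 cycles.
#'   \item cfDNA with 1 ng or more: no WGA, input is the available mass
#'     (capped at the 10 ng the library protocol takes), 22 + 7 cycles.
#' }
#'
#' @param sample_type `"FFPE"`, `"SF"` or `"cfDNA"`.
#' @param ayr an [compute_ayr()] result or a bare AYR value (FFPE only).
#' @param mass_ng available DNA mass in ng (cfDNA only).
#' @param ayr_threshold minimum AYR for FFPE to proceed.
#' @return a `library_plan` list: `sample_type` (routed:
#'   FFPE/SF/cfDNA_WGA/cfDNA_noWGA), `input_ng`, `cycles_pcr1`, `cycles_pcr2`,
#'   `proceed`, `reject_reason`.
#' @export
library_plan <- function(sample_type = c("FFPE", "SF", "cfDNA"),
                         ayr = NULL, mass_ng = NULL, ayr_threshold = 0.3) {
  sample_type <- match.arg(sample_type)
  plan <- function(type, input, c1, c2) {
    structure(list(sample_type = type, input_ng = input, cycles_pcr1 = c1,
                   cycles_pcr2 = c2, proceed = TRUE, reject_reason = ""),
              class = "library_plan")
  }
  reject <- function(type, reason) {
    structure(list(sample_type = type, input_ng = NA_real_,
                   cycles_pcr1 = NA_integer_, cycles_pcr2 = NA_integer_,
                   proceed = FALSE, reject_reason = reason),
              class = "library_plan")
  }
  switch(sample_type,
    FFPE = {
      if (is.null(ayr)) stop("library_plan: FFPE requires an AYR result", call. = FALSE)
      a <- if (inherits(ayr, "ayr_result")) ayr$ayr else as.numeric(ayr)
      if (a >= ayr_threshold) plan("FFPE", 20, 22L, 5L)
      else reject("FFPE", "fragmentation_below_threshold")
    },
    SF = plan("SF", 10, 19L, 5L),
    cfDNA = {
      if (is.null(mass_ng)) stop("library_plan: cfDNA requires mass_ng", call. = FALSE)
      if (mass_ng <= 0) stop("library_plan: cfDNA mass must be positive", call. = FALSE)
      if (mass_ng < 1) plan("cfDNA_WGA", 10, 19L, 5L)
      else plan("cfDNA_noWGA", min(mass_ng, 10), 22L, 7L)
    }
  )
}

#' @export
print.library_plan <- function(x, ...) {
  if (x$proceed) {
    cat(sprintf("library_plan: %s, %.1f ng input, %d + %d cycles\n",
                x$sample_type, x$input_ng, x$cycles_pcr1, x$cycles_pcr2))
  } else {
    cat(sprintf("library_plan: %s REJECTED (%s)\n", x$sample_type, x$reject_reason))
  }
  invisible(x)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10(quantity) over a dilution series of a
#' genomic DNA standard. Amplification efficiency is `10^(-1/slope) - 1`
#' (1.0 = perfect doubling per cycle, slope -3.32).
#'
#' @param quantity_pg standard quantities in pg.
#' @param ct measured Ct values.
#' @return a `standard_curve` list: `slope`, `intercept`, `r2`, `efficiency`,
#'   `ct_range`.
#' @export
fit_standard_curve <- function(quantity_pg, ct) {
  if (length(unique(quantity_pg)) < 2L) {
    stop("fit_standard_curve: need at least 2 distinct quantities", call. = FALSE)
  }
  lq <- log10(quantity_pg)
  if (diff(range(lq)) < 1) {
    warning("fit_standard_curve: standards span less than one log10 decade",
            call. = FALSE)
  }
  fit <- lm(ct ~ lq)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warning("fit_standard_curve: non-negative slope; curve is not a valid qPCR calibration",
            call. = FALSE)
  }
  eff <- 10^(-1 / slope) - 1
  if (slope < 0 && (eff < 0.9 || eff > 1.1)) {
    warning(sprintf("fit_standard_curve: efficiency %.2f outside [0.9, 1.1]", eff),
            call. = FALSE)
  }
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r2 = r2,
    efficiency = eff,
    ct_range = range(ct)
  ), class = "standard_curve")
}

#' Quantify DNA from replicate Ct values
#'
#' Replicate Cts are averaged first, then interpolated on the standard curve:
#' `quantity = 10^((ct - intercept) / slope)` (pg/uL-equivalent on the
#' standard's scale). Total mass is concentration times volume. A mean Ct more
#' than 2 cycles outside the calibrated Ct range triggers an extrapolation
#' warning but still returns a value.
#'
#' @param ct_replicates one or more Ct measurements of the same sample.
#' @param curve a [fit_standard_curve()] result.
#' @param volume_ul sample volume in uL.
#' @return mass in ng, with attributes `concentration_pg_ul` and `cv` (the
#'   replicate coefficient of variation, NA for a single replicate).
#' @export
quantify_dna <- function(ct_replicates, curve, volume_ul = 1) {
  if (length(ct_replicates) < 1L) {
    stop("quantify_dna: need at least one Ct replicate", call. = FALSE)
  }
  stopifnot(inherits(curve, "standard_curve"))
  ct <- mean(ct_replicates)
  if (ct < curve$ct_range[1] - 2 || ct > curve$ct_range[2] + 2) {
    warning("quantify_dna: mean Ct outside calibrated range (+/- 2 cycles); extrapolating",
            call. = FALSE)
  }
  conc_pg_ul <- 10^((ct - curve$intercept) / curve$slope)
  mass_ng <- conc_pg_ul * volume_ul / 1000
  cv <- if (length(ct_replicates) > 1L) sd(ct_replicates) / ct else NA_real_
  structure(mass_ng, concentration_pg_ul = conc_pg_ul, cv = cv)
}

#' Read a yield table TSV
#'
#' Expects tab-separated columns `fragment_bp`, `sample_yield`,
#' `reference_yield`; lines starting with `#` are treated as header/comments.
#'
#' @param path input path.
#' @return a [yield_table()].
#' @export
read_yield_table <- function(path) {
  df <- read_tsv_hash(path, c("fragment_bp", "sample_yield", "reference_yield"))
  yield_table(as.numeric(df$sample_yield), as.numeric(df$reference_yield),
              as.integer(df$fragment_bp))
}
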
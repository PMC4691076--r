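# ---- assay performance evaluation ------------------------------------------

#' Confusion counts against a truth set
#'
#' Matches variant sets on the normalized `(chrom, pos, ref, alt)` key.
#' True negatives are only defined when the caller supplies a count of
#' assessable negative sites (e.g. catalog positions screened and found
#' wild-type); without it `tn` is `NA` and specificity is not computable.
#'
#' @param calls data.frame of final reported variants.
#' @param truth data.frame of expected variants.
#' @param negatives optional count of assessable negative sites.
#' @return a `confusion_counts` list: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(calls, truth, negatives = NULL) {
  for (df in list(calls, truth)) {
    if (nrow(df) && any(is_non_parsimonious(df$ref, df$alt))) {
      stop("confusion: inputs must be normalized (parsimonious alleles)",
           call. = FALSE)
    }
  }
  ck <- if (nrow(calls)) unique(variant_key(calls)) else character(0)
  tk <- if (nrow(truth)) unique(variant_key(truth)) else character(0)
  tp <- length(intersect(ck, tk))
  fp <- length(setdiff(ck, tk))
  fn <- length(setdiff(tk, ck))
  tn <- if (is.null(negatives)) NA_integer_ else as.integer(negatives - fp)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score-test inversion interval with center
#' `(p + z^2/2n) / (1 + z^2/n)` and half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, clipped to `[0, 1]`. No
#' continuity correction. Well-behaved for proportions at or near 0 and 1,
#' which is the regime of small validation panels (e.g. 24/25 successes).
#'
#' @param successes number of successes.
#' @param trials number of trials (>= 1).
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' round(wilson_interval(24, 25) * 100, 1)  # 80.5 99.3
#' @export
wilson_interval <- function(successes, trials, conf = 0.95) {
  if (trials < 1L) stop("wilson_interval: trials must be >= 1", call. = FALSE)
  if (successes < 0L || successes > trials) {
    stop("wilson_interval: successes must lie in [0, trials]", call. = FALSE)
  }
  z <- qnorm((1 + conf) / 2)
  p <- successes / trials
  n <- trials
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, center - half), min(1, center + half))
}

#' Sensitivity, specificity and PPV with Wilson confidence intervals
#'
#' `sensitivity = tp/(tp+fn)`, `ppv = tp/(tp+fp)`,
#' `specificity = tn/(tn+fp)` (only when `tn` is available). A metric whose
#' denominator is zero or undefined is reported as `NA`, never as 0.
#'
#' @param counts a [confusion()] result.
#' @param conf confidence level for the Wilson intervals.
#' @return a `perf_report` list with point estimates and `ci_*` bounds.
#' @export
proportion_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  metric <- function(num, den) {
    if (is.na(den) || den == 0) {
      list(est = NA_real_, ci = c(NA_real_, NA_real_))
    } else {
      list(est = num / den, ci = wilson_interval(num, den, conf))
    }
  }
  sens <- metric(counts$tp, counts$tp + counts$fn)
  ppv <- metric(counts$tp, counts$tp + counts$fp)
  spec <- if (is.na(counts$tn)) {
    list(est = NA_real_, ci = c(NA_real_, NA_real_))
  } else {
    metric(counts$tn, counts$tn + counts$fp)
  }
  structure(list(
    sensitivity = sens$est, ci_sensitivity = sens$ci,
    specificity = spec$est, ci_specificity = spec$ci,
    ppv = ppv$est, ci_ppv = ppv$ci,
    conf_level = conf, counts = counts
  ), class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  show <- function(name, est, ci) {
    if (is.na(est)) {
      cat(sprintf("  %-12s not assessable\n", name))
    } else {
      cat(sprintf("  %-12s %.1f%% (%.0f%% CI %.1f, %.1f)\n", name, est * 100,
                  x$conf_level * 100, ci[1] * 100, ci[2] * 100))
    }
  }
  cat("assay performance:\n")
  show("sensitivity", x$sensitivity, x$ci_sensitivity)
  show("specificity", x$specificity, x$ci_specificity)
  show("PPV", x$ppv, x$ci_ppv)
  invisible(x)
}

#' Limit of detection from a dilution series
#'
#' Given per-dilution detection outcomes over replicates, reports the raw
#' detection rate at each nominal allele fraction and the LOD: the smallest
#' nominal AF detected in more than half of replicates. No monotone smoothing
#' is applied.
#'
#' @param per_dilution named list: names are nominal allele fractions (as
#'   numbers, e.g. `"0.05"`), values logical vectors of per-replicate
#'   detection flags.
#' @return an `lod_result` list: `nominal_afs`, `detection_rate`, `lod`
#'   (`NA` when no dilution reaches majority detection).
#' @examples
#' determine_lod(list("0.5" = TRUE, "0.1" = TRUE, "0.05" = TRUE,
#'                    "0.01" = FALSE))
#' @export
determine_lod <- function(per_dilution) {
  if (!length(per_dilution)) stop("determine_lod: empty mapping", call. = FALSE)
  if (any(!vapply(per_dilution, length, 0L))) {
    stop("determine_lod: every dilution needs >= 1 replicate", call. = FALSE)
  }
  afs <- as.numeric(names(per_dilution))
  rates <- vapply(per_dilution, mean, 0)
  detected <- afs[rates > 0.5]
  structure(list(
    nominal_afs = afs,
    detection_rate = setNames(rates, names(per_dilution)),
    lod = if (length(detected)) min(detected) else NA_real_
  ), class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  for (i in seq_along(x$nominal_afs)) {
    cat(sprintf("  AF %4.1f%%: detected in %.0f%% of replicates\n",
                x$nominal_afs[i] * 100, x$detection_rate[i] * 100))
  }
  if (is.na(x$lod)) cat("  LOD: not reached\n")
  else cat(sprintf("  LOD: %.1f%% allele fraction\n", x$lod * 100))
  invisible(x)
}
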
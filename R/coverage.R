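# ---- per-amplicon coverage metrics -----------------------------------------

#' Summarize per-amplicon coverage
#'
#' Computes the mean amplicon depth, the count of amplicons strictly below
#' `min_depth` (the clinical 500x floor), and coverage uniformity: the
#' percentage of amplicons whose depth is at least `uniformity_factor` times
#' the mean amplicon depth (the platform convention, 0.2x mean, applied at
#' amplicon granularity). When a panel is supplied, under-covered amplicons
#' with GC at or above `gc_threshold` are flagged.
#'
#' @param depths named numeric vector of per-amplicon depths.
#' @param min_depth coverage floor in reads.
#' @param uniformity_factor fraction of the mean defining uniformity.
#' @param panel optional `amplicon_panel` for GC flagging.
#' @param gc_threshold GC fraction for flagging.
#' @return a `coverage_summary` list: `mean_depth`, `n_below_min`,
#'   `uniformity_pct`, `n_amplicons`, `below_min` (names), `flagged_gc`
#'   (names, empty without a panel).
#' @examples
#' coverage_summary(c(a = 6000, b = 6000, c = 400))
#' @export
coverage_summary <- function(depths, min_depth = 500, uniformity_factor = 0.2,
                             panel = NULL, gc_threshold = 0.60) {
  if (!length(depths)) stop("coverage_summary: empty depth mapping", call. = FALSE)
  mean_depth <- mean(depths)
  below <- names(depths)[depths < min_depth] %||% character(0)
  flagged <- if (!is.null(panel)) {
    flag_gc_amplicons(panel, below, gc_threshold)
  } else character(0)
  structure(list(
    mean_depth = mean_depth,
    n_below_min = sum(depths < min_depth),
    uniformity_pct = 100 * mean(depths >= uniformity_factor * mean_depth),
    n_amplicons = length(depths),
    below_min = below,
    flagged_gc = flagged
  ), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage_summary: mean %.1fx over %d amplicons; %d below floor; uniformity %.1f%%\n",
              x$mean_depth, x$n_amplicons, x$n_below_min, x$uniformity_pct))
  if (length(x$flagged_gc)) {
    cat("  high-GC under-covered:", paste(x$flagged_gc, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag high-GC amplicons among an under-covered set
#'
#' @param panel an `amplicon_panel`.
#' @param under_covered character vector of amplicon names.
#' @param gc_threshold GC fraction at or above which an amplicon is flagged.
#' @return character vector of flagged amplicon names.
#' @export
flag_gc_amplicons <- function(panel, under_covered, gc_threshold = 0.60) {
  if (!length(under_covered)) return(character(0))
  m <- match(under_covered, panel$name)
  if (anyNA(m)) {
    stop(sprintf("flag_gc_amplicons: unknown amplicon '%s'",
                 under_covered[which(is.na(m))[1]]), call. = FALSE)
  }
  under_covered[panel$gc[m] >= gc_threshold]
}

#' Correlation between sample integrity (AYR) and coverage uniformity
#'
#' Pearson product-moment correlation across samples; degraded samples are
#' expected to show lower uniformity, giving a strongly positive coefficient.
#'
#' @param ayr numeric vector of per-sample AYR values.
#' @param uniformity_pct matching vector of uniformity percentages.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
ayr_uniformity_correlation <- function(ayr, uniformity_pct) {
  if (length(ayr) != length(uniformity_pct) || length(ayr) < 3L) {
    stop("ayr_uniformity_correlation: need >= 3 paired samples", call. = FALSE)
  }
  if (sd(ayr) == 0 || sd(uniformity_pct) == 0) {
    stop("ayr_uniformity_correlation: correlation undefined for constant input",
         call. = FALSE)
  }
  cor(ayr, uniformity_pct, method = "pearson")
}
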
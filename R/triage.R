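# ---- consensus triage cascade ----------------------------------------------

#' Triage configuration
#'
#' Thresholds of the reportable-variant rule cascade. The defaults encode the
#' assay's true-positive criterion: allele fraction of at least 5% with
#' coverage of at least 500x; variants in the 5-20% band are routed to
#' pyrosequencing, above 20% to Sanger sequencing, when only caller A saw
#' them.
#'
#' @param min_af limit of detection on allele fraction.
#' @param min_depth minimum coverage in reads.
#' @param validation_band allele-fraction band routed to pyrosequencing.
#' @param homopolymer_min_len minimum run length for the WGA artifact rule.
#' @param wga_sample whether the sample went through WGA.
#' @return a `triage_config` list.
#' @export
triage_config <- function(min_af = 0.05, min_depth = 500L,
                          validation_band = c(0.05, 0.20),
                          homopolymer_min_len = 5L, wga_sample = FALSE) {
  stopifnot(min_af > 0, min_af <= validation_band[2], validation_band[2] <= 1,
            min_depth >= 0, homopolymer_min_len >= 2)
  structure(list(min_af = min_af, min_depth = min_depth,
                 validation_band = validation_band,
                 homopolymer_min_len = homopolymer_min_len,
                 wga_sample = isTRUE(wga_sample)),
            class = "triage_config")
}

#' Merge and triage two callers' call sets
#'
#' Applies the consensus/filter cascade to the union of the two call sets,
#' keyed by normalized `(chrom, pos, ref, alt)`. Rules fire in order; the
#' first match assigns status and reason:
#' \enumerate{
#'   \item depth below `min_depth` -> filtered, `insufficient_coverage`
#'   \item WGA sample, insertion in a homopolymer of
#'     `homopolymer_min_len`+ bp -> filtered, `wga_artifact` (checked before
#'     the LOD so a known artifact is reported as an artifact, not as a
#'     sub-LOD variant; most WGA artifacts sit below the LOD)
#'   \item allele fraction below `min_af` -> filtered, `below_LOD`
#'   \item indel seen only by caller B -> filtered, `callerB_indel` (caller
#'     B's indel calls in this assay context are unreliable)
#'   \item substitution seen by both callers -> confirmed (concordant)
#'   \item substitution seen only by caller A: within the validation band ->
#'     requires_orthogonal_validation (pyrosequencing); above the band ->
#'     confirmed when the catalog marks it pathogenic, otherwise
#'     requires_orthogonal_validation (Sanger)
#'   \item substitution seen only by caller B -> filtered, `callerB_only`
#'   \item indel seen by caller A (alone or with B) -> confirmed (caller A is
#'     authoritative for indels)
#' }
#' Concordance compares presence only; the callers may disagree on allele
#' fraction. After the cascade each variant is annotated against the catalog
#' and classified by rarity (global minor allele frequency below 0.01 =
#' rare).
#'
#' @param calls_a,calls_b normalized calls data.frames (see
#'   [normalize_variants()]).
#' @param config a [triage_config()].
#' @param panel optional `amplicon_panel`, used to fill missing homopolymer
#'   annotation.
#' @param catalog optional catalog data.frame (see [demo_catalog()]).
#' @return a `triaged_variants` data.frame: call columns plus `concordant`,
#'   `status` (`confirmed` / `requires_orthogonal_validation` / `filtered`),
#'   `reason`, `validation_method` (`PS`/`SS` or NA), `catalog_id`,
#'   `pathogenic`, `gmaf`, `rarity`.
#' @export
triage <- function(calls_a, calls_b, config = triage_config(), panel = NULL,
                   catalog = NULL) {
  for (nm in c("A", "B")) {
    cc <- if (nm == "A") calls_a else calls_b
    if (nrow(cc) && any(is_non_parsimonious(cc$ref, cc$alt))) {
      stop(sprintf("triage: calls_%s contain non-normalized alleles; run normalize_variants() first",
                   tolower(nm)), call. = FALSE)
    }
  }
  keys_a <- if (nrow(calls_a)) variant_key(calls_a) else character(0)
  keys_b <- if (nrow(calls_b)) variant_key(calls_b) else character(0)
  keys <- union(keys_a, keys_b)
  if (!length(keys)) {
    out <- cbind(empty_calls()[0, ],
                 data.frame(concordant = logical(), status = character(),
                            reason = character(), validation_method = character(),
                            catalog_id = character(), pathogenic = logical(),
                            gmaf = numeric(), rarity = character()))
    class(out) <- c("triaged_variants", "data.frame")
    return(out)
  }
  ia <- match(keys, keys_a)
  ib <- match(keys, keys_b)
  common <- intersect(names(calls_a), names(calls_b))
  df <- rbind(
    if (any(!is.na(ia))) calls_a[ia[!is.na(ia)], common, drop = FALSE],
    if (any(is.na(ia))) calls_b[ib[is.na(ia)], common, drop = FALSE]
  )
  # restore the union's key order (A-representatives first build order)
  df <- df[match(keys, variant_key(df)), , drop = FALSE]
  in_a <- !is.na(ia)
  in_b <- !is.na(ib)
  df$caller <- ifelse(in_a & in_b, "A+B", ifelse(in_a, "A", "B"))
  df$concordant <- in_a & in_b
  if (!is.null(panel)) {
    need <- is.na(df$hp_len)
    if (any(need)) df$hp_len[need] <- annotate_hp_len(df[need, , drop = FALSE], panel)
  }
  df$hp_len[is.na(df$hp_len)] <- 0L
  df$kind <- variant_kind(df$ref, df$alt)
  is_indel <- df$kind %in% c("INS", "DEL")
  is_sub <- !is_indel

  # catalog annotation (needed by rule 6 before assignment)
  df$catalog_id <- NA_character_
  df$pathogenic <- FALSE
  df$gmaf <- NA_real_
  if (!is.null(catalog) && nrow(catalog)) {
    m <- match(variant_key(df), variant_key(catalog))
    hit <- !is.na(m)
    df$catalog_id[hit] <- ifelse(is.na(catalog$cosmic_like_id[m[hit]]),
                                 catalog$dbsnp_like_id[m[hit]],
                                 catalog$cosmic_like_id[m[hit]])
    df$pathogenic[hit] <- catalog$pathogenic[m[hit]]
    df$gmaf[hit] <- catalog$gmaf[m[hit]]
  }
  df$rarity <- ifelse(is.na(df$gmaf), "unknown",
                      ifelse(df$gmaf < 0.01, "rare", "common"))

  status <- rep(NA_character_, nrow(df))
  reason <- rep("none", nrow(df))
  vmethod <- rep(NA_character_, nrow(df))
  assign_rule <- function(cond, st, rs = "none") {
    cond <- cond & is.na(status)
    status[cond] <<- st
    reason[cond] <<- rs
    cond
  }
  assign_rule(df$depth < config$min_depth, "filtered", "insufficient_coverage")
  if (config$wga_sample) {
    assign_rule(df$kind == "INS" & df$hp_len >= config$homopolymer_min_len,
                "filtered", "wga_artifact")
  }
  assign_rule(df$af < config$min_af, "filtered", "below_LOD")
  assign_rule(is_indel & !in_a & in_b, "filtered", "callerB_indel")
  assign_rule(is_sub & in_a & in_b, "confirmed")
  band_hi <- config$validation_band[2]
  ps <- assign_rule(is_sub & in_a & !in_b & df$af <= band_hi,
                    "requires_orthogonal_validation")
  vmethod[ps] <- "PS"
  assign_rule(is_sub & in_a & !in_b & df$af > band_hi & df$pathogenic,
              "confirmed")
  ss <- assign_rule(is_sub & in_a & !in_b & df$af > band_hi,
                    "requires_orthogonal_validation")
  vmethod[ss] <- "SS"
  assign_rule(is_sub & !in_a & in_b, "filtered", "callerB_only")
  assign_rule(is_indel & in_a, "confirmed")
  stopifnot(!anyNA(status))  # the cascade is total over the union

  if (config$wga_sample) {
    hp_del <- df$kind == "DEL" & df$hp_len >= config$homopolymer_min_len &
      status != "filtered"
    if (any(hp_del)) {
      warning(sprintf("triage: %d deletion(s) in homopolymer context retained (artifact rule targets insertions)",
                      sum(hp_del)), call. = FALSE)
    }
  }
  df$status <- status
  df$reason <- reason
  df$validation_method <- vmethod
  rownames(df) <- NULL
  class(df) <- c("triaged_variants", "data.frame")
  df
}

#' @export
print.triaged_variants <- function(x, ...) {
  cat(sprintf("triaged_variants: %d variants (%d confirmed, %d pending validation, %d filtered)\n",
              nrow(x), sum(x$status == "confirmed"),
              sum(x$status == "requires_orthogonal_validation"),
              sum(x$status == "filtered")))
  NextMethod()
}

#' Fold orthogonal validation outcomes back into a triage result
#'
#' Variants that were pending pyrosequencing or Sanger validation flip to
#' `confirmed` when validated and to `filtered` (reason
#' `failed_orthogonal_validation`) when not. Supplying a variant that is not
#' awaiting validation is a contract error.
#'
#' @param triaged a [triage()] result.
#' @param results data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `validated` (logical), or a named logical vector keyed
#'   `"chrom:pos:ref:alt"`.
#' @return the updated `triaged_variants` data.frame.
#' @export
apply_validation_results <- function(triaged, results) {
  if (is.data.frame(results)) {
    keys <- variant_key(results)
    flags <- results$validated
  } else {
    keys <- names(results)
    flags <- as.logical(results)
  }
  if (!length(keys)) return(triaged)
  m <- match(keys, variant_key(triaged))
  if (anyNA(m) ||
      any(triaged$status[m] != "requires_orthogonal_validation")) {
    stop("apply_validation_results: every result must address a variant awaiting orthogonal validation",
         call. = FALSE)
  }
  triaged$status[m] <- ifelse(flags, "confirmed", "filtered")
  triaged$reason[m] <- ifelse(flags, "none", "failed_orthogonal_validation")
  triaged$validation_method[m[!flags]] <- triaged$validation_method[m[!flags]]
  triaged
}
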
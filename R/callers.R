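# ---- desk-scale variant callers --------------------------------------------
#
# Two independent callers stand in for the platform's closed caller pair:
# caller A is a frequency-threshold caller (mirroring a hotspot-panel plugin
# with preset gates), caller B an exact-binomial-test caller with Phred
# banding (mirroring a general-purpose germline caller whose indel calls in
# homopolymers are known to be unreliable; the triage cascade, not the
# caller, handles that). What is preserved from the original architecture:
# two callers with different algorithms feeding one consensus triage, caller
# B's Phred 5/30 quality bands, and caller A's authority over indels.

#' Sequencing error model for the binomial caller
#'
#' @param per_base_rate per-base substitution probability.
#' @return an `error_model` list with `per_base_rate` and `per_allele_rate`
#'   (`per_base_rate / 3`, the null rate for any one alternate allele).
#' @export
error_model <- function(per_base_rate = 0.005) {
  stopifnot(per_base_rate > 0, per_base_rate < 1)
  structure(list(per_base_rate = per_base_rate,
                 per_allele_rate = per_base_rate / 3),
            class = "error_model")
}

# shared: pileup alt rows -> call frame skeleton
pileup_alt_rows <- function(pileups) {
  alt <- pileups[pileups$allele_ref != "." & pileups$depth > 0L, , drop = FALSE]
  n_zero <- sum(pileups$depth == 0L & pileups$allele_ref != ".")
  if (n_zero) {
    message(sprintf("caller: skipped %d zero-depth site alleles", n_zero))
  }
  alt
}

#' Caller A: frequency-threshold caller
#'
#' Emits one call per non-reference allele (SNV, MNV or indel) meeting both
#' gates: at least `min_alt_count` supporting reads and an observed allele
#' fraction of at least `call_floor_af`. The default floor (1%) sits below
#' the assay's 5% limit of detection on purpose: triage, not calling,
#' enforces the LOD. The quality score `min(99, af * min(depth, 1000))` is a
#' monotone heuristic; triage never consumes it.
#'
#' @param pileups a pileup frame from [simulate_pileups()] or
#'   [read_pileups()].
#' @param min_alt_count minimum supporting reads.
#' @param call_floor_af minimum observed allele fraction.
#' @return a calls data.frame (`chrom`, `pos`, `ref`, `alt`, `af`, `depth`,
#'   `alt_count`, `caller`, `quality`, `quality_band`, `kind`, `hp_len`).
#' @export
call_threshold <- function(pileups, min_alt_count = 10L, call_floor_af = 0.01) {
  alt <- pileup_alt_rows(pileups)
  af <- alt$count / alt$depth
  keep <- alt$count >= min_alt_count & af >= call_floor_af
  alt <- alt[keep, , drop = FALSE]
  if (!nrow(alt)) return(empty_calls())
  data.frame(
    chrom = alt$chrom, pos = alt$pos, ref = alt$allele_ref,
    alt = alt$allele_alt, af = af[keep], depth = alt$depth,
    alt_count = alt$count, caller = "A",
    quality = pmin(99, af[keep] * pmin(alt$depth, 1000)),
    quality_band = "normal", p_value = NA_real_,
    kind = variant_kind(alt$allele_ref, alt$allele_alt),
    hp_len = NA_integer_, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Caller B: exact binomial-test caller
#'
#' For each non-reference allele, tests the observed count against the null
#' `X ~ Binomial(depth, per_allele_rate)`; the Phred-scaled quality is
#' `-10 log10 P[X >= count]`, capped at 99. An allele is called when quality
#' exceeds `min_phred` (default 5); calls with quality in (5, 30] are banded
#' `"low"`, above 30 `"normal"`.
#'
#' @param pileups a pileup frame.
#' @param model an [error_model()].
#' @param min_phred minimum Phred quality to call.
#' @return a calls data.frame (same columns as [call_threshold()], plus the
#'   exact tail probability in `p_value`, which survives the 99 cap on the
#'   Phred score).
#' @export
call_binomial <- function(pileups, model = error_model(), min_phred = 5) {
  stopifnot(inherits(model, "error_model"))
  alt <- pileup_alt_rows(pileups)
  if (!nrow(alt)) return(empty_calls())
  p <- pbinom(alt$count - 1L, alt$depth, model$per_allele_rate,
              lower.tail = FALSE)
  quality <- pmin(99, -10 * log10(p))
  keep <- quality > min_phred
  alt <- alt[keep, , drop = FALSE]
  if (!nrow(alt)) return(empty_calls())
  q <- quality[keep]
  data.frame(
    chrom = alt$chrom, pos = alt$pos, ref = alt$allele_ref,
    alt = alt$allele_alt, af = alt$count / alt$depth, depth = alt$depth,
    alt_count = alt$count, caller = "B", quality = q,
    quality_band = ifelse(q <= 30, "low", "normal"), p_value = p[keep],
    kind = variant_kind(alt$allele_ref, alt$allele_alt),
    hp_len = NA_integer_, stringsAsFactors = FALSE, row.names = NULL
  )
}

# TRUE where a (ref, alt) pair is not in canonical parsimonious form
is_non_parsimonious <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  trailing <- (nr > 1L | na > 1L) &
    substr(ref, nr, nr) == substr(alt, na, na)
  leading <- nr > 1L & na > 1L & substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  trailing | leading
}

# left-align + parsimony-reduce one variant against a chromosome sequence
# (0-based pos); returns list(pos, ref, alt)
left_align_one <- function(chrom_seq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref)
    na <- nchar(alt)
    if (nr > 0L && na > 0L && (nr > 1L || na > 1L) &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 0L) {  # contig start: re-anchor on the following base
          b <- substr(chrom_seq, pos + nchar(ref) + 1L, pos + nchar(ref) + 1L)
          ref <- paste0(ref, b)
          alt <- paste0(alt, b)
          break
        }
        b <- substr(chrom_seq, pos, pos)  # base at 0-based pos-1
        pos <- pos - 1L
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else if (nr > 1L && na > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nr)
      alt <- substr(alt, 2L, na)
      pos <- pos + 1L
    } else break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant calls
#'
#' Left-aligns and parsimony-reduces indels against the panel reference
#' (SNVs pass through unchanged), verifies that each call's reference allele
#' matches the reference sequence, and annotates `hp_len`: the length of the
#' homopolymer run containing or immediately adjacent to the call position
#' (0 when none). Normalization is idempotent, so caller A, caller B and
#' truth-set representations of the same event land on the same
#' `(chrom, pos, ref, alt)` key.
#'
#' @param calls a calls data.frame.
#' @param panel the `amplicon_panel` providing the reference and homopolymer
#'   annotation.
#' @return the calls data.frame with normalized `pos`/`ref`/`alt`, recomputed
#'   `kind`, and `hp_len` filled in.
#' @export
normalize_variants <- function(calls, panel) {
  if (!nrow(calls)) return(calls)
  ref_set <- attr(panel, "reference")
  chrom_cache <- new.env(parent = emptyenv())
  get_chrom <- function(ch) {
    if (!exists(ch, chrom_cache)) {
      assign(ch, as.character(ref_set[[ch]]), chrom_cache)
    }
    get(ch, chrom_cache)
  }
  for (i in seq_len(nrow(calls))) {
    cs <- get_chrom(calls$chrom[i])
    span <- substr(cs, calls$pos[i] + 1L, calls$pos[i] + nchar(calls$ref[i]))
    if (span != calls$ref[i]) {
      stop(sprintf("normalize_variants: ref allele '%s' at %s:%d disagrees with reference '%s'",
                   calls$ref[i], calls$chrom[i], calls$pos[i], span),
           call. = FALSE)
    }
    if (nchar(calls$ref[i]) > 1L || nchar(calls$alt[i]) > 1L) {
      v <- left_align_one(cs, calls$pos[i], calls$ref[i], calls$alt[i])
      calls$pos[i] <- v$pos
      calls$ref[i] <- v$ref
      calls$alt[i] <- v$alt
    }
  }
  calls$kind <- variant_kind(calls$ref, calls$alt)
  calls$hp_len <- annotate_hp_len(calls, panel)
  calls
}

# homopolymer run length containing or adjacent to each call position
annotate_hp_len <- function(calls, panel) {
  runs <- attr(panel, "homopolymers")
  vapply(seq_len(nrow(calls)), function(i) {
    hit <- runs$chrom == calls$chrom[i] &
      runs$start - 1L <= calls$pos[i] & calls$pos[i] <= runs$end
    if (any(hit)) max(runs$run_length[hit]) else 0L
  }, 0L)
}
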
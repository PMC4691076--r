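#' GC fraction of a nucleotide sequence
#'
#' Computes (G + C) / (A + C + G + T). `N` bases are excluded from both the
#' numerator and the denominator, so the value reflects only the called bases.
#'
#' @param seq a single nucleotide string (alphabet `ACGTN`, case-insensitive)
#'   or a [Biostrings::DNAString].
#' @return fraction in `[0, 1]`.
#' @examples
#' gc_fraction("ACGTGC")  # 4 of 6 -> 0.667
#' @export
gc_fraction <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("gc_fraction: sequence must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq)) {
    stop("gc_fraction: sequence contains characters outside ACGTN", call. = FALSE)
  }
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) {
    stop("gc_fraction: sequence has no called (non-N) bases", call. = FALSE)
  }
  unname((counts[["C"]] + counts[["G"]]) / denom)
}

#' Maximal homopolymer runs in a sequence
#'
#' Finds maximal single-base runs of at least `min_len` bases. Runs at or above
#' 5 bp are the error-prone context for polymerase slippage and for insertion
#' artifacts of multiple-displacement whole-genome amplification.
#'
#' @param seq nucleotide string.
#' @param offset genomic start coordinate of `seq` (0-based); reported run
#'   coordinates are shifted by this amount.
#' @param min_len minimum run length in bp (>= 2).
#' @param chrom optional chromosome label carried into the result.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `base`, `run_length`, sorted by `start`. Zero rows when no run qualifies.
#' @examples
#' homopolymer_runs("TTTTTTCAAAAA", min_len = 5)
#' @export
homopolymer_runs <- function(seq, offset = 0L, min_len = 5L, chrom = NA_character_) {
  if (min_len < 2L) stop("homopolymer_runs: min_len must be >= 2", call. = FALSE)
  seq <- toupper(as.character(seq))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  data.frame(
    chrom = rep(chrom, sum(keep)),
    start = as.integer(offset + starts[keep]),
    end = as.integer(offset + ends[keep]),
    base = r$values[keep],
    run_length = as.integer(r$lengths[keep]),
    stringsAsFactors = FALSE
  )
}

#' Load an amplicon panel from a BED file and a reference
#'
#' Reads a BED6 interval file (name in column 4) describing the panel's
#' amplicons, extracts each amplicon's sequence from the reference, and
#' annotates GC content and homopolymer runs. Coordinates are 0-based
#' half-open, both on disk and internally; conversion to 1-based happens only
#' at the VCF boundary.
#'
#' @param bed_file path to a BED file.
#' @param reference path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param reference_id label recorded for the reference build.
#' @param hp_min_len minimum homopolymer run length to annotate (bp).
#' @return an `amplicon_panel`: a data.frame with columns `name`, `chrom`,
#'   `start`, `end`, `gene`, `length`, `gc`, plus attributes `reference`
#'   (DNAStringSet), `reference_id` and `homopolymers`.
#' @export
load_panel <- function(bed_file, reference, reference_id = "demo", hp_min_len = 5L) {
  ref <- if (inherits(reference, "DNAStringSet")) reference else {
    Biostrings::readDNAStringSet(reference)
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  lines <- readLines(bed_file)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  recs <- strsplit(lines, "\t", fixed = TRUE)
  amp <- lapply(seq_along(recs), function(i) {
    f <- recs[[i]]
    if (length(f) < 4L) {
      stop(sprintf("load_panel: malformed BED line %d: expected >= 4 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("load_panel: malformed BED line %d: non-numeric coordinates", i),
           call. = FALSE)
    }
    list(chrom = f[1], start = start, end = end, name = f[4],
         gene = sub("_[0-9]+$", "", f[4]))
  })
  df <- data.frame(
    name = vapply(amp, `[[`, "", "name"),
    chrom = vapply(amp, `[[`, "", "chrom"),
    start = vapply(amp, `[[`, 0L, "start"),
    end = vapply(amp, `[[`, 0L, "end"),
    gene = vapply(amp, `[[`, "", "gene"),
    stringsAsFactors = FALSE
  )
  build_panel(df, ref, reference_id = reference_id, hp_min_len = hp_min_len)
}

# assemble + validate an amplicon_panel from an interval data.frame and reference
build_panel <- function(df, ref, reference_id = "demo", hp_min_len = 5L) {
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("panel: empty or inverted interval for amplicon '%s' (%d-%d)",
                 df$name[bad[1]], df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("panel: amplicon names must be unique", call. = FALSE)
  }
  missing_chrom <- setdiff(unique(df$chrom), names(ref))
  if (length(missing_chrom)) {
    stop(sprintf("panel: chromosome '%s' absent from reference", missing_chrom[1]),
         call. = FALSE)
  }
  lens <- setNames(Biostrings::width(ref), names(ref))
  out_of_bounds <- which(df$end > lens[df$chrom] | df$start < 0L)
  if (length(out_of_bounds)) {
    stop(sprintf("panel: amplicon '%s' outside reference bounds",
                 df$name[out_of_bounds[1]]), call. = FALSE)
  }
  df$length <- df$end - df$start
  seqs <- vapply(seq_len(nrow(df)), function(i) {
    as.character(Biostrings::subseq(ref[[df$chrom[i]]], df$start[i] + 1L, df$end[i]))
  }, "")
  n_frac <- vapply(seqs, function(s) {
    mean(strsplit(s, "", fixed = TRUE)[[1]] == "N")
  }, 0)
  if (any(n_frac > 0.10)) {
    warning(sprintf("panel: amplicon '%s' has > 10%% N bases",
                    df$name[which.max(n_frac)]), call. = FALSE)
  }
  df$gc <- vapply(seqs, gc_fraction, 0)
  hp <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    homopolymer_runs(seqs[i], offset = df$start[i], min_len = hp_min_len,
                     chrom = df$chrom[i])
  }))
  hp <- unique(hp)
  hp <- hp[order(hp$chrom, hp$start), , drop = FALSE]
  rownames(df) <- NULL
  rownames(hp) <- NULL
  structure(df,
    reference = ref, reference_id = reference_id, homopolymers = hp,
    hp_min_len = as.integer(hp_min_len),
    class = c("amplicon_panel", "data.frame")
  )
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("amplicon_panel: %d amplicons, %d genes, reference '%s'\n",
              nrow(x), length(unique(x$gene)), attr(x, "reference_id")))
  cat(sprintf("  GC range %.2f-%.2f; %d homopolymer runs >= %d bp\n",
              min(x$gc), max(x$gc), nrow(attr(x, "homopolymers")),
              attr(x, "hp_min_len")))
  invisible(x)
}

#' Number of amplicons in a panel
#' @param panel an `amplicon_panel`.
#' @return integer count.
#' @export
n_amplicons <- function(panel) nrow(panel)

#' @export
`[.amplicon_panel` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("name", "chrom", "start", "end") %in% names(out))) {
    for (a in c("reference", "reference_id", "homopolymers", "hp_min_len")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- class(x)
  }
  out
}

# reference base(s) at 0-based [start, end)
reference_slice <- function(panel, chrom, start, end) {
  ref <- attr(panel, "reference")
  if (!chrom %in% names(ref)) {
    stop(sprintf("reference_slice: unknown chromosome '%s'", chrom), call. = FALSE)
  }
  as.character(Biostrings::subseq(ref[[chrom]], start + 1L, end))
}

#' Write a panel summary TSV
#'
#' @param panel an `amplicon_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_summary <- function(panel, path) {
  df <- as.data.frame(panel)[, c("name", "chrom", "start", "end", "gene", "length", "gc")]
  writeLines(c(stamp_line(), paste0("#", paste(names(df), collapse = "\t"))), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write a panel's intervals as BED6
#' @inheritParams write_panel_summary
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  df <- data.frame(panel$chrom, panel$start, panel$end, panel$name, 0L, "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a panel's reference as FASTA
#' @inheritParams write_panel_summary
#' @return `path`, invisibly.
#' @export
write_panel_reference <- function(panel, path) {
  Biostrings::writeXStringSet(attr(panel, "reference"), path)
  invisible(path)
}
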
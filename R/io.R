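# ---- format readers/writers ------------------------------------------------
#
# TSV dialect: tab-separated, '#'-prefixed header lines (the last one names
# the columns), UTF-8, '.' for missing. Every writer stamps tool version and,
# when known, the seed and a config hash, and every reader tolerates the
# stamp. Positions are 1-based in files (TSV and VCF) and 0-based in memory.

#' Hash a configuration object
#'
#' Stable content hash (xxHash via rlang) used to stamp output artifacts so a
#' result can be traced to the exact configuration that produced it.
#'
#' @param x any R object.
#' @return character hash.
#' @export
config_hash <- function(x) rlang::hash(x)

stamp_line <- function(seed = NULL, config = NULL, prefix = "#") {
  parts <- c(paste0("ampliqc=", as.character(packageVersion("ampliqc"))))
  if (!is.null(seed)) parts <- c(parts, paste0("seed=", seed))
  if (!is.null(config)) parts <- c(parts, paste0("config=", config_hash(config)))
  paste0(prefix, paste(parts, collapse = ";"))
}

# read a '#'-headered TSV; the last comment line carries the column names
read_tsv_hash <- function(path, required = NULL) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  if (!any(is_comment)) {
    df <- read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                     stringsAsFactors = FALSE)
  } else {
    header <- sub("^#", "", lines[max(which(is_comment))])
    cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
    body <- lines[!is_comment]
    df <- if (length(body)) {
      read.delim(text = paste(body, collapse = "\n"), header = FALSE,
                 sep = "\t", na.strings = ".", stringsAsFactors = FALSE,
                 col.names = cols, check.names = FALSE)
    } else {
      setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    }
  }
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

write_tsv_hash <- function(df, path, seed = NULL, config = NULL) {
  writeLines(c(stamp_line(seed, config),
               paste0("#", paste(names(df), collapse = "\t"))), path)
  if (nrow(df)) {
    df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = FALSE,
                                 append = TRUE))
  }
  invisible(path)
}

#' Write / read simulated pileups as TSV
#'
#' The file carries one row per site with 1-based positions: `chrom`, `pos`,
#' `ref`, `depth`, base-support columns `A`/`C`/`G`/`T` (the reference base's
#' column holds the reference-supporting count), and one extra column per
#' non-SNV allele observed anywhere in the file, named `ins:<seq>` (inserted
#' sequence), `del:<seq>` (deleted sequence) or `mnv:<ref>><alt>`. The
#' round-trip back to the in-memory long format is lossless.
#'
#' @param pileups pileup frame (see [simulate_pileups()]).
#' @param path file path.
#' @param seed,config optional provenance stamped into the header.
#' @return `path` (writer) / pileup frame (reader).
#' @export
write_pileups <- function(pileups, path, seed = NULL, config = NULL) {
  sites <- unique(pileups[, c("chrom", "pos", "ref", "depth")])
  key <- paste(sites$chrom, sites$pos)
  j <- match(paste(pileups$chrom, pileups$pos), key)
  base_cols <- matrix(0L, nrow = nrow(sites), ncol = 4L,
                      dimnames = list(NULL, c("A", "C", "G", "T")))
  is_ref_row <- pileups$allele_ref == "."
  is_snv <- !is_ref_row & nchar(pileups$allele_ref) == 1L &
    nchar(pileups$allele_alt) == 1L
  sel <- is_ref_row & pileups$ref %in% colnames(base_cols)
  base_cols[cbind(j[sel], match(pileups$ref[sel], colnames(base_cols)))] <-
    pileups$count[sel]
  base_cols[cbind(j[is_snv], match(pileups$allele_alt[is_snv],
                                   colnames(base_cols)))] <-
    pileups$count[is_snv]
  extra_cols <- list()
  for (i in which(!is_ref_row & !is_snv)) {
    r <- pileups[i, ]
    kind <- variant_kind(r$allele_ref, r$allele_alt)
    col <- switch(kind,
      INS = paste0("ins:", substr(r$allele_alt, nchar(r$allele_ref) + 1L,
                                  nchar(r$allele_alt))),
      DEL = paste0("del:", substr(r$allele_ref, nchar(r$allele_alt) + 1L,
                                  nchar(r$allele_ref))),
      paste0("mnv:", r$allele_ref, ">", r$allele_alt)
    )
    if (is.null(extra_cols[[col]])) extra_cols[[col]] <- rep(0L, nrow(sites))
    extra_cols[[col]][j[i]] <- extra_cols[[col]][j[i]] + r$count
  }
  out <- data.frame(chrom = sites$chrom, pos = sites$pos + 1L, ref = sites$ref,
                    depth = sites$depth, base_cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (col in names(extra_cols)) out[[col]] <- extra_cols[[col]]
  write_tsv_hash(out, path, seed, config)
}

#' @rdname write_pileups
#' @export
read_pileups <- function(path) {
  df <- read_tsv_hash(path, c("chrom", "pos", "ref", "depth", "A", "C", "G", "T"))
  extra <- setdiff(names(df), c("chrom", "pos", "ref", "depth", "A", "C", "G", "T"))
  rows <- list()
  for (b in c("A", "C", "G", "T")) {
    cnt <- as.integer(df[[b]])
    is_ref <- df$ref == b
    sel <- cnt > 0L | is_ref
    rows[[b]] <- data.frame(
      chrom = df$chrom[sel], pos = as.integer(df$pos[sel]) - 1L,
      ref = df$ref[sel], depth = as.integer(df$depth[sel]),
      allele_ref = ifelse(is_ref[sel], ".", df$ref[sel]),
      allele_alt = ifelse(is_ref[sel], ".", b),
      count = cnt[sel], stringsAsFactors = FALSE
    )
  }
  for (col in extra) {
    cnt <- as.integer(df[[col]])
    sel <- cnt > 0L
    if (!any(sel)) next
    tag <- sub(":.*$", "", col)
    payload <- sub("^[a-z]+:", "", col)
    ar <- aa <- character(sum(sel))
    if (tag == "ins") {
      ar <- df$ref[sel]
      aa <- paste0(df$ref[sel], payload)
    } else if (tag == "del") {
      ar <- paste0(df$ref[sel], payload)
      aa <- df$ref[sel]
    } else {
      parts <- strsplit(payload, ">", fixed = TRUE)[[1]]
      ar <- rep(parts[1], sum(sel))
      aa <- rep(parts[2], sum(sel))
    }
    rows[[col]] <- data.frame(
      chrom = df$chrom[sel], pos = as.integer(df$pos[sel]) - 1L,
      ref = df$ref[sel], depth = as.integer(df$depth[sel]),
      allele_ref = ar, allele_alt = aa, count = cnt[sel],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$allele_alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

VCF_INFO_KEYS <- c("AF", "DP", "AO", "CALLER", "QBAND", "HPLEN")

#' Write / read variant calls as VCF 4.2
#'
#' Sites-only single-caller VCF carrying the call annotations in INFO keys
#' `AF` (allele fraction), `DP` (depth), `AO` (alternate observations),
#' `CALLER` (A/B), `QBAND` (normal/low) and `HPLEN` (homopolymer context
#' length). File positions are 1-based; the reader converts back to the
#' package's 0-based convention. A missing required INFO key is a schema
#' error naming the key and record.
#'
#' @param calls calls data.frame.
#' @param path file path.
#' @param reference_id reference build label for the header.
#' @param seed,config optional provenance stamped into the header.
#' @param filter optional character vector for the FILTER column (defaults
#'   to `.`).
#' @return `path` (writer) / calls data.frame (reader).
#' @export
write_vcf <- function(calls, path, reference_id = "unknown", seed = NULL,
                      config = NULL, filter = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", sub("^#", "", stamp_line(seed, config, prefix = ""))),
    paste0("##reference=", reference_id),
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Observed allele fraction">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Site depth">',
    '##INFO=<ID=AO,Number=1,Type=Integer,Description="Alternate allele observations">',
    '##INFO=<ID=CALLER,Number=1,Type=String,Description="Calling algorithm (A=frequency threshold, B=exact binomial)">',
    '##INFO=<ID=QBAND,Number=1,Type=String,Description="Quality band (normal or low)">',
    '##INFO=<ID=HPLEN,Number=1,Type=Integer,Description="Homopolymer run length at or adjacent to the site (0=none)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- if (nrow(calls)) {
    info <- sprintf("AF=%.6g;DP=%d;AO=%d;CALLER=%s;QBAND=%s;HPLEN=%d",
                    calls$af, calls$depth, calls$alt_count, calls$caller,
                    calls$quality_band,
                    ifelse(is.na(calls$hp_len), 0L, calls$hp_len))
    paste(calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt,
          sprintf("%.4g", calls$quality), filter %||% ".", info, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(empty_calls())
  bad_alt <- is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  if (any(bad_alt)) {
    stop(sprintf("read_vcf: missing ALT allele at record %d",
                 which(bad_alt)[1]), call. = FALSE)
  }
  info <- lapply(VCF_INFO_KEYS, function(k) {
    val <- vcfR::extract.info(v, element = k)
    if (is.null(val) || all(is.na(val))) {
      stop(sprintf("read_vcf: required INFO key '%s' absent from %s", k, path),
           call. = FALSE)
    }
    if (anyNA(val)) {
      stop(sprintf("read_vcf: INFO key '%s' missing at record %d of %s",
                   k, which(is.na(val))[1], path), call. = FALSE)
    }
    val
  })
  names(info) <- VCF_INFO_KEYS
  quality <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]) - 1L,
    ref = ref, alt = alt,
    af = as.numeric(info$AF), depth = as.integer(info$DP),
    alt_count = as.integer(info$AO), caller = info$CALLER,
    quality = quality, quality_band = info$QBAND,
    kind = variant_kind(ref, alt), hp_len = as.integer(info$HPLEN),
    filter = fix[, "FILTER"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a triage result
#'
#' `write_triage_vcf()` emits a VCF whose FILTER column carries the triage
#' outcome (`PASS` for confirmed, the reason code for filtered,
#' `requires_orthogonal_validation` for pending variants).
#' `write_triage_tsv()` and `write_triage_summary()` emit the tabular report
#' and a JSON summary of status/reason tallies.
#'
#' @param triaged a [triage()] result.
#' @param path output path.
#' @param reference_id,seed,config provenance for the VCF header.
#' @return `path`, invisibly.
#' @export
write_triage_vcf <- function(triaged, path, reference_id = "unknown",
                             seed = NULL, config = NULL) {
  filt <- ifelse(triaged$status == "confirmed", "PASS",
                 ifelse(triaged$status == "filtered", triaged$reason,
                        "requires_orthogonal_validation"))
  write_vcf(triaged, path, reference_id, seed, config, filter = filt)
}

#' @rdname write_triage_vcf
#' @export
write_triage_tsv <- function(triaged, path, seed = NULL, config = NULL) {
  df <- as.data.frame(triaged)
  df$pos <- df$pos + 1L  # 1-based on disk
  write_tsv_hash(df, path, seed, config)
}

#' @rdname write_triage_vcf
#' @export
write_triage_summary <- function(triaged, path, seed = NULL, config = NULL) {
  summary <- list(
    tool = paste0("ampliqc ", as.character(packageVersion("ampliqc"))),
    seed = seed,
    config = if (!is.null(config)) config_hash(config) else NULL,
    n_variants = nrow(triaged),
    by_status = as.list(table(triaged$status)),
    by_reason = as.list(table(triaged$reason[triaged$status == "filtered"])),
    confirmed = if (any(triaged$status == "confirmed")) {
      t2 <- triaged[triaged$status == "confirmed", ]
      lapply(seq_len(nrow(t2)), function(i) list(
        chrom = t2$chrom[i], pos = t2$pos[i] + 1L, ref = t2$ref[i],
        alt = t2$alt[i], af = t2$af[i], catalog_id = t2$catalog_id[i]
      ))
    } else list()
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a mutation catalog TSV
#'
#' Columns `chrom`, `pos` (1-based on disk), `ref`, `alt`, `cosmic_like_id`,
#' `dbsnp_like_id`, `gmaf`, `pathogenic`; `.` for missing.
#'
#' @param catalog catalog data.frame (see [demo_catalog()]).
#' @param path file path.
#' @return `path` (writer) / catalog data.frame (reader).
#' @export
write_catalog <- function(catalog, path) {
  df <- catalog
  df$pos <- df$pos + 1L
  write_tsv_hash(df, path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv_hash(path, c("chrom", "pos", "ref", "alt", "pathogenic"))
  df$pos <- as.integer(df$pos) - 1L
  df$gmaf <- as.numeric(df$gmaf)
  df$pathogenic <- as.logical(df$pathogenic)
  df
}

#' Write / read a truth-set VCF
#'
#' Minimal VCF 4.2 with the true allele fraction in INFO key `TAF` and the
#' variant label in ID.
#'
#' @param truth data.frame with `chrom`, `pos`, `ref`, `alt`, `af`, `label`.
#' @param path file path.
#' @param reference_id reference build label.
#' @return `path` (writer) / truth data.frame (reader).
#' @export
write_truth_vcf <- function(truth, path, reference_id = "unknown") {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", sub("^#", "", stamp_line(prefix = ""))),
    paste0("##reference=", reference_id),
    '##INFO=<ID=TAF,Number=1,Type=Float,Description="True allele fraction">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- if (nrow(truth)) {
    paste(truth$chrom, truth$pos + 1L,
          truth$label %||% ".", truth$ref, truth$alt, ".", ".",
          sprintf("TAF=%.6g", truth$af), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_truth_vcf
#' @export
read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  taf <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "TAF")))
  data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"], af = taf,
    label = fix[, "ID"], stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a run configuration JSON
#'
#' @param path JSON file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
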
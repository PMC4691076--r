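# fixtures are built in code: a tiny hand-written panel with known GC and a
# planted homopolymer, and constructors for pileup/call frames.

# chrT: 60 bp; positions 20-26 hold AAAAAAA (7-run); chrG is GC-rich
TINY_REF_SEQS <- c(
  chrT = paste0("ACGTACGTACGTACGTACGT", "AAAAAAA", "CGTACGTACGTACGTACGTACGTACGTACGTAC"),
  chrG = "GGCCGGCCGGCCGGCCGGCCGGCCGGCCGGCCGGCCGGCC"
)

tiny_panel <- function() {
  bed <- tempfile(fileext = ".bed")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    "chrT\t0\t40\tTINY_1\t0\t+",
    "chrT\t42\t58\tTINY_2\t0\t+",
    "chrG\t0\t40\tGCAMP_1\t0\t+"
  ), bed)
  writeLines(c(">chrT", TINY_REF_SEQS[["chrT"]], ">chrG", TINY_REF_SEQS[["chrG"]]), fa)
  load_panel(bed, fa, reference_id = "tiny-test")
}

# one site's pileup rows; alleles is a named count vector keyed "REF>ALT",
# remainder of depth becomes reference support
make_site <- function(chrom, pos, ref, depth, alleles = c()) {
  rows <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, depth = as.integer(depth),
    allele_ref = ".", allele_alt = ".",
    count = as.integer(depth - sum(alleles)), stringsAsFactors = FALSE
  )
  for (k in names(alleles)) {
    parts <- strsplit(k, ">", fixed = TRUE)[[1]]
    rows <- rbind(rows, data.frame(
      chrom = chrom, pos = as.integer(pos), ref = ref,
      depth = as.integer(depth), allele_ref = parts[1], allele_alt = parts[2],
      count = as.integer(alleles[[k]]), stringsAsFactors = FALSE
    ))
  }
  rows
}

make_call <- function(chrom, pos, ref, alt, af, depth, caller = "A",
                      quality = 50, quality_band = "normal", hp_len = 0L) {
  data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, af = af,
    depth = as.integer(depth), alt_count = as.integer(round(af * depth)),
    caller = caller, quality = quality, quality_band = quality_band,
    kind = variant_kind(ref, alt), hp_len = as.integer(hp_len),
    stringsAsFactors = FALSE
  )
}
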
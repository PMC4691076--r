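# ---- packaged demo panel ----------------------------------------------------
#
# The commercial colon/lung hotspot panel design is proprietary, so the package
# ships a synthetic but structurally faithful stand-in: 90 amplicons over the
# 22 lung/colon cancer genes, built on a generated mini-reference. Five
# amplicons carry the recurrently under-covered high-GC identities
# (AKT1_1, FGFR3_2, NOTCH1_1, STK11_3, TP53_2), and the reference contains
# exactly five homopolymer runs of >= 5 bp (the eligible sites for WGA
# insertion artifacts). The construction is deterministic (fixed internal
# seed), so coordinates are stable across sessions and independent of any
# user-supplied simulation seed.

DEMO_GENES <- c(
  "AKT1", "ALK", "BRAF", "CTNNB1", "DDR2", "EGFR", "ERBB2", "ERBB4",
  "FBXW7", "FGFR1", "FGFR2", "FGFR3", "KRAS", "MAP2K1", "MET", "NOTCH1",
  "NRAS", "PIK3CA", "PTEN", "SMAD4", "STK11", "TP53"
)

DEMO_HIGH_GC <- c("AKT1_1", "FGFR3_2", "NOTCH1_1", "STK11_3", "TP53_2")

# amplicon -> (relative run start within amplicon, base, run length)
DEMO_HOMOPOLYMERS <- list(
  BRAF_2  = list(rel = 60L, base = "A", len = 6L),
  MET_1   = list(rel = 45L, base = "T", len = 5L),
  PTEN_2  = list(rel = 70L, base = "A", len = 7L),
  ERBB2_1 = list(rel = 55L, base = "G", len = 5L),
  SMAD4_3 = list(rel = 40L, base = "C", len = 6L)
)

# sequence with an exact GC base count and no homopolymer run >= 5; long runs
# are broken by swapping their last base with a random unlike base elsewhere
exact_seq <- function(n, gc) {
  n_gc <- round(gc * n)
  pool <- c(rep(c("G", "C"), length.out = n_gc),
            rep(c("A", "T"), length.out = n - n_gc))
  s <- sample(pool)
  for (iter in 1:200) {
    r <- rle(s)
    bad <- which(r$lengths >= 5L)
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    for (b in bad) {
      i <- ends[b]
      j <- sample(which(s != s[i]), 1L)
      tmp <- s[i]
      s[i] <- s[j]
      s[j] <- tmp
    }
  }
  paste(s, collapse = "")
}

# random sequence with a target GC fraction and no homopolymer run >= max_run+1
random_seq <- function(n, gc, max_run = 4L) {
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- character(n)
  run_base <- ""
  run_len <- 0L
  for (i in seq_len(n)) {
    b <- sample(bases, 1L, prob = probs)
    if (b == run_base && run_len >= max_run) {
      b <- sample(bases[bases != run_base], 1L,
                  prob = probs[bases != run_base])
    }
    if (b == run_base) run_len <- run_len + 1L else {
      run_base <- b
      run_len <- 1L
    }
    out[i] <- b
  }
  paste(out, collapse = "")
}

#' The packaged 90-amplicon demo panel
#'
#' Builds the deterministic demo panel: 90 amplicons across 22 genes, one
#' mini-contig per gene, and exactly five homopolymer runs of >= 5 bp planted
#' in five distinct amplicons. Five amplicons carry the recurrently
#' under-covered identities and are modeled as long (250 bp), CpG-island-like
#' targets with GC fixed at 0.836; the remaining 85 are 100-160 bp with GC
#' 0.40-0.55. Amplicon coordinates and sequences are identical on every call.
#'
#' @return an `amplicon_panel` (see [load_panel()]).
#' @examples
#' panel <- demo_panel()
#' n_amplicons(panel)  # 90
#' @export
demo_panel <- function() {
  with_seed(20151203, {
    per_gene <- setNames(rep(4L, length(DEMO_GENES)), DEMO_GENES)
    per_gene[c("EGFR", "TP53")] <- 5L  # 20*4 + 2*5 = 90
    pad <- 30L
    gap <- 25L
    rows <- list()
    seqs <- character(0)
    for (gene in DEMO_GENES) {
      n_amp <- per_gene[[gene]]
      lens <- sample(100:160, n_amp, replace = TRUE)
      names <- paste0(gene, "_", seq_len(n_amp))
      high <- names %in% DEMO_HIGH_GC
      lens[high] <- 250L
      gcs <- ifelse(high, 0.836, runif(n_amp, 0.40, 0.55))
      contig <- random_seq(pad, 0.45)
      starts <- integer(n_amp)
      for (i in seq_len(n_amp)) {
        starts[i] <- nchar(contig)
        amp_seq <- exact_seq(lens[i], gcs[i])
        hp <- DEMO_HOMOPOLYMERS[[names[i]]]
        if (!is.null(hp)) {
          run <- strrep(hp$base, hp$len)
          others <- setdiff(c("A", "C", "G", "T"), hp$base)
          # flanks differ from the run base and from their outer neighbour,
          # so the planted run stays maximal at exactly hp$len
          left_outer <- substr(amp_seq, hp$rel - 1L, hp$rel - 1L)
          right_outer <- substr(amp_seq, hp$rel + hp$len + 2L, hp$rel + hp$len + 2L)
          lflank <- setdiff(others, left_outer)[1]
          rflank <- setdiff(others, right_outer)[1]
          substr(amp_seq, hp$rel, hp$rel + hp$len + 1L) <-
            paste0(lflank, run, rflank)
        }
        contig <- paste0(contig, amp_seq, random_seq(gap, 0.45))
      }
      contig <- paste0(contig, random_seq(pad - gap, 0.45))
      seqs[[paste0(gene, "_locus")]] <- contig
      rows[[gene]] <- data.frame(
        name = names, chrom = paste0(gene, "_locus"),
        start = starts, end = starts + lens, gene = gene,
        stringsAsFactors = FALSE
      )
    }
    ref <- Biostrings::DNAStringSet(unlist(seqs))
    build_panel(do.call(rbind, rows), ref, reference_id = "ampliqc-demo-1")
  })
}

# single catalog/truth site: read ref alleles off the panel reference
demo_site <- function(panel, amp_name, rel, type = c("SNV", "MNV", "DEL", "INS"),
                      del_len = 15L, ins_seq = "TGA") {
  type <- match.arg(type)
  a <- panel[panel$name == amp_name, ]
  if (nrow(a) != 1L) stop("unknown demo amplicon: ", amp_name, call. = FALSE)
  pos <- a$start + rel
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  switch(type,
    SNV = {
      ref <- reference_slice(panel, a$chrom, pos, pos + 1L)
      list(chrom = a$chrom, pos = pos, ref = ref, alt = unname(flip[ref]))
    },
    MNV = {
      ref <- reference_slice(panel, a$chrom, pos, pos + 2L)
      alt <- paste(flip[strsplit(ref, "")[[1]]], collapse = "")
      list(chrom = a$chrom, pos = pos, ref = ref, alt = alt)
    },
    DEL = {
      ref <- reference_slice(panel, a$chrom, pos, pos + del_len + 1L)
      list(chrom = a$chrom, pos = pos, ref = ref, alt = substr(ref, 1L, 1L))
    },
    INS = {
      ref <- reference_slice(panel, a$chrom, pos, pos + 1L)
      list(chrom = a$chrom, pos = pos, ref = ref, alt = paste0(ref, ins_seq))
    }
  )
}

#' Mini mutation catalog mapped onto the demo panel
#'
#' A small COSMIC/dbSNP-style catalog whose entries are placed at fixed
#' offsets inside demo-panel amplicons, with reference alleles read directly
#' off the demo reference (so keys always match panel-derived calls). Two
#' intronic-style SNPs carry a global minor allele frequency below 0.01
#' ("rare"); one common SNP carries 0.54.
#'
#' @param panel the demo panel (defaults to [demo_panel()]).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `cosmic_like_id`, `dbsnp_like_id`, `gmaf`, `pathogenic`.
#' @export
demo_catalog <- function(panel = demo_panel()) {
  spec <- list(
    list("KRAS_1", 30L, "SNV", "COSM516", NA, NA, TRUE),
    list("KRAS_1", 45L, "SNV", "COSM518", NA, NA, TRUE),
    list("KRAS_1", 60L, "SNV", "COSM520", NA, NA, TRUE),
    list("KRAS_1", 75L, "SNV", "COSM521", NA, NA, TRUE),
    list("KRAS_2", 40L, "SNV", "COSM527", NA, NA, TRUE),
    list("EGFR_1", 50L, "SNV", "COSM6224", NA, NA, TRUE),
    list("EGFR_3", 35L, "DEL", "COSM6225", NA, NA, TRUE),
    list("EGFR_3", 70L, "DEL", "COSM12384", NA, NA, TRUE),
    list("EGFR_4", 55L, "MNV", "COSM24267", NA, NA, TRUE),
    list("MET_2", 30L, "SNV", "COSM706", NA, NA, TRUE),
    list("MET_2", 50L, "SNV", "COSM710", NA, NA, TRUE),
    list("MET_2", 70L, "SNV", "COSM1579024", NA, NA, TRUE),
    list("TP53_1", 45L, "SNV", NA, "rs1042522", 0.54, FALSE),
    list("DDR2_1", 40L, "SNV", NA, "rs200983597", 0.004, FALSE),
    list("DDR2_1", 65L, "SNV", NA, "rs143729297", 0.008, FALSE)
  )
  rows <- lapply(spec, function(s) {
    site <- demo_site(panel, s[[1]], s[[2]], s[[3]], del_len = 15L)
    data.frame(
      chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      cosmic_like_id = s[[4]], dbsnp_like_id = s[[5]],
      gmaf = as.numeric(s[[6]]), pathogenic = s[[7]],
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  # keys are stored in normalized (left-aligned, parsimonious) form so they
  # always match normalized caller output
  norm <- normalize_variants(df, panel)
  df$pos <- norm$pos
  df$ref <- norm$ref
  df$alt <- norm$alt
  df
}

#' Demo truth variant sets
#'
#' `demo_truth_set()` returns a mixed truth set (catalog SNVs, a 15-bp
#' deletion, an MNV, and SNPs) with allele fractions typical of the tumor
#' samples the workflow targets. `demo_dilution_truth()` returns the single
#' gatekeeper-mutation-style SNV used for dilution-series limit-of-detection
#' runs, placed in an EGFR amplicon.
#'
#' @param panel the demo panel.
#' @param af true allele fraction for the dilution variant.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `af`, `label`.
#' @export
demo_truth_set <- function(panel = demo_panel()) {
  cat <- demo_catalog(panel)
  pick <- function(id, af) {
    r <- cat[which(cat$cosmic_like_id %in% id | cat$dbsnp_like_id %in% id)[1], ]
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               af = af, label = id, stringsAsFactors = FALSE)
  }
  rbind(
    pick("COSM518", 0.298),
    pick("COSM6224", 0.453),
    pick("COSM6225", 0.078),
    pick("COSM24267", 0.378),
    pick("rs1042522", 0.50),
    pick("rs200983597", 0.50)
  )
}

#' @rdname demo_truth_set
#' @export
demo_dilution_truth <- function(panel = demo_panel(), af = 0.05) {
  site <- demo_site(panel, "EGFR_2", 50L, "SNV")
  data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
             alt = site$alt, af = af, label = "p.Thr790Met-like",
             stringsAsFactors = FALSE)
}
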
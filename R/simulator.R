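# ---- pileup-level amplicon simulator ---------------------------------------
#
# The simulator reproduces the assay's stated failure modes at the pileup
# level (per-site depth and allele counts), which is the unit the callers and
# the triage cascade consume: degradation-linked dropout of long amplicons,
# GC-dependent under-coverage, uniform substitution sequencing error, dilution
# mixtures, and WGA insertion artifacts at homopolymers. Read-level output is
# deliberately out of scope.

#' Simulation profile for one sample
#'
#' @param sample_type `"FFPE"`, `"SF"`, `"cfDNA_WGA"` or `"cfDNA_noWGA"`.
#' @param ayr Average Yield Ratio driving length-dependent dropout (1 =
#'   intact, no dropout).
#' @param mean_depth target mean reads per amplicon for an intact template.
#' @param error_rate per-base substitution probability (split equally among
#'   the three non-reference bases).
#' @param gc_penalty_knee GC fraction above which coverage decays.
#' @param gc_penalty_slope linear decay rate above the knee; the default
#'   (10/3) halves coverage at GC 0.75.
#' @param wga whether the sample went through whole-genome amplification.
#' @param wga_artifact_prob per-eligible-homopolymer probability of an
#'   insertion artifact.
#' @param wga_artifact_af_range allele-fraction range of artifacts (uniform).
#' @param seed per-sample RNG seed.
#' @param artifact_seed panel-level RNG seed for artifact placement; samples
#'   sharing it receive artifacts at the same sites (recurrent artifacts).
#' @return a `sample_profile` list.
#' @export
sample_profile <- function(sample_type = "SF", ayr = 1, mean_depth = 6000,
                           error_rate = 0.005, gc_penalty_knee = 0.60,
                           gc_penalty_slope = 10 / 3, wga = FALSE,
                           wga_artifact_prob = 0.5,
                           wga_artifact_af_range = c(0.01, 0.10),
                           seed = 1L, artifact_seed = seed) {
  stopifnot(
    ayr > 0, ayr <= 1, mean_depth > 0,
    error_rate >= 0, error_rate <= 1,
    wga_artifact_prob >= 0, wga_artifact_prob <= 1,
    length(wga_artifact_af_range) == 2L,
    all(wga_artifact_af_range > 0), all(wga_artifact_af_range <= 1)
  )
  structure(list(
    sample_type = sample_type, ayr = ayr, mean_depth = mean_depth,
    error_rate = error_rate, gc_penalty_knee = gc_penalty_knee,
    gc_penalty_slope = gc_penalty_slope, wga = wga,
    wga_artifact_prob = wga_artifact_prob,
    wga_artifact_af_range = wga_artifact_af_range,
    seed = as.integer(seed), artifact_seed = as.integer(artifact_seed)
  ), class = "sample_profile")
}

# forward model: AYR implied by mean intact-template length mu over the
# multiplex-PCR fragment ladder
ayr_from_mu <- function(mu, fragment_lengths = c(200, 300, 400)) {
  mean(exp(-fragment_lengths / mu))
}

#' Degradation model: intact-template length from an AYR
#'
#' Models the surviving template as exponentially length-dependent,
#' `P(intact at length L) = exp(-L / mu)`, and solves
#' `mean_L exp(-L / mu) = AYR` over the 200/300/400 bp fragment ladder by
#' bisection (to well within 1e-6 in AYR). This is the link between the
#' multiplex-PCR integrity score and length-dependent amplicon dropout.
#'
#' @param ayr Average Yield Ratio in (0, 1]; 1 maps to `mu = Inf` (no
#'   dropout).
#' @param fragment_lengths the PCR fragment ladder in bp.
#' @return a `degradation_model` list: `mu` (bp), `ayr`, `fragment_lengths`.
#' @examples
#' mu_from_ayr(0.3816312)$mu  # ~300 bp
#' @export
mu_from_ayr <- function(ayr, fragment_lengths = c(200, 300, 400)) {
  if (ayr <= 0) stop("mu_from_ayr: ayr must be positive", call. = FALSE)
  if (ayr >= 1) {
    return(structure(list(mu = Inf, ayr = 1, fragment_lengths = fragment_lengths),
                     class = "degradation_model"))
  }
  lo <- 1e-3
  hi <- 1e3
  while (ayr_from_mu(hi, fragment_lengths) < ayr) hi <- hi * 2
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    val <- ayr_from_mu(mid, fragment_lengths)
    if (abs(val - ayr) < 1e-9) break
    if (val < ayr) lo <- mid else hi <- mid
  }
  structure(list(mu = mid, ayr = ayr, fragment_lengths = fragment_lengths),
            class = "degradation_model")
}

# piecewise-linear GC coverage penalty: 1 at or below the knee, linear decay
# above, floored at 0
gc_penalty <- function(gc, knee = 0.60, slope = 10 / 3) {
  pmax(0, 1 - slope * pmax(0, gc - knee))
}

# expected per-amplicon depth under a profile
expected_depths <- function(panel, profile) {
  mu <- mu_from_ayr(profile$ayr)$mu
  drop <- if (is.infinite(mu)) rep(1, nrow(panel)) else exp(-panel$length / mu)
  profile$mean_depth * drop * gc_penalty(panel$gc, profile$gc_penalty_knee,
                                         profile$gc_penalty_slope)
}

#' Simulate per-amplicon coverage
#'
#' Draws each amplicon's depth from
#' `Poisson(mean_depth * exp(-length/mu) * g(gc))`, where `mu` comes from the
#' profile's AYR via [mu_from_ayr()] and `g` is a piecewise-linear GC penalty
#' (1 below the knee, decaying above it). Deterministic under the profile
#' seed.
#'
#' @param panel an `amplicon_panel`.
#' @param profile a [sample_profile()].
#' @return named integer vector of depths (names are amplicon names).
#' @export
simulate_coverage <- function(panel, profile) {
  if (nrow(panel) == 0L) stop("simulate_coverage: empty panel", call. = FALSE)
  lambda <- expected_depths(panel, profile)
  with_seed(derive_seed(profile$seed, 1L),
            setNames(rpois(nrow(panel), lambda), panel$name))
}

# vectorized sequential-binomial split of n trials among alleles with
# probabilities in `p` (columns); remainder is the reference count.
# exact multinomial via the chain rule, vectorized over sites.
multinomial_counts <- function(n, p) {
  remaining <- n
  used <- rep(0, length(n))
  out <- matrix(0L, nrow = length(n), ncol = ncol(p))
  for (j in seq_len(ncol(p))) {
    cond <- ifelse(1 - used > 0, pmin(1, p[, j] / (1 - used)), 0)
    out[, j] <- rbinom(length(n), remaining, cond)
    remaining <- remaining - out[, j]
    used <- used + p[, j]
  }
  list(counts = out, ref = remaining)
}

#' Simulate per-site pileups over a panel
#'
#' Every base of every amplicon receives the amplicon's simulated depth
#' (see [simulate_coverage()]; both functions draw the same depths under the
#' same seed). At a truth-variant site the alternate allele count is
#' `Binomial(depth, af*(1-e) + (1-af)*e/3)` with `e` the per-base error rate;
#' all sites additionally receive error-only substitution counts at rate
#' `e/3` per non-reference base. Counts at each site sum exactly to depth.
#'
#' @param panel an `amplicon_panel`.
#' @param truth `NULL`, or a data.frame with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `af` (and optionally `label`). Every truth variant must lie
#'   inside exactly one amplicon.
#' @param profile a [sample_profile()].
#' @return a data.frame with columns `chrom`, `pos` (0-based), `ref` (site
#'   base), `depth`, `allele_ref`, `allele_alt` (both `"."` for
#'   reference-supporting reads), `count`.
#' @export
simulate_pileups <- function(panel, truth = NULL, profile = sample_profile()) {
  depths <- simulate_coverage(panel, profile)
  ref <- attr(panel, "reference")
  site_list <- lapply(seq_len(nrow(panel)), function(i) {
    s <- reference_slice(panel, panel$chrom[i], panel$start[i], panel$end[i])
    data.frame(
      chrom = panel$chrom[i],
      pos = seq(panel$start[i], panel$end[i] - 1L),
      ref = strsplit(s, "", fixed = TRUE)[[1]],
      depth = unname(depths[panel$name[i]]),
      stringsAsFactors = FALSE
    )
  })
  sites <- do.call(rbind, site_list)

  truth_idx <- integer(0)
  if (!is.null(truth) && nrow(truth)) {
    hits <- vapply(seq_len(nrow(truth)), function(k) {
      span_end <- truth$pos[k] + nchar(truth$ref[k])
      sum(panel$chrom == truth$chrom[k] & panel$start <= truth$pos[k] &
            panel$end >= span_end)
    }, 0L)
    if (any(hits != 1L)) {
      stop(sprintf("simulate_pileups: truth variant at %s:%d falls inside %d amplicons (need exactly 1)",
                   truth$chrom[which(hits != 1L)[1]],
                   truth$pos[which(hits != 1L)[1]],
                   hits[which(hits != 1L)[1]]), call. = FALSE)
    }
    truth_idx <- match(paste(truth$chrom, truth$pos),
                       paste(sites$chrom, sites$pos))
  }

  e <- profile$error_rate
  pe <- e / 3
  bases <- c("A", "C", "G", "T")

  with_seed(derive_seed(profile$seed, 2L), {
    # error-only sites: three non-reference substitution alleles
    plain <- if (length(truth_idx)) sites[-truth_idx, , drop = FALSE] else sites
    plain <- plain[plain$ref %in% bases, , drop = FALSE]
    p3 <- matrix(pe, nrow = nrow(plain), ncol = 3L)
    mc <- multinomial_counts(plain$depth, p3)
    other_map <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                          "A", "C", "G"), nrow = 4L, byrow = TRUE,
                        dimnames = list(bases, NULL))
    other <- other_map[plain$ref, , drop = FALSE]
    plain_rows <- data.frame(
      chrom = rep(plain$chrom, 4L),
      pos = rep(plain$pos, 4L),
      ref = rep(plain$ref, 4L),
      depth = rep(plain$depth, 4L),
      allele_ref = c(rep(plain$ref, 3L), rep(".", nrow(plain))),
      allele_alt = c(other[, 1], other[, 2], other[, 3],
                     rep(".", nrow(plain))),
      count = c(mc$counts[, 1], mc$counts[, 2], mc$counts[, 3], mc$ref),
      stringsAsFactors = FALSE
    )
    plain_rows$allele_ref[plain_rows$allele_alt == "."] <- "."

    var_rows <- NULL
    if (length(truth_idx)) {
      var_rows <- do.call(rbind, lapply(seq_along(truth_idx), function(k) {
        st <- sites[truth_idx[k], ]
        af <- truth$af[k]
        p_alt <- af * (1 - e) + (1 - af) * pe
        err_bases <- if (nchar(truth$ref[k]) == 1L && nchar(truth$alt[k]) == 1L) {
          setdiff(bases, c(st$ref, truth$alt[k]))  # SNV truth occupies one error base
        } else {
          setdiff(bases, st$ref)
        }
        p <- matrix(c(p_alt, rep(pe, length(err_bases))), nrow = 1L)
        mc1 <- multinomial_counts(st$depth, p)
        data.frame(
          chrom = st$chrom, pos = st$pos, ref = st$ref, depth = st$depth,
          allele_ref = c(truth$ref[k], rep(st$ref, length(err_bases)), "."),
          allele_alt = c(truth$alt[k], err_bases, "."),
          count = c(mc1$counts[1, ], mc1$ref),
          stringsAsFactors = FALSE
        )
      }))
    }
    out <- rbind(plain_rows, var_rows)
    out <- out[out$count > 0L | out$allele_ref == ".", , drop = FALSE]
    out <- out[order(out$chrom, out$pos, out$allele_alt), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Mixing fractions for a dilution series
#'
#' Fraction of mutant stock to mix with wild-type material to hit each target
#' allele fraction: `f = target / stock_af`.
#'
#' @param stock_af allele fraction of the mutant stock.
#' @param targets target allele fractions (each in `(0, stock_af]`).
#' @return named numeric vector of mixing fractions.
#' @export
make_dilution_series <- function(stock_af, targets) {
  stopifnot(stock_af > 0, stock_af <= 1)
  if (any(targets <= 0) || any(targets > stock_af)) {
    stop("make_dilution_series: targets must lie in (0, stock_af]", call. = FALSE)
  }
  setNames(targets / stock_af, paste0(targets * 100, "%"))
}

#' Inject WGA homopolymer insertion artifacts into pileups
#'
#' Each homopolymer run of at least 5 bp in the panel independently receives
#' a 1-bp insertion artifact (one more copy of the run base, left-aligned to
#' the base preceding the run) with probability `wga_artifact_prob`, at an
#' allele fraction drawn uniformly from `wga_artifact_af_range`. Artifact
#' placement and target fractions come from a panel-level stream seeded by
#' `artifact_seed`, so samples sharing that seed show the same recurrent
#' artifacts; only read counts are drawn per sample. Sites already carrying
#' the identical allele (e.g. a truth insertion) are skipped, so the ledger
#' never overlaps the truth set.
#'
#' @param pileups output of [simulate_pileups()].
#' @param panel the `amplicon_panel` the pileups were simulated from.
#' @param profile a [sample_profile()] with `wga = TRUE`.
#' @return list with `pileups` (counts re-balanced so sums still equal depth)
#'   and `ledger` (data.frame of ground-truth artifacts: `chrom`, `pos`,
#'   `ref`, `alt`, `af_target`, `base`, `run_length`).
#' @export
inject_wga_artifacts <- function(pileups, panel, profile) {
  empty_ledger <- data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    af_target = numeric(), base = character(), run_length = integer(),
    stringsAsFactors = FALSE
  )
  if (!isTRUE(profile$wga)) {
    warning("inject_wga_artifacts: profile$wga is FALSE; no-op", call. = FALSE)
    return(list(pileups = pileups, ledger = empty_ledger))
  }
  runs <- attr(panel, "homopolymers")
  runs <- runs[runs$run_length >= 5L, , drop = FALSE]
  if (nrow(runs) == 0L) return(list(pileups = pileups, ledger = empty_ledger))

  placement <- with_seed(derive_seed(profile$artifact_seed, 3L), {
    sel <- rbinom(nrow(runs), 1L, profile$wga_artifact_prob) == 1L
    afs <- runif(nrow(runs), profile$wga_artifact_af_range[1],
                 profile$wga_artifact_af_range[2])
    list(sel = sel, afs = afs)
  })
  runs <- runs[placement$sel, , drop = FALSE]
  afs <- placement$afs[placement$sel]
  if (nrow(runs) == 0L) return(list(pileups = pileups, ledger = empty_ledger))

  ledger <- empty_ledger
  with_seed(derive_seed(profile$seed, 4L), {
    for (i in seq_len(nrow(runs))) {
      anchor <- runs$start[i] - 1L
      site <- which(pileups$chrom == runs$chrom[i] & pileups$pos == anchor)
      if (!length(site)) next  # anchor outside the panel footprint
      ref_base <- pileups$ref[site[1]]
      alt <- paste0(ref_base, runs$base[i])
      if (any(pileups$allele_ref[site] == ref_base &
                pileups$allele_alt[site] == alt)) next  # identical truth allele
      depth <- pileups$depth[site[1]]
      cnt <- rbinom(1L, depth, afs[i])
      ref_row <- site[pileups$allele_ref[site] == "."]
      cnt <- min(cnt, pileups$count[ref_row])
      pileups$count[ref_row] <- pileups$count[ref_row] - cnt
      pileups <- rbind(pileups, data.frame(
        chrom = runs$chrom[i], pos = anchor, ref = ref_base, depth = depth,
        allele_ref = ref_base, allele_alt = alt, count = cnt,
        stringsAsFactors = FALSE
      ))
      ledger <- rbind(ledger, data.frame(
        chrom = runs$chrom[i], pos = anchor, ref = ref_base, alt = alt,
        af_target = afs[i], base = runs$base[i],
        run_length = runs$run_length[i], stringsAsFactors = FALSE
      ))
    }
  })
  pileups <- pileups[order(pileups$chrom, pileups$pos, pileups$allele_alt), ,
                     drop = FALSE]
  rownames(pileups) <- NULL
  list(pileups = pileups, ledger = ledger)
}
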
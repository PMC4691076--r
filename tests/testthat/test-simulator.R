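test_that("mu_from_ayr solves the fragment-ladder equation", {
  # forward evaluation at mu = 300 bp over the 200/300/400 ladder
  ayr_300 <- mean(exp(-c(200, 300, 400) / 300))
  m <- mu_from_ayr(ayr_300)
  expect_equal(m$mu, 300, tolerance = 1e-3)

  # round trip: forward model of the solved mu reproduces the input AYR
  for (a in c(0.1, 0.3, 0.5, 0.8, 0.95)) {
    mu <- mu_from_ayr(a)$mu
    expect_equal(mean(exp(-c(200, 300, 400) / mu)), a, tolerance = 1e-6)
  }

  expect_true(mu_from_ayr(0.999)$mu > 1e5)
  expect_true(is.infinite(mu_from_ayr(1)$mu))
  expect_error(mu_from_ayr(0), "positive")
  expect_error(mu_from_ayr(-0.5), "positive")
})

test_that("simulate_coverage is seed-deterministic with Poisson means", {
  p <- demo_panel()
  prof <- sample_profile(ayr = 1, mean_depth = 6000, seed = 101)
  d1 <- simulate_coverage(p, prof)
  d2 <- simulate_coverage(p, prof)
  expect_identical(d1, d2)
  expect_equal(length(d1), 90L)

  # intact sample, amplicons below the GC knee: empirical mean within 3 SE
  low_gc <- p$name[p$gc <= prof$gc_penalty_knee]
  se <- sqrt(6000 / length(low_gc))
  expect_lt(abs(mean(d1[low_gc]) - 6000), 3 * se)

  # high-GC amplicons lose coverage
  high_gc <- p$name[p$gc > 0.65]
  expect_true(length(high_gc) >= 5)
  expect_lt(mean(d1[high_gc]), mean(d1[low_gc]))
})

test_that("lower AYR drops more amplicons below 500x, and long amplicons drop fastest", {
  p <- demo_panel()
  worse <- 0L
  for (s in 1:20) {
    d_low <- simulate_coverage(p, sample_profile(ayr = 0.3, mean_depth = 6000, seed = s))
    d_high <- simulate_coverage(p, sample_profile(ayr = 0.8, mean_depth = 6000, seed = s))
    worse <- worse + (sum(d_low < 500) > sum(d_high < 500))
  }
  expect_equal(worse, 20L)

  # length monotonicity of the dropout model: a 400-bp context loses
  # proportionally more than a 140-bp amplicon as AYR falls
  mu3 <- mu_from_ayr(0.3)$mu
  mu9 <- mu_from_ayr(0.9)$mu
  short_ratio <- exp(-140 / mu3) / exp(-140 / mu9)
  long_ratio <- exp(-400 / mu3) / exp(-400 / mu9)
  expect_gt(short_ratio, long_ratio)
})

test_that("simulate_pileups honors truth, error model and the depth invariant", {
  p <- tiny_panel()
  # no variants, no error -> pure reference everywhere
  prof0 <- sample_profile(mean_depth = 500, error_rate = 0, seed = 3)
  pure <- simulate_pileups(p, NULL, prof0)
  expect_true(all(pure$allele_ref == "."))
  expect_true(all(pure$count == pure$depth))

  # determinism
  prof <- sample_profile(mean_depth = 1200, seed = 4)
  truth <- data.frame(chrom = "chrT", pos = 10L, ref = "G", alt = "T",
                      af = 0.5, label = "t1", stringsAsFactors = FALSE)
  expect_identical(simulate_pileups(p, truth, prof),
                   simulate_pileups(p, truth, prof))

  # counts sum exactly to depth at every site
  pl <- simulate_pileups(p, truth, prof)
  sums <- tapply(pl$count, paste(pl$chrom, pl$pos), sum)
  deps <- tapply(pl$depth, paste(pl$chrom, pl$pos), max)
  expect_true(all(sums == deps))

  # truth outside the panel footprint is a placement error
  bad <- data.frame(chrom = "chrT", pos = 41L, ref = "C", alt = "A",
                    af = 0.5, stringsAsFactors = FALSE)
  expect_error(simulate_pileups(p, bad, prof), "exactly 1")
})

test_that("observed allele fractions concentrate around the truth", {
  p <- tiny_panel()
  truth5 <- data.frame(chrom = "chrT", pos = 10L, ref = "G", alt = "T",
                       af = 0.5, stringsAsFactors = FALSE)
  af_of <- function(pl, truth) {
    hit <- pl$pos == truth$pos & pl$allele_alt == truth$alt & pl$allele_ref == truth$ref
    pl$count[hit][1] / pl$depth[hit][1]
  }
  afs <- vapply(1:200, function(s) {
    pl <- simulate_pileups(p, truth5, sample_profile(mean_depth = 1200, seed = 1000 + s))
    af_of(pl, truth5)
  }, 0)
  expect_gt(mean(afs), 0.48)
  expect_lt(mean(afs), 0.52)

  # a 1% dilution at 1200x essentially never reaches the 5% LOD
  truth1 <- truth5
  truth1$af <- 0.01
  af1 <- vapply(1:200, function(s) {
    pl <- simulate_pileups(p, truth1, sample_profile(mean_depth = 1200, seed = 2000 + s))
    af_of(pl, truth1)
  }, 0)
  expect_gt(mean(af1 < 0.05), 0.99)
})

test_that("make_dilution_series computes mixing fractions", {
  f <- make_dilution_series(0.5, c(0.5, 0.10, 0.01))
  expect_equal(unname(f), c(1.0, 0.20, 0.02))
  expect_error(make_dilution_series(0.5, 0.6), "infeasible|\\(0, stock_af\\]")
})

test_that("WGA artifacts are injected at homopolymers, recurrently and ledgered", {
  p <- demo_panel()
  prof0 <- sample_profile(mean_depth = 6000, wga = TRUE, wga_artifact_prob = 0,
                          seed = 5)
  pl <- simulate_pileups(p, NULL, prof0)
  res0 <- inject_wga_artifacts(pl, p, prof0)
  expect_identical(res0$pileups, pl)
  expect_equal(nrow(res0$ledger), 0L)

  # probability 1 on a panel with exactly 5 eligible runs -> 5 artifacts
  prof1 <- sample_profile(mean_depth = 6000, wga = TRUE, wga_artifact_prob = 1,
                          seed = 5)
  res1 <- inject_wga_artifacts(pl, p, prof1)
  expect_equal(nrow(res1$ledger), 5L)
  expect_true(all(variant_kind(res1$ledger$ref, res1$ledger$alt) == "INS"))
  hp <- attr(p, "homopolymers")
  expect_setequal(res1$ledger$pos, hp$start - 1L)

  # panel-level stream: same artifact_seed, different sample seed -> same sites
  prof_a <- sample_profile(mean_depth = 6000, wga = TRUE, wga_artifact_prob = 0.5,
                           seed = 11, artifact_seed = 99)
  prof_b <- sample_profile(mean_depth = 6000, wga = TRUE, wga_artifact_prob = 0.5,
                           seed = 12, artifact_seed = 99)
  led_a <- inject_wga_artifacts(simulate_pileups(p, NULL, prof_a), p, prof_a)$ledger
  led_b <- inject_wga_artifacts(simulate_pileups(p, NULL, prof_b), p, prof_b)$ledger
  expect_identical(led_a[, c("chrom", "pos", "ref", "alt", "af_target")],
                   led_b[, c("chrom", "pos", "ref", "alt", "af_target")])

  # artifact sites never collide with the demo truth set
  truth <- demo_truth_set(p)
  expect_length(intersect(paste(led_a$chrom, led_a$pos),
                          paste(truth$chrom, truth$pos)), 0)

  # wga = FALSE is a warning no-op
  prof_off <- sample_profile(mean_depth = 6000, wga = FALSE, seed = 5)
  expect_warning(res_off <- inject_wga_artifacts(pl, p, prof_off), "no-op")
  expect_identical(res_off$pileups, pl)
})

test_that("artifact allele fractions are uniform on the configured range", {
  p <- demo_panel()
  hp_loci <- unique(attr(p, "homopolymers")$chrom)
  sub <- p[p$chrom %in% hp_loci, ]
  afs <- unlist(lapply(1:80, function(s) {
    prof <- sample_profile(mean_depth = 100, wga = TRUE, wga_artifact_prob = 1,
                           seed = s, artifact_seed = s)
    pl <- simulate_pileups(sub, NULL, prof)
    inject_wga_artifacts(pl, p, prof)$ledger$af_target
  }))
  # Uniform(0.01, 0.10): P(af < 0.05) = 4/9; 400 draws, 3 SE ~ 0.075
  expect_equal(length(afs), 400L)
  expect_lt(abs(mean(afs < 0.05) - 4 / 9), 0.075)
  expect_true(all(afs >= 0.01 & afs <= 0.10))
})
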
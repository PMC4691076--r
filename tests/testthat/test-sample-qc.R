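test_that("compute_ayr averages per-fragment ratios and maps degradation", {
  intact <- compute_ayr(yield_table(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(intact$ayr, 1)
  expect_equal(intact$degradation_pct, 0)
  expect_equal(intact$decision, "pass")

  # AYR 0.3 corresponds to 70% degradation and still passes the default gate
  deg <- compute_ayr(yield_table(c(0.3, 0.3, 0.3), c(1, 1, 1)))
  expect_equal(deg$ayr, 0.3)
  expect_equal(deg$degradation_pct, 70)
  expect_equal(deg$decision, "pass")

  # arithmetic mean, not any other reduction
  mix <- compute_ayr(yield_table(c(0.6, 0.3, 0.0), c(1, 1, 1)))
  expect_equal(mix$ayr, 0.3)

  expect_error(compute_ayr(yield_table(c(1, 1, 1), c(1, 0, 1))), "300 bp")
  expect_warning(compute_ayr(yield_table(c(1.5, 1, 1), c(1, 1, 1))), "1.2")
})

test_that("degradation percentage is strictly decreasing in AYR and clipped", {
  ayrs <- seq(0.05, 1, by = 0.05)
  deg <- vapply(ayrs, function(a) {
    compute_ayr(yield_table(rep(a, 3), rep(1, 3)))$degradation_pct
  }, 0)
  expect_true(all(diff(deg) < 0))
  expect_equal(deg[length(deg)], 0)
  over <- suppressWarnings(compute_ayr(yield_table(rep(1.5, 3), rep(1, 3))))
  expect_equal(over$degradation_pct, 0)  # clipped at 0, never negative
})

test_that("purity gate uses strict 1.7 thresholds and never blocks", {
  expect_equal(assess_purity(1.8, 1.9)$status, "pass")
  expect_equal(assess_purity(1.7, 1.9)$status, "warn")  # boundary is exclusive
  expect_equal(assess_purity(1.9, 1.2)$status, "warn")
  expect_error(assess_purity(0, 1.9), "positive")
})

test_that("library_plan routes each sample type to its protocol", {
  ffpe <- library_plan("FFPE", ayr = compute_ayr(yield_table(rep(0.3, 3), rep(1, 3))))
  expect_true(ffpe$proceed)
  expect_equal(ffpe$input_ng, 20)
  expect_equal(c(ffpe$cycles_pcr1, ffpe$cycles_pcr2), c(22L, 5L))

  rejected <- library_plan("FFPE", ayr = 0.2)
  expect_false(rejected$proceed)
  expect_equal(rejected$reject_reason, "fragmentation_below_threshold")
  expect_true(is.na(rejected$input_ng))

  sf <- library_plan("SF")
  expect_equal(sf$input_ng, 10)
  expect_equal(c(sf$cycles_pcr1, sf$cycles_pcr2), c(19L, 5L))

  wga <- library_plan("cfDNA", mass_ng = 0.5)
  expect_equal(wga$sample_type, "cfDNA_WGA")
  expect_equal(wga$input_ng, 10)
  expect_equal(c(wga$cycles_pcr1, wga$cycles_pcr2), c(19L, 5L))

  nowga <- library_plan("cfDNA", mass_ng = 2.1)
  expect_equal(nowga$sample_type, "cfDNA_noWGA")
  expect_equal(nowga$input_ng, 2.1)
  expect_equal(c(nowga$cycles_pcr1, nowga$cycles_pcr2), c(22L, 7L))

  # boundary: exactly 1 ng of cfDNA does NOT trigger WGA (strict "< 1 ng")
  expect_equal(library_plan("cfDNA", mass_ng = 1.0)$sample_type, "cfDNA_noWGA")

  expect_error(library_plan("FFPE"), "AYR")
  expect_error(library_plan("cfDNA"), "mass_ng")
  expect_error(library_plan("cfDNA", mass_ng = -1), "positive")
})

test_that("standard curve fitting recovers slope, efficiency and r2", {
  # perfect 10-fold series at 100% efficiency: slope -log2(10) cycles/decade
  q <- 10^(1:7)
  ct <- 40 - log2(10) * log10(q)
  curve <- fit_standard_curve(q, ct)
  expect_equal(curve$slope, -log2(10), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-12)

  # two-point closed form
  c2 <- suppressWarnings(fit_standard_curve(c(10, 1e6), c(35, 18.4)))
  expect_equal(c2$slope, (18.4 - 35) / 5, tolerance = 1e-12)
  expect_equal(c2$r2, 1)

  # noisy series vs the normal-equation oracle
  set.seed(5)
  q7 <- 10^seq(1, 6, length.out = 7)
  ct7 <- 38 - 3.4 * log10(q7) + rnorm(7, sd = 0.3)
  fit <- suppressWarnings(fit_standard_curve(q7, ct7))
  X <- cbind(1, log10(q7))
  beta <- solve(t(X) %*% X, t(X) %*% ct7)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit$slope, beta[2], tolerance = 1e-9)

  expect_error(fit_standard_curve(c(10, 10), c(30, 31)), "distinct")
  w <- capture_warnings(fit_standard_curve(c(10, 50), c(30, 28)))
  expect_match(w, "decade", all = FALSE)
})

test_that("quantify_dna inverts the forward curve prediction", {
  q <- 10^(1:6)
  ct <- 39 - 3.32 * log10(q)
  curve <- fit_standard_curve(q, ct)

  # Ct observed at the 1000 pg standard, 1 uL -> 1 ng
  ct_1000 <- 39 - 3.32 * 3
  expect_equal(as.numeric(quantify_dna(ct_1000, curve, volume_ul = 1)), 1,
               tolerance = 1e-9)

  # replicates are averaged before interpolation
  paired <- quantify_dna(c(ct_1000 - 0.5, ct_1000 + 0.5), curve, volume_ul = 4)
  expect_equal(as.numeric(paired), as.numeric(quantify_dna(ct_1000, curve, 4)),
               tolerance = 1e-12)

  # algebraic inverse against randomized curves
  set.seed(9)
  for (i in 1:10) {
    slope <- runif(1, -3.9, -3.0)
    intercept <- runif(1, 35, 42)
    cts <- intercept + slope * log10(10^(1:6))
    cv <- suppressWarnings(fit_standard_curve(10^(1:6), cts))
    ct_obs <- runif(1, min(cts), max(cts))
    expect_equal(as.numeric(quantify_dna(ct_obs, cv, 1)),
                 10^((ct_obs - intercept) / slope) / 1000, tolerance = 1e-9)
  }
  expect_warning(quantify_dna(5, curve, 1), "extrapolating")
  expect_error(quantify_dna(numeric(0), curve, 1), "replicate")
})
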
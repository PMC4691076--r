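# a small hand-built catalog for rule and rarity checks
toy_catalog <- function() {
  data.frame(
    chrom = c("chrT", "chrT", "chrT"),
    pos = c(5L, 10L, 30L),
    ref = c("C", "G", "C"),
    alt = c("A", "T", "G"),
    cosmic_like_id = c("COSM518", NA, "COSM_PATH"),
    dbsnp_like_id = c(NA, "rs_rare", NA),
    gmaf = c(NA, 0.004, NA),
    pathogenic = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("the rule cascade assigns the documented statuses in order", {
  cfg <- triage_config(wga_sample = TRUE)
  cat <- toy_catalog()

  concordant <- make_call("chrT", 5, "C", "A", af = 0.298, depth = 2000)
  below_lod <- make_call("chrT", 7, "A", "G", af = 0.044, depth = 2000)
  low_cov <- make_call("chrT", 8, "T", "C", af = 0.03, depth = 200)
  b_only <- make_call("chrT", 9, "C", "T", af = 0.25, depth = 2000, caller = "B")
  wga_ins <- make_call("chrT", 19, "T", "TA", af = 0.03, depth = 2000, hp_len = 6L)
  a_only_ps <- make_call("chrT", 11, "G", "A", af = 0.10, depth = 2000)
  a_only_ss <- make_call("chrT", 12, "T", "G", af = 0.25, depth = 2000)
  a_only_path <- make_call("chrT", 30, "C", "G", af = 0.25, depth = 2000)
  indel_a <- make_call("chrT", 15, "GT", "G", af = 0.30, depth = 2000)
  indel_b <- make_call("chrT", 17, "A", "AT", af = 0.30, depth = 2000, caller = "B")

  calls_a <- rbind(concordant, below_lod, low_cov, wga_ins, a_only_ps,
                   a_only_ss, a_only_path, indel_a)
  calls_b <- rbind(concordant, b_only, indel_b, wga_ins)
  res <- triage(calls_a, calls_b, cfg, catalog = cat)

  status_of <- function(pos) res$status[res$pos == pos]
  reason_of <- function(pos) res$reason[res$pos == pos]

  expect_equal(status_of(5), "confirmed")          # concordant SNV
  expect_true(res$concordant[res$pos == 5])
  expect_equal(res$catalog_id[res$pos == 5], "COSM518")

  expect_equal(reason_of(7), "below_LOD")          # 4.4% variant
  expect_equal(reason_of(8), "insufficient_coverage")  # coverage precedes LOD
  expect_equal(reason_of(9), "callerB_only")       # unconfirmed caller-B SNV
  expect_equal(reason_of(19), "wga_artifact")      # artifact rule precedes LOD
  expect_equal(status_of(11), "requires_orthogonal_validation")
  expect_equal(res$validation_method[res$pos == 11], "PS")  # 5-20% band
  expect_equal(status_of(12), "requires_orthogonal_validation")
  expect_equal(res$validation_method[res$pos == 12], "SS")  # above 20%
  expect_equal(status_of(30), "confirmed")         # catalog-pathogenic override
  expect_equal(status_of(15), "confirmed")         # caller A owns indels
  expect_equal(reason_of(17), "callerB_indel")

  # structural invariants: one status each, filtered iff reason set,
  # confirmed implies both thresholds
  expect_true(all(res$status %in%
    c("confirmed", "requires_orthogonal_validation", "filtered")))
  expect_true(all((res$status == "filtered") == (res$reason != "none")))
  conf <- res[res$status == "confirmed", ]
  expect_true(all(conf$af >= cfg$min_af & conf$depth >= cfg$min_depth))
})

test_that("rarity classification follows the 1% global MAF convention", {
  calls <- rbind(
    make_call("chrT", 10, "G", "T", af = 0.5, depth = 2000),  # gmaf 0.004
    make_call("chrT", 5, "C", "A", af = 0.5, depth = 2000),   # no gmaf
    make_call("chrT", 40, "A", "C", af = 0.5, depth = 2000)   # not in catalog
  )
  res <- triage(calls, calls, triage_config(), catalog = toy_catalog())
  expect_equal(res$rarity[res$pos == 10], "rare")
  expect_equal(res$rarity[res$pos == 5], "unknown")   # catalog hit, gmaf absent
  expect_equal(res$rarity[res$pos == 40], "unknown")

  common_cat <- toy_catalog()
  common_cat$gmaf[1] <- 0.54
  res2 <- triage(calls, calls, triage_config(), catalog = common_cat)
  expect_equal(res2$rarity[res2$pos == 5], "common")
})

test_that("triage of its own confirmed output is a fixed point", {
  calls <- rbind(
    make_call("chrT", 5, "C", "A", af = 0.298, depth = 2000),
    make_call("chrT", 15, "GT", "G", af = 0.30, depth = 2000),
    make_call("chrT", 11, "G", "A", af = 0.10, depth = 2000)
  )
  first <- triage(calls, calls, triage_config())
  expect_true(all(first$status == "confirmed"))
  conf_cols <- intersect(names(calls), names(first))
  second <- triage(as.data.frame(first)[, conf_cols],
                   as.data.frame(first)[, conf_cols], triage_config())
  expect_equal(second$status, first$status)
  expect_equal(variant_key(second), variant_key(first))
})

test_that("non-normalized input is rejected as a contract error", {
  sloppy <- make_call("chrT", 20, "AA", "AAA", af = 0.3, depth = 2000)
  expect_error(triage(sloppy, sloppy[0, ], triage_config()), "normalize")
})

test_that("validation outcomes flip pending variants and only those", {
  calls_a <- rbind(
    make_call("chrT", 11, "G", "A", af = 0.10, depth = 2000),
    make_call("chrT", 12, "T", "G", af = 0.12, depth = 2000),
    make_call("chrT", 5, "C", "A", af = 0.30, depth = 2000)
  )
  calls_b <- make_call("chrT", 5, "C", "A", af = 0.30, depth = 2000)
  res <- triage(calls_a, calls_b, triage_config())
  pending <- res[res$status == "requires_orthogonal_validation", ]
  expect_equal(nrow(pending), 2L)

  # all validated -> all confirmed
  all_ok <- data.frame(chrom = pending$chrom, pos = pending$pos,
                       ref = pending$ref, alt = pending$alt, validated = TRUE)
  res_ok <- apply_validation_results(res, all_ok)
  expect_true(all(res_ok$status %in% "confirmed"))

  # empty results leave the triage untouched
  expect_identical(apply_validation_results(res, setNames(logical(0), character(0))),
                   res)

  # exactly one failure flips exactly one status
  one_fail <- all_ok
  one_fail$validated <- c(TRUE, FALSE)
  res_mixed <- apply_validation_results(res, one_fail)
  expect_equal(sum(res_mixed$status == "filtered"), 1L)
  expect_equal(res_mixed$reason[res_mixed$status == "filtered"],
               "failed_orthogonal_validation")

  # addressing a non-pending variant is a contract error
  bad <- data.frame(chrom = "chrT", pos = 5L, ref = "C", alt = "A",
                    validated = TRUE)
  expect_error(apply_validation_results(res, bad), "awaiting")
})
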
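test_that("variants are classed SNV vs indel by allele lengths", {
  expect_equal(classifyVariantType("A", "G"), "snv")
  expect_equal(classifyVariantType("A", "AT"), "indel")
  expect_equal(classifyVariantType("ACG", "A"), "indel")
  expect_equal(classifyVariantType(c("A", "C"), c("T", "CTT")),
               c("snv", "indel"))
})

test_that("a crafted fixture is partitioned exactly by the filter chain", {
  # 10 records: 3 non-autosomal, 2 het, 1 low GQ, 4 passing (hand count)
  rec <- rbind(
    makeRecords(3, contig = c("X", "Y", "MT"), ad_ref = 1L, ad_alt = 30L),
    makeRecords(2, pos = c(900L, 901L), gt = "het", ad_ref = 15L,
                ad_alt = 16L),
    makeRecords(1, pos = 950L, gq = 5L, ad_ref = 1L, ad_alt = 29L),
    makeRecords(4, pos = 1:4 * 10L, ad_ref = c(0L, 1L, 2L, 0L),
                ad_alt = c(30L, 29L, 38L, 44L)))
  af <- afMapFor(rec, 0.5)
  sel <- selectInformative(rec, af, filterConfig())
  expect_equal(sum(sel$report), nrow(rec))
  expect_equal(unname(sel$report["retained"]), 4L)
  expect_equal(unname(sel$report["non_autosomal"]), 3L)
  expect_equal(unname(sel$report["not_hom_alt"]), 2L)
  expect_equal(unname(sel$report["gq_fail"]), 1L)
  expect_equal(nrow(sel$records), 4L)
  expect_equal(sel$records$p, rep(0.5, 4))
})

test_that("window bounds follow the stated inclusivity/exclusivity", {
  cfg <- filterConfig()
  one <- function(...) {
    r <- makeRecords(1, ...)
    selectInformative(r, afMapFor(r, 0.5), cfg)
  }
  # DP inclusive on both ends
  expect_equal(unname(one(ad_ref = 1L, ad_alt = 18L, dp = 19L)$report["dp_fail"]), 1L)
  expect_equal(unname(one(ad_ref = 1L, ad_alt = 19L, dp = 20L)$report["retained"]), 1L)
  expect_equal(unname(one(ad_ref = 2L, ad_alt = 98L, dp = 100L)$report["retained"]), 1L)
  expect_equal(unname(one(ad_ref = 2L, ad_alt = 99L, dp = 101L)$report["dp_fail"]), 1L)
  # GQ inclusive at the cutoff
  expect_equal(unname(one(gq = 20L)$report["retained"]), 1L)
  expect_equal(unname(one(gq = 19L)$report["gq_fail"]), 1L)

  # reference-AF window is strict: p = 0.95 and p = 0.90 are both out
  r <- makeRecords(1)
  expect_equal(unname(selectInformative(r, afMapFor(r, 0.05), cfg)$report["af_out_of_window"]), 1L)
  expect_equal(unname(selectInformative(r, afMapFor(r, 0.10), cfg)$report["af_out_of_window"]), 1L)
  expect_equal(unname(selectInformative(r, afMapFor(r, 0.11), cfg)$report["retained"]), 1L)

  # missing AF entry rejects the record instead of inventing p
  empty <- alleleFrequencyMap(character(0), integer(0), character(0),
                              character(0), numeric(0))
  expect_equal(unname(selectInformative(r, empty, cfg)$report["af_missing"]), 1L)

  # indel handling follows the configured variant type
  ind <- makeRecords(1, ref = "A", alt = "AT")
  expect_equal(unname(selectInformative(ind, afMapFor(ind, 0.5), cfg)$report["wrong_variant_type"]), 1L)
  cfgInd <- filterConfig(variantTypes = "indel")
  expect_equal(unname(selectInformative(ind, afMapFor(ind, 0.5), cfgInd)$report["retained"]), 1L)
})

test_that("the filter report partitions any input exactly", {
  cfg <- filterConfig()
  for (seed in 1:15) {
    rec <- randomRecords(200L, seed)
    af <- afMapFor(rec[seq_len(150), ], runif(1, 0.05, 0.95))
    sel <- selectInformative(rec, af, cfg)
    expect_equal(sum(sel$report), 200L)
    expect_equal(unname(sel$report["retained"]), nrow(sel$records))
  }
})

test_that("filtering is idempotent and tightening is monotone", {
  rec <- randomRecords(400L, 7)
  af <- afMapFor(rec, 0.5)
  cfg <- filterConfig()
  sel <- selectInformative(rec, af, cfg)
  again <- selectInformative(sel$records[names(rec)], af, cfg)
  expect_equal(nrow(again$records), nrow(sel$records))
  expect_equal(unname(again$report["retained"]), nrow(sel$records))
  expect_true(all(again$report[setdiff(names(again$report), "retained")] == 0L))

  n0 <- nrow(sel$records)
  tighter <- list(filterConfig(minGq = 50L),
                  filterConfig(minDp = 25L, maxDp = 80L),
                  filterConfig(minRefAf = 0.2, maxRefAf = 0.8),
                  filterConfig(minGq = 90L, minDp = 28L, maxDp = 40L))
  for (cfgT in tighter) {
    expect_lte(nrow(selectInformative(rec, af, cfgT)$records), n0)
  }
})

test_that("het/hom ratio counts quality-passing calls and flags degeneracies", {
  base <- rbind(
    makeRecords(6, pos = 1:6 * 10L, gt = "het", ad_ref = 15L, ad_alt = 15L),
    makeRecords(4, pos = 7:10 * 10L, gt = "hom_alt", ad_ref = 0L,
                ad_alt = 30L))
  expect_equal(hetHomRatio(base), 1.5)

  # a low-GQ het must not count
  withBad <- rbind(base, makeRecords(1, pos = 999L, gt = "het", gq = 3L,
                                     ad_ref = 15L, ad_alt = 15L))
  expect_equal(hetHomRatio(withBad), 1.5)

  homOnly <- makeRecords(10, pos = 1:10 * 10L, gt = "hom_alt",
                         ad_ref = 0L, ad_alt = 30L)
  expect_equal(hetHomRatio(homOnly), 0)

  hetOnly <- makeRecords(5, pos = 1:5 * 10L, gt = "het", ad_ref = 15L,
                         ad_alt = 15L)
  expect_identical(hetHomRatio(hetOnly), Inf)

  none <- makeRecords(2, gt = "hom_ref", ad_ref = 30L, ad_alt = 0L)
  expect_true(is.nan(hetHomRatio(none)))
})
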
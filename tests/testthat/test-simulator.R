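test_that("site allele frequencies are seeded, truncated draws from Beta", {
  q1 <- simulateSiteAFs(500, c(1, 1), seed = 11)
  q2 <- simulateSiteAFs(500, c(1, 1), seed = 11)
  expect_identical(q1, q2)
  expect_true(all(q1 >= 0.05 & q1 <= 0.95))
  expect_length(simulateSiteAFs(0), 0L)

  # U-shaped spectrum: empirical tail mass matches the truncated Beta CDF
  qU <- simulateSiteAFs(20000, c(0.2, 0.2), seed = 12)
  inWin <- function(x) (pbeta(x, 0.2, 0.2) - pbeta(0.05, 0.2, 0.2)) /
    (pbeta(0.95, 0.2, 0.2) - pbeta(0.05, 0.2, 0.2))
  expected <- inWin(0.15) + (1 - inWin(0.85))
  observed <- mean(qU < 0.15 | qU > 0.85)
  expect_lt(abs(observed - expected), 3 * sqrt(expected * (1 - expected) / 20000))
  # U-shape: more mass near the bounds than a flat spectrum's 2/9
  expect_gt(observed, 2 / 9)
})

test_that("truth genotypes follow Hardy-Weinberg at each site", {
  expect_true(all(simulateTruthGenotypes(rep(1, 5), 20, seed = 1) == 2L))
  expect_true(all(simulateTruthGenotypes(rep(0, 5), 20, seed = 1) == 0L))

  G <- simulateTruthGenotypes(0.5, 10000, seed = 2)
  fracHomAlt <- mean(G == 2L)
  expect_lt(abs(fracHomAlt - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("two-way pairing is a cross-stratum permutation; n-way has none", {
  strata <- rep(1:6, each = 5)
  perm <- assignContaminants(30, "two_way", strata, seed = 3)
  expect_equal(sort(perm), 1:30)            # everyone contaminates once
  expect_true(all(perm != 1:30))            # never self
  expect_true(all(strata[perm] != strata))  # never own stratum

  expect_equal(assignContaminants(2, "two_way", c(1, 2), seed = 1), c(2, 1))
  expect_error(assignContaminants(3, "two_way", rep(1, 3), seed = 1),
               "impossible")
  expect_null(assignContaminants(30, "n_way", seed = 1))
})

test_that("read mixing honors the contamination and error limits", {
  homAlt <- matrix(2L, 200, 2, dimnames = list(NULL, c("S01", "S02")))
  clean <- simulateReads(homAlt, rate = 0, mixing = "n_way",
                         meanDepth = 30, seqError = 0, seed = 4)
  expect_true(all(clean$ad_ref == 0L))
  expect_identical(clean$ad_ref + clean$ad_alt, clean$dp)

  # full replacement by a hom-ref contaminant leaves no alternate reads
  truth <- cbind(S01 = rep(2L, 200), S02 = rep(0L, 200))
  swap <- simulateReads(truth, rate = 1, mixing = "two_way",
                        assignment = c(2L, 1L), meanDepth = 30,
                        seqError = 0, seed = 5)
  expect_true(all(swap$ad_alt[, 1] == 0L))
  expect_true(all(swap$ad_ref[, 1] == swap$dp[, 1]))

  # depth is always conserved, error model included
  noisy <- simulateReads(matrix(rbinom(600, 2, 0.5), 300, 2,
                                dimnames = list(NULL, c("S01", "S02"))),
                         rate = 0.1, mixing = "n_way", meanDepth = 30,
                         seqError = 0.01, seed = 6)
  expect_identical(noisy$ad_ref + noisy$ad_alt, noisy$dp)
})

test_that("the flat-prior caller matches a brute-force likelihood oracle", {
  oracle <- function(r, a, e) {
    ll <- c(hom_ref = r * log(1 - e) + ifelse(a == 0, 0, a * log(e)),
            het = (r + a) * log(0.5),
            hom_alt = ifelse(r == 0, 0, r * log(e)) + a * log(1 - e))
    srt <- sort(ll, decreasing = TRUE)
    list(gt = names(ll)[which.max(ll)],
         gq = min(99L, as.integer(round(10 * (srt[1] - srt[2]) / log(10)))))
  }
  expect_equal(callGenotypes(0, 30)$gt, "hom_alt")
  expect_equal(callGenotypes(0, 30)$gq, oracle(0, 30, 0.001)$gq)
  expect_equal(callGenotypes(15, 15)$gt, "het")
  expect_equal(callGenotypes(0, 0)$gt, "missing")
  expect_true(is.na(callGenotypes(0, 0)$gq))

  # full sweep at DP = 51: calls and GQ agree with the oracle everywhere
  swept <- callGenotypes(0:51, 51:0, seqError = 0.001)
  want <- lapply(0:51, function(r) oracle(r, 51 - r, 0.001))
  expect_equal(swept$gt, vapply(want, `[[`, character(1), "gt"))
  expect_equal(swept$gq, vapply(want, `[[`, integer(1), "gq"))
  # reference-read infiltration flips the call to het from 6 reads on
  expect_equal(max(which(swept$gt == "hom_alt")) - 1L, 5L)
})

test_that("cohort emission is deterministic in the seed", {
  sc <- simScenario(nSites = 60, nSamples = 4, rates = c(0, 0.05),
                    nStrata = 2, seqError = 0, seed = 123)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  p1 <- simulateCohort(sc, d1)
  p2 <- simulateCohort(sc, d2)
  expect_identical(readLines(p1$truth), readLines(p2$truth))
  expect_identical(readLines(p1$truth_genotypes), readLines(p2$truth_genotypes))
  expect_identical(readLines(p1$vcf[[2]]), readLines(p2$vcf[[2]]))
  expect_identical(readLines(p1$af), readLines(p2$af))

  scOther <- simScenario(nSites = 60, nSamples = 4, rates = c(0, 0.05),
                         nStrata = 2, seed = 124)
  p3 <- simulateCohort(scOther, d3)
  expect_false(identical(readLines(p1$truth_genotypes),
                         readLines(p3$truth_genotypes)))

  # the error-free null cohort yields exactly zero estimates downstream
  run <- charrFromVcf(p1$vcf[["0"]], p1$af, filterConfig(minSites = 10L))
  expect_true(all(run$table$charr == 0))
})

test_that("hom-alt to het conversion grows with contamination and deflates the estimate", {
  sc <- simScenario(nSites = 6000, nSamples = 12, rates = c(0.01, 0.10),
                    nStrata = 6, seed = 31)
  st <- runSimulationStudy(sc, filterConfig(minSites = 100L),
                           computeMle = FALSE)
  conv <- st$summary$mean_frac_homalt_called_het
  expect_gt(conv[2], 3 * conv[1])  # materially larger at c = 0.10
  # mean estimates are ordered with the true rates
  expect_lt(st$summary$mean_charr[1], st$summary$mean_charr[2])
  # at c = 0.10 the estimate sits below truth (hom->het deflation)
  expect_lt(st$summary$mean_charr[2], 0.10)
  # and the het/hom QC ratio flags the contaminated cohort
  expect_gt(st$summary$mean_het_hom_ratio[2], st$summary$mean_het_hom_ratio[1])
})

test_that("pooled contamination is estimated more faithfully than single-source at high rates", {
  scN <- simScenario(nSites = 6000, nSamples = 12, rates = 0.10,
                     mixing = "n_way", nStrata = 6, seed = 77)
  scT <- simScenario(nSites = 6000, nSamples = 12, rates = 0.10,
                     mixing = "two_way", nStrata = 6, seed = 77)
  mN <- runSimulationStudy(scN, filterConfig(minSites = 100L),
                           computeMle = FALSE)$summary$mean_charr
  mT <- runSimulationStudy(scT, filterConfig(minSites = 100L),
                           computeMle = FALSE)$summary$mean_charr
  expect_lt(abs(mN - 0.10), abs(mT - 0.10))
})
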
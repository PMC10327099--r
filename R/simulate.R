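# Genotype-level contamination simulator. Reads are simulated as allele
# counts, not sequences: the estimator consumes only GT/AD/DP/GQ, so read
# positions, mapping and base qualities would add nothing testable. Each
# cohort run draws from a single RNG stream seeded once, in documented
# order: site AFs, site alleles, truth genotypes, pairing, then per-rate
# read draws.

GT_LABELS <- c("hom_ref", "het", "hom_alt")

#' Simulate population alternate-allele frequencies
#'
#' Draws i.i.d. from Beta(shape\[1\], shape\[2\]) and resamples any draw
#' outside \[0.05, 0.95\] until all lie inside, so hom-alt sites exist
#' across the usable reference-AF window.
#'
#' @param nSites number of sites.
#' @param shape positive Beta shape pair; `c(1, 1)` (default) is flat over
#'   the truncation window, `c(0.2, 0.2)` gives a U-shaped spectrum.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return numeric vector of alt-allele frequencies in \[0.05, 0.95\].
#' @export
simulateSiteAFs <- function(nSites, shape = c(1, 1), seed = NULL) {
  stopifnot(length(shape) == 2L, all(shape > 0))
  if (!is.null(seed)) set.seed(seed)
  nSites <- as.integer(nSites)
  if (nSites <= 0L) return(numeric(0))
  q <- rbeta(nSites, shape[1], shape[2])
  out <- which(q < 0.05 | q > 0.95)
  while (length(out)) {
    q[out] <- rbeta(length(out), shape[1], shape[2])
    out <- out[q[out] < 0.05 | q[out] > 0.95]
  }
  q
}

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' Per site with alt AF q, each sample's genotype is drawn with
#' probabilities (1-q)^2, 2q(1-q), q^2 for hom-ref, het, hom-alt
#' (equivalently, alt dosage ~ Binomial(2, q)).
#'
#' @param q alt-allele frequencies (one per site).
#' @param nSamples cohort size.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return integer matrix (sites x samples) of alt dosages 0/1/2; columns
#'   named `S01`, `S02`, ...
#' @export
simulateTruthGenotypes <- function(q, nSamples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nSamples <- as.integer(nSamples)
  G <- matrix(rbinom(length(q) * nSamples, 2L, rep(q, nSamples)),
              nrow = length(q), ncol = nSamples)
  colnames(G) <- sprintf("S%02d", seq_len(nSamples))
  G
}

#' Assign a contaminant to every sample
#'
#' Two-way mixing pairs every sample with a fixed contaminant from a
#' different stratum via a random permutation with no fixed points and no
#' within-stratum images, so each sample serves as original and as
#' contaminant exactly once. n-way mixing has no fixed assignment: the
#' contaminant of each read is drawn fresh from all other samples.
#'
#' @param nSamples cohort size.
#' @param mixing `"two_way"` or `"n_way"`.
#' @param strata stratum label per sample (required for two-way; at least 2
#'   distinct strata, no stratum holding more than half the cohort).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return for two-way, an integer vector `partner` with
#'   `partner[i]` = index of sample i's contaminant; for n-way, `NULL`.
#' @export
assignContaminants <- function(nSamples, mixing = c("n_way", "two_way"),
                               strata = NULL, seed = NULL) {
  mixing <- match.arg(mixing)
  if (!is.null(seed)) set.seed(seed)
  nSamples <- as.integer(nSamples)
  if (mixing == "n_way") return(NULL)
  if (is.null(strata) || length(strata) != nSamples) {
    stopConfig("two-way mixing needs one stratum label per sample")
  }
  sizes <- table(strata)
  if (length(sizes) < 2L || max(sizes) > nSamples / 2) {
    stopConfig("two-way cross-stratum pairing impossible: need >= 2 strata, none holding more than half the samples")
  }
  ok <- function(perm) {
    all(perm != seq_len(nSamples)) && all(strata[perm] != strata)
  }
  for (i in seq_len(10000L)) {
    perm <- sample.int(nSamples)
    if (ok(perm)) return(perm)
  }
  # deterministic fallback: sort by stratum, rotate by the largest stratum
  # size -- every sample then maps outside its own contiguous block
  ord <- order(strata)
  shift <- max(sizes)
  perm <- integer(nSamples)
  perm[ord] <- ord[(seq_len(nSamples) + shift - 1L) %% nSamples + 1L]
  perm
}

#' Internal: P(read reports the reference allele | alt dosage), including
#' the allele-flip error e. het reads stay at 1/2 (the flip is symmetric).
#' @noRd
refReadProb <- function(G, e) {
  rp <- matrix(c(1 - e, 0.5, e)[G + 1L], nrow = nrow(G), ncol = ncol(G))
  dimnames(rp) <- dimnames(G)
  rp
}

#' Simulate per-site allele depths under read-level contamination
#'
#' Per sample and site, total depth is Poisson(meanDepth). Each read
#' independently originates from a contaminant with probability `rate`
#' (two-way: the fixed partner; n-way: a sample drawn fresh and uniformly
#' from the others, so the pool's mean allele profile applies per read) and
#' from the sample itself otherwise. The read's allele is drawn from the
#' origin's *true* genotype (physical reads come from the true DNA), then
#' flipped to the site's other allele with probability `seqError`.
#' `ad_ref + ad_alt = dp` always: no third allele is modeled.
#'
#' @param truth integer truth matrix (sites x samples) of alt dosages.
#' @param rate contamination rate in \[0, 1).
#' @param mixing `"n_way"` or `"two_way"`.
#' @param assignment two-way partner vector from [assignContaminants()].
#' @param meanDepth Poisson depth mean.
#' @param seqError per-read allele-flip probability.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list of integer matrices `ad_ref`, `ad_alt`, `dp` (sites x
#'   samples).
#' @export
simulateReads <- function(truth, rate, mixing = c("n_way", "two_way"),
                          assignment = NULL, meanDepth = 30,
                          seqError = 0.001, seed = NULL) {
  mixing <- match.arg(mixing)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.matrix(truth), rate >= 0, rate <= 1)
  nJ <- nrow(truth); nS <- ncol(truth)
  rp <- refReadProb(truth, seqError)
  if (mixing == "two_way") {
    if (is.null(assignment) || length(assignment) != nS) {
      stopConfig("two-way mixing needs a contaminant assignment")
    }
    rpCont <- rp[, assignment, drop = FALSE]
  } else {
    if (nS < 2L) stopConfig("n-way mixing needs at least 2 samples")
    rpCont <- (rowSums(rp) - rp) / (nS - 1)
  }
  dp <- matrix(rpois(nJ * nS, meanDepth), nJ, nS)
  nCont <- matrix(rbinom(nJ * nS, dp, rate), nJ, nS)
  refOwn <- matrix(rbinom(nJ * nS, dp - nCont, rp), nJ, nS)
  refCont <- matrix(rbinom(nJ * nS, nCont, rpCont), nJ, nS)
  adRef <- refOwn + refCont
  dimnames(adRef) <- dimnames(truth)
  adAlt <- dp - adRef
  dimnames(adAlt) <- dimnames(truth)
  dimnames(dp) <- dimnames(truth)
  list(ad_ref = adRef, ad_alt = adAlt, dp = dp)
}

#' Flat-prior maximum-likelihood diploid genotype caller
#'
#' Per-read likelihoods under the three diploid genotypes are
#' P(ref read | hom_ref) = 1 - e, P(ref | het) = 1/2, P(ref | hom_alt) = e
#' (symmetric for alt reads), combined with a flat genotype prior. The call
#' is the maximizing genotype; GQ is the phred-scaled likelihood ratio of
#' the best to the second-best genotype, capped at 99. Zero total depth
#' yields a missing call. This is the mechanism by which excess reference
#' reads at high contamination convert true hom-alt sites into het calls.
#'
#' @param adRef,adAlt allele-depth vectors or matrices (same shape).
#' @param seqError per-read allele error probability.
#' @return list with `gt` (`hom_ref` / `het` / `hom_alt` / `missing`) and
#'   integer `gq` (`NA` for missing calls), each shaped like the input.
#' @examples
#' callGenotypes(3, 48)           # hom_alt, GQ 63
#' callGenotypes(15, 15)$gt       # het
#' @export
callGenotypes <- function(adRef, adAlt, seqError = 0.001) {
  stopifnot(length(adRef) == length(adAlt), seqError >= 0, seqError < 1)
  dims <- dim(adRef)
  r <- as.numeric(adRef); a <- as.numeric(adAlt)
  xlog <- function(k, p) ifelse(k == 0, 0, k * log(p))  # 0*log(0) = 0
  ll0 <- xlog(r, 1 - seqError) + xlog(a, seqError)
  ll1 <- (r + a) * log(0.5)
  ll2 <- xlog(r, seqError) + xlog(a, 1 - seqError)
  best <- pmax(ll0, ll1, ll2)
  second <- pmax(pmin(ll0, ll1), pmin(pmax(ll0, ll1), ll2))  # middle value
  gtIdx <- ifelse(ll0 >= ll1 & ll0 >= ll2, 1L, ifelse(ll1 >= ll2, 2L, 3L))
  gq <- as.integer(pmin(round(10 * (best - second) / log(10)), 99))
  gt <- GT_LABELS[gtIdx]
  none <- (r + a) == 0
  gt[none] <- "missing"
  gq[none] <- NA_integer_
  if (!is.null(dims)) {
    dim(gt) <- dims; dim(gq) <- dims
    dimnames(gt) <- dimnames(adRef); dimnames(gq) <- dimnames(adRef)
  }
  list(gt = gt, gq = gq)
}

#' Internal: site metadata (coordinates and alleles) for a simulated cohort.
#' Sites cycle over autosomes 1..22 with increasing positions; REF is drawn
#' uniformly from A/C/G/T and ALT from the remaining bases (consumes RNG).
#' @noRd
simulateSiteMeta <- function(nSites) {
  j <- seq_len(nSites)
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, nSites, replace = TRUE)]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  data.frame(contig = as.character((j - 1L) %% 22L + 1L),
             pos = 10000L + ((j - 1L) %/% 22L) * 100L + ((j - 1L) %% 22L),
             ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Internal: strata labels for a scenario (round-robin assignment)
#' @noRd
scenarioStrata <- function(scenario) {
  rep_len(seq_len(scenario@nStrata), scenario@nSamples)
}

#' Internal: genotype-record data.frame for one simulated sample
#' @noRd
sampleRecords <- function(meta, sid, gt, adRef, adAlt, dp, gq) {
  data.frame(contig = meta$contig, pos = meta$pos, ref = meta$ref,
             alt = meta$alt, sample_id = sid, gt = gt,
             ad_ref = as.integer(adRef), ad_alt = as.integer(adAlt),
             dp = as.integer(dp), gq = as.integer(gq),
             multi_allelic = FALSE, stringsAsFactors = FALSE)
}

#' Internal: serialize one rate's cohort as a VCF
#' @noRd
writeCohortVcf <- function(path, meta, q, calls, reads) {
  sampleIds <- colnames(reads$dp)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=charr-simulator",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Simulated population alternate allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds), collapse = "\t"))
  gtStr <- matrix(c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                    missing = "./.")[calls$gt],
                  nrow = nrow(calls$gt))
  gqStr <- ifelse(is.na(calls$gq), ".", as.character(calls$gq))
  cells <- matrix(paste0(gtStr, ":", reads$ad_ref, ",", reads$ad_alt, ":",
                         reads$dp, ":", gqStr),
                  nrow = nrow(gtStr))
  lines <- paste(meta$contig, meta$pos, ".", meta$ref, meta$alt, ".", "PASS",
                 sprintf("AF=%.6g", q), "GT:AD:DP:GQ",
                 apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stopInput("cannot write: ", path))
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Internal: one full cohort draw (shared by simulateCohort and
#' runSimulationStudy). Seeds the stream and returns everything in memory.
#' @noRd
drawCohort <- function(scenario) {
  set.seed(scenario@seed)
  q <- simulateSiteAFs(scenario@nSites, scenario@afBetaShape)
  meta <- simulateSiteMeta(scenario@nSites)
  G <- simulateTruthGenotypes(q, scenario@nSamples)
  strata <- scenarioStrata(scenario)
  assignment <- if (scenario@mixing == "two_way") {
    assignContaminants(scenario@nSamples, "two_way", strata)
  } else NULL
  perRate <- lapply(scenario@rates, function(rate) {
    reads <- simulateReads(G, rate, scenario@mixing, assignment,
                           scenario@meanDepth, scenario@seqError)
    calls <- callGenotypes(reads$ad_ref, reads$ad_alt, scenario@seqError)
    list(rate = rate, reads = reads, calls = calls)
  })
  list(q = q, meta = meta, truth = G, strata = strata,
       assignment = assignment, perRate = perRate)
}

#' Simulate a cohort and write it out as standard files
#'
#' Draws site allele frequencies, Hardy-Weinberg truth genotypes and
#' contaminated reads for every configured rate, calls genotypes with the
#' flat-prior ML caller, and writes: one multi-sample VCF per contamination
#' rate (`cohort_c<rate>.vcf` with GT/AD/DP/GQ and INFO/AF), the sites
#' table of true simulated allele frequencies (`af_sites.tsv`), the truth
#' table of per-sample contamination (`truth.tsv`), the per-site true
#' genotype matrix (`truth_genotypes.tsv`), and a resolved-scenario echo
#' (`scenario.json`). Outputs are fully reproducible from the scenario seed.
#'
#' @param scenario a [SimScenario-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of the written paths (`vcf` is named by rate).
#' @export
simulateCohort <- function(scenario, outdir) {
  stopifnot(is(scenario, "SimScenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stopInput("cannot create output directory: ", outdir)
  cohort <- drawCohort(scenario)
  meta <- cohort$meta
  sampleIds <- colnames(cohort$truth)

  vcfPaths <- vapply(cohort$perRate, function(pr) {
    path <- file.path(outdir, sprintf("cohort_c%s.vcf", formatC(pr$rate, format = "g")))
    writeCohortVcf(path, meta, cohort$q, pr$calls, pr$reads)
    path
  }, character(1))
  names(vcfPaths) <- formatC(scenario@rates, format = "g")

  afPath <- file.path(outdir, "af_sites.tsv")
  write.table(data.frame(contig = meta$contig, pos = meta$pos,
                         ref = meta$ref, alt = meta$alt,
                         af = sprintf("%.6g", cohort$q)),
              afPath, sep = "\t", quote = FALSE, row.names = FALSE)

  truthPath <- file.path(outdir, "truth.tsv")
  truthTab <- do.call(rbind, lapply(cohort$perRate, function(pr) {
    data.frame(sample_id = sampleIds, true_c = pr$rate,
               mixing = scenario@mixing,
               contaminant_id = if (scenario@mixing == "two_way") {
                 sampleIds[cohort$assignment]
               } else "pool",
               stratum = cohort$strata, stringsAsFactors = FALSE)
  }))
  write.table(truthTab, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)

  tgPath <- file.path(outdir, "truth_genotypes.tsv")
  write.table(cbind(meta[, c("contig", "pos", "ref", "alt")],
                    as.data.frame(cohort$truth)),
              tgPath, sep = "\t", quote = FALSE, row.names = FALSE)

  scenPath <- file.path(outdir, "scenario.json")
  jsonlite::write_json(
    list(nSamples = scenario@nSamples, nSites = scenario@nSites,
         rates = scenario@rates, mixing = scenario@mixing,
         meanDepth = scenario@meanDepth, seqError = scenario@seqError,
         afBetaShape = scenario@afBetaShape, nStrata = scenario@nStrata,
         seed = scenario@seed,
         package_version = as.character(utils::packageVersion("charr"))),
    scenPath, auto_unbox = TRUE, digits = NA)

  invisible(list(vcf = vcfPaths, af = afPath, truth = truthPath,
                 truth_genotypes = tgPath, scenario = scenPath))
}

#' Run a full simulation study in memory
#'
#' For every configured contamination rate: simulate reads, call genotypes,
#' run the real selection chain against the true simulated allele
#' frequencies, and compute the per-sample estimate (plus, optionally, the
#' grid-search MLE). Summarizes mean estimate, relative bias and mean
#' retained-site count per rate.
#'
#' @param scenario a [SimScenario-class].
#' @param cfg a [FilterConfig-class] (defaults to the recommended settings).
#' @param outdir optional; when given, `study_per_sample.tsv` and
#'   `study_summary.tsv` are written there.
#' @param computeMle also run [charrGridMLE()] per sample (default `TRUE`).
#' @return list with `per_sample` (rate, sample, estimate, site count,
#'   het/hom ratio, fraction of true hom-alt sites called het, and MLE
#'   columns) and `summary` (per rate: mean estimate, relative bias
#'   `(mean - true)/true`, mean retained sites).
#' @export
runSimulationStudy <- function(scenario, cfg = filterConfig(), outdir = NULL,
                               computeMle = TRUE) {
  stopifnot(is(scenario, "SimScenario"), is(cfg, "FilterConfig"))
  cohort <- drawCohort(scenario)
  meta <- cohort$meta
  afm <- alleleFrequencyMap(meta$contig, meta$pos, meta$ref, meta$alt,
                            cohort$q, sourceLabel = "simulated")
  sampleIds <- colnames(cohort$truth)

  perSample <- do.call(rbind, lapply(cohort$perRate, function(pr) {
    do.call(rbind, lapply(seq_along(sampleIds), function(i) {
      rec <- sampleRecords(meta, sampleIds[i], pr$calls$gt[, i],
                           pr$reads$ad_ref[, i], pr$reads$ad_alt[, i],
                           pr$reads$dp[, i], pr$calls$gq[, i])
      sel <- selectInformative(rec, afm, cfg)
      hh <- hetHomRatio(rec, cfg)
      res <- computeCharr(sel$records, sampleIds[i], cfg@minSites, hh)
      homAlt <- cohort$truth[, i] == 2L
      conv <- if (any(homAlt)) {
        mean(pr$calls$gt[homAlt, i] == "het")
      } else NA_real_
      row <- data.frame(true_c = pr$rate, sample_id = sampleIds[i],
                        charr = res@charr, n_sites = res@nSites,
                        mean_dp = res@meanDp, het_hom_ratio = hh,
                        insufficient = res@insufficient,
                        frac_homalt_called_het = conv,
                        stringsAsFactors = FALSE)
      if (computeMle && nrow(sel$records) > 0L) {
        mle <- charrGridMLE(sel$records, sampleId = sampleIds[i])
        row$c_mle <- mle@cMle
        row$c_closed_form <- mle@cClosedForm
        row$loglik_at_max <- mle@loglikAtMax
      } else if (computeMle) {
        row$c_mle <- NA_real_; row$c_closed_form <- NA_real_
        row$loglik_at_max <- NA_real_
      }
      row
    }))
  }))
  rownames(perSample) <- NULL

  summary <- do.call(rbind, lapply(split(perSample, perSample$true_c),
    function(d) {
      m <- mean(d$charr, na.rm = TRUE)
      tc <- d$true_c[1]
      data.frame(true_c = tc, mean_charr = m,
                 relative_bias = if (tc > 0) (m - tc) / tc else NA_real_,
                 mean_n_sites = mean(d$n_sites),
                 mean_het_hom_ratio = mean(d$het_hom_ratio),
                 mean_frac_homalt_called_het =
                   mean(d$frac_homalt_called_het, na.rm = TRUE))
    }))
  summary <- summary[order(summary$true_c), , drop = FALSE]
  rownames(summary) <- NULL

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(perSample, file.path(outdir, "study_per_sample.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(outdir, "study_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(per_sample = perSample, summary = summary)
}
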
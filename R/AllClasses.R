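# S4 classes for configuration, allele-frequency lookup, results and
# simulation scenarios. Genotype records themselves travel as a plain
# data.frame (one row per sample x site; see readGenotypes) -- they are a
# stream, not an object with invariants of its own.

#' Internal: condition constructors with stable classes for the CLI
#' @noRd
stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("charr_config_error", "error", "condition")))
}

#' @noRd
stopInput <- function(...) {
  stop(errorCondition(paste0(...), class = c("charr_input_error", "error", "condition")))
}

# ---------------------------------------------------------------------------
# FilterConfig

#' Variant-selection thresholds
#'
#' Holds every threshold of the variant-selection chain used to pick the
#' informative homozygous-alternate records: genotype quality, the depth
#' window, the reference-allele-frequency window, the variant-type
#' restriction, the autosome restriction, and the minimum number of sites
#' below which a per-sample estimate is flagged insufficient.
#'
#' Defaults are the recommended operating point: autosomal bi-allelic SNVs
#' with GQ >= 20, 20 <= DP <= 100 (inclusive), 0.10 < reference AF < 0.90
#' (strict), and at least 500 retained sites.
#'
#' @slot minGq minimum genotype quality (inclusive).
#' @slot minDp,maxDp depth window (inclusive on both ends).
#' @slot minRefAf,maxRefAf reference-allele-frequency window (exclusive).
#' @slot variantTypes one of `"snv"`, `"indel"`, `"all"`.
#' @slot autosomesOnly restrict to contigs 1..22 (after normalization).
#' @slot minSites sites below this flag the estimate as insufficient.
#' @export
setClass("FilterConfig",
  representation(
    minGq = "integer", minDp = "integer", maxDp = "integer",
    minRefAf = "numeric", maxRefAf = "numeric",
    variantTypes = "character", autosomesOnly = "logical",
    minSites = "integer"
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@minGq < 0L) msg <- c(msg, "minGq must be >= 0")
    if (object@minDp >= object@maxDp) msg <- c(msg, "minDp must be < maxDp")
    if (!(object@minRefAf >= 0 && object@minRefAf < object@maxRefAf &&
          object@maxRefAf <= 1)) {
      msg <- c(msg, "need 0 <= minRefAf < maxRefAf <= 1")
    }
    if (!object@variantTypes %in% c("snv", "indel", "all")) {
      msg <- c(msg, "variantTypes must be one of 'snv', 'indel', 'all'")
    }
    if (object@minSites < 0L) msg <- c(msg, "minSites must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a variant-selection configuration
#'
#' @param minGq minimum genotype quality, inclusive (default 20).
#' @param minDp,maxDp inclusive depth window (defaults 20, 100).
#' @param minRefAf,maxRefAf exclusive reference-AF window (defaults
#'   0.10, 0.90). A symmetric window of at least (0.05, 0.95) is advisable:
#'   hom-alt sites whose reference allele is very rare turn a single noisy
#'   reference read into a disproportionately large estimator term.
#' @param variantTypes `"snv"` (default), `"indel"`, or `"all"`.
#' @param autosomesOnly keep contigs 1..22 only (default `TRUE`).
#' @param minSites minimum retained sites for a trustworthy estimate
#'   (default 500).
#' @return A [FilterConfig-class] object.
#' @examples
#' cfg <- filterConfig()
#' cfg
#' @export
filterConfig <- function(minGq = 20L, minDp = 20L, maxDp = 100L,
                         minRefAf = 0.10, maxRefAf = 0.90,
                         variantTypes = c("snv", "indel", "all"),
                         autosomesOnly = TRUE, minSites = 500L) {
  variantTypes <- match.arg(variantTypes)
  out <- tryCatch(
    new("FilterConfig",
        minGq = as.integer(minGq), minDp = as.integer(minDp),
        maxDp = as.integer(maxDp), minRefAf = as.numeric(minRefAf),
        maxRefAf = as.numeric(maxRefAf), variantTypes = variantTypes,
        autosomesOnly = isTRUE(autosomesOnly),
        minSites = as.integer(minSites)),
    error = function(e) stopConfig(conditionMessage(e)))
  out
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:",
      sprintf("GQ >= %d; %d <= DP <= %d; %.2f < ref AF < %.2f; types=%s; %s; minSites=%d\n",
              object@minGq, object@minDp, object@maxDp, object@minRefAf,
              object@maxRefAf, object@variantTypes,
              if (object@autosomesOnly) "autosomes only" else "all contigs",
              object@minSites))
})

# ---------------------------------------------------------------------------
# AlleleFrequencyMap

#' Allele-frequency lookup table
#'
#' Maps a normalized site key (contig, 1-based position, REF, ALT) to the
#' population alternate-allele frequency q. The reference-allele frequency
#' is always derived as p = 1 - q, never stored. Keys never allele-swap:
#' a table entry with REF/ALT exchanged is a lookup miss by design, since a
#' silently swapped p would corrupt the estimator.
#'
#' @slot entries named numeric vector of alt-allele frequencies; names are
#'   `"contig:pos:REF:ALT"` after contig normalization and allele
#'   uppercasing.
#' @slot sourceLabel free-text provenance of the frequencies.
#' @slot nDuplicates number of duplicate keys resolved last-wins at load.
#' @export
setClass("AlleleFrequencyMap",
  representation(entries = "numeric", sourceLabel = "character",
                 nDuplicates = "integer"),
  validity = function(object) {
    if (length(object@entries) &&
        (any(is.na(object@entries)) || any(object@entries < 0) ||
         any(object@entries > 1))) {
      return("all allele frequencies must lie in [0, 1]")
    }
    if (length(object@entries) && is.null(names(object@entries))) {
      return("entries must be named by site key")
    }
    TRUE
  }
)

#' Build an allele-frequency map from vectors
#'
#' @param contig,pos,ref,alt parallel vectors defining the sites.
#' @param af alternate-allele frequencies in \[0, 1\].
#' @param sourceLabel provenance label stored with the map.
#' @return An [AlleleFrequencyMap-class]. Duplicate keys resolve last-wins;
#'   the number of duplicates is kept in the object.
#' @examples
#' m <- alleleFrequencyMap("1", 1000, "A", "G", 0.35)
#' afLookup(m, "chr1", 1000, "A", "G")  # 0.35; "chr" prefix is normalized
#' @export
alleleFrequencyMap <- function(contig, pos, ref, alt, af,
                               sourceLabel = "user") {
  af <- as.numeric(af)
  bad <- which(is.na(af) | af < 0 | af > 1)
  if (length(bad)) {
    stopInput("allele frequency outside [0, 1] at entry ", bad[1])
  }
  key <- afKey(contig, pos, ref, alt)
  dup <- duplicated(key, fromLast = TRUE)
  nDup <- sum(dup)
  if (nDup > 0L) {
    warning(sprintf("%d duplicate site key(s) in allele-frequency source; last entry wins", nDup))
    key <- key[!dup]; af <- af[!dup]
  }
  names(af) <- key
  new("AlleleFrequencyMap", entries = af, sourceLabel = sourceLabel,
      nDuplicates = as.integer(nDup))
}

setMethod("show", "AlleleFrequencyMap", function(object) {
  cat(sprintf("AlleleFrequencyMap: %d site(s), source '%s'%s\n",
              length(object@entries), object@sourceLabel,
              if (object@nDuplicates)
                sprintf(" (%d duplicates resolved last-wins)", object@nDuplicates)
              else ""))
})

#' @describeIn AlleleFrequencyMap-class number of stored sites
#' @param x an `AlleleFrequencyMap`
#' @export
setMethod("length", "AlleleFrequencyMap", function(x) length(x@entries))

# ---------------------------------------------------------------------------
# CharrResult

#' Per-sample contamination estimate
#'
#' @slot sampleId sample identifier.
#' @slot charr contamination estimate: mean over retained hom-alt sites of
#'   RR / (p (AR + RR)). `NA` when no sites were retained.
#' @slot nSites number of hom-alt sites used (m).
#' @slot meanDp mean depth over the used sites.
#' @slot hetHomRatio het / hom-alt call ratio over quality-passing records
#'   (`Inf` when hom-alt count is zero with het calls present, `NaN` when
#'   both are zero). High contamination converts hom-alt calls to het, so an
#'   elevated ratio flags samples whose estimate is likely deflated.
#' @slot insufficient `TRUE` when `nSites` is below the configured minimum.
#' @export
setClass("CharrResult",
  representation(sampleId = "character", charr = "numeric",
                 nSites = "integer", meanDp = "numeric",
                 hetHomRatio = "numeric", insufficient = "logical"),
  validity = function(object) {
    if (!is.na(object@charr) && object@charr < 0) {
      return("charr must be >= 0")
    }
    TRUE
  }
)

setMethod("show", "CharrResult", function(object) {
  cat(sprintf(
    "CharrResult '%s': charr=%s over %d site(s)%s; mean DP %.1f; het/hom %.3g\n",
    object@sampleId,
    if (is.na(object@charr)) "NA" else sprintf("%.6f", object@charr),
    object@nSites,
    if (object@insufficient) " [INSUFFICIENT]" else "",
    object@meanDp, object@hetHomRatio))
})

#' @describeIn CharrResult-class the contamination estimate
#' @param x a `CharrResult`
#' @export
charrValue <- function(x) x@charr

#' @describeIn CharrResult-class number of hom-alt sites used
#' @export
nSitesUsed <- function(x) x@nSites

#' @describeIn CharrResult-class whether the estimate used fewer sites than
#'   the configured minimum
#' @export
insufficientSites <- function(x) x@insufficient

#' @describeIn CharrResult-class the sample identifier
#' @export
sampleId <- function(x) x@sampleId

#' Coerce results to the standard output table
#'
#' @param x a `CharrResult` or list of them.
#' @param row.names,optional,... ignored; present for generic compatibility.
#' @return `data.frame` with columns `sample_id`, `charr`, `n_hom_alt_used`,
#'   `mean_dp`, `het_hom_ratio`, `insufficient_sites_flag`.
#' @export
setMethod("as.data.frame", "CharrResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(sample_id = x@sampleId, charr = x@charr,
               n_hom_alt_used = x@nSites, mean_dp = x@meanDp,
               het_hom_ratio = x@hetHomRatio,
               insufficient_sites_flag = x@insufficient,
               stringsAsFactors = FALSE)
  })

# ---------------------------------------------------------------------------
# MleResult

#' Grid-search maximum-likelihood contamination estimate
#'
#' @slot sampleId sample identifier.
#' @slot cMle grid point maximizing the hom-alt read log-likelihood; ties
#'   break toward the smaller (more conservative) rate.
#' @slot gridStart,gridStop,gridStep the search grid.
#' @slot loglikAtMax log-likelihood at `cMle`.
#' @slot cClosedForm the closed-form approximation
#'   `sum(RR) / sum(p * (AR + RR))`, valid when every `c * p` is small.
#' @export
setClass("MleResult",
  representation(sampleId = "character", cMle = "numeric",
                 gridStart = "numeric", gridStop = "numeric",
                 gridStep = "numeric", loglikAtMax = "numeric",
                 cClosedForm = "numeric"),
  validity = function(object) {
    if (object@cMle < object@gridStart - 1e-12 ||
        object@cMle > object@gridStop + 1e-12) {
      return("cMle must lie on the grid")
    }
    TRUE
  }
)

setMethod("show", "MleResult", function(object) {
  cat(sprintf(
    "MleResult '%s': c_mle=%.4f (grid %.3g..%.3g by %.3g), closed form %.6f, logL %.3f\n",
    object@sampleId, object@cMle, object@gridStart, object@gridStop,
    object@gridStep, object@cClosedForm, object@loglikAtMax))
})

#' @describeIn MleResult-class the grid maximum-likelihood estimate
#' @param x an `MleResult`
#' @export
cMle <- function(x) x@cMle

#' @describeIn MleResult-class the closed-form ratio estimate
#' @export
cClosedForm <- function(x) x@cClosedForm

# ---------------------------------------------------------------------------
# SimScenario

#' Contamination-simulation scenario
#'
#' Describes one synthetic cohort: its size, the number of biallelic SNV
#' sites, the contamination rates to simulate, the mixing mode (a single
#' fixed contaminant per sample, or a pool of all other samples), the depth
#' and sequencing-error model, the site allele-frequency spectrum, the
#' ancestry-like strata used to constrain two-way pairing, and the seed.
#'
#' @slot nSamples cohort size (default 30 = 6 strata x 5).
#' @slot nSites number of biallelic SNV sites.
#' @slot rates contamination rates to simulate (default
#'   0.005, 0.01, 0.02, 0.05, 0.10).
#' @slot mixing `"two_way"` (one fixed contaminant per sample, cross-stratum,
#'   each sample original and contaminant exactly once) or `"n_way"`
#'   (every read's contaminant drawn fresh, uniformly, from all other
#'   samples).
#' @slot meanDepth Poisson mean of per-site depth (default 30).
#' @slot seqError per-read probability that the sequenced allele is flipped
#'   to the other allele of the site (default 0.001).
#' @slot afBetaShape Beta shape pair for the alt-AF spectrum; draws are
#'   restricted to \[0.05, 0.95\] by resampling. Default `c(1, 1)`.
#' @slot nStrata number of ancestry-like strata; samples are assigned
#'   round-robin (default 6).
#' @slot seed integer seed; every stochastic step in a cohort run draws from
#'   one stream seeded here.
#' @export
setClass("SimScenario",
  representation(nSamples = "integer", nSites = "integer",
                 rates = "numeric", mixing = "character",
                 meanDepth = "numeric", seqError = "numeric",
                 afBetaShape = "numeric", nStrata = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
    if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
    if (length(object@rates) < 1L || any(object@rates < 0) ||
        any(object@rates >= 1)) {
      msg <- c(msg, "every contamination rate must lie in [0, 1)")
    }
    if (!object@mixing %in% c("two_way", "n_way")) {
      msg <- c(msg, "mixing must be 'two_way' or 'n_way'")
    }
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
    if (object@seqError < 0 || object@seqError >= 1) {
      msg <- c(msg, "seqError must lie in [0, 1)")
    }
    if (length(object@afBetaShape) != 2L || any(object@afBetaShape <= 0)) {
      msg <- c(msg, "afBetaShape must be two positive numbers")
    }
    if (object@nStrata < 1L || object@nStrata > object@nSamples) {
      msg <- c(msg, "nStrata must be in 1..nSamples")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a simulation scenario
#'
#' @param nSites number of biallelic SNV sites to simulate.
#' @param nSamples cohort size (default 30).
#' @param rates contamination rates (default
#'   `c(0.005, 0.01, 0.02, 0.05, 0.10)`).
#' @param mixing `"n_way"` (default) or `"two_way"`.
#' @param meanDepth Poisson depth mean (default 30).
#' @param seqError per-read allele-flip probability (default 0.001).
#' @param afBetaShape Beta shape pair for the alt-AF spectrum (default
#'   `c(1, 1)`, i.e. flat over the \[0.05, 0.95\] truncation window).
#' @param nStrata ancestry-like strata for two-way pairing (default 6).
#' @param seed integer seed (default 1).
#' @return A [SimScenario-class] object.
#' @examples
#' sc <- simScenario(nSites = 500, nSamples = 6, rates = 0.02, seed = 7)
#' sc
#' @export
simScenario <- function(nSites, nSamples = 30L,
                        rates = c(0.005, 0.01, 0.02, 0.05, 0.10),
                        mixing = c("n_way", "two_way"),
                        meanDepth = 30, seqError = 0.001,
                        afBetaShape = c(1, 1), nStrata = 6L, seed = 1L) {
  mixing <- match.arg(mixing)
  tryCatch(
    new("SimScenario", nSamples = as.integer(nSamples),
        nSites = as.integer(nSites), rates = as.numeric(rates),
        mixing = mixing, meanDepth = as.numeric(meanDepth),
        seqError = as.numeric(seqError),
        afBetaShape = as.numeric(afBetaShape),
        nStrata = as.integer(nStrata), seed = as.integer(seed)),
    error = function(e) stopConfig(conditionMessage(e)))
}

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: %d samples (%d strata) x %d sites; %s mixing; rates %s\n  depth ~ Poisson(%.3g); seq error %.4g; alt-AF ~ Beta(%.3g, %.3g) on [0.05, 0.95]; seed %d\n",
    object@nSamples, object@nStrata, object@nSites, object@mixing,
    paste(object@rates, collapse = ", "), object@meanDepth, object@seqError,
    object@afBetaShape[1], object@afBetaShape[2], object@seed))
})
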
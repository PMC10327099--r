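# The estimator itself: reference allele balance, the frequency-adjusted
# per-sample mean, the hom-alt read likelihood and its grid-search MLE.

#' Reference allele balance
#'
#' The reference-allele read depth divided by the sum of reference and
#' alternate allele depths. The denominator is AD_ref + AD_alt, not DP: DP
#' may include reads assigned to neither allele.
#'
#' @param adRef,adAlt per-allele read depths (vectorized).
#' @return `adRef / (adRef + adAlt)` in \[0, 1\].
#' @examples
#' abRef(3, 48)   # ~0.0588: ~6% reference reads at a hom-alt call
#' @export
abRef <- function(adRef, adAlt) {
  tot <- adRef + adAlt
  if (any(tot == 0L)) {
    stop("abRef undefined for AD summing to zero (record should have been depth-filtered)")
  }
  adRef / tot
}

#' Internal: validate a filtered record set for the estimator/likelihood
#' @noRd
checkFiltered <- function(filtered) {
  stopifnot(is.data.frame(filtered),
            all(c("ad_ref", "ad_alt", "p") %in% names(filtered)))
  if (nrow(filtered) == 0L) return(invisible(filtered))
  if (any(filtered$p <= 0 | filtered$p >= 1)) {
    stop("reference AF p outside (0, 1) reached the estimator; the filter must reject these")
  }
  if (any(filtered$ad_ref + filtered$ad_alt == 0L)) {
    stop("record with AD summing to zero reached the estimator")
  }
  invisible(filtered)
}

#' Compute the contamination estimate for one sample
#'
#' The estimate is the mean over the m retained hom-alt sites of
#' \deqn{RR_j / (p_j (AR_j + RR_j)),}
#' the reference allele balance divided by the reference-allele frequency.
#' Its expectation under read-level contamination at rate c is c at every
#' site, so the mean estimates the sample's contamination rate.
#'
#' @param filtered retained records with a `p` column, as produced by
#'   [selectInformative()].
#' @param sampleId sample identifier stored in the result.
#' @param minSites sites below this flag the result insufficient
#'   (default 500).
#' @param hetHomRatio optional precomputed het/hom-alt ratio to store.
#' @return A [CharrResult-class]. An empty input yields `charr = NA`,
#'   `nSites = 0`, `insufficient = TRUE` (batch runs must not abort on a
#'   sample with nothing retained).
#' @examples
#' rec <- data.frame(ad_ref = c(2, 1), ad_alt = c(38, 49), p = c(0.5, 0.25),
#'                   dp = c(40, 50))
#' charrValue(computeCharr(rec, "s1"))  # mean(0.1, 0.08) = 0.09
#' @export
computeCharr <- function(filtered, sampleId = "sample", minSites = 500L,
                         hetHomRatio = NA_real_) {
  checkFiltered(filtered)
  m <- nrow(filtered)
  if (m == 0L) {
    return(new("CharrResult", sampleId = as.character(sampleId),
               charr = NA_real_, nSites = 0L, meanDp = NaN,
               hetHomRatio = as.numeric(hetHomRatio), insufficient = TRUE))
  }
  est <- mean(filtered$ad_ref /
                (filtered$p * (filtered$ad_ref + filtered$ad_alt)))
  meanDp <- if ("dp" %in% names(filtered)) mean(filtered$dp) else NaN
  new("CharrResult", sampleId = as.character(sampleId), charr = est,
      nSites = as.integer(m), meanDp = as.numeric(meanDp),
      hetHomRatio = as.numeric(hetHomRatio),
      insufficient = m < as.integer(minSites))
}

#' Log-likelihood of the hom-alt read data at contamination rate c
#'
#' Each read at a hom-alt site is reference with probability `c * p` and
#' alternate otherwise, giving
#' \deqn{\ell(c) = \sum_j AR_j \log(1 - c p_j) + RR_j \log(c p_j).}
#' At `c = 0` the convention `0 * log(0) = 0` applies, so a sample with no
#' reference reads has finite likelihood there (and is maximized there).
#'
#' @param c contamination rate, `>= 0` with `c * p < 1` for every site.
#' @param filtered retained records with `p` (see [selectInformative()]).
#' @return the log-likelihood; `-Inf` if `c = 0` while reference reads were
#'   observed.
#' @export
charrLogLik <- function(c, filtered) {
  checkFiltered(filtered)
  if (length(c) != 1L || is.na(c) || c < 0) {
    stop("c must be a single value >= 0")
  }
  cp <- c * filtered$p
  if (any(cp >= 1)) stop("c * p >= 1 puts the read model outside its domain")
  rr <- filtered$ad_ref
  ar <- filtered$ad_alt
  if (c == 0) {
    if (any(rr > 0)) return(-Inf)
    return(0)
  }
  sum(ar * log1p(-cp)) + sum(rr * log(cp))
}

#' Grid-search maximum-likelihood contamination estimate
#'
#' Evaluates [charrLogLik()] at every grid point (default 0 to 0.1 in steps
#' of 0.001) and returns the maximizing point, ties broken toward the
#' smaller rate. Grid points where any `c * p >= 1` are skipped. Also
#' returns the closed-form approximation
#' `sum(RR) / sum(p * (AR + RR))`, exact in the limit where every
#' `1 - c p_j` is close to 1; the mean-per-site estimator of
#' [computeCharr()] tracks both closely at low contamination.
#'
#' @param filtered non-empty retained records with `p`.
#' @param gridStart,gridStop,gridStep search grid (defaults 0, 0.1, 0.001).
#' @param sampleId identifier stored in the result.
#' @return An [MleResult-class].
#' @export
charrGridMLE <- function(filtered, gridStart = 0, gridStop = 0.1,
                         gridStep = 0.001, sampleId = "sample") {
  checkFiltered(filtered)
  if (nrow(filtered) == 0L) stop("cannot run the grid search on an empty record set")
  if (!(gridStart >= 0 && gridStep > 0 && gridStop > gridStart)) {
    stopConfig("need 0 <= gridStart < gridStop and gridStep > 0")
  }
  grid <- seq(gridStart, gridStop, by = gridStep)
  ll <- vapply(grid, function(cc) {
    if (any(cc * filtered$p >= 1)) return(-Inf)
    charrLogLik(cc, filtered)
  }, numeric(1))
  if (!any(is.finite(ll))) {
    stop("log-likelihood not finite at any grid point")
  }
  best <- which.max(ll)  # first max: ties resolve to the smallest c
  closed <- sum(filtered$ad_ref) /
    sum(filtered$p * (filtered$ad_ref + filtered$ad_alt))
  new("MleResult", sampleId = as.character(sampleId), cMle = grid[best],
      gridStart = gridStart, gridStop = gridStop, gridStep = gridStep,
      loglikAtMax = ll[best], cClosedForm = closed)
}
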
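# High-level per-VCF drivers: read once, split by sample, filter, estimate.

#' Internal: resolve an AF argument (map object, or path + mode)
#' @noRd
resolveAf <- function(af, mode = "sites_table") {
  if (is(af, "AlleleFrequencyMap")) return(af)
  readAlleleFrequencies(af, mode = mode)
}

#' Compute contamination estimates for every sample of a VCF
#'
#' @param vcfPath path to the VCF.
#' @param af an [AlleleFrequencyMap-class], or a path to a sites table /
#'   VCF with INFO/AF (see `afMode`).
#' @param cfg a [FilterConfig-class].
#' @param samples optional sample subset.
#' @param afMode how to read `af` when it is a path (`"sites_table"` or
#'   `"info_af"`).
#' @return list with `table` (one row per sample in output-column form),
#'   `results` (list of [CharrResult-class]) and `reports` (named list of
#'   filter reports).
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "charr")
#' aft <- system.file("extdata", "toy_af.tsv", package = "charr")
#' charrFromVcf(vcf, aft)$table
#' @export
charrFromVcf <- function(vcfPath, af, cfg = filterConfig(), samples = NULL,
                         afMode = "sites_table") {
  afm <- resolveAf(af, afMode)
  records <- readGenotypes(vcfPath, samples)
  bySample <- split(records, factor(records$sample_id,
                                    levels = unique(records$sample_id)))
  results <- vector("list", length(bySample))
  reports <- vector("list", length(bySample))
  names(results) <- names(reports) <- names(bySample)
  for (sid in names(bySample)) {
    sel <- selectInformative(bySample[[sid]], afm, cfg)
    hh <- hetHomRatio(bySample[[sid]], cfg)
    results[[sid]] <- computeCharr(sel$records, sid, cfg@minSites, hh)
    reports[[sid]] <- sel$report
  }
  tab <- do.call(rbind, lapply(results, as.data.frame))
  rownames(tab) <- NULL
  list(table = tab, results = results, reports = reports)
}

#' Grid-search MLE for every sample of a VCF
#'
#' @inheritParams charrFromVcf
#' @param gridStart,gridStop,gridStep search grid passed to
#'   [charrGridMLE()].
#' @return `data.frame` with columns `sample_id`, `c_mle`, `c_closed_form`,
#'   `loglik_at_max`, `n_sites` (`NA` rows for samples with nothing
#'   retained).
#' @export
mleFromVcf <- function(vcfPath, af, cfg = filterConfig(), samples = NULL,
                       afMode = "sites_table", gridStart = 0,
                       gridStop = 0.1, gridStep = 0.001) {
  afm <- resolveAf(af, afMode)
  records <- readGenotypes(vcfPath, samples)
  bySample <- split(records, factor(records$sample_id,
                                    levels = unique(records$sample_id)))
  rows <- lapply(names(bySample), function(sid) {
    sel <- selectInformative(bySample[[sid]], afm, cfg)
    if (nrow(sel$records) == 0L) {
      return(data.frame(sample_id = sid, c_mle = NA_real_,
                        c_closed_form = NA_real_, loglik_at_max = NA_real_,
                        n_sites = 0L, stringsAsFactors = FALSE))
    }
    mle <- charrGridMLE(sel$records, gridStart, gridStop, gridStep, sid)
    data.frame(sample_id = sid, c_mle = mle@cMle,
               c_closed_form = mle@cClosedForm,
               loglik_at_max = mle@loglikAtMax,
               n_sites = nrow(sel$records), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
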
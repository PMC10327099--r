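# The variant-selection chain: reduce a sample's genotype records to the
# informative hom-alt set, with an exhaustive audit of why each record was
# rejected. Rejection reasons are assigned in a fixed precedence so the
# report is deterministic.

FILTER_REASONS <- c("non_autosomal", "multi_allelic", "wrong_variant_type",
                    "gq_fail", "dp_fail", "not_hom_alt", "af_missing",
                    "af_out_of_window", "retained")

#' Classify a variant as SNV or indel
#'
#' A variant is an SNV iff both alleles are single bases; anything else
#' (insertions, deletions, MNPs) is classed `"indel"`.
#'
#' @param ref,alt allele strings (vectorized).
#' @return character vector of `"snv"` / `"indel"`.
#' @examples
#' classifyVariantType(c("A", "A", "ACG"), c("G", "AT", "A"))
#' @export
classifyVariantType <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

#' Internal: quality gates shared by selectInformative and hetHomRatio.
#' Returns the first failed gate per record ("" = all gates passed).
#' Precedence: non_autosomal, multi_allelic, wrong_variant_type, gq_fail,
#' dp_fail. Depth-uninformative records (AD summing to zero or NA) fail the
#' depth gate: every estimator term divides by AR + RR.
#' @noRd
qualityGateFate <- function(records, cfg) {
  n <- nrow(records)
  fate <- character(n)
  open <- rep(TRUE, n)
  mark <- function(fate, open, cond, reason) {
    hit <- open & cond
    fate[hit] <- reason
    list(fate = fate, open = open & !hit)
  }
  if (cfg@autosomesOnly) {
    s <- mark(fate, open,
              !(records$contig %in% as.character(1:22)), "non_autosomal")
    fate <- s$fate; open <- s$open
  }
  s <- mark(fate, open, records$multi_allelic %in% TRUE, "multi_allelic")
  fate <- s$fate; open <- s$open
  if (cfg@variantTypes != "all") {
    vt <- classifyVariantType(records$ref, records$alt)
    s <- mark(fate, open, is.na(records$alt) | vt != cfg@variantTypes,
              "wrong_variant_type")
    fate <- s$fate; open <- s$open
  }
  s <- mark(fate, open, is.na(records$gq) | records$gq < cfg@minGq, "gq_fail")
  fate <- s$fate; open <- s$open
  adSum <- records$ad_ref + records$ad_alt
  s <- mark(fate, open,
            is.na(records$dp) | records$dp < cfg@minDp |
              records$dp > cfg@maxDp | is.na(adSum) | adSum == 0L,
            "dp_fail")
  s$fate
}

#' Select the informative homozygous-alternate records of one sample
#'
#' Applies the selection chain in fixed precedence: autosomal, bi-allelic,
#' variant type, GQ, depth window, hom-alt genotype, allele frequency
#' present, reference AF inside the (exclusive) window. Each input record is
#' assigned exactly one fate, so the report partitions the input.
#'
#' Records whose site has no allele-frequency entry are rejected
#' (`af_missing`) rather than given a default: a wrong p biases the
#' estimator directly.
#'
#' @param records genotype records of one sample (see [readGenotypes()]).
#' @param af an [AlleleFrequencyMap-class].
#' @param cfg a [FilterConfig-class].
#' @return list with `records` — the retained rows plus a `p` column
#'   (reference-allele frequency `1 - q`) — and `report`, a named integer
#'   vector over all rejection reasons plus `retained`.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "charr")
#' afm <- readAlleleFrequencies(
#'   system.file("extdata", "toy_af.tsv", package = "charr"))
#' sel <- selectInformative(readGenotypes(vcf), afm, filterConfig())
#' sel$report
#' @export
selectInformative <- function(records, af, cfg = filterConfig()) {
  stopifnot(is(af, "AlleleFrequencyMap"), is(cfg, "FilterConfig"))
  n <- nrow(records)
  fate <- qualityGateFate(records, cfg)
  open <- fate == ""
  fate[open & records$gt != "hom_alt"] <- "not_hom_alt"
  open <- fate == ""

  p <- rep(NA_real_, n)
  if (any(open)) {
    q <- afLookup(af, records$contig[open], records$pos[open],
                  records$ref[open], records$alt[open])
    p[open] <- 1 - q
  }
  fate[open & is.na(p)] <- "af_missing"
  open <- fate == ""
  fate[open & !(p > cfg@minRefAf & p < cfg@maxRefAf)] <- "af_out_of_window"
  open <- fate == ""
  fate[open] <- "retained"

  report <- vapply(FILTER_REASONS, function(r) sum(fate == r), integer(1))
  kept <- records[fate == "retained", , drop = FALSE]
  kept$p <- p[fate == "retained"]
  rownames(kept) <- NULL
  list(records = kept, report = report)
}

#' Heterozygous / homozygous-alternate call ratio
#'
#' Computed over records passing the autosome, bi-allelic, variant-type, GQ
#' and depth gates (the genotype gate is replaced by membership in
#' \{het, hom_alt\}). Excess reference reads at high contamination convert
#' hom-alt calls to het, deflating the contamination estimate while
#' inflating this ratio — an elevated value is the recommended flag for
#' potentially highly contaminated samples.
#'
#' @param records genotype records of one sample.
#' @param cfg a [FilterConfig-class].
#' @return `het / hom_alt` count ratio; `Inf` if there are het calls but no
#'   hom-alt calls; `NaN` if there are neither.
#' @export
hetHomRatio <- function(records, cfg = filterConfig()) {
  fate <- qualityGateFate(records, cfg)
  gt <- records$gt[fate == ""]
  nHet <- sum(gt == "het")
  nHom <- sum(gt == "hom_alt")
  if (nHom == 0L) {
    if (nHet > 0L) Inf else NaN
  } else {
    nHet / nHom
  }
}
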
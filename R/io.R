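# VCF genotype ingestion, allele-frequency sources, result tables.
# Parsing goes through VariantAnnotation; this layer flattens the
# site-by-sample matrices into the per-record stream the filter consumes.

#' Normalize a contig name
#'
#' Strips a leading `"chr"` so that `"chr1"` and `"1"` join to the same
#' allele-frequency key.
#' @param x character vector of contig names.
#' @return normalized character vector.
#' @export
normalizeContig <- function(x) sub("^chr", "", as.character(x))

#' Internal: canonical allele-frequency join key
#' @noRd
afKey <- function(contig, pos, ref, alt) {
  paste(normalizeContig(contig), as.integer(pos),
        toupper(as.character(ref)), toupper(as.character(alt)), sep = ":")
}

#' Look up alternate-allele frequencies
#'
#' @param map an [AlleleFrequencyMap-class].
#' @param contig,pos,ref,alt parallel site vectors; contigs are normalized
#'   and alleles uppercased before the lookup. REF/ALT are never swapped:
#'   a swapped entry is a miss.
#' @return numeric vector of alt-allele frequencies q, `NA` on miss. The
#'   reference-allele frequency is `1 - q`.
#' @export
afLookup <- function(map, contig, pos, ref, alt) {
  stopifnot(is(map, "AlleleFrequencyMap"))
  unname(map@entries[afKey(contig, pos, ref, alt)])
}

#' Internal: classify GT strings into genotype classes
#' @noRd
classifyGT <- function(gt) {
  one <- function(g) {
    if (is.na(g)) return("missing")
    g <- gsub("|", "/", g, fixed = TRUE)
    if (grepl(".", g, fixed = TRUE)) return("missing")
    a <- suppressWarnings(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
    if (anyNA(a) || !length(a)) return("missing")
    if (all(a == 0L)) return("hom_ref")
    if (length(unique(a)) == 1L) return("hom_alt")
    "het"
  }
  u <- unique(gt)
  vapply(u, one, character(1))[match(gt, u)]
}

#' Internal: first/second AD component from readVcf output
#' (list-matrix for Number=R fields, or a 3-d array)
#' @noRd
adComponent <- function(ad, k) {
  if (is.null(ad)) return(NULL)
  if (is.array(ad) && length(dim(ad)) == 3L) {
    out <- ad[, , k, drop = TRUE]
    return(matrix(as.integer(out), nrow = dim(ad)[1]))
  }
  matrix(vapply(ad, function(x) {
    if (length(x) >= k && !is.na(x[k])) as.integer(x[k]) else NA_integer_
  }, integer(1)), nrow = nrow(ad))
}

#' Read per-sample genotype records from a VCF
#'
#' Flattens a (possibly multi-sample) VCF into one record per sample x site
#' with the fields the estimator needs: genotype class, per-allele depths,
#' total depth and genotype quality. Multi-allelic records are marked, not
#' split (the filter drops them; splitting would require AD re-derivation).
#' Records with missing GT or missing AD are classed `"missing"`; missing
#' DP/GQ stay `NA` and fail the corresponding filter gate.
#'
#' @param vcfPath path to a VCF (plain or bgzipped) with GT in FORMAT.
#' @param samples optional character vector restricting to these sample ids;
#'   a requested sample absent from the file is an error.
#' @return `data.frame` with columns `contig` (normalized), `pos`, `ref`,
#'   `alt` (first alternate allele), `sample_id`, `gt` (one of `hom_ref`,
#'   `het`, `hom_alt`, `missing`), `ad_ref`, `ad_alt`, `dp`, `gq`,
#'   `multi_allelic`. Attribute `contigPrefixStripped` records whether a
#'   leading `"chr"` was removed.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "charr")
#' head(readGenotypes(vcf))
#' @export
readGenotypes <- function(vcfPath, samples = NULL) {
  if (!file.exists(vcfPath)) stopInput("cannot read VCF: ", vcfPath)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcfPath, genome = "unspecified")),
    error = function(e) stopInput("failed to parse VCF '", vcfPath, "': ",
                                  conditionMessage(e)))
  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g)) {
    stopInput("VCF FORMAT lacks GT: ", vcfPath)
  }
  gtm <- g$GT
  sampleIds <- colnames(gtm)
  if (!is.null(samples)) {
    missing <- setdiff(samples, sampleIds)
    if (length(missing)) {
      stopInput("sample(s) not present in VCF: ",
                paste(missing, collapse = ", "))
    }
    sel <- match(samples, sampleIds)
  } else {
    sel <- seq_along(sampleIds)
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  rawContig <- as.character(seqnames(rr))
  contig <- normalizeContig(rawContig)
  pos <- BiocGenerics::start(rr)
  refA <- toupper(as.character(VariantAnnotation::ref(vcf)))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- elementNROWS(altL)
  altAll <- toupper(as.character(unlist(altL)))
  alt1 <- rep(NA_character_, length(nAlt))
  has <- nAlt > 0L
  alt1[has] <- altAll[cumsum(nAlt)[has] - nAlt[has] + 1L]
  multi <- nAlt > 1L

  nSite <- length(pos)
  adRefM <- adComponent(g$AD, 1L)
  adAltM <- adComponent(g$AD, 2L)
  dpM <- if (!is.null(g$DP)) g$DP else NULL
  gqM <- if (!is.null(g$GQ)) g$GQ else NULL

  pick <- function(m, j) {
    if (is.null(m)) rep(NA_integer_, nSite) else as.integer(m[, j])
  }

  blocks <- lapply(sel, function(j) {
    gt <- classifyGT(as.character(gtm[, j]))
    adr <- pick(adRefM, j); ada <- pick(adAltM, j)
    gt[is.na(adr) | is.na(ada)] <- "missing"
    data.frame(contig = contig, pos = pos, ref = refA, alt = alt1,
               sample_id = sampleIds[j], gt = gt,
               ad_ref = adr, ad_alt = ada,
               dp = pick(dpM, j), gq = pick(gqM, j),
               multi_allelic = multi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "contigPrefixStripped") <- any(rawContig != contig)
  out
}

#' Load an allele-frequency source
#'
#' Two source modes are supported: the `INFO/AF` field of a VCF
#' (`mode = "info_af"`; multi-allelic records are skipped), or an external
#' tab-separated sites table with header columns `contig`, `pos`, `ref`,
#' `alt`, `af` (`mode = "sites_table"`). Using frequencies from a large
#' external reference panel is preferable when the local callset is small:
#' the adjustment divides by the reference-allele frequency of the
#' *contaminating* population, which a small callset estimates poorly.
#'
#' @param source file path.
#' @param mode `"sites_table"` or `"info_af"`.
#' @return An [AlleleFrequencyMap-class] keyed by normalized site; duplicate
#'   keys resolve last-wins with a warning.
#' @examples
#' tsv <- system.file("extdata", "toy_af.tsv", package = "charr")
#' readAlleleFrequencies(tsv, mode = "sites_table")
#' @export
readAlleleFrequencies <- function(source, mode = c("sites_table", "info_af")) {
  mode <- match.arg(mode)
  if (!file.exists(source)) stopInput("cannot read AF source: ", source)
  if (mode == "sites_table") {
    tab <- tryCatch(read.delim(source, stringsAsFactors = FALSE),
                    error = function(e) stopInput("failed to read sites table: ",
                                                  conditionMessage(e)))
    need <- c("contig", "pos", "ref", "alt", "af")
    if (!all(need %in% names(tab))) {
      stopInput("sites table must have columns: ", paste(need, collapse = ", "))
    }
    if (nrow(tab) == 0L) {
      return(new("AlleleFrequencyMap", entries = numeric(0),
                 sourceLabel = basename(source), nDuplicates = 0L))
    }
    af <- suppressWarnings(as.numeric(tab$af))
    bad <- which(is.na(af) | af < 0 | af > 1)
    if (length(bad)) {
      stopInput("allele frequency outside [0, 1] at data line ", bad[1],
                " of ", source)
    }
    alleleFrequencyMap(tab$contig, tab$pos, tab$ref, tab$alt, af,
                       sourceLabel = basename(source))
  } else {
    vcf <- tryCatch(
      suppressWarnings(VariantAnnotation::readVcf(source, genome = "unspecified")),
      error = function(e) stopInput("failed to parse VCF '", source, "': ",
                                    conditionMessage(e)))
    info <- VariantAnnotation::info(vcf)
    if (!"AF" %in% names(info)) {
      stopInput("VCF INFO lacks AF: ", source)
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    altL <- VariantAnnotation::alt(vcf)
    keep <- elementNROWS(altL) == 1L
    afL <- info$AF
    af1 <- vapply(seq_along(afL), function(i) {
      v <- afL[[i]]
      if (length(v) >= 1L) as.numeric(v[1]) else NA_real_
    }, numeric(1))
    keep <- keep & !is.na(af1)
    if (!any(keep)) {
      return(new("AlleleFrequencyMap", entries = numeric(0),
                 sourceLabel = basename(source), nDuplicates = 0L))
    }
    bad <- which(keep & (af1 < 0 | af1 > 1))
    if (length(bad)) {
      stopInput("INFO/AF outside [0, 1] at record ", bad[1], " of ", source)
    }
    alleleFrequencyMap(as.character(seqnames(rr))[keep],
                       BiocGenerics::start(rr)[keep],
                       as.character(VariantAnnotation::ref(vcf))[keep],
                       as.character(unlist(altL[keep])),
                       af1[keep], sourceLabel = basename(source))
  }
}

#' Write per-sample results as a tab-separated table
#'
#' @param results a list of [CharrResult-class] objects (or a single one),
#'   or a data.frame already in output-column form. An empty list writes a
#'   header-only file.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCharrResults <- function(results, path) {
  if (is(results, "CharrResult")) results <- list(results)
  if (is.data.frame(results)) {
    tab <- results
  } else if (length(results) == 0L) {
    tab <- data.frame(sample_id = character(0), charr = numeric(0),
                      n_hom_alt_used = integer(0), mean_dp = numeric(0),
                      het_hom_ratio = numeric(0),
                      insufficient_sites_flag = logical(0))
  } else {
    tab <- do.call(rbind, lapply(results, as.data.frame))
  }
  fmt <- function(x) {
    ifelse(is.finite(x), sprintf("%.6f", x),
           ifelse(is.nan(x), "nan", ifelse(is.na(x), "NA",
                  ifelse(x > 0, "inf", "-inf"))))
  }
  out <- data.frame(sample_id = tab$sample_id,
                    charr = fmt(tab$charr),
                    n_hom_alt_used = tab$n_hom_alt_used,
                    mean_dp = fmt(tab$mean_dp),
                    het_hom_ratio = fmt(tab$het_hom_ratio),
                    insufficient_sites_flag =
                      ifelse(tab$insufficient_sites_flag, "true", "false"),
                    stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stopInput("cannot write: ", path))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
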
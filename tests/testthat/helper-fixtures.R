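# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

# A genotype-record data.frame in the shape readGenotypes() produces.
makeRecords <- function(n = 1L, contig = "1", pos = NULL, ref = "A",
                        alt = "G", sample_id = "s1", gt = "hom_alt",
                        ad_ref = 0L, ad_alt = 30L, dp = NULL, gq = 99L,
                        multi_allelic = FALSE) {
  if (is.null(pos)) pos <- seq_len(n) * 100L
  out <- data.frame(contig = rep_len(as.character(contig), n),
                    pos = rep_len(as.integer(pos), n),
                    ref = rep_len(ref, n), alt = rep_len(alt, n),
                    sample_id = rep_len(sample_id, n),
                    gt = rep_len(gt, n),
                    ad_ref = rep_len(as.integer(ad_ref), n),
                    ad_alt = rep_len(as.integer(ad_alt), n),
                    dp = if (is.null(dp)) {
                      rep_len(as.integer(ad_ref), n) + rep_len(as.integer(ad_alt), n)
                    } else rep_len(as.integer(dp), n),
                    gq = rep_len(as.integer(gq), n),
                    multi_allelic = rep_len(multi_allelic, n),
                    stringsAsFactors = FALSE)
  out
}

# An AF map covering exactly the sites of a record set.
afMapFor <- function(records, q) {
  u <- !duplicated(records[c("contig", "pos", "ref", "alt")])
  alleleFrequencyMap(records$contig[u], records$pos[u], records$ref[u],
                     records$alt[u], rep_len(q, sum(u)))
}

# Random records across contigs (incl. non-autosomes), genotypes and
# quality values, for the conservation / monotonicity properties.
randomRecords <- function(n, seed) {
  set.seed(seed)
  makeRecords(
    n = n,
    contig = sample(c(as.character(1:22), "X", "Y", "MT"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T", "AT"), n, replace = TRUE),
    alt = sample(c("A", "G", "T", "TTG"), n, replace = TRUE),
    gt = sample(c("hom_ref", "het", "hom_alt", "missing"), n,
                replace = TRUE, prob = c(0.2, 0.3, 0.4, 0.1)),
    ad_ref = sample(0:10, n, replace = TRUE),
    ad_alt = sample(0:60, n, replace = TRUE),
    dp = sample(5:120, n, replace = TRUE),
    gq = sample(0:99, n, replace = TRUE),
    multi_allelic = sample(c(TRUE, FALSE), n, replace = TRUE,
                           prob = c(0.1, 0.9)))
}

# Write VCF body lines under a minimal GT:AD:DP:GQ header.
writeVcfFixture <- function(lines, samples = "s1",
                            path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

writeSitesTable <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
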
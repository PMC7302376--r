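#' Construct a table of heterozygous variant sites
#'
#' @param pos Integer vector of genomic positions (1-based, strictly
#'   increasing).
#' @param ref Character vector of reference alleles (single bases).
#' @param alt Character vector of alternate alleles; multiple alternates are
#'   comma-separated.
#' @param dosage Integer vector: number of alternate alleles in the genotype
#'   (biallelic sites), `1 <= dosage <= ploidy - 1`.
#' @return A `data.frame` of class `"variant_sites"` with columns `index`
#'   (consecutive 1..M), `pos`, `ref`, `alt`, `dosage`.
#' @export
variant_sites <- function(pos, ref, alt, dosage) {
  pos <- as.integer(pos)
  if (is.unsorted(pos, strictly = TRUE))
    stop("variant positions must be strictly increasing")
  df <- data.frame(index = seq_along(pos), pos = pos,
                   ref = as.character(ref), alt = as.character(alt),
                   dosage = as.integer(dosage),
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_sites", "data.frame")
  df
}

#' Load heterozygous SNPs from a VCF file
#'
#' Reads a single-sample VCF with polyploid genotypes, keeps biallelic-style
#' SNPs whose genotype contains at least one reference and one alternate
#' allele (homozygous sites carry no phase information), and renumbers the
#' retained sites 1..M in position order.  Indels and sites with more than
#' three alternate alleles are skipped.
#'
#' @param vcf_source Path to a VCF 4.x file (plain text or bgzipped).
#' @param ploidy Expected ploidy K; the GT arity of every record must match.
#' @return A `"variant_sites"` data frame (see [variant_sites()]).
#' @export
load_heterozygous_variants <- function(vcf_source, ploidy) {
  vcf <- VariantAnnotation::readVcf(vcf_source, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  if (ncol(gt) != 1L)
    stop(sprintf("multi-sample VCF not supported (%d samples)", ncol(gt)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- lapply(rr$ALT, as.character)
  gts <- gt[, 1L]

  keep <- logical(length(pos)); dosage <- integer(length(pos))
  altstr <- character(length(pos))
  for (i in seq_along(pos)) {
    alleles <- strsplit(gts[i], "[/|]")[[1L]]
    if (any(alleles == ".")) next
    a <- as.integer(alleles)
    if (length(a) != ploidy)
      stop(sprintf("GT arity %d does not match ploidy %d at position %d",
                   length(a), ploidy, pos[i]))
    alts <- altl[[i]]
    if (nchar(ref[i]) != 1L || any(nchar(alts) != 1L)) next  # indel / MNP
    if (length(alts) > 3L) {
      warning(sprintf("site at %d has %d alternate alleles; dropped",
                      pos[i], length(alts)))
      next
    }
    d <- sum(a > 0L)
    if (d == 0L || d == ploidy) next                          # homozygous
    keep[i] <- TRUE
    dosage[i] <- d
    altstr[i] <- paste(alts, collapse = ",")
  }
  o <- order(pos[keep])
  variant_sites(pos[keep][o], ref[keep][o], altstr[keep][o],
                dosage[keep][o])
}

## allele string -> codes: element j of the returned character vector is the
## base encoded by allele code j-1 (ref first, then alternates).
site_alleles <- function(variants, i) {
  c(variants$ref[i], strsplit(variants$alt[i], ",")[[1L]])
}
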
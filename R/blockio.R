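#' Write haplotype blocks to a text file
#'
#' HapCUT2-like layout: each block starts with a header line giving the
#' haplotype length (number of sites), the number of fragments supporting
#' the block and its MEC score; then one row per variant with the 1-based
#' variant index, the genomic position, K allele columns (gap printed as
#' `-`) and K quality columns (the number of matching fragment calls per
#' haplotype at that site).  Blocks end with a `********` line.
#'
#' @param blocks List of `"haplotype_block"` objects.
#' @param path Output path.
#' @param positions Genomic position of every variant index.
#' @return `path`, invisibly.
#' @export
write_block_file <- function(blocks, path, positions) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    K <- nrow(b$haplotypes)
    writeLines(sprintf("BLOCK length %d fragments %d MEC %d",
                       length(b$idx), b$n_fragments, as.integer(b$mec)), con)
    for (j in seq_along(b$idx)) {
      al <- ifelse(is.na(b$haplotypes[, j]), "-", b$haplotypes[, j])
      writeLines(paste(c(b$idx[j], positions[b$idx[j]], al,
                         b$support[, j]), collapse = "\t"), con)
    }
    writeLines("********", con)
  }
  invisible(path)
}

#' Read haplotype blocks written by [write_block_file()]
#'
#' @param path Input path.
#' @param ploidy K (number of allele columns per row).
#' @return List of `"haplotype_block"` objects (with `n_fragments` and
#'   `mec` from the headers).
#' @export
read_block_file <- function(path, ploidy) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (hdr[1L] != "BLOCK")
      stop(sprintf("block file %s line %d: expected BLOCK header", path, i))
    len <- as.integer(hdr[3L]); nfrag <- as.integer(hdr[5L])
    mec <- as.integer(hdr[7L])
    idx <- integer(len)
    hap <- matrix(NA_integer_, ploidy, len)
    support <- matrix(0L, ploidy, len)
    for (j in seq_len(len)) {
      tok <- strsplit(lines[i + j], "\t")[[1L]]
      idx[j] <- as.integer(tok[1L])
      al <- tok[3:(2L + ploidy)]
      hap[, j] <- suppressWarnings(as.integer(ifelse(al == "-", NA, al)))
      support[, j] <- as.integer(tok[(3L + ploidy):(2L + 2L * ploidy)])
    }
    if (lines[i + len + 1L] != "********")
      stop(sprintf("block file %s: missing terminator after line %d",
                   path, i + len))
    blocks[[length(blocks) + 1L]] <-
      structure(list(idx = idx, haplotypes = hap, support = support,
                     mec = mec, n_fragments = nfrag),
                class = "haplotype_block")
    i <- i + len + 2L
  }
  blocks
}

#' Write ground-truth haplotypes to a text file
#'
#' One row per SNP: 1-based index, genomic position, K allele columns.
#'
#' @param truth A `"ground_truth"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_file <- function(truth, path) {
  K <- nrow(truth$haplotypes)
  rows <- vapply(seq_along(truth$pos), function(j)
    paste(c(j, truth$pos[j], truth$haplotypes[, j]), collapse = "\t"),
    character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a ground-truth haplotype file written by [write_truth_file()]
#'
#' @param path Input path.
#' @return A `"ground_truth"`.
#' @export
read_truth_file <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  ground_truth(t(m[, -(1:2), drop = FALSE]), m[, 2L])
}
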
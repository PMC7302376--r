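#' Extract per-read fragments from aligned reads
#'
#' Scans a SAM/BAM file, compares the read base at every covered
#' heterozygous SNP against the site's reference and alternate alleles, and
#' emits one fragment per read pair (mates sharing a QNAME are merged).
#' Bases matching neither the reference nor any alternate are skipped.
#' Unmapped, secondary and supplementary records are ignored (counted in the
#' `skipped` attribute).  Fragments with fewer than two calls are discarded
#' unless they carry a barcode: a barcoded single-SNP read becomes
#' informative once reads of its barcode are merged, so the two-call filter
#' is deferred to [merge_by_barcode()].  `strict_two_snp = TRUE` restores the
#' literal remove-before-merging order.
#'
#' @param sam_source Path to a SAM or BAM file; reads may carry a `BX`
#'   barcode tag.
#' @param variants `"variant_sites"` table from
#'   [load_heterozygous_variants()].
#' @param strict_two_snp Drop sub-two-call fragments even when barcoded.
#' @return List of fragments with `origin = "read"`; attribute `skipped`
#'   counts ignored alignment records.
#' @export
extract_read_fragments <- function(sam_source, variants,
                                   strict_two_snp = FALSE) {
  bam <- sam_source
  if (grepl("\\.sam$", sam_source, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_source, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq", "qual"),
    tag = "BX")
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(b$qname)
  if (n == 0L) return(structure(list(), skipped = 0L))
  seqs <- as.character(b$seq)
  quals <- as.character(b$qual)
  bx <- b$tag$BX
  if (is.null(bx)) bx <- rep(NA_character_, n)

  skipped <- 0L
  site_allele_list <- lapply(seq_len(nrow(variants)),
                             function(i) site_alleles(variants, i))
  # per-read calls, keyed by qname for mate merging
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(n)) {
    fl <- b$flag[r]
    if (bitwAnd(fl, 4L) != 0L || bitwAnd(fl, 256L) != 0L ||
        bitwAnd(fl, 2048L) != 0L || is.na(b$pos[r])) {
      skipped <- skipped + 1L
      next
    }
    map <- cigar_reference_map(b$cigar[r], b$pos[r])
    if (length(map$refpos) == 0L) next
    lo <- map$refpos[1L]; hi <- map$refpos[length(map$refpos)]
    vsel <- which(variants$pos >= lo & variants$pos <= hi)
    if (length(vsel) == 0L && is.na(bx[r])) next
    idx <- integer(0); allele <- integer(0); qual <- integer(0)
    if (length(vsel)) {
      qv <- utf8ToInt(quals[r]) - 33L
      bases <- strsplit(seqs[r], "")[[1L]]
      for (vi in vsel) {
        hit <- match(variants$pos[vi], map$refpos)
        if (is.na(hit)) next                       # position deleted in read
        qo <- map$qpos[hit]
        code <- match(bases[qo], site_allele_list[[vi]]) - 1L
        if (is.na(code)) next                      # neither ref nor alt
        idx <- c(idx, variants$index[vi])
        allele <- c(allele, code)
        qual <- c(qual, qv[qo])
      }
    }
    key <- b$qname[r]
    prev <- if (exists(key, envir = acc)) get(key, envir = acc) else NULL
    if (is.null(prev)) {
      assign(key, list(idx = idx, allele = allele, qual = qual,
                       barcode = bx[r]), envir = acc)
    } else {
      assign(key, list(idx = c(prev$idx, idx),
                       allele = c(prev$allele, allele),
                       qual = c(prev$qual, qual),
                       barcode = if (is.na(prev$barcode)) bx[r]
                                 else prev$barcode),
             envir = acc)
    }
  }
  out <- list()
  for (key in sort(ls(acc))) {
    v <- get(key, envir = acc)
    rc <- resolve_calls(v$idx, v$allele, v$qual)
    if (length(rc$idx) == 0L) next
    if (length(rc$idx) < 2L && (strict_two_snp || is.na(v$barcode))) next
    out[[length(out) + 1L]] <- fragment(key, rc$idx, rc$allele, rc$qual,
                                        origin = "read", barcode = v$barcode)
  }
  structure(out, skipped = skipped)
}

## Walk a CIGAR string; return parallel vectors of reference positions and
## 1-based read offsets for every aligned (M/=/X) base.
cigar_reference_map <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  refpos <- integer(0); qpos <- integer(0)
  r <- pos; q <- 1L
  for (k in seq_along(op)) {
    L <- len[k]
    switch(op[k],
      "M" = , "=" = , "X" = {
        refpos <- c(refpos, r:(r + L - 1L))
        qpos <- c(qpos, q:(q + L - 1L))
        r <- r + L; q <- q + L
      },
      "I" = , "S" = { q <- q + L },
      "D" = , "N" = { r <- r + L },
      "H" = , "P" = NULL)
  }
  list(refpos = refpos, qpos = qpos)
}

#' Merge read fragments sharing a barcode
#'
#' All calls of fragments with the same barcode are united into one
#' barcode-specific fragment.  Where two reads of a barcode disagree at a
#' site, the call with the higher base quality wins; an equal-quality
#' conflict between different alleles drops the site.  Unbarcoded fragments
#' pass through unchanged.  Merged fragments retaining fewer than two calls
#' are discarded.
#'
#' @param fragments List of fragments (typically `origin = "read"`).
#' @return List of fragments; barcoded ones have `origin = "barcode"` and
#'   `id = barcode`.
#' @export
merge_by_barcode <- function(fragments) {
  bcs <- vapply(fragments, function(f) f$barcode, character(1))
  out <- fragments[is.na(bcs)]
  out <- out[vapply(out, n_calls, integer(1)) >= 2L]
  for (bc in sort(unique(bcs[!is.na(bcs)]))) {
    grp <- fragments[!is.na(bcs) & bcs == bc]
    rc <- resolve_calls(unlist(lapply(grp, `[[`, "idx")),
                        unlist(lapply(grp, `[[`, "allele")),
                        unlist(lapply(grp, `[[`, "qual")))
    if (length(rc$idx) < 2L) next
    out[[length(out) + 1L]] <- fragment(bc, rc$idx, rc$allele, rc$qual,
                                        origin = "barcode", barcode = bc)
  }
  out
}
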
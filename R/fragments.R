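#' Construct a haplotype-informative fragment
#'
#' A fragment is an ordered set of allele calls at heterozygous SNP sites,
#' together with its provenance: a single read (pair), all reads sharing a
#' barcode, or a single DNA molecule deconvolved from a barcode.
#'
#' @param id Fragment identifier (unique within a fragment set).
#' @param idx Integer vector of 1-based variant indices, strictly increasing.
#' @param allele Integer vector of allele codes (0 = reference, 1..3 =
#'   alternates), same length as `idx`.
#' @param qual Integer vector of Phred base qualities, same length as `idx`.
#' @param origin One of `"read"`, `"barcode"`, `"molecule"`.
#' @param barcode Barcode string, or `NA` for unbarcoded fragments.
#' @param ordinal Molecule ordinal within its barcode (molecule origin only).
#' @return An object of class `"fragment"`.
#' @export
fragment <- function(id, idx, allele, qual, origin = "read",
                     barcode = NA_character_, ordinal = NA_integer_) {
  idx <- as.integer(idx); allele <- as.integer(allele); qual <- as.integer(qual)
  stopifnot(length(idx) == length(allele), length(idx) == length(qual))
  if (length(idx) == 0L) stop("fragment must have at least one call")
  if (is.unsorted(idx, strictly = TRUE))
    stop("fragment calls must be sorted by variant index without duplicates")
  if (!all(allele %in% 0:3)) stop("allele codes must be in 0..3")
  if (any(qual < 0L)) stop("qualities must be >= 0")
  origin <- match.arg(origin, c("read", "barcode", "molecule"))
  if (origin == "molecule" && (is.na(barcode) || is.na(ordinal)))
    stop("molecule fragments must carry a barcode and an ordinal")
  structure(list(id = as.character(id), origin = origin,
                 barcode = as.character(barcode),
                 ordinal = as.integer(ordinal),
                 idx = idx, allele = allele, qual = qual),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  bc <- if (is.na(x$barcode)) "" else paste0(" barcode=", x$barcode)
  ord <- if (is.na(x$ordinal)) "" else paste0("_", x$ordinal)
  cat(sprintf("<fragment %s [%s]%s%s: %d calls, sites %d..%d>\n",
              x$id, x$origin, bc, ord, length(x$idx),
              min(x$idx), max(x$idx)))
  invisible(x)
}

n_calls <- function(f) length(f$idx)

#' Number of calls per fragment
#' @param fragments List of fragments.
#' @return Integer vector.
#' @export
fragment_sizes <- function(fragments) vapply(fragments, n_calls, integer(1))

## Resolve multiple calls at the same variant index.
## Rule: the call with the highest Phred quality wins; if two *different*
## alleles tie at the maximum quality the site is dropped entirely.
## Returns a list(idx, allele, qual) sorted by idx.
resolve_calls <- function(idx, allele, qual) {
  o <- order(idx, -qual)
  idx <- idx[o]; allele <- allele[o]; qual <- qual[o]
  first <- !duplicated(idx)
  starts <- which(first)
  ends <- c(starts[-1L] - 1L, length(idx))
  out_idx <- integer(0); out_allele <- integer(0); out_qual <- integer(0)
  for (g in seq_along(starts)) {
    s <- starts[g]; e <- ends[g]
    qmax <- qual[s]                      # sorted: first has max quality
    top <- s:e
    top <- top[qual[top] == qmax]
    if (length(unique(allele[top])) > 1L) next   # equal-quality conflict: drop
    out_idx <- c(out_idx, idx[s])
    out_allele <- c(out_allele, allele[s])
    out_qual <- c(out_qual, qmax)
  }
  list(idx = out_idx, allele = out_allele, qual = out_qual)
}

## Split sorted variant indices into maximal runs of consecutive integers.
## Returns list of integer index ranges into the call vectors.
consecutive_parts <- function(idx) {
  if (length(idx) == 0L) return(list())
  brk <- which(diff(idx) != 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(idx))
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

FRAGMENT_DIALECTS <- c("short_read", "barcoded", "barcode_specific",
                       "molecule_specific")

dialect_origin <- function(dialect) {
  switch(dialect,
         short_read = "read", barcoded = "read",
         barcode_specific = "barcode", molecule_specific = "molecule")
}

#' Write a fragment file
#'
#' Serializes fragments into the compact whitespace-separated fragment file
#' layout: number of parts, fragment id, an optional third column (barcode,
#' or `barcode_ordinal` for molecule fragments), then for each part of
#' consecutive variant indices its 1-based start index and the concatenated
#' allele digits, and finally one string of Phred+33 characters covering all
#' alleles in order.
#'
#' @param fragments List of `fragment` objects.
#' @param path Output file path.
#' @param dialect One of `"short_read"`, `"barcoded"`, `"barcode_specific"`,
#'   `"molecule_specific"`; governs the third column.
#' @return `path`, invisibly.
#' @export
write_fragment_file <- function(fragments, path, dialect = "barcoded") {
  dialect <- match.arg(dialect, FRAGMENT_DIALECTS)
  lines <- vapply(fragments, function(f) {
    parts <- consecutive_parts(f$idx)
    part_cols <- unlist(lapply(parts, function(p)
      c(f$idx[p[1L]], paste(f$allele[p], collapse = ""))))
    third <- switch(dialect,
      short_read = character(0),
      barcoded = if (is.na(f$barcode)) "-" else f$barcode,
      barcode_specific = f$barcode,
      molecule_specific = paste0(f$barcode, "_", f$ordinal))
    qstr <- intToUtf8(f$qual + 33L)
    paste(c(length(parts), f$id, third, part_cols, qstr), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fragment file
#'
#' Inverse of [write_fragment_file()]; `read(write(F)) == F` for every
#' dialect.
#'
#' @param path Input file path.
#' @param dialect Fragment-file dialect, see [write_fragment_file()].
#' @return List of `fragment` objects.
#' @export
read_fragment_file <- function(path, dialect = "barcoded") {
  dialect <- match.arg(dialect, FRAGMENT_DIALECTS)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(ln) {
    tok <- strsplit(lines[ln], "[ \t]+")[[1L]]
    n_parts <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(n_parts))
      stop(sprintf("fragment file %s line %d: bad part count '%s'",
                   path, ln, tok[1L]))
    id <- tok[2L]
    has_third <- dialect != "short_read"
    barcode <- NA_character_; ordinal <- NA_integer_
    at <- 3L
    if (has_third) {
      third <- tok[3L]; at <- 4L
      if (dialect == "molecule_specific") {
        m <- regmatches(third, regexec("^(.*)_([0-9]+)$", third))[[1L]]
        if (length(m) != 3L)
          stop(sprintf("fragment file %s line %d: bad molecule name '%s'",
                       path, ln, third))
        barcode <- m[2L]; ordinal <- as.integer(m[3L])
      } else if (third != "-") barcode <- third
    }
    if (length(tok) != at + 2L * n_parts)
      stop(sprintf(
        "fragment file %s line %d: %d columns inconsistent with %d parts",
        path, ln, length(tok), n_parts))
    idx <- integer(0); allele <- integer(0)
    for (p in seq_len(n_parts)) {
      st <- as.integer(tok[at]); al <- tok[at + 1L]; at <- at + 2L
      a <- as.integer(strsplit(al, "")[[1L]])
      idx <- c(idx, st + seq_along(a) - 1L)
      allele <- c(allele, a)
    }
    qstr <- tok[length(tok)]
    qual <- utf8ToInt(qstr) - 33L
    if (length(qual) != length(allele))
      stop(sprintf(
        "fragment file %s line %d: %d quality characters for %d alleles",
        path, ln, length(qual), length(allele)))
    fragment(id, idx, allele, qual, origin = dialect_origin(dialect),
             barcode = barcode, ordinal = ordinal)
  })
}
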
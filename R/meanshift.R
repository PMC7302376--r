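#' Mean-shift configuration for molecule deconvolution
#'
#' @param bandwidth Flat-kernel radius in bp.  The pipeline default is half
#'   the expected molecule length, reflecting that two molecules sharing a
#'   barcode are usually far apart on the genome because molecule coverage
#'   is very low.
#' @param convergence_tol Stop iterating a seed when its shift falls below
#'   this many bp; default `1e-3 * bandwidth`, matching the reference
#'   mean-shift implementation (and keeping the procedure scale
#'   equivariant).
#' @param max_iter Maximum mean-shift iterations per seed.
#' @param min_calls_per_molecule Clusters with fewer calls are discarded.
#' @return A list of class `"mean_shift_config"`.
#' @export
mean_shift_config <- function(bandwidth, convergence_tol = 1e-3 * bandwidth,
                              max_iter = 300L, min_calls_per_molecule = 2L) {
  stopifnot(bandwidth > 0, max_iter >= 1L)
  structure(list(bandwidth = bandwidth, convergence_tol = convergence_tol,
                 max_iter = max_iter,
                 min_calls_per_molecule = as.integer(min_calls_per_molecule)),
            class = "mean_shift_config")
}

#' One-dimensional mean-shift clustering with a flat kernel
#'
#' Every point seeds an iteration that repeatedly moves to the mean of all
#' points within `bandwidth`, until the shift is below `tol` or `max_iter`
#' is reached.  Converged modes are deduplicated by non-maximum suppression:
#' modes are ranked by the number of points within their window (ties broken
#' by the larger coordinate, as in the scikit-learn reference), and a mode
#' within `bandwidth` of an accepted one is removed.  Points are assigned to
#' the nearest surviving mode.
#'
#' @param x Numeric vector of positions.
#' @param bandwidth Kernel radius.
#' @param tol Convergence threshold on the per-iteration shift.
#' @param max_iter Iteration cap per seed.
#' @return List with `modes` (numeric) and `labels` (integer, 1-based,
#'   parallel to `x`).
#' @export
mean_shift_1d <- function(x, bandwidth, tol = 1e-3 * bandwidth,
                          max_iter = 300L) {
  stopifnot(length(x) >= 1L, bandwidth > 0)
  modes <- vapply(x, function(s) {
    for (it in seq_len(max_iter)) {
      inwin <- x[abs(x - s) <= bandwidth]
      m <- mean(inwin)
      if (abs(m - s) < tol) { s <- m; break }
      s <- m
    }
    s
  }, numeric(1))
  intensity <- vapply(modes, function(m) sum(abs(x - m) <= bandwidth),
                      integer(1))
  uni <- !duplicated(modes)
  cand <- data.frame(mode = modes[uni], intensity = intensity[uni])
  cand <- cand[order(-cand$intensity, -cand$mode), , drop = FALSE]
  kept <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    m <- cand$mode[i]
    if (!length(kept) || all(abs(kept - m) > bandwidth))
      kept <- c(kept, m)
  }
  labels <- vapply(x, function(p) which.min(abs(kept - p)), integer(1))
  list(modes = kept, labels = labels)
}

#' Split a barcode-specific fragment into molecule-specific fragments
#'
#' Clusters the genomic positions of the fragment's calls by flat-kernel
#' mean-shift.  Each cluster with at least `min_calls_per_molecule` calls
#' becomes one molecule fragment named `<barcode>_<ordinal>`; ordinals run
#' from 1 per barcode in order of ascending leftmost position.  Smaller
#' clusters are discarded, so the emitted calls are always a subset of the
#' input calls.
#'
#' @param frag A fragment with `origin = "barcode"`.
#' @param variants `"variant_sites"` table giving the genomic position of
#'   each variant index.
#' @param config A [mean_shift_config()].
#' @return List of fragments with `origin = "molecule"` (possibly empty).
#' @export
split_barcode_fragment <- function(frag, variants, config) {
  stopifnot(inherits(config, "mean_shift_config"))
  if (frag$origin != "barcode")
    stop("split_barcode_fragment expects a barcode-origin fragment")
  pos <- variants$pos[match(frag$idx, variants$index)]
  if (anyNA(pos)) stop("fragment call index missing from variant table")
  cl <- mean_shift_1d(pos, config$bandwidth, tol = config$convergence_tol,
                      max_iter = config$max_iter)
  out <- list()
  keep <- which(tabulate(cl$labels) >= config$min_calls_per_molecule)
  if (!length(keep)) return(out)
  left <- vapply(keep, function(k) min(pos[cl$labels == k]), numeric(1))
  keep <- keep[order(left)]
  for (ord in seq_along(keep)) {
    sel <- which(cl$labels == keep[ord])
    out[[ord]] <- fragment(paste0(frag$barcode, "_", ord),
                           frag$idx[sel], frag$allele[sel], frag$qual[sel],
                           origin = "molecule", barcode = frag$barcode,
                           ordinal = ord)
  }
  out
}

#' Split all barcode fragments into molecules
#'
#' Applies [split_barcode_fragment()] per barcode-origin fragment;
#' fragments without a barcode (or not of barcode origin) pass through
#' unchanged.  Output is sorted by first variant index.
#'
#' @inheritParams split_barcode_fragment
#' @param fragments List of fragments.
#' @return List of fragments.
#' @export
split_all <- function(fragments, variants, config) {
  out <- list()
  for (f in fragments) {
    if (f$origin == "barcode" && !is.na(f$barcode)) {
      out <- c(out, split_barcode_fragment(f, variants, config))
    } else {
      out <- c(out, list(f))
    }
  }
  first <- vapply(out, function(f) f$idx[1L], integer(1))
  out[order(first)]
}
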
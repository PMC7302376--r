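#' Ground-truth haplotype set
#'
#' @param haplotypes K x M integer matrix of allele codes (no gaps); every
#'   column must be heterozygous (at least two distinct alleles).
#' @param pos Genomic positions of the M variant sites.
#' @return Object of class `"ground_truth"`.
#' @export
ground_truth <- function(haplotypes, pos) {
  stopifnot(is.matrix(haplotypes), !anyNA(haplotypes),
            ncol(haplotypes) == length(pos))
  het <- apply(haplotypes, 2L, function(col) length(unique(col)) > 1L)
  if (!all(het)) stop("ground truth contains homozygous sites")
  structure(list(haplotypes = haplotypes, pos = as.integer(pos)),
            class = "ground_truth")
}

## all permutations of 1..n (n <= 8), in lexicographic order
permutations <- function(n) {
  if (n > 8L) stop("permutation enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

block_truth_alleles <- function(block, truth) {
  col <- block$idx
  if (any(col < 1L | col > ncol(truth$haplotypes)))
    stop("block variant indices outside the ground truth")
  truth$haplotypes[, col, drop = FALSE]
}

#' Reconstruction rate of a haplotype block
#'
#' `RR = 1 - min_p sum_k D_H(hat_h_k, h_{p_k}) / (K * L)`, minimized over
#' all K! row permutations `p`.  By default, positions where any
#' reconstructed haplotype has a gap are excluded from both `L` and the
#' Hamming distances; with `gaps_as_errors = TRUE` gaps count as
#' mismatches and all block positions are evaluated.
#'
#' @param block A `"haplotype_block"`.
#' @param truth A `"ground_truth"` covering the block's variant indices.
#' @param gaps_as_errors Count gap positions as errors instead of
#'   excluding them.
#' @return Scalar in [0, 1] (`NA` if no position is evaluable).
#' @export
reconstruction_rate <- function(block, truth, gaps_as_errors = FALSE) {
  K <- nrow(block$haplotypes)
  if (K != nrow(truth$haplotypes))
    stop("ploidy mismatch between block and ground truth")
  H <- block_truth_alleles(block, truth)
  E <- block$haplotypes
  if (!gaps_as_errors) {
    keep <- colSums(is.na(E)) == 0L
    E <- E[, keep, drop = FALSE]
    H <- H[, keep, drop = FALSE]
  }
  L <- ncol(E)
  if (L == 0L) return(NA_real_)
  perms <- permutations(K)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    d <- sum(E != H[p, , drop = FALSE], na.rm = TRUE) +
      if (gaps_as_errors) sum(is.na(E)) else 0L
    if (d < best) best <- d
  }
  1 - best / (K * L)
}

#' Vector error rate of a haplotype block
#'
#' Finds the minimum number of haplotype-assignment switches needed to
#' match the reconstructed block to the truth, by dynamic programming over
#' positions with one state per row permutation.  The objective is
#' lexicographic: residual allele mismatches first, switches second; a
#' transition between permutations costs the number of indices at which
#' they differ.  Gap positions contribute no mismatch cost.
#'
#' @inheritParams reconstruction_rate
#' @return List with `switches`, `rate` (switches / number of block
#'   positions) and `mismatches` (residual allele errors of the optimal
#'   path).
#' @export
vector_error_rate <- function(block, truth) {
  K <- nrow(block$haplotypes)
  if (K != nrow(truth$haplotypes))
    stop("ploidy mismatch between block and ground truth")
  H <- block_truth_alleles(block, truth)
  E <- block$haplotypes
  L <- ncol(E)
  perms <- permutations(K)
  P <- nrow(perms)
  big <- K * L + 1                      # one mismatch outweighs any switches
  # per-position, per-permutation mismatch cost
  mcost <- matrix(0, P, L)
  for (r in seq_len(P)) {
    p <- perms[r, ]
    mcost[r, ] <- colSums(E != H[p, , drop = FALSE], na.rm = TRUE)
  }
  # permutation transition cost = # differing indices
  tcost <- matrix(0L, P, P)
  for (a in seq_len(P)) for (b in seq_len(P))
    tcost[a, b] <- sum(perms[a, ] != perms[b, ])
  dp <- big * mcost[, 1L]
  sw <- rep(0L, P)
  if (L >= 2L) for (j in 2:L) {
    step <- sweep(tcost, 1L, dp, "+")   # from-state cost + transition
    from <- apply(step, 2L, which.min)
    dp <- step[cbind(from, seq_len(P))] + big * mcost[, j]
    sw <- sw[from] + tcost[cbind(from, seq_len(P))]
  }
  i <- which.min(dp)
  total <- dp[i]
  mism <- (total - sw[i]) / big
  list(switches = sw[i], rate = sw[i] / L, mismatches = mism)
}

#' Minimum error correction score of a block against fragments
#'
#' `MEC = sum_i min_k (number of sites where fragment i covers haplotype k
#' and the alleles differ)`.  Calls at variant indices outside the block
#' and gap positions of a haplotype never count.
#'
#' @param fragments List of fragments.
#' @param block A `"haplotype_block"`.
#' @return Non-negative integer.
#' @export
mec <- function(fragments, block) {
  K <- nrow(block$haplotypes)
  total <- 0L
  for (f in fragments) {
    cols <- match(f$idx, block$idx)
    sel <- !is.na(cols)
    if (!any(sel)) next
    a <- f$allele[sel]; cols <- cols[sel]
    # a haplotype is eligible as the nearest one only if it covers at
    # least one of the fragment's sites; otherwise an all-gap haplotype
    # would have distance zero by vacuity
    d <- vapply(seq_len(K), function(k) {
      h <- block$haplotypes[k, cols]
      if (all(is.na(h))) return(NA_real_)
      sum(h != a, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(d))) next
    total <- total + min(d, na.rm = TRUE)
  }
  as.integer(total)
}

#' Block-length statistics
#'
#' Mean block length in SNPs, and the N50 genomic span in bp: with blocks
#' sorted by decreasing span, the span of the block at which the
#' cumulative span first reaches half the total span.
#'
#' @param blocks List of `"haplotype_block"` objects.
#' @param truth_positions Genomic position of every variant index.
#' @return List with `mean_len_snps` and `n50_bp` (zeros for an empty
#'   list).
#' @export
block_stats <- function(blocks, truth_positions) {
  if (!length(blocks)) return(list(mean_len_snps = 0, n50_bp = 0))
  lens <- vapply(blocks, function(b) length(b$idx), numeric(1))
  spans <- vapply(blocks, function(b) {
    p <- truth_positions[b$idx]
    max(p) - min(p)
  }, numeric(1))
  spans <- sort(spans, decreasing = TRUE)
  cum <- cumsum(spans)
  n50 <- spans[which(cum >= sum(spans) / 2)[1L]]
  list(mean_len_snps = mean(lens), n50_bp = n50)
}

#' Evaluate a set of haplotype blocks against the ground truth
#'
#' @param blocks List of `"haplotype_block"` objects.
#' @param truth A `"ground_truth"`.
#' @return Object of class `"hap_evaluation"`: per-block reconstruction
#'   rates and vector error rates, their unweighted and length-weighted
#'   averages, the total MEC (sum of block MECs), block-length statistics
#'   and position counts.
#' @export
evaluate_blocks <- function(blocks, truth) {
  rr <- vapply(blocks, reconstruction_rate, numeric(1), truth = truth)
  ver <- lapply(blocks, vector_error_rate, truth = truth)
  vrate <- vapply(ver, `[[`, numeric(1), "rate")
  switches <- vapply(ver, `[[`, numeric(1), "switches")
  lens <- vapply(blocks, function(b) length(b$idx), numeric(1))
  mecs <- vapply(blocks, `[[`, numeric(1), "mec")
  gaps <- vapply(blocks, function(b) sum(is.na(b$haplotypes)), numeric(1))
  ok <- !is.na(rr)
  structure(list(
    per_block = data.frame(length_snps = lens, rr = rr, ver = vrate,
                           switches = switches, mec = mecs),
    rr_mean = mean(rr[ok]),
    rr_weighted = if (any(ok)) sum(rr[ok] * lens[ok]) / sum(lens[ok])
                  else NA_real_,
    ver_mean = mean(vrate),
    ver_weighted = sum(vrate * lens) / sum(lens),
    total_mec = as.integer(sum(mecs)),
    stats = block_stats(blocks, truth$pos),
    n_blocks = length(blocks),
    n_positions = sum(lens),
    n_gap_positions = sum(gaps)),
    class = "hap_evaluation")
}

#' @export
print.hap_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation: %d blocks, %d sites | RR %.4f, VER %.4f, ",
           "MEC %d | mean len %.1f SNPs, N50 %g bp>\n"),
    x$n_blocks, x$n_positions, x$rr_mean, x$ver_mean, x$total_mec,
    x$stats$mean_len_snps, x$stats$n50_bp))
  invisible(x)
}
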
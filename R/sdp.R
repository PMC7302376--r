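#' Conflict weight matrix between fragments
#'
#' For every pair of fragments sharing at least one SNP, the weight is
#' `(#mismatched - #matched alleles) / #shared SNPs`, so agreement gives -1,
#' full conflict +1.  Pairs sharing no SNP are structural zeros
#' (contributing nothing to the clustering objective), and the diagonal is
#' -1 (a fragment agrees with itself).
#'
#' @param fragments List of at least two fragments.
#' @return List of class `"conflict_weights"` with `ids`, the symmetric
#'   matrix `W`, and `shared` (pairwise shared-SNP counts).
#' @export
build_conflict_weights <- function(fragments) {
  ids <- vapply(fragments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate fragment ids")
  n <- length(fragments)
  if (n < 2L) stop("need at least two fragments")
  all_idx <- sort(unique(unlist(lapply(fragments, `[[`, "idx"))))
  m <- length(all_idx)
  cover <- matrix(0L, n, m)
  matched <- matrix(0, n, n)
  per_allele <- lapply(0:3, function(a) matrix(0L, n, m))
  for (i in seq_len(n)) {
    f <- fragments[[i]]
    col <- match(f$idx, all_idx)
    cover[i, col] <- 1L
    for (a in 0:3) {
      sel <- f$allele == a
      if (any(sel)) per_allele[[a + 1L]][i, col[sel]] <- 1L
    }
  }
  shared <- tcrossprod(cover)
  for (a in 0:3) matched <- matched + tcrossprod(per_allele[[a + 1L]])
  mismatched <- shared - matched
  W <- matrix(0, n, n)
  nz <- shared > 0
  W[nz] <- (mismatched[nz] - matched[nz]) / shared[nz]
  diag(W) <- -1
  structure(list(ids = ids, W = W, shared = shared),
            class = "conflict_weights")
}

psd_project <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  Z <- e$vectors %*% (d * t(e$vectors))
  (Z + t(Z)) / 2
}

min_eigenvalue <- function(M) {
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

## repair X onto the primal feasible set {X psd, X_ii = 1, X_ij >= lb}
## exactly, with a single eigendecomposition: project onto the PSD cone,
## normalize the diagonal to 1 by congruence (which preserves PSD), then
## mix toward the identity just far enough to restore the elementwise
## lower bound -- (1-a) X + a I is PSD with unit diagonal for any a in
## [0, 1], and a = v / (v - lb) absorbs a residual violation of v.
project_primal_feasible <- function(X, lb, ...) {
  Xp <- psd_project(X)
  s <- 1 / sqrt(pmax(diag(Xp), 1e-8))
  Xp <- Xp * (s %o% s)
  diag(Xp) <- 1
  v <- max(0, lb - min(Xp))
  if (v > 0) {
    a <- v / (v - lb)
    Xp <- (1 - a) * Xp + a * diag(nrow(Xp))
  }
  Xp
}

#' Solve the max-K-cut semidefinite relaxation
#'
#' Minimizes `Tr(W X)` over `X` with `X_ij >= -1/(K-1)`, `X_ii = 1` and `X`
#' positive semidefinite.  (The diagonal normalization is required to keep
#' the problem bounded, since `diag(W) = -1`.)  The solver maximizes the
#' dual augmented Lagrangian: with the multiplier matrix `Y` fixed, the
#' inner maximization over the inequality multipliers, the diagonal
#' multipliers and the dual slack `Z >= 0` decouples -- the multiplier
#' update is elementwise closed-form and the `Z` update is a projection
#' onto the positive semidefinite cone -- after which `Y` takes a
#' multiplier step of size `sigma = mu` along the residual.  `-Y` converges
#' to the primal `X`.  Iterations stop when the relative duality gap
#' `|obj_p - obj_d| / (1 + |obj_p| + |obj_d|)` between the repaired
#' (feasible) primal point and a feasible dual point drops below `gap_tol`,
#' so the reported gap is a true certificate.
#'
#' @param W Symmetric conflict weight matrix (or a `"conflict_weights"`
#'   object).
#' @param K Ploidy (number of clusters), `K >= 2`.
#' @param gap_tol Relative duality gap at which to stop (default 0.01).
#' @param max_iter Outer iteration cap.
#' @param mu Initial augmented-Lagrangian penalty parameter.
#' @return Object of class `"kcut_sdp"`: `X` (primal, feasible), `lambda`
#'   (inequality multipliers, off-diagonal), `nu` (diagonal multipliers),
#'   `Z`, `Y`, `mu`, `obj_p`, `obj_d`, `gap`, `iterations`, `converged`,
#'   plus feasibility diagnostics `psd_violation` and `bound_violation`.
#' @export
solve_max_kcut_sdp <- function(W, K, gap_tol = 0.01, max_iter = 20000L,
                               mu = 1) {
  if (inherits(W, "conflict_weights")) W <- W$W
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(is.finite(W)), K >= 2)
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  N <- nrow(W)
  lb <- -1 / (K - 1)
  if (N == 1L) {
    return(structure(list(X = matrix(1, 1, 1), lambda = matrix(0, 1, 1),
                          nu = W[1, 1], Z = matrix(0, 1, 1),
                          Y = matrix(-1, 1, 1), mu = mu, K = K,
                          obj_p = W[1, 1], obj_d = W[1, 1], gap = 0,
                          iterations = 0L, converged = TRUE,
                          psd_violation = 0, bound_violation = 0),
                     class = "kcut_sdp"))
  }
  Y <- -diag(N)                       # Y tracks -X; X = I is feasible
  Z <- matrix(0, N, N)
  lam <- matrix(0, N, N)
  off <- !diag(N)
  prev_res <- Inf; stall <- 0L
  obj_p <- obj_d <- NA_real_; gap <- Inf
  X <- diag(N)
  last_check <- list(X = X, obj_p = sum(W * X), obj_d = -Inf, gap = Inf)
  for (it in seq_len(max_iter)) {
    for (sweep in 1:2) {
      C <- W - Z
      lam <- pmax(C + (Y + lb) / mu, 0)     # inequality multipliers
      nu <- diag(C) + (1 + diag(Y)) / mu    # diagonal (equality) multipliers
      diag(lam) <- nu
      Z <- psd_project((W - lam) + Y / mu)
    }
    H <- (W - lam) - Z
    Y <- Y + mu * H
    if (it %% 10 == 0 || it == max_iter) {
      # feasible dual point: shift nu so that Z_feas = W - lam is psd
      S <- W - lam
      delta <- max(0, -min_eigenvalue(S))
      obj_d <- lb * sum(lam[off]) + sum(diag(lam)) - N * delta
      # eigen-free monitoring estimate (clip-only repair); the strict
      # repair runs only when the gap looks converged, and the returned
      # certificate is recomputed from the strictly repaired point
      Xq <- pmax(-(Y + t(Y)) / 2, lb)
      diag(Xq) <- 1
      gq <- sum(W * Xq)
      gap <- abs(gq - obj_d) / (1 + abs(gq) + abs(obj_d))
      if (gap <= gap_tol) {
        X <- project_primal_feasible(Xq, lb)
        obj_p <- sum(W * X)
        gap <- abs(obj_p - obj_d) / (1 + abs(obj_p) + abs(obj_d))
        if (gap <= gap_tol) {
          return(structure(list(
            X = X, lambda = lam * off, nu = diag(lam),
            Z = S + delta * diag(N),
            Y = Y, mu = mu, K = K, obj_p = obj_p, obj_d = obj_d, gap = gap,
            iterations = it, converged = TRUE,
            psd_violation = max(0, -min_eigenvalue(X)),
            bound_violation = max(0, max(lb - X[off]))),
            class = "kcut_sdp"))
        }
      }
      res <- sqrt(sum(H^2))
      if (res > 0.95 * prev_res) {          # residual stalls: raise penalty
        stall <- stall + 1L
        if (stall >= 3L) { mu <- mu * 1.5; stall <- 0L }
      }
      prev_res <- res
    }
  }
  stop(sprintf(
    "max-K-cut SDP did not converge in %d iterations (last gap %.3g)",
    max_iter, gap))
}

#' @export
print.kcut_sdp <- function(x, ...) {
  cat(sprintf(
    "<max-%d-cut SDP: N = %d, primal %.6g, dual %.6g, gap %.3g (%d iters)>\n",
    x$K, nrow(x$X), x$obj_p, x$obj_d, x$gap, x$iterations))
  invisible(x)
}

## clustering objective: sum of W over ordered same-cluster pairs
## (including the diagonal); the quantity the SDP relaxes.
kcut_objective <- function(W, labels) {
  sum(W[outer(labels, labels, "==")])
}

#' Exhaustive max-K-cut oracle
#'
#' Enumerates all labelings (first fragment pinned to cluster 1 by
#' symmetry) and returns the minimizer of the clustering objective
#' `sum over same-cluster ordered pairs (i, j) of W_ij`.  Labels are
#' canonicalized so clusters appear in order of first occurrence.
#'
#' @param W Symmetric weight matrix, `N <= 12`.
#' @param K Number of clusters.
#' @return List with `labels` and `objective`.
#' @export
brute_force_max_kcut <- function(W, K) {
  if (inherits(W, "conflict_weights")) W <- W$W
  N <- nrow(W)
  if (N > 12L) stop("brute force limited to N <= 12")
  best_obj <- Inf; best_lab <- NULL
  lab <- integer(N)
  # incremental objective: adding i to cluster c adds W_ii + 2*sum_{j<i in c}
  recurse <- function(i, obj) {
    if (i > N) {
      if (obj < best_obj - 1e-12) { best_obj <<- obj; best_lab <<- lab }
      return()
    }
    kmax <- if (i == 1L) 1L else min(K, max(lab[seq_len(i - 1L)]) + 1L)
    for (c in seq_len(kmax)) {
      lab[i] <<- c
      prev <- which(lab[seq_len(i - 1L)] == c)
      recurse(i + 1L, obj + W[i, i] + 2 * sum(W[i, prev]))
    }
    lab[i] <<- 0L
  }
  recurse(1L, 0)
  list(labels = best_lab, objective = best_obj)
}

#' Randomized rounding of the SDP solution into K clusters
#'
#' Per restart, K standard-normal N-vectors are drawn and fragment i is
#' assigned to the cluster whose random vector has the largest inner
#' product with column i of the solved `X`.  Among restarts, when
#' `fragments` are supplied the assignment whose majority-vote consensus
#' has the smallest MEC wins (ties: earliest restart); otherwise the
#' smallest realized clustering objective wins.
#'
#' @param state A converged `"kcut_sdp"` (or any list with `X` and `K`).
#' @param restarts Number of random restarts (>= 1).
#' @param rng_seed Integer seed; makes the rounding deterministic.
#' @param fragments Optional fragment list for MEC-based selection.
#' @param W Weight matrix for the realized objective (defaults to the one
#'   implied by `fragments`, or is not needed when selecting by MEC only).
#' @return Object of class `"kcut_assignment"`: `labels`, `objective`,
#'   `mec` (NA without fragments), `restart`, `seed`.
#' @export
round_assignment <- function(state, restarts = 100L, rng_seed = 1L,
                             fragments = NULL, W = NULL) {
  X <- state$X; K <- state$K
  N <- nrow(X)
  stopifnot(restarts >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(rng_seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    V <- matrix(stats::rnorm(N * K), N, K)
    scores <- crossprod(X, V)           # column i of X vs each v_k
    labels <- max.col(scores, ties.method = "first")
    crit <- if (is.null(fragments)) {
      if (is.null(W)) stop("need W or fragments to score assignments")
      kcut_objective(W, labels)
    } else {
      consensus_haplotypes(fragments, labels, K, quiet = TRUE)$mec
    }
    if (is.null(best) || crit < best$crit) {
      best <- list(labels = labels, crit = crit, restart = r)
    }
  }
  labels <- best$labels
  obj <- if (!is.null(W)) kcut_objective(W, labels) else NA_real_
  mec <- if (!is.null(fragments)) best$crit else NA_real_
  if (length(unique(labels)) == 1L && K > 1L)
    warning("all fragments rounded into a single cluster")
  structure(list(labels = labels, objective = obj, mec = mec,
                 restart = best$restart, seed = rng_seed),
            class = "kcut_assignment")
}

#' Majority-vote consensus haplotypes from a fragment clustering
#'
#' For each cluster k and covered variant index, the haplotype allele is
#' the modal allele among the cluster's calls at that site (ties: lowest
#' allele code; no covering call: gap, stored as `NA`).  Per-site support
#' counts (number of matching fragment calls) and the block MEC are
#' populated.
#'
#' @param fragments List of fragments.
#' @param labels Integer cluster label per fragment (1..K), or a
#'   `"kcut_assignment"`.
#' @param K Ploidy.
#' @param quiet Suppress the empty-cluster warning.
#' @return Object of class `"haplotype_block"`: `idx` (sorted variant
#'   indices), `haplotypes` (K x L integer matrix, `NA` = gap), `support`
#'   (K x L), `mec`, `n_fragments`.
#' @export
consensus_haplotypes <- function(fragments, labels, K, quiet = FALSE) {
  if (inherits(labels, "kcut_assignment")) labels <- labels$labels
  stopifnot(length(labels) == length(fragments), all(labels %in% 1:K))
  idx <- sort(unique(unlist(lapply(fragments, `[[`, "idx"))))
  L <- length(idx)
  hap <- matrix(NA_integer_, K, L)
  support <- matrix(0L, K, L)
  f_idx <- lapply(fragments, function(f) match(f$idx, idx))
  for (k in seq_len(K)) {
    members <- which(labels == k)
    if (!length(members)) {
      if (!quiet) warning(sprintf("cluster %d is empty; haplotype %d is all gaps", k, k))
      next
    }
    counts <- matrix(0L, 4L, L)         # rows: allele codes 0..3
    for (i in members) {
      f <- fragments[[i]]
      cols <- f_idx[[i]]
      counts[cbind(f$allele + 1L, cols)] <-
        counts[cbind(f$allele + 1L, cols)] + 1L
    }
    covered <- colSums(counts) > 0L
    if (any(covered)) {
      mode_row <- apply(counts[, covered, drop = FALSE], 2L, which.max)
      hap[k, covered] <- mode_row - 1L  # which.max takes first (lowest code)
      support[k, covered] <- counts[cbind(mode_row, which(covered))]
    }
  }
  blk <- structure(list(idx = idx, haplotypes = hap, support = support,
                        mec = NA_real_, n_fragments = length(fragments)),
                   class = "haplotype_block")
  blk$mec <- mec(fragments, blk)
  blk
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf(
    "<haplotype block: %d sites (%d..%d), ploidy %d, %d fragments, MEC %g>\n",
    length(x$idx), min(x$idx), max(x$idx), nrow(x$haplotypes),
    x$n_fragments, x$mec))
  invisible(x)
}

#' Local-search refinement of a fragment clustering by MEC
#'
#' Alternates majority-vote consensus with nearest-haplotype reassignment:
#' each fragment moves to the haplotype with the fewest mismatches over
#' its covered (non-gap) sites, ties keeping the current label.  Both
#' half-steps are weakly MEC-decreasing (the k-means argument), so the
#' procedure converges; it repairs the occasional misassignment that
#' survives randomized rounding.  Deterministic.
#'
#' @param fragments List of fragments.
#' @param labels Integer cluster labels (or a `"kcut_assignment"`).
#' @param K Ploidy.
#' @param max_iter Sweep cap.
#' @return Integer label vector.
#' @export
refine_assignment <- function(fragments, labels, K, max_iter = 50L) {
  if (inherits(labels, "kcut_assignment")) labels <- labels$labels
  for (it in seq_len(max_iter)) {
    blk <- consensus_haplotypes(fragments, labels, K, quiet = TRUE)
    new <- labels
    cur_d <- numeric(length(fragments))
    for (i in seq_along(fragments)) {
      f <- fragments[[i]]
      cols <- match(f$idx, blk$idx)
      d <- vapply(seq_len(K), function(k) {
        h <- blk$haplotypes[k, cols]
        if (all(is.na(h))) return(Inf)
        sum(h != f$allele, na.rm = TRUE)
      }, numeric(1))
      best <- which(d == min(d))
      if (!(labels[i] %in% best)) new[i] <- best[1L]
      cur_d[i] <- d[new[i]]
    }
    if (identical(new, labels)) {
      # converged; if a cluster collapsed while mismatches remain, seed it
      # with the worst-fitting fragment and keep sweeping (an empty
      # cluster can never be repopulated by nearest-haplotype moves)
      empty <- setdiff(seq_len(K), unique(new))
      worst <- which.max(cur_d)
      if (length(empty) && length(cur_d) && cur_d[worst] > 0 &&
          sum(new == new[worst]) > 1L) {
        new[worst] <- empty[1L]
      } else break
    }
    labels <- new
  }
  labels
}

#' Assemble one strongly connected component into a haplotype block
#'
#' Runs the full assembly core on one component: conflict weights,
#' max-K-cut SDP, randomized rounding (best-of-restarts by MEC), MEC
#' local-search refinement, and majority-vote consensus.
#'
#' @param fragments Fragments of one component (at least K).
#' @param K Ploidy.
#' @param gap_tol SDP duality-gap threshold.
#' @param restarts Rounding restarts.
#' @param rng_seed Rounding seed.
#' @param refine Apply [refine_assignment()] after rounding.
#' @return A `"haplotype_block"` with attributes `sdp_gap`, `seed`,
#'   `restart`, `objective`.
#' @export
assemble_component <- function(fragments, K, gap_tol = 0.01,
                               restarts = 100L, rng_seed = 1L,
                               refine = TRUE) {
  if (length(fragments) < K)
    stop(sprintf("underdetermined component: %d fragments for ploidy %d",
                 length(fragments), K))
  cw <- build_conflict_weights(fragments)
  state <- solve_max_kcut_sdp(cw$W, K, gap_tol = gap_tol)
  asg <- round_assignment(state, restarts = restarts, rng_seed = rng_seed,
                          fragments = fragments, W = cw$W)
  labels <- if (refine) refine_assignment(fragments, asg, K) else asg$labels
  blk <- consensus_haplotypes(fragments, labels, K)
  attr(blk, "sdp_gap") <- state$gap
  attr(blk, "seed") <- rng_seed
  attr(blk, "restart") <- asg$restart
  attr(blk, "objective") <- asg$objective
  blk
}
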
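# max-K-cut assembly core: conflict weights, SDP, rounding, consensus

random_conflict_W <- function(N) {
  W <- matrix(sample(c(-1, 0, 1), N * N, TRUE), N)
  W <- round((W + t(W)) / 2)
  diag(W) <- -1
  W
}

test_that("conflict weights follow (mismatched - matched) / shared", {
  # shared 2, matched 1, mismatched 1 -> 0
  f1 <- frag("a", 1:2, c(0L, 0L))
  f2 <- frag("b", 1:2, c(0L, 1L))
  expect_equal(build_conflict_weights(list(f1, f2))$W[1, 2], 0)
  # identical over 3 SNPs -> -1
  f3 <- frag("c", 1:3, c(0L, 1L, 1L))
  f4 <- frag("d", 1:3, c(0L, 1L, 1L))
  cw <- build_conflict_weights(list(f3, f4))
  expect_equal(cw$W[1, 2], -1)
  expect_equal(diag(cw$W), c(-1, -1))
  # fully conflicting over 2 SNPs -> +1
  f5 <- frag("e", 1:2, c(0L, 0L))
  f6 <- frag("f", 1:2, c(1L, 1L))
  expect_equal(build_conflict_weights(list(f5, f6))$W[1, 2], 1)
  # no shared SNP -> structural zero
  f7 <- frag("g", 5:6, c(0L, 0L))
  expect_equal(build_conflict_weights(list(f1, f7))$W[1, 2], 0)
})

test_that("the SDP reproduces closed-form optima", {
  # N = 2, K = 2: X = [[1,-1],[-1,1]], objective -4
  W <- matrix(c(-1, 1, 1, -1), 2)
  s <- solve_max_kcut_sdp(W, 2, gap_tol = 1e-5)
  expect_lt(abs(s$obj_p - (-4)), 1e-3)
  expect_equal(s$X, matrix(c(1, -1, -1, 1), 2), tolerance = 1e-3)
  # N = 3, K = 3 symmetric: X_offdiag = -1/2, objective -6
  W <- matrix(1, 3, 3); diag(W) <- -1
  s <- solve_max_kcut_sdp(W, 3, gap_tol = 1e-5)
  expect_lt(abs(s$obj_p - (-6)), 1e-3)
  expect_equal(s$X[1, 2], -1/2, tolerance = 1e-3)
  # W = 0: any feasible X optimal, gap 0
  s <- solve_max_kcut_sdp(matrix(0, 3, 3), 2)
  expect_equal(s$obj_p, 0)
  expect_equal(s$gap, 0)
  # N = 1 trivial
  s <- solve_max_kcut_sdp(matrix(-1, 1, 1), 3)
  expect_equal(s$X, matrix(1, 1, 1))
})

test_that("solver termination invariants hold on random instances", {
  set.seed(8)
  for (rep in 1:8) {
    N <- sample(5:15, 1); K <- sample(2:4, 1)
    W <- matrix(runif(N * N, -1, 1), N); W <- (W + t(W)) / 2; diag(W) <- -1
    s <- solve_max_kcut_sdp(W, K)
    expect_true(s$converged)
    expect_lte(s$gap, 0.01)
    expect_lt(max(abs(diag(s$X) - 1)), 1e-6)
    expect_gte(min(s$X), -1 / (K - 1) - 1e-6)
    e <- eigen(s$X, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(e), -1e-6)
    expect_true(all(s$lambda >= 0))
    ez <- eigen(s$Z, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ez), -1e-6)
  }
})

test_that("brute-force oracle enumerates the clustering optimum", {
  # split labels, objective -2 (diagonal only)
  W <- matrix(c(-1, 1, 1, -1), 2)
  bf <- brute_force_max_kcut(W, 2)
  expect_identical(bf$labels, c(1L, 2L))
  expect_equal(bf$objective, -2)
  # all-agreement: one cluster
  W <- matrix(-1, 4, 4)
  bf <- brute_force_max_kcut(W, 3)
  expect_identical(bf$labels, rep(1L, 4))
  expect_equal(bf$objective, -16)
  # pairwise conflicts, K = 3: all singletons
  W <- matrix(1, 3, 3); diag(W) <- -1
  bf <- brute_force_max_kcut(W, 3)
  expect_identical(bf$labels, 1:3)
  expect_equal(bf$objective, -3)
  expect_error(brute_force_max_kcut(matrix(0, 13, 13), 2), "N <= 12")
})

test_that("the SDP objective lower-bounds the brute-force optimum", {
  set.seed(19)
  for (rep in 1:12) {
    N <- sample(4:10, 1); K <- sample(2:3, 1)
    W <- random_conflict_W(N)
    bf <- brute_force_max_kcut(W, K)
    s <- solve_max_kcut_sdp(W, K)
    expect_lte(s$obj_d, bf$objective + 1e-9)
  }
})

test_that("rounding respects block structure and improves with restarts", {
  # exact block-structured X: same-cluster fragments get identical labels
  K <- 3; sizes <- c(3, 2, 2); N <- sum(sizes)
  lab0 <- rep(seq_len(K), sizes)
  X <- outer(lab0, lab0, function(a, b) ifelse(a == b, 1, -1 / (K - 1)))
  st <- list(X = X, K = K)
  W <- -X  # any scoring matrix
  for (seed in 1:5) {
    a <- round_assignment(st, restarts = 3, rng_seed = seed, W = W)
    expect_identical(a$labels[1:3], rep(a$labels[1L], 3L))
    expect_identical(a$labels[4:5], rep(a$labels[4L], 2L))
    expect_identical(a$labels[6:7], rep(a$labels[6L], 2L))
  }
  # determinism given the seed
  a1 <- round_assignment(st, restarts = 10, rng_seed = 4, W = W)
  a2 <- round_assignment(st, restarts = 10, rng_seed = 4, W = W)
  expect_identical(a1$labels, a2$labels)
  # more restarts never increase the selection criterion
  set.seed(33)
  pc <- planted_component(K = 3, L = 8, frags_per_hap = 2, seed = 33)
  noisy <- lapply(pc$fragments, function(f) {
    flip <- runif(length(f$allele)) < 0.2
    f$allele[flip] <- 1L - f$allele[flip]
    f
  })
  cw <- build_conflict_weights(noisy)
  st <- solve_max_kcut_sdp(cw$W, 3)
  m1 <- round_assignment(st, restarts = 1, rng_seed = 9,
                         fragments = noisy, W = cw$W)$mec
  m50 <- round_assignment(st, restarts = 50, rng_seed = 9,
                          fragments = noisy, W = cw$W)$mec
  expect_lte(m50, m1)
})

test_that("rounding of the identity matrix is exchangeable across fragments", {
  st <- list(X = diag(4), K = 2)
  W <- matrix(0, 4, 4)
  counts <- matrix(0, 4, 2)
  for (seed in 1:400) {
    a <- suppressWarnings(
      round_assignment(st, restarts = 1, rng_seed = seed, W = W))
    counts[cbind(1:4, a$labels)] <- counts[cbind(1:4, a$labels)] + 1
  }
  # each fragment lands in cluster 1 about half the time
  expect_true(all(abs(counts[, 1] / 400 - 0.5) < 0.12))
})

test_that("majority-vote consensus applies modal, tie and gap rules", {
  fr <- list(frag("a", 1:2, c(0L, 0L)), frag("b", 1:2, c(0L, 1L)),
             frag("c", 1:2, c(1L, 0L)), frag("d", 3:4, c(1L, 1L)))
  labels <- c(1L, 1L, 1L, 2L)
  blk <- suppressWarnings(consensus_haplotypes(fr, labels, 3))
  # site 1 cluster 1: {0,0,1} -> 0 with support 2
  expect_identical(blk$haplotypes[1, 1], 0L)
  expect_identical(blk$support[1, 1], 2L)
  # site 2 cluster 1: {0,1,0} -> 0; tie case below
  blk2 <- consensus_haplotypes(list(frag("a", 1:2, c(0L, 1L)),
                                    frag("b", 1:2, c(1L, 1L))),
                               c(1L, 1L), 1)
  expect_identical(blk2$haplotypes[1, 1], 0L)    # {0,1} tie -> lowest code
  # cluster 2 never covers sites 1:2 -> gaps
  expect_true(all(is.na(blk$haplotypes[2, 1:2])))
  # empty cluster warns and yields all gaps
  expect_warning(b3 <- consensus_haplotypes(fr, labels, 3), "empty")
  expect_true(all(is.na(b3$haplotypes[3, ])))
})

test_that("label permutation permutes haplotypes and preserves MEC", {
  pc <- planted_component(K = 3, L = 10, frags_per_hap = 3, seed = 4)
  labels <- rep(1:3, each = 3)
  b1 <- consensus_haplotypes(pc$fragments, labels, 3)
  perm <- c(3L, 1L, 2L)
  b2 <- consensus_haplotypes(pc$fragments, perm[labels], 3)
  expect_identical(b1$mec, b2$mec)
  expect_identical(b1$haplotypes[1, ], b2$haplotypes[3, ])
  expect_identical(b1$mec, 0L)                  # noiseless: consistent
})

test_that("assemble_component recovers planted haplotypes exactly", {
  pc <- planted_component(K = 3, L = 12, frags_per_hap = 2, seed = 6)
  blk <- assemble_component(pc$fragments, K = 3, restarts = 50,
                            rng_seed = 2)
  expect_identical(blk$mec, 0L)
  # equals the generating haplotypes up to row permutation
  expect_equal(reconstruction_rate(blk, pc$truth), 1)
  # brute-force oracle agrees the planted partition is optimal
  cw <- build_conflict_weights(pc$fragments)
  bf <- brute_force_max_kcut(cw$W, 3)
  expect_equal(kcut_objective_for_test(cw$W, rep(1:3, each = 2)),
               bf$objective)
  # underdetermined component
  expect_error(assemble_component(pc$fragments[1:2], K = 3),
               "underdetermined")
})

test_that("an all-agreement component collapses to one haplotype", {
  fr <- lapply(1:4, function(i) frag(paste0("f", i), 1:5,
                                     c(0L, 1L, 0L, 1L, 1L)))
  w <- capture_warnings(
    blk <- assemble_component(fr, K = 2, restarts = 5, rng_seed = 1))
  expect_true(any(grepl("single cluster|empty", w)))
  filled <- rowSums(!is.na(blk$haplotypes))
  expect_setequal(filled, c(5L, 0L))
})
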
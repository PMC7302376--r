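# shared builders for in-code fixtures

frag <- function(id, idx, allele, qual = 30L, origin = "read",
                 barcode = NA_character_, ordinal = NA_integer_) {
  if (length(qual) == 1L) qual <- rep(qual, length(idx))
  fragment(id, idx, allele, qual, origin = origin, barcode = barcode,
           ordinal = ordinal)
}

## random fragment over M sites with n calls (no duplicate indices)
random_fragment <- function(id, M = 30L, n = sample(2:8, 1L),
                           origin = "read", barcode = NA_character_,
                           ordinal = NA_integer_) {
  idx <- sort(sample(M, min(n, M)))
  frag(id, idx, sample(0:3, length(idx), replace = TRUE),
       sample(5:40, length(idx), replace = TRUE), origin = origin,
       barcode = barcode, ordinal = ordinal)
}

## fragments covering a common index window: a dense community in the
## shared-SNP graph
community_fragments <- function(n, lo, hi, prefix, len = 10L) {
  lapply(seq_len(n), function(i) {
    s <- sample(lo:(hi - len + 1L), 1L)
    frag(paste0(prefix, i), s:(s + len - 1L),
         sample(0:1, len, replace = TRUE))
  })
}

## K planted haplotypes over L sites plus per-haplotype noiseless fragments
planted_component <- function(K, L, frags_per_hap, seed = 1L) {
  set.seed(seed)
  repeat {
    hap <- matrix(0L, K, L)
    for (j in seq_len(L)) hap[sample(K, sample(K - 1L, 1L)), j] <- 1L
    if (nrow(unique(hap)) == K) break          # all haplotypes distinct
  }
  fragments <- list()
  for (k in seq_len(K)) for (r in seq_len(frags_per_hap))
    fragments[[length(fragments) + 1L]] <-
      frag(sprintf("h%d_f%d", k, r), seq_len(L), hap[k, ])
  list(haplotypes = hap, fragments = fragments,
       truth = ground_truth(hap, seq_len(L) * 100L))
}

## minimal single-sample VCF text for given positions/genotypes
write_test_vcf <- function(path, pos, ref, alt, gt, G = 100000L) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=sim1,length=%d>", G),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE"), collapse = "\t"),
    sprintf("sim1\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", pos, ref, alt, gt)),
    path)
  path
}

## minimal SAM with one alignment row per element of `reads`
## each read: list(qname, pos, seq, qual (single char ok), bx, flag, cigar)
write_test_sam <- function(path, reads, G = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:sim1\tLN:%d", G))
  rows <- vapply(reads, function(r) {
    flag <- if (is.null(r$flag)) 0L else r$flag
    cigar <- if (is.null(r$cigar)) paste0(nchar(r$seq), "M") else r$cigar
    qual <- if (is.null(r$qual)) strrep("I", nchar(r$seq)) else r$qual
    bx <- if (is.null(r$bx)) NULL else paste0("BX:Z:", r$bx)
    paste(c(r$qname, flag, "sim1", r$pos, 60L, cigar, "*", 0L, 0L,
            r$seq, qual, bx), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

## exhaustive vector-error oracle over all permutation sequences,
## vectorized over the P^L sequence space; minimizes (mismatches,
## switches) lexicographically.  Independent of the package's DP.
ver_oracle_enum <- function(E, H) {
  K <- nrow(E); L <- ncol(E)
  perms <- matrix(1L, 1, 1)
  if (K > 1L) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), ,
                   drop = FALSE]
  }
  P <- nrow(perms)
  mcost <- matrix(0L, P, L)
  for (r in seq_len(P))
    mcost[r, ] <- colSums(E != H[perms[r, ], , drop = FALSE], na.rm = TRUE)
  tcost <- matrix(0L, P, P)
  for (a in seq_len(P)) for (b in seq_len(P))
    tcost[a, b] <- sum(perms[a, ] != perms[b, ])
  S <- as.matrix(expand.grid(rep(list(seq_len(P)), L)))
  mism <- rep(0L, nrow(S)); sw <- rep(0L, nrow(S))
  for (j in seq_len(L)) {
    mism <- mism + mcost[cbind(S[, j], j)]
    if (j > 1L) sw <- sw + tcost[cbind(S[, j - 1L], S[, j])]
  }
  i <- order(mism, sw)[1L]
  list(mismatches = mism[i], switches = sw[i])
}

## clustering objective recomputed independently of the package internals
kcut_objective_for_test <- function(W, labels) {
  sum(W[outer(labels, labels, "==")])
}

## independent BFS component labelling (test-side oracle)
connected_components_for_test <- function(W) {
  n <- nrow(W); lab <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L; q <- s; lab[s] <- cur
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      nb <- which(W[v, ] > 0 & lab == 0L)
      lab[nb] <- cur; q <- c(q, nb)
    }
  }
  lab
}

expect_same_fragment <- function(a, b) {
  expect_identical(a$idx, b$idx)
  expect_identical(a$allele, b$allele)
  expect_identical(a$qual, b$qual)
}
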
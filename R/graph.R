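#' Build the shared-SNP fragment graph
#'
#' Vertices are fragments; the weight of edge (i, j) is the number of
#' variant indices covered by both fragments (allele values are irrelevant
#' at this stage).  The diagonal is zero.
#'
#' @param fragments List of fragments with unique ids.
#' @return List of class `"fragment_graph"` with elements `ids` and the
#'   symmetric integer weight matrix `W`.
#' @export
build_share_graph <- function(fragments) {
  ids <- vapply(fragments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate fragment ids")
  n <- length(fragments)
  all_idx <- sort(unique(unlist(lapply(fragments, `[[`, "idx"))))
  B <- matrix(0L, n, length(all_idx))
  for (i in seq_len(n))
    B[i, match(fragments[[i]]$idx, all_idx)] <- 1L
  W <- tcrossprod(B)
  storage.mode(W) <- "integer"
  diag(W) <- 0L
  structure(list(ids = ids, W = W), class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  ne <- sum(x$W > 0) / 2
  cat(sprintf("<fragment graph: %d vertices, %d edges, total weight %g>\n",
              length(x$ids), ne, sum(x$W)/2))
  invisible(x)
}

subgraph <- function(graph, members) {
  sel <- match(members, graph$ids)
  structure(list(ids = graph$ids[sel],
                 W = graph$W[sel, sel, drop = FALSE]),
            class = "fragment_graph")
}

#' Symmetric normalized Laplacian of a fragment graph
#'
#' `L = D^{-1/2} (D - W) D^{-1/2}` with `D` the diagonal degree (row-sum)
#' matrix.  All vertices must have positive degree; remove isolated
#' vertices first.
#'
#' @param graph A `"fragment_graph"`.
#' @return Symmetric matrix with eigenvalues in [0, 2].
#' @export
normalized_laplacian <- function(graph) {
  d <- rowSums(graph$W)
  if (any(d <= 0)) stop("graph has zero-degree vertices; remove them first")
  s <- 1 / sqrt(d)
  L <- -(s %o% s) * graph$W
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Bipartition a connected graph by the sign of the Fiedler vector
#'
#' Computes the eigenvector of the second smallest eigenvalue of the
#' normalized Laplacian and splits vertices by its sign (zero entries join
#' the positive side; if that leaves a side empty, the entry of smallest
#' magnitude is moved across).
#'
#' @param graph A connected `"fragment_graph"` with at least two vertices.
#' @return List with `members_1` and `members_2` (vectors of fragment ids).
#' @export
spectral_bipartition <- function(graph) {
  n <- length(graph$ids)
  stopifnot(n >= 2L)
  L <- normalized_laplacian(graph)
  e <- eigen(L, symmetric = TRUE)
  fiedler <- e$vectors[, n - 1L]        # second smallest eigenvalue
  side1 <- fiedler < 0
  if (all(side1) || !any(side1)) {
    # numerically one-signed vector: move the smallest-magnitude entry
    j <- which.min(abs(fiedler))
    side1 <- rep(FALSE, n); side1[j] <- TRUE
  }
  list(members_1 = graph$ids[side1], members_2 = graph$ids[!side1])
}

#' Normalized cut value of a bipartition
#'
#' `NC = cut/assoc_1 + cut/assoc_2`, where `cut` is the total weight between
#' the two sides and `assoc_k` is the total weight incident to side k
#' (row sums of `W`).  `NC` lies in [0, 2]; a side with zero association is
#' reported as the maximally bad value 2.
#'
#' @param graph A `"fragment_graph"`.
#' @param members_1,members_2 Fragment-id vectors partitioning the vertex
#'   set.
#' @return Scalar NC value.
#' @export
ncut_value <- function(graph, members_1, members_2) {
  i1 <- match(members_1, graph$ids); i2 <- match(members_2, graph$ids)
  if (anyNA(i1) || anyNA(i2) || length(i1) + length(i2) != length(graph$ids)
      || anyDuplicated(c(i1, i2)))
    stop("members must partition the vertex set")
  cut <- sum(graph$W[i1, i2, drop = FALSE])
  a1 <- sum(graph$W[i1, , drop = FALSE])
  a2 <- sum(graph$W[i2, , drop = FALSE])
  if (a1 == 0 || a2 == 0) return(2)
  cut / a1 + cut / a2
}

## connected components by breadth-first search on the weight matrix
connected_component_labels <- function(W) {
  n <- nrow(W)
  lab <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(W[v, ] > 0 & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Recursively partition a fragment graph into strongly connected components
#'
#' Graph-theoretic connected components are extracted first (a disconnected
#' graph makes the Fiedler vector degenerate).  Each component is then
#' recursively bipartitioned by [spectral_bipartition()]; a split is
#' accepted while its normalized-cut value is at most `t`, so recursion
#' stops when the candidate split's NC exceeds `t` or a component has fewer
#' than `min_size` members.  NC is evaluated on the current subgraph's own
#' weights.
#'
#' @param graph A `"fragment_graph"`.
#' @param t NC acceptance threshold (default 0.03).
#' @param min_size Do not split components smaller than this (use `2 *
#'   ploidy` in the pipeline).
#' @return List of character vectors of fragment ids; isolated vertices are
#'   returned as singleton leaves.
#' @export
recursive_partition <- function(graph, t = 0.03, min_size = 4L) {
  leaves <- list()
  recurse <- function(g) {
    n <- length(g$ids)
    if (n == 1L) { leaves[[length(leaves) + 1L]] <<- g$ids; return() }
    lab <- connected_component_labels(g$W)
    if (max(lab) > 1L) {
      for (c in seq_len(max(lab))) recurse(subgraph(g, g$ids[lab == c]))
      return()
    }
    if (n < min_size) { leaves[[length(leaves) + 1L]] <<- g$ids; return() }
    sp <- spectral_bipartition(g)
    nc <- ncut_value(g, sp$members_1, sp$members_2)
    if (nc > t) { leaves[[length(leaves) + 1L]] <<- g$ids; return() }
    recurse(subgraph(g, sp$members_1))
    recurse(subgraph(g, sp$members_2))
  }
  recurse(graph)
  leaves
}
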
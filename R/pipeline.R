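#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end phasing pipeline.
#' The defaults are the published operating point: normalized-cut
#' threshold `t = 0.03` and SDP duality-gap tolerance 0.01.  `mode =
#' "fast"` lowers the rounding restarts to 10 and loosens the gap
#' tolerance to 0.05; the strongly connected components (and hence the
#' block site partition) are identical between modes, only the allele
#' assignments within blocks may differ.
#'
#' @param ploidy K >= 2.
#' @param nc_threshold Normalized-cut acceptance threshold.
#' @param molecule_length Expected molecule length in bp; the mean-shift
#'   bandwidth defaults to half of it.
#' @param bandwidth Mean-shift bandwidth in bp.
#' @param gap_tol SDP relative duality-gap tolerance.
#' @param restarts Rounding restarts per component.
#' @param seed Master seed; every per-component rounding seed derives from
#'   it.
#' @param mode `"accurate"` or `"fast"`.
#' @param min_component Minimum component size eligible for splitting
#'   (default `2 * ploidy`).
#' @param split_molecules Apply mean-shift molecule splitting.
#' @param max_component Components larger than this are sub-split by
#'   raising the NC threshold (dense SDP size cap).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(ploidy, nc_threshold = 0.03,
                            molecule_length = 50000,
                            bandwidth = molecule_length / 2,
                            gap_tol = 0.01, restarts = 100L, seed = 1L,
                            mode = c("accurate", "fast"),
                            min_component = 2L * ploidy,
                            split_molecules = TRUE,
                            max_component = 1500L) {
  mode <- match.arg(mode)
  if (mode == "fast") { restarts <- 10L; gap_tol <- 0.05 }
  structure(list(ploidy = as.integer(ploidy), nc_threshold = nc_threshold,
                 molecule_length = molecule_length, bandwidth = bandwidth,
                 gap_tol = gap_tol, restarts = as.integer(restarts),
                 seed = as.integer(seed), mode = mode,
                 min_component = as.integer(min_component),
                 split_molecules = isTRUE(split_molecules),
                 max_component = as.integer(max_component)),
            class = "pipeline_config")
}

## split any oversized leaf further by doubling the NC threshold
cap_component_size <- function(leaves, graph, config) {
  out <- list()
  for (mem in leaves) {
    if (length(mem) <= config$max_component) {
      out <- c(out, list(mem)); next
    }
    warning(sprintf(
      "component of %d fragments exceeds cap %d; splitting at a raised NC threshold",
      length(mem), config$max_component))
    sub <- recursive_partition(subgraph(graph, mem),
                               t = config$nc_threshold * 2,
                               min_size = config$min_component)
    out <- c(out, cap_component_size(sub, graph, config))
  }
  out
}

#' Run the full linked-read polyploid phasing pipeline
#'
#' Stages: optional molecule splitting of barcode fragments (mean-shift),
#' shared-SNP graph construction, recursive normalized-cut partitioning
#' into strongly connected components, per-component assembly (conflict
#' weights, max-K-cut SDP, randomized rounding, majority-vote consensus),
#' and, when a ground truth is supplied, evaluation.  Components are
#' processed independently; results do not depend on their order.
#' Components with fewer than K fragments cannot support K haplotypes and
#' are skipped (counted in the manifest).
#'
#' @param fragments List of fragments (barcode- or molecule-origin).
#' @param variants `"variant_sites"` table (positions are needed for
#'   molecule splitting and block statistics).
#' @param config A [pipeline_config()].
#' @param truth Optional `"ground_truth"` for evaluation.
#' @return Object of class `"linkhap_run"`: `blocks`, `components`
#'   (fragment-id sets), `evaluation` (or `NULL`), `manifest` (per-stage
#'   counters and per-component diagnostics), `config`.
#' @export
run_pipeline <- function(fragments, variants, config, truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, mode = config$mode,
                   n_input_fragments = length(fragments))
  if (config$split_molecules) {
    ms <- mean_shift_config(bandwidth = config$bandwidth)
    fragments <- split_all(fragments, variants, ms)
  }
  manifest$n_fragments <- length(fragments)
  if (!length(fragments)) stop("stage split: no fragments to phase")
  graph <- build_share_graph(fragments)
  leaves <- recursive_partition(graph, t = config$nc_threshold,
                                min_size = config$min_component)
  leaves <- cap_component_size(leaves, graph, config)
  manifest$n_components <- length(leaves)
  ids <- vapply(fragments, `[[`, character(1), "id")
  blocks <- list()
  comp_log <- list()
  skipped <- 0L
  for (ci in seq_along(leaves)) {
    mem <- leaves[[ci]]
    if (length(mem) < config$ploidy) { skipped <- skipped + 1L; next }
    comp_frags <- fragments[match(mem, ids)]
    # seed derived from the component's content, not its position, so
    # results are independent of processing order
    h <- sum(utf8ToInt(paste(sort(mem), collapse = "|")) *
               (seq_len(nchar(paste(sort(mem), collapse = "|"))) %% 97L))
    sub_seed <- as.integer((config$seed + h) %% 2147483647L)
    blk <- tryCatch(
      assemble_component(comp_frags, config$ploidy,
                         gap_tol = config$gap_tol,
                         restarts = config$restarts, rng_seed = sub_seed),
      error = function(e)
        stop(sprintf("stage assemble, component %d: %s", ci,
                     conditionMessage(e))))
    attr(blk, "component") <- ci
    blocks[[length(blocks) + 1L]] <- blk
    comp_log[[length(comp_log) + 1L]] <-
      data.frame(component = ci, n_fragments = length(mem),
                 seed = sub_seed, sdp_gap = attr(blk, "sdp_gap"),
                 mec = blk$mec)
  }
  manifest$n_skipped_components <- skipped
  manifest$components <- if (length(comp_log))
    do.call(rbind, comp_log) else NULL
  evaluation <- if (!is.null(truth)) evaluate_blocks(blocks, truth)
  structure(list(blocks = blocks, components = leaves,
                 evaluation = evaluation, manifest = manifest,
                 config = config),
            class = "linkhap_run")
}

#' @export
print.linkhap_run <- function(x, ...) {
  cat(sprintf(
    "<linkhap run: %d fragments -> %d components -> %d blocks (mode %s)>\n",
    x$manifest$n_fragments, x$manifest$n_components, length(x$blocks),
    x$config$mode))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' @export
summary.linkhap_run <- function(object, ...) {
  x <- object
  cat("Linked-read polyploid phasing run\n")
  cat(sprintf("  ploidy %d, mode %s, seed %d\n", x$config$ploidy,
              x$config$mode, x$config$seed))
  cat(sprintf("  fragments: %d in, %d after molecule splitting\n",
              x$manifest$n_input_fragments, x$manifest$n_fragments))
  cat(sprintf("  components: %d (%d below ploidy, skipped)\n",
              x$manifest$n_components, x$manifest$n_skipped_components))
  cat(sprintf("  blocks: %d, total MEC %g\n", length(x$blocks),
              sum(vapply(x$blocks, `[[`, numeric(1), "mec"))))
  if (!is.null(x$evaluation)) {
    e <- x$evaluation
    cat(sprintf("  reconstruction rate %.4f, vector error rate %.4f\n",
                e$rr_mean, e$ver_mean))
    cat(sprintf("  mean block length %.1f SNPs, N50 %g bp\n",
                e$stats$mean_len_snps, e$stats$n50_bp))
  }
  invisible(x)
}

#' @export
plot.linkhap_run <- function(x, ...) {
  lens <- vapply(x$blocks, function(b) length(b$idx), numeric(1))
  if (!length(lens)) stop("no blocks to plot")
  graphics::hist(lens, breaks = "FD", col = "grey80",
                 main = "Haplotype block lengths",
                 xlab = "Block length (SNPs)", ...)
  invisible(x)
}
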
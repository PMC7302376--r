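#' Linked-read simulation configuration
#'
#' Parameters of the fragment-level simulator.  The defaults state the
#' simulated world: SNPs at a rate of one per 1000 bp over a 1 Mb region,
#' molecules of mean length 50 kb, 10 molecules per barcode, and a molecule
#' coverage of 0.2 per haploid genome (the 10X Chromium operating point);
#' `p_obs` is the probability that a SNP inside a molecule yields an
#' allele observation, standing in for read coverage within the molecule.
#'
#' @param ploidy K >= 2.
#' @param region_length Region length G in bp; must exceed
#'   `molecule_length`.
#' @param snp_rate Per-bp SNP probability.
#' @param molecule_length Mean molecule length in bp.
#' @param molecule_length_dist `"fixed"` or `"exponential"`.
#' @param molecules_per_barcode Mean molecules per barcode.
#' @param molecules_per_barcode_dist `"fixed"` or `"poisson"`.
#' @param molecule_coverage Molecule coverage per haploid genome.
#' @param p_obs Per-SNP allele observation probability inside a molecule.
#' @param error_rate Probability that an observed allele is flipped to a
#'   (uniformly chosen) different allele of the site.
#' @param base_quality Phred quality attached to every simulated call.
#' @param gap Optional `c(lo, hi)` interval with no SNPs (an assembly-gap
#'   N-region).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(ploidy = 3L, region_length = 1e6, snp_rate = 0.001,
                       molecule_length = 50000,
                       molecule_length_dist = c("fixed", "exponential"),
                       molecules_per_barcode = 10L,
                       molecules_per_barcode_dist = c("fixed", "poisson"),
                       molecule_coverage = 0.2, p_obs = 0.9,
                       error_rate = 0.01, base_quality = 30L,
                       gap = NULL, seed = 1L) {
  stopifnot(ploidy >= 2L, region_length > molecule_length,
            snp_rate >= 0, snp_rate <= 1, p_obs >= 0, p_obs <= 1,
            error_rate >= 0, error_rate <= 1, molecule_coverage > 0)
  structure(list(
    ploidy = as.integer(ploidy), region_length = region_length,
    snp_rate = snp_rate, molecule_length = molecule_length,
    molecule_length_dist = match.arg(molecule_length_dist),
    molecules_per_barcode = molecules_per_barcode,
    molecules_per_barcode_dist = match.arg(molecules_per_barcode_dist),
    molecule_coverage = molecule_coverage, p_obs = p_obs,
    error_rate = error_rate, base_quality = as.integer(base_quality),
    gap = gap, seed = as.integer(seed)), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Generate planted polyploid haplotypes
#'
#' SNP positions are drawn at rate `snp_rate` uniformly over the region
#' (excluding the gap interval); each site is biallelic with a dosage
#' uniform on 1..K-1 and the alternate allele assigned to a uniformly
#' chosen subset of the K haplotypes.  Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (a `"variant_sites"` table) and `truth`
#'   (a `"ground_truth"`).
#' @export
generate_truth <- function(config) {
  set.seed(config$seed)
  G <- config$region_length
  allowed <- seq_len(G)
  if (!is.null(config$gap))
    allowed <- allowed[allowed < config$gap[1L] | allowed > config$gap[2L]]
  n <- stats::rbinom(1L, length(allowed), config$snp_rate)
  if (n == 0L)
    stop("no SNPs drawn; increase region_length or snp_rate")
  pos <- sort(sample(allowed, n))
  K <- config$ploidy
  hap <- matrix(0L, K, n)
  dosage <- sample(seq_len(K - 1L), n, replace = TRUE)
  for (j in seq_len(n))
    hap[sample(K, dosage[j]), j] <- 1L
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  list(variants = variant_sites(pos, ref, alt, dosage),
       truth = ground_truth(hap, pos))
}

#' Simulate barcoded linked-read fragments from planted haplotypes
#'
#' The number of molecules is `round(molecule_coverage * G * K /
#' molecule_length)`.  Each molecule originates uniformly from one of the K
#' haplotypes, starts uniformly in the region, and observes each SNP it
#' spans with probability `p_obs`; an observed allele is flipped to the
#' site's other allele with probability `error_rate`.  Molecules are
#' grouped onto barcodes (`molecules_per_barcode` per barcode) and their
#' calls merged per barcode with the same quality rule as
#' [merge_by_barcode()], emulating the barcode-specific fragment file
#' before molecule splitting.  Fragments with fewer than two calls are
#' dropped.
#'
#' @param sim Output of [generate_truth()].
#' @param config The same [sim_config()].
#' @return List with `fragments` (barcode-origin), `molecule_fragments`
#'   (the per-molecule calls before barcode merging, `origin =
#'   "molecule"`), and `molecules` (truth table: barcode, ordinal,
#'   haplotype, start, end).
#' @export
simulate_fragments <- function(sim, config) {
  set.seed(config$seed + 1L)
  variants <- sim$variants; truth <- sim$truth
  K <- config$ploidy; G <- config$region_length
  n_mol <- round(config$molecule_coverage * G * K / config$molecule_length)
  if (n_mol < 1L) stop("configuration yields no molecules")
  hap_of <- sample(K, n_mol, replace = TRUE)
  len <- switch(config$molecule_length_dist,
    fixed = rep(config$molecule_length, n_mol),
    exponential = stats::rexp(n_mol, 1 / config$molecule_length))
  start <- floor(stats::runif(n_mol, 1, G - len + 1))
  start <- pmax(1, start)
  end <- pmin(G, start + len - 1)
  # group molecules onto barcodes
  m <- config$molecules_per_barcode
  sizes <- integer(0)
  while (sum(sizes) < n_mol) {
    s <- if (config$molecules_per_barcode_dist == "poisson")
      stats::rpois(1L, m) else m
    sizes <- c(sizes, max(1L, s))
  }
  bc_of <- rep(seq_along(sizes), sizes)[seq_len(n_mol)]
  bc_names <- sprintf("BC%05d", seq_along(sizes))

  mol_calls <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    sel <- which(variants$pos >= start[i] & variants$pos <= end[i])
    if (length(sel))
      sel <- sel[stats::runif(length(sel)) <= config$p_obs]
    if (!length(sel)) next
    a <- truth$haplotypes[hap_of[i], sel]
    flip <- stats::runif(length(sel)) <= config$error_rate
    a[flip] <- 1L - a[flip]            # biallelic: flip to the other allele
    mol_calls[[i]] <- list(idx = variants$index[sel], allele = a,
                           qual = rep(config$base_quality, length(sel)))
  }
  # per-barcode ordinals by ascending leftmost covered position
  molecules <- data.frame(barcode = bc_names[bc_of], ordinal = NA_integer_,
                          haplotype = hap_of, start = start, end = end,
                          n_calls = vapply(mol_calls, function(x)
                            if (is.null(x)) 0L else length(x$idx),
                            integer(1)))
  mol_frags <- list()
  frags <- list()
  for (b in unique(bc_of)) {
    mids <- which(bc_of == b)
    mids <- mids[molecules$n_calls[mids] > 0L]
    if (!length(mids)) next
    left <- vapply(mids, function(i) min(variants$pos[match(
      mol_calls[[i]]$idx, variants$index)]), numeric(1))
    mids <- mids[order(left)]
    for (o in seq_along(mids)) {
      i <- mids[o]
      molecules$ordinal[i] <- o
      cc <- mol_calls[[i]]
      mol_frags[[length(mol_frags) + 1L]] <-
        fragment(paste0(bc_names[b], "_", o), cc$idx, cc$allele, cc$qual,
                 origin = "molecule", barcode = bc_names[b], ordinal = o)
    }
    rc <- resolve_calls(
      unlist(lapply(mids, function(i) mol_calls[[i]]$idx)),
      unlist(lapply(mids, function(i) mol_calls[[i]]$allele)),
      unlist(lapply(mids, function(i) mol_calls[[i]]$qual)))
    if (length(rc$idx) < 2L) next
    frags[[length(frags) + 1L]] <-
      fragment(bc_names[b], rc$idx, rc$allele, rc$qual,
               origin = "barcode", barcode = bc_names[b])
  }
  list(fragments = frags, molecule_fragments = mol_frags,
       molecules = molecules)
}

#' Emit SAM and VCF fixtures reproducing simulated fragments
#'
#' Writes a minimal single-sample VCF (polyploid GT per site) and a minimal
#' single-end SAM whose 151 bp reads carry `BX` barcode tags.  One read is
#' emitted per molecule allele observation; read bases at SNPs the molecule
#' did not observe are set to a base matching neither the reference nor the
#' alternate, so they are skipped at extraction.  Running
#' [extract_read_fragments()] then [merge_by_barcode()] on the files
#' reproduces the simulated barcode fragments exactly.
#'
#' @param sim Output of [generate_truth()].
#' @param frag_sim Output of [simulate_fragments()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return List with paths `sam` and `vcf`.
#' @export
emit_fixture_sam_vcf <- function(sim, frag_sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  variants <- sim$variants
  G <- config$region_length
  K <- config$ploidy
  vcf_path <- file.path(dir, "sites.vcf")
  sam_path <- file.path(dir, "reads.sam")

  gt <- vapply(variants$dosage, function(d)
    paste(c(rep("0", K - d), rep("1", d)), collapse = "/"), character(1))
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=sim1,length=%d>", as.integer(G)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "SAMPLE"), collapse = "\t"),
           sprintf("sim1\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                   variants$pos, variants$ref, variants$alt, gt))
  writeLines(vcf, vcf_path)

  read_len <- 151L
  qchar <- intToUtf8(config$base_quality + 33L)
  other_base <- function(i) {                  # neither ref nor alt
    setdiff(BASES, site_alleles(variants, i))[1L]
  }
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:sim1\tLN:%d", as.integer(G)))
  rn <- 0L
  for (f in frag_sim$molecule_fragments) {
    for (j in seq_along(f$idx)) {
      vi <- match(f$idx[j], variants$index)
      p0 <- variants$pos[vi]
      startp <- max(1L, min(as.integer(p0) - 75L, as.integer(G) - read_len + 1L))
      bases <- strsplit(paste(sample(BASES, read_len, replace = TRUE),
                              collapse = ""), "")[[1L]]
      span <- which(variants$pos >= startp &
                    variants$pos <= startp + read_len - 1L)
      for (vs in span) {
        off <- variants$pos[vs] - startp + 1L
        hit <- match(variants$index[vs], f$idx)
        bases[off] <- if (is.na(hit)) other_base(vs)
          else site_alleles(variants, vs)[f$allele[hit] + 1L]
      }
      rn <- rn + 1L
      lines <- c(lines, paste(
        c(sprintf("sim_%s_r%d", f$id, rn), 0L, "sim1", startp, 60L,
          paste0(read_len, "M"), "*", 0L, 0L,
          paste(bases, collapse = ""),
          strrep(qchar, read_len),
          paste0("BX:Z:", f$barcode)), collapse = "\t"))
    }
  }
  writeLines(lines, sam_path)
  list(sam = sam_path, vcf = vcf_path)
}
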
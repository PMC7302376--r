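---
title: "Phasing polyploid genomes from barcoded linked reads: methods and design"
author: "linkhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing polyploid genomes from barcoded linked reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkhap)
```

## The problem

A K-ploid organism carries K homologous copies of each chromosome; the
sequence of alleles along one copy is a haplotype.  Haplotype assembly
reconstructs the K haplotypes from sequencing reads that each originate
from a single (unknown) copy.  Linked-read libraries (10X Chromium and
similar synthetic-long-read protocols) attach a 16 bp barcode to all short
reads amplified from the same droplet, and each droplet holds a handful of
long (10-100 kb) DNA molecules.  The barcode therefore carries long-range
phase information -- but indirectly: roughly ten molecules share a
barcode, and they come from *different* chromosome copies.

`linkhap` turns barcoded alignments plus called polyploid genotypes into
phased haplotype blocks in four stages:

1. **Extraction and barcode merging** -- allele calls at heterozygous SNPs
   are pulled from the reads and united per barcode
   (`extract_read_fragments()`, `merge_by_barcode()`).
2. **Molecule deconvolution** -- each barcode's calls are split into
   molecule-specific fragments by one-dimensional mean-shift clustering of
   their genomic positions (`split_all()`).
3. **Strongly connected components** -- the fragment graph weighted by
   shared-SNP counts is recursively bipartitioned by normalized cut;
   weakly bridged groups of fragments are phased separately
   (`recursive_partition()`).
4. **Assembly core** -- each component is phased by a max-K-cut
   semidefinite relaxation with randomized rounding, local-search
   refinement and majority-vote consensus (`assemble_component()`).

`run_pipeline()` composes the stages and returns a classed result with
`print`, `summary` and `plot` methods.

## Models and procedures

### Fragments and barcode merging

A *fragment* is a sparse vector of allele calls (codes 0-3, 0 =
reference) with Phred qualities, indexed by the 1-based ordinal of the
SNP among the retained heterozygous sites.  Reads covering fewer than two
SNPs carry no phase information on their own and are discarded -- but a
*barcoded* single-SNP read is kept until after barcode merging, because
its call becomes informative once combined with the rest of its barcode.
(The strict drop-before-merge order is available via `strict_two_snp`.)
Conflicting calls at a site are resolved by base quality; an
equal-quality conflict between different alleles drops the site, which is
conservative and introduces no haplotype bias.

### Mean-shift molecule splitting

Molecule coverage is low, so two molecules sharing a barcode are usually
far apart on the genome.  The covered SNP positions of one barcode are
clustered with a flat-kernel mean shift whose bandwidth defaults to half
the expected molecule length (a required pipeline parameter, default
50 kb).  The kernel semantics mirror the scikit-learn reference
implementation: every point seeds an iteration to the mean of in-window
points until the shift falls below `1e-3 * bandwidth`; converged modes
are deduplicated by non-maximum suppression ordered by window occupancy,
and points join the nearest surviving mode.  Note that a *chain* of
points spaced below the bandwidth does **not** collapse to one mode under
a flat kernel -- interior seeds are already stationary -- so a chain
fragments into local modes about two bandwidths apart; the unit tests
freeze this reference behaviour.  The convergence tolerance scales with
the bandwidth, which keeps the partition scale-equivariant.  Clusters
with fewer than two calls are dropped.  Two molecules that genuinely
overlap the same region merge into one cluster; this is a known
limitation of position-only deconvolution.

### Normalized-cut components

The fragment graph has one vertex per fragment and edge weight equal to
the number of SNPs covered by both endpoints.  With degree matrix `D`,
the symmetric normalized Laplacian is `L = D^(-1/2) (D - W) D^(-1/2)`;
the sign pattern of its Fiedler vector (second-smallest eigenvalue)
proposes a bipartition, accepted while its normalized cut

    NC = cut / assoc_1 + cut / assoc_2

is at most `t = 0.03`.  Recursion also stops below `min_component = 2K`
vertices, since smaller groups cannot support K haplotypes.  Connected
components are extracted by BFS before any spectral step (a disconnected
graph makes the Fiedler vector degenerate), zero entries of the Fiedler
vector join the positive side, and NC is always evaluated on the current
subgraph's own weights.  Eigenvalue problems are solved densely (LAPACK);
components are capped at 1500 fragments (larger ones are re-split at a
doubled threshold), so dense decompositions are adequate throughout.

### The max-K-cut assembly core

Within one component, fragments i and j sharing at least one SNP receive
the conflict weight

    W_ij = (#mismatched - #matched alleles) / #shared SNPs  in [-1, 1],

with `W_ii = -1` and structural zeros elsewhere.  Splitting the fragments
into K clusters to minimize within-cluster conflict is relaxed to the
semidefinite program

    minimize  Tr(W X)
    s.t.      X_ij >= -1/(K-1),   X_ii = 1,   X PSD.

The diagonal constraint is essential: without it the problem is unbounded
below (take `X = cI`, `c -> Inf`, since `diag(W) = -1`); it is the
standard normalization of the max-K-cut relaxation this formulation
derives from.

**Solver.**  The dual augmented Lagrangian is maximized with the
multiplier matrix `Y` tracking the (negated) primal solution.  Because
each inequality multiplier touches one symmetric off-diagonal pair and
each diagonal multiplier one diagonal entry, the inner maximization
decouples entrywise: the multiplier update is elementwise closed-form and
the dual slack update is a single projection onto the PSD cone, after
which `Y` takes a multiplier step of size `sigma = mu` along the
constraint residual.  The penalty starts at `mu = 1` and grows by 1.5
whenever the residual stalls.  (A Newton-CG inner solve would be the
general-purpose choice; it is unnecessary here precisely because the
subproblem separates.)

**Certificates.**  Termination is decided on a *repaired* primal/dual
pair: the primal iterate is made feasible by one PSD projection, a
diagonal congruence normalization and a mix toward the identity that
restores the elementwise bound; the dual point is made feasible by
shifting the diagonal multipliers until the slack matrix is PSD.  The
relative duality gap

    |obj_p - obj_d| / (1 + |obj_p| + |obj_d|)

between these feasible points is a true optimality certificate; iteration
stops at `gap_tol` (default 0.01, `0.05` in fast mode).  The printed form
of the gap in the source formulation lacks the absolute values, but both
objectives are negative here and the literature convention (absolute
values) is the meaningful one.  Feasibility at termination is within
1e-6 elementwise, by construction usually exact.

**Rounding.**  Per restart, K standard-normal N-vectors are drawn and
fragment i joins the cluster whose vector has the largest inner product
with column i of the solved X.  Among restarts (default 100, 10 in fast
mode) the assignment whose majority-vote consensus has the smallest MEC
wins; without fragments (pure matrix instances) the realized clustering
objective is used instead.  All restarts derive from one seed, and the
pipeline derives each component's seed from the component's *content*,
so results are independent of component processing order.

**Refinement.**  Randomized rounding occasionally leaves a misassigned
fragment, or collapses a cluster entirely on chain-structured components
whose relaxation optimum is shallow.  A deterministic local search
follows: alternate majority-vote consensus with nearest-haplotype
reassignment (ties keep the current label); both half-steps weakly
decrease MEC (the k-means argument), so the search converges.  If a
cluster is empty at convergence while mismatches remain, it is reseeded
with the worst-fitting fragment -- that move strictly decreases MEC, so
termination is preserved.  On noiseless full-coverage simulations this
combination recovers the planted haplotypes exactly; it can be disabled
with `refine = FALSE` in `assemble_component()`.

**Consensus.**  Per cluster and site, the haplotype allele is the modal
allele of the cluster's calls (ties: lowest allele code, deterministic),
uncovered sites are gaps, and per-site support counts (matching calls)
are reported as the quality column of the block output.

### Evaluation

*Reconstruction rate* is `1 - min_p sum_k D_H(est_k, true_{p_k}) / (K L)`
over all K! row permutations.  Sites where any reconstructed haplotype
has a gap are excluded from `L` and the distances by default
(`gaps_as_errors = TRUE` counts them as mismatches).  *Vector error rate*
is the minimum number of row-assignment switches needed to match the
truth, divided by block length, computed by dynamic programming over
positions with one state per permutation and a lexicographic objective:
residual allele mismatches dominate, switches break ties; both components
are reported.  *MEC* sums, over fragments, the mismatch count against the
nearest haplotype, with gap positions never counting; a haplotype
covering none of a fragment's sites is ineligible as its nearest one
(otherwise an all-gap haplotype would win vacuously, which would also
derail MEC-based rounding selection).  Per-block metrics are averaged
unweighted across blocks; a length-weighted average is also reported.
Mean block length is in SNPs and the N50 block length in bp (genomic
span), matching the two conventions used for these statistics.

## The simulator: a stated world

`sim_config()` fixes the synthetic world: SNPs at rate `snp_rate`
(default 1/1000 bp) uniformly over a region (default 1 Mb), biallelic
with dosage uniform on 1..K-1; molecules of mean length 50 kb, 10 per
barcode, molecule coverage 0.2 per haploid genome (the 10X operating
point); each SNP inside a molecule observed with probability `p_obs`
(standing in for within-molecule read coverage) and flipped to the other
allele with probability `error_rate`.  An optional interval with no SNPs
emulates a reference assembly gap (N-region).  All randomness flows from
one seed; identical configurations are byte-identical.

What the generator does *not* emulate: barcode sequencing errors,
alignment and mapping artefacts, indels and multiallelic sites, PCR
duplicates, GC bias, and read-level structure (insert sizes matter only
to the SAM fixture emitter, which writes 151 bp single-end reads whose
bases encode the simulated calls exactly).  A green end-to-end test
therefore establishes the correctness of the pipeline's logic under the
stated observation model, not robustness to upstream artefacts.

Operating points used by the test suite, chosen once: the noiseless
sanity world uses molecule coverage 4 per haploid with 100 kb molecules
over 200 kb ("full coverage": every pair of nearby fragments overlaps,
so exact recovery is information-theoretically trivial and any loss would
indicate an implementation fault).  The trend checks (error-rate
monotonicity, the value of molecule splitting at 10 molecules per
barcode, block span versus molecule length) run at 1 Mb / ~1000 SNPs
with molecule coverage 2-4, averaged over 20-30 seeds; the error-rate
trend uses 30 seeds because a 1% error-rate step moves mean RR by less
than seed-to-seed variation at this scale.

## Numerical choices and degenerate inputs

- SDP: `mu = 1` initial penalty, two inner sweeps per outer iteration,
  convergence checks every 10 iterations with an eigendecomposition-free
  monitoring estimate; `N = 1` returns the trivial certificate; `W = 0`
  terminates immediately with gap 0.
- Mean shift: seeds at all points, 300 iteration cap, suppression ties
  broken toward the larger mode (reference semantics); single-call
  barcodes produce no molecules.
- Spectral splits: a numerically one-signed Fiedler vector moves its
  smallest-magnitude entry across so neither side is empty; a side with
  zero association reports NC = 2 (refuse-to-split).
- Consensus ties take the lowest allele code; empty clusters warn and
  yield all-gap haplotypes.
- Components with fewer than K fragments cannot determine K haplotypes
  and are skipped with a manifest counter.

## Known limitations

- Position-only molecule splitting merges molecules that overlap on the
  genome; joint deconvolution across barcodes is out of scope.
- The max-K-cut objective does not always prefer the planted partition at
  thin coverage; restarts plus refinement mitigate but do not eliminate
  this, and reconstruction rates below 1 at molecule coverage 2 reflect
  the method, not a bug.
- The SDP solve is dense (O(N^3) per iteration); the component size cap
  keeps this tractable, at the cost of re-splitting very large
  components at a doubled NC threshold.
- Runtime at scale: the accurate mode is considerably slower than fast
  mode; both share the same components and differ only within-block.
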
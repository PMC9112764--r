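---
title: "Variant-aware pseudo-long reads from metagenomic short-read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-aware pseudo-long reads from metagenomic short-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plrforge)
```

## The problem

Short-read metagenome assemblies fragment wherever closely related genomes —
strains of one species, or conserved regions shared across species — differ
by only a handful of nucleotides. Known microbial reference genomes are a
powerful guide through such regions, but a naive reference-guided consensus
erases exactly the small variation that distinguishes the strains.

`plrforge` synthesizes *pseudo-long reads* (PLRs): artificial long sequences
tiled along reference intervals that are continuously covered by mapped
short reads, with the observed strain variation preserved. Where the pileup
supports two (or more) co-occurring allele combinations, the package emits
one PLR per combination, so downstream hybrid assemblers receive long,
strain-faithful sequences rather than a blended consensus.

The tool consumes coordinate-sorted SAM/BAM alignments plus the reference
multi-FASTA; producing those alignments (and choosing which references to
map against) is deliberately outside its boundary, which keeps the pipeline
hermetic and testable. A typical upstream recipe is a standard short-read
aligner run separately against each candidate reference genome with default
settings.

## Pipeline

Six stages, each exposed as an ordinary function on tibbles so intermediate
results can be inspected:

1. **Filter + pile up** (`build_pileup`). Records with mapping quality
   below 20, or flagged unmapped / QC-fail / duplicate / secondary, are
   skipped — mirroring the classical `-q 20` plus
   `UNMAP,QCFAIL,DUP,SECONDARY` pileup filter. Supplementary alignments are
   also excluded so a fragment can never contribute twice at one column.
   The pileup keeps *which fragment* carried *which base* at every
   position; this per-fragment identity is what later turns paired-end
   fragments into variant-linking evidence. Both mates of a pair count as
   one fragment: where they overlap and agree the base is counted once,
   where they disagree the fragment contributes nothing at that column.
   Base qualities are not used. Insertions relative to the reference have
   no reference coordinate and are ignored; deletion and `N` calls make the
   read non-covering at that column.
2. **Containers** (`build_containers`). Each reference is broken at every
   position with zero passing coverage; the maximal covered runs are *PLR
   containers*. Containers shorter than 100 bp are discarded — strictly
   shorter, so a 100 bp container survives.
3. **Graph** (`build_graph`). Each container column is classified by allele
   frequency: bases with count at least half of the most frequent base's
   count are retained (the boundary is inclusive: exactly half is kept).
   One retained base makes the column part of a *normal node* (maximal runs
   of such columns, carrying the consensus *aligned* base — the reference
   only supplies coordinates); two or more retained bases make it a
   single-column *bubble* with one node per nucleotide. Node order along
   the container defines the graph's directed edges.
4. **Bubble vectors and clustering** (`extract_bubble_vectors`,
   `cluster_vectors`). A fragment informative at two or more bubble columns
   becomes a vector $V_i = (v_{i1}, \dots, v_{iB})$,
   $v_{ij} \in \{A, C, G, T, \text{-}\}$, with `-` marking columns the
   fragment does not inform (including columns where it carries a
   filtered-out low-frequency allele). The consistency distance
   $D(V_i, V_j) = \sum_b d_b$ counts positions where both vectors are
   informative and disagree; pairs sharing no informative position get a
   fixed sentinel $B + 1 > 1$ so they can never merge at cutoff 0.
   Agglomerative clustering cut at distance 0 is performed; at that cutoff
   single linkage merges exactly the zero-distance pairs and their
   transitive closure, i.e. the connected components of the zero-distance
   graph, so the implementation computes components directly with
   union-find (deterministic, and verified in the tests against a
   brute-force distance-matrix + graph-components oracle).
5. **Combinations** (`build_combinations`). Each cluster is integrated into
   one allele assignment over all $B$ bubble columns; columns no member
   informs stay `-`. A bubble linked by no fragment anywhere is `-` in
   every combination — it is never enumerated per allele, which would
   explode combinatorially without evidence.
6. **Sequences** (`assemble_paths`, `write_plr_fasta`). Each combination is
   walked left to right across the container: normal columns copy the
   consensus, bubble columns copy the combination element, `-` becomes `N`.
   Every PLR has exactly the container's length. `mask_to_nplr` produces
   the matched control (one sequence per container with `N` at *every*
   bubble column), useful for quantifying what the resolved variant bases
   add beyond mere elongation.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_mapq` | 20 | phred | minimum mapping quality into the pileup |
| `min_container_len` | 100 | bp | discard shorter containers (strict `<`) |
| `min_rel_freq` | 0.5 | ratio | allele kept if count ≥ ratio × top count |
| `min_cluster_support` | 1 | fragments | clusters below this support seed no path |

All four are exposed on `plr_gen()`, `run_plr_gen()` and the command line.
The defaults are the method's canonical operating point; `min_rel_freq` is
the sensitivity/precision dial for bubble detection (lower values admit
rarer strains but also sequencing errors), and `min_cluster_support` is an
optional guard against singleton-read haplotypes in noisy data.

## Design choices where the design was open

* **Linkage criterion.** Only "agglomerative clustering with cutoff 0" is
  inherent to the method; the linkage is unspecified. Single linkage is the
  unique choice under which a cutoff of 0 reduces to connected components
  of the zero-distance relation, making the result independent of merge
  order and of the input permutation. Complete or average linkage at
  cutoff 0 would depend on tie-breaking between non-comparable pairs.
* **Transitive conflicts.** Zero-distance merging can chain $V_1 \equiv
  V_2$, $V_2 \equiv V_3$ while $V_1$ and $V_3$ disagree at a column
  (possible because comparability is not transitive). Such clusters are
  resolved per column by multiplicity-weighted majority (ties to the
  alphabetically smallest base) and flagged with a warning carrying the
  container id; crashing on real data that violates the clean-cluster
  assumption is not acceptable for a production tool.
* **Frequency boundary.** A minor allele at exactly half the major count is
  retained; only ratios strictly below the cutoff are discarded.
* **Overlapping mates.** Agreement counts once; disagreement removes the
  fragment's evidence at that column rather than arbitrarily preferring a
  mate.
* **Ordering contracts.** Clusters are numbered by (minimum first-bubble
  position, descending support, lexicographic elements); containers are
  processed per reference in FASTA order, then by start. Together with the
  absence of any randomness in the core pipeline this makes every output
  byte-identical across reruns — asserted in the tests.
* **Coordinates.** 1-based inclusive internally (the R/Bioconductor
  convention); emitted FASTA headers are 1-based inclusive and BED output
  is 0-based half-open, as those formats require.

## The simulator: what it emulates, and what it does not

`simulate_community()` generates the package's entire test bed: random
reference replicons; 1–3 strain haplotypes per replicon differing by point
substitutions (at each site one strain, chosen uniformly, carries a
substituted base); paired-end reads (2 × 101 bp by default, matching
common short-read library layouts) drawn uniformly along each strain with
Gaussian insert sizes (truncated below at the read length) and uniform
per-base substitution errors; and perfect-knowledge alignments that place
every read at its true origin with full-match CIGARs
(`simulate_alignments`), so the pipeline is testable without an external
aligner. Fixing the seed makes every output file byte-identical.

SNV sites are placed as a Bernoulli process by default. For experiments
that require every adjacent variant pair to be spannable by one fragment,
`max_snv_gap` switches placement to uniform gaps on
$[2/\text{rate} - m,\ m]$, which preserves the marginal site rate while
bounding the spacing; a sensible cap is `insert_mean - 2 * insert_sd`, so
that typical fragments (not just the long tail) can co-cover neighbouring
sites with both mates.

The simulator deliberately omits: indels and structural variation,
quality-dependent and strand-biased error profiles, abundance skews between
strains, contaminant genomes, and mapping ambiguity (its alignments are
perfect-knowledge). Passing tests therefore demonstrate the algorithmic
contracts — filters, container arithmetic, bubble detection, linkage
clustering, sequence assembly — not robustness to alignment artefacts of
real data, which enter through whatever aligner produces the input BAM.

Test problem sizes are 500 bp – 10 kb replicons at 10–40× per strain;
these exercise every code path (tens of containers, dozens of bubble
columns, hundreds of linking vectors) while keeping the whole suite around
two minutes.

## Exact haplotype recovery is probabilistic at finite depth

With two strains at equal depth $\lambda$ per strain, the per-strain
fragment count at a site is approximately Poisson($\lambda$), and a true
variant column survives the frequency filter only while the minor count
stays at or above half the major count. The probability that a site drops
out is $P(2X < Y)$ with $X, Y \sim \text{Poisson}(\lambda)$ per side —
about 0.9% two-sided at $\lambda = 30$. A 10 kb container with ~50
engineered SNVs therefore resolves *all* of its sites with probability
around $0.99^{50} \approx 0.6$; in the remaining runs one or a few columns
collapse into normal nodes and the affected PLR differs from its source
haplotype at exactly those positions. This is intrinsic to frequency-based
bubble detection at finite depth, not an implementation artefact: the
package's own fixed-seed recovery test documents one such site (minor 8
vs major 20, correctly filtered at the 0.5 boundary). Raising depth
suppresses the effect quadratically in the exponent; at 60× per strain the
per-site dropout is below 0.01%.

## Known limitations

* Bubbles are single-column substitutions; indel variation between strains
  is not modelled and will fragment containers or bias the consensus.
* Containers never span coverage gaps, even 1 bp ones; there is no
  gap-bridging heuristic.
* More than ~4 haplotypes per region cannot be represented at one column
  (the alphabet has four letters), and low-frequency strains below
  `min_rel_freq` of the dominant one are invisible by design.
* Unlinked bubbles surface as `N`; consumers that cannot handle `N` should
  use `drop_n`.
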
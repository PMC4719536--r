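---
title: "Pooled BAC assembly support: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled BAC assembly support: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacpool)
```

# The problem

Large cereal and grass genomes (bread wheat, sugarcane) are dominated by
repeats — on the order of 80 % of the sequence — which defeats
whole-genome shotgun contiguity. A BAC-by-BAC strategy sidesteps this by
assembling ~100–130 kb cloned inserts one at a time, but sequencing each
clone in its own indexed library is expensive. Pooling several
non-overlapping BACs under one index restores throughput at the cost of
two new problems this package addresses: deciding how much coverage each
clone needs, and working out, after assembly, which contig came from
which clone. Around those sit routine but consequential bookkeeping
stages: removing *E. coli* and cloning-vector contamination and clonal
duplicates before assembly, validating assemblies with long-insert mate
pairs, and turning mate-pair mappings into scaffolding links.

The assembler itself is deliberately external and pluggable: the package
orchestrates everything around it and consumes its contigs as FASTA.

# Coverage saturation

Per-clone coverage requirements are estimated empirically: read pairs
are subsampled **with replacement** to a grid of target coverages
(default 200x–3000x in 100-fold steps; `plan_subsamples()` with 11
clones enumerates 319 jobs), each subset is assembled, and total
assembly length is plotted against coverage. The subsample size is

$$ n = \left\lceil \frac{c \cdot U}{2\,\ell} \right\rceil $$

for coverage $c$, unit length $U$ and effective read length $\ell$
(reads may be truncated first via `trim_to`, e.g. to 70 bp).

The curve is smoothed with LOESS — local polynomial regression with
tricube weights $w_i = (1-(d_i/d_{\max})^3)^3$ over the
$\lceil \mathrm{span}\cdot n\rceil$ nearest points — at span 0.75 and
degree 2, fitted over the 200x–1000x window where the signal is
monotone; beyond ~1000x erroneous reads make assembly length drift. The
implementation is written directly from this definition (each local fit
is a weighted least-squares solve) so that it can be verified against an
independent normal-equations oracle, which the test suite does to
1e-8.

"Levelled off" needs a rule to be computable: `find_plateau()` returns
the smallest coverage whose smoothed length reaches $(1-\varepsilon)$
of the window maximum, with $\varepsilon = 1\,\%$ by default. Smaller
$\varepsilon$ can only move the plateau right, which the suite asserts.

The tests exercise the full loop with a deliberately simple toy
assembler (canonical k-mers observed at least twice, k = 31) on an
8 kb repeat-free clone over a 2x–30x grid — small enough to run in
seconds, yet showing the rise-then-plateau shape and recovering ≥ 99 %
of the insert length at the detected plateau. The toy assembler needs a
count threshold to produce a rising regime at all; it stands in for the
real assembler's data hunger, not for its algorithm.

# Pre-processing QC

Contaminant removal realises a zero-mismatch single-read screen as an
exact set-membership test: every substring of length $w$ (= read
length) of the *E. coli* and vector references, on both strands, is
indexed, and a pair is discarded when either read is a member —
**pair-atomic** removal, since the mate of a contaminated read is
suspect too. Words containing `N` are never indexed, so ambiguous reads
never match (conservative). When a pair matches both references the
vector class wins, a deterministic accounting choice. Clonal duplicates
— byte-identical `(read1, read2)` pairs, or identical after mate swap
plus reverse complement (the same fragment read from the other strand)
— are removed after contaminant filtering, keeping the first
representative. Coverage is reported per 120 kb cloning unit, rounded
to integer folds.

On simulated pools the filter is *exactly* measurable because the mock
contaminant references are generated to share no read-length substring
with the inserts (verified by a 31-mer census: sharing a 150 bp window
implies sharing a 31-mer). Recall of planted contaminant pairs is then
provably 100 % and insert false-removals provably 0, which the
acceptance suite confirms on >10^5 pairs.

# Deconvolution by BAC-end sequences

In a pooled assembly, each clone's true boundary contigs carry its
BAC-end sequences (BES) near a contig edge. Repeats make raw best-hit
assignment unreliable — a BES can match many interior repeat copies —
so hits are scored

$$ S = b - d_s $$

where $b$ is the alignment bit score (it already folds in identity and
aligned length) and $d_s = \min(\text{start},\ \text{len} -
\text{end})$ is the shortest distance from the hit to a contig edge.
The highest-$S$ hit wins; a BES is only eligible when its length
exceeds 120 bp and is below an upper bound $X$ (default 1000 bp — a
Sanger-read upper bound; the bound is configurable because no canonical
value exists). Ties break by higher $b$, then smaller $d_s$, then
contig id; ties are vanishingly rare in practice and the chain merely
makes output deterministic.

Clones with no BES are handled with 120 bp **vector-end proxies**: the
vector sequence flanking the insertion site appears at the outer contig
ends of such a clone. Proxies bypass the >120 bp filter (they are
exactly 120 bp, the filter would otherwise exclude them by
construction) and are flagged as such in reports. Contigs claimed by
BES of two clones are reported as conflicts and never auto-resolved:
a conflict means overlapping clones or misassembly, a call for a human.

`pair_pool_to_singletons()` checks pooled-vs-singleton assembly
integrity by pairing each pool contig to the singleton assembly with
the largest summed bit score, reporting the aligned fraction (union of
query intervals); pairings under 50 % aligned are unpaired, and a
runner-up within 50 % of the winner flags the contig as shared.

# Mate-pair orientation QC and scaffolding links

After circularisation, a correct long-insert (6–10 kb) mate pair maps
*outward*: ordering the mates by position, the leftmost is on the minus
strand and the rightmost on plus (RF). Inward-facing pairs (FR) are the
short-insert shadow library; same-facing pairs (FF/RR, reported
jointly) are chimeric junction artefacts. Classification is positional
— defined on the leftmost/rightmost mate, not mate labels — so it is
invariant to read naming, and the simulator randomises mate labels to
keep the tests honest. Insert size is the **outer distance** (rightmost
end − leftmost start); the convention is declared rather than inferred,
and the per-class medians in reports use it.

Validation pairs require unique mapping of both mates, 100 % identity
and reads >100 bp on one contig. Scaffolding pairs require 100 %
identity at full read length with both mates in the same pool; selected
pairs are written as a standard 6-column tab file (1-based inclusive
coordinates, deterministic ordering). Link bundles group inter-contig
pairs by unordered contig pair and relative orientation and drop
bundles with fewer than K = 10 links. The gap estimate is the median of
(configured insert midpoint − span of mate A to its gap-facing end −
span of mate B), the gap-facing end being rightward of a minus-strand
mate and leftward of a plus-strand mate.

A known limitation: gap-spanning pairs are length-biased (a longer
insert spans a gap in more positions), so with a wide library (6–10 kb)
the spanning pairs' mean insert exceeds the configured midpoint and the
gap estimate is biased low by a few hundred bp. The gap-recovery test
therefore uses a 6–7 kb library, where the estimator's assumption
holds; with wide libraries, gap estimates should be read as
order-of-magnitude.

# Pool design and size validation

Pools must contain mutually non-overlapping clones. Overlap is derived
from physical-map (FPC) adjacency: consecutive minimal-tiling-path
clones in the same FPC contig overlap by construction — a proxy chosen
because FPC provides ordering but not coordinates. Pooling is a greedy
randomised partition with up to 1000 restarts rather than exact graph
colouring: instances are small and sparse, and on failure the error
names the largest overlap clique (found via igraph), which is the
actual obstruction. The lane arithmetic is direct:
`expected_lane_coverage(40e9, 384, 120000)` ≈ 868x, inside the
empirically optimal 450x–900x band, which justifies multiplexing 384
BACs (96 pools of four) per lane.

Assembly sizes are validated against FPC size estimates with a
classical paired t test (`stats::t.test` under the hood, with explicit
handling of zero-variance differences); FPC sizes are consumed as
given — they are approximations from restriction-fragment counts, and
the comparison's point is precisely that the two measurements agree on
average.

# The simulator: what it emulates, and what it does not

`simulate_clone()` builds inserts as a mosaic of unique sequence and
copies (1 % per-base divergence) of a small per-clone repeat library,
hitting the requested repeat fraction exactly (a final truncated copy
absorbs rounding). Defaults follow the regime the package targets:
120 kb inserts, 80 % repeat content, 150 bp paired-end reads at ~500 bp
inserts, mate pairs uniform on 6–10 kb with a
(99 %, 0.3 %, 0.7 %) RF/FR/FF+RR mix, contamination at 13 % *E. coli*,
4 % vector, 0.6 % clonal — values chosen once, near the middle of the
observed per-pool ranges. BES are the terminal 600 bp with 0.1 %
substitution error: long enough to pass the >120 bp filter, short
enough to be Sanger-like.

Everything is deterministic under a seed (RNG state is saved and
restored around every generator), truth labels ride along with every
read pair, and contamination counts are set so each class's share of
the *final* total matches its nominal fraction.

Deliberately not modelled: base-quality error profiles, indels,
real *E. coli* K-12 or pIndigoBAC5 sequences (mock contaminants are
random and provably disjoint from inserts — which is what makes filter
metrics exact), and any repeat family structure beyond the mosaic
model. Consequently, passing tests demonstrate the *logic* of each
stage — exact filtering, scoring, classification, bundling — under
clean mappings; they do not demonstrate robustness to sequencing error
or alignment ambiguity on real data, where the external aligner's
behaviour dominates.

# Numerical and scale choices

Test and acceptance problem sizes are scaled to what the analyses need
rather than to production volumes: QC properties are measured on
~1.3 × 10^5 simulated pairs (binomial 3σ at the configured fractions is
then well under the asserted tolerances), deconvolution on 10 pools of
four 12 kb clones, orientation closure on 2 × 10^4 mate pairs, and the
saturation loop on an 8 kb clone. All coordinates are 0-based
half-open internally; the only conversions happen at format boundaries
(BLAST tabular, SSPACE tab), and minus-strand hits are stored with
ascending coordinates plus a strand flag so edge-distance and
orientation arithmetic never branch on strand.
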
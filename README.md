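# bacpool

Assembly support for pooled BAC sequencing in R.

Repeat-rich genomes (wheat, sugarcane and relatives are ~80 % repeats)
are still best assembled BAC by BAC, and the economics only work when
several non-overlapping BACs are pooled under one sequencing index —
e.g. 384 BACs as 96 pools of four in a single 40 Gbp lane, giving
`40e9 / (384 × 120000) ≈ 868x` per BAC. `bacpool` implements the
analysis stages around a pluggable external assembler:

- **Read QC** — pair-atomic removal of *E. coli* / cloning-vector
  contamination via an exact full-read screen (zero mismatches, both
  strands), clonal-duplicate removal, and per-120 kb-unit coverage
  accounting.
- **Coverage saturation** — with-replacement subsampling across a
  coverage grid (200x–3000x by default), LOESS smoothing (tricube
  weights, span 0.75, degree 2, implemented from the definition and
  tested against a brute-force weighted-least-squares oracle), and
  plateau detection to find the assembler's optimal coverage.
- **Pool deconvolution** — assigning contigs of a pooled assembly back
  to source clones by scoring BAC-end-sequence hits with
  `S = bit_score − d_s`, where `d_s` is the hit's shortest distance to
  a contig edge; 120 bp vector-end proxies anchor clones lacking BES;
  conflicts are reported, never auto-resolved.
- **Mate-pair QC and scaffolding links** — RF / FR / FF+RR orientation
  classification (outward-facing RF is the correct mate-pair class;
  FR is the shadow library; FF/RR are chimeras), Table-style summaries,
  SSPACE-dialect tab files, and link bundling with a K = 10 threshold
  and median-based gap estimates.
- **Pool design** — greedy randomised partition of clones into pools
  with no physical-map overlap inside any pool, plus the paired t test
  of assembly sizes against FPC size estimates.
- **A ground-truthed simulator** — BAC clones with controlled repeat
  content, PE/MP reads with configurable contamination and orientation
  mixes, and BES — so every stage above is exactly measurable.

## Worked example

Simulate a four-clone pool, contaminate it, and run the QC:

```r
library(bacpool)

clones <- lapply(1:4, function(i)
  simulate_clone(paste0("cl", i), length = 15000, repeat_fraction = 0.3,
                 repeat_unit_length = 500, seed = i))
pool <- simulate_pool("demo", clones)
cfg  <- sim_config(seed = 9, read_length = 100,
                   frac_ecoli = 0.13, frac_vector = 0.04, frac_clonal = 0.006)
sim  <- simulate_pool_reads(pool, target_coverage = 60, cfg)

qc <- run_readqc(sim$pairs,
                 ecoli_ref  = sim$contaminants["ecoli"],
                 vector_ref = sim$contaminants["vector"],
                 n_bacs = 4, unit_length = 15000)
qc
#> Pre-processing QC report
#>   input pairs     : 21845
#>   vector removed  : 878 (4.02 %)
#>   E. coli removed : 2865 (13.12 %)
#>   clonal removed  : 107 (0.49 %)
#>   kept pairs      : 17995
#>   coverage        : 73x raw, 60x filtered
```

The removal percentages recover the simulated contamination fractions
(13 % / 4 % / 0.6 %), and filtered coverage lands on the 60x target.
Because the mock contaminants provably share no read-length substring
with the inserts, recall of planted contaminant pairs is exactly 100 %
with zero insert pairs lost.

Deconvolute the (here: truth-contig) assembly with BES scoring:

```r
contigs <- setNames(vapply(clones, `[[`, "", "insert"), paste0("ctg", 1:4))
bq <- bes_queries_from_clones(clones)
write_fasta(contigs, "contigs.fa")
write_fasta(setNames(bq$sequence, bq$bes_id), "bes.fa")
system("makeblastdb -in contigs.fa -dbtype nucl -logfile /dev/null")
system("blastn -query bes.fa -db contigs.fa -outfmt 6 -out hits.tsv")

hits <- read_blast_tabular("hits.tsv")
asn <- assign_bes(bq, hits, setNames(nchar(contigs), names(contigs)))
deconvolute_pool(asn, bq, sapply(clones, `[[`, "clone_id"), names(contigs))
#> Pool deconvolution report
#>   clones       : 4 (4 anchored)
#>   contigs mapped: 4
#>   conflicts    : 0
#>   unassigned   : 0
```

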
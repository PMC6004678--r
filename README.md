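# mitescan

De novo discovery and comparative analysis of **miniature
inverted-repeat transposable elements (MITEs)** in small genome
assemblies — viral genomes and other compact assemblies up to a few
megabases.

MITEs are short (< ~800 bp) non-autonomous DNA transposons: they carry
terminal inverted repeats (TIRs), create a short target site
duplication (TSD) on integration, amplify to high copy numbers with
strong length homogeneity, and encode no protein. Surveying them in
small genomes answers questions that matter to virologists and mobile
DNA researchers alike: have elements been transpositionally active
inside the genome, which superfamily machinery mobilizes them, does a
cellular host carry the autonomous partner, and were the elements
acquired by horizontal transfer (HT)?

`mitescan` implements the complete analysis as composable R functions:

* **Discovery** — seed-and-verify search for TIR-flanked candidates
  (arm 8–60 bp, mismatch budget, element window 50–800 bp), then
  single-linkage clustering into multi-copy families (≥ 80% identity
  over ≥ 80% mutual coverage, ≥ 3 copies).
* **Annotation** — boundary refinement from copy+flank multiple
  alignments with a TSD-duplication polish, exact TSD calling
  (2–10 bp), the classical false-positive filters (> 800 bp, no
  TIR/TSD, compound elements), and superfamily classification from
  TIR/TSD signatures (hAT, hATm `TAGGGTG…CACCCTA` 8–9 bp TSD,
  CMC/CACTA `CAC…GTG` 2 bp TSD, Tc1/mariner `TA`, IS200/IS605-like).
* **Quantification** — majority-rule consensus building, library-based
  copy annotation (fragments < 80 bp excluded), per-family statistics
  on interval unions, and copy–consensus distances: p-distance and
  Kimura 2-parameter, `d = -1/2 ln(1−2P−Q) − 1/4 ln(1−2Q)`, with
  pairwise deletion.
* **Comparative analyses** — paralogous empty sites and orthologous
  presence/absence from flank anchoring (50/100 bp flanks, ≥ 85%
  identity, ≤ 15 bp apart), and HT screening by the identity/coverage
  rule (present iff ≥ 60% identity over ≥ 60% of the consensus).
* **Autonomous partners** — 1–10 kb candidates sharing ≥ 8/15 terminal
  bases with a family and carrying a transposase-scale ORF (≥ 300 aa),
  with deletion-derivative flagging and terminus logo matrices.
* **Phylogenetics** — neighbor-joining trees of up to 50 full-length
  copies (p-distance, pairwise deletion), column-bootstrap supports
  (1000 replicates), and bipartition-level monophyly tests.
* **Synthetic data** — a generator that plants the whole story (TIRs,
  TSDs, divergence, truncation, empty sites, autonomous partner, HT
  pairs) with a complete ground-truth record, plus recovery scoring.

## Worked example

Simulate the default 200 kb genome with three planted MITE families
(40, 25 and 10 copies at 5% per-copy divergence), run discovery,
quantification and recovery scoring, and inspect the result:

```r
library(mitescan)

ts <- simulate_genomes(sim_spec(seed = 5L, autonomous = NULL,
                                ht_pairs = NULL, empty_site_pairs = 0L))
cfg <- pipeline_config(ts$genomes, outdir = "mite_run", seed = 5L,
                       stages = c("discover", "quantify", "evaluate"),
                       truth = ts)
res <- run_pipeline(cfg)
print(res$recovery)
for (f in res$families) print(f)
```

```
recovery_report
  family: P=1.000 R=1.000 F1=1.000
  copies: P=1.000 R=0.987 F1=0.993 count_err=-0.013
  tsd exact: 1.000  boundary offset mean=0.00 max=0
mite_family 'hAT-NA1' [hAT]: 20 members, consensus 300 bp, TSD 8
mite_family 'Unk-NA2' [Unknown]: 10 members, consensus 180 bp, TSD 2
mite_family 'hAT-NA3' [hAT]: 6 members, consensus 420 bp, TSD 8
```

Reading the report: all three planted families were recovered with no
spurious ones (family precision/recall 1.0); 74 of the 75 planted
copies were re-annotated by the consensus library (copy count error
−1.3%, within the ±10% working tolerance); every TSD length on the
refined members matched the planted duplication, and refined member
boundaries sat exactly on the planted coordinates. The two 8-bp-TSD
families classify as hAT by signature; the 2-bp-TSD family has random
termini by construction, so it lands in `Unk` (unknown superfamily) —
its name `Unk-NA2` follows the `X-NA#` nomenclature with ordinals
assigned by descending copy number.

The run directory contains the consensus library (`families.fa`),
copy annotations (`copies.gff3`, 1-based, with Family / Completeness /
Divergence / TSD attributes), per-family statistics (`stats.tsv`),
empty-site, orthologous-site and HT reports, newick trees under
`trees/`, a `MANIFEST`, and a log naming every filtered item with its
reason.

A thin command-line wrapper for shell use ships at
`inst/scripts/mitescan.R` (verbs `run`, `simulate`, `evaluate`).

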
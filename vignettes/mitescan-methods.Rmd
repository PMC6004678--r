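---
title: "Methods: MITE discovery and comparative analysis in small genomes"
author: "mitescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MITE discovery and comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Miniature inverted-repeat transposable elements (MITEs) are short
(< ~800 bp) non-autonomous DNA transposons. They carry terminal inverted
repeats (TIRs), create a short target site duplication (TSD) at
insertion, reach high copy numbers with strong length homogeneity, and
encode no protein. `mitescan` detects such elements de novo in small
genome assemblies (viral-scale, up to a few Mb), builds families and
consensus sequences, classifies them into DNA-transposon superfamilies
by TIR/TSD signatures, quantifies copies against the consensus library,
and runs the comparative analyses used to argue for transposition
activity and horizontal transfer (HT): paralogous empty sites,
orthologous presence/absence, cross-genome identity screens,
autonomous-partner linkage, and neighbor-joining (NJ) trees of copies.

The package assumes assemblies small enough that exact seed-and-extend
scanning is affordable; it trades speed for exactness everywhere.

# Discovery

`find_tir_candidates()` enumerates exact k-mer seeds that match their
reverse complement downstream within the element length window
(50-800 bp by default; the 800 bp ceiling is the MITE size class and
also the first false-positive filter). Seeds are extended outward and
inward under the TIR mismatch budget (default arm 8-60 bp, <= 2
mismatches).

Two numerical choices matter here:

* **Seed length** is `max(4, min(6, tir_min_len))`, deliberately shorter
  than the minimum arm. An exact seed as long as the arm cannot tolerate
  internal arm mismatches that the mismatch budget is supposed to allow;
  a 6-mer seed restores pigeonhole coverage at these genome scales for a
  modest constant cost.
* **Boundary preference.** Among all arm delimitations consistent with a
  seed we pick fewest mismatches, then the longer arm, then the
  outermost boundary. Preferring long arms first lets chance-paired
  flanking bases drag boundaries outward; preferring clean arms keeps
  the initial boundary within a base or two of the true edge, which the
  refinement stage then fixes exactly.

Chance inverted repeats are abundant in random sequence at these
settings (tens per 10 kb). This is intentional: single-locus inverted
repeats are eliminated by the family stage (`min_copies = 3` by
default), not by the detector. Candidates overlapping by more than half
their span are reduced to the one with fewer TIR mismatches (tie:
longer TIR, then leftmost).

Circular genomes are scanned on a linearized copy extended by
`elem_max_len - 1` wrap-around bases; duplicate images beyond the
origin are dropped.

# Family building

`cluster_into_families()` performs single-linkage clustering: two
candidates are linked when a local alignment (either orientation)
reaches 80% identity with at least 80% coverage of both sequences. A
shared 11-mer prefilter (>= 5 common k-mers, both orientations) keeps
the number of alignments near-linear; pairs below ~75% identity cannot
reach the threshold and share essentially no 11-mers. Members are
oriented against the longest member of their cluster; after the
consensus is built, the lexicographically smaller of (consensus,
reverse complement) defines the family plus strand, so orientations are
reproducible run to run. Orientation must be decided per family rather
than per candidate: at a few percent divergence a single terminal
substitution can flip a per-candidate lexicographic choice and split a
family in two.

# Boundary refinement and TSD calling

`refine_boundaries()` aligns members extended by 100 bp of flank
(multiple alignments are computed with mafft, `--retree 2
--maxiterate 0`, deterministic and order-preserving; one standard,
well-tested aligner was preferred over a hand-rolled center-star
merge). Per-column conservation is the modal-base frequency; the family
core is the column set where at least half the members lie inside their
current calls — a per-column majority vote that already absorbs
per-copy boundary noise. Boundaries extend outward through conserved
(>= 0.8) columns, which recovers ends the initial TIR calls clipped.
If flank columns stay conserved for more than 20 columns the context
(tandem or segmental duplication) cannot define a boundary; the family
is flagged `boundary_indeterminate` and left unchanged.

Column refinement alone cannot resolve one genuine ambiguity: a
**palindromic TSD** (e.g. `TA`, `GC`) pairs with itself and is
indistinguishable from two extra TIR columns in any alignment — of the
copies or of the consensus. The only signal that locates the element
edge in that case is the duplication test itself: at the true boundary
the left flank suffix equals the right flank prefix at each insertion
site. The refinement therefore finishes with a TSD polish: each
member's two boundaries are micro-adjusted (up to 6 bp per end, in
element orientation) to offsets supported by a TSD call, the family
agrees on one TSD length (the length supported by the most members;
ties go to smaller mean offsets, then the longer length), and inward
moves may only excise residues from *unconserved* columns so a
conserved element terminus can never be relabelled as TSD.
Per-member rather than family-uniform offsets are required because the
aligner places per-site TSD residues in slightly different columns.

`call_tsd()` reports the longest exact direct repeat (2-10 bp) whose
left copy ends exactly at the element start and whose right copy begins
exactly at the element end. Exactness is deliberate: the TSD is a
literal duplication created at integration. The 2-10 bp window covers
every reported MITE TSD length with one-off headroom. The family TSD
length is the modal length across members; disagreeing members are
flagged, not dropped.

# Filters and classification

`apply_candidate_filters()` applies, in order: consensus longer than
800 bp (`too_long`); no TIR within the mismatch budget (`no_tir`);
fewer than two members with an identical-length TSD call (`no_tsd`);
consensus containing a >= 80% identity match covering >= 50% of another
family's consensus (`compound`). Families with a perfect >= 10 bp TIR
are exempt from the TSD requirement when the signature table carries a
TSD-less superfamily (IS200/IS605-like elements insert without target
duplication as far as is known; the exemption is flagged in output
rather than silently applied). The verdicts are pure functions of the
family, hence idempotent and order-independent.

`classify_superfamily()` matches the modal TSD length and the consensus
termini against an editable signature table
(`inst/extdata/superfamily_signatures.tsv`): hAT (8-bp TSD, no terminus
motif), hATm (8-9 bp TSD, `TAGGGTG`/`CACCCTA` termini, <= 1 mismatch),
CMC/CACTA (2-3 bp TSD, invariable `CAC`/`GTG`), Tc1/mariner (2-bp TSD
that must itself be `TA`), IS200/IS605 (no TSD, perfect >= 10 bp TIR).
Ties go to the longer terminus motif; no match yields `"Unknown"`,
named `Unk-NA#`.

`hairpin_pairing_score()` stands in for thermodynamic folding: the 5'
half is globally aligned to the reverse complement of the 3' half and
the match fraction returned. Random 200-mers score 0.46 on average
(Monte-Carlo, 1000 draws, sd 0.03); constructed stems score > 0.9.

# Quantification

`build_consensus()` is per-column majority over non-gap characters,
dropping columns under 50% occupancy, ties broken A < C < G < T.
`annotate_copies()` re-scans each genome with every family consensus
using the package's seed-and-extend engine (exact 11-mer seeds,
windowed local alignment, both strands). Hits below 70% identity are
ignored (the counting threshold is not standardized anywhere we know
of; 70% is exposed in `mask_params()`), hits shorter than 80 bp are
discarded as fragments too short to count, and copies covering less
than 80% of the consensus are labelled `fragment`. Per-family
statistics use interval unions so nested or overlapping hits are never
double-counted.

Per-copy divergence is the mismatch fraction over gap-free aligned
columns (pairwise deletion); `copy_divergence()` also implements the
Kimura two-parameter distance
`d = -1/2 log(1-2P-Q) - 1/4 log(1-2Q)` and reports saturation as an
error rather than `NaN`. The maximum-composite-likelihood distance used
by some desktop suites is substituted by p/K2P: composite likelihood
needs rate estimation that is not parameterized here, and at the
range level (copy-to-consensus distances of ~0.05-0.4) the model choice
does not move the numbers materially.

# Comparative analyses

Empty-site and orthologous-site detection anchor on element flanks (50
or 100 bp, >= 85% identity, flanks "adjacent" when separated by at most
15 bp — the tolerance for small indels at an excision/pre-insertion
site, exposed in `empty_site_params()`). This flank-anchored approach
replaces gene-synteny circle plots: it produces the same evidence
(orthologous empty sites) without requiring gene annotation, and it is
testable on synthetic data. A locus only counts as an empty paralog if
no copy of the same family lies between the flank hits.

`ht_presence_call()` declares a family present in a genome when the
best local alignment of the consensus reaches 60% identity over 60% of
the consensus length. BLAST bit-score/e-value thresholds are recorded
as provenance metadata in `ht_screen_params()` but never used:
e-values depend on the search engine and database size and do not
reproduce. Presence is monotone in both thresholds by construction.

# Autonomous partners

`link_autonomous_partner()` anchors on consensus similarity in the
scanned genomes, delimits 1-10 kb candidates by the best pair of
terminus windows (15 nt), and requires at least 8/15 matches per end
plus an open reading frame of >= 300 amino acids. The ORF floor
replaces a conserved-domain database search: transposases run ~370-620
aa, MITEs encode nothing, and 300 aa cleanly separates the two without
external databases. The 8/15 default reflects the observed range of
reported MITE/partner terminus matches (5-8/10 for loose pairings,
13/15 and 10/10 for confident ones); candidates at >= 13/15 are tiered
`"confident"`, the rest `"loose"`, rather than forced into a binary
verdict. A candidate whose internal sequence still aligns to the MITE
consensus at >= 70% identity is flagged as the family's
deletion-derivative source. `find_orfs()` is a plain ATG-to-stop
scanner on both strands; the stop codon is inside the reported span, so
`protein_length_aa = span/3 - 1` always.

`terminus_logo_matrix()` summarizes 30-nt windows across element
boundaries (15 nt flank including the TSD, 15 nt element) as base
frequencies plus information content `2 - H` bits per column.

# Phylogenetics

Copy trees use pairwise-deletion p-distances on a mafft alignment of
full-length copies (fragments are excluded with a logged count —
distance estimates from sub-half-length fragments are dominated by
missing data). Families over 50 copies are uniformly subsampled to 50
under the run seed. NJ agglomeration is delegated to `ape::nj`;
negative branch lengths are clamped to zero with the deficit moved to
the sister branch so path lengths through the parent are preserved.
Bootstrap supports resample alignment columns with replacement (1000
replicates by default), rebuild the NJ tree per replicate and count the
original bipartitions via `ape::prop.clades`; replicates that leave a
pair with no comparable sites are redrawn with a message. Monophyly is
tested at the bipartition level (a subset is monophyletic iff it or its
complement is a split of the unrooted tree), which is the claim an
unrooted NJ tree can actually support.

# Synthetic data and what passing tests mean

`simulate_genomes()` plants the full generative story: families with
perfect-TIR consensus sequences, per-copy substitutions at a configured
rate, TSD duplication at insertion, truncated copies (losing 20-60%
from one end), paralogous empty sites (flank junctions without the
element), an autonomous partner carrying the derived family's termini
and a transposase-scale ORF, and HT pairs planted across genomes at a
controlled cross-divergence with single- vs multi-transfer topologies.
Each insertion resamples on collision, shifts earlier coordinates
consistently, and is recorded in a truth table from which every
inserted sequence can be re-extracted exactly.

The default fixture mirrors the study scale the package targets: a
200 kb virus genome with three families of 40, 25 and 10 copies
(element sizes 300/180/420 bp, within the reported 116-422 bp range;
TSDs of 8 and 2 bp; 5% per-copy divergence; 10% truncation), plus a
2 Mb host carrying the 3 kb / 500-aa autonomous partner and five HT
copies at 10% cross-divergence. Background sequence is i.i.d. at 50%
GC.

Copies mutate by substitution only unless an indel mode is configured;
this keeps TIR and TSD calls exactly checkable while divergence-based
properties are still exercised. The generator does **not** emulate
genome composition (genes, isochores, repeats other than the planted
ones), insertion-site preferences, nested insertions, or assembly
artefacts. Passing recovery tests therefore demonstrates correctness
of the machinery under the stated element model, not robustness to
every property of real assemblies.

# Known limitations and edge behavior

* Families at the minimum copy number (3) with *short palindromic*
  TSDs sit at the edge of identifiability: with so few sites the
  duplication signal can be mimicked by chance flank agreement, and a
  boundary may settle a base or two off, occasionally costing the
  family its TIR call. From ~5-10 members the member majority makes
  this vanishingly rare.
* The IS200/IS605 TSD exemption is a modelling guess (the literature
  does not state a TSD for those elements here); it is flagged in
  output.
* Copy counting by local alignment clips terminal mismatches, so
  masking-derived boundaries can be off by a base or two; TSD accuracy
  is therefore assessed on refined family members, and reported copy
  counts are robust to the clipping.
* Element classes without TIRs (LTR retrotransposons, LINEs,
  Helitrons) are out of scope by design.

# Determinism and problem sizes

All alignment scoring is fixed (match +2, mismatch -3, gap open 5, gap
extend 2); every tie-break is documented and deterministic; a single
run seed fans out to per-stage seeds by stable hashing of stage names,
so stage results do not depend on execution order, and identical
configurations produce byte-identical TSV/GFF3/newick products.

The shipped test-suite exercises detection fixtures of 8-50 kb,
recovery at the full 200 kb default fixture, bootstrap checks at
100-200 replicates on 200-300 column alignments, and NJ exactness up
to 8 taxa by comparison with generating topologies; these sizes were
chosen to exercise every code path at the scale the statistics need,
while the package defaults (1000 bootstrap replicates, 50-copy cap)
remain the analysis-grade settings.
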
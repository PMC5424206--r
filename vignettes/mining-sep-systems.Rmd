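---
title: "Mining SepRS/SepCysS systems and genetic-code traits from metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SepRS/SepCysS systems and genetic-code traits from metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepmine)
```

## The inference problem

RNA-dependent cysteine biosynthesis charges tRNA^Cys^ with
*O*-phosphoserine (SepRS) and converts it on the tRNA to cysteine
(SepCysS, a PLP enzyme), with SepCysE scaffolding the complex in some
lineages.  Locating these systems in metagenome assemblies is not one
computation but a chain: (i) homologs must be collected at similarity
levels where a single fixed query misses most of the family, (ii) contigs
must be attributed to genomes so that a SepRS found on one contig can be
paired with a SepCysS on another, (iii) gene neighborhoods distinguish
operonic from merely co-binned partners, (iv) clade structure and
reference-anchored sequence features (active-site residues, indels,
truncations, tRNA identity elements) characterize what was found, and
(v) co-occurrence with pyrrolysine (Pyl) and selenocysteine (Sec)
machinery puts each genome's genetic code in context.  `sepmine`
implements that chain, and ships a synthetic-metagenome generator whose
ground truth lets every step be scored end-to-end.

## Iterative homolog search

`local_align()` is an exact Smith–Waterman local alignment with affine
gaps (BLOSUM62 by default; a gap of length $k$ costs `gap_open` $+ k\,$
`gap_extend`), carried out by Biostrings — no heuristic seeding, which is
affordable at desk scale and removes one source of irreproducibility.
The retention statistic is the BLAST-style *positives* percentage:

$$\mathrm{sim} = 100 \cdot \frac{\#\{\text{columns with substitution score} > 0\}}{\#\{\text{all alignment columns, gaps included}\}}$$

`iterative_search()` retains database sequences at `threshold = 40` (the
field's working anchor for this family's detectability) **and** query
coverage ≥ 0.6.  The coverage gate is ours: percent similarity over a
*trimmed* local alignment has a fat upper tail — a short conserved motif
can score > 50% between unrelated proteins — and without the gate the
expansion chains into unrelated families.  Retained hits are grouped by
single-linkage at 60% similarity; the medoid of each group is re-queried
until no new sequence is retained.  Raising the threshold can only
shrink the result (tested property).

Two reading notes, fixed deliberately: "similarity" is computed over
alignment columns with gap columns in the denominator (the closest
standard reading of a BLASTp positives percentage), and the pair order is
canonicalized before alignment so the statistic is exactly symmetric even
when several local alignments tie for the optimum.

## Contig binning and decontamination

`bin_contigs()` single-links contigs that satisfy **both** hard gates
|ΔGC| ≤ `gc_tol` (0.025) and |Δlog₂ depth| ≤ `depth_tol_log2` (0.5);
contigs shorter than `min_len` (2 kb) stay unbinned, and zero-depth
contigs get a pseudo-depth of 0.01 with a warning.  Depth is compared on
the log scale because coverage noise is multiplicative.  Hard gates were
chosen over model-based clustering because the original analysis of this
kind was threshold-like and manual, and gates are auditable: every link
can be explained by two numbers.  `purge_conflicts()` generalizes ad hoc
contaminant removal into one rule — the modal marker taxon of a bin is
its identity; marker-labeled contigs disagreeing with it are removed;
ties remove nothing and warn.

## Gene pairing

`call_operons()` merges same-contig, same-strand genes whose intergenic
gaps are ≤ `max_gap` (150 nt; "vicinity" made operational, exposed as a
flag).  `pair_systems()` then pairs each SepRS with all SepCysS genes at
the strongest available evidence level — operon, then contig, then bin —
so a genome carrying two SepCysS copies on different contigs yields one
record with two bin-level partners.  Pairing never crosses bins; SepRS
without a partner anywhere in its bin, and SepCysS without a SepRS, are
reported unpaired rather than force-matched.

## Alignment, trees and clades

`build_msa()` is classic progressive alignment: 3-mer distances → UPGMA
guide tree → profile–profile global alignment with the same affine
scoring as the search (the inner dynamic program is compiled C++).  With
two sequences it reduces exactly to the optimal global pairwise
alignment, which is how it is tested.  `protein_distance()` applies the
20-state Poisson correction $d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$
over shared non-gap columns, capped at 5.0 at saturation; `nj_tree()` is
standard neighbor joining (ape) with negative branches clamped to zero;
`ml_optimize()` optimizes branch lengths and (by NNI) topology under JTT
with uniform rates via phangorn.  Alignment gaps enter the likelihood as
missing data — every state equally likely at the site — which is the
"use all sites" reading; `complete_deletion = TRUE` is available for the
other reading.  `bootstrap_support()` resamples columns (default 100
replicates), re-runs distance + NJ + ML per replicate, and reports the
percentage of replicates containing each internal split.

Clade delineation on real trees is usually done by eye.  To make it
testable, `partition_clades()` defines clades operationally:
single-linkage clusters at ≥ 50% similarity, with clusters of at least
`min_clade_size = 3` members called major clades and everything smaller
called orphans.  `assign_to_reference_clades()` gives each query the
label of its most similar labeled reference when that similarity reaches
50%, and `"novel"` otherwise.  The ML tree with supports is still
emitted for inspection; the similarity partition is what the automated
checks consume.

## Feature rules

`evaluate_features()` works in reference coordinates via
`map_reference()`: the reference row's non-gap columns are numbered
1…L, and rules address those numbers.  The synthetic references adopt
the archaeal clade-I numbering convention (loop 144–147, indel junction
234/235, residue 444 in SepRS), so the rules read naturally:

* *PLP conservation* — member matches the reference residue at every
  PLP-binding position;
* *persulfide count* — cysteines among the three listed positions (0–3);
* *loop 144–147* — absent iff **all** spanned columns are gaps;
* *indel 234/235* — member minus reference residue count over a window
  of `flank = 8` reference positions on each side of the junction plus
  any inserted columns between them.  The window form makes the measure
  invariant to exactly where inside the window the aligner placed the
  event, and to all-gap columns elsewhere;
* *residue 444* — hydrophobic {A,I,L,M,F,V,W,Y}, hydrophilic
  {D,E,N,Q,K,R,S,T,H}, otherwise `other`; a gap reports `deleted`.

`detect_seprs_truncation()` calls ΔC when the local alignment to the
reference covers < 50% of the C-terminal anticodon-binding span while
covering ≥ 60% of the catalytic span (conservative span-coverage gates;
both exposed).  `classify_sepcysE_homolog()` distinguishes the
full-length scaffold, the short stand-alone N-domain gene preceding
SepCysS (`split_n`), and the N-domain fused to SepCysS (`fused_N`) with
similar gates (match ≥ 40% similarity at ≥ 60% model coverage; fused
N-match inside the first 120 residues; split genes < 150 aa).
`classify_trna()` does not fold tRNAs: the anticodon position comes from
annotation, and N37 is simply the base 3′ of it — with explicit no-calls
when the annotation is missing or truncated.

## The synthetic study system

`generate_metagenome()` emulates the statistical structure the inference
assumes, not sequencing physics.  Eight genome presets span GC 0.32–0.67
in steps of 0.05 and coverage 10–1280× in factors of two, so any two
genomes differ by at least one binning gate with wide margins.  Each
genome plants its systems as loci on dedicated contigs (coding ≤ ~30% of
the contig; intergenic composition is *compensated* per contig so the
contig hits the genome GC target in expectation despite the constrained
GC of back-translated codons).  Planted content covers: the compact
tRNA^Cys^–SepCysSn–SepCysS–SepRS operon; contig- and bin-level pairing
including a two-copy SepCysS genome; an unpaired SepRS; SepRS-ΔC with a
persulfide-free SepCysS and both tRNA^Cys^ variants (A37 and G37);
bacterial-type features (Asp444, missing loop, −8 indel); full, split
and fused SepCysE; all three Pyl architectures with accessory clusters;
and the four-selenoprotein Sec trait twice, once with a split SPS.
Truth tables record every contig's genome, every gene's family and
clade, expected pairings with their evidence level, per-protein feature
values, per-genome traits and tRNA identities.

Protein families evolve under a 20-state uniform substitution process
(expected identity $\tfrac1{20} + \tfrac{19}{20}e^{-\frac{20}{19}d}$ at
distance $d$ — a closed form the generator is tested against), chosen
over JTT deliberately so the generator does not share a model with the
ML inference it validates.  Indels and diagnostic residues are planted,
not sampled; feature sites are re-imposed after substitution so they
cannot drift unless a plan says "absent".

**Divergence calibration.**  The literature anchor for this family is a
working figure of ~40% similarity between distant relatives, with
searches succeeding by iterative expansion; no quantitative divergence
levels for clades exist.  The defaults were therefore calibrated once on
the generator and frozen: within-clade similarity ~75–85%
(`d_within = 0.14`, SepCysS 0.10) and cross-clade similarity in the low
40s (SepRS/PylRS `d_between = 0.45`, orphans 0.55) — straddling the 40%
retention threshold from above while staying below the 50% partition
threshold.  Because raw evolutionary wander blurs these bands, lineage
seeds are drawn *banded*: candidates are redrawn until their realized
divergence is within ~3% of expectation and their pairwise similarity
falls inside the model's `sim_band`.  SepCysS, with seven clades and
therefore many more lineage pairs under the 50% threshold, uses a larger
`d_between = 0.68` and a lower band.  Conserved anchor residues flank
the 144–147 loop and the 234/235 junction so planted indels align
unambiguously.

**What passing does and does not show.**  The generator has uniform
intergenic composition, no repeats, no strain mixtures, no chimeric
contigs, no assembly error, idealized depth noise (lognormal, σ = 0.1)
and planted annotations.  Recovery here demonstrates that the pipeline's
logic is correct under the assumptions the original analysis made; it
does not certify performance on real assemblies, where binning and gene
calling dominate the error budget.

## Numerical choices and degenerate inputs

Distances cap at 5.0 substitutions/site; pairs with no shared columns
warn and return the cap.  ML branch optimization runs to tolerance 1e-6
with NNI moves accepted only on improvement; likelihood never decreases
across accepted moves (tested).  Ambiguity codes beyond X/N are rejected
at IO rather than remapped.  Alignment score ties are broken by the
alignment engine deterministically; the tested contract is score
optimality (verified against exhaustive enumeration on short
sequences).  Group and bin ids are dense from 1, numbered by first
member in input order, making results permutation-invariant up to
relabeling.  Empty databases, empty alignments, single-sequence MSAs,
zero-depth contigs, tied marker votes, missing tRNA annotations and
out-of-range rule positions all have defined behavior (empty result,
error, or warning + no-call) covered by tests.

## Problem sizes

The shipped presets are sized for a single CPU: ~30 SepRS, ~40 SepCysS
and ~21 PylRS sequences for the clade analyses, and a ~0.8 Mb, ~100
contig, 8-genome metagenome for the pipeline analyses.  The full test
suite runs in ~3 minutes; `scripts/acceptance.R` in ~2.
Tree inference is intended for ≤ ~200 taxa; gamma rate heterogeneity,
model selection and Bayesian inference are out of scope.

## Known limitations

* Single-linkage at a fixed 50% similarity is a knife-edge definition of
  a clade: one cross-clade pair cresting the threshold merges two
  clades.  With the shipped presets this is rare but not impossible at
  arbitrary generator seeds; the acceptance script therefore evaluates
  clade structure on the shipped preset realizations, which is also how
  the presets are defined.
* Pairing never crosses bins, by design; a SepCysS on an unbinned contig
  is invisible to pairing even when the right partner is obvious.
* Sec detection is homology-level only (no in-frame-UGA gene calling,
  no SECIS elements); Pyl methyltransferase subtypes are labels.
* The CLI's `phylo` subcommand with the default 100 bootstrap replicates
  is the slowest step and scales with alignment length × replicates.
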
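---
title: "Tracing B-cell lymphoma relapse with VDJ repertoires and paired exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing B-cell lymphoma relapse with VDJ repertoires and paired exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaltrace)
```

## The scientific problem

Diffuse large B-cell lymphoma (DLBCL) relapses frequently, and whether a
relapse regrows from the bulk of the diagnosed tumor or from a rare,
pre-existing subclone changes what a rational therapy should target. Mature
B-cell tumors carry a built-in lineage barcode that most cancers lack: every
B cell performs one VDJ recombination at the immunoglobulin heavy-chain (IGH)
locus -- one V, one D and one J segment joined with exonuclease trimming and
non-templated (N) junction bases -- and germinal-center B cells then accumulate
somatic hypermutation (SHM) inside the rearranged sequence. The (V, D, J)
combination identifies the malignant clone; the SHM pattern inside the
dominant rearrangement subdivides it into subclones and records their
genealogy.

`clonaltrace` implements the full analysis built on this idea for matched
diagnosis--relapse pairs:

1. **VDJ annotation** of deep paired-end amplicon reads against a germline
   segment library (seeded, ungapped local alignment; triple-hit filter).
2. **Clonality profiling**: counts of unique rearrangements, unique
   rearrangements per $10^3$ mapped read pairs, and the one or two dominant
   rearrangements per sample.
3. **SHM subclone tables** within the dominant rearrangement, with the
   standard inclusion filters (at least 10 supporting reads, at least 80%
   germline identity), Shannon entropy as a diversity measure, mutational
   distances, and the fate of the major diagnosis subclone at relapse.
4. **Phylogenetics**: neighbor-joining trees over selected subclone SHM
   profiles, rooted at the germline (mutation-free) outgroup, and a testable
   classification of each pair as *early-divergent* (relapse grown from a
   subclone that split off long before the diagnosis major expanded) or
   *late-divergent* (relapse within one or two SHM of the diagnosis major).
5. **Paired-exome analysis**: gained/lost SNV calling from per-site read
   counts (2x2 test + Benjamini--Hochberg control at 10% FDR), exon-level
   copy-number segmentation by circular binary segmentation (CBS), and a
   coordinate sweep for regions deleted in several relapse samples.
6. **Ultra-deep resequencing**: per-class background-error models
   (mean $\pm$ s.d. over same-class control positions of the amplicon) and a
   minor-clone detection rule, with the detection-limit arithmetic
   (20 supporting reads in two million is 0.001%).

A synthetic-data generator produces every input with known ground truth, so
each stage -- and the end-to-end mode classification -- is validated as
parameter recovery.

## The generator: what it emulates

`simulation_config()` fixes the study conditions. A tumor pair shares one
rearrangement drawn from a toy germline library (default 20 V / 10 D / 6 J
segments with class-typical lengths; any user FASTA with IGHV/IGHD/IGHJ ids
is accepted instead). SHM accumulates along a discrete-generation branching
genealogy: each generation adds at least one new substitution per lineage
(Poisson around `shm_rate` $\times$ length, default rate 0.003/base/generation
on a ~300 nt amplicon, i.e. about one mutation per generation). Mutation
positions are globally unique within a simulation, so symmetric differences
between profiles count branch-private mutations exactly.

The two relapse modes differ in where the relapse lineage attaches:

* **late-divergent** -- the relapse major is the diagnosis major plus 1--2
  substitutions; the diagnosis major profile persists in the relapse sample
  (mean retained frequency 0.30); minor subclones are shallow 1--2-mutation
  variants of their major, so relapse subclone mass concentrates within 1--2
  mutations of the diagnosis major.
* **early-divergent** -- diagnosis and relapse majors sit on branches that
  split `divergence_depth` (default 6) generations before the diagnosis
  expansion, each accumulating that many private mutations; the relapse
  major is planted in the diagnosis sample at 0.2% (the order of magnitude
  at which ultra-deep resequencing finds relapse precursors); the diagnosis
  major is nearly extinct at relapse (0.2%); minors branch at random depths,
  giving the flatter, more diverse subclone distribution observed for
  early-divergent diagnoses (major frequency 0.45 vs 0.70).

Thirty polyclonal background clones with their own rearrangements make up
30% of each sample, so dominant-rearrangement percentages land near the
65--70% typical of clonal tumors rather than a degenerate 100%. Reads are
2 x 150 nt pairs with i.i.d. substitution error (default 0.002/base) and flat
qualities. Exome truth uses mode-dependent gain/loss balances (44 gained / 8
lost per 150 sites late; 32 / 36 early, matching the observed imbalance
between modes), binomial counts at Poisson ~65X depths. Exon profiles embed
log2-shift segments over a Gaussian-dispersed baseline; pileups plant a
minor clone over a 3e-4 per-class background at two million reads.

**What it does not emulate** (so passing tests bound, but do not prove,
behaviour on real data): read indels and quality-dependent errors, PCR
amplification bias and chimeras, allele-level (\*01-style) germline variants,
class-switch and light-chain loci, mutation hot-spot motifs (AID targeting),
sharing of SHM positions between independent branches, exome alignment and
variant-calling artifacts, and GC-content or mappability structure in exon
counts.

## Key parameters (defaults are the analysis constants)

| parameter | default | meaning |
|---|---|---|
| `min_count`, `min_identity` | 10 reads, 0.80 | subclone inclusion filters, both boundaries inclusive |
| annotation seeds | k = 12 (V, J), k = 8 (D) | exact-seed lengths; the short D word is what makes 10--40 nt D segments findable |
| class score minima | V 40, D 8, J 20 | ungapped +1/-1 score floors for the triple-hit filter |
| `top_k`, `n_random` | 10, 5 | subclones per sample entering the tree: top-10 by Jaccard similarity to the other sample's major, top-10 by abundance, 5 random minors |
| `d_min` | 3 mutations | mutual exclusive-mutation threshold (and clade-proximity radius) for calling early divergence |
| `min_depth`, `min_vaf` | 20X, 0.25 | per-site variant filters, satisfied in at least one sample |
| FDR `q` | 0.1 | BH step-up level for gain/loss significance |
| `min_total_reads` | 100 (strict >) | exon coverage filter before smoothing |
| `alpha`, `nperm`, `undo_sd` | 0.01, 1000, 1.5 | CBS split significance, permutations, undo threshold in residual s.d. |
| gain/loss thresholds | +0.3 / -0.3 (strict) | segment mean log2-ratio classification |
| `k`, `min_support` | 3 s.d., 20 reads | minor-clone detection rule |

## Design choices where the method description was open

* **Pair handling.** Overlap merging is attempted first (staggered 16-mer
  seeds from both mates; consensus takes mate-1 bases at disagreements under
  flat qualities). 2 x 150 nt reads on a 300--350 nt product often do not
  overlap; unmerged pairs are annotated with mate 1 carrying V and the
  reverse-complemented mate 2 carrying D and J, required in D < J order. The
  template length of an unmerged pair is recovered from the V hit on the
  reverse mate: V is never trimmed at its 5' end, so it anchors template
  coordinate 1 and `T = length(mate2) - (qstart - rstart)`. Reads whose
  inferred template length disagrees with the sample consensus stay in the
  rearrangement counts but are excluded from subclone profiling.
* **Germline reference reconstruction.** The unmutated VDJ reference of a
  dominant rearrangement is rebuilt from the reads themselves: germline
  segment bases are projected along each read's hit diagonals (outward from
  the junctions only) and combined by count-weighted majority; junction
  columns that no hit covers use the majority read base, which all clones of
  a rearrangement share. A handful of junction-adjacent columns can remain
  ambiguous; because every read of the rearrangement is compared against the
  *same* reference, pairwise mutational distances, subclone identity classes,
  entropy and fate are invariant to such consistent reference errors -- only
  absolute identity shifts by a base or two in ~350.
* **Mutational distance and trees.** Distances are symmetric differences of
  SHM profiles on the shared reference (equivalent to alignment-column
  mismatch counts, without re-running a multiple aligner). Neighbor joining
  is the standard Saitou--Nei agglomeration; negative branch lengths are
  clamped to zero; trees are rooted at the germline (empty-profile) leaf.
* **The divergence call.** "Clusters in a separate branch" is made
  operational: early-divergent iff the clade at the relapse major's parent
  node excludes the diagnosis major and contains no diagnosis subclone
  within `d_min` mutations of it, *and* both majors carry at least `d_min`
  exclusive mutations. Late pairs fail the mutual-exclusivity condition by
  construction (at most 2 differing mutations); `d_min = 3` sits between
  the two regimes and is configurable.
* **Chi-square vs exact test.** Both are implemented; the chi-square (no
  continuity correction) is the default. The FDR-calibration experiment uses
  the exact test: BH's guarantee assumes valid per-site p-values, and the
  chi-square approximation is anti-conservative in the far tail that the
  minimum over a thousand null sites probes.
* **"Standard deviation > 1.5"** is read as the CBS undo-splits parameter
  (adjacent segments closer than 1.5 residual s.d. are re-merged), the
  standard role of that constant in CBS practice.
* **Smoothing** is a centred running-median/MAD shrink (window 5, 3 MADs);
  with a locally constant profile the MAD is zero and an outlier collapses
  to the window median.
* **Entropy** is reported in bits; only cross-sample comparisons matter and
  these are base-invariant. Identity is measured against the full assembled
  VDJ reference. A subclone is an exact SHM-profile equivalence class; no
  near-identity clustering. Mutation positions are 1-based throughout,
  rendered `pos:ref>alt`.
* **Counting unit** is the read pair. Samples with two dominant
  rearrangements are analysed per rearrangement (pass `key =` to
  `sample_subclones()`).
* **Pileup reference base** is inferred as the per-position majority allele,
  keeping the pileup TSV to its plain count columns.
* **D-segment trimming** in the generator leaves at least 10 nt of D (the
  shortest germline D): a shorter remnant is unseedable by construction for
  any junction-annotation method that requires a D hit.
* **Degenerate inputs.** `shm_rate = 0` produces mutation-free clones (the
  per-generation mutation floor applies only at positive rates). Empty
  subclone tables are legal results of filtering, but entropy and tree
  building on them raise errors. All-zero 2x2 tables raise; zero-margin
  tables return p = 1. A zero-s.d. background detects any frequency above
  its mean, support permitting.

## Numerical scale of the validation

The shipped tests and `scripts/acceptance.R` run at sizes chosen to make the
properties sharp on a single CPU: 100 simulated pairs (50 per mode) for mode
recovery; 20 pairs per mode for the entropy, fate and gain:loss contrasts;
$10^5$ read pairs (with 10x and 100x thinning) for subsampling stability;
1000 random 2x2 tables and 1000 random p-vectors against brute-force
oracles; 20 random additive 5-taxon matrices against an exhaustive
15-topology search; 100 seeded CBS runs on 100-exon profiles; 200 null
replicates of 1000 sites for FDR calibration; 25 replicates of two-million-
read pileups for minor-clone detection. End-to-end pipeline checks use 3000
read pairs per sample.

## Known limitations

* The annotator is ungapped: read indels (not simulated, and excluded from
  SHM profiles by design) would fragment hits rather than shift them.
* D assignment is intrinsically fragile when little of D survives trimming;
  the generator's 10 nt floor acknowledges rather than solves this.
* The divergence rule assumes both majors are observable in their subclone
  tables; a relapse whose major fails the 10-read/80%-identity filters
  cannot be classified.
* CBS permutation p-values are resolution-limited by `nperm`; splits with
  true p near `alpha` are decided conservatively (early stopping only
  rejects, never accepts, a split).
* The cohort-level heterogeneity statistics ship as a reference summary
  table; they are cohort description, not something recomputable from
  synthetic data.
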
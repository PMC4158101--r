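# clonaltrace

Clonal-evolution analysis of matched diagnosis–relapse B-cell lymphomas from
immunoglobulin VDJ repertoires and paired exomes.

Mature B-cell tumors carry a natural clonality barcode: the heavy-chain VDJ
rearrangement tags the malignant clone, and somatic hypermutation (SHM)
accumulating inside the rearranged sequence records the genealogy of its
subclones. `clonaltrace` uses both to ask how a relapse arose: directly from
the major diagnosis clone (**late-divergent** — the relapse major differs by
only 1–2 SHM and the diagnosis major persists at relapse) or from a rare
subclone that split off early (**early-divergent** — majors separated by many
mutually exclusive SHM, the diagnosis major nearly extinct at relapse, and
the relapse precursor sometimes detectable at ~0.1–0.2% of the diagnosis
sample by ultra-deep resequencing).

The package provides, as plain R functions over data frames and standard
formats (FASTA/FASTQ, TSV, Newick, JSON):

- **VDJ annotation** of deep paired-end amplicon reads by exact k-mer
  seeding (k = 12 for V/J, k = 8 for the short D segments) with ungapped
  +1/−1 extension against a germline segment library; reads lacking any of
  the three hits, or with hits out of V<D<J order, are filtered.
- **Clonality profiling** — unique (V, D, J) combinations, unique
  rearrangements per 10³ mapped pairs, dominant rearrangements with
  percentages (`count_rearrangements()`, `dominant_rearrangements()`,
  `subsample_reads()`).
- **SHM subclone analysis** within the dominant rearrangement —
  subclone tables under the ≥10-read / ≥80%-identity filters, Shannon
  entropy (bits), mutational distance (symmetric difference of SHM sets),
  major-clone fate, distance spectra.
- **Phylogenetics** — neighbor-joining trees over selected subclone
  profiles, germline-rooted, and the early/late divergence call
  (`analyze_pair()`, `classify_divergence()`).
- **Paired-exome evolution** — ≥20X / ≥25% variant filters, chi-square or
  Fisher 2×2 tests with Benjamini–Hochberg control at 10% FDR and
  gained/lost classification; exon log2-ratio smoothing, circular binary
  segmentation (implemented in the package), strict ±0.3 gain/loss
  thresholds, and recurrent-deletion sweeps across samples.
- **Ultra-deep resequencing** — per-class background error models
  (mean ± s.d.), a mean + 3·s.d. / ≥20-read minor-clone detection rule, and
  the detection-limit arithmetic (20 reads in 2,000,000 → 0.001%).
- **A synthetic-data generator** (`simulation_config()`,
  `simulate_tumor_pair()`, `simulate_reads()`, `simulate_variant_table()`,
  `simulate_exon_counts()`, `simulate_amplicon_pileup()`) that produces every
  input with known ground truth, so the whole pipeline is validated as
  parameter recovery.

See the vignette (`vignettes/clonal-evolution.Rmd`) for the model, the
generator's assumptions, and every design decision.

## Worked example

Simulate an early-divergent diagnosis–relapse pair and run the full
pipeline end to end:

```r
library(clonaltrace)
res <- run_pipeline(simulation_config(seed = 102, mode = "early_divergent",
                                      n_read_pairs = 3000L))
print(res$report)
```

```
pair_report (seed 102, simulated mode early_divergent)
  diagnosis: 2984 mapped, 9.72 unique/10^3, dominant IGHV5-01 IGHD10-01 IGHJ5-01 (70.8%), 9 subclones, entropy 2.58 bits
  relapse:   2984 mapped, 10.39 unique/10^3, dominant IGHV5-01 IGHD10-01 IGHJ5-01 (70.4%), 8 subclones, entropy 2.26 bits
  call: early_divergent (distance 13, fate 0.000)
  exome: 32 gained / 38 lost (ratio 0.842); 2 CNA segments
  deep reseq: 0.2296% vs background 0.0297% +/- 0.0014% -> detected
```

Reading the report: both samples share the dominant rearrangement
`IGHV5-01 IGHD10-01 IGHJ5-01` at ~70% of mapped pairs (they are clonally
related), but the major subclones' SHM profiles differ at 13 sites and the
diagnosis major's exact profile has frequency 0.000 at relapse — the relapse
grew from an early-diverged subclone, which the classifier calls
`early_divergent`, in agreement with the simulation truth (`res$truth$mode`).
Consistently, the exome gained and lost similar SNV numbers (ratio 0.84;
late-divergent pairs give ratios near 4–5), and ultra-deep resequencing finds
the planted 0.2% relapse-precursor clone at diagnosis against a 0.03%
background conversion rate. The diagnosis subclone table behind those
numbers:

```r
head(as.data.frame(res$diagnosis$subclones)[, c("n_mutations", "count",
                                                "frequency", "identity")], 5)
```

```
  n_mutations count frequency identity
1          16   491    0.4281    0.952
2          16   133    0.1160    0.952
3          12   124    0.1081    0.964
4          14   111    0.0968    0.958
5          13    95    0.0828    0.961
```

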
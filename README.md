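# dhsdyn

Open chromatin — regions hypersensitive to DNase I digestion (DHS sites) —
reorganizes extensively as cells differentiate. Profiling DNase-seq peaks
across staged differentiation (e.g. proliferating pre-osteoblasts, matrix
depositing and mineralizing osteoblasts) raises a chain of recurring analysis
questions: which peak calls are reproducible across biological replicates?
How many accessible sites are shared between stages, and how many are gained
or lost at each transition? Where do the dynamic sites fall relative to gene
structure (promoters, exons, first introns, intergenic space)? How often do
they coincide with transcription-factor occupancy (here RUNX2 and CTCF ChIP
peaks)? And do localized accessibility signals just downstream of transcript
end sites (TES+500 / TES+1000) track expression changes?

`dhsdyn` implements that pipeline as a tested, reusable R package in
Bioconductor style (S4 classes over `GenomicRanges`), together with a
seeded synthetic-data generator that plants known ground truth for every
stage of the analysis, so the whole pipeline is validated end to end by
planted-truth recovery and per-base oracle tests.

## The core operations

All coordinates are BED-convention 0-based half-open on disk and `GRanges`
1-based closed in memory; overlap means ≥ 1 shared bp throughout.

* **Replicate consensus** — for the connected components of mutually
  overlapping peak calls from two biological replicates, every component
  supported by *both* replicates contributes its merged span; calls present
  in a single replicate are treated as false positives and discarded.
* **Stage Venn** — the "unique site" universe is the merged union of all
  stage consensus sets; each universe region is flagged per stage it
  overlaps, and pattern counts partition the universe exactly.
* **Gained/lost sites** — `lost = from-sites with no overlap in to`,
  `gained = to-sites with no overlap in from`, with the conservation
  identities `n_lost + n_shared_from = |from|` and
  `n_gained + n_shared_to = |to|` and the loss/gain ratio.
* **Genomic partitions** — promoter (TSS −2000/+500, strand-aware,
  configurable), coding exon, intron (first vs later, in transcription
  order) and intergenic footprints; peaks are counted non-mutually
  exclusively in every category they touch.
* **Regulome overlap** — per-stage Venn counting of DHS × RUNX2 × CTCF
  co-occupancy, reported from both the DHS side and the TF side.
* **Signal profiles** — fixed-bin (25 bp) coverage tracks, optionally masked
  to consensus peaks; strand-aware TES ± 2 kb profile matrices with
  leftmost-maximum summits; quantile-scaled metagene profiles; and
  summit-window classification of genes into TES+500 / TES+1000 / NONE
  groups.
* **Expression classes** — inclusive two-fold pseudocounted fold-change
  classification (UP/DOWN/UNCHANGED) and cross-tabulation against the
  TES-flank groups.

## Worked example

```r
library(dhsdyn)

design <- syntheticDesign(seed = 42)   # 3 stages x 2 replicates, planted truth
gs     <- generateSynthetic(design)
report <- runBundle(gs$bundle)

report$consensus_counts
#>  d0  d9 d28
#> 236 213 218

report$venn_counts
#>        d0    d0&d28     d0&d9 d0&d9&d28       d28        d9    d9&d28
#>        73        21        31       111        61        46        25

report$comparisons$d0_to_d9[c("n_lost", "n_gained", "loss_gain_ratio")]
#> $n_lost: 94   $n_gained: 71   $loss_gain_ratio: 1.32

round(report$regulome$d9$fractions, 3)
#>       with_either      runx2_in_dhs       ctcf_in_dhs runx2_outside_dhs
#>             0.484             0.627             0.696             0.373
#>  ctcf_outside_dhs
#>             0.304

report$tes_group_sizes
#>  TES_PLUS_500 TES_PLUS_1000          NONE
#>            50            50           100

report$crosstab
#>            group
#> class       TES_PLUS_500 TES_PLUS_1000 NONE
#>   UP                   0            43    0
#>   DOWN                44             0    0
#>   UNCHANGED            6             7  100

verifyTruth(report, gs$truth)$tes_recovery
#> [1] 1
```

Reading those numbers: of 368 merged-union unique sites, 111 are common to
all three stages and 180 are stage-exclusive; the first transition loses
more sites than it gains (ratio 1.32); at the middle stage 48.4% of DHS
sites carry RUNX2 and/or CTCF; all 100 genes planted with a TES-flank
accessibility bump are recovered into their planted group, and the
expression cross-tabulation concentrates UP genes in the TES+1000 column
and DOWN genes in the TES+500 column — the planted association, recovered
at its 0.9 planting fidelity.

The same pipeline runs from files (`runPipeline(config)` with BED/bedGraph/
TSV inputs; see `?validateConfig`), and
`inst/scripts/dhsdyn-cli.R` exposes `generate` / `run` / `verify` / `report`
subcommands for shell use.

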
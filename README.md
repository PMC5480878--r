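# clonetrack

Clonal IGH amplicon sequencing analysis for follicular neoplasia.

## What this package is for

Clonal, t(14;18)-positive B cells confined to germinal centers (*in situ*
follicular neoplasia, a follicular-lymphoma precursor) can be characterised
by targeted sequencing of their rearranged immunoglobulin heavy-chain (IGH)
gene: ongoing somatic hypermutation (SHM) shows up as intraclonal sequence
diversity, and cell migration between follicles and lymph nodes
("follicular trafficking") shows up as the same subclones appearing in
multiple microdissected samples.

`clonetrack` implements the complete analysis for a consensus-primer IGH
framework-2 (FR2) amplicon assay sequenced as non-overlapping paired-end
reads (2 × 112 bp over a 268 bp amplicon, the 44 unsequenced interior bases
bridged by `N`s):

* **read processing** — barcode demultiplexing, primer trimming, per-base
  quality filtering (phred > 20), gap-aware mate merging, dereplication,
  and a 0.1% unique-read frequency noise floor;
* **V(D)J annotation** — ungapped ends-free alignment to an annotated
  germline reference (V/J calls with % identity, D resolution, CDR3 and
  junction at the conserved Cys/Trp anchors, productivity);
* **clone discrimination** — each unique sequence is compared with the
  patient's monoclonal reference rearrangement (same V and J gene, same
  CDR3 length, CDR3 amino-acid identity ≥ 0.70);
* **subclone grouping** — exact partition of clone-specific sequences by
  CDR3 amino-acid sequence (productive and unproductive kept apart);
* **SHM / antigen-selection statistics** — per-region mutation calls,
  replacement/silent (R/S) ratios per CDR and framework region (compared
  against the 2.845 germline expectation), substitution spectra with a
  formalin-deamination artifact flag, and Asn-X-Ser/Thr N-glycosylation
  sequon scanning;
* **genealogy & trafficking** — neighbor-joining tree of group consensus
  sequences rooted at the germline, nearest-to-germline (founder) report,
  and the group × sample trafficking matrix with
  interfollicular/internodal sharing classification.

Because no raw data exist for the study design this emulates, the package
includes a first-class synthetic-data generator (`simulation_config()`,
`simulate_run()`) that produces barcoded paired-end reads from a simulated
SHM lineage distributed across microdissected-follicle samples, with full
ground-truth labels. Everything is tibble-in / tibble-out and composes with
the pipe; fitted results have `tidy()` / `glance()` methods and
`autoplot()` figures.

## Worked example

```r
library(clonetrack)

cfg <- simulation_config(seed = 1, n_samples = 4, n_groups = 5,
                         n_unproductive = 1, group_sizes = c(4, 3, 2, 2, 2),
                         coverage = 2000, contamination = c(0.2, 0.5),
                         migration_rate = 0.3)
sim <- simulate_run(cfg)   # reference + lineage + follicles + reads + truth
res <- run_pipeline(sim)   # the full analysis
res
#> <clonetrack_result>
#>   samples:            4 (4 evaluable)
#>   clone groups:       8 (29 unique clone sequences)
#>   clone-specific:     61.3% of merged reads
#>   R/S (CDR | FR):     10.68 | 1.14
#>   shared groups:      62%; nearest to germline: G3
```

Four samples were sequenced at 2,000 pairs each with 20–50% contaminating
reactive-B-cell reads; 61.3% of merged reads are clone-specific. The five
simulated CDR3 groups are recovered (plus three small error-derived
singleton/doubleton groups — sequencing error is on in this run, and rare
variants that survive the noise floor form their own groups, as real
outlier reads do):

```r
res$groups
#> # A tibble: 8 × 5
#>   group_id cdr3_aa     productive n_members total_count
#>   <chr>    <chr>       <lgl>          <int>       <int>
#> 1 G1       ARNGSGWMFSY TRUE              16        1514
#> 2 G2       ARNGSAWYPLY FALSE             10         823
#> 3 G3       ARNGSGWYFDY TRUE              11         822
#> 4 G4       AINGSKWYFDY TRUE               5         394
#> 5 G5       ARNGSGWYEDY TRUE               2         218
#> 6 G6       ARNGSGWYFDY FALSE              2           4
#> 7 G7       AINGSKWYCDY TRUE               1           2
#> 8 G8       ARNGSGWYFAY TRUE               1           2
```

`G3` carries the founder CDR3 (`ARNGSGWYFDY`, which contains the N-X-S/T
glycosylation sequon `NGS`) and is reported as genetically closest to the
germline — the origin of the genealogical tree. The CDR R/S ratio (10.7)
far exceeds the framework ratio (1.14), which sits below the 2.845 germline
expectation: the signature of antigen selection with a structurally
conserved receptor. Per-sample composition and sharing:

```r
res$composition        # totals, % clone-specific, % unproductive, evaluability
tidy(res)              # per-group table incl. sharing class and germline distance
glance(res)            # one-row summary
autoplot(res$trafficking)   # group × sample heatmap
plot(res$rooting$tree)      # germline-rooted genealogy
```

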
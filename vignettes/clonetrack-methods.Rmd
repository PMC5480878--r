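---
title: "Methods: clonal IGH amplicon analysis with clonetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal IGH amplicon analysis with clonetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrack)
```

## The problem

*In situ* follicular neoplasia (ISFN) consists of clonal, t(14;18)-positive
B cells confined to germinal centers of otherwise reactive lymph nodes — a
precursor of follicular lymphoma. Two hallmarks of the manifest lymphoma can
be interrogated at this precursor stage with targeted sequencing of the
rearranged immunoglobulin heavy-chain (IGH) locus: **ongoing somatic
hypermutation** (SHM), visible as intraclonal sequence diversity, and
**follicular trafficking**, visible as the same subclones appearing in
multiple microdissected follicles and lymph nodes.

`clonetrack` implements the full analysis for a consensus-primer IGH
framework-2 (FR2) amplicon assay sequenced as short paired-end reads:

1. **Read processing** — demultiplexing by sample barcode, primer trimming,
   per-base quality filtering, merging of the mates across the unsequenced
   amplicon interior with an `N` spacer, exact dereplication, and a relative
   frequency noise floor.
2. **V(D)J annotation** — ungapped ends-free alignment against an annotated
   germline reference; V/J allele calls with percent identity, D resolution
   inside the junction, region projection, CDR3/junction extraction at the
   conserved Cys/Trp anchors, and productivity.
3. **Clone discrimination** — classification of every unique sequence
   against the patient's monoclonal reference rearrangement (V gene, J gene,
   CDR3 length, CDR3 amino-acid identity).
4. **Subclone grouping** — exact partition of clone-specific sequences by
   CDR3 amino-acid sequence, with productive and unproductive rearrangements
   kept apart.
5. **SHM and selection statistics** — per-region mutation calls against the
   germline configuration, replacement/silent (R/S) ratios, substitution
   spectra with a formalin-artifact flag, and N-glycosylation sequon
   scanning.
6. **Genealogy and trafficking** — group consensus sequences, p-distances,
   a neighbor-joining genealogy rooted at the germline, and the
   group-by-sample trafficking matrix with interfollicular/internodal
   sharing classification.

Because the study this design emulates deposited no raw data, the package
ships a first-class, fully seeded synthetic-data generator that produces
barcoded paired-end FASTQ-shaped reads with complete ground-truth labels;
every analysis step is validated against that truth or against independent
brute-force oracles.

## The amplicon geometry

The default design is a 268 bp amplicon running from a consensus FR2 primer
site in the V segment to a consensus site at the 3' end of the J segment,
sequenced as 2 × 112 bp mates. The mates do not overlap: 268 − 2·112 = 44
interior bases (inside FR3) are never observed and are represented by 44
`N` characters in the merged sequence, so

```
merged = mate1 + N×44 + reverse_complement(mate2)
```

and merged length = |mate1| + 44 + |mate2| always holds. All positions of
the merged sequence map to amplicon positions by a constant shift (the
forward-primer length), which keeps the reading frame intact; codons that
contain `N` translate as `X` and are never counted as stop codons.
Coordinates in every tibble are 1-based closed intervals (the natural R
convention); the on-disk germline region sidecar TSV uses 0-based half-open
coordinates as its interchange format.

## The synthetic study

The generator's defaults reproduce the conditions of the emulated study;
they are fixed study conditions, not tuning knobs:

| Parameter | Default | Rationale |
|---|---|---|
| samples | 16, over 5 lymph nodes (12 from one node) | microdissection layout of the study |
| read length / amplicon | 112 nt / 268 bp, 44 nt N-gap | sequencing design |
| CDR3 groups | 11 (8 productive, 3 with an engineered stop) | observed subclone structure |
| unique clone sequences | 97 (group sizes 1–31) | observed dereplicated diversity |
| contamination | 15–96% per sample, uniform | observed clonal-read range of 3.4–85.6% |
| founder SHM load | 20 substitutions vs germline | observed V identity near 87.5% |
| mutation ceiling | ≤ ~13% per sequence | observed point-mutation ceiling of 12.7% |
| migration rate | 0.08 per group per extra sample | reproduces ~3 of 11 groups private in 16 samples |
| coverage | 30,000 pairs/sample | low end of the reported 30,528–143,320 range |
| barcodes | one unique 7-mer per sample | lane-level barcode reuse is irrelevant to the analysis and not modelled |
| quality strings | constant Q40; 5% of reads carry one Q15 base | exercises the quality filter |

Further modelling choices, and what they mean for interpreting green tests:

* **Substitution-only SHM.** The observed intraclonal variation is point
  mutations, so the lineage model never inserts or deletes; all sequences in
  a clone have equal length and alignment is ungapped. A `gapped = TRUE`
  flag on the annotation functions falls back to a Smith–Waterman-style
  aligner (Biostrings) with the same identity definition for robustness on
  indel-bearing input, but nothing in the default analysis depends on it.
* **CDR bias and selection shaping.** Mutations land with a 3× density
  multiplier in the CDRs. In addition the engine models antigen selection as
  probabilistic vetoes: a framework replacement survives with probability
  0.6 (structural conservation of the receptor) and a CDR silent mutation
  with probability 0.27. These two constants were calibrated once so that
  the *expected* R/S ratios match the values reported for this lesion type —
  about 1.8 in the frameworks (below the 2.845 inherent germline mean, which
  the package treats as a cited constant, not something it recomputes) and
  about 11 in the CDRs. A single simulated study fluctuates around those
  expectations, exactly as a single patient does. Setting both vetoes to 0
  and the bias to 1 recovers a neutral engine, which is what the
  binomial-oracle tests exercise.
* **Reduced J-segment SHM.** SHM targeting decays sharply 3' of the V
  segment, so J sites mutate at 0.3× the framework rate
  (`j_shm_weight`). Besides realism this keeps the short visible J window
  (about 26 nt after gap masking) from being swamped by chance clustering of
  mutations, which would make J assignment of genuine clone reads unstable.
* **Primer overwriting.** Synthesised reads carry the primer sequence at
  the primer sites regardless of template mutations there, as PCR primer
  incorporation does in reality. Together with the restriction of
  study-mode SHM to positions observable after trimming and gap masking,
  this makes ground-truth labels exactly recoverable in noiseless runs.
* **Engineered group structure.** Study-mode lineages guarantee the
  configured number of CDR3 groups: each non-founder group differs from the
  founder CDR3 at 1–3 amino-acid positions (never touching the N-X-S/T
  sequon carried by the founder junction, so every productive group retains
  it, mirroring the lesion's glycosylation-motif biology), and unproductive
  groups carry an engineered FR3 stop codon. Within-group members radiate
  from the group founder with 1–3 private substitutions. `group_parent`
  chooses between a nested genealogy (`"any"`, default) and a star from the
  founder (`"founder"`), the latter bounding the deepest mutation load.
* **Background diversity.** Contaminating reactive-B-cell reads are random
  productive-looking rearrangements whose junctions differ from the
  founder's CDR3 at ≥6 of 11 amino acids, so ground-truth clone membership
  is unambiguous. By default each sample draws its background from 40
  contaminating clonotypes — microdissected germinal centers contain
  oligoclonal expansions, and a background of pure singletons would be
  annihilated by the 0.1% noise floor, contradicting the observed
  contaminant fractions. `background_clones = "per_read"` switches to fully
  diverse backgrounds (used by the clone-discrimination acceptance check,
  which classifies every read below the noise floor).
* **What the simulator does not model.** PCR chimeras, indel sequencing
  errors, lane/flowcell structure, barcode collisions across lanes, and the
  translocation breakpoint itself are all out of scope. Passing tests
  therefore demonstrate correctness of the analysis logic under the stated
  error model, not robustness to chimeric artefacts.

## Numerical and procedural choices

* **Quality floor.** "Per-base quality above 20" is read strictly: the
  default threshold is phred ≥ 21 for *every* base of both mates. Pass
  `min_base_quality = 20` for the inclusive reading.
* **Noise floor.** Unique sequences with frequency strictly below 0.1% of
  the sample's merged high-quality reads are dropped; a sequence exactly at
  the boundary is retained. Frequencies are computed against the pre-filter
  total, which makes the filter idempotent. The floor is applied before
  annotation (the processing order of the emulated workflow).
* **Alignment.** Ends-free ungapped alignment scores match +2 / mismatch −2
  with `N` contributing 0; identity is percent matches over aligned non-N
  columns. The best V is chosen by identity with ties broken by longer
  alignment, then lexicographic allele name; equal-identity J ties take the
  lexicographically first allele and are flagged. Reads with no V or J above
  60% identity (over ≥30 / ≥12 columns) are "non-IGH" — note that most
  contaminating reads are *alignable* (they are real rearrangements); clone
  membership is a separate decision.
* **Clone membership.** "Differing profoundly" is operationalised as: same
  V gene and J gene as the monoclonal reference, identical CDR3 length, and
  CDR3 amino-acid identity ≥ 0.70 (configurable; the emulated study gives no
  number). D-gene agreement is deliberately not required, since junction
  mutations can obscure the D. A ±1-codon CDR3-length tolerance exists for
  gapped mode.
* **R/S classification.** Each mutation is applied alone to its germline
  codon; multi-mutation codons are therefore classified per mutation against
  the germline context (the sequential alternative is noted but not
  implemented as default, since the source procedure does not specify).
  J-segment mutations are reported as their own region, not pooled into FR.
* **Sequon scanning.** The motif is Asn-X-Ser/Thr; the default "literal"
  mode places no constraint on X beyond being a known residue, and the
  "strict" mode additionally excludes proline, the biochemically inert
  middle residue. An unknown residue (`X`) anywhere in the motif prevents a
  match.
* **Trees.** The guide-tree web service used by the emulated workflow is
  replaced by neighbor-joining (deterministic, closed-form checkable) on
  p-distances between per-group majority-consensus sequences, with negative
  branch lengths clamped to zero and a UPGMA flag as an alternative;
  consensus ties fall back to the reference base. The nearest-to-germline
  report is computed from raw mismatch counts, independently of the tree.
  Fewer than three leaves give a degenerate-tree state rather than an error.
  Trees are built on nucleotide consensus; CDR3 amino-acid distances are
  available by passing those sequences to the same functions.
* **Trafficking.** A group is present in a sample at ≥1 read by default
  (`min_presence_count` guards against index hopping); groups in ≥2 samples
  of one site are interfollicular-shared, in ≥2 sites internodal-shared.
* **Outlier reads.** Clone-specific sequences whose CDR3 matches no other
  sequence simply form singleton groups; no ad-hoc tree augmentation is
  attempted for them.

## Problem sizes

Tests and the acceptance script run the study at desk scale as a package
choice: the default profile (16 samples, 11 groups, 97 unique clone
sequences) at 4,000 read pairs per sample in `scripts/acceptance.R`, and
smaller mixes (hundreds to 10,000 pairs) in the test suite. The pipeline's
behaviour is size-stable because every step is either exact (string
operations, exact partitions) or validated by statistical oracles at the
sizes used.

## Known limitations

* The germline reference is synthetic: segment sequences are simulated with
  realistic structure (regions, anchors, primer sites) but are not IMGT
  alleles, and no IMGT unique numbering is implemented; region anchors are
  carried as annotations on the reference instead. Equivalence with
  IMGT/V-QUEST output is therefore out of scope.
* Clone discrimination assumes a single dominant clone with a known
  reference rearrangement; polyclonal lesions or biclonal cases are not
  modelled.
* The R/S selection statistics are plain count ratios; no focused-selection
  or multinomial selection test is provided, and no hotspot-motif (WRCY)
  analysis is performed.
* Phylogenetics is distance-based only; no maximum-likelihood or Bayesian
  reconstruction, and no ancestral-sequence inference.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1, n_samples = 4, n_groups = 5,
                         n_unproductive = 1, group_sizes = c(4, 3, 2, 2, 2),
                         coverage = 2000, contamination = c(0.2, 0.5),
                         migration_rate = 0.3)
sim <- simulate_run(cfg)
res <- run_pipeline(sim)
glance(res)          # one-row study summary
tidy(res)            # per-group table with sharing and germline distance
autoplot(res$trafficking)
```
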
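## Read synthesis: barcoded paired-end amplicon reads with ground truth.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study in one validated list. The
#' defaults emulate the sequencing study the package is designed around: a
#' 268 bp FR2-to-J amplicon read as 2 x 112 bp pairs leaving a 44 nt
#' unsequenced FR3 window, 16 microdissected samples from 5 lymph nodes, 11
#' CDR3 groups (3 unproductive) totalling 97 unique clone sequences, 15-96%
#' contaminating polyclonal reads per sample, and per-sample coverage at the
#' low end of the study's reported range.
#'
#' @param seed Integer seed; mandatory, drives every stochastic step.
#' @param read_length Sequencer read length (nt per mate).
#' @param n_samples Number of follicle samples.
#' @param site_labels Optional anatomic site per sample.
#' @param n_groups,n_unproductive,group_sizes Subclone group structure
#'   (see [simulate_clone_groups()]).
#' @param founder_mutations Archival SHM load of the founder clone.
#' @param member_mutation_range,branch_mutation_range Ongoing-SHM ranges.
#' @param group_parent Lineage topology of engineered groups (see
#'   [simulate_clone_groups()]).
#' @param cdr_bias CDR mutation-density multiplier.
#' @param j_shm_weight Relative SHM rate over the J segment.
#' @param fr_replacement_veto,cdr_silent_veto Selection-shaping vetoes.
#' @param migration_rate Per-group probability of seeding each additional
#'   sample.
#' @param contamination Length-2 per-sample contamination fraction range.
#' @param background_clones `"per_read"` (every contaminating read has its
#'   own junction) or an integer number of contaminating clonotypes per
#'   sample.
#' @param coverage Read pairs per sample (scalar or per-sample vector).
#' @param sequencing_error_rate Per-base substitution error rate.
#' @param deamination_artifact_rate Per-G/C-base rate of formalin-type
#'   G>A / C>T artifacts on the read sense.
#' @param low_quality_read_fraction Fraction of reads carrying one
#'   sub-threshold (Q15) base, exercising the quality filter.
#' @param min_base_quality Phred threshold used downstream.
#' @param noise_threshold Unique-read frequency floor used downstream.
#' @param n_v,n_d,n_j Germline allele counts.
#' @param cells_range Per-node, per-sample cell-count range.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed,
                              read_length = 112L,
                              n_samples = 16L,
                              site_labels = NULL,
                              n_groups = 11L,
                              n_unproductive = 3L,
                              group_sizes = NULL,
                              founder_mutations = 20L,
                              member_mutation_range = c(1, 3),
                              branch_mutation_range = c(1, 4),
                              group_parent = "any",
                              cdr_bias = CDR_BIAS_DEFAULT,
                              j_shm_weight = J_SHM_WEIGHT_DEFAULT,
                              fr_replacement_veto = FR_REPLACEMENT_VETO_DEFAULT,
                              cdr_silent_veto = CDR_SILENT_VETO_DEFAULT,
                              migration_rate = 0.08,
                              contamination = c(0.15, 0.96),
                              background_clones = 40L,
                              coverage = 30000L,
                              sequencing_error_rate = 0.001,
                              deamination_artifact_rate = 0,
                              low_quality_read_fraction = 0.05,
                              min_base_quality = 21L,
                              noise_threshold = 0.001,
                              n_v = 4L, n_d = 4L, n_j = 4L,
                              cells_range = c(50, 500)) {
  if (missing(seed)) stop("a seed is mandatory")
  rates <- c(fr_replacement_veto, cdr_silent_veto, migration_rate, contamination,
             sequencing_error_rate, deamination_artifact_rate,
             low_quality_read_fraction, noise_threshold)
  stopifnot(all(rates >= 0), all(rates <= 1), read_length >= 1)
  cfg <- list(seed = as.integer(seed), read_length = as.integer(read_length),
              n_samples = as.integer(n_samples), site_labels = site_labels,
              n_groups = as.integer(n_groups),
              n_unproductive = as.integer(n_unproductive),
              group_sizes = group_sizes,
              founder_mutations = as.integer(founder_mutations),
              member_mutation_range = member_mutation_range,
              branch_mutation_range = branch_mutation_range,
              group_parent = group_parent,
              cdr_bias = cdr_bias,
              j_shm_weight = j_shm_weight,
              fr_replacement_veto = fr_replacement_veto,
              cdr_silent_veto = cdr_silent_veto,
              migration_rate = migration_rate, contamination = contamination,
              background_clones = background_clones,
              coverage = coverage,
              sequencing_error_rate = sequencing_error_rate,
              deamination_artifact_rate = deamination_artifact_rate,
              low_quality_read_fraction = low_quality_read_fraction,
              min_base_quality = as.integer(min_base_quality),
              noise_threshold = noise_threshold,
              n_v = n_v, n_d = n_d, n_j = n_j, cells_range = cells_range)
  structure(cfg, class = "sim_config")
}

#' Formalin-artifact control preset
#'
#' A monoclonal, no-ongoing-SHM single-sample configuration with a
#' deamination artifact process switched on, emulating a formalin-fixed
#' cell-line control run: called "mutations" should then be dominated by
#' G>A / C>T transitions.
#'
#' @param seed Integer seed.
#' @param coverage Read pairs for the single sample.
#' @param deamination_artifact_rate Per-G/C-base artifact rate.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
config_artifact_control <- function(seed, coverage = 20000L,
                                    deamination_artifact_rate = 0.002, ...) {
  simulation_config(seed = seed, n_samples = 1L, n_groups = 1L,
                    n_unproductive = 0L, group_sizes = 1L,
                    founder_mutations = 10L, migration_rate = 0,
                    contamination = c(0, 0), coverage = coverage,
                    sequencing_error_rate = 0,
                    deamination_artifact_rate = deamination_artifact_rate,
                    low_quality_read_fraction = 0, ...)
}

## Random contaminating clonotype: a productive-looking rearrangement whose
## CDR3 differs from the founder's at >= `min_aa_dist` amino acids.
random_background_clonotype <- function(ref, founder_cdr3_aa, junction_length,
                                        min_aa_dist = 6L) {
  vs <- segments_of_class(ref, "V")$name
  ds <- segments_of_class(ref, "D")$name
  js <- segments_of_class(ref, "J")$name
  repeat {
    junction <- random_codons(junction_length %/% 3L)
    spec <- founder_spec(v_call = sample(vs, 1L), d_call = sample(ds, 1L),
                         j_call = sample(js, 1L), junction = junction)
    full <- recombine_segments(ref, spec)
    cdr3 <- cdr3_aa_of(full, junction_length)
    if (grepl("\\*", cdr3)) next
    d <- sum(strsplit(cdr3, "")[[1]] != strsplit(founder_cdr3_aa, "")[[1]])
    if (d >= min_aa_dist) return(list(spec = spec, sequence = full, cdr3_aa = cdr3))
  }
}

apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

apply_deamination <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_gc <- stringr::str_count(seqs, "[GC]")
  n_hit <- rbinom(length(seqs), n_gc, rate)
  for (i in which(n_hit > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    gc <- which(ch %in% c("G", "C"))
    sel <- if (length(gc) == 1L) gc else sample(gc, n_hit[i])
    ch[sel] <- ifelse(ch[sel] == "G", "A", "T")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Synthesise barcoded paired-end reads with ground truth
#'
#' Emits, for every sample, `coverage` read pairs: mate 1 from the
#' forward-primer end of the amplicon and mate 2 from the reverse-primer end
#' (reverse-complemented), with the primer sequence overwriting the template
#' at the primer sites (as PCR does). Clone reads are drawn from the lineage
#' nodes present in the sample proportional to their cell counts;
#' contaminating reads come from random productive-looking rearrangements
#' with junctions at least 6 aa away from the founder's. Sequencing errors,
#' deamination artifacts (G>A / C>T on the read sense) and a configurable
#' fraction of one-low-quality-base reads are applied afterwards.
#'
#' @param follicles A `follicle_samples` from [distribute_to_follicles()].
#' @param lineage The `clone_lineage` the samples were built from.
#' @param ref The `germline_set`.
#' @param config A `sim_config` (coverage, error rates, read length ...).
#' @return List with `reads` (tibble: read_id, barcode, mate1, qual1, mate2,
#'   qual2), and `truth` (tibble: read_id, sample_id, origin node or
#'   background clonotype id, n_true_mutations vs the germline recombinant).
#' @export
synthesize_reads <- function(follicles, lineage, ref, config) {
  set.seed(child_seed(config$seed, 5L))
  rl <- config$read_length
  fwd <- ref$primers$forward
  rev <- ref$primers$reverse
  jl <- attr(lineage, "junction_length")
  naive <- attr(lineage, "naive_sequence")
  amp_len <- nchar(amplicon_of(ref, naive))
  if (amp_len < nchar(fwd) + nchar(rev)) {
    stop("amplicon shorter than the primer pair")
  }
  if (2L * rl > amp_len) stop("read pairs longer than the amplicon")

  node_amplicon <- setNames(amplicon_of(ref, lineage$sequence), lineage$node_id)
  node_nmut <- setNames(hamming(lineage$sequence, naive), lineage$node_id)
  founder_cdr3 <- lineage$cdr3_aa[1]
  coverage <- rep_len(config$coverage, nrow(follicles$samples))

  all_reads <- list(); all_truth <- list()
  counter <- 0L
  for (s in seq_len(nrow(follicles$samples))) {
    sid <- follicles$samples$sample_id[s]
    bc <- follicles$samples$barcode[s]
    cov <- as.integer(coverage[s])
    cells <- follicles$cells[follicles$cells$sample_id == sid, ]
    if (nrow(cells) == 0L) {
      n_bg <- cov
    } else {
      n_bg <- rbinom(1L, cov, follicles$samples$contamination_fraction[s])
    }
    n_cl <- cov - n_bg

    origins <- character(0); amplicons <- character(0); nmut <- integer(0)
    if (n_cl > 0L) {
      draw <- as.integer(rmultinom(1L, n_cl, prob = cells$cells))
      origins <- rep(cells$node_id, draw)
      amplicons <- node_amplicon[origins]
      nmut <- node_nmut[origins]
    }
    if (n_bg > 0L) {
      if (identical(config$background_clones, "per_read")) {
        bg <- replicate(n_bg, random_background_clonotype(ref, founder_cdr3, jl),
                        simplify = FALSE)
        bg_ids <- sprintf("BG_%s_%05d", sid, seq_len(n_bg))
        bg_amp <- vapply(bg, function(b) amplicon_of(ref, b$sequence), character(1))
        bg_draw <- seq_len(n_bg)
      } else {
        k <- as.integer(config$background_clones)
        bg <- replicate(k, random_background_clonotype(ref, founder_cdr3, jl),
                        simplify = FALSE)
        bg_ids <- sprintf("BG_%s_%05d", sid, seq_len(k))
        bg_amp <- vapply(bg, function(b) amplicon_of(ref, b$sequence), character(1))
        bg_draw <- rep(seq_len(k), as.integer(rmultinom(1L, n_bg, rep(1, k))))
      }
      origins <- c(origins, bg_ids[bg_draw])
      amplicons <- c(amplicons, bg_amp[bg_draw])
      nmut <- c(nmut, rep(NA_integer_, n_bg))
    }
    perm <- sample.int(length(origins))
    origins <- origins[perm]; amplicons <- amplicons[perm]; nmut <- nmut[perm]

    mate1 <- paste0(fwd, substr(amplicons, nchar(fwd) + 1L, rl))
    rc <- revcomp(amplicons)
    mate2 <- paste0(rev, substr(rc, nchar(rev) + 1L, rl))
    mate1 <- apply_deamination(
      apply_substitution_errors(mate1, config$sequencing_error_rate),
      config$deamination_artifact_rate)
    mate2 <- apply_deamination(
      apply_substitution_errors(mate2, config$sequencing_error_rate),
      config$deamination_artifact_rate)

    qual1 <- rep(strrep("I", rl), length(mate1))   # constant Q40
    qual2 <- qual1
    if (config$low_quality_read_fraction > 0) {
      low <- which(runif(length(mate1)) < config$low_quality_read_fraction)
      for (i in low) {
        pos <- sample.int(rl, 1L)
        if (runif(1) < 0.5) {
          qual1[i] <- str_assign(qual1[i], pos, "0")   # Q15, below threshold
        } else {
          qual2[i] <- str_assign(qual2[i], pos, "0")
        }
      }
    }

    ids <- sprintf("RD%08d", counter + seq_along(mate1))
    counter <- counter + length(mate1)
    all_reads[[s]] <- tibble::tibble(read_id = ids, barcode = bc,
                                     mate1 = mate1, qual1 = qual1,
                                     mate2 = mate2, qual2 = qual2)
    all_truth[[s]] <- tibble::tibble(read_id = ids, sample_id = sid,
                                     origin = origins, n_true_mutations = nmut)
  }
  list(reads = dplyr::bind_rows(all_reads), truth = dplyr::bind_rows(all_truth))
}

#' Run the full synthetic study
#'
#' Builds the germline reference, the study-shaped lineage, the follicle
#' samples and the reads in one seeded call.
#'
#' @param config A [simulation_config()].
#' @return A `clone_simulation` list: `config`, `reference`, `lineage`,
#'   `follicles`, `sample_sheet`, `reads`, `truth`.
#' @export
#' @examples
#' sim <- simulate_run(simulation_config(seed = 1, n_samples = 2, n_groups = 3,
#'                                       n_unproductive = 1, coverage = 200))
#' dplyr::count(sim$truth, sample_id)
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- build_germline_set(n_v = config$n_v, n_d = config$n_d, n_j = config$n_j,
                            seed = config$seed)
  lineage <- simulate_clone_groups(
    ref, founder = founder_spec(), n_groups = config$n_groups,
    n_unproductive = config$n_unproductive, group_sizes = config$group_sizes,
    founder_mutations = config$founder_mutations,
    member_mutation_range = config$member_mutation_range,
    branch_mutation_range = config$branch_mutation_range,
    group_parent = config$group_parent,
    cdr_bias = config$cdr_bias,
    j_shm_weight = config$j_shm_weight,
    fr_replacement_veto = config$fr_replacement_veto,
    cdr_silent_veto = config$cdr_silent_veto,
    read_length = config$read_length, seed = config$seed)
  follicles <- distribute_to_follicles(
    lineage, n_samples = config$n_samples,
    migration_rate = config$migration_rate, seed = config$seed,
    site_labels = config$site_labels, contamination = config$contamination,
    cells_range = config$cells_range)
  synth <- synthesize_reads(follicles, lineage, ref, config)
  structure(list(config = config, reference = ref, lineage = lineage,
                 follicles = follicles,
                 sample_sheet = follicles$samples[, c("sample_id", "barcode", "site_label")],
                 reads = synth$reads, truth = synth$truth),
            class = "clone_simulation")
}

#' @export
print.clone_simulation <- function(x, ...) {
  cat("<clone_simulation> ", nrow(x$sample_sheet), " samples, ",
      nrow(x$reads), " read pairs, ", nrow(x$lineage), " lineage nodes\n", sep = "")
  invisible(x)
}

#' Write a simulated run as FASTQ mate files
#'
#' Emits `reads_R1.fastq` and `reads_R2.fastq` (optionally gzipped) with the
#' per-sample barcode carried as a `BC:Z:` header tag.
#'
#' @param reads Reads tibble from [synthesize_reads()]/[simulate_run()].
#' @param dir Output directory.
#' @param compress Write `.gz` files.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_run_fastq <- function(reads, dir, compress = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- file.path(dir, paste0(c("reads_R1", "reads_R2"), ext))
  nm <- paste0(reads$read_id, " BC:Z:", reads$barcode)
  for (k in 1:2) {
    seqs <- Biostrings::DNAStringSet(setNames(reads[[paste0("mate", k)]], nm))
    Biostrings::writeXStringSet(seqs, paths[k], format = "fastq",
                                qualities = Biostrings::BStringSet(reads[[paste0("qual", k)]]),
                                compress = compress)
  }
  invisible(paths)
}

#' Read FASTQ mate files written by [write_run_fastq()]
#'
#' @param dir Directory containing `reads_R1.fastq(.gz)` and
#'   `reads_R2.fastq(.gz)`.
#' @return Reads tibble (read_id, barcode, mate1, qual1, mate2, qual2).
#' @export
read_run_fastq <- function(dir) {
  find1 <- function(stem) {
    p <- file.path(dir, paste0(stem, c(".fastq", ".fastq.gz")))
    p <- p[file.exists(p)]
    if (!length(p)) stop("no ", stem, " FASTQ found in ", dir)
    p[1]
  }
  parse <- function(path) {
    ## readQualityScaledDNAStringSet warns about dropping (empty) metadata
    ## columns; that is expected here
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    nm <- names(x)
    tibble::tibble(read_id = sub(" .*$", "", nm),
                   barcode = stringr::str_match(nm, "BC:Z:([ACGTN]+)")[, 2],
                   seq = unname(as.character(x)),
                   qual = unname(as.character(Biostrings::quality(x))))
  }
  r1 <- parse(find1("reads_R1"))
  r2 <- parse(find1("reads_R2"))
  stopifnot(identical(r1$read_id, r2$read_id))
  tibble::tibble(read_id = r1$read_id, barcode = r1$barcode,
                 mate1 = r1$seq, qual1 = r1$qual,
                 mate2 = r2$seq, qual2 = r2$qual)
}
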
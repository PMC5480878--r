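## End-to-end analysis: processing -> annotation -> clone discrimination ->
## grouping -> SHM/selection statistics -> genealogy -> trafficking.

#' Run the full clonal analysis pipeline
#'
#' Executes the complete analysis on a simulated run (or equivalently shaped
#' inputs): read processing ([process_reads()]), V(D)J annotation
#' ([annotate_vdj()]), clone discrimination against the monoclonal reference
#' ([classify_clone()]), CDR3 grouping ([group_by_cdr3()]), per-sample
#' composition, mutation calling with R/S and spectrum summaries, sequon
#' scanning, the germline-rooted genealogy and the trafficking matrix.
#'
#' The monoclonal reference defaults to the simulation's founder sequence
#' (the in-silico counterpart of the Sanger-derived clonal rearrangement);
#' pass `clone_ref_sequence` to override. Mutations are called against the
#' naive germline recombinant projected into merged-read coordinates.
#'
#' @param sim A `clone_simulation` from [simulate_run()], or a list with
#'   `reads`, `sample_sheet`, `reference`, `config` and (optionally)
#'   `lineage`.
#' @param clone_ref_sequence Optional monoclonal reference sequence in
#'   merged-read coordinates.
#' @param min_cdr3_identity Clone-membership CDR3 identity threshold.
#' @param noise_threshold Override of the config's unique-frequency floor.
#' @param min_presence_count Presence floor for the trafficking matrix.
#' @return A `clonetrack_result` list: `log`, `annotations`, `groups`,
#'   `composition`, `mutations`, `selection`, `spectrum`, `sequons`,
#'   `consensus`, `distances`, `tree`, `rooting`, `trafficking`,
#'   `clone_reference`.
#' @export
#' @examples
#' sim <- simulate_run(simulation_config(seed = 1, n_samples = 2, n_groups = 3,
#'                                       n_unproductive = 1, coverage = 300,
#'                                       contamination = c(0.2, 0.4)))
#' res <- run_pipeline(sim)
#' glance(res)
run_pipeline <- function(sim, clone_ref_sequence = NULL,
                         min_cdr3_identity = 0.70, noise_threshold = NULL,
                         min_presence_count = 1) {
  cfg <- sim$config
  ref <- sim$reference
  if (is.null(noise_threshold)) noise_threshold <- cfg$noise_threshold
  gap <- {
    naive_amp <- amplicon_of(ref, attr(sim$lineage, "naive_sequence"))
    nchar(naive_amp) - 2L * cfg$read_length
  }

  processed <- process_reads(sim$reads, sim$sample_sheet, ref$primers,
                             gap_n_count = gap,
                             min_base_quality = cfg$min_base_quality,
                             noise_threshold = noise_threshold)
  ann <- annotate_vdj(processed$uniques, ref)

  if (is.null(clone_ref_sequence)) {
    founder_amp <- amplicon_of(ref, attr(sim$lineage, "founder_sequence"))
    clone_ref_sequence <- merged_coords(founder_amp, ref, cfg$read_length)$sequence
  }
  cref <- clone_reference(clone_ref_sequence, ref)
  ann <- classify_clone(ann, cref, min_cdr3_identity = min_cdr3_identity)
  groups <- group_by_cdr3(ann)
  composition <- sample_composition(ann, groups)

  ## germline configuration in merged coordinates, for mutation calling
  naive_amp <- amplicon_of(ref, attr(sim$lineage, "naive_sequence"))
  rmap <- amplicon_region_map(ref,
                              junction_length = attr(sim$lineage, "junction_length"))
  mc <- merged_coords(naive_amp, ref, cfg$read_length, region_map = rmap)
  cs <- ann[isTRUE_v(ann$clone_specific), , drop = FALSE]
  mutations <- call_mutations(cs, mc$sequence, mc$region_map)
  mutations <- classify_rs(mutations, mc$sequence, frame_start = mc$frame_start)
  selection <- rs_summary(mutations)
  ## the artifact spectrum looks at intraclonal variation, i.e. substitutions
  ## relative to the dominant (monoclonal reference) sequence — shared SHM of
  ## the clone must not mask a deamination signature
  intraclonal <- call_mutations(cs, clone_ref_sequence, mc$region_map)
  spectrum <- substitution_spectrum(intraclonal)

  prod_groups <- groups[groups$productive, , drop = FALSE]
  sequons <- scan_sequons(prod_groups$cdr3_aa)
  if (nrow(sequons) > 0L) {
    sequons$group_id <- prod_groups$group_id[sequons$seq_index]
  }

  consensus <- group_consensus(cs, groups, mc$sequence)
  tree <- NULL; rooting <- NULL; dists <- NULL
  if (nrow(consensus) >= 1L) {
    seqs <- setNames(c(consensus$consensus, mc$sequence),
                     c(consensus$group_id, "germline"))
    dists <- pairwise_distances(seqs)
    tree <- build_tree(dists)
    rooting <- root_to_germline(tree, dists)
  }
  trafficking <- trafficking_matrix(groups, sim$sample_sheet,
                                    min_count = min_presence_count)

  structure(list(log = processed$log, annotations = ann, groups = groups,
                 composition = composition, mutations = mutations,
                 selection = selection, spectrum = spectrum, sequons = sequons,
                 consensus = consensus, distances = dists, tree = tree,
                 rooting = rooting, trafficking = trafficking,
                 clone_reference = cref, config = cfg),
            class = "clonetrack_result")
}

#' @export
print.clonetrack_result <- function(x, ...) {
  g <- glance(x)
  cat("<clonetrack_result>\n")
  cat("  samples:            ", g$n_samples, " (", g$n_evaluable, " evaluable)\n", sep = "")
  cat("  clone groups:       ", g$n_groups, " (", g$n_unique_clone_sequences,
      " unique clone sequences)\n", sep = "")
  cat("  clone-specific:     ", sprintf("%.1f%%", g$pct_clone_specific),
      " of merged reads\n", sep = "")
  cat("  R/S (CDR | FR):     ", sprintf("%.2f | %.2f", g$cdr_rs_ratio, g$fr_rs_ratio), "\n", sep = "")
  cat("  shared groups:      ", sprintf("%.0f%%", 100 * g$shared_group_fraction),
      "; nearest to germline: ", g$nearest_group, "\n", sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `clonetrack_result`.
#' @param ... Unused.
#' @export
tidy.clonetrack_result <- function(x, ...) {
  cls <- x$trafficking$group_class
  out <- dplyr::left_join(tibble::as_tibble(x$groups), cls, by = "group_id")
  if (!is.null(x$rooting)) {
    out <- dplyr::left_join(out, x$rooting$ordering, by = "group_id")
  }
  out
}

#' @rdname run_pipeline
#' @export
glance.clonetrack_result <- function(x, ...) {
  sel <- x$selection
  ratio_of <- function(set) {
    r <- sel$rs_ratio[sel$region_set == set]
    if (length(r) == 0L) NA_real_ else r
  }
  cs <- x$annotations[isTRUE_v(x$annotations$clone_specific), , drop = FALSE]
  tibble::tibble(
    n_samples = nrow(x$composition),
    n_evaluable = sum(x$composition$evaluable),
    n_groups = nrow(x$groups),
    n_unique_clone_sequences = length(unique(cs$sequence)),
    pct_clone_specific = 100 * sum(cs$count) / sum(x$annotations$count),
    pct_unproductive = if (sum(cs$count) > 0)
      100 * sum(cs$count[!isTRUE_v(cs$productive)]) / sum(cs$count) else NA_real_,
    cdr_rs_ratio = ratio_of("CDR"),
    fr_rs_ratio = ratio_of("FR"),
    fr_rs_below_germline = isTRUE(sel$below_germline_expectation[sel$region_set == "FR"]),
    n_sequon_groups = length(unique(x$sequons$group_id)),
    n_productive_groups = sum(x$groups$productive),
    shared_group_fraction = x$trafficking$summary$shared_fraction,
    nearest_group = if (is.null(x$rooting)) NA_character_ else x$rooting$nearest_group,
    artifact_flag = attr(x$spectrum, "artifact_flag")
  )
}

#' Tidy a clone grouping
#'
#' @param x A `clone_groups` object.
#' @param ... Unused.
#' @return The member-level tibble (uid, sample, count, CDR3, group id).
#' @export
tidy.clone_groups <- function(x, ...) {
  tibble::as_tibble(attr(x, "members"))
}

#' Tidy a genealogy tree into its edge table
#'
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @return Tibble of edges: `parent`, `child`, `length`, `label` (leaf
#'   labels, `NA` for internal nodes).
#' @export
tidy.clone_tree <- function(x, ...) {
  if (is.null(x$phylo)) {
    return(tibble::tibble(parent = integer(), child = integer(),
                          length = numeric(), label = character()))
  }
  phy <- x$phylo
  tibble::tibble(parent = phy$edge[, 1], child = phy$edge[, 2],
                 length = phy$edge.length,
                 label = ifelse(phy$edge[, 2] <= length(phy$tip.label),
                                phy$tip.label[phy$edge[, 2]], NA_character_))
}
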
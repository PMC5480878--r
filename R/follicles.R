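## Distribution of subclones across microdissected follicle samples.

default_site_labels <- function(n_samples) {
  if (n_samples == 16L) {
    ## study profile: 12 samples (8 single + 4 pooled follicles) from one
    ## node, plus one pooled sample from each of four further nodes
    c(rep("LN16", 12L), "LN09", "LN14", "LN15", "LN19")
  } else {
    sprintf("LN%02d", (seq_len(n_samples) - 1L) %/% 4L + 1L)
  }
}

random_barcodes <- function(n, width = 7L) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, random_dna(width)))
  }
  out[seq_len(n)]
}

#' Distribute a clonal lineage across follicle samples
#'
#' Each CDR3 group (the migrating subclone unit) is assigned one home sample
#' uniformly at random and, independently with probability `migration_rate`,
#' additionally seeds each other sample. Every lineage node of a group
#' receives a cell count in each sample the group occupies. The returned
#' ground-truth occupancy matrix is the reference for trafficking recovery.
#'
#' @param lineage A `clone_lineage`.
#' @param n_samples Number of samples (>= 1).
#' @param migration_rate Probability that a group seeds any given additional
#'   sample.
#' @param seed Integer seed.
#' @param site_labels Character vector of anatomic sites, one per sample;
#'   defaults to the 16-sample / 5-lymph-node study profile (or blocks of 4).
#' @param contamination Length-2 range from which each sample's contaminating
#'   (non-clonal B cell) read fraction is drawn uniformly.
#' @param cells_range Range of per-node, per-sample cell counts.
#' @return A `follicle_samples` list: `samples` (sample_id, site_label,
#'   barcode, contamination_fraction), `cells` (node_id, sample_id, cells)
#'   and `occupancy` (group_id x sample_id logical matrix, the ground truth).
#' @export
distribute_to_follicles <- function(lineage, n_samples = 16, migration_rate = 0.08,
                                    seed, site_labels = NULL,
                                    contamination = c(0.15, 0.96),
                                    cells_range = c(50, 500)) {
  stopifnot(!missing(seed), n_samples >= 1,
            migration_rate >= 0, migration_rate <= 1,
            all(contamination >= 0), all(contamination <= 1))
  set.seed(child_seed(seed, 4L))
  if (is.null(site_labels)) site_labels <- default_site_labels(n_samples)
  stopifnot(length(site_labels) == n_samples)

  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    site_label = site_labels,
    barcode = random_barcodes(n_samples),
    contamination_fraction = runif(n_samples, contamination[1], contamination[2])
  )

  groups <- unique(lineage$group_id)
  occupancy <- matrix(FALSE, nrow = length(groups), ncol = n_samples,
                      dimnames = list(groups, sample_ids))
  for (g in seq_along(groups)) {
    home <- sample.int(n_samples, 1L)
    occupancy[g, home] <- TRUE
    if (n_samples > 1L && migration_rate > 0) {
      extra <- runif(n_samples - 1L) < migration_rate
      occupancy[g, setdiff(seq_len(n_samples), home)[extra]] <- TRUE
    }
  }

  cells <- purrr::map_dfr(seq_along(groups), function(g) {
    nodes <- lineage$node_id[lineage$group_id == groups[g]]
    occ <- sample_ids[occupancy[g, ]]
    tidyr::crossing(node_id = nodes, sample_id = occ)
  })
  cells$cells <- sample(seq.int(cells_range[1], cells_range[2]),
                        nrow(cells), replace = TRUE)

  structure(list(samples = samples, cells = cells, occupancy = occupancy),
            class = "follicle_samples")
}

#' @export
print.follicle_samples <- function(x, ...) {
  cat("<follicle_samples> ", nrow(x$samples), " samples, ",
      nrow(x$occupancy), " groups; ",
      sum(rowSums(x$occupancy) > 1L), " group(s) occupy >1 sample\n", sep = "")
  invisible(x)
}
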
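## Germline-rooted genealogy of clone groups and the group x sample
## trafficking matrix.

#' Consensus sequence of each clone group
#'
#' Per-column majority vote over the member sequences of each group; `N`s do
#' not vote, and ties fall back to the reference base at that column.
#'
#' @param annotations A [classify_clone()] result (clone-specific rows are
#'   used) with `cdr3_aa`/`productive` defining groups, or any tibble with
#'   `group_id` and `sequence`.
#' @param groups A [group_by_cdr3()] result used to map rows to groups
#'   (ignored when `annotations` already has `group_id`).
#' @param reference_sequence Tie-breaking reference of the same length.
#' @return Tibble: `group_id`, `consensus`.
#' @export
group_consensus <- function(annotations, groups = NULL, reference_sequence) {
  if (!"group_id" %in% names(annotations)) {
    stopifnot(!is.null(groups))
    key <- paste(annotations$cdr3_aa, annotations$productive)
    gkey <- paste(groups$cdr3_aa, groups$productive)
    annotations$group_id <- groups$group_id[match(key, gkey)]
  }
  rows <- annotations[!is.na(annotations$group_id), , drop = FALSE]
  rch <- strsplit(reference_sequence, "")[[1]]
  purrr::map_dfr(split(rows, rows$group_id), function(g) {
    m <- matrix(unlist(strsplit(g$sequence, ""), use.names = FALSE),
                ncol = nrow(g))
    cons <- vapply(seq_len(nrow(m)), function(i) {
      v <- m[i, ]
      v <- v[v != "N"]
      if (!length(v)) return("N")
      tab <- table(v)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) top else {
        if (rch[i] %in% top) rch[i] else sort(top)[1L]
      }
    }, character(1))
    tibble::tibble(group_id = g$group_id[1], consensus = paste(cons, collapse = ""))
  })
}

#' Pairwise distances between aligned sequences
#'
#' p-distance (mismatches over comparable columns) between every pair of
#' equal-length sequences, excluding columns where either sequence has `N`;
#' the raw mismatch counts are kept alongside.
#'
#' @param sequences Named character vector (names become matrix labels), or
#'   tibble with `group_id`/`consensus` columns.
#' @return A `clone_dist` list: `p` (p-distance matrix), `raw` (mismatch
#'   counts), `comparable` (column counts).
#' @export
pairwise_distances <- function(sequences) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$consensus, sequences$group_id)
  }
  stopifnot(length(unique(nchar(sequences))) == 1L)
  n <- length(sequences)
  labs <- names(sequences)
  chs <- strsplit(sequences, "")
  p <- raw <- comp <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- chs[[i]] != "N" & chs[[j]] != "N"
      d <- sum(chs[[i]][ok] != chs[[j]][ok])
      raw[i, j] <- raw[j, i] <- d
      comp[i, j] <- comp[j, i] <- sum(ok)
      p[i, j] <- p[j, i] <- if (sum(ok) > 0) d / sum(ok) else 0
    }
  }
  structure(list(p = p, raw = raw, comparable = comp), class = "clone_dist")
}

#' Build the group genealogy tree
#'
#' Neighbor-joining (default) on the p-distance matrix, with negative branch
#' lengths clamped to zero; `method = "upgma"` gives an ultrametric
#' alternative. With fewer than three labels a degenerate tree state is
#' returned rather than an error.
#'
#' @param dists A `clone_dist` from [pairwise_distances()], or a symmetric
#'   numeric matrix.
#' @param method `"nj"` or `"upgma"`.
#' @return A `clone_tree`: list with `phylo` (an [ape::read.tree()]-style
#'   tree or `NULL` when degenerate), `newick`, `labels`, `degenerate`.
#' @export
build_tree <- function(dists, method = c("nj", "upgma")) {
  method <- match.arg(method)
  m <- if (inherits(dists, "clone_dist")) dists$p else as.matrix(dists)
  labs <- rownames(m)
  if (nrow(m) < 3L) {
    newick <- if (nrow(m) == 2L) {
      sprintf("(%s:%f,%s:%f);", labs[1], m[1, 2] / 2, labs[2], m[1, 2] / 2)
    } else if (nrow(m) == 1L) sprintf("(%s:0);", labs[1]) else NA_character_
    phy <- if (!is.na(newick)) ape::read.tree(text = newick) else NULL
    return(structure(list(phylo = phy, newick = newick, labels = labs,
                          degenerate = TRUE, method = method),
                     class = "clone_tree"))
  }
  phy <- if (method == "nj") {
    ape::nj(stats::as.dist(m))
  } else {
    ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  structure(list(phylo = phy, newick = ape::write.tree(phy), labels = labs,
                 degenerate = FALSE, method = method),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", length(x$labels), " leaves (", x$method,
      if (x$degenerate) ", degenerate" else "", ")\n", sep = "")
  if (!is.na(x$newick)) cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.clone_tree <- function(x, ...) {
  if (is.null(x$phylo)) stop("degenerate tree: nothing to plot")
  plot(x$phylo, ...)
}

#' Root the genealogy on the germline and rank groups by distance
#'
#' Places the root on the germline leaf's edge and reports, independently of
#' the tree, which group is genetically closest to the germline by raw
#' mismatch count (ties reported and broken lexicographically). The closest
#' group represents the origin of the genealogical tree.
#'
#' @param tree A `clone_tree` whose leaves include `germline_label`.
#' @param dists The `clone_dist` the tree was built from (for the raw
#'   mismatch counts).
#' @param germline_label Label of the germline leaf.
#' @return List: `tree` (rooted `clone_tree`), `nearest_group`,
#'   `nearest_tied` (labels sharing the minimal distance), `ordering`
#'   (tibble of groups by raw distance to germline).
#' @export
root_to_germline <- function(tree, dists, germline_label = "germline") {
  if (!germline_label %in% tree$labels) {
    stop("germline label ", germline_label, " is not among the tree leaves")
  }
  raw <- dists$raw[germline_label, setdiff(tree$labels, germline_label)]
  ordering <- tibble::tibble(group_id = names(raw),
                             mismatches_to_germline = as.numeric(raw))
  ordering <- dplyr::arrange(ordering, .data$mismatches_to_germline,
                             .data$group_id)
  tied <- ordering$group_id[ordering$mismatches_to_germline ==
                              min(ordering$mismatches_to_germline)]
  rooted <- tree
  if (!tree$degenerate) {
    phy <- ape::root(tree$phylo, outgroup = germline_label, resolve.root = TRUE)
    rooted$phylo <- phy
    rooted$newick <- ape::write.tree(phy)
  }
  list(tree = rooted, nearest_group = tied[1], nearest_tied = tied,
       ordering = ordering)
}

#' Assemble the group x sample trafficking matrix
#'
#' Builds the read-count matrix of clone groups across samples, classifies
#' each group as shared (present in at least two samples at
#' `min_count` reads) or private, and summarises sharing within one
#' anatomic site (interfollicular) versus across sites (internodal).
#'
#' @param groups A [group_by_cdr3()] result whose `members` attribute
#'   carries `sample_id` and `count`.
#' @param sample_sheet Tibble with `sample_id` and `site_label`.
#' @param min_count Minimum reads for a group to count as present in a
#'   sample (default 1; raise to guard against index hopping).
#' @return A `trafficking_matrix`: list with `counts` (group x sample
#'   matrix), `group_class` (tibble: group_id, n_samples, n_sites, class,
#'   scope), and `summary` (counts of private / interfollicular / internodal
#'   groups and the shared fraction).
#' @export
trafficking_matrix <- function(groups, sample_sheet, min_count = 1) {
  members <- attr(groups, "members")
  stopifnot(!is.null(members), "sample_id" %in% names(members))
  samples <- sample_sheet$sample_id
  counts <- matrix(0, nrow(groups), length(samples),
                   dimnames = list(groups$group_id, samples))
  agg <- dplyr::summarise(dplyr::group_by(members, .data$group_id, .data$sample_id),
                          n = sum(.data$count), .groups = "drop")
  for (i in seq_len(nrow(agg))) {
    counts[agg$group_id[i], agg$sample_id[i]] <- agg$n[i]
  }
  present <- counts >= min_count
  sites <- sample_sheet$site_label[match(colnames(counts), sample_sheet$sample_id)]
  group_class <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    occ <- which(present[i, ])
    n_sites <- length(unique(sites[occ]))
    tibble::tibble(
      group_id = rownames(counts)[i],
      n_samples = length(occ),
      n_sites = n_sites,
      class = if (length(occ) >= 2L) "shared" else "private",
      scope = if (length(occ) < 2L) "private" else
        if (n_sites >= 2L) "internodal" else "interfollicular")
  })
  summary <- tibble::tibble(
    n_groups = nrow(group_class),
    n_private = sum(group_class$class == "private"),
    n_shared = sum(group_class$class == "shared"),
    n_interfollicular = sum(group_class$scope == "interfollicular"),
    n_internodal = sum(group_class$scope == "internodal"),
    shared_fraction = mean(group_class$class == "shared"))
  structure(list(counts = counts, group_class = group_class, summary = summary),
            class = "trafficking_matrix")
}

#' @export
print.trafficking_matrix <- function(x, ...) {
  cat("<trafficking_matrix> ", nrow(x$counts), " groups x ", ncol(x$counts),
      " samples; shared fraction ",
      sprintf("%.2f", x$summary$shared_fraction), "\n", sep = "")
  invisible(x)
}
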
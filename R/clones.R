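## Clone-specific read discrimination against the monoclonal reference
## rearrangement, CDR3-defined grouping, and per-sample composition.

gene_of <- function(call) sub("\\*.*$", "", call)

#' Annotate the monoclonal reference rearrangement
#'
#' Wraps an annotated clone reference (e.g. the Sanger-derived rearrangement
#' of the dominant clone) for use by [classify_clone()]. The reference must
#' annotate as productive and IGH-specific.
#'
#' @param sequence The reference rearrangement nucleotides (amplicon or
#'   merged coordinates).
#' @param ref A `germline_set`.
#' @param label Reference label.
#' @return A `clone_reference` list with the sequence, its annotation row
#'   and the label.
#' @export
clone_reference <- function(sequence, ref, label = "monoclonal-reference") {
  ann <- annotate_vdj(tibble::tibble(sequence = sequence), ref)
  if (!isTRUE(ann$specific)) stop("clone reference does not annotate as IGH")
  if (!isTRUE(ann$productive)) stop("clone reference is not productive")
  structure(list(sequence = sequence, annotation = ann, label = label),
            class = "clone_reference")
}

#' Discriminate clone-specific reads
#'
#' A read is clone-specific when it matches the monoclonal reference on the
#' V gene and the J gene, has the same CDR3 amino-acid length, and its CDR3
#' amino-acid identity to the reference is at least `min_cdr3_identity`.
#' Sequences differing profoundly on any criterion are classed unrelated;
#' the first failed criterion is recorded. D-gene agreement is deliberately
#' not required (junction mutations can obscure the D). With
#' `cdr3_length_tolerance > 0` (for gapped mode) CDR3 lengths may differ by
#' up to that many codons; identity is then computed over the shorter
#' length.
#'
#' @param annotations An [annotate_vdj()] result.
#' @param reference A [clone_reference()].
#' @param min_cdr3_identity CDR3 amino-acid identity threshold (default
#'   0.70).
#' @param cdr3_length_tolerance Allowed CDR3 length difference in codons.
#' @return `annotations` with `clone_specific` (logical) and
#'   `classify_reason` (`NA` when specific; otherwise `"not-IGH"`,
#'   `"V-mismatch"`, `"J-mismatch"`, `"CDR3-length"` or `"CDR3-identity"`).
#' @export
classify_clone <- function(annotations, reference, min_cdr3_identity = 0.70,
                           cdr3_length_tolerance = 0) {
  ra <- reference$annotation
  ref_cdr3 <- strsplit(ra$cdr3_aa, "")[[1]]
  n <- nrow(annotations)
  reason <- rep(NA_character_, n)

  not_igh <- !annotations$specific
  v_mis <- !not_igh & gene_of(annotations$v_call) != gene_of(ra$v_call)
  j_mis <- !not_igh & !v_mis & gene_of(annotations$j_call) != gene_of(ra$j_call)
  len_diff <- abs(nchar(annotations$cdr3_aa) - nchar(ra$cdr3_aa))
  len_mis <- !not_igh & !v_mis & !j_mis & (is.na(len_diff) |
                                             len_diff > cdr3_length_tolerance)
  undecided <- !(not_igh | v_mis | j_mis | len_mis)
  ident_ok <- rep(FALSE, n)
  for (i in which(undecided)) {
    a <- strsplit(annotations$cdr3_aa[i], "")[[1]]
    k <- min(length(a), length(ref_cdr3))
    if (k == 0L) next
    ident_ok[i] <- mean(a[seq_len(k)] == ref_cdr3[seq_len(k)]) >= min_cdr3_identity
  }
  reason[not_igh] <- "not-IGH"
  reason[v_mis] <- "V-mismatch"
  reason[j_mis] <- "J-mismatch"
  reason[len_mis] <- "CDR3-length"
  reason[undecided & !ident_ok] <- "CDR3-identity"
  annotations$clone_specific <- undecided & ident_ok
  annotations$classify_reason <- reason
  annotations
}

#' Group clone-specific sequences by identical CDR3 amino-acid sequence
#'
#' Exact-string partition of the clone-specific set on the CDR3 amino-acid
#' sequence; productive and unproductive sequences never share a group.
#' Group ids `G1..Gn` are assigned by descending total read count, ties
#' broken by lexicographic CDR3.
#'
#' @param annotations A [classify_clone()] result (rows with
#'   `clone_specific == TRUE` are grouped; others ignored). A `count` column
#'   (from [dereplicate()]) weights totals; absent, each row counts once.
#' @return A `clone_groups` object: tibble with `group_id`, `cdr3_aa`,
#'   `productive`, `n_members`, `total_count`, and a `members` attribute
#'   mapping every clone-specific row to its group.
#' @export
group_by_cdr3 <- function(annotations) {
  cs <- annotations[isTRUE_v(annotations$clone_specific), , drop = FALSE]
  if (!"count" %in% names(cs)) cs$count <- 1L
  members <- dplyr::select(cs, dplyr::any_of(c("uid", "sample_id", "count")),
                           "cdr3_aa", "productive")
  groups <- dplyr::summarise(dplyr::group_by(cs, .data$cdr3_aa, .data$productive),
                             n_members = dplyr::n(),
                             total_count = sum(.data$count), .groups = "drop")
  groups <- dplyr::arrange(groups, dplyr::desc(.data$total_count), .data$cdr3_aa)
  groups$group_id <- paste0("G", seq_len(nrow(groups)))
  groups <- groups[, c("group_id", "cdr3_aa", "productive", "n_members",
                       "total_count")]
  members$group_id <- groups$group_id[match(paste(members$cdr3_aa, members$productive),
                                            paste(groups$cdr3_aa, groups$productive))]
  structure(groups, members = members,
            class = c("clone_groups", class(tibble::tibble())))
}

isTRUE_v <- function(x) !is.na(x) & x

#' Per-sample composition summary
#'
#' For every sample: total merged reads, percentage of clone-specific and
#' unrelated reads, percentage of unproductive rearrangements among the
#' clone-specific reads, and the number of CDR3 groups detected. Samples
#' with zero clone-specific reads are flagged not evaluable.
#'
#' @param annotations A [classify_clone()] result carrying `sample_id` and
#'   `count` columns (unique sequences with read counts).
#' @param groups The matching [group_by_cdr3()] result.
#' @param totals Optional tibble (`sample_id`, `total`) of per-sample read
#'   totals to report percentages against; defaults to the totals present in
#'   `annotations`.
#' @return Tibble: `sample_id`, `total_reads`, `pct_clone_specific`,
#'   `pct_unrelated`, `pct_unproductive`, `n_groups`, `evaluable`.
#' @export
sample_composition <- function(annotations, groups, totals = NULL) {
  if (!"count" %in% names(annotations)) annotations$count <- 1L
  by_sample <- dplyr::summarise(
    dplyr::group_by(annotations, .data$sample_id),
    total_reads = sum(.data$count),
    specific_reads = sum(.data$count[isTRUE_v(.data$clone_specific)]),
    unproductive_reads = sum(.data$count[isTRUE_v(.data$clone_specific) &
                                           !isTRUE_v(.data$productive)]),
    n_groups = dplyr::n_distinct(.data$cdr3_aa[isTRUE_v(.data$clone_specific)]),
    .groups = "drop")
  if (!is.null(totals)) {
    by_sample$total_reads <- totals$total[match(by_sample$sample_id,
                                                totals$sample_id)]
  }
  dplyr::mutate(by_sample,
                pct_clone_specific = 100 * .data$specific_reads / .data$total_reads,
                pct_unrelated = 100 - .data$pct_clone_specific,
                pct_unproductive = ifelse(.data$specific_reads > 0,
                                          100 * .data$unproductive_reads /
                                            .data$specific_reads, NA_real_),
                evaluable = .data$specific_reads > 0)[
                  , c("sample_id", "total_reads", "pct_clone_specific",
                      "pct_unrelated", "pct_unproductive", "n_groups",
                      "evaluable")]
}
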
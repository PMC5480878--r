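## Read cleanup: demultiplexing, primer trimming, quality filtering,
## gap-aware mate merging, dereplication and the frequency noise floor.

hamming_to <- function(x, target) {
  ## vectorised Hamming distance of each string in x to one target of the
  ## same width (positions beyond either width count as mismatches upstream)
  n <- nchar(target)
  tch <- strsplit(target, "")[[1]]
  m <- matrix(unlist(strsplit(substr(x, 1L, n), ""), use.names = FALSE),
              nrow = n)
  colSums(m != tch)
}

#' Assign reads to samples by barcode
#'
#' Each read is assigned to the unique sample whose barcode matches within
#' `max_mismatch` substitutions (exact matching by default); reads matching
#' no barcode — or, under mismatch tolerance, more than one equally well —
#' stay unassigned (`sample_id` = `NA`). The assignment is a partition:
#' per-sample counts plus unassigned always sum to the input size.
#'
#' @param reads Tibble with `barcode` (plus any other columns, preserved).
#' @param sample_sheet Tibble with `sample_id` and `barcode` (collision-free,
#'   equal-width barcodes).
#' @param max_mismatch Allowed barcode mismatches (default 0).
#' @return `reads` with a `sample_id` column prepended.
#' @export
demultiplex <- function(reads, sample_sheet, max_mismatch = 0) {
  if (anyDuplicated(sample_sheet$barcode)) {
    stop("duplicate barcode(s) in sample sheet: ",
         paste(unique(sample_sheet$barcode[duplicated(sample_sheet$barcode)]),
               collapse = ", "))
  }
  if (length(unique(nchar(sample_sheet$barcode))) != 1L) {
    stop("barcodes must have equal length")
  }
  if (max_mismatch == 0) {
    sample_id <- sample_sheet$sample_id[match(reads$barcode, sample_sheet$barcode)]
  } else {
    d <- vapply(sample_sheet$barcode, function(b) hamming_to(reads$barcode, b),
                numeric(nrow(reads)))
    d <- matrix(d, nrow = nrow(reads))
    best <- apply(d, 1L, min)
    n_best <- rowSums(d == best)
    idx <- apply(d, 1L, which.min)
    sample_id <- ifelse(best <= max_mismatch & n_best == 1L,
                        sample_sheet$sample_id[idx], NA_character_)
  }
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id), reads)
}

#' Trim amplification primers off read pairs
#'
#' Mate 1 must begin with the forward primer and mate 2 with the reverse
#' primer, each within `max_mismatch` substitutions; matching primers are
#' removed from the 5' ends and the corresponding quality prefixes dropped.
#' Pairs missing a primer are retained with a `trim_reason`
#' (`"missing-forward-primer"` / `"missing-reverse-primer"`) and untrimmed
#' mates; downstream steps use only rows with `trim_reason` `NA`.
#'
#' @param reads Tibble with `mate1`, `qual1`, `mate2`, `qual2`.
#' @param primers List with `forward` and `reverse` primer sequences (e.g.
#'   `ref$primers`).
#' @param max_mismatch Allowed substitutions within each primer (default 0).
#' @return `reads` with trimmed mates/qualities and a `trim_reason` column.
#' @export
trim_primers <- function(reads, primers, max_mismatch = 0) {
  p1 <- nchar(primers$forward)
  p2 <- nchar(primers$reverse)
  ok1 <- hamming_to(reads$mate1, primers$forward) <= max_mismatch &
    nchar(reads$mate1) > p1
  ok2 <- hamming_to(reads$mate2, primers$reverse) <= max_mismatch &
    nchar(reads$mate2) > p2
  reason <- dplyr::case_when(!ok1 ~ "missing-forward-primer",
                             !ok2 ~ "missing-reverse-primer",
                             TRUE ~ NA_character_)
  ok <- is.na(reason)
  out <- reads
  out$mate1[ok] <- substr(reads$mate1[ok], p1 + 1L, nchar(reads$mate1[ok]))
  out$qual1[ok] <- substr(reads$qual1[ok], p1 + 1L, nchar(reads$qual1[ok]))
  out$mate2[ok] <- substr(reads$mate2[ok], p2 + 1L, nchar(reads$mate2[ok]))
  out$qual2[ok] <- substr(reads$qual2[ok], p2 + 1L, nchar(reads$qual2[ok]))
  out$trim_reason <- reason
  out
}

#' Filter read pairs on per-base quality
#'
#' A pair passes only if every base of both mates has phred quality at or
#' above `min_base_quality`. The default of 21 is the strict reading of a
#' "quality above 20" rule; pass 20 for the inclusive variant.
#'
#' @param reads Tibble with `qual1`, `qual2` (and matching sequences).
#' @param min_base_quality Minimum phred score required for every base.
#' @return `reads` with a logical `quality_pass` column.
#' @export
quality_filter <- function(reads, min_base_quality = 21) {
  if (any(nchar(reads$mate1) != nchar(reads$qual1)) ||
      any(nchar(reads$mate2) != nchar(reads$qual2))) {
    stop("sequence and quality strings differ in length")
  }
  reads$quality_pass <- min_phred(reads$qual1) >= min_base_quality &
    min_phred(reads$qual2) >= min_base_quality
  reads
}

#' Merge mates across the unsequenced gap
#'
#' The amplicon is longer than the two reads cover, so the mates are joined
#' with a spacer of `gap_n_count` `N` bases standing in for the unsequenced
#' interior window: `merged = mate1 + N...N + reverse-complement(mate2)`.
#' The merged length is always `nchar(mate1) + gap_n_count + nchar(mate2)`.
#'
#' @param reads Tibble with `mate1`, `mate2` (trimmed, QC-passed).
#' @param gap_n_count Number of `N` bases bridging the gap (default 44).
#' @return Tibble with `read_id`, `sample_id` (if present) and `sequence`.
#' @export
merge_with_gap <- function(reads, gap_n_count = 44) {
  stopifnot(gap_n_count >= 0)
  keep <- intersect(c("read_id", "sample_id"), names(reads))
  out <- reads[, keep, drop = FALSE]
  out$sequence <- paste0(reads$mate1, strrep("N", gap_n_count), revcomp(reads$mate2))
  tibble::as_tibble(out)
}

#' Collapse identical merged reads into unique sequences
#'
#' Exact-string dereplication within each sample. Counts are conserved
#' (their sum equals the number of input reads per sample) and frequencies
#' are normalised against the per-sample pre-filter total.
#'
#' @param merged Tibble with `sample_id` and `sequence`.
#' @return Tibble of unique sequences: `sample_id`, `uid`, `sequence`,
#'   `count`, `frequency`, `sample_total`.
#' @export
dereplicate <- function(merged) {
  out <- dplyr::count(merged, .data$sample_id, .data$sequence, name = "count")
  out <- dplyr::mutate(dplyr::group_by(out, .data$sample_id),
                       sample_total = sum(.data$count),
                       frequency = .data$count / .data$sample_total)
  out <- dplyr::arrange(dplyr::ungroup(out), .data$sample_id,
                        dplyr::desc(.data$count), .data$sequence)
  out <- dplyr::mutate(dplyr::group_by(out, .data$sample_id),
                       uid = sprintf("%s_U%05d", .data$sample_id,
                                     dplyr::row_number()))
  dplyr::ungroup(out)[, c("sample_id", "uid", "sequence", "count",
                          "frequency", "sample_total")]
}

#' Remove low-frequency unique sequences
#'
#' Unique sequences with a per-sample frequency strictly below `threshold`
#' are treated as noise and removed; a sequence sitting exactly on the
#' threshold is retained. Counts and frequencies of retained rows are left
#' untouched (frequencies remain relative to the pre-filter total), so the
#' filter is idempotent.
#'
#' @param uniques Tibble from [dereplicate()].
#' @param threshold Frequency floor (default 0.001, i.e. 0.1%).
#' @return Filtered tibble.
#' @export
noise_filter <- function(uniques, threshold = 0.001) {
  stopifnot(threshold >= 0)
  uniques[uniques$frequency >= threshold, , drop = FALSE]
}

#' Run the read-processing chain
#'
#' Demultiplex, trim primers, quality-filter, merge with the N-gap,
#' dereplicate and apply the frequency noise floor, collecting per-step
#' accounting.
#'
#' @param reads Reads tibble (read_id, barcode, mates, qualities).
#' @param sample_sheet Tibble with `sample_id`, `barcode`.
#' @param primers List with `forward`/`reverse` primers.
#' @param gap_n_count `N` spacer length.
#' @param min_base_quality Phred floor for every base.
#' @param noise_threshold Unique-sequence frequency floor.
#' @param max_barcode_mismatch,max_primer_mismatch Matching tolerances.
#' @return List with `uniques` (post-filter unique sequences), `merged`
#'   (per-read merged sequences), and `log` (per-sample step accounting).
#' @export
process_reads <- function(reads, sample_sheet, primers, gap_n_count = 44,
                          min_base_quality = 21, noise_threshold = 0.001,
                          max_barcode_mismatch = 0, max_primer_mismatch = 0) {
  dm <- demultiplex(reads, sample_sheet, max_mismatch = max_barcode_mismatch)
  assigned <- dm[!is.na(dm$sample_id), , drop = FALSE]
  tr <- trim_primers(assigned, primers, max_mismatch = max_primer_mismatch)
  trimmed <- tr[is.na(tr$trim_reason), , drop = FALSE]
  qc <- quality_filter(trimmed, min_base_quality = min_base_quality)
  passed <- qc[qc$quality_pass, , drop = FALSE]
  merged <- merge_with_gap(passed, gap_n_count = gap_n_count)
  uniques <- dereplicate(merged)
  kept <- noise_filter(uniques, threshold = noise_threshold)

  count_by <- function(df) {
    if (nrow(df) == 0L) {
      return(setNames(integer(0), character(0)))
    }
    table(df$sample_id)
  }
  samples <- sample_sheet$sample_id
  log <- tibble::tibble(
    sample_id = samples,
    demultiplexed = as.integer(count_by(assigned)[samples]),
    trimmed = as.integer(count_by(trimmed)[samples]),
    quality_passed = as.integer(count_by(passed)[samples]),
    unique_sequences = as.integer(count_by(uniques)[samples]),
    unique_after_noise_filter = as.integer(count_by(kept)[samples])
  )
  log[is.na(log)] <- 0L
  attr(log, "unassigned") <- sum(is.na(dm$sample_id))
  list(uniques = kept, merged = merged, log = log)
}

#' Write per-sample unique sequences as FASTA
#'
#' Headers follow `>uid;count=N;freq=F`.
#'
#' @param uniques Tibble from [dereplicate()]/[noise_filter()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_uniques_fasta <- function(uniques, path) {
  nm <- sprintf("%s;count=%d;freq=%.6f", uniques$uid, uniques$count,
                uniques$frequency)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(uniques$sequence, nm)), path)
  invisible(path)
}
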
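## V(D)J annotation of merged unique sequences against the germline
## reference: substitution-only (ungapped) alignment, region projection,
## junction/CDR3 extraction, productivity and V identity.
##
## Alignment is delegated to Biostrings::pairwiseAlignment in ends-free
## ("overlap") mode with prohibitive gap penalties, which makes it an exact
## ungapped sliding alignment; `N` scores 0 against anything and is excluded
## from identity. A `gapped = TRUE` escape hatch relaxes the gap penalties
## for robustness on indel-bearing input; identity is computed with the same
## definition either way.

align_submatrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

## Ends-free alignment of many reads against one germline segment.
## Returns per-read tibble: score, identity (% over non-N ungapped columns),
## columns (aligned non-N columns), read_start, germ_start (1-based).
##
## The ungapped path enumerates every diagonal (offset) with at least
## `min_overlap` columns and scores it vectorised across all reads of equal
## length (match +2, mismatch -2, N contributes 0), keeping the best-scoring
## diagonal per read — the exact ends-free optimum under prohibitive gap
## penalties. The gapped path defers to Biostrings::pairwiseAlignment.
align_to_segment <- function(seqs, segment_seq, gapped = FALSE,
                             min_overlap = 5L) {
  if (gapped) {
    return(align_to_segment_gapped(seqs, segment_seq))
  }
  a <- align_ungapped_cpp(seqs, segment_seq, as.integer(min_overlap))
  cols <- a$m + a$mm
  tibble::tibble(
    score = as.numeric(a$score),
    identity = ifelse(cols > 0, 100 * a$m / cols, NA_real_),
    columns = as.numeric(cols),
    read_start = a$read_start,
    germ_start = a$read_start + a$offset,
    read_end = a$read_end,
    germ_end = a$read_end + a$offset
  )
}

align_to_segment_gapped <- function(seqs, segment_seq) {
  pat <- Biostrings::DNAStringSet(seqs)
  al <- Biostrings::pairwiseAlignment(
    pat, Biostrings::DNAString(segment_seq), type = "overlap",
    substitutionMatrix = align_submatrix(),
    gapOpening = 10, gapExtension = 4)
  m <- Biostrings::nmatch(al)
  mm <- Biostrings::nmismatch(al)
  nN <- Biostrings::letterFrequency(Biostrings::alignedPattern(al), "N")[, 1]
  cols <- m + mm - nN
  tibble::tibble(
    score = Biostrings::score(al),
    identity = ifelse(cols > 0, 100 * m / cols, NA_real_),
    columns = cols,
    read_start = Biostrings::start(Biostrings::pattern(al)),
    germ_start = Biostrings::start(Biostrings::subject(al)),
    read_end = Biostrings::end(Biostrings::pattern(al)),
    germ_end = Biostrings::end(Biostrings::subject(al))
  )
}

## Best segment per read among candidates, with the tie rule: higher
## identity, then more aligned columns, then lexicographically first name.
best_segment <- function(seqs, segments, min_identity, min_columns,
                         gapped = FALSE) {
  if (length(seqs) == 0L) {
    return(tibble::tibble(call = character(), identity = numeric(),
                          columns = numeric(), read_start = integer(),
                          germ_start = integer(), read_end = integer(),
                          germ_end = integer(), tie = logical()))
  }
  per_seg <- lapply(seq_len(nrow(segments)), function(i) {
    a <- align_to_segment(seqs, segments$sequence[i], gapped = gapped)
    a$call <- segments$name[i]
    a
  })
  n <- length(seqs)
  pick <- rep(NA_integer_, n)
  tie <- rep(FALSE, n)
  id_mat <- vapply(per_seg, function(a) a$identity, numeric(n))
  col_mat <- vapply(per_seg, function(a) a$columns, numeric(n))
  id_mat <- matrix(id_mat, nrow = n)
  col_mat <- matrix(col_mat, nrow = n)
  ord_names <- order(segments$name)
  for (i in seq_len(n)) {
    ids <- id_mat[i, ]
    cs <- col_mat[i, ]
    ids[is.na(ids) | cs < min_columns] <- -Inf
    best_id <- max(ids)
    if (!is.finite(best_id) || best_id < min_identity) next
    cand <- which(ids == best_id)
    if (length(cand) > 1L) {
      cand <- cand[cs[cand] == max(cs[cand])]
      if (length(cand) > 1L) {
        tie[i] <- TRUE
        cand <- cand[order(match(cand, ord_names))][1L]
        cand <- cand[1L]
      }
    }
    pick[i] <- cand[1L]
  }
  out <- tibble::tibble(call = NA_character_, identity = NA_real_,
                        columns = NA_real_, read_start = NA_integer_,
                        germ_start = NA_integer_, read_end = NA_integer_,
                        germ_end = NA_integer_, tie = tie, .rows = n)
  for (j in seq_along(per_seg)) {
    rows <- which(pick == j)
    if (!length(rows)) next
    a <- per_seg[[j]]
    out$call[rows] <- a$call[rows]
    out$identity[rows] <- a$identity[rows]
    out$columns[rows] <- a$columns[rows]
    out$read_start[rows] <- a$read_start[rows]
    out$germ_start[rows] <- a$germ_start[rows]
    out$read_end[rows] <- a$read_end[rows]
    out$germ_end[rows] <- a$germ_end[rows]
  }
  out
}

#' Align sequences against the germline V segments
#'
#' Ungapped ends-free alignment against every V allele; the best V is chosen
#' by percent identity over aligned non-N columns (ties: longer alignment,
#' then lexicographically first allele name). Reads with no V above
#' `min_identity` (default 60%) over at least `min_columns` columns are left
#' uncalled ("unalignable").
#'
#' @param sequences Character vector (or tibble with a `sequence` column).
#' @param ref A `germline_set`.
#' @param min_identity Identity floor in percent.
#' @param min_columns Minimum aligned non-N columns.
#' @param gapped Allow gaps in the alignment (off by default).
#' @return Tibble: `v_call`, `v_identity`, `v_columns`, `v_read_start`,
#'   `v_germ_start`, `v_read_end`, `v_germ_end`, `v_tie`.
#' @export
align_v <- function(sequences, ref, min_identity = 60, min_columns = 30,
                    gapped = FALSE) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (nrow(segments_of_class(ref, "V")) < 1L) stop("reference has no V segments")
  b <- best_segment(sequences, segments_of_class(ref, "V"),
                    min_identity, min_columns, gapped = gapped)
  setNames(b, c("v_call", "v_identity", "v_columns", "v_read_start",
                "v_germ_start", "v_read_end", "v_germ_end", "v_tie"))
}

#' Align sequences against the germline J segments
#'
#' As [align_v()], over the 3' end of the read; equal-identity ties pick the
#' lexicographically first allele and are flagged in `j_tie`.
#'
#' @inheritParams align_v
#' @return Tibble: `j_call`, `j_identity`, `j_columns`, `j_read_start`,
#'   `j_germ_start`, `j_read_end`, `j_germ_end`, `j_tie`.
#' @export
align_j <- function(sequences, ref, min_identity = 60, min_columns = 12,
                    gapped = FALSE) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  b <- best_segment(sequences, segments_of_class(ref, "J"),
                    min_identity, min_columns, gapped = gapped)
  setNames(b, c("j_call", "j_identity", "j_columns", "j_read_start",
                "j_germ_start", "j_read_end", "j_germ_end", "j_tie"))
}

## Longest ungapped run of consecutive matches between junction and D
## (thin wrapper over the compiled kernel; used singly in tests).
longest_common_run <- function(junction, d_seq) {
  r <- longest_run_cpp(junction, d_seq)
  list(length = r$length[1, 1], junction_start = r$start[1, 1])
}

#' Resolve the D segment within a junction
#'
#' Scans every D allele for its longest ungapped run of consecutive matches
#' inside the junction nucleotides; the best D with a run of at least
#' `min_d_match` is called (ties: first in lexicographic allele order).
#' Returns no call when nothing qualifies (e.g. a junction of pure
#' N-nucleotides).
#'
#' @param junctions Character vector of junction nucleotide sequences.
#' @param ref A `germline_set`.
#' @param min_d_match Minimum consecutive matching nucleotides (default 5).
#' @return Tibble: `d_call`, `d_match_length`, `d_frame` (reading frame of
#'   the D match relative to the junction's first position, 0-2).
#' @export
resolve_d <- function(junctions, ref, min_d_match = 5) {
  ds <- segments_of_class(ref, "D")
  ds <- ds[order(ds$name), ]
  out <- tibble::tibble(d_call = rep(NA_character_, length(junctions)),
                        d_match_length = NA_integer_, d_frame = NA_integer_)
  ok <- !is.na(junctions) & nchar(junctions) > 0L
  if (!any(ok)) return(out)
  r <- longest_run_cpp(junctions[ok], ds$sequence)
  ## best D per junction: longest run, ties to the first (lexicographically
  ## smallest) allele
  best_j <- apply(r$length, 1L, which.max)
  best_len <- r$length[cbind(seq_len(sum(ok)), best_j)]
  best_at <- r$start[cbind(seq_len(sum(ok)), best_j)]
  qual <- best_len >= min_d_match
  idx <- which(ok)[qual]
  out$d_call[idx] <- ds$name[best_j[qual]]
  out$d_match_length[idx] <- as.integer(best_len[qual])
  out$d_frame[idx] <- as.integer((best_at[qual] - 1L) %% 3L)
  out
}

#' Annotate merged sequences against the germline reference
#'
#' Full V(D)J annotation of merged unique sequences (which may contain the
#' N spacer): best V and J call with identities, D resolution inside the
#' junction, region projection through the V alignment, junction/CDR3
#' extraction using the conserved Cys (end of FR3) and Trp (J anchor)
#' anchors carried on the germline segments, reading frame, stop-codon scan
#' (codons containing N translate as unknown and never count as stops) and
#' productivity. Sequences whose V or J cannot be aligned are marked
#' non-IGH-specific (`specific = FALSE`).
#'
#' @param uniques Tibble with a `sequence` column (e.g. from
#'   [dereplicate()]); all other columns are preserved.
#' @param ref A `germline_set`.
#' @param min_identity Identity floor (%) below which a read is unalignable.
#' @param min_d_match Minimum consecutive D match (see [resolve_d()]).
#' @param gapped Allow alignment gaps.
#' @return Input tibble extended with `v_call`, `v_identity`, `j_call`,
#'   `j_tie`, `d_call`, `d_frame`, `junction`, `cdr3_nt`, `cdr3_aa`,
#'   `cdr3_start`, `cdr3_end`, `frame_offset`, `in_frame`, `stop_codon`,
#'   `productive`, `specific`, and alignment bookkeeping columns.
#' @export
annotate_vdj <- function(uniques, ref, min_identity = 60, min_d_match = 5,
                         gapped = FALSE) {
  if (!is.data.frame(uniques)) uniques <- tibble::tibble(sequence = uniques)
  seqs <- uniques$sequence
  av <- align_v(seqs, ref, min_identity = min_identity, gapped = gapped)
  aj <- align_j(seqs, ref, min_identity = min_identity, gapped = gapped)
  out <- dplyr::bind_cols(uniques, av, aj)

  vb <- v_region_bounds()
  fr3_end <- vb$end[vb$region == "FR3"]
  anchors <- setNames(ref$segments$anchor, ref$segments$name)

  n <- nrow(out)
  cdr3_start <- cdr3_end <- rep(NA_integer_, n)
  frame_offset <- rep(NA_integer_, n)
  L <- nchar(seqs)
  ok <- !is.na(out$v_call) & !is.na(out$j_call)
  if (any(ok)) {
    ## read position of germline coordinate g: g - germ_start + read_start
    v_off <- out$v_read_start - out$v_germ_start       # read = germ + v_off
    cdr3_start_ok <- fr3_end + v_off + 1L
    j_anchor <- anchors[out$j_call]
    cdr3_end_ok <- j_anchor + (out$j_read_start - out$j_germ_start) - 1L
    cdr3_start[ok] <- as.integer(cdr3_start_ok[ok])
    cdr3_end[ok] <- as.integer(cdr3_end_ok[ok])
    ## frame: germline V codon boundaries sit at germline positions == 1
    ## (mod 3); read position r maps to germline r - v_off
    frame_offset[ok] <- as.integer(v_off[ok] %% 3L)
  }
  bad_interval <- ok & (is.na(cdr3_start) | is.na(cdr3_end) |
                          cdr3_start > cdr3_end + 1L | cdr3_start < 1L |
                          cdr3_end > L)
  ok <- ok & !bad_interval

  junction <- cdr3_nt <- cdr3_aa <- rep(NA_character_, n)
  in_frame <- stop_codon <- productive <- rep(NA, n)
  if (any(ok)) {
    i <- which(ok)
    cdr3_nt[i] <- substr(seqs[i], cdr3_start[i], cdr3_end[i])
    ## junction = conserved Cys codon .. conserved Trp codon inclusive
    junction[i] <- substr(seqs[i], cdr3_start[i] - 3L, cdr3_end[i] + 3L)
    cdr3_aa[i] <- translate_nt(cdr3_nt[i])
    in_frame[i] <- (nchar(cdr3_nt[i]) %% 3L) == 0L &
      ((cdr3_start[i] - 1L - frame_offset[i]) %% 3L) == 0L
    ## stop scan over the translatable span in the V frame
    aa_full <- translate_nt(substr(seqs[i], 1L, L[i]), frame_start = frame_offset[i] + 1L)
    stop_codon[i] <- grepl("\\*", aa_full)
    productive[i] <- in_frame[i] & !stop_codon[i]
  }

  out$d_call <- NA_character_
  out$d_match_length <- NA_integer_
  out$d_frame <- NA_integer_
  if (any(ok)) {
    dres <- resolve_d(cdr3_nt[ok], ref, min_d_match = min_d_match)
    out$d_call[ok] <- dres$d_call
    out$d_match_length[ok] <- dres$d_match_length
    out$d_frame[ok] <- dres$d_frame
  }
  out$junction <- junction
  out$cdr3_nt <- cdr3_nt
  out$cdr3_aa <- cdr3_aa
  out$cdr3_start <- cdr3_start
  out$cdr3_end <- cdr3_end
  out$frame_offset <- frame_offset
  out$in_frame <- in_frame
  out$stop_codon <- stop_codon
  out$productive <- productive
  out$specific <- ok
  out
}

#' Region intervals covered by a read
#'
#' Projects the germline V region bounds (and the CDR3/J intervals) through
#' a read's alignments, clipped to the read; the FR2 assay truncates
#' FR1/CDR1, so only regions actually covered appear.
#'
#' @param annotation One row of an [annotate_vdj()] result.
#' @return Tibble with `region`, `start`, `end` (read coordinates, 1-based
#'   closed).
#' @export
read_region_map <- function(annotation) {
  stopifnot(nrow(annotation) == 1L)
  if (!isTRUE(annotation$specific)) {
    return(tibble::tibble(region = character(), start = integer(), end = integer()))
  }
  L <- nchar(annotation$sequence)
  v_off <- annotation$v_read_start - annotation$v_germ_start
  vb <- v_region_bounds()
  vb$start <- vb$start + v_off
  vb$end <- vb$end + v_off
  vb <- vb[vb$end >= 1L & vb$start <= annotation$cdr3_start - 1L, ]
  vb$start <- pmax(vb$start, 1L)
  vb$end <- pmin(vb$end, annotation$cdr3_start - 1L, L)
  extra <- tibble::tibble(
    region = c("CDR3", "J"),
    start = c(annotation$cdr3_start, annotation$cdr3_end + 1L),
    end = c(annotation$cdr3_end, min(annotation$j_read_end, L)))
  extra <- extra[extra$start <= extra$end, ]
  out <- dplyr::bind_rows(vb, extra)
  out[out$start <= out$end & out$start >= 1L, ]
}

#' Export annotations as an AIRR-style rearrangement table
#'
#' @param annotations An [annotate_vdj()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangement_tsv <- function(annotations, path) {
  cols <- tibble::tibble(
    sequence_id = if ("uid" %in% names(annotations)) annotations$uid else
      as.character(seq_len(nrow(annotations))),
    sequence = annotations$sequence,
    v_call = annotations$v_call,
    d_call = annotations$d_call,
    j_call = annotations$j_call,
    junction = annotations$junction,
    junction_aa = translate_nt(annotations$junction),
    cdr3_aa = annotations$cdr3_aa,
    productive = annotations$productive,
    v_identity = annotations$v_identity,
    frame = annotations$frame_offset
  )
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
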
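## Somatic-hypermutation statistics: mutation calling versus a reference
## configuration, replacement/silent classification and per-region ratios,
## substitution spectra with a formalin-artifact flag, and N-glycosylation
## sequon scanning.

GERMLINE_RS_EXPECTATION <- 2.845  # inherent mean R/S of human germline VH genes

#' Call point mutations against a reference sequence
#'
#' Column-by-column comparison of each sequence with an equal-length
#' reference (typically the unmutated germline recombinant of the clone
#' projected into merged-read coordinates). Columns where either side is `N`
#' are skipped; every remaining mismatch yields one record with its region
#' label.
#'
#' @param sequences Character vector, or tibble with `sequence` (and
#'   optionally `uid`) columns.
#' @param reference_sequence Reference string of the same length.
#' @param region_map Tibble (`region`, `start`, `end`; same coordinates as
#'   the sequences, 1-based closed), e.g. from [amplicon_region_map()]
#'   shifted to merged coordinates via [merged_coords()].
#' @return Tibble: `uid`, `position`, `region`, `from_base`, `to_base`,
#'   `codon_index`.
#' @export
call_mutations <- function(sequences, reference_sequence, region_map = NULL) {
  if (is.data.frame(sequences)) {
    uid <- if ("uid" %in% names(sequences)) sequences$uid else
      as.character(seq_len(nrow(sequences)))
    sequences <- sequences$sequence
  } else {
    uid <- as.character(seq_along(sequences))
  }
  stopifnot(all(nchar(sequences) == nchar(reference_sequence)))
  rch <- strsplit(reference_sequence, "")[[1]]
  out <- purrr::map2_dfr(sequences, uid, function(s, id) {
    ch <- strsplit(s, "")[[1]]
    valid <- ch != "N" & rch != "N"
    pos <- which(valid & ch != rch)
    if (!length(pos)) {
      return(tibble::tibble(uid = character(), position = integer(),
                            region = character(), from_base = character(),
                            to_base = character(), codon_index = integer()))
    }
    tibble::tibble(uid = id, position = pos,
                   region = NA_character_,
                   from_base = rch[pos], to_base = ch[pos],
                   codon_index = (pos - 1L) %/% 3L + 1L)
  })
  if (!is.null(region_map) && nrow(out) > 0L) {
    out$region <- region_of_positions(out$position, region_map)
  }
  out
}

#' Classify mutations as replacement or silent
#'
#' Each mutation is applied alone to its germline codon (other positions
#' held at germline): replacement (R) if the amino acid changes, silent (S)
#' otherwise, unclassified if the codon contains `N` or is not fully inside
#' the coding frame. Multi-mutation codons are therefore classified per
#' mutation, independently, against the germline codon.
#'
#' @param mutations Tibble from [call_mutations()].
#' @param reference_sequence The same reference the mutations were called
#'   against.
#' @param frame_start 1-based position of the first codon of
#'   `reference_sequence`.
#' @return `mutations` with an `rs_class` column (`"R"`, `"S"` or
#'   `"unclassified"`).
#' @export
classify_rs <- function(mutations, reference_sequence, frame_start = 1) {
  n <- nrow(mutations)
  rs <- character(n)
  L <- nchar(reference_sequence)
  for (i in seq_len(n)) {
    pos <- mutations$position[i]
    cs <- pos - ((pos - frame_start) %% 3L)
    if (cs < frame_start || cs + 2L > L || pos < frame_start) {
      rs[i] <- "unclassified"
      next
    }
    codon <- substr(reference_sequence, cs, cs + 2L)
    if (grepl("[^ACGT]", codon)) {
      rs[i] <- "unclassified"
      next
    }
    mutated <- str_assign(codon, pos - cs + 1L, mutations$to_base[i])
    rs[i] <- if (translate_nt(codon) == translate_nt(mutated)) "S" else "R"
  }
  mutations$rs_class <- rs
  mutations
}

#' Per-region replacement/silent summary
#'
#' Counts R and S mutations per region and for the pooled CDR and FR sets,
#' computes R/S ratios (undefined when S = 0, with the R count still
#' reported) and compares framework ratios against the inherent germline VH
#' expectation of 2.845.
#'
#' @param mutations A [classify_rs()] result.
#' @param cdr_regions,fr_regions Region labels pooled into the CDR and FR
#'   sets.
#' @param germline_expectation Reference R/S value for the comparison flag.
#' @return A `selection_summary` tibble: `region_set`, `n_R`, `n_S`,
#'   `n_unclassified`, `rs_ratio`, `ratio_defined`, `below_germline_expectation`.
#' @export
rs_summary <- function(mutations, cdr_regions = c("CDR1", "CDR2", "CDR3"),
                       fr_regions = c("FR1", "FR2", "FR3"),
                       germline_expectation = GERMLINE_RS_EXPECTATION) {
  one <- function(label, rows) {
    n_r <- sum(rows$rs_class == "R")
    n_s <- sum(rows$rs_class == "S")
    tibble::tibble(region_set = label, n_R = n_r, n_S = n_s,
                   n_unclassified = sum(rows$rs_class == "unclassified"),
                   rs_ratio = if (n_s > 0) n_r / n_s else NA_real_,
                   ratio_defined = n_s > 0)
  }
  regions <- sort(unique(mutations$region[!is.na(mutations$region)]))
  out <- dplyr::bind_rows(
    purrr::map_dfr(regions, function(r) one(r, mutations[!is.na(mutations$region) &
                                                           mutations$region == r, ])),
    one("CDR", mutations[mutations$region %in% cdr_regions, ]),
    one("FR", mutations[mutations$region %in% fr_regions, ])
  )
  out$below_germline_expectation <- ifelse(
    out$region_set %in% c("FR", fr_regions) & out$ratio_defined,
    out$rs_ratio < germline_expectation, NA)
  structure(out, germline_expectation = germline_expectation,
            class = c("selection_summary", class(tibble::tibble())))
}

#' Substitution spectrum with formalin-artifact flag
#'
#' Tabulates the 12 ordered base substitutions (sense strand of the merged
#' sequence). The artifact flag is raised when G>A plus C>T transitions —
#' the signature of formalin-driven cytosine deamination — exceed
#' `artifact_fraction` of all mutations.
#'
#' @param mutations Tibble from [call_mutations()].
#' @param artifact_fraction Flagging threshold (default 0.6).
#' @return A `mutation_spectrum` tibble (`from_base`, `to_base`, `count`,
#'   `fraction`) with attributes `artifact_flag` and `deamination_fraction`.
#' @export
substitution_spectrum <- function(mutations, artifact_fraction = 0.6) {
  grid <- tidyr::crossing(from_base = DNA_BASES, to_base = DNA_BASES)
  grid <- grid[grid$from_base != grid$to_base, ]
  counts <- dplyr::count(mutations, .data$from_base, .data$to_base, name = "count")
  out <- dplyr::left_join(grid, counts, by = c("from_base", "to_base"))
  out$count[is.na(out$count)] <- 0L
  total <- sum(out$count)
  out$fraction <- if (total > 0) out$count / total else 0
  deam <- sum(out$count[(out$from_base == "G" & out$to_base == "A") |
                          (out$from_base == "C" & out$to_base == "T")])
  flag <- total > 0 && (deam / total) > artifact_fraction
  structure(out, artifact_flag = flag,
            deamination_fraction = if (total > 0) deam / total else NA_real_,
            class = c("mutation_spectrum", class(tibble::tibble())))
}

#' Scan amino-acid sequences for N-glycosylation sequons
#'
#' Finds Asn-X-Ser/Thr acceptor motifs: positions `i` with `aa[i] == "N"`
#' and `aa[i+2]` in `{S, T}`. The default `"literal"` mode places no
#' constraint on the middle residue (beyond it being a known amino acid);
#' `"strict"` additionally excludes proline at the middle position. An
#' unknown residue (`X`) at any motif position prevents a match.
#'
#' @param aa Character vector of amino-acid sequences (`X` allowed for
#'   unknown residues).
#' @param mode `"literal"` or `"strict"`.
#' @return Tibble: `seq_index`, `aa`, `position` (of the Asn, 1-based); zero
#'   rows when nothing matches.
#' @export
#' @examples
#' scan_sequons("ANGSW")
#' scan_sequons("NPT", mode = "strict")
scan_sequons <- function(aa, mode = c("literal", "strict")) {
  mode <- match.arg(mode)
  pat <- if (mode == "literal") "N(?=[^X*][ST])" else "N(?=[^XP*][ST])"
  hits <- stringr::str_locate_all(aa, stringr::regex(pat))
  purrr::map2_dfr(hits, seq_along(hits), function(h, i) {
    if (nrow(h) == 0L) {
      return(tibble::tibble(seq_index = integer(), aa = character(),
                            position = integer()))
    }
    tibble::tibble(seq_index = i, aa = aa[i], position = as.integer(h[, 1]))
  })
}

#' Shift an amplicon-coordinate object into merged-read coordinates
#'
#' Merged reads are the amplicon minus the two primers, with the
#' unsequenced interior window replaced by `N`s; positions simply shift by
#' the forward-primer length. Returns the reference sequence masked to
#' merged form and the region map / frame start in merged coordinates.
#'
#' @param amplicon Reference amplicon sequence (primers included).
#' @param ref The `germline_set` (for primer lengths).
#' @param read_length Sequencer read length.
#' @param region_map Optional amplicon-coordinate region map to shift.
#' @return List: `sequence` (masked merged reference), `region_map`,
#'   `frame_start`, `offset` (amplicon position of merged position 1 minus
#'   one).
#' @export
merged_coords <- function(amplicon, ref, read_length = 112L,
                          region_map = NULL) {
  p1 <- nchar(ref$primers$forward)
  p2 <- nchar(ref$primers$reverse)
  L <- nchar(amplicon)
  gap <- L - 2L * read_length
  stopifnot(gap >= 0L)
  merged <- paste0(substr(amplicon, p1 + 1L, read_length),
                   strrep("N", gap),
                   substr(amplicon, read_length + gap + 1L, L - p2))
  rm2 <- NULL
  if (!is.null(region_map)) {
    rm2 <- region_map
    rm2$start <- pmax(rm2$start - p1, 1L)
    rm2$end <- pmin(rm2$end - p1, nchar(merged))
    rm2 <- rm2[rm2$start <= rm2$end, ]
  }
  list(sequence = merged, region_map = rm2,
       frame_start = (3L - (p1 %% 3L)) %% 3L + 1L,
       offset = p1)
}
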
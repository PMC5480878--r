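## Synthetic germline V/D/J reference with region-boundary annotations.
##
## The default design mirrors a consensus-primer FR2 clonality assay:
## every V allele shares the forward-primer binding site at the start of
## FR2 and every J allele shares the reverse-primer binding site at its
## 3' end, so one primer pair amplifies all rearrangements. Region bounds
## are 1-based closed in memory; the sidecar TSV written/read by
## write_germline_set()/read_germline_set() uses 0-based half-open
## coordinates as its interchange convention.

## V-region layout (nt, in-frame): FR1 75 | CDR1 24 | FR2 51 | CDR2 24 | FR3 114
V_REGION_LENGTHS <- c(FR1 = 75L, CDR1 = 24L, FR2 = 51L, CDR2 = 24L, FR3 = 114L)
V_LENGTH <- sum(V_REGION_LENGTHS)          # 288
V_AMPLICON_START <- 100L                   # FR2 start: the assay covers FR2..J
J_LENGTH <- 52L
J_TRIM_DEFAULT <- 3L                       # 5' nucleotides of J lost at the junction
J_ANCHOR_START <- 7L                       # conserved Trp codon (TGG) at J[7..9]
D_LENGTH <- 24L
PRIMER_LENGTH <- 20L
JUNCTION_LENGTH_DEFAULT <- 30L

## Founder junction: codes ARNGSGWYFD; with the first J codon (Y) the CDR3
## amino-acid sequence is ARNGSGWYFDY, which carries one N-X-S/T sequon
## (N.S at positions 3..5), as acquired by follicular-lymphoma receptors.
FOUNDER_JUNCTION <- "GCTAGAAATGGAAGCGGTTGGTACTTCGAT"

v_region_bounds <- function() {
  ends <- cumsum(V_REGION_LENGTHS)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble::tibble(region = names(V_REGION_LENGTHS),
                 start = unname(starts), end = unname(ends))
}

#' Build a synthetic annotated germline V/D/J reference
#'
#' Generates a seeded set of V, D and J alleles with the fixed region layout
#' used by the FR2 amplicon design: all V alleles share the forward-primer
#' site at the start of FR2 and end FR3 on the conserved Cys codon; all J
#' alleles carry the conserved Trp anchor and share the reverse-primer site.
#' The first D allele embeds the default founder junction core so that the
#' founder rearrangement has a resolvable D segment. Alternatively, a
#' reference previously written with [write_germline_set()] can be loaded via
#' `fixture`.
#'
#' @param n_v,n_d,n_j Number of V, D and J alleles to synthesise (each >= 2).
#' @param seed Integer seed; the same seed yields a byte-identical reference.
#' @param fixture Optional directory containing `segments.fasta`,
#'   `regions.tsv`, `segments.tsv` and `primers.tsv` (see
#'   [write_germline_set()]); when given, the reference is read from disk and
#'   validated instead of simulated.
#' @return A `germline_set`: list with `segments` (tibble: name,
#'   segment_class, sequence, reading_frame, anchor), `regions` (tibble of V
#'   region bounds, 1-based closed), `primers` and `design` parameters.
#' @export
#' @examples
#' ref <- build_germline_set(seed = 1)
#' ref$segments
build_germline_set <- function(n_v = 4, n_d = 4, n_j = 4, seed = 1,
                               fixture = NULL) {
  if (!is.null(fixture)) {
    return(read_germline_set(fixture))
  }
  stopifnot(n_v >= 2, n_d >= 2, n_j >= 2)
  set.seed(child_seed(seed, 1L))

  fr2_shared <- random_codons(7L)                      # 21 nt incl. primer site
  fwd_primer <- substr(fr2_shared, 1L, PRIMER_LENGTH)

  v_seqs <- vapply(seq_len(n_v), function(i) {
    fr1 <- random_codons(V_REGION_LENGTHS[["FR1"]] / 3L)
    cdr1 <- random_codons(V_REGION_LENGTHS[["CDR1"]] / 3L)
    fr2 <- paste0(fr2_shared, random_codons((V_REGION_LENGTHS[["FR2"]] - 21L) / 3L))
    cdr2 <- random_codons(V_REGION_LENGTHS[["CDR2"]] / 3L)
    fr3 <- paste0(random_codons(V_REGION_LENGTHS[["FR3"]] / 3L - 1L), "TGC")
    paste0(fr1, cdr1, fr2, cdr2, fr3)
  }, character(1))

  ## J tail (3' 20 nt) is the shared reverse-primer binding site; it sits one
  ## nucleotide out of codon phase inside J, so reject tails that would place
  ## a stop codon in the J reading frame.
  repeat {
    j_tail <- substr(random_codons(7L), 1L, PRIMER_LENGTH)
    if (!grepl("\\*", translate_nt(j_tail, frame_start = 2L))) break
  }
  j_seqs <- vapply(seq_len(n_j), function(i) {
    first_codon <- if (i == 1L) "TAC" else random_codons(1L)
    repeat {
      mid <- random_dna(J_LENGTH - 3L - 3L - 3L - PRIMER_LENGTH - 3L)
      s <- paste0(random_dna(3L), first_codon, "TGG", mid,
                  random_codons(1L), j_tail)
      ## reject stop codons in the reading frame used after junction trimming
      if (!grepl("\\*", translate_nt(s, frame_start = J_TRIM_DEFAULT + 1L))) {
        return(s)
      }
    }
  }, character(1))

  d_core <- substr(FOUNDER_JUNCTION, 7L, 24L)
  d_seqs <- vapply(seq_len(n_d), function(i) {
    if (i == 1L) paste0(random_dna(3L), d_core, random_dna(3L)) else random_dna(D_LENGTH)
  }, character(1))

  segments <- tibble::tibble(
    name = c(sprintf("IGHV3-S%02d*01", seq_len(n_v)),
             sprintf("IGHD2-S%02d*01", seq_len(n_d)),
             sprintf("IGHJ4-S%02d*01", seq_len(n_j))),
    segment_class = rep(c("V", "D", "J"), c(n_v, n_d, n_j)),
    sequence = c(v_seqs, d_seqs, j_seqs),
    reading_frame = 0L,
    anchor = c(rep(NA_integer_, n_v + n_d), rep(J_ANCHOR_START, n_j))
  )
  regions <- tidyr::crossing(segment = segments$name[segments$segment_class == "V"],
                             v_region_bounds())
  regions <- dplyr::arrange(regions, .data$segment, .data$start)

  ref <- structure(list(
    segments = segments,
    regions = regions,
    primers = list(forward = fwd_primer,
                   reverse = revcomp(substr(j_seqs[1], J_LENGTH - PRIMER_LENGTH + 1L, J_LENGTH))),
    design = list(v_amplicon_start = V_AMPLICON_START,
                  j_trim = J_TRIM_DEFAULT,
                  junction_length = JUNCTION_LENGTH_DEFAULT,
                  amplicon_length = (V_LENGTH - V_AMPLICON_START + 1L) +
                    JUNCTION_LENGTH_DEFAULT + (J_LENGTH - J_TRIM_DEFAULT))
  ), class = "germline_set")
  validate_germline_set(ref)
  ref
}

#' Validate a germline reference
#'
#' Checks the `germline_set` invariants: unique segment names, V region
#' bounds that partition a prefix of the V sequence without overlap, absence
#' of region bounds on D and J segments, and ACGT-only sequences.
#'
#' @param ref A `germline_set`.
#' @return `ref`, invisibly; errors describe the offending segment.
#' @export
validate_germline_set <- function(ref) {
  seg <- ref$segments
  if (anyDuplicated(seg$name)) {
    stop("duplicate segment names: ",
         paste(unique(seg$name[duplicated(seg$name)]), collapse = ", "))
  }
  bad <- !grepl("^[ACGT]+$", seg$sequence)
  if (any(bad)) {
    stop("non-ACGT characters in segment(s): ", paste(seg$name[bad], collapse = ", "))
  }
  non_v <- seg$name[seg$segment_class != "V"]
  if (any(ref$regions$segment %in% non_v)) {
    stop("region bounds present on non-V segment(s): ",
         paste(intersect(ref$regions$segment, non_v), collapse = ", "))
  }
  for (nm in unique(ref$regions$segment)) {
    b <- dplyr::arrange(ref$regions[ref$regions$segment == nm, ], .data$start)
    if (b$start[1] != 1L) stop("region bounds of ", nm, " do not start at position 1")
    if (any(b$start[-1] != b$end[-nrow(b)] + 1L)) {
      stop("region bounds of ", nm, " overlap or leave gaps")
    }
    v_len <- nchar(seg$sequence[seg$name == nm])
    if (b$end[nrow(b)] > v_len) stop("region bounds of ", nm, " exceed the sequence")
  }
  invisible(ref)
}

#' @export
print.germline_set <- function(x, ...) {
  cls <- table(x$segments$segment_class)
  cat("<germline_set> ", paste(sprintf("%d %s", cls, names(cls)), collapse = ", "),
      "; amplicon design ", x$design$amplicon_length, " nt\n", sep = "")
  invisible(x)
}

germline_segment <- function(ref, name) {
  i <- match(name, ref$segments$name)
  if (is.na(i)) stop("unknown segment allele: ", name)
  ref$segments[i, ]
}

segments_of_class <- function(ref, class) {
  ref$segments[ref$segments$segment_class == class, ]
}

#' Write a germline reference to plain-text files
#'
#' Emits `segments.fasta` (sequences), `segments.tsv` (class, reading frame,
#' J anchors), `regions.tsv` (V region bounds, 0-based half-open on disk) and
#' `primers.tsv` into `dir`.
#'
#' @param ref A `germline_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_germline_set <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(setNames(ref$segments$sequence, ref$segments$name))
  Biostrings::writeXStringSet(seqs, file.path(dir, "segments.fasta"))
  write.table(ref$segments[, c("name", "segment_class", "reading_frame", "anchor")],
              file.path(dir, "segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  regions0 <- dplyr::mutate(ref$regions, start = .data$start - 1L)  # 0-based half-open
  write.table(regions0, file.path(dir, "regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tibble::tibble(primer = c("forward", "reverse"),
                             sequence = c(ref$primers$forward, ref$primers$reverse)),
              file.path(dir, "primers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a germline reference written by [write_germline_set()]
#'
#' @param dir Directory holding the reference files.
#' @return A validated `germline_set`.
#' @export
read_germline_set <- function(dir) {
  fa <- file.path(dir, "segments.fasta")
  seqs <- Biostrings::readDNAStringSet(fa)
  seq_chr <- as.character(seqs)
  bad <- !grepl("^[ACGT]+$", seq_chr)
  if (any(bad)) {
    stop("malformed FASTA record(s) in ", fa, ": ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  meta <- tibble::as_tibble(read.delim(file.path(dir, "segments.tsv")))
  if (!setequal(meta$name, names(seqs))) {
    stop("segments.tsv and segments.fasta disagree on segment names")
  }
  meta$sequence <- unname(seq_chr[meta$name])
  meta$anchor <- as.integer(meta$anchor)
  regions <- tibble::as_tibble(read.delim(file.path(dir, "regions.tsv")))
  regions$start <- regions$start + 1L                      # back to 1-based closed
  primers <- read.delim(file.path(dir, "primers.tsv"))
  ref <- structure(list(
    segments = meta[, c("name", "segment_class", "sequence", "reading_frame", "anchor")],
    regions = regions,
    primers = list(forward = primers$sequence[primers$primer == "forward"],
                   reverse = primers$sequence[primers$primer == "reverse"]),
    design = list(v_amplicon_start = V_AMPLICON_START,
                  j_trim = J_TRIM_DEFAULT,
                  junction_length = JUNCTION_LENGTH_DEFAULT,
                  amplicon_length = (V_LENGTH - V_AMPLICON_START + 1L) +
                    JUNCTION_LENGTH_DEFAULT + (J_LENGTH - J_TRIM_DEFAULT))
  ), class = "germline_set")
  validate_germline_set(ref)
  ref
}

#' Describe a founder rearrangement
#'
#' Names the germline alleles and the junction insert (the N-D-N nucleotides
#' between the end of V and the retained 5' end of J) of a rearrangement.
#'
#' @param v_call,d_call,j_call Allele names present in the reference
#'   (`d_call` is informational; the junction nucleotides are given
#'   explicitly).
#' @param junction Junction insert nucleotides (default: the built-in founder
#'   junction, whose CDR3 carries one N-X-S/T sequon).
#' @param j_trim Number of 5' J nucleotides removed by the rearrangement.
#' @return A `founder_spec` list.
#' @export
founder_spec <- function(v_call = "IGHV3-S01*01", d_call = "IGHD2-S01*01",
                         j_call = "IGHJ4-S01*01", junction = FOUNDER_JUNCTION,
                         j_trim = J_TRIM_DEFAULT) {
  structure(list(v_call = v_call, d_call = d_call, j_call = j_call,
                 junction = junction, j_trim = j_trim),
            class = "founder_spec")
}

#' Recombine germline segments into a naive rearrangement
#'
#' Joins the full V sequence, the junction insert and the trimmed J sequence.
#' This is the unmutated ("germline") configuration of a clone, used both by
#' the simulator and as the reference coordinate system for mutation calling.
#'
#' @param ref A `germline_set`.
#' @param spec A [founder_spec()].
#' @return Character scalar: the rearranged nucleotide sequence.
#' @export
recombine_segments <- function(ref, spec) {
  v <- germline_segment(ref, spec$v_call)
  j <- germline_segment(ref, spec$j_call)
  if (!is.null(spec$d_call)) germline_segment(ref, spec$d_call)  # lookup check
  paste0(v$sequence, spec$junction,
         substr(j$sequence, spec$j_trim + 1L, nchar(j$sequence)))
}

#' Region map of a rearranged amplicon
#'
#' Returns the coordinates, on the amplicon (which starts at FR2), of the
#' regions covered by the FR2 assay: FR2, CDR2, FR3, CDR3 (junction insert
#' plus the first retained J codon) and the remaining J.
#'
#' @param ref A `germline_set`.
#' @param junction_length Junction insert length in nt.
#' @param j_trim 5' J trimming of the rearrangement.
#' @return Tibble with `region`, `start`, `end` (1-based closed amplicon
#'   coordinates).
#' @export
amplicon_region_map <- function(ref, junction_length = ref$design$junction_length,
                                j_trim = ref$design$j_trim) {
  off <- ref$design$v_amplicon_start - 1L
  vb <- v_region_bounds()
  vb <- vb[vb$end > off, ]
  vb$start <- pmax(vb$start - off, 1L)
  vb$end <- vb$end - off
  v_end <- max(vb$end)
  cdr3_end <- v_end + junction_length + 3L
  j_end <- v_end + junction_length + (J_LENGTH - j_trim)
  dplyr::bind_rows(
    vb,
    tibble::tibble(region = c("CDR3", "J"),
                   start = c(v_end + 1L, cdr3_end + 1L),
                   end = c(cdr3_end, j_end))
  )
}

## Amplicon of a full rearranged sequence (FR2 start through J end).
amplicon_of <- function(ref, full_sequence) {
  substr(full_sequence, ref$design$v_amplicon_start, nchar(full_sequence))
}
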
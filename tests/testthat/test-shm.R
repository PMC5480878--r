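test_that("mutation calling records mismatched non-N columns with regions", {
  refseq <- "ATGGCTAAGGCT"
  rmap <- tibble::tibble(region = c("FR2", "CDR2"), start = c(1L, 7L),
                         end = c(6L, 12L))
  expect_equal(nrow(call_mutations(refseq, refseq, rmap)), 0)

  one <- call_mutations(sub("AAG", "AGG", refseq), refseq, rmap)
  expect_equal(one$position, 8L)
  expect_equal(one$region, "CDR2")
  expect_equal(one$from_base, "A")
  expect_equal(one$to_base, "G")

  # N on either side silences the column
  expect_equal(nrow(call_mutations("ATGNCTAAGGCT", refseq, rmap)), 0)
  expect_equal(nrow(call_mutations(refseq, "ATGNCTAAGGCT", rmap)), 0)
})

test_that("simulated lineage mutations are recovered exactly", {
  ref <- tiny_ref()
  lin <- simulate_clone_groups(ref, n_groups = 2, n_unproductive = 0,
                               group_sizes = c(2, 1), founder_mutations = 8,
                               seed = 6)
  naive <- attr(lin, "naive_sequence")
  for (i in seq_len(nrow(lin))) {
    called <- call_mutations(lin$sequence[i], naive)
    truth_pos <- which(strsplit(lin$sequence[i], "")[[1]] !=
                         strsplit(naive, "")[[1]])
    expect_equal(called$position, truth_pos)
  }
})

test_that("R/S classification handles the canonical codon cases", {
  m <- tibble::tibble(uid = "u", position = c(3L, 5L, 8L),
                      region = NA_character_,
                      from_base = c("G", "G", "N"),
                      to_base = c("A", "A", "A"),
                      codon_index = c(1L, 2L, 3L))
  # GAG->GAA silent (Glu), AGT->AAT replacement (Ser->Asn), N codon unclassified
  out <- classify_rs(m, "GAGAGTNNN")
  expect_equal(out$rs_class, c("S", "R", "unclassified"))
})

test_that("R/S ratios reproduce the arithmetic and degenerate cases", {
  mk <- function(region, rs) tibble::tibble(region = region, rs_class = rs)
  cdr <- mk(rep("CDR2", 12), c(rep("R", 11), "S"))
  s <- rs_summary(cdr)
  expect_equal(s$rs_ratio[s$region_set == "CDR"], 11)
  fr <- mk(rep("FR3", 14), c(rep("R", 9), rep("S", 5)))
  s2 <- rs_summary(fr)
  expect_equal(s2$rs_ratio[s2$region_set == "FR"], 1.8)
  expect_true(s2$below_germline_expectation[s2$region_set == "FR"])
  # S = 0: undefined ratio, flagged, R count still reported
  s3 <- rs_summary(mk(rep("FR2", 3), rep("R", 3)))
  fr_row <- s3[s3$region_set == "FR", ]
  expect_true(is.na(fr_row$rs_ratio))
  expect_false(fr_row$ratio_defined)
  expect_equal(fr_row$n_R, 3)
})

test_that("R/S agrees with exhaustive single-variant enumeration (seqinr oracle)", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) {
    for (pos in 1:3) {
      for (to in setdiff(bases, substr(codon, pos, pos))) {
        m <- tibble::tibble(position = pos, to_base = to)
        got <- classify_rs(m, codon)$rs_class
        mut <- codon
        substr(mut, pos, pos) <- to
        aa0 <- seqinr::translate(seqinr::s2c(codon))
        aa1 <- seqinr::translate(seqinr::s2c(mut))
        expect_identical(got, if (aa0 == aa1) "S" else "R")
      }
    }
  }
})

test_that("substitution spectrum counts and artifact flag behave", {
  recs <- tibble::tibble(from_base = c("G", "G", "G"), to_base = c("A", "A", "A"))
  sp <- substitution_spectrum(recs)
  expect_equal(sum(tibble::as_tibble(sp)$count), 3)
  expect_equal(tibble::as_tibble(sp)$count[tibble::as_tibble(sp)$from_base == "G" &
                                             tibble::as_tibble(sp)$to_base == "A"], 3)
  expect_true(attr(sp, "artifact_flag"))

  uniform <- tidyr::crossing(from_base = c("A", "C", "G", "T"),
                             to_base = c("A", "C", "G", "T"))
  uniform <- uniform[uniform$from_base != uniform$to_base, ]
  expect_false(attr(substitution_spectrum(uniform), "artifact_flag"))
})

test_that("sequon scanning matches its definition in both modes", {
  expect_equal(scan_sequons("ANGSW")$position, 2L)
  # N-P-T: a hit in the literal motif, excluded under the strict rule
  expect_equal(nrow(scan_sequons("NPT")), 1)
  expect_equal(nrow(scan_sequons("NPT", mode = "strict")), 0)
  # X anywhere in the motif prevents a match
  expect_equal(nrow(scan_sequons(c("XGT", "NXS", "NGX"))), 0)
  # overlapping motifs are all reported
  expect_equal(scan_sequons("NNSS")$position, c(1L, 2L))
})

test_that("sequon scanning equals a sliding-window oracle on random strings", {
  set.seed(3)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  strs <- vapply(1:800, function(i)
    paste(sample(alphabet, 12, replace = TRUE, prob = c(rep(1, 20), 3)),
          collapse = ""), character(1))
  oracle <- function(s, strict) {
    ch <- strsplit(s, "")[[1]]
    hits <- integer(0)
    for (i in seq_len(length(ch) - 2)) {
      ok <- ch[i] == "N" && ch[i + 2] %in% c("S", "T") && ch[i + 1] != "X"
      if (strict) ok <- ok && ch[i + 1] != "P"
      if (ok) hits <- c(hits, i)
    }
    hits
  }
  for (strict in c(FALSE, TRUE)) {
    got <- scan_sequons(strs, mode = if (strict) "strict" else "literal")
    want <- purrr::map_dfr(seq_along(strs), function(i) {
      h <- oracle(strs[i], strict)
      tibble::tibble(seq_index = rep(i, length(h)), position = h)
    })
    expect_equal(got[, c("seq_index", "position")], want)
  }
})

test_that("CDR mutation density exceeds FR density under the 3x bias", {
  ref <- tiny_ref()
  lin <- simulate_lineage(ref, n_rounds = 1, mutation_rate = 0.02,
                          n_children = 300, cdr_bias = 3,
                          fr_replacement_veto = 0, cdr_silent_veto = 0,
                          seed = 12)
  muts <- dplyr::bind_rows(lin$mutations)
  rmap <- full_region_map(attr(lin, "junction_length"))
  muts$region <- region_of_positions(muts$position, rmap)
  widths <- setNames(rmap$end - rmap$start + 1L, rmap$region)
  dens <- function(set) sum(muts$region %in% set) / sum(widths[set])
  expect_gt(dens(c("CDR1", "CDR2", "CDR3")), dens(c("FR1", "FR2", "FR3")))
})
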
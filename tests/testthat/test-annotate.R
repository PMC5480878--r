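test_that("exact germline fragments align at 100% identity to their allele", {
  ref <- tiny_ref()
  v2 <- ref$segments$sequence[ref$segments$name == "IGHV3-S02*01"]
  frag <- substr(v2, 60, 240)
  av <- align_v(frag, ref)
  expect_equal(av$v_call, "IGHV3-S02*01")
  expect_equal(av$v_identity, 100)
  expect_equal(av$v_germ_start - av$v_read_start + 1L, 60L)

  j2 <- ref$segments$sequence[ref$segments$name == "IGHJ4-S02*01"]
  aj <- align_j(substr(j2, 4, 52), ref)
  expect_equal(aj$j_call, "IGHJ4-S02*01")
  expect_equal(aj$j_identity, 100)
})

test_that("identity arithmetic: 5 substitutions over 100 columns give 95%", {
  ref <- tiny_ref()
  v1 <- ref$segments$sequence[ref$segments$name == "IGHV3-S01*01"]
  frag <- substr(v1, 101, 200)
  ch <- strsplit(frag, "")[[1]]
  for (p in c(10, 30, 50, 70, 90)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  av <- align_v(paste(ch, collapse = ""), ref)
  expect_equal(av$v_call, "IGHV3-S01*01")
  expect_equal(av$v_identity, 95)
  expect_equal(av$v_columns, 100)
})

test_that("N columns are excluded from both numerator and denominator", {
  ref <- tiny_ref()
  v1 <- ref$segments$sequence[ref$segments$name == "IGHV3-S01*01"]
  frag <- substr(v1, 101, 200)
  frag_n <- paste0(substr(frag, 1, 40), strrep("N", 20), substr(frag, 61, 100))
  av <- align_v(frag_n, ref)
  expect_equal(av$v_identity, 100)
  expect_equal(av$v_columns, 80)
})

test_that("equal-identity J candidates tie to the first allele, flagged", {
  ref <- tiny_ref()
  ## all J alleles share their 3' 20 nt (the reverse-primer site)
  j1 <- ref$segments$sequence[ref$segments$name == "IGHJ4-S01*01"]
  shared <- substr(j1, nchar(j1) - 19, nchar(j1))
  aj <- align_j(shared, ref, min_columns = 12)
  expect_equal(aj$j_call, "IGHJ4-S01*01")
  expect_true(aj$j_tie)
})

test_that("D resolution matches an exhaustive substring-scan oracle", {
  ref <- tiny_ref()
  ds <- segments_of_class(ref, "D")
  ds <- ds[order(ds$name), ]
  # exact 8-mer of a D inside an otherwise random junction
  d2 <- ds$sequence[ds$name == "IGHD2-S02*01"]
  junc <- paste0("CATCAT", substr(d2, 5, 12), "GTACGTAGA")
  r <- resolve_d(junc, ref, min_d_match = 5)
  expect_equal(r$d_call, "IGHD2-S02*01")
  expect_gte(r$d_match_length, 8L)
  # pure-N junction: no call
  expect_true(is.na(resolve_d(strrep("N", 20), ref)$d_call))

  # randomized junctions against a naive R oracle
  oracle_run <- function(a, b) {
    best <- 0L
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    for (i in seq_along(av)) for (j in seq_along(bv)) {
      k <- 0L
      while (i + k <= length(av) && j + k <= length(bv) &&
             av[i + k] == bv[j + k]) k <- k + 1L
      best <- max(best, k)
    }
    best
  }
  set.seed(14)
  juncs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  got <- resolve_d(juncs, ref, min_d_match = 5)
  for (i in seq_along(juncs)) {
    runs <- vapply(ds$sequence, function(d) oracle_run(juncs[i], d), integer(1))
    if (max(runs) < 5) {
      expect_true(is.na(got$d_call[i]))
    } else {
      expect_equal(got$d_call[i], ds$name[which.max(runs)])
      expect_equal(got$d_match_length[i], max(runs))
    }
  }
})

test_that("annotation recovers the founder and its regions on merged reads", {
  ref <- tiny_ref()
  spec <- founder_spec()
  naive <- recombine_segments(ref, spec)
  merged <- merged_form(ref, naive)
  ann <- annotate_vdj(merged, ref)
  expect_true(ann$specific)
  expect_equal(ann$v_call, spec$v_call)
  expect_equal(ann$j_call, spec$j_call)
  expect_equal(ann$d_call, spec$d_call)
  expect_true(ann$productive)
  expect_false(ann$stop_codon)              # N-gap codons never count as stops
  expect_equal(ann$cdr3_aa, "ARNGSGWYFDY")
  rm <- read_region_map(ann)
  expect_true(all(rm$start <= rm$end))
  expect_true(all(diff(rm$start) > 0))      # ordered
  expect_true(all(rm$end[-nrow(rm)] < rm$start[-1]))  # disjoint
  expect_true(all(rm$end <= nchar(merged)))
  expect_setequal(rm$region, c("FR2", "CDR2", "FR3", "CDR3", "J"))
})

test_that("frameshifted junctions and engineered stops are unproductive", {
  ref <- tiny_ref()
  spec <- founder_spec()
  # junction shortened by one nucleotide: out of frame
  fs <- founder_spec(junction = substr(spec$junction, 2, nchar(spec$junction)))
  ann_fs <- annotate_vdj(amplicon_of(ref, recombine_segments(ref, fs)), ref)
  expect_false(ann_fs$in_frame)
  expect_false(ann_fs$productive)

  # TAA engineered into FR3
  naive <- recombine_segments(ref, spec)
  mutated <- paste0(substr(naive, 1, 270), "TAA", substr(naive, 274, nchar(naive)))
  ann_stop <- annotate_vdj(amplicon_of(ref, mutated), ref)
  expect_true(ann_stop$stop_codon)
  expect_false(ann_stop$productive)
  expect_true(ann_stop$in_frame)
})

test_that("unalignable sequences are marked nonspecific, not errors", {
  ref <- tiny_ref()
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  ann <- annotate_vdj(junk, ref)
  expect_false(ann$specific)
  expect_true(is.na(ann$cdr3_aa))
})
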
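make_sheet <- function(n) {
  tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)),
                 barcode = c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT",
                             "ACGTACG", "TGCATGC")[seq_len(n)],
                 site_label = "LN1")
}

test_that("demultiplexing partitions reads and matches a naive oracle", {
  set.seed(1)
  sheet <- make_sheet(4)
  bcs <- c(sheet$barcode, "AACAAAA")  # one off-by-one barcode
  reads <- tibble::tibble(read_id = sprintf("r%04d", 1:3000),
                          barcode = sample(bcs, 3000, replace = TRUE))
  dm <- demultiplex(reads, sheet)
  # partition property
  expect_equal(sum(!is.na(dm$sample_id)) + sum(is.na(dm$sample_id)), nrow(reads))
  # brute-force dictionary oracle
  oracle <- table(factor(sheet$sample_id[match(reads$barcode, sheet$barcode)],
                         levels = sheet$sample_id))
  got <- table(factor(dm$sample_id, levels = sheet$sample_id))
  expect_equal(as.integer(got), as.integer(oracle))
  # exact matching: the 1-mismatch barcode stays unassigned
  expect_true(all(is.na(dm$sample_id[reads$barcode == "AACAAAA"])))
  # ... but is recovered under a 1-mismatch allowance
  dm1 <- demultiplex(reads, sheet, max_mismatch = 1)
  expect_true(all(dm1$sample_id[reads$barcode == "AACAAAA"] == "S01"))
  # duplicate barcodes are a configuration error
  bad <- sheet; bad$barcode[2] <- bad$barcode[1]
  expect_error(demultiplex(reads, bad), "duplicate barcode")
})

test_that("primer trimming removes primers and reports missing ones", {
  primers <- list(forward = "ACGTACGTAC", reverse = "GGCCGGCCGG")
  mk <- function(m1, m2) tibble::tibble(
    read_id = "r1", mate1 = m1, qual1 = strrep("I", nchar(m1)),
    mate2 = m2, qual2 = strrep("I", nchar(m2)))
  r <- trim_primers(mk(paste0(primers$forward, "TTTT"),
                       paste0(primers$reverse, "AAAA")), primers)
  expect_identical(r$mate1, "TTTT")
  expect_identical(r$mate2, "AAAA")
  expect_identical(r$qual1, "IIII")
  expect_true(is.na(r$trim_reason))

  r2 <- trim_primers(mk("TTTTTTTTTTTTTT", paste0(primers$reverse, "AAAA")),
                     primers)
  expect_identical(r2$trim_reason, "missing-forward-primer")
  expect_identical(r2$mate1, "TTTTTTTTTTTTTT")  # untrimmed when rejected

  one_off <- paste0("CCGTACGTAC", "TTTT")
  expect_identical(trim_primers(mk(one_off, paste0(primers$reverse, "A")),
                                primers)$trim_reason, "missing-forward-primer")
  expect_true(is.na(trim_primers(mk(one_off, paste0(primers$reverse, "A")),
                                 primers, max_mismatch = 1)$trim_reason))
})

test_that("quality filter demands every base at or above the threshold", {
  mk <- function(q1) tibble::tibble(mate1 = "ACGT", qual1 = q1,
                                    mate2 = "ACGT", qual2 = "IIII")
  q <- function(phred) intToUtf8(rep(phred + 33, 4))
  expect_true(quality_filter(mk(q(30)))$quality_pass)
  expect_false(quality_filter(mk(paste0(substr(q(30), 1, 3), "0")))$quality_pass)  # one Q15
  # boundary: one base exactly Q20 fails the default (strict "above 20") ...
  expect_false(quality_filter(mk(paste0(substr(q(40), 1, 3), "5")))$quality_pass)
  # ... and passes an inclusive threshold of 20
  expect_true(quality_filter(mk(paste0(substr(q(40), 1, 3), "5")),
                             min_base_quality = 20)$quality_pass)
  expect_error(quality_filter(tibble::tibble(mate1 = "ACGT", qual1 = "III",
                                             mate2 = "A", qual2 = "I")),
               "differ in length")
})

test_that("gap merging obeys the length law and the amplicon arithmetic", {
  reads <- tibble::tibble(read_id = "r", mate1 = strrep("A", 112),
                          mate2 = strrep("C", 112))
  m <- merge_with_gap(reads, gap_n_count = 44)
  expect_equal(nchar(m$sequence), 112 + 44 + 112)
  expect_equal(nchar(m$sequence), 268)           # the clonal amplicon length
  expect_identical(m$sequence,
                   paste0(strrep("A", 112), strrep("N", 44), strrep("G", 112)))
  # zero gap degenerates to plain concatenation with the mate reverse-complemented
  m0 <- merge_with_gap(tibble::tibble(read_id = "r", mate1 = "ACGT", mate2 = "AATT"),
                       gap_n_count = 0)
  expect_identical(m0$sequence, paste0("ACGT", "AATT"))
})

test_that("dereplication counts match a brute-force oracle and conserve reads", {
  simple <- tibble::tibble(sample_id = "S01",
                           sequence = c("AAA", "AAA", "AAT"))
  u <- dereplicate(simple)
  expect_equal(u$count[u$sequence == "AAA"], 2)
  expect_equal(u$frequency[u$sequence == "AAT"], 1 / 3, tolerance = 1e-12)

  set.seed(7)
  seqs <- vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    character(1))
  merged <- tibble::tibble(sample_id = rep(c("S01", "S02"), each = 1000),
                           sequence = seqs)
  u <- dereplicate(merged)
  expect_equal(sum(u$count), 2000)
  for (s in c("S01", "S02")) {
    oracle <- table(merged$sequence[merged$sample_id == s])
    got <- setNames(u$count[u$sample_id == s], u$sequence[u$sample_id == s])
    expect_equal(as.integer(got[names(oracle)]), as.integer(oracle))
    expect_equal(sum(u$frequency[u$sample_id == s]), 1, tolerance = 1e-12)
  }
})

test_that("the noise floor removes strictly-below-threshold uniques and is idempotent", {
  u <- dereplicate(tibble::tibble(
    sample_id = "S01",
    sequence = c(rep("AAA", 1998), "CCC", "GGG")))
  u$count[u$sequence == "CCC"] <- 2L   # craft exact boundary: 2/2000 = 0.1%
  u$frequency <- u$count / u$sample_total
  kept <- noise_filter(u, threshold = 0.001)
  expect_true("CCC" %in% kept$sequence)       # exactly at the floor: retained
  expect_false("GGG" %in% kept$sequence)      # 1/2000 < 0.1%: removed
  expect_identical(noise_filter(kept, threshold = 0.001), kept)  # idempotent
  expect_identical(noise_filter(u, threshold = 0), u)            # 0 = identity
  # retained counts and frequencies are unchanged by filtering
  expect_equal(kept$count, u$count[match(kept$sequence, u$sequence)])
})

test_that("process_reads keeps per-step accounting consistent", {
  sim <- tiny_sim()
  pr <- process_reads(sim$reads, sim$sample_sheet, sim$reference$primers)
  expect_equal(sum(pr$log$demultiplexed) + attr(pr$log, "unassigned"),
               nrow(sim$reads))
  expect_true(all(pr$log$trimmed <= pr$log$demultiplexed))
  expect_true(all(pr$log$quality_passed <= pr$log$trimmed))
  # merged read counts equal quality-passed counts
  expect_equal(nrow(pr$merged), sum(pr$log$quality_passed))
  # all merged sequences share the design length
  expect_equal(unique(nchar(pr$merged$sequence)), 268 - 2 * 20)
})
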
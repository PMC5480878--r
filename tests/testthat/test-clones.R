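ref_and_clone <- function() {
  ref <- tiny_ref()
  spec <- founder_spec()
  naive <- recombine_segments(ref, spec)
  cref <- clone_reference(merged_form(ref, naive), ref)
  list(ref = ref, spec = spec, naive = naive, cref = cref)
}

test_that("classification accepts the reference and reports failure reasons", {
  fx <- ref_and_clone()
  ann <- annotate_vdj(fx$cref$sequence, fx$ref)
  cl <- classify_clone(ann, fx$cref)
  expect_true(cl$clone_specific)
  expect_true(is.na(cl$classify_reason))

  # same V, different J gene -> unrelated with reason J-mismatch
  other_j <- founder_spec(j_call = "IGHJ4-S03*01")
  ann_j <- annotate_vdj(merged_form(fx$ref, recombine_segments(fx$ref, other_j)),
                        fx$ref)
  cl_j <- classify_clone(ann_j, fx$cref)
  expect_false(cl_j$clone_specific)
  expect_equal(cl_j$classify_reason, "J-mismatch")

  # different V gene
  other_v <- founder_spec(v_call = "IGHV3-S03*01")
  cl_v <- classify_clone(
    annotate_vdj(merged_form(fx$ref, recombine_segments(fx$ref, other_v)), fx$ref),
    fx$cref)
  expect_equal(cl_v$classify_reason, "V-mismatch")

  # junction replaced by a distant one: CDR3 identity failure
  distant <- founder_spec(junction = "TGGCACCCTATCAACGATATTAGAGAGCAC")
  cl_d <- classify_clone(
    annotate_vdj(merged_form(fx$ref, recombine_segments(fx$ref, distant)), fx$ref),
    fx$cref)
  expect_false(cl_d$clone_specific)
  expect_equal(cl_d$classify_reason, "CDR3-identity")
})

test_that("CDR3 grouping partitions exactly and orders by total count", {
  ann <- tibble::tibble(
    uid = sprintf("u%d", 1:5),
    sample_id = c("S01", "S01", "S02", "S02", "S01"),
    count = c(10L, 5L, 4L, 2L, 1L),
    cdr3_aa = c("ARAAA", "ARAAA", "ARCCC", "ARAAA", "ARDDD"),
    productive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    clone_specific = TRUE)
  g <- group_by_cdr3(ann)
  expect_equal(nrow(g), 3)
  expect_equal(g$group_id, c("G1", "G2", "G3"))
  expect_equal(g$cdr3_aa[1], "ARAAA")          # 17 reads, largest
  expect_equal(g$total_count, c(17L, 4L, 1L))
  expect_equal(sum(g$n_members), 5)
  # unproductive sequences form their own group even at shared CDR3
  ann2 <- ann
  ann2$cdr3_aa[5] <- "ARAAA"
  g2 <- group_by_cdr3(ann2)
  expect_equal(nrow(g2), 3)
  expect_equal(sum(g2$productive), 2)

  # invariance to input order (same groups; member rows follow input order)
  perm <- c(4, 1, 5, 3, 2)
  g_perm <- group_by_cdr3(ann[perm, ])
  expect_equal(lapply(g_perm, identity), lapply(g, identity))  # column-wise
  m1 <- dplyr::arrange(tidy(g), uid)
  m2 <- dplyr::arrange(tidy(g_perm), uid)
  expect_equal(m1, m2)

  # partition equals a brute-force equality grouping
  oracle <- split(ann$uid, paste(ann$cdr3_aa, ann$productive))
  members <- tidy(g)
  got <- split(members$uid, members$group_id)
  expect_setequal(lapply(unname(oracle), sort), lapply(unname(got), sort))
})

test_that("at zero ongoing SHM all clone reads form a single founder group", {
  fx <- ref_and_clone()
  lin <- simulate_clone_groups(fx$ref, n_groups = 1, n_unproductive = 0,
                               group_sizes = 1, founder_mutations = 6, seed = 2)
  m <- merged_form(fx$ref, attr(lin, "founder_sequence"))
  ann <- classify_clone(
    annotate_vdj(tibble::tibble(sample_id = "S01", uid = "u1", count = 50L,
                                sequence = m), fx$ref),
    clone_reference(m, fx$ref))
  g <- group_by_cdr3(ann)
  expect_equal(nrow(g), 1)
  expect_equal(g$cdr3_aa, lin$cdr3_aa[1])
})

test_that("sample composition accounts reads and flags unevaluable samples", {
  ann <- tibble::tibble(
    sample_id = rep(c("S01", "S02"), c(3, 2)),
    uid = sprintf("u%d", 1:5),
    count = c(40L, 40L, 20L, 30L, 70L),
    cdr3_aa = c("ARAAA", "ARAAA", "ARBBB", "ARCCC", "ARDDD"),
    productive = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    clone_specific = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  g <- group_by_cdr3(ann)
  comp <- sample_composition(ann, g)
  s1 <- comp[comp$sample_id == "S01", ]
  expect_equal(s1$pct_clone_specific, 80)            # 80 of 100 reads
  expect_equal(s1$pct_unrelated, 20)
  expect_equal(s1$pct_unproductive, 50)              # 40 of 80 specific reads
  expect_true(s1$evaluable)
  s2 <- comp[comp$sample_id == "S02", ]
  expect_equal(s2$pct_clone_specific, 0)
  expect_false(s2$evaluable)                         # no clone-specific reads
  expect_true(is.na(s2$pct_unproductive))
})

test_that("classification plus grouping conserves counts", {
  sim <- tiny_sim()
  res <- run_pipeline(sim)
  ann <- res$annotations
  expect_equal(sum(res$groups$total_count) +
                 sum(ann$count[!isTRUE_v(ann$clone_specific)]),
               sum(ann$count))
})
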
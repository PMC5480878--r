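test_that("group consensus follows majority vote with reference tie-breaks", {
  refseq <- "AAAA"
  one <- tibble::tibble(group_id = "G1", sequence = "ACGT")
  expect_equal(group_consensus(one, reference_sequence = refseq)$consensus, "ACGT")

  maj <- tibble::tibble(group_id = "G1",
                        sequence = c("ACGT", "ACGA", "ACGT"))
  expect_equal(group_consensus(maj, reference_sequence = refseq)$consensus, "ACGT")

  # 1/1 tie at the last column falls back to the reference base
  tie <- tibble::tibble(group_id = "G1", sequence = c("ACGT", "ACGA"))
  expect_equal(group_consensus(tie, reference_sequence = refseq)$consensus, "ACGA")
  # N never votes
  withN <- tibble::tibble(group_id = "G1", sequence = c("ACGN", "ACGC", "ACNC"))
  expect_equal(group_consensus(withN, reference_sequence = refseq)$consensus, "ACGC")

  # random groups equal a naive per-column tally oracle
  set.seed(4)
  for (rep in 1:5) {
    seqs <- vapply(1:7, function(i)
      paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                   prob = c(1, 1, 1, 1, 0.3)), collapse = ""), character(1))
    refr <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    got <- group_consensus(tibble::tibble(group_id = "G", sequence = seqs),
                           reference_sequence = refr)$consensus
    want <- vapply(1:30, function(p) {
      col <- substring(seqs, p, p)
      col <- col[col != "N"]
      if (!length(col)) return("N")
      tab <- sort(table(col), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1) top else if (substr(refr, p, p) %in% top)
        substr(refr, p, p) else sort(top)[1]
    }, character(1))
    expect_equal(got, paste(want, collapse = ""))
  }
})

test_that("p-distances exclude N columns and match a brute-force scan", {
  s <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAT", c = "AANNAAAAAT")
  d <- pairwise_distances(s)
  expect_equal(d$p["a", "a"], 0)
  expect_equal(d$raw["a", "b"], 1)
  expect_equal(d$p["a", "b"], 0.1)
  expect_equal(d$comparable["a", "c"], 8)
  expect_equal(d$p["a", "c"], 1 / 8)
  expect_true(isSymmetric(d$p))

  # 3 mismatches over 100 comparable columns -> 0.03
  x <- strrep("A", 100)
  y <- paste0(strrep("A", 97), "TTT")
  expect_equal(pairwise_distances(c(x = x, y = y))$p["x", "y"], 0.03)

  set.seed(9)
  seqs <- setNames(vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE,
                 prob = c(1, 1, 1, 1, 0.2)), collapse = ""), character(1)),
    paste0("s", 1:6))
  d2 <- pairwise_distances(seqs)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    ok <- a != "N" & b != "N"
    expect_equal(d2$raw[i, j], sum(a[ok] != b[ok]))
    expect_equal(d2$p[i, j], sum(a[ok] != b[ok]) / sum(ok))
  }
})

test_that("three-taxon neighbor joining matches the closed-form solution", {
  m <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(m)
  expect_false(tr$degenerate)
  phy <- tr$phylo
  # closed form: a = (dAB + dAC - dBC)/2 = 0, b = 2, c = 4
  lens <- setNames(phy$edge.length[match(seq_along(phy$tip.label), phy$edge[, 2])],
                   phy$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(0, 2, 4))
  # newick round-trips losslessly
  back <- ape::read.tree(text = tr$newick)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  expect_equal(sort(back$edge.length), sort(phy$edge.length))
})

test_that("NJ recovers additive 4- and 5-taxon trees with exact path lengths", {
  # additive matrix from a known 4-taxon tree: ((A:1,B:2):3,(C:4,D:5))
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["A", "C"] <- d4["C", "A"] <- 8
  d4["A", "D"] <- d4["D", "A"] <- 9
  d4["B", "C"] <- d4["C", "B"] <- 9
  d4["B", "D"] <- d4["D", "B"] <- 10
  d4["C", "D"] <- d4["D", "C"] <- 9
  tr <- build_tree(d4)
  # four-point oracle: the true split pairs have the smallest sum
  sums <- c(AB_CD = d4["A", "B"] + d4["C", "D"],
            AC_BD = d4["A", "C"] + d4["B", "D"],
            AD_BC = d4["A", "D"] + d4["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
  # NJ tree reproduces every pairwise path length (hence the true topology)
  expect_equal(ape::cophenetic.phylo(tr$phylo)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-9)

  # 5 taxa on a random additive tree
  set.seed(21)
  phy5 <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
  d5 <- ape::cophenetic.phylo(phy5)
  tr5 <- build_tree(d5)
  expect_equal(ape::cophenetic.phylo(tr5$phylo)[rownames(d5), colnames(d5)], d5,
               tolerance = 1e-9)
})

test_that("degenerate inputs give a degenerate-tree state, not an error", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- build_tree(d2)
  expect_true(tr$degenerate)
  expect_match(tr$newick, "A")
})

test_that("germline rooting identifies the nearest group with tie handling", {
  s <- c(G1 = "AAAAAAAAAA", G2 = "AAAAAAATTT", germline = "AAAAAAAAAT")
  d <- pairwise_distances(s)
  tr <- build_tree(d)
  r <- root_to_germline(tr, d)
  expect_equal(r$nearest_group, "G1")
  expect_equal(r$ordering$group_id, c("G1", "G2"))
  # equidistant groups: tie reported, lexicographic winner
  s2 <- c(G2 = "AAAT", G1 = "AATA", germline = "AAAA")
  d2 <- pairwise_distances(s2)
  r2 <- root_to_germline(build_tree(d2), d2)
  expect_equal(sort(r2$nearest_tied), c("G1", "G2"))
  expect_equal(r2$nearest_group, "G1")
  expect_error(root_to_germline(build_tree(d2), d2, germline_label = "gl"),
               "not among the tree leaves")
})

test_that("trafficking classification distinguishes follicle- and node-level sharing", {
  g <- structure(
    tibble::tibble(group_id = c("G1", "G2", "G3"),
                   cdr3_aa = c("A", "B", "C"), productive = TRUE,
                   n_members = c(2L, 2L, 1L), total_count = c(20L, 10L, 5L)),
    members = tibble::tibble(
      group_id = c("G1", "G1", "G2", "G2", "G3"),
      sample_id = c("S01", "S02", "S01", "S03", "S02"),
      count = c(12L, 8L, 6L, 4L, 5L)),
    class = c("clone_groups", class(tibble::tibble())))
  sheet <- tibble::tibble(sample_id = c("S01", "S02", "S03"),
                          site_label = c("LN1", "LN1", "LN2"))
  tm <- trafficking_matrix(g, sheet)
  expect_equal(unname(rowSums(tm$counts)), c(20, 10, 5))  # conservation
  cls <- setNames(tm$group_class$scope, tm$group_class$group_id)
  expect_equal(unname(cls["G1"]), "interfollicular")  # two samples, one node
  expect_equal(unname(cls["G2"]), "internodal")       # across nodes
  expect_equal(unname(cls["G3"]), "private")
  expect_equal(tm$summary$shared_fraction, 2 / 3)
  # presence floor can demote weakly supported sharing
  tm5 <- trafficking_matrix(g, sheet, min_count = 5)
  expect_equal(tm5$group_class$class[tm5$group_class$group_id == "G2"], "private")
})
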
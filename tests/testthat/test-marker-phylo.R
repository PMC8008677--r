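test_that("the profile distance obeys its closed forms", {
  # d = -ln(S_AB / min(S_AA, S_BB))
  expect_identical(score_to_distance(2, 2, 3), 0)
  expect_equal(score_to_distance(1, 2, 3), log(2))
  expect_identical(score_to_distance(5, 2, 3), 0)   # clamped
  expect_identical(score_to_distance(-1, 2, 3), Inf)
  expect_error(score_to_distance(1, 0, 3), "positive")

  # self distance is zero
  set.seed(101)
  msa <- vapply(1:6, function(i)
    paste(sample(phagering:::AA20, 40, replace = TRUE), collapse = ""),
    "")
  pd <- profile_distance(msa, msa)
  expect_identical(pd$distance, 0)

  # constructed pair with S_AB = 0.5 * min(S_AA, S_BB): one shared
  # conserved half, one disjoint half (raw frequencies, no pseudocounts)
  A <- rep(strrep("A", 20), 4)
  B <- rep(paste0(strrep("A", 10), strrep("W", 10)), 4)
  pd2 <- profile_distance(A, B, smoothing = 0)
  expect_equal(pd2$S_AB, 0.5 * min(pd2$S_AA, pd2$S_BB))
  expect_equal(pd2$distance, log(2))

  # symmetry
  msb <- vapply(1:6, function(i)
    paste(sample(phagering:::AA20, 40, replace = TRUE), collapse = ""),
    "")
  expect_equal(profile_distance(msa, msb)$distance,
               profile_distance(msb, msa)$distance)

  # duplicating every sequence leaves the frequency vectors unchanged
  expect_equal(profile_distance(c(msa, msa), msb)$distance,
               profile_distance(msa, msb)$distance)

  expect_error(profile_distance(rep("ACDEF", 3), msa), "10 columns")
})

test_that("UPGMA reproduces hand-computed joins and groups tips by
          depth", {
  D <- matrix(c(0, 0.2, 1, 0.2, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  gd <- build_guide_dendrogram(D)
  expect_equal(sort(gd$heights), c(0.1, 0.5))
  # at merge_depth 1.5 all tips group together; at 0.05 all stay single
  expect_identical(length(unique(gd$groups)), 1L)
  gd2 <- build_guide_dendrogram(D, merge_depth = 0.05)
  expect_identical(length(unique(gd2$groups)), 3L)
  # depth between the joins: A and B group, C stays out
  gd3 <- build_guide_dendrogram(D, merge_depth = 0.3)
  expect_identical(gd3$groups[["A"]], gd3$groups[["B"]])
  expect_false(gd3$groups[["C"]] == gd3$groups[["A"]])
  # equal distances: any join order gives the same heights
  De <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  gde <- build_guide_dendrogram(De)
  expect_equal(unname(gde$heights), rep(0.2, 3))
  # validation
  Dbad <- D; Dbad[1, 2] <- -1
  expect_error(build_guide_dendrogram(Dbad), "negative|symmetric")
})

test_that("UPGMA dendrograms are ultrametric on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(102)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    M <- matrix(runif(n * n, 0.1, 2), n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    gd <- build_guide_dendrogram(D)
    # all leaves equidistant from the root
    depths <- ape::node.depth.edgelength(gd$phylo)
    tip_depths <- depths[seq_len(n)]
    expect_lt(max(tip_depths) - min(tip_depths), 1e-8)
    # heights non-decreasing toward the root
    expect_true(all(diff(gd$hclust$height) >= -1e-12))
  }
  # independent cross-check of the whole tree against phangorn's UPGMA
  set.seed(103)
  M <- matrix(runif(36, 0.1, 2), 6)
  D <- (M + t(M)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:6), paste0("t", 1:6))
  ours <- build_guide_dendrogram(D)$phylo
  ref <- phangorn::upgma(as.dist(D))
  expect_equal(as.matrix(ape::cophenetic.phylo(ours))[paste0("t", 1:6),
                                                      paste0("t", 1:6)],
               as.matrix(ape::cophenetic.phylo(ref))[paste0("t", 1:6),
                                                     paste0("t", 1:6)],
               tolerance = 1e-10)
})

test_that("column filtering enforces the gap and homogeneity rules", {
  # 3 gaps in 4 rows: removed by the > 50% gap rule
  msa <- c("AC-W", "AC-W", "AD-W", "A--W")
  fa <- filter_alignment(msa)
  expect_identical(fa$kept, c(1L, 2L, 4L))
  # identical-residue columns have homogeneity exactly 1
  expect_equal(fa$stats$homogeneity[c(1, 4)], c(1, 1))
  # uniformly random columns over 200 rows fall below 0.1 almost always
  set.seed(104)
  n_low <- 0
  for (i in 1:40) {
    col <- sample(phagering:::AA20, 200, replace = TRUE)
    f1 <- filter_alignment(vapply(col, function(a) a, ""))
    n_low <- n_low + (f1$stats$homogeneity[1] < 0.1)
  }
  expect_gte(n_low / 40, 0.95)
  # idempotence
  fb <- filter_alignment(fa$alignment)
  expect_identical(unname(fb$alignment), unname(fa$alignment))
  expect_identical(length(fb$kept), length(fa$kept))
})

test_that("the gene-sharing network weights shared clusters
          hypergeometrically", {
  memb <- data.frame(
    genome = rep(c("g1", "g2", "g3"), each = 50),
    cluster = c(1:50, c(1:30, 101:120), 201:250))
  net <- gene_sharing_network(memb, universe = 1000)
  # planted family: 30 of 50 clusters shared in a 1000-cluster universe
  e12 <- net[net$source == "g1" & net$target == "g2", ]
  expect_identical(e12$shared, 30L)
  expect_gt(e12$weight, 20)
  expect_equal(e12$weight,
               -stats::phyper(29, 50, 950, 50, lower.tail = FALSE,
                              log.p = TRUE) / log(10))
  # genomes sharing nothing have no edge; no self edges
  expect_false(any(net$source == net$target))
  expect_false(any((net$source == "g3") | (net$target == "g3")))
})
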
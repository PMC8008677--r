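test_that("ANI estimates track known mutation rates", {
  set.seed(71)
  g <- random_dna(20000)
  self <- estimate_ani(g, g)
  expect_equal(self$ani, 100)
  expect_equal(self$aligned_fraction, 100)
  # symmetry
  h <- mutate_seq(g, 0.03)
  e1 <- estimate_ani(g, h); e2 <- estimate_ani(h, g)
  expect_identical(e1$ani, e2$ani)
  expect_true(abs(e1$ani - 97) < 0.5)
  expect_gt(e1$aligned_fraction, 95)
  # unrelated genomes barely align
  r <- estimate_ani(random_dna(50000), random_dna(50000))
  expect_lt(r$aligned_fraction, 10)
  # reverse-complemented relatives are still recognized
  erc <- estimate_ani(g, revcomp(h))
  expect_true(abs(erc$ani - 97) < 0.5)
  expect_identical(erc$orientation, "-")
  # degenerate input
  expect_error(estimate_ani(strrep("N", 2000), g), "degenerate")
})

test_that("greedy dereplication recovers planted families", {
  set.seed(72)
  anc <- random_dna(15000)
  fam <- stats::setNames(vapply(1:5, function(i) mutate_seq(anc, 0.02),
                                ""), paste0("fam", 1:5))
  solo <- stats::setNames(vapply(1:3, function(i) random_dna(12000), ""),
                          paste0("solo", 1:3))
  cl <- dereplicate_genomes(c(fam, solo))
  expect_identical(length(unique(cl$representative)), 4L)
  expect_identical(sort(cl$member), sort(c(names(fam), names(solo))))
  # all family members share one representative
  expect_identical(length(unique(cl$representative[cl$member %in%
                                                     names(fam)])), 1L)
  # a pair at ~94% ANI stays split under the 95% threshold
  p1 <- random_dna(10000)
  pair <- dereplicate_genomes(c(a = p1, b = mutate_seq(p1, 0.061)))
  expect_identical(length(unique(pair$representative)), 2L)
  # idempotence: dereplicating the representatives changes nothing
  reps <- unique(cl$representative)
  again <- dereplicate_genomes(c(fam, solo)[reps])
  expect_identical(unique(again$representative), reps)
})

test_that("dereplication matches the all-pairs brute-force oracle", {
  set.seed(73)
  anc1 <- random_dna(8000); anc2 <- random_dna(9000)
  genomes <- c(
    stats::setNames(vapply(1:4, function(i) mutate_seq(anc1, 0.02), ""),
                    paste0("a", 1:4)),
    stats::setNames(vapply(1:3, function(i) mutate_seq(anc2, 0.03), ""),
                    paste0("b", 1:3)),
    stats::setNames(vapply(1:3, function(i) random_dna(7000), ""),
                    paste0("x", 1:3)))
  got <- dereplicate_genomes(genomes)
  exp <- oracle_dereplicate(genomes)
  expect_identical(got, exp)
  # post-hoc audit: every member satisfies the thresholds against its rep
  for (i in seq_len(nrow(got))) {
    if (got$member[i] == got$representative[i]) next
    e <- estimate_ani(genomes[[got$member[i]]],
                      genomes[[got$representative[i]]])
    expect_gte(e$ani, 95)
    expect_gte(e$aligned_fraction, 80)
  }
})

test_that("protein clustering honors identity and coverage thresholds", {
  set.seed(74)
  base <- paste(sample(phagering:::AA20, 200, replace = TRUE),
                collapse = "")
  # duplicates collapse
  dup <- cluster_proteins(c(p1 = base, p2 = base), id_min = 95,
                          cov_min = 50)
  expect_identical(length(unique(dup$representative)), 1L)
  # ~90% identity fails a 95% threshold
  v <- strsplit(base, "")[[1]]
  i <- sample(200, 20)
  v[i] <- vapply(v[i], function(a)
    sample(setdiff(phagering:::AA20, a), 1), "")
  far <- paste(v, collapse = "")
  cl90 <- cluster_proteins(c(p1 = base, p2 = far), id_min = 95,
                           cov_min = 50)
  expect_identical(length(unique(cl90$representative)), 2L)
  # ...but joins at a 50% threshold
  cl50 <- cluster_proteins(c(p1 = base, p2 = far), id_min = 50,
                           cov_min = 50)
  expect_identical(length(unique(cl50$representative)), 1L)
  # high identity with only ~40% mutual coverage stays split
  other <- paste(sample(phagering:::AA20, 240, replace = TRUE),
                 collapse = "")
  aover <- paste0(base, substr(other, 1, 120))   # 320 aa, tail overlap
  bover <- paste0(substr(other, 1, 120),
                  paste(sample(phagering:::AA20, 200, replace = TRUE),
                        collapse = ""))
  clc <- cluster_proteins(c(a = aover, b = bover), id_min = 95,
                          cov_min = 50)
  expect_identical(length(unique(clc$representative)), 2L)
})
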
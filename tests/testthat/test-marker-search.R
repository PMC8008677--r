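test_that("profile construction behaves on degenerate alignments", {
  uniform_bg <- stats::setNames(rep(1 / 20, 20), phagering:::AA20)
  # identical sequences: that sequence achieves the model's maximal score
  seqs <- rep(paste(rep(c("A", "C", "D", "W"), 5), collapse = ""), 8)
  p <- build_profile(seqs, background = uniform_bg)
  self <- phagering:::.profile_scores(p, c(x = seqs[1]),
                                      min_cols = p$columns)
  expect_equal(self$score, sum(apply(p$scores, 1, max)))

  # half A / half V column scores A and V equally (symmetric background)
  msa <- c(strrep("A", 12), strrep("A", 12), strrep("V", 12),
           strrep("V", 12))
  p2 <- build_profile(msa, background = uniform_bg)
  expect_equal(unname(p2$scores[1, "A"]), unname(p2$scores[1, "V"]))

  # a residue absent from every column scores negative log-odds
  expect_lt(p2$scores[1, "W"], 0)

  # ragged alignments are rejected
  expect_error(build_profile(c("ACDEFGHIKL", "ACDEFGHIK")), "ragged")

  # columns with > 50% gaps are dropped
  gappy <- c("A-CDEFGHIKL", "A-CDEFGHIKL", "AWCDEFGHIKL")
  expect_identical(build_profile(gappy)$columns, 10L)
})

test_that("planted marker proteins are detected among shuffled decoys", {
  profiles <- test_profiles()
  terl <- profiles[["terl_synthetic"]]
  set.seed(61)
  emit <- sample_profile_protein(terl)
  decoys <- vapply(1:500, function(i)
    paste(sample(strsplit(emit, "")[[1]]), collapse = ""), "")
  names(decoys) <- paste0("shuf", 1:500)
  prots <- c(c(planted = emit), decoys)
  hits <- search_profiles(prots, profiles["terl_synthetic"],
                          e_cutoff = 0.01)
  expect_true("planted" %in% hits$protein)
  expect_lt(hits$evalue[hits$protein == "planted"], 0.01)
  expect_identical(hits$category[hits$protein == "planted"], "TerL")
})

test_that("shuffled proteins rarely reach e < 0.01", {
  profiles <- test_profiles()
  set.seed(62)
  n_hit <- 0
  for (i in 1:300) {
    d <- paste(sample(phagering:::AA20, 180, replace = TRUE,
                      prob = codon_background()), collapse = "")
    h <- search_profiles(c(d = d), profiles["terl_synthetic"],
                         e_cutoff = 0.01)
    n_hit <- n_hit + (nrow(h) > 0)
  }
  expect_lte(n_hit / 300, 0.01)
})

test_that("searches are deterministic and monotone in the cutoff", {
  profiles <- test_profiles()
  set.seed(63)
  prots <- stats::setNames(vapply(1:40, function(i)
    paste(sample(phagering:::AA20, 150, replace = TRUE), collapse = ""),
    ""), paste0("p", 1:40))
  h1 <- search_profiles(prots, profiles, e_cutoff = 0.5)
  h2 <- search_profiles(prots, profiles, e_cutoff = 0.5)
  expect_identical(h1, h2)
  h_tight <- search_profiles(prots, profiles, e_cutoff = 0.05)
  # raising the cutoff never removes hits
  expect_true(all(paste(h_tight$protein, h_tight$profile) %in%
                    paste(h1$protein, h1$profile)))
})

test_that("the two-round classifier applies the length and marker rules", {
  profiles <- test_profiles()
  set.seed(64)
  # 2.9 kb contig with a strong TerL marker: below the length rule
  short <- make_marker_contig(profiles, length_bp = 2900, repeat_len = 60,
                              categories = "TerL")
  shortc <- find_terminal_repeat(short)$canonical_seq
  # 6 kb circular contig with a portal marker: phage
  good <- make_marker_contig(profiles, length_bp = 6000, repeat_len = 60,
                             categories = "portal")
  goodc <- find_terminal_repeat(good)$canonical_seq
  # contig whose only hit is the non-marker RT profile: round-1 retained,
  # never called phage
  rtp <- profiles[["rt_synthetic"]]
  g <- random_dna(6000)
  gene <- phagering:::.reverse_translate(sample_profile_protein(rtp))
  substr(g, 501, 500 + nchar(gene)) <- gene
  calls <- classify_contigs(c(short = shortc, good = goodc, rtonly = g),
                            profiles)
  expect_identical(calls$is_phage[calls$contig_id == "short"], FALSE)
  expect_identical(calls$markers_found[calls$contig_id == "short"], "TerL")
  expect_identical(calls$is_phage[calls$contig_id == "good"], TRUE)
  expect_identical(calls$markers_found[calls$contig_id == "good"],
                   "portal")
  rt_row <- calls[calls$contig_id == "rtonly", ]
  expect_false(rt_row$is_phage)
  expect_true(rt_row$round1_pass)
  # a looser round 2 than round 1 is a configuration error
  expect_error(classify_contigs(c(a = goodc), profiles, e1 = 0.01,
                                e2 = 0.05), "e2")
})

test_that("classification is invariant under rotation of a circular
          contig", {
  profiles <- test_profiles()
  set.seed(65)
  ctg <- make_marker_contig(profiles, length_bp = 6000, repeat_len = 70)
  canon <- find_terminal_repeat(ctg)$canonical_seq
  rot <- paste0(substr(canon, 2001, nchar(canon)), substr(canon, 1, 2000))
  c1 <- classify_contigs(c(g = canon), profiles)
  c2 <- classify_contigs(c(g = rot), profiles)
  expect_identical(c1$is_phage, c2$is_phage)
  expect_identical(c1$markers_found, c2$markers_found)
})
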
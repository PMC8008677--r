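test_that("planted repeat pairs are found in both search stages", {
  spec <- dgr_spec(tr_length = 120, n_vr = 2,
                   adenine_mutation_fraction = 0.5,
                   vr_distance_from_rt = c(4000, 20000))
  dg <- generate_dgr_genome(spec, seed = 91, genome_length = 40000)
  rp <- find_repeat_pairs(dg$seq, dg$truth$rt)
  expect_gte(nrow(rp), 2)
  # the proximal VR is a stage-1 (in-window) discovery
  near <- rp[abs(rp$vr_start - dg$truth$vr[1, "start"]) < 10, ]
  expect_gte(nrow(near), 1)
  expect_true(any(near$within_10kb_window))
  # the distal VR (20 kb from the RT) is only reachable by stage 2
  far <- rp[abs(rp$vr_start - dg$truth$vr[2, "start"]) < 10, ]
  expect_gte(nrow(far), 1)
  expect_false(any(far$within_10kb_window))
  expect_true(all(far$stage == 2))
  expect_true(all(rp$identity >= 75))
  # a missing RT annotation is an error
  expect_error(find_repeat_pairs(dg$seq, NULL), "rt_locus")
})

test_that("repeats below the stage-2 identity floor are rejected", {
  set.seed(92)
  g <- random_dna(30000)
  tr <- random_dna(120)
  substr(g, 4001, 4120) <- tr
  vr70 <- mutate_seq(tr, 0.30)                  # ~70% identity
  substr(g, 8001, 8120) <- vr70
  rp <- find_repeat_pairs(g, rt_locus = c(3000, 3900))
  hits <- rp[abs(rp$vr_start - 8000) < 30, ]
  # nothing at >= 75% identity over >= 50% coverage survives there
  expect_true(nrow(hits) == 0 ||
                all(hits$length < 0.5 * 120 | hits$identity >= 75))
  realized <- mean(strsplit(tr, "")[[1]] == strsplit(vr70, "")[[1]])
  expect_lt(realized, 0.75)
})

test_that("the adenine-bias statistic matches the closed-form binomial",
          {
  tr <- paste(rep(c("A", "C", "G"), 40), collapse = "")  # 120 nt, 40 A
  vv <- strsplit(tr, "")[[1]]
  a_pos <- which(vv == "A")
  vv[a_pos[1:15]] <- "T"
  vr <- paste(vv, collapse = "")
  rep1 <- adenine_bias_test(tr, vr)
  expect_identical(rep1$n_A_positions, 40L)
  expect_identical(rep1$n_A_substituted, 15L)
  expect_identical(rep1$n_nonA_substituted, 0L)
  expect_equal(rep1$p_value,
               stats::pbinom(14, 15, 1 / 3, lower.tail = FALSE))
  expect_true(rep1$hypervariable)

  # identical repeats: p = 1, not hypervariable
  rep0 <- adenine_bias_test(tr, tr)
  expect_identical(rep0$p_value, 1)
  expect_false(rep0$hypervariable)

  # permuting the VR order changes nothing
  vv2 <- strsplit(tr, "")[[1]]; vv2[a_pos[10:20]] <- "C"
  vrs <- c(vr, paste(vv2, collapse = ""))
  expect_identical(adenine_bias_test(tr, vrs)[1:6],
                   adenine_bias_test(tr, rev(vrs))[1:6])

  # substitutions off the adenine positions weaken the call
  vv3 <- strsplit(tr, "")[[1]]
  nonA <- which(vv3 != "A")
  vv3[nonA[1:15]] <- "A"
  repX <- adenine_bias_test(tr, paste(vv3, collapse = ""))
  expect_false(repX$hypervariable)

  expect_error(adenine_bias_test("", character(0)), "aligned")
  expect_error(adenine_bias_test(tr, substr(tr, 1, 50)), "length")
})

test_that("generator DGR truth obeys its contract", {
  # mismatches confined to template adenines when noise is zero
  spec <- dgr_spec(tr_length = 150, n_vr = 2,
                   adenine_mutation_fraction = 0.4)
  dg <- generate_dgr_genome(spec, seed = 93)
  tr <- dg$truth$tr_seq
  tv <- strsplit(tr, "")[[1]]
  for (k in 1:2) {
    vr <- substr(dg$seq, dg$truth$vr[k, "start"] + 1,
                 dg$truth$vr[k, "end"])
    mism <- which(strsplit(vr, "")[[1]] != tv)
    expect_true(all(tv[mism] == "A"))
    expect_identical(mism - 1L, dg$truth$mutated_adenines)
  }
  # exact mutated-adenine count: round(fraction * n_A)
  tr40 <- paste(rep(c("A", "C", "G"), 40), collapse = "")   # exactly 40 A
  dg40 <- generate_dgr_genome(dgr_spec(adenine_mutation_fraction = 0.5),
                              seed = 94, tr_seq = tr40)
  expect_identical(dg40$truth$n_tr_adenines, 40L)
  expect_identical(length(dg40$truth$mutated_adenines), 20L)
  # adenine-poor templates are refused
  expect_error(generate_dgr_genome(dgr_spec(tr_length = 20), seed = 95,
                                   tr_seq = strrep("CGT", 7)),
               "adenines")
})

test_that("type-I error stays below alpha under a uniform-substitution
          null", {
  set.seed(96)
  n_rej <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    tr <- random_dna(120)
    vv <- strsplit(tr, "")[[1]]
    idx <- sample(120, 12)                      # uniform positions
    vv[idx] <- vapply(vv[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    r <- adenine_bias_test(tr, paste(vv, collapse = ""), alpha = 0.01)
    n_rej <- n_rej + r$hypervariable
  }
  expect_lte(n_rej / n_rep, 0.05)
})
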
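test_that("spacer matching applies the 95/95 rule at the boundary", {
  set.seed(81)
  g <- c(gen = random_dna(30000))
  sp <- substr(g[[1]], 1001, 1032)              # 32 nt, exact
  v <- strsplit(sp, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  sp1 <- paste(v, collapse = "")                # 1 mismatch: 31/32 = 96.9%
  v[20] <- setdiff(c("A", "C", "G", "T"), v[20])[1]
  sp2 <- paste(v, collapse = "")                # 2 mismatches: 93.75%
  tab <- data.frame(spacer_id = c("s0", "s1", "s2"),
                    sequence = c(sp, sp1, sp2))
  m <- match_spacers(tab, g)
  expect_setequal(m$spacer_id, c("s0", "s1"))
  expect_equal(m$identity[m$spacer_id == "s0"], 100)
  expect_equal(m$identity[m$spacer_id == "s1"], 100 * 31 / 32)
  expect_identical(m$start[m$spacer_id == "s0"], 1000L)
  expect_identical(m$end[m$spacer_id == "s0"], 1032L)
})

test_that("spacer matcher equals the sliding-window oracle", {
  set.seed(82)
  g <- random_dna(20000)
  # plant spacers forward, reverse, across the origin, and mutated
  planted <- c(substr(g, 5001, 5032),
               revcomp(substr(g, 9001, 9036)),
               paste0(substr(g, 19990, 20000), substr(g, 1, 21)),
               mutate_seq(substr(g, 12001, 12032), 1 / 32),
               random_dna(32))
  tab <- data.frame(spacer_id = paste0("s", seq_along(planted)),
                    sequence = planted)
  got <- match_spacers(tab, c(gen = g))
  for (i in seq_along(planted)) {
    o <- oracle_spacer_hits(planted[i], g)
    gi <- got[got$spacer_id == paste0("s", i), ]
    expect_identical(nrow(gi), nrow(o))
    if (nrow(o)) {
      oo <- o[order(o$start), ]; gg <- gi[order(gi$start), ]
      expect_identical(gg$start, oo$start)
      expect_identical(gg$strand, oo$strand)
      expect_equal(gg$identity, oo$identity)
    }
  }
})

test_that("reverse-complementing the genome mirrors the match set", {
  set.seed(83)
  g <- random_dna(10000)
  tab <- data.frame(spacer_id = c("f", "r"),
                    sequence = c(substr(g, 2001, 2032),
                                 revcomp(substr(g, 7001, 7032))))
  a <- match_spacers(tab, c(gen = g), circular = FALSE)
  b <- match_spacers(tab, c(gen = revcomp(g)), circular = FALSE)
  expect_identical(nrow(a), nrow(b))
  L <- nchar(g)
  mirrored <- data.frame(spacer_id = b$spacer_id, start = L - b$end,
                         end = L - b$start,
                         strand = ifelse(b$strand == "+", "-", "+"))
  key <- function(d) sort(sprintf("%s:%d:%d:%s", d$spacer_id, d$start,
                                  d$end, d$strand))
  expect_identical(key(a[, names(mirrored)]), key(mirrored))
})

test_that("host prediction propagates taxonomy and flags multi-genus
          targeting", {
  set.seed(84)
  gA <- random_dna(12000); gB <- random_dna(12000)
  shared <- substr(gA, 3001, 3032)
  substr(gB, 5001, 5032) <- shared               # verbatim protospacer
  spacers <- data.frame(
    spacer_id = c("b1", "p1", "b2"),
    sequence = c(shared, substr(gA, 7001, 7032), random_dna(32)),
    phylum = c("Bacteroidota", "Bacteroidota", "Bacillota"),
    genus = c("Bacteroides", "Prevotella", "Clostridium"))
  m <- match_spacers(spacers, c(A = gA, B = gB))
  hp <- predict_hosts(m, spacers)
  hostA <- hp$hosts[hp$hosts$contig_id == "A" & hp$hosts$rank == "genus", ]
  expect_setequal(hostA$taxon, c("Bacteroides", "Prevotella"))
  expect_true("A" %in% hp$multi_genus$contig_id)
  expect_false("B" %in% hp$multi_genus$contig_id)
  sharedp <- hp$shared_protospacers
  expect_identical(nrow(sharedp), 1L)
  expect_setequal(c(sharedp$contig_a, sharedp$contig_b), c("A", "B"))
  # unknown spacer ids are an error
  bad <- m; bad$spacer_id[1] <- "nope"
  expect_error(predict_hosts(bad, spacers), "unknown spacer")
})

test_that("the anti-CRISPR gate is exactly the stated conjunction", {
  set.seed(85)
  # exhaustive truth table over the four criteria, randomized instances
  combos <- expand.grid(score_ok = c(TRUE, FALSE),
                        directon_ok = c(TRUE, FALSE),
                        hth_ok = c(TRUE, FALSE),
                        db_clean = c(TRUE, FALSE))
  for (rep in 1:3) for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    score <- if (cb$score_ok) runif(1, 0.9, 1) else runif(1, 0, 0.899)
    dsize <- if (cb$directon_ok) sample(1:5, 1) else sample(6:9, 1)
    # one contig, one run of co-oriented genes of length dsize
    starts <- seq(0, by = 1000, length.out = dsize)
    orfs <- data.frame(contig_id = "c", start = starts,
                       end = starts + 900, strand = "+",
                       protein_id = paste0("p", seq_len(dsize)))
    target <- "p1"
    hth_carrier <- paste0("p", sample(seq_len(dsize), 1))
    ann <- data.frame(protein_id = c(target, hth_carrier),
                      hth = c(FALSE, cb$hth_ok),
                      strong_db_hit = c(!cb$db_clean, FALSE))
    res <- screen_acr(data.frame(protein_id = target, score = score),
                      orfs, annotations = ann)
    expect_identical(res$verdict,
                     cb$score_ok && cb$directon_ok && cb$hth_ok &&
                       cb$db_clean)
  }
  # out-of-range scores are rejected
  orfs1 <- data.frame(contig_id = "c", start = 0, end = 900, strand = "+",
                      protein_id = "p1")
  expect_error(screen_acr(data.frame(protein_id = "p1", score = 1.2),
                          orfs1), "\\[0, 1\\]")
})

test_that("directons split at strand flips and large gaps", {
  orfs <- data.frame(
    contig_id = "c",
    start = c(0, 1000, 2000, 3500, 4500),
    end = c(900, 1900, 2900, 4400, 5400),
    strand = c("+", "+", "-", "-", "-"),
    protein_id = paste0("p", 1:5))
  d <- build_directons(orfs, gap_max = 250)
  # p1+p2 co-oriented adjacent; p3 flips strand; p3->p4 gap 600 splits
  expect_identical(d$directon_id[d$protein_id %in% c("p1", "p2")],
                   rep(d$directon_id[d$protein_id == "p1"], 2))
  expect_false(d$directon_id[d$protein_id == "p3"] ==
                 d$directon_id[d$protein_id == "p2"])
  expect_false(d$directon_id[d$protein_id == "p4"] ==
                 d$directon_id[d$protein_id == "p3"])
  expect_identical(d$directon_size[d$protein_id == "p4"], 2L)
})
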
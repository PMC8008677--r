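# Shared fixtures and independent brute-force oracles. Oracles deliberately
# take the dumb path (full scans, direct per-position comparison) so they
# share nothing with the kernels they check.

.fixture_env <- new.env()

# profiles are expensive to calibrate; build once per test run
test_profiles <- function() {
  if (is.null(.fixture_env$profiles))
    .fixture_env$profiles <- load_marker_profiles()
  .fixture_env$profiles
}

mutate_seq <- function(s, rate, alphabet = c("A", "C", "G", "T")) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < rate)
  v[i] <- vapply(v[i], function(b) sample(setdiff(alphabet, b), 1), "")
  paste(v, collapse = "")
}

# exhaustive terminal-repeat scan: longest r in [min_len, L/2] with
# prefix == suffix (N never matches), classified against max_len
oracle_terminal_repeat <- function(seq, min_len = 50, max_len = 200) {
  L <- nchar(seq)
  if (L < 2 * min_len)
    return(list(is_circular = FALSE, repeat_length = NA_integer_,
                reason = "too_short"))
  for (r in seq(floor(L / 2), min_len)) {
    pre <- substr(seq, 1, r)
    if (pre == substr(seq, L - r + 1, L) &&
        !grepl("N", pre, fixed = TRUE)) {
      if (r > max_len)
        return(list(is_circular = FALSE, repeat_length = NA_integer_,
                    reason = "repeat_exceeds_max"))
      return(list(is_circular = TRUE, repeat_length = r, reason = "ok"))
    }
  }
  list(is_circular = FALSE, repeat_length = NA_integer_,
       reason = "no_repeat")
}

# sliding-window spacer matcher: every lag, both strands, direct counting
oracle_spacer_hits <- function(spacer, genome, id_min = 95, cov_min = 95,
                               circular = TRUE) {
  slen <- nchar(spacer)
  gx <- if (circular) paste0(genome, substr(genome, 1, slen - 1)) else
    genome
  gv <- phagering:::dna_to_int(gx)
  out <- list(); n <- 0
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else revcomp(spacer)
    qv <- phagering:::dna_to_int(q)
    nlag <- length(gv) - slen + 1
    if (nlag < 1) next
    m <- integer(nlag)
    for (i in seq_len(slen))
      m <- m + as.integer(qv[i] > 0 & qv[i] == gv[i:(i + nlag - 1)])
    for (d in which(100 * m / slen >= id_min)) {
      st <- d - 1L
      if (circular && st >= nchar(genome)) next  # duplicate of wrapped hit
      n <- n + 1
      out[[n]] <- data.frame(start = st, end = st + slen,
                             strand = strand,
                             identity = 100 * m[d] / slen)
    }
  }
  if (n == 0) return(data.frame(start = integer(0), end = integer(0),
                                strand = character(0),
                                identity = numeric(0)))
  do.call(rbind, out)
}

# all-pairs greedy dereplication oracle: full ANI matrix first, then the
# longest-first first-fit assignment
oracle_dereplicate <- function(genomes, ani_min = 95, cov_min = 80) {
  ids <- names(genomes)
  n <- length(ids)
  ani <- cov <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { ani[i, j] <- 100; cov[i, j] <- 100; next }
    e <- estimate_ani(genomes[[i]], genomes[[j]])
    ani[i, j] <- ifelse(is.na(e$ani), 0, e$ani)
    cov[i, j] <- e$aligned_fraction
  }
  ord <- ids[order(-nchar(genomes), ids)]
  reps <- character(0); assign <- character(0)
  for (id in ord) {
    hit <- reps[ani[id, reps] >= ani_min & cov[id, reps] >= cov_min]
    if (length(hit) == 0) { reps <- c(reps, id); assign[id] <- id }
    else assign[id] <- hit[1]
  }
  data.frame(member = ids, representative = unname(assign[ids]))
}

# a small circular phage-like contig with markers, for classifier tests
make_marker_contig <- function(profiles, length_bp = 6000, repeat_len = 80,
                               categories = c("TerL", "MCP", "portal")) {
  g <- random_dna(length_bp)
  at <- 500L
  for (m in categories) {
    pr <- Filter(function(p) p$category == m, profiles)[[1]]
    aa <- sample_profile_protein(pr)
    gene <- phagering:::.reverse_translate(aa)
    substr(g, at + 1, at + nchar(gene)) <- gene
    at <- at + nchar(gene) + 300L
  }
  paste0(g, substr(g, 1, repeat_len))
}
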
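# Diversity-generating retroelement (DGR) detection and the adenine-bias
# hallmark test. Stage 1 finds near-exact repeat pairs inside a 10-kb
# window centered on the reverse transcriptase; stage 2 re-searches each
# template repeat genome-wide (ungapped, >= 75% identity over >= 50% of
# the template). The hallmark statistic formalizes the signature of
# DGR-mediated hypervariation: substitutions confined to template adenine
# positions.

#' Find template/variable repeat pairs near a reverse transcriptase
#'
#' @param genome a DNA string
#' @param rt_locus RT position: a single center coordinate or `c(start,
#'   end)` (0-based)
#' @param window width (bp) of the RT-centered stage-1 window
#' @param stage1_min_len,stage1_min_id stage-1 thresholds: near-exact
#'   repeats (defaults 80 bp, 85% identity; typical DGR template repeats
#'   are 50-150 bp)
#' @param stage2_min_id,stage2_min_cov stage-2 thresholds: each stage-1
#'   template re-searched genome-wide at >= 75% identity over >= 50% of
#'   its length, ungapped
#' @param both_strands also search the reverse strand for variable repeats
#' @return data frame of repeat pairs: `tr_start`, `tr_end`, `vr_start`,
#'   `vr_end` (0-based half-open, forward strand), `vr_strand`,
#'   `identity` (percent), `length`, `within_10kb_window`, `stage`
#' @export
find_repeat_pairs <- function(genome, rt_locus, window = 10000,
                              stage1_min_len = 80, stage1_min_id = 0.85,
                              stage2_min_id = 0.75, stage2_min_cov = 0.5,
                              both_strands = TRUE) {
  if (missing(rt_locus) || is.null(rt_locus) || all(is.na(rt_locus)))
    stop("rt_locus is required (supply an RT annotation)")
  center <- if (length(rt_locus) >= 2)
    as.integer(mean(rt_locus[1:2])) else as.integer(rt_locus[1])
  L <- nchar(genome)
  w0 <- max(0L, center - as.integer(window / 2))
  w1 <- min(L, center + as.integer(window / 2))
  win <- substr(genome, w0 + 1, w1)
  wv <- dna_to_int(win)

  seg <- cpp_lag_segments(wv, wv, stage1_min_id, stage1_min_len,
                          self = TRUE)
  pairs <- list(); n <- 0
  add_pair <- function(ts, te, vs, ve, strand, mt, len, stage) {
    # the repeat closer to the RT is the template
    if (abs((ts + te) / 2 - center) > abs((vs + ve) / 2 - center)) {
      tmp <- c(ts, te); ts <- vs; te <- ve; vs <- tmp[1]; ve <- tmp[2]
    }
    n <<- n + 1
    pairs[[n]] <<- data.frame(
      tr_start = ts, tr_end = te, vr_start = vs, vr_end = ve,
      vr_strand = strand, identity = 100 * mt / len, length = len,
      within_10kb_window = vs >= w0 && ve <= w1, stage = stage)
  }
  if (nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      as <- seg$a_start[i] + w0; bs <- seg$b_start[i] + w0
      len <- seg$length[i]
      if (as + len > bs) next                   # overlapping intervals
      add_pair(as, as + len, bs, bs + len, "+", seg$matches[i], len, 1L)
    }
  }

  # stage 2: each stage-1 template searched genome-wide
  if (n > 0) {
    stage1 <- do.call(rbind, pairs)
    trs <- unique(stage1[, c("tr_start", "tr_end")])
    gv <- dna_to_int(genome)
    gv_rc <- dna_to_int(revcomp(genome))
    for (i in seq_len(nrow(trs))) {
      ts <- trs$tr_start[i]; te <- trs$tr_end[i]
      tl <- te - ts
      tv <- gv[(ts + 1):te]
      min_len2 <- as.integer(ceiling(stage2_min_cov * tl))
      hits <- cpp_lag_segments(tv, gv, stage2_min_id, min_len2,
                               self = FALSE)
      if (nrow(hits)) for (j in seq_len(nrow(hits))) {
        vs <- hits$b_start[j]; len <- hits$length[j]
        ve <- vs + len
        # skip the template itself and anything overlapping it
        if (vs < te && ve > ts) next
        # the aligned template sub-interval starts at the HSP offset
        th <- ts + hits$a_start[j]
        add_pair(th, th + len, vs, ve, "+", hits$matches[j], len, 2L)
      }
      if (both_strands) {
        hits <- cpp_lag_segments(tv, gv_rc, stage2_min_id, min_len2,
                                 self = FALSE)
        if (nrow(hits)) for (j in seq_len(nrow(hits))) {
          len <- hits$length[j]
          vs <- L - (hits$b_start[j] + len)     # map to forward strand
          ve <- vs + len
          if (vs < te && ve > ts) next
          th <- ts + hits$a_start[j]
          add_pair(th, th + len, vs, ve, "-", hits$matches[j], len, 2L)
        }
      }
    }
  }
  if (n == 0)
    return(data.frame(tr_start = integer(0), tr_end = integer(0),
                      vr_start = integer(0), vr_end = integer(0),
                      vr_strand = character(0), identity = numeric(0),
                      length = integer(0), within_10kb_window = logical(0),
                      stage = integer(0)))
  res <- do.call(rbind, pairs)
  # collapse duplicates (stage 2 re-finds stage-1 pairs)
  res <- res[order(res$stage, -res$identity), , drop = FALSE]
  res <- res[!duplicated(res[, c("tr_start", "vr_start", "vr_strand")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Test for adenine-specific substitution between template and variable
#' repeats
#'
#' Columns of the ungapped TR/VR alignment are partitioned by the template
#' base; a column counts as substituted when any VR differs from the
#' template there (however many VRs mutate it). Under DGR-mediated
#' hypervariation substitutions concentrate at template adenines; the
#' p-value is the binomial tail probability of seeing at least the observed
#' number of substituted adenine columns if substitutions fell uniformly,
#' i.e. `P(X >= n_A_sub | n = n_sub_total, p = fraction of template
#' positions that are A)`. A repeat is called hypervariable when `p <
#' alpha` and at least `min_sub` adenine columns are substituted.
#'
#' @param tr template-repeat DNA string
#' @param vr_set character vector of variable repeats, each the same length
#'   as `tr` (ungapped alignment)
#' @param alpha significance level
#' @param min_sub minimum substituted adenine columns
#' @return list of class `dgr_report`: `n_columns`, `n_A_positions`,
#'   `n_A_substituted`, `n_nonA_substituted`, `substituted_positions`
#'   (0-based), `p_value`, `hypervariable`
#' @export
adenine_bias_test <- function(tr, vr_set, alpha = 0.01, min_sub = 3) {
  if (nchar(tr) == 0 || length(vr_set) == 0)
    stop("no aligned columns")
  if (any(nchar(vr_set) != nchar(tr)))
    stop("variable repeats must match the template length (ungapped ",
         "alignment)")
  tv <- strsplit(toupper(tr), "")[[1]]
  sub <- rep(FALSE, length(tv))
  for (vr in vr_set) {
    vv <- strsplit(toupper(vr), "")[[1]]
    sub <- sub | (vv != tv & tv %in% DNA_BASES4 & vv %in% DNA_BASES4)
  }
  isA <- tv == "A"
  nA_sub <- sum(sub & isA)
  nOther_sub <- sum(sub & !isA)
  n_sub <- nA_sub + nOther_sub
  pA <- mean(isA)
  p <- if (n_sub == 0) 1 else
    stats::pbinom(nA_sub - 1, n_sub, pA, lower.tail = FALSE)
  structure(list(n_columns = length(tv),
                 n_A_positions = sum(isA),
                 n_A_substituted = nA_sub,
                 n_nonA_substituted = nOther_sub,
                 substituted_positions = which(sub) - 1L,
                 p_value = p,
                 hypervariable = p < alpha && nA_sub >= min_sub),
            class = "dgr_report")
}

#' Run the adenine-bias test over the repeat pairs of one genome
#'
#' Repeat pairs found by [find_repeat_pairs()] may report slightly
#' different trims of the same template (each pair is an independently
#' scored segment). Pairs are grouped by overlapping template intervals;
#' within each group the longest template serves as the column reference
#' and every variable repeat is projected onto those columns through its
#' own template offsets, padded with N where it does not reach (N columns
#' never count as substitutions). One report is returned per template
#' group.
#'
#' @param genome the genome the pairs were found on
#' @param pairs data frame from [find_repeat_pairs()]
#' @param alpha,min_sub forwarded to [adenine_bias_test()]
#' @return list of `dgr_report`s, each with the contributing `pairs`
#'   attached as an attribute
#' @export
dgr_adenine_report <- function(genome, pairs, alpha = 0.01, min_sub = 3) {
  if (nrow(pairs) == 0) return(list())
  # group pairs whose template intervals overlap
  o <- order(pairs$tr_start, -pairs$tr_end)
  pairs <- pairs[o, , drop = FALSE]
  grp <- integer(nrow(pairs)); g <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(pairs))) {
    if (pairs$tr_start[i] >= cur_end) { g <- g + 1L
      cur_end <- pairs$tr_end[i] }
    else cur_end <- max(cur_end, pairs$tr_end[i])
    grp[i] <- g
  }
  out <- list()
  for (gi in unique(grp)) {
    pg <- pairs[grp == gi, , drop = FALSE]
    ref <- pg[which.max(pg$tr_end - pg$tr_start), ]
    rs <- ref$tr_start; re <- ref$tr_end
    tr <- substr(genome, rs + 1, re)
    vrs <- character(0)
    for (j in seq_len(nrow(pg))) {
      v <- substr(genome, pg$vr_start[j] + 1, pg$vr_end[j])
      if (pg$vr_strand[j] == "-") v <- revcomp(v)
      # project this pair's VR onto the reference template columns
      lead <- pg$tr_start[j] - rs
      if (lead < 0) { v <- substr(v, 1 - lead, nchar(v)); lead <- 0 }
      v <- substr(v, 1, max(0, (re - rs) - lead))
      padded <- paste0(strrep("N", lead), v,
                       strrep("N", (re - rs) - lead - nchar(v)))
      vrs <- c(vrs, padded)
    }
    rep <- adenine_bias_test(tr, vrs, alpha = alpha, min_sub = min_sub)
    attr(rep, "pairs") <- pg
    out[[length(out) + 1L]] <- rep
  }
  out
}

#' @export
print.dgr_report <- function(x, ...) {
  cat(sprintf(paste0("<dgr_report> %d columns, %d/%d adenines substituted,",
                     " %d non-adenines substituted, p = %.3g%s\n"),
              x$n_columns, x$n_A_substituted, x$n_A_positions,
              x$n_nonA_substituted, x$p_value,
              if (x$hypervariable) " [hypervariable]" else ""))
  invisible(x)
}

#' Read a template/variable repeat alignment from FASTA
#'
#' The first record is the template repeat, the remainder are variable
#' repeats. Columns where the template carries a gap are dropped; gap
#' characters in a variable repeat are treated as unaligned (never counted
#' as substitutions).
#'
#' @param path aligned FASTA file
#' @return list with `tr` and `vr_set` ready for [adenine_bias_test()]
#' @export
read_repeat_alignment <- function(path) {
  x <- read_fasta(path)
  if (length(x) < 2) stop("alignment needs a template and >= 1 variable ",
                          "repeat")
  m <- do.call(rbind, strsplit(x, ""))
  keep <- m[1, ] != "-" & m[1, ] != "."
  m <- m[, keep, drop = FALSE]
  m[m == "-" | m == "."] <- "N"   # unaligned, never a substitution
  list(tr = paste(m[1, ], collapse = ""),
       vr_set = apply(m[-1, , drop = FALSE], 1, paste, collapse = ""))
}

#' Render a TR/VR alignment with substituted columns marked
#'
#' @param tr,vr_set as in [adenine_bias_test()]
#' @return character vector of display lines (template, one line per VR
#'   with dots at matches, and a marker line flagging substituted adenine
#'   columns with `*` and other substituted columns with `.`)
#' @export
render_dgr_alignment <- function(tr, vr_set) {
  tv <- strsplit(tr, "")[[1]]
  lines <- c(sprintf("TR   %s", tr))
  for (i in seq_along(vr_set)) {
    vv <- strsplit(vr_set[[i]], "")[[1]]
    disp <- ifelse(vv == tv, ".", vv)
    lines <- c(lines, sprintf("VR%-2d %s", i, paste(disp, collapse = "")))
  }
  rep <- adenine_bias_test(tr, vr_set, alpha = 1)
  mark <- rep("", length(tv))
  mark[] <- " "
  mark[rep$substituted_positions + 1] <- "."
  mark[intersect(rep$substituted_positions + 1, which(tv == "A"))] <- "*"
  c(lines, sprintf("     %s", paste(mark, collapse = "")))
}
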
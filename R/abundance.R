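# Read recruitment and length-normalized fractional abundance. Reads are
# first decontaminated against a decoy database by exact k-mer screening,
# then assigned to the best-matching genome by exact-seed ungapped
# extension; ties split fractionally. The fractional abundance of genome i
# is (c_i / L_i) / sum_j (c_j / L_j): reads per base, normalized to sum to
# one.

#' Recruit reads to a genome database
#'
#' @param reads named character vector of reads
#' @param genomes named character vector of (canonicalized) genome
#'   sequences
#' @param decoys optional named character vector (host/vector
#'   contamination); a read is removed when at least `decoy_frac` of its
#'   k-mers occur in the decoy set (either strand)
#' @param k seed/screen k-mer size
#' @param decoy_frac decontamination threshold
#' @param circular search across the origin (recycled over genomes)
#' @param min_identity minimum read identity for a valid assignment
#' @param window_bp coverage window width
#' @return list of class `recruitment`: `counts` (per-genome, fractional
#'   for ties), `coverage` (per-genome numeric vector of per-window mean
#'   depth), `n_reads`, `n_decontaminated`, `n_unmapped`,
#'   `n_skipped_short`
#' @export
recruit_reads <- function(reads, genomes, decoys = NULL, k = 31,
                          decoy_frac = 0.5, circular = TRUE,
                          min_identity = 0.9, window_bp = 100) {
  circular <- rep_len(circular, length(genomes))
  lens <- nchar(genomes)
  counts <- stats::setNames(numeric(length(genomes)), names(genomes))
  coverage <- lapply(seq_along(genomes), function(i)
    numeric(ceiling(lens[i] / window_bp)))
  names(coverage) <- names(genomes)
  res_empty <- structure(list(counts = counts, coverage = coverage,
                              n_reads = length(reads),
                              n_decontaminated = 0L, n_unmapped = 0L,
                              n_skipped_short = 0L),
                         class = "recruitment")
  if (length(reads) == 0) return(res_empty)

  short <- nchar(reads) < k
  n_short <- sum(short)
  if (n_short) {
    warning(n_short, " read(s) shorter than k = ", k, " skipped")
    reads <- reads[!short]
  }
  n_dec <- 0L
  if (!is.null(decoys) && length(reads)) {
    dk <- unique(unlist(lapply(c(decoys, revcomp(decoys)), .kmers, k)))
    hit_frac <- vapply(reads, function(r) {
      rk <- .kmers(r, k)
      mean(rk %in% dk)
    }, 0)
    n_dec <- sum(hit_frac >= decoy_frac)
    reads <- reads[hit_frac < decoy_frac]
  }
  if (length(reads) == 0) {
    res_empty$n_decontaminated <- n_dec
    res_empty$n_skipped_short <- n_short
    return(res_empty)
  }

  rl <- nchar(reads)
  max_rl <- max(rl)
  gx <- ifelse(circular, paste0(genomes, substr(genomes, 1, max_rl - 1)),
               genomes)
  gkm <- lapply(gx, .kmers, k)

  nr <- length(reads)
  best <- matrix(-1L, nr, length(genomes))     # match count per genome
  pos <- matrix(NA_integer_, nr, length(genomes))
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") reads else revcomp(reads)
    offsets <- unique(pmax(1L, c(1L, max_rl %/% 2L - k %/% 2L,
                                 max_rl - k + 1L)))
    for (gi in seq_along(genomes)) {
      for (off in offsets) {
        ok <- rl >= off + k - 1L
        seeds <- substr(rs, off, off + k - 1L)
        cand <- match(seeds, gkm[[gi]])
        lag <- cand - off                       # 0-based placement
        sel <- which(ok & !is.na(cand) & lag >= 0 &
                       (lag + rl) <= nchar(gx[gi]))
        if (length(sel) == 0) next
        frag <- substring(gx[gi], lag[sel] + 1L, lag[sel] + rl[sel])
        exact <- frag == rs[sel]
        mt <- integer(length(sel))
        mt[exact] <- rl[sel][exact]
        if (any(!exact)) {
          ix <- which(!exact)
          mt[ix] <- vapply(ix, function(q) {
            a <- dna_to_int(rs[sel[q]]); b <- dna_to_int(frag[q])
            sum(a > 0 & a == b)
          }, 0L)
        }
        upd <- mt > best[sel, gi]
        if (any(upd)) {
          best[sel[upd], gi] <- mt[upd]
          pos[sel[upd], gi] <- lag[sel[upd]]
        }
      }
    }
  }

  row_best <- apply(best, 1, max)
  valid <- row_best >= min_identity * rl
  n_unmapped <- sum(!valid)
  n_ties <- rowSums(best == row_best)
  for (gi in seq_along(genomes)) {
    sel <- which(valid & best[, gi] == row_best)
    if (length(sel) == 0) next
    wgt <- 1 / n_ties[sel]
    counts[gi] <- sum(wgt)
    L <- lens[gi]
    p0 <- pos[sel, gi]
    rls <- rl[sel]
    nw <- length(coverage[[gi]])
    # distribute each read over the (few) windows it spans
    max_span <- max(rls) %/% window_bp + 1L
    acc <- numeric(nw)
    for (kk in 0:max_span) {
      wi <- p0 %/% window_bp + kk
      ov <- pmin(p0 + rls, (wi + 1L) * window_bp) -
        pmax(p0, wi * window_bp)
      keep <- ov > 0
      if (!any(keep)) next
      wiw <- (wi[keep] %% nw) + 1L   # wrap origin-spanning reads
      contrib <- wgt[keep] * ov[keep] / window_bp
      cc <- rowsum(contrib, wiw)
      acc[as.integer(rownames(cc))] <- acc[as.integer(rownames(cc))] +
        cc[, 1]
    }
    coverage[[gi]] <- acc
  }
  structure(list(counts = counts, coverage = coverage,
                 n_reads = length(reads) + n_short + n_dec,
                 n_decontaminated = n_dec, n_unmapped = n_unmapped,
                 n_skipped_short = n_short),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf(paste0("<recruitment> %d reads: %d decontaminated, ",
                     "%d unmapped, %.1f recruited over %d genomes\n"),
              x$n_reads, x$n_decontaminated, x$n_unmapped,
              sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Length-normalized fractional abundance
#'
#' `F_i = (c_i / L_i) / sum_j (c_j / L_j)`; all zeros when no read is
#' recruited. A genome is flagged detected when it recruits at least one
#' read.
#'
#' @param counts named numeric vector of per-genome read counts (fractional
#'   allowed), or a `recruitment` object
#' @param lengths per-genome lengths in bp (ignored when `counts` is a
#'   `recruitment`; taken from its coverage vectors' genomes otherwise
#'   required)
#' @return data frame: `genome`, `count`, `length`, `fraction`, `detected`
#' @export
fractional_abundance <- function(counts, lengths = NULL) {
  if (inherits(counts, "recruitment")) {
    if (is.null(lengths))
      stop("supply genome lengths alongside a recruitment object")
    counts <- counts$counts
  }
  if (any(counts < 0)) stop("validation error: negative count")
  if (is.null(lengths) || any(lengths <= 0))
    stop("validation error: lengths must be positive")
  rpb <- counts / lengths
  s <- sum(rpb)
  frac <- if (s == 0) rep(0, length(counts)) else rpb / s
  data.frame(genome = names(counts), count = as.numeric(counts),
             length = as.numeric(lengths), fraction = as.numeric(frac),
             detected = counts >= 1, row.names = NULL)
}

#' Per-genome read counts from a SAM file
#'
#' Thin convenience parser for alignments produced by an external mapper:
#' counts primary mapped alignments per reference.
#'
#' @param path SAM text file
#' @return named numeric vector of counts
#' @export
read_sam_counts <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) return(stats::setNames(numeric(0), character(0)))
  f <- strsplit(lines, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  rname <- vapply(f, function(x) x[3], "")
  keep <- bitwAnd(flag, 4L) == 0 & bitwAnd(flag, 256L) == 0 &
    bitwAnd(flag, 2048L) == 0 & rname != "*"
  tb <- table(rname[keep])
  stats::setNames(as.numeric(tb), names(tb))
}
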
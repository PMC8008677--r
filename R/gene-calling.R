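# ORF prediction under a selectable genetic code. Deterministic maximal-ORF
# calling (start codons ATG/GTG/TTG, both strands, optional origin wrap on
# circular contigs) stands in for a trained gene caller: the downstream
# contract only needs translated ORFs with coordinates, not polished gene
# boundaries. The amber-glutamine code models the TAG -> Gln reassignment
# observed in some gut phages.

ORF_START_CODONS <- c("ATG", "GTG", "TTG")

#' Genetic code table
#'
#' `"standard-bacterial"` is the canonical code (stops TAA/TAG/TGA);
#' `"amber-gln"` differs only at TAG, which is read through as glutamine.
#'
#' @param id `"standard-bacterial"` or `"amber-gln"`
#' @return list with `id`, `table` (64 codon -> amino-acid map, `*` = stop)
#'   and `stops`
#' @export
genetic_code <- function(id = c("standard-bacterial", "amber-gln")) {
  id <- match.arg(id)
  tab <- Biostrings::GENETIC_CODE
  if (id == "amber-gln") tab["TAG"] <- "Q"
  list(id = id, table = tab, stops = names(tab)[tab == "*"])
}

# ORFs on one (already oriented, possibly doubled) strand string
.orfs_linear <- function(s, tab, min_aa) {
  n <- nchar(s)
  out <- vector("list", 3)
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < min_aa + 1) next
    pos <- seq(f + 1, by = 3, length.out = ncod)
    codons <- substring(s, pos, pos + 2)
    aa <- unname(tab[codons])
    aa[is.na(aa)] <- "X"   # ambiguous bases: unknown residue, not a stop
    stops <- which(aa == "*")
    if (length(stops) == 0) next
    is_start <- codons %in% ORF_START_CODONS
    starts <- which(is_start)
    if (length(starts) == 0) next
    prev <- c(0L, stops[-length(stops)])
    si <- findInterval(prev, starts) + 1L          # first start after prev stop
    ok <- si <= length(starts)
    st <- ifelse(ok, starts[pmin(si, length(starts))], NA_integer_)
    keep <- ok & !is.na(st) & st < stops & (stops - st) >= min_aa
    if (!any(keep)) next
    st <- st[keep]; sp <- stops[keep]
    aaseq <- vapply(seq_along(st), function(i) {
      a <- aa[st[i]:(sp[i] - 1)]
      a[1] <- "M"
      paste(a, collapse = "")
    }, "")
    out[[f + 1]] <- data.frame(
      start = pos[st] - 1L,                 # 0-based
      end = pos[sp] + 2L,                   # half-open, includes stop codon
      aa_seq = aaseq)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Call open reading frames
#'
#' Reports all maximal start-to-stop ORFs of at least `min_aa` residues on
#' both strands. Coordinates are 0-based half-open on the forward strand and
#' include the stop codon; on circular contigs ORFs may span the origin, in
#' which case `end` exceeds the contig length.
#'
#' @param seq a single DNA string
#' @param code genetic code id (see [genetic_code()]) or a code object
#' @param min_aa minimum protein length (stop excluded)
#' @param circular whether the sequence is a circular genome
#' @return data frame with columns `start`, `end`, `strand`, `aa_seq`, `code`
#' @export
call_orfs <- function(seq, code = "standard-bacterial", min_aa = 30,
                      circular = FALSE) {
  gc <- if (is.list(code)) code else genetic_code(code)
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), aa_seq = character(0),
                      code = character(0))
  if (L < 3 * (min_aa + 1)) return(empty)
  s_fwd <- if (circular) paste0(seq, seq) else seq
  Ld <- nchar(s_fwd)

  fw <- .orfs_linear(s_fwd, gc$table, min_aa)
  if (!is.null(fw)) {
    fw$strand <- "+"
    if (circular) {
      len <- fw$end - fw$start
      keep <- fw$start < L & len <= L
      fw <- fw[keep, , drop = FALSE]
    }
  }
  rv <- .orfs_linear(as.character(revcomp(s_fwd)), gc$table, min_aa)
  if (!is.null(rv)) {
    len <- rv$end - rv$start
    st <- Ld - rv$end
    rv <- data.frame(start = st, end = st + len, aa_seq = rv$aa_seq,
                     strand = "-")
    if (circular) {
      rv$end <- rv$end - (rv$start %/% L) * L
      rv$start <- rv$start %% L
      len <- rv$end - rv$start
      rv <- rv[len <= L, , drop = FALSE]
      rv <- rv[!duplicated(rv[c("start", "end")]), , drop = FALSE]
    }
  }
  res <- rbind(fw, rv)
  if (is.null(res) || nrow(res) == 0) return(empty)
  res$code <- gc$id
  res$start <- as.integer(res$start)
  res$end <- as.integer(res$end)
  res <- res[order(res$start, res$end, res$strand), c("start", "end",
                                                      "strand", "aa_seq",
                                                      "code")]
  rownames(res) <- NULL
  res
}

#' Fraction of bases covered by at least one called ORF
#'
#' @param orfs data frame from [call_orfs()]
#' @param L contig length in bp
#' @param circular wrap coordinates beyond `L` back to the origin
#' @return coding density in \[0, 1\]
#' @export
coding_density <- function(orfs, L, circular = FALSE) {
  if (nrow(orfs) == 0) return(0)
  cov <- logical(L)
  for (i in seq_len(nrow(orfs))) {
    idx <- orfs$start[i]:(orfs$end[i] - 1L)
    if (circular) idx <- idx %% L
    cov[idx + 1L] <- TRUE
  }
  mean(cov)
}

#' Choose a genetic code for a contig
#'
#' When an amber-suppressor tRNA annotation is supplied the amber-glutamine
#' code is selected outright (annotation dominates). Otherwise a fallback
#' heuristic compares coding density under the two codes and switches to
#' amber-glutamine when re-coding gains at least `gain_threshold` (default
#' ten percentage points); TAG read-through can only lengthen ORFs, so the
#' gain is never negative, and a genuine reassignment restores whole genes
#' that the standard code shatters into sub-threshold fragments.
#'
#' @param seq a single DNA string (>= 3 kb recommended; shorter contigs give
#'   noisy densities)
#' @param suppressor_trna TRUE when an external tRNA scan found an
#'   amber-suppressor tRNA on this contig
#' @param gain_threshold minimum coding-density gain to call reassignment
#' @param min_aa,circular passed to [call_orfs()]
#' @return list with `code` (selected id), `density_standard`,
#'   `density_amber`
#' @export
assess_code_reassignment <- function(seq, suppressor_trna = FALSE,
                                     gain_threshold = 0.10, min_aa = 30,
                                     circular = FALSE) {
  if (isTRUE(suppressor_trna))
    return(list(code = "amber-gln", density_standard = NA_real_,
                density_amber = NA_real_))
  L <- nchar(seq)
  d_std <- coding_density(call_orfs(seq, "standard-bacterial", min_aa,
                                    circular), L, circular)
  d_amb <- coding_density(call_orfs(seq, "amber-gln", min_aa, circular),
                          L, circular)
  code <- if (d_amb - d_std >= gain_threshold) "amber-gln"
          else "standard-bacterial"
  list(code = code, density_standard = d_std, density_amber = d_amb)
}
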
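# Genome dereplication at 95% ANI over 80% of the (shorter) genome length,
# and greedy centroid protein clustering. ANI comes from shared-k-mer
# anchoring: exact k-mer seeds shared by the two genomes are grouped into
# syntenic blocks by diagonal, block identity is counted base-by-base, and
# ANI is the length-weighted identity over blocks.

#' Estimate average nucleotide identity between two genomes
#'
#' @param a,b DNA strings (>= 1 kb each)
#' @param k seed k-mer size
#' @param max_gap seeds on the same diagonal closer than this are merged
#'   into one block
#' @param min_block_id blocks below this identity are discarded as spurious
#' @return list with `ani` (percent identity over aligned blocks; NA when
#'   nothing aligns), `aligned_fraction` (percent of the shorter genome
#'   covered by blocks), `n_blocks`, `orientation`
#' @export
estimate_ani <- function(a, b, k = 16, max_gap = 2000, min_block_id = 0.7) {
  la <- nchar(a); lb <- nchar(b)
  if (la < 1000 || lb < 1000) stop("genomes must be >= 1 kb")
  if (grepl("^N+$", a) || grepl("^N+$", b))
    stop("degenerate (all-N) genome")
  # exact symmetry: order the pair canonically
  if (la > lb || (la == lb && a > b)) {
    r <- estimate_ani(b, a, k, max_gap, min_block_id)
    return(r)
  }
  best <- list(ani = NA_real_, aligned_fraction = 0, n_blocks = 0L,
               orientation = "+")
  for (ori in c("+", "-")) {
    bb <- if (ori == "+") b else revcomp(b)
    r <- .ani_one(a, bb, k, max_gap, min_block_id)
    if (r$aligned_fraction > best$aligned_fraction) {
      best <- r; best$orientation <- ori
    }
  }
  best
}

.ani_one <- function(a, b, k, max_gap, min_block_id) {
  ka <- .kmers(a, k); kb <- .kmers(b, k)
  # positions of shared seeds (first occurrence in b per a-kmer plus
  # duplicates handled through matching both directions)
  m <- match(ka, kb)
  ia <- which(!is.na(m)); ib <- m[ia]
  out <- list(ani = NA_real_, aligned_fraction = 0, n_blocks = 0L)
  if (length(ia) == 0) return(out)
  d <- ia - ib
  o <- order(d, ia)
  ia <- ia[o]; ib <- ib[o]; d <- d[o]
  new_block <- c(TRUE, diff(d) != 0 | diff(ia) > max_gap)
  blk <- cumsum(new_block)
  va <- dna_to_int(a); vb <- dna_to_int(b)
  starts_a <- tapply(ia, blk, min); ends_a <- tapply(ia, blk, max) + k - 1
  starts_b <- tapply(ib, blk, min)
  ids <- numeric(length(starts_a)); lens <- integer(length(starts_a))
  for (i in seq_along(starts_a)) {
    sa <- starts_a[[i]]; ea <- ends_a[[i]]; sb <- starts_b[[i]]
    len <- ea - sa + 1
    seg_a <- va[sa:ea]; seg_b <- vb[sb:(sb + len - 1)]
    mt <- sum(seg_a > 0 & seg_a == seg_b)
    ids[i] <- mt / len; lens[i] <- len
  }
  keep <- ids >= min_block_id
  if (!any(keep)) return(out)
  sa <- as.integer(starts_a)[keep]; le <- lens[keep]; idv <- ids[keep]
  cov <- .union_length(sa - 1L, sa - 1L + le)
  list(ani = 100 * sum(idv * le) / sum(le),
       aligned_fraction = 100 * cov / nchar(a),
       n_blocks = sum(keep))
}

#' Greedy genome dereplication
#'
#' Genomes are sorted by descending length; each is assigned to the first
#' representative with ANI >= `ani_min` and aligned fraction >= `cov_min`
#' (percent of the shorter genome), else it opens a new cluster. With the
#' default thresholds this reproduces the 95%-identity / 80%-length
#' dereplication convention.
#'
#' @param genomes named character vector of (canonicalized) genome sequences
#' @param ani_min,cov_min thresholds in percent
#' @param k seed size passed to [estimate_ani()]
#' @return data frame with columns `member`, `representative`; clusters
#'   partition the input and each representative is its own longest member
#' @export
dereplicate_genomes <- function(genomes, ani_min = 95, cov_min = 80,
                                k = 16) {
  stopifnot(length(genomes) >= 1)
  ord <- order(-nchar(genomes), names(genomes))
  reps <- character(0)
  assign <- character(length(genomes))
  names(assign) <- names(genomes)[ord]
  for (id in names(genomes)[ord]) {
    placed <- NA_character_
    for (rp in reps) {
      e <- estimate_ani(genomes[[id]], genomes[[rp]], k = k)
      if (!is.na(e$ani) && e$ani >= ani_min &&
          e$aligned_fraction >= cov_min) { placed <- rp; break }
    }
    if (is.na(placed)) { reps <- c(reps, id); placed <- id }
    assign[[id]] <- placed
  }
  out <- data.frame(member = names(genomes),
                    representative = unname(assign[names(genomes)]))
  rownames(out) <- NULL
  out
}

# identity/coverage of member vs representative from an ends-free pairwise
# protein alignment
.protein_id_cov <- function(member, rep) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(member), Biostrings::AAString(rep),
    type = "overlap",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  alp <- as.character(Biostrings::alignedPattern(pa))
  aln_len <- nchar(alp)
  if (aln_len == 0) return(c(identity = 0, coverage = 0))
  mt <- Biostrings::nmatch(pa)
  span <- Biostrings::width(Biostrings::pattern(pa))
  c(identity = 100 * mt / aln_len,
    coverage = 100 * span / nchar(member))
}

#' Greedy centroid protein clustering
#'
#' Longest-first greedy clustering: a protein joins the first existing
#' representative to which it aligns with at least `id_min` percent global
#' identity over at least `cov_min` percent of its own length (coverage is
#' measured on the member).
#'
#' @param proteins named character vector of protein sequences
#' @param id_min,cov_min thresholds in percent (e.g. 95/50 for genome-wide
#'   protein dereplication, 50/50 for marker clustering)
#' @return data frame `member`, `representative`
#' @export
cluster_proteins <- function(proteins, id_min = 95, cov_min = 50) {
  if (length(proteins) == 0)
    return(data.frame(member = character(0),
                      representative = character(0)))
  ord <- order(-nchar(proteins), names(proteins))
  reps <- character(0)
  assign <- character(length(proteins))
  names(assign) <- names(proteins)[ord]
  for (id in names(proteins)[ord]) {
    placed <- NA_character_
    for (rp in reps) {
      if (proteins[[id]] == proteins[[rp]]) { placed <- rp; break }
      ic <- .protein_id_cov(proteins[[id]], proteins[[rp]])
      if (ic["identity"] >= id_min && ic["coverage"] >= cov_min) {
        placed <- rp; break
      }
    }
    if (is.na(placed)) { reps <- c(reps, id); placed <- id }
    assign[[id]] <- placed
  }
  out <- data.frame(member = names(proteins),
                    representative = unname(assign[names(proteins)]))
  rownames(out) <- NULL
  out
}
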
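# Marker-cluster comparison: profile-profile distances from aligned marker
# families, a UPGMA guide dendrogram with depth-based tip grouping, column
# filtering of merged alignments, and a hypergeometric gene-sharing
# network.

# Per-column residue frequency matrix of an alignment (gaps excluded).
# Smoothing mixes the observed frequencies with a uniform background:
# unlike additive pseudocounts, the mixture is invariant to duplicating
# every sequence, so cluster size does not perturb the profile.
.column_freqs <- function(msa, smoothing = 0.05) {
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  t(apply(m, 2, function(col) {
    cnt <- table(factor(col, levels = AA20))
    f <- as.numeric(cnt) / max(1, sum(cnt))
    (1 - smoothing) * f + smoothing / 20
  }))
}

# best ungapped local profile-profile score: column score is the log-odds
# of the frequency-vector dot product against a uniform background,
# maximised over diagonals by a Kadane scan
.profile_profile_score <- function(fa, fb) {
  M <- log(20 * tcrossprod(fa, fb))    # WA x WB column-pair scores
  wa <- nrow(M); wb <- ncol(M)
  best <- -Inf
  for (d in (-(wa - 1)):(wb - 1)) {
    i0 <- max(1, 1 - d); i1 <- min(wa, wb - d)
    v <- M[cbind(i0:i1, (i0:i1) + d)]
    run <- 0; mx <- -Inf
    for (s in v) {
      run <- if (run > 0) run + s else s
      if (run > mx) mx <- run
    }
    if (mx > best) best <- mx
  }
  best
}

#' Profile-profile distance between two marker-cluster alignments
#'
#' Computes similarity scores `S_AB` (best ungapped profile-profile
#' alignment), `S_AA` and `S_BB` (self-similarity, computed identically)
#' and converts them to the distance `-ln(S_AB / min(S_AA, S_BB))`,
#' clamped at zero.
#'
#' @param msaA,msaB character vectors of aligned protein sequences (>= 10
#'   columns each)
#' @param smoothing uniform-background mixture weight for the column
#'   frequencies (duplication-invariant); set to 0 for raw observed
#'   frequencies
#' @return list: `S_AB`, `S_AA`, `S_BB`, `distance` (`Inf` when `S_AB <=
#'   0`, i.e. no positive-scoring alignment exists)
#' @export
profile_distance <- function(msaA, msaB, smoothing = 0.05) {
  if (length(msaA) == 0 || length(msaB) == 0)
    stop("empty alignment")
  if (unique(nchar(msaA))[1] < 10 || unique(nchar(msaB))[1] < 10)
    stop("alignment shorter than 10 columns")
  fa <- .column_freqs(msaA, smoothing)
  fb <- .column_freqs(msaB, smoothing)
  sab <- .profile_profile_score(fa, fb)
  saa <- .profile_profile_score(fa, fa)
  sbb <- .profile_profile_score(fb, fb)
  list(S_AB = sab, S_AA = saa, S_BB = sbb,
       distance = score_to_distance(sab, saa, sbb))
}

#' Convert similarity scores to a profile distance
#'
#' `d = -ln(S_AB / min(S_AA, S_BB))`, clamped at 0 (a cross-similarity
#' exceeding the weaker self-similarity counts as distance zero).
#'
#' @param s_ab,s_aa,s_bb similarity scores; the self-similarities must be
#'   positive
#' @return non-negative distance; `Inf` when `s_ab <= 0`
#' @export
score_to_distance <- function(s_ab, s_aa, s_bb) {
  if (s_aa <= 0 || s_bb <= 0)
    stop("self-similarities must be positive")
  if (s_ab <= 0) return(Inf)
  max(0, -log(s_ab / min(s_aa, s_bb)))
}

#' UPGMA guide dendrogram with depth-based tip grouping
#'
#' Builds the UPGMA dendrogram (average-linkage agglomeration; node height
#' = half the merge distance, so the tree is ultrametric) and groups tips
#' whose subtree root lies at depth strictly below `merge_depth`; those
#' groups guide the progressive merging of cluster alignments.
#'
#' @param D square symmetric distance matrix with zero diagonal (no NaN or
#'   negative entries; `Inf` entries are capped at 1.05x the largest
#'   finite distance)
#' @param merge_depth tip-group depth threshold
#' @return list of class `guide_dendrogram`: `hclust`, `phylo`
#'   (`ape::phylo`), `heights` (node depths), `groups` (named integer
#'   vector of tip-group ids)
#' @export
build_guide_dendrogram <- function(D, merge_depth = 1.5) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(is.nan(D)) || any(is.na(D) & !is.nan(D)))
    stop("distance matrix contains NaN/NA")
  if (any(D < 0)) stop("distance matrix contains negative entries")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  if (any(is.infinite(D))) {
    fin <- max(D[is.finite(D)], 1)
    D[is.infinite(D)] <- 1.05 * fin
  }
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("c", seq_len(nrow(D)))
  # lexicographic label order makes tie-breaking deterministic
  o <- order(rownames(D))
  D <- D[o, o]
  if (nrow(D) < 2) {
    gr <- stats::setNames(1L, rownames(D))
    return(structure(list(hclust = NULL, phylo = NULL, heights = numeric(0),
                          groups = gr), class = "guide_dendrogram"))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  groups <- stats::cutree(hc, h = 2 * merge_depth - 1e-9)
  structure(list(hclust = hc,
                 phylo = ape::as.phylo(hc),
                 heights = hc$height / 2,
                 groups = groups),
            class = "guide_dendrogram")
}

#' @export
print.guide_dendrogram <- function(x, ...) {
  cat(sprintf("<guide_dendrogram> %d tips, %d tip groups, root depth %.3f\n",
              length(x$groups), length(unique(x$groups)),
              if (length(x$heights)) max(x$heights) else 0))
  invisible(x)
}

#' Write a guide dendrogram as newick
#' @param x a `guide_dendrogram`
#' @param path output file
#' @export
write_dendrogram <- function(x, path) {
  ape::write.tree(x$phylo, file = path)
  invisible(path)
}

#' Filter alignment columns by gap fraction and homogeneity
#'
#' Removes columns with more than 50% gaps and columns whose homogeneity
#' falls below 0.1. Homogeneity is normalized conservation under a
#' substitution matrix: `h = (mean pairwise score - expected random-pair
#' score) / (mean same-residue score - expected random-pair score)`,
#' clipped to \[0, 1\], where the same-residue term uses the column's own
#' residue frequencies (so a column of identical residues scores exactly
#' 1) and the random-pair expectation uses a uniform residue background.
#'
#' @param msa character vector of aligned sequences
#' @param max_gap maximum gap fraction (strictly greater is removed)
#' @param min_h minimum homogeneity
#' @param submat substitution matrix name (a Biostrings data matrix)
#' @return list of class `filtered_alignment`: `alignment` (filtered),
#'   `kept` (column indices), `stats` (per-column `gap_fraction`,
#'   `homogeneity`)
#' @export
filter_alignment <- function(msa, max_gap = 0.5, min_h = 0.1,
                             submat = "BLOSUM62") {
  stopifnot(length(msa) >= 1)
  B <- .get_submat(submat)[AA20, AA20]
  q <- rep(1 / 20, 20)
  e_rand <- as.numeric(t(q) %*% B %*% q)
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  m[!(m %in% AA20)] <- "-"
  nc <- ncol(m)
  gap_frac <- colMeans(m == "-")
  h <- vapply(seq_len(nc), function(j) {
    res <- m[m[, j] != "-", j]
    if (length(res) < 2) return(0)
    cnt <- table(factor(res, levels = AA20))
    f <- as.numeric(cnt) / sum(cnt)
    npair <- sum(cnt) * (sum(cnt) - 1)
    # mean over ordered pairs of distinct rows
    pair_mat <- outer(as.numeric(cnt), as.numeric(cnt)) -
      diag(as.numeric(cnt))
    s_mean <- sum(pair_mat * B) / npair
    s_same <- sum(f * diag(B))
    val <- (s_mean - e_rand) / (s_same - e_rand)
    min(1, max(0, val))
  }, 0)
  keep <- which(gap_frac <= max_gap & h >= min_h)
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(list(alignment = stats::setNames(out, names(msa)),
                 kept = keep,
                 stats = data.frame(column = seq_len(nc),
                                    gap_fraction = gap_frac,
                                    homogeneity = h)),
            class = "filtered_alignment")
}

.get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Gene-sharing network of genomes
#'
#' Edge weight between two genomes is `-log10` of the hypergeometric tail
#' probability of sharing at least the observed number of protein clusters
#' given each genome's cluster count and the cluster universe.
#'
#' @param membership data frame with columns `genome` and `cluster`
#'   (protein-cluster id per genome protein, e.g. from
#'   [cluster_proteins()] representatives joined to their source genomes)
#' @param weight_min drop edges below this weight
#' @param universe optional total cluster count (defaults to the number of
#'   distinct clusters in `membership`)
#' @return data frame: `source`, `target`, `shared`, `weight`
#' @export
gene_sharing_network <- function(membership, weight_min = 1,
                                 universe = NULL) {
  sets <- lapply(split(membership$cluster, membership$genome), unique)
  N <- if (is.null(universe)) length(unique(membership$cluster)) else
    universe
  ids <- names(sets)
  out <- list(); n <- 0
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    k <- length(intersect(sets[[i]], sets[[j]]))
    if (k == 0) next
    a <- length(sets[[i]]); b <- length(sets[[j]])
    lw <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE,
                        log.p = TRUE)
    w <- -lw / log(10)
    if (w >= weight_min) {
      n <- n + 1
      out[[n]] <- data.frame(source = ids[j], target = ids[i],
                             shared = k, weight = w)
    }
  }
  if (n == 0)
    return(data.frame(source = character(0), target = character(0),
                      shared = integer(0), weight = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stack equal-length protein sequences into an alignment
#'
#' Marker proteins emitted from the same profile share its column space and
#' can be stacked directly; genuinely diverged families should instead be
#' aligned externally and read with [read_fasta()].
#'
#' @param proteins named character vector of equal-length proteins
#' @return the vector, validated
#' @export
stack_alignment <- function(proteins) {
  if (length(unique(nchar(proteins))) != 1)
    stop("sequences differ in length; supply a real alignment instead")
  proteins
}
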
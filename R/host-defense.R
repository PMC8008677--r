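# CRISPR spacer -> protospacer host prediction and anti-CRISPR candidate
# screening. Spacer matching is ungapped seed-and-extend from exact 8-mer
# seeds on both strands with no complexity filtering; a match is accepted
# when the spacer is >= 95% identical over >= 95% of its length. The Acr
# screen is a four-criterion conjunction over an externally supplied
# per-protein score plus genomic context.

#' Match CRISPR spacers against genomes
#'
#' @param spacers data frame with at least `spacer_id` and `sequence`
#'   (spacer length >= 16 nt), or a named character vector
#' @param genomes named character vector of (canonicalized) genome sequences
#' @param word exact seed length
#' @param id_min,cov_min acceptance thresholds in percent: identity over the
#'   aligned span, coverage of the full spacer length
#' @param circular search across the origin of circular genomes
#' @return data frame: `spacer_id`, `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `identity`, `coverage`,
#'   `spacer_seq`, `protospacer_seq`
#' @export
match_spacers <- function(spacers, genomes, word = 8, id_min = 95,
                          cov_min = 95, circular = TRUE) {
  if (!is.data.frame(spacers))
    spacers <- data.frame(spacer_id = names(spacers),
                          sequence = unname(spacers))
  stopifnot(all(nchar(spacers$sequence) >= 16))
  out <- list(); n <- 0
  for (gi in seq_along(genomes)) {
    gid <- names(genomes)[gi]
    g <- genomes[[gi]]
    L <- nchar(g)
    maxsp <- max(nchar(spacers$sequence))
    gx <- if (circular) paste0(g, substr(g, 1, maxsp - 1)) else g
    gv <- dna_to_int(gx)
    gk <- .kmers(gx, word)
    for (si in seq_len(nrow(spacers))) {
      sp <- toupper(spacers$sequence[si])
      slen <- nchar(sp)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") sp else revcomp(sp)
        qv <- dna_to_int(q)
        seeds <- .kmers(q, word)
        hit_pos <- which(gk %in% seeds)
        if (length(hit_pos) == 0) next
        # candidate placements: lag = genome pos - seed offset
        offs <- match(gk[hit_pos], seeds)      # first offset per seed value
        lag_set <- integer(0)
        seed_offsets <- split(seq_along(seeds), seeds)
        for (h in seq_along(hit_pos)) {
          so <- seed_offsets[[gk[hit_pos[h]]]]
          lag_set <- c(lag_set, hit_pos[h] - so)
        }
        lag_set <- sort(unique(lag_set))
        lag_set <- lag_set[lag_set > -slen & lag_set < length(gv)]
        for (d in lag_set) {
          i0 <- max(1L, 1L - d); i1 <- min(slen, length(gv) - d)
          span <- i1 - i0 + 1L
          if (span < 1) next
          qs <- qv[i0:i1]; gs <- gv[(i0 + d):(i1 + d)]
          mt <- sum(qs > 0 & qs == gs)
          identity <- 100 * mt / span
          coverage <- 100 * span / slen
          if (identity >= id_min && coverage >= cov_min) {
            st <- i0 + d - 1L                    # 0-based on gx
            en <- st + span
            if (circular && st >= L) { st <- st - L; en <- en - L }
            n <- n + 1
            out[[n]] <- data.frame(
              spacer_id = spacers$spacer_id[si], contig_id = gid,
              start = st, end = en, strand = strand,
              identity = identity, coverage = coverage,
              spacer_seq = sp,
              protospacer_seq = substr(gx, i0 + d, i1 + d))
          }
        }
      }
    }
  }
  if (n == 0)
    return(data.frame(spacer_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), spacer_seq = character(0),
                      protospacer_seq = character(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("spacer_id", "contig_id", "start",
                               "strand")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict phage hosts from spacer matches
#'
#' Propagates the source taxonomy of each matching spacer to the targeted
#' phage, flags phages targeted by two or more host genera, and reports
#' protospacers shared verbatim between phages (possible recent
#' cross-species transfer or shared sequence).
#'
#' @param matches output of [match_spacers()]
#' @param spacers spacer table with `spacer_id` plus taxonomy columns
#'   (e.g. `phylum`, `genus`)
#' @param ranks taxonomy columns of `spacers` to propagate
#' @return list with `hosts` (contig_id, rank, taxon, n_spacers),
#'   `multi_genus` (contig_id, n_genera, genera), `shared_protospacers`
#'   (contig_a, contig_b, protospacer_seq)
#' @export
predict_hosts <- function(matches, spacers, ranks = c("phylum", "genus")) {
  unknown <- setdiff(matches$spacer_id, spacers$spacer_id)
  if (length(unknown))
    stop("unknown spacer id(s): ", paste(head(unknown, 5), collapse = ", "))
  ranks <- intersect(ranks, names(spacers))
  m <- merge(matches, spacers[, c("spacer_id", ranks)], by = "spacer_id")
  hosts <- do.call(rbind, lapply(ranks, function(rk) {
    agg <- stats::aggregate(m$spacer_id,
                            by = list(contig_id = m$contig_id,
                                      taxon = m[[rk]]),
                            FUN = function(x) length(unique(x)))
    data.frame(contig_id = agg$contig_id, rank = rk, taxon = agg$taxon,
               n_spacers = agg$x)
  }))
  multi <- NULL
  if ("genus" %in% ranks) {
    g <- stats::aggregate(m$genus, by = list(contig_id = m$contig_id),
                          FUN = function(x) length(unique(x)))
    genera <- stats::aggregate(m$genus, by = list(contig_id = m$contig_id),
                               FUN = function(x)
                                 paste(sort(unique(x)), collapse = ","))
    multi <- data.frame(contig_id = g$contig_id, n_genera = g$x,
                        genera = genera$x)
    multi <- multi[multi$n_genera >= 2, , drop = FALSE]
    rownames(multi) <- NULL
  }
  shared <- data.frame(contig_a = character(0), contig_b = character(0),
                       protospacer_seq = character(0))
  sp_by_seq <- split(matches$contig_id, matches$protospacer_seq)
  for (s in names(sp_by_seq)) {
    cs <- sort(unique(sp_by_seq[[s]]))
    if (length(cs) >= 2) {
      pr <- t(utils::combn(cs, 2))
      shared <- rbind(shared,
                      data.frame(contig_a = pr[, 1], contig_b = pr[, 2],
                                 protospacer_seq = s))
    }
  }
  rownames(shared) <- NULL
  list(hosts = hosts, multi_genus = multi, shared_protospacers = shared)
}

#' Build directons from an ORF table
#'
#' A directon is a maximal run of adjacent, co-oriented ORFs whose
#' intergenic gaps do not exceed `gap_max`.
#'
#' @param orfs data frame with `contig_id`, `start`, `end`, `strand`,
#'   `protein_id`
#' @param gap_max maximum intergenic gap in bp
#' @return the ORF table with a `directon_id` column and a `directon_size`
#'   column
#' @export
build_directons <- function(orfs, gap_max = 250) {
  orfs <- orfs[order(orfs$contig_id, orfs$start), , drop = FALSE]
  brk <- c(TRUE, orfs$contig_id[-1] != orfs$contig_id[-nrow(orfs)] |
             orfs$strand[-1] != orfs$strand[-nrow(orfs)] |
             (orfs$start[-1] - orfs$end[-nrow(orfs)]) > gap_max)
  orfs$directon_id <- cumsum(brk)
  sz <- table(orfs$directon_id)
  orfs$directon_size <- as.integer(sz[as.character(orfs$directon_id)])
  rownames(orfs) <- NULL
  orfs
}

#' Screen proteins for anti-CRISPR candidates
#'
#' A protein passes when (1) the mean score of its 50%-identity protein
#' cluster is at least `score_min`, (2) it sits in a directon of at most
#' `max_directon` genes, (3) its directon encodes at least one HTH
#' domain-containing protein, and (4) its cluster has no strong database
#' hit. The score itself is an input: the screen is the genomic-context
#' filter, not the scoring model.
#'
#' @param scores data frame `protein_id`, `score` (each in \[0, 1\])
#' @param orfs ORF table (see [build_directons()]) covering the scored
#'   proteins
#' @param annotations data frame `protein_id`, `hth` (logical),
#'   `strong_db_hit` (logical); proteins absent from the table default to
#'   FALSE for both
#' @param proteins optional named character vector of sequences; when given,
#'   proteins are clustered at `cluster_id_min` percent identity and scores
#'   are averaged per cluster, otherwise every protein is its own cluster
#' @param score_min,max_directon gate thresholds
#' @param cluster_id_min,cluster_cov_min clustering thresholds in percent
#' @param gap_max directon gap in bp
#' @return data frame: `protein_id`, `cluster`, `mean_cluster_score`,
#'   `directon_size`, `directon_has_hth`, `strong_db_hit`, `verdict`
#' @export
screen_acr <- function(scores, orfs, annotations = NULL, proteins = NULL,
                       score_min = 0.9, max_directon = 5,
                       cluster_id_min = 50, cluster_cov_min = 50,
                       gap_max = 250) {
  if (any(scores$score < 0 | scores$score > 1))
    stop("validation error: scores must lie in [0, 1]")
  if (!is.null(proteins)) {
    cl <- cluster_proteins(proteins, id_min = cluster_id_min,
                           cov_min = cluster_cov_min)
  } else {
    cl <- data.frame(member = scores$protein_id,
                     representative = scores$protein_id)
  }
  scores$cluster <- cl$representative[match(scores$protein_id, cl$member)]
  mean_by_cl <- tapply(scores$score, scores$cluster, mean)
  scores$mean_cluster_score <- as.numeric(mean_by_cl[scores$cluster])

  dirs <- build_directons(orfs, gap_max = gap_max)
  idx <- match(scores$protein_id, dirs$protein_id)
  if (anyNA(idx))
    stop("scored protein(s) missing from the ORF table")
  scores$directon_id <- dirs$directon_id[idx]
  scores$directon_size <- dirs$directon_size[idx]

  ann <- data.frame(protein_id = dirs$protein_id,
                    hth = FALSE, strong_db_hit = FALSE)
  if (!is.null(annotations)) {
    # a protein may appear on several annotation rows; any TRUE counts
    hth_any <- tapply(annotations$hth, annotations$protein_id, any)
    db_any <- tapply(annotations$strong_db_hit, annotations$protein_id,
                     any)
    j <- match(ann$protein_id, names(hth_any))
    ann$hth <- ifelse(is.na(j), FALSE, as.logical(hth_any[j]))
    ann$strong_db_hit <- ifelse(is.na(j), FALSE, as.logical(db_any[j]))
  }
  hth_by_dir <- tapply(ann$hth, dirs$directon_id, any)
  scores$directon_has_hth <-
    as.logical(hth_by_dir[as.character(scores$directon_id)])
  scores$strong_db_hit <-
    ann$strong_db_hit[match(scores$protein_id, ann$protein_id)]
  # strong DB hit disqualifies the whole cluster
  db_by_cl <- tapply(scores$strong_db_hit, scores$cluster, any)
  scores$cluster_db_hit <- as.logical(db_by_cl[scores$cluster])

  scores$verdict <- scores$mean_cluster_score >= score_min &
    scores$directon_size <= max_directon &
    scores$directon_has_hth &
    !scores$cluster_db_hit
  scores[, c("protein_id", "cluster", "mean_cluster_score",
             "directon_size", "directon_has_hth", "strong_db_hit",
             "verdict")]
}

#' Stand-in anti-CRISPR scorer for fixtures
#'
#' A transparent heuristic standing in for a trained Acr model when
#' exercising the screen on synthetic data: favors short proteins with
#' high lysine and overall charge, rescaled to \[0, 1\]. Not a validated
#' predictor.
#'
#' @param proteins named character vector
#' @return data frame `protein_id`, `score`
#' @export
acr_standin_scores <- function(proteins) {
  sc <- vapply(proteins, function(p) {
    n <- nchar(p)
    v <- strsplit(p, "")[[1]]
    kfrac <- mean(v == "K")
    charged <- mean(v %in% c("K", "R", "D", "E"))
    short <- exp(-pmax(0, n - 60) / 120)
    pmin(1, pmax(0, 0.5 * short + 3 * kfrac + charged))
  }, 0)
  data.frame(protein_id = names(proteins), score = unname(sc))
}
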
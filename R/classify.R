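# The two-round marker-based phage decision rule. Round 1 casts a wide net
# (e < 0.05) over ORFs called under the standard code; contigs with any hit
# are re-assessed for amber (TAG -> Gln) reassignment and re-translated;
# round 2 re-searches everything at e < 0.01. A contig is called phage when
# it exceeds 3 kb and carries a round-2 hit to a terminase large subunit,
# major capsid, or portal profile.

MARKER_CATEGORIES <- c("TerL", "MCP", "portal")

#' Call ORFs and pool proteins across contigs
#' @keywords internal
.pool_proteins <- function(contigs, codes, min_aa, circular) {
  orfs <- lapply(names(contigs), function(id) {
    o <- call_orfs(contigs[[id]], codes[[id]], min_aa = min_aa,
                   circular = circular)
    if (nrow(o)) o$contig_id <- id
    o
  })
  orfs <- do.call(rbind, orfs[vapply(orfs, nrow, 0L) > 0])
  if (is.null(orfs))
    return(list(orfs = NULL, proteins = character(0)))
  orfs$protein_id <- sprintf("%s|%d-%d%s", orfs$contig_id, orfs$start,
                             orfs$end, orfs$strand)
  list(orfs = orfs,
       proteins = stats::setNames(orfs$aa_seq, orfs$protein_id))
}

#' Classify contigs as phage by the two-round marker rule
#'
#' @param contigs named character vector of (canonicalized) contig sequences
#' @param profiles calibrated profiles from [load_marker_profiles()]
#' @param e1,e2 round-1 and round-2 e-value cutoffs; `e2` must not exceed
#'   `e1` (the second round is the stricter one)
#' @param min_len contigs must be strictly longer than this (bp) to be
#'   called phage
#' @param min_aa minimum ORF length for gene calling
#' @param circular treat contigs as circular genomes (origin-spanning ORFs)
#' @param suppressor_trna optional named logical vector: contigs with an
#'   externally annotated amber-suppressor tRNA
#' @param gain_threshold coding-density gain for the reassignment heuristic
#' @return data frame with one row per contig: `contig_id`, `length`,
#'   `is_phage`, `markers_found` (comma-separated subset of
#'   TerL/MCP/portal), `round1_pass`, `round2_pass`, `code`. Round-2 hits
#'   are attached as attribute `"hits"`, called ORFs as attribute `"orfs"`.
#' @export
classify_contigs <- function(contigs, profiles, e1 = 0.05, e2 = 0.01,
                             min_len = 3000, min_aa = 30, circular = TRUE,
                             suppressor_trna = NULL,
                             gain_threshold = 0.10) {
  if (e2 > e1)
    stop("round-2 cutoff e2 must not be looser than round-1 cutoff e1")
  ids <- names(contigs)
  codes <- stats::setNames(rep("standard-bacterial", length(ids)), ids)

  r1 <- .pool_proteins(contigs, as.list(codes), min_aa, circular)
  hits1 <- search_profiles(r1$proteins, profiles, e_cutoff = e1)
  r1_contigs <- if (is.null(r1$orfs)) character(0) else
    unique(r1$orfs$contig_id[r1$orfs$protein_id %in% hits1$protein])

  # re-assess the genetic code of round-1 positives
  for (id in r1_contigs) {
    flag <- isTRUE(suppressor_trna[[id]])
    a <- assess_code_reassignment(contigs[[id]], suppressor_trna = flag,
                                  gain_threshold = gain_threshold,
                                  min_aa = min_aa, circular = circular)
    codes[[id]] <- a$code
  }

  r2 <- .pool_proteins(contigs, as.list(codes), min_aa, circular)
  hits2 <- search_profiles(r2$proteins, profiles, e_cutoff = e2)
  hits2$contig_id <- if (nrow(hits2) == 0) character(0) else
    r2$orfs$contig_id[match(hits2$protein, r2$orfs$protein_id)]

  marker_hits <- hits2[hits2$category %in% MARKER_CATEGORIES, ,
                       drop = FALSE]
  markers_by_contig <- vapply(ids, function(id) {
    m <- sort(unique(marker_hits$category[marker_hits$contig_id == id]))
    paste(m, collapse = ",")
  }, "")

  res <- data.frame(
    contig_id = ids,
    length = nchar(unname(contigs)),
    round1_pass = ids %in% r1_contigs,
    round2_pass = ids %in% unique(hits2$contig_id),
    markers_found = markers_by_contig,
    code = unname(codes[ids]),
    row.names = NULL)
  res$is_phage <- res$length > min_len & res$markers_found != ""
  res <- res[, c("contig_id", "length", "is_phage", "markers_found",
                 "round1_pass", "round2_pass", "code")]
  attr(res, "hits") <- hits2
  attr(res, "orfs") <- r2$orfs
  res
}
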
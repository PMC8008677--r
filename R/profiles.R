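# Marker profile models. A profile is a fixed-width position-specific
# log-odds matrix built from an aligned protein family, scored against
# query proteins by ungapped local alignment. Significance comes from an
# empirical Gumbel calibration on shuffled decoy proteins, cached with the
# profile. This keeps the hit/no-hit contract of a profile-HMM search while
# remaining fully self-contained (no insert/delete states).

#' Background amino-acid frequencies induced by uniform random codons
#'
#' The null model for metagenomic ORFs: residues are distributed as the 61
#' sense codons of the standard code, not uniformly over the 20 residues.
#' Used both as the log-odds background and as the decoy residue sampler.
#' @return named numeric vector over the 20 residues, summing to 1
#' @export
codon_background <- function() {
  tab <- Biostrings::GENETIC_CODE
  tab <- tab[tab != "*"]
  p <- table(factor(unname(tab), levels = AA20))
  stats::setNames(as.numeric(p) / sum(p), AA20)
}

#' Build a position-specific log-odds profile from a protein alignment
#'
#' Columns with more than 50% gaps are dropped from the model. Residue
#' frequencies get a pseudocount of 0.5 per residue per column; scores are
#' `log(freq / background)`.
#'
#' @param msa named character vector of aligned protein sequences (equal
#'   length; `-` or `.` for gaps), or an `AAStringSet`
#' @param name profile name
#' @param category one of `"TerL"`, `"MCP"`, `"portal"`, `"other-phage"`
#' @param pseudocount added per residue per column
#' @param background residue background frequencies; defaults to
#'   [codon_background()]
#' @return object of class `profile_model` with the score matrix (columns x
#'   20 residues), per-column frequencies, and metadata
#' @export
build_profile <- function(msa, name = "profile",
                          category = c("other-phage", "TerL", "MCP",
                                       "portal"),
                          pseudocount = 0.5, background = NULL) {
  category <- match.arg(category)
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  if (length(msa) < 2) stop("a profile needs at least 2 sequences")
  w <- unique(nchar(msa))
  if (length(w) != 1) stop("ragged alignment: sequences differ in length")
  if (is.null(background)) background <- codon_background()
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  gapfrac <- colMeans(m == "-" | m == ".")
  keep <- which(gapfrac <= 0.5)
  if (length(keep) < 10) stop("profile has fewer than 10 usable columns")
  freq <- t(apply(m[, keep, drop = FALSE], 2, function(col) {
    cnt <- table(factor(col, levels = AA20))
    (as.numeric(cnt) + pseudocount) / (sum(cnt) + 20 * pseudocount)
  }))
  colnames(freq) <- AA20
  scores <- log(sweep(freq, 2, background, "/"))
  structure(list(name = name, category = category, scores = scores,
                 freq = freq, columns = nrow(scores),
                 background = background, n_seq = length(msa),
                 calibration = NULL),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %s (%s): %d columns from %d sequences%s\n",
              x$name, x$category, x$columns, x$n_seq,
              if (is.null(x$calibration)) ", uncalibrated"
              else sprintf(", Gumbel(mu=%.2f, beta=%.2f)",
                           x$calibration$mu, x$calibration$beta)))
  invisible(x)
}

# best ungapped local score of each protein against one profile
.profile_scores <- function(profile, proteins, min_cols = 25) {
  if (length(proteins) == 0)
    return(data.frame(protein = character(0), score = numeric(0),
                      start = integer(0), end = integer(0)))
  lens <- nchar(proteins)
  stream <- aa_to_int(paste(proteins, collapse = "*"))
  pid <- rep(seq_along(proteins), times = lens + c(rep(1L,
              length(proteins) - 1L), 0L))
  # the '*' separators encode to 0; mark them -1 so segments cannot cross
  sep_at <- cumsum(lens + 1L)[-length(proteins)]
  stream[sep_at] <- -1L
  res <- cpp_profile_scan(profile$scores, stream, pid,
                          length(proteins),
                          min(min_cols, profile$columns))
  off <- c(0L, cumsum(lens + 1L))[seq_along(proteins)]
  data.frame(protein = names(proteins),
             score = res$score,
             start = res$start - off,      # 0-based within protein
             end = res$end - off + 1L,     # half-open
             row.names = NULL)
}

#' Calibrate a profile's score distribution on shuffled decoys
#'
#' Scores `n_decoys` random proteins drawn from the background composition
#' (lengths spanning 0.5-2x the profile width) and fits a Gumbel location
#' and scale by the method of moments. The fit is cached on the profile and
#' converts raw scores to p-values, hence e-values.
#'
#' @param profile a `profile_model`
#' @param n_decoys number of decoy proteins (>= 100)
#' @param seed RNG seed, stored with the calibration
#' @return the profile with a `calibration` element
#' @export
calibrate_profile <- function(profile, n_decoys = 500, seed = 101) {
  stopifnot(n_decoys >= 100)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- profile$columns
  lens <- sample(seq(max(30, round(0.5 * W)), round(2 * W)), n_decoys,
                 replace = TRUE)
  bg <- profile$background
  decoys <- vapply(lens, function(n)
    paste(sample(AA20, n, replace = TRUE, prob = bg), collapse = ""), "")
  names(decoys) <- paste0("decoy", seq_len(n_decoys))
  sc <- .profile_scores(profile, decoys)$score
  beta <- stats::sd(sc) * sqrt(6) / pi
  mu <- mean(sc) - 0.5772156649 * beta
  profile$calibration <- list(mu = mu, beta = beta, n_decoys = n_decoys,
                              seed = seed)
  profile
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Gumbel upper-tail p-value, guarded against underflow to keep e-values > 0
.gumbel_p <- function(s, mu, beta) {
  z <- (s - mu) / beta
  p <- -expm1(-exp(-z))
  pmax(p, exp(pmax(-z, -700)), .Machine$double.xmin)
}

#' Search proteins against a set of calibrated profiles
#'
#' Each protein is scored by its best ungapped local alignment to each
#' profile; the e-value is the Gumbel tail probability of the score times
#' the number of proteins searched (expected false hits at threshold t are
#' then t per profile).
#'
#' @param proteins named character vector of protein sequences
#' @param profiles list of calibrated `profile_model`s
#' @param e_cutoff report hits with e-value below this
#' @param min_cols minimum aligned profile columns per hit
#' @return data frame: `protein`, `profile`, `category`, `score`, `evalue`,
#'   `start`, `end` (0-based half-open span on the protein)
#' @export
search_profiles <- function(proteins, profiles, e_cutoff = 0.05,
                            min_cols = 25) {
  stopifnot(length(profiles) > 0)
  if (is.null(names(proteins)) && length(proteins) > 0)
    names(proteins) <- paste0("prot", seq_along(proteins))
  hits <- lapply(profiles, function(pr) {
    if (is.null(pr$calibration))
      stop("profile '", pr$name, "' is not calibrated")
    df <- .profile_scores(pr, proteins)
    df$profile <- pr$name
    df$category <- pr$category
    p <- .gumbel_p(df$score, pr$calibration$mu, pr$calibration$beta)
    df$evalue <- p * max(1L, length(proteins))
    df
  })
  out <- do.call(rbind, hits)
  out <- out[is.finite(out$score) & out$evalue < e_cutoff, , drop = FALSE]
  out <- out[order(out$evalue, out$protein), c("protein", "profile",
                                               "category", "score",
                                               "evalue", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Sample a protein from a profile's column frequencies
#'
#' Emits one residue per model column from the observed column frequencies;
#' such emissions score near the model maximum and serve as guaranteed
#' detectable planted markers.
#'
#' @param profile a `profile_model`
#' @return a single protein string
#' @export
sample_profile_protein <- function(profile) {
  paste(apply(profile$freq, 1, function(f) sample(AA20, 1, prob = f)),
        collapse = "")
}

#' Load the packaged marker profiles
#'
#' Reads the synthetic marker alignments shipped with the package (large
#' terminase subunit, major capsid protein, portal, and a reverse
#' transcriptase as a non-marker phage profile), builds the profile models
#' and calibrates them.
#'
#' @param dir directory of aligned FASTA files; defaults to the packaged set
#' @param n_decoys,seed calibration settings (see [calibrate_profile()])
#' @return named list of calibrated `profile_model`s
#' @export
load_marker_profiles <- function(dir = system.file("extdata", "profiles",
                                                   package = "phagering"),
                                 n_decoys = 500, seed = 101) {
  files <- list.files(dir, pattern = "\\.afa$", full.names = TRUE)
  if (length(files) == 0) stop("no profile alignments found in ", dir)
  cat_map <- c(terl = "TerL", mcp = "MCP", portal = "portal")
  profs <- lapply(files, function(f) {
    base <- sub("_synthetic\\.afa$", "", sub("\\.afa$", "", basename(f)))
    key <- sub("_.*$", "", tolower(base))
    category <- if (key %in% names(cat_map)) cat_map[[key]] else "other-phage"
    p <- build_profile(read_fasta(f), name = base, category = category)
    calibrate_profile(p, n_decoys = n_decoys, seed = seed)
  })
  stats::setNames(profs, vapply(profs, `[[`, "", "name"))
}
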
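# Synthetic metagenome generator with full ground truth. Communities mix
# circular phage genomes (terminal direct repeats + planted marker genes
# emitted from the packaged profiles), circular plasmid decoys (repeats,
# genes, but no markers), and linear fragments. Options plant TAG-recoded
# genomes, DGR cassettes and CRISPR protospacers, and draw virome reads
# from a known abundance vector. Everything is deterministic given the
# seed.

#' Configuration for a synthetic community
#'
#' Defaults emulate a small gut-virome-like test community: compact phage
#' genomes of 5-15 kb with assembler-style terminal repeats of 50-200 bp,
#' gene-dense plasmid decoys and linear fragments.
#'
#' @param n_phage_circular,n_plasmid_circular,n_linear_fragment contig
#'   counts per class
#' @param phage_length_range,plasmid_length_range,linear_length_range
#'   genome/fragment length ranges in bp
#' @param repeat_length_range terminal direct-repeat length range in bp
#' @param n_recoded number of phage genomes using the amber-glutamine code
#' @param n_markers_per_phage how many of the three hallmark genes (TerL,
#'   MCP, portal) each phage carries (1-3)
#' @param dgr_specs list of [dgr_spec()]s; each is planted in one phage
#' @param spacer_specs data frame with columns `genus`, `phylum`,
#'   `n_targeting`, `n_nontargeting`; NULL for no spacer table
#' @param gc background G+C fraction
#' @param coding_fraction approximate fraction of each genome covered by
#'   planted filler genes
#' @param seed integer RNG seed
#' @return a validated list of class `community_config`
#' @export
community_config <- function(n_phage_circular = 20, n_plasmid_circular = 5,
                             n_linear_fragment = 10,
                             phage_length_range = c(5000, 15000),
                             plasmid_length_range = c(3000, 8000),
                             linear_length_range = c(2000, 6000),
                             repeat_length_range = c(50, 200),
                             n_recoded = 0, n_markers_per_phage = 3,
                             dgr_specs = list(), spacer_specs = NULL,
                             gc = 0.5, coding_fraction = 0.7, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_phage_circular, n_plasmid_circular, n_linear_fragment,
              n_recoded)
  if (any(counts < 0)) stop("configuration error: counts must be >= 0")
  if (n_recoded > n_phage_circular)
    stop("configuration error: n_recoded exceeds n_phage_circular")
  rr <- repeat_length_range
  if (length(rr) != 2 || rr[1] < 1 || rr[1] > rr[2] ||
      rr[2] > min(phage_length_range[1], plasmid_length_range[1]) / 2)
    stop("configuration error: repeat_length_range must lie in [1, min ",
         "genome length / 2]")
  if (!n_markers_per_phage %in% 1:3)
    stop("configuration error: n_markers_per_phage must be 1, 2 or 3")
  class(cfg) <- "community_config"
  cfg
}

#' DGR cassette specification
#'
#' @param tr_length template-repeat length in bp (>= 20)
#' @param n_vr number of variable repeats copied from the template
#' @param adenine_mutation_fraction fraction of template adenines that are
#'   substituted in each variable repeat
#' @param vr_identity nominal TR/VR identity; informational, the realized
#'   identity follows from the adenine substitutions and noise
#' @param vr_distance_from_rt distance (bp) from the RT gene to each VR;
#'   recycled to length `n_vr`
#' @param background_noise per-position substitution rate at non-adenine
#'   positions (0 = the pure DGR hallmark)
#' @export
dgr_spec <- function(tr_length = 120, n_vr = 1,
                     adenine_mutation_fraction = 0.5, vr_identity = NA,
                     vr_distance_from_rt = 4000, background_noise = 0) {
  if (tr_length < 20) stop("tr_length must be >= 20")
  if (adenine_mutation_fraction < 0 || adenine_mutation_fraction > 1 ||
      background_noise < 0 || background_noise > 1)
    stop("fractions must lie in [0, 1]")
  structure(as.list(environment()), class = "dgr_spec")
}

# sample one integer from [lo, hi] (safe for degenerate ranges, unlike
# sample(lo:hi, 1) which falls back to sample.int when lo == hi)
.rint <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  as.integer(lo + floor(runif(1) * (hi - lo + 1)))

# reverse-translate a protein, avoiding stop codons; optionally re-encode a
# set of residue positions (which must be Q) as amber TAG
.CODON_CHOICES <- local({
  tab <- Biostrings::GENETIC_CODE
  tab <- tab[tab != "*"]
  split(names(tab), unname(tab))
})

.reverse_translate <- function(aa, amber_at = integer(0)) {
  res <- strsplit(aa, "")[[1]]
  codons <- vapply(res, function(a) {
    ch <- .CODON_CHOICES[[a]]
    if (is.null(ch)) ch <- .CODON_CHOICES[["A"]]
    ch[sample.int(length(ch), 1)]
  }, "")
  if (length(amber_at)) codons[amber_at] <- "TAG"
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# random protein from the codon-induced background
.random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = codon_background()),
        collapse = "")
}

# plant a gene (DNA string) at a free slot; returns updated genome + locus
.plant <- function(genome, gene, slots) {
  len <- nchar(gene)
  ok <- which(slots$end - slots$start >= len)
  if (length(ok) == 0) return(NULL)
  i <- ok[sample.int(length(ok), 1)]
  at <- slots$start[i]   # 0-based insertion point
  substr(genome, at + 1, at + len) <- gene
  # split the slot
  slots$start[i] <- at + len
  list(genome = genome, start = at, end = at + len, slots = slots)
}

# build one gene-dense genome; markers: named character vector of marker
# proteins to plant (possibly empty); recode: plant amber TAGs
.build_genome <- function(len, gc, coding_fraction, markers = character(0),
                          recode = FALSE) {
  g <- random_dna(len, gc)
  # carve non-overlapping slots on a grid
  slot_w <- 1500L
  starts <- seq(0L, len - slot_w, by = slot_w)
  slots <- data.frame(start = starts, end = starts + slot_w - 100L)
  loci <- list()
  # markers first (never recoded in their proximal half, so that a
  # standard-code prefix ORF still reaches round 1)
  for (m in names(markers)) {
    aa <- markers[[m]]
    amber_at <- integer(0)
    if (recode) {
      na <- nchar(aa)
      cand <- seq(ceiling(na * 0.55), na)
      amber_at <- sort(sample(cand, max(1, round(0.08 * length(cand)))))
      aa_vec <- strsplit(aa, "")[[1]]
      aa_vec[amber_at] <- "Q"
      aa <- paste(aa_vec, collapse = "")
    }
    p <- .plant(g, .reverse_translate(aa, amber_at), slots)
    if (is.null(p)) stop("genome too short to plant markers")
    g <- p$genome; slots <- p$slots
    loci[[m]] <- c(start = p$start, end = p$end)
  }
  # filler genes up to the target coding fraction
  target <- coding_fraction * len
  planted <- sum(vapply(loci, function(x) x["end"] - x["start"], 0))
  while (planted < target) {
    na <- sample(120:320, 1)
    amber_at <- if (recode)
      sort(sample(seq_len(na), max(2, round(na / 18)))) else integer(0)
    aa_vec <- strsplit(.random_protein(na), "")[[1]]
    aa_vec[amber_at] <- "Q"
    gene <- .reverse_translate(paste(aa_vec, collapse = ""), amber_at)
    p <- .plant(g, gene, slots)
    if (is.null(p)) break
    g <- p$genome; slots <- p$slots
    planted <- planted + nchar(gene)
  }
  list(seq = g, marker_loci = loci, slots = slots)
}

#' Generate a DGR-carrying genome
#'
#' Lays out a reverse-transcriptase gene (emitted from a supplied RT
#' profile or a random gene), a template repeat (TR) adjacent to it, and
#' `n_vr` variable repeats at the configured distances. Each VR differs
#' from the TR only at template adenine positions (a fraction
#' `adenine_mutation_fraction` of them, rounded), plus optional uniform
#' background noise at non-adenine positions.
#'
#' @param spec a [dgr_spec()]
#' @param seed RNG seed
#' @param genome_length total genome length (grown if the layout needs more)
#' @param gc background G+C fraction
#' @param tr_seq optional explicit template-repeat sequence (overrides
#'   `tr_length`)
#' @return list with `seq`, and a `truth` list: `rt` (start, end), `tr`
#'   (start, end), `vr` (matrix of starts/ends), `mutated_adenines`
#'   (template-relative 0-based positions substituted in any VR),
#'   `n_tr_adenines`
#' @export
generate_dgr_genome <- function(spec, seed = 1, genome_length = 30000,
                                gc = 0.5, tr_seq = NULL) {
  stopifnot(inherits(spec, "dgr_spec"))
  set.seed(seed)
  if (is.null(tr_seq)) tr_seq <- random_dna(spec$tr_length, gc)
  trv <- strsplit(tr_seq, "")[[1]]
  a_pos <- which(trv == "A")
  if (length(a_pos) < 5)
    stop("template repeat has fewer than 5 adenines; the adenine-bias ",
         "test would be underpowered")
  dists <- rep_len(spec$vr_distance_from_rt, spec$n_vr)
  L <- max(genome_length, 6000 + max(dists) + 2 * nchar(tr_seq) + 1000)
  g <- random_dna(L, gc)

  rt_start <- 3000L
  rt_aa <- .random_protein(300)
  rt_gene <- .reverse_translate(rt_aa)
  substr(g, rt_start + 1, rt_start + nchar(rt_gene)) <- rt_gene
  rt_end <- rt_start + nchar(rt_gene)
  rt_center <- as.integer((rt_start + rt_end) / 2)

  tr_start <- rt_end + 200L
  substr(g, tr_start + 1, tr_start + nchar(tr_seq)) <- tr_seq

  n_mut <- round(spec$adenine_mutation_fraction * length(a_pos))
  mutated <- sort(if (n_mut > 0) sample(a_pos, n_mut) else integer(0))
  vr_loci <- matrix(NA_integer_, spec$n_vr, 2,
                    dimnames = list(NULL, c("start", "end")))
  for (k in seq_len(spec$n_vr)) {
    vrv <- trv
    if (length(mutated))
      vrv[mutated] <- vapply(trv[mutated], function(b)
        sample(setdiff(DNA_BASES4, b), 1), "")
    if (spec$background_noise > 0) {
      non_a <- setdiff(seq_along(trv), a_pos)
      flip <- non_a[runif(length(non_a)) < spec$background_noise]
      vrv[flip] <- vapply(trv[flip], function(b)
        sample(setdiff(DNA_BASES4, b), 1), "")
    }
    vr_start <- rt_center + dists[k] + (k - 1L) * (nchar(tr_seq) + 400L)
    if (vr_start + nchar(tr_seq) > L)
      stop("genome_length too small for the requested VR layout")
    substr(g, vr_start + 1, vr_start + length(vrv)) <-
      paste(vrv, collapse = "")
    vr_loci[k, ] <- c(vr_start, vr_start + length(vrv))
  }
  list(seq = g,
       truth = list(rt = c(start = rt_start, end = rt_end),
                    tr = c(start = tr_start,
                           end = tr_start + nchar(tr_seq)),
                    vr = vr_loci,
                    tr_seq = tr_seq,
                    mutated_adenines = mutated - 1L,
                    n_tr_adenines = length(a_pos)))
}

#' Generate a synthetic community with ground truth
#'
#' @param config a [community_config()]
#' @param profiles calibrated marker profiles ([load_marker_profiles()]);
#'   required when phages are generated
#' @return list with `contigs` (named character vector), `truth` (data
#'   frame: one row per contig with class label, repeat length, genetic
#'   code, canonical length), `marker_loci`, `dgr_truth`, `spacers` (data
#'   frame or NULL), `protospacers`, `abundance` (named true abundance
#'   vector over phage contigs)
#' @export
generate_community <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  contigs <- character(0)
  rows <- list()
  marker_loci <- list()
  dgr_truth <- list()
  protospacers <- NULL

  need_markers <- config$n_phage_circular > 0
  if (need_markers && is.null(profiles))
    stop("profiles are required to plant marker genes")
  marker_profiles <- if (need_markers)
    Filter(function(p) p$category %in% MARKER_CATEGORIES, profiles)

  recoded_ids <- seq_len(config$n_recoded)
  dgr_assign <- rep_len(c(seq_along(config$dgr_specs),
                          rep(0, max(0, config$n_phage_circular -
                                       length(config$dgr_specs)))),
                        max(config$n_phage_circular, 1))

  for (i in seq_len(config$n_phage_circular)) {
    id <- sprintf("phage_%03d", i)
    recode <- i %in% recoded_ids
    dgr_i <- dgr_assign[i]
    if (dgr_i > 0) {
      spec <- config$dgr_specs[[dgr_i]]
      dg <- generate_dgr_genome(spec,
                                seed = (config$seed * 1000L + i) %%
                                  .Machine$integer.max,
                                genome_length =
                                  .rint(config$phage_length_range[1],
                                        config$phage_length_range[2]),
                                gc = config$gc)
      g <- dg$seq
      # plant markers downstream of the DGR cassette, extending the genome
      # with random sequence if the layout needs room
      ml <- list()
      cats <- sample(names(marker_profiles), config$n_markers_per_phage)
      at <- max(dg$truth$vr[, "end"], dg$truth$tr[["end"]]) + 300L
      for (m in cats) {
        aa <- sample_profile_protein(marker_profiles[[m]])
        gene <- .reverse_translate(aa)
        if (at + nchar(gene) + 200L > nchar(g))
          g <- paste0(g, random_dna(at + nchar(gene) + 500L - nchar(g),
                                    config$gc))
        substr(g, at + 1, at + nchar(gene)) <- gene
        ml[[m]] <- c(start = at, end = at + nchar(gene))
        at <- at + nchar(gene) + 250L
      }
      dgr_truth[[id]] <- dg$truth
      gb <- list(seq = g, marker_loci = ml)
    } else {
      L <- .rint(config$phage_length_range[1], config$phage_length_range[2])
      cats <- sample(names(marker_profiles), config$n_markers_per_phage)
      markers <- stats::setNames(vapply(cats, function(m)
        sample_profile_protein(marker_profiles[[m]]), ""), cats)
      gb <- .build_genome(L, config$gc, config$coding_fraction, markers,
                          recode = recode)
    }
    r <- .rint(config$repeat_length_range[1], config$repeat_length_range[2])
    contigs[[id]] <- paste0(gb$seq, substr(gb$seq, 1, r))
    marker_loci[[id]] <- gb$marker_loci
    rows[[id]] <- data.frame(
      contig_id = id, class = "phage", repeat_length = r,
      genetic_code = if (recode) "amber-gln" else "standard-bacterial",
      canonical_length = nchar(gb$seq), has_dgr = dgr_i > 0)
  }

  for (i in seq_len(config$n_plasmid_circular)) {
    id <- sprintf("plasmid_%03d", i)
    L <- .rint(config$plasmid_length_range[1],
               config$plasmid_length_range[2])
    gb <- .build_genome(L, config$gc, config$coding_fraction)
    r <- .rint(config$repeat_length_range[1], config$repeat_length_range[2])
    contigs[[id]] <- paste0(gb$seq, substr(gb$seq, 1, r))
    rows[[id]] <- data.frame(
      contig_id = id, class = "plasmid", repeat_length = r,
      genetic_code = "standard-bacterial", canonical_length = L,
      has_dgr = FALSE)
  }

  for (i in seq_len(config$n_linear_fragment)) {
    id <- sprintf("linear_%03d", i)
    L <- .rint(config$linear_length_range[1],
               config$linear_length_range[2])
    gb <- .build_genome(L, config$gc, config$coding_fraction)
    contigs[[id]] <- gb$seq
    rows[[id]] <- data.frame(
      contig_id = id, class = "linear", repeat_length = NA_integer_,
      genetic_code = "standard-bacterial", canonical_length = L,
      has_dgr = FALSE)
  }

  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  spacers <- NULL
  if (!is.null(config$spacer_specs) && config$n_phage_circular > 0) {
    ss <- config$spacer_specs
    phage_ids <- truth$contig_id[truth$class == "phage"]
    sp_rows <- list(); pp_rows <- list(); n <- 0
    for (j in seq_len(nrow(ss))) {
      for (t in seq_len(ss$n_targeting[j])) {
        n <- n + 1
        tgt <- sample(phage_ids, 1)
        g <- contigs[[tgt]]
        at <- sample.int(nchar(g) - 32L, 1)
        sp_rows[[n]] <- data.frame(
          spacer_id = sprintf("sp%04d", n),
          sequence = substr(g, at, at + 31L),
          phylum = ss$phylum[j], genus = ss$genus[j])
        pp_rows[[n]] <- data.frame(spacer_id = sprintf("sp%04d", n),
                                   contig_id = tgt, start = at - 1L,
                                   end = at + 31L)
      }
      for (t in seq_len(ss$n_nontargeting[j])) {
        n <- n + 1
        sp_rows[[n]] <- data.frame(
          spacer_id = sprintf("sp%04d", n),
          sequence = random_dna(32, config$gc),
          phylum = ss$phylum[j], genus = ss$genus[j])
      }
    }
    spacers <- do.call(rbind, sp_rows)
    protospacers <- do.call(rbind, pp_rows)
    rownames(spacers) <- rownames(protospacers) <- NULL
  }

  ab <- NULL
  if (config$n_phage_circular > 0) {
    w <- stats::rgamma(config$n_phage_circular, shape = 1)
    ab <- stats::setNames(w / sum(w),
                          truth$contig_id[truth$class == "phage"])
  }

  list(contigs = contigs, truth = truth, marker_loci = marker_loci,
       dgr_truth = dgr_truth, spacers = spacers,
       protospacers = protospacers, abundance = ab, config = config)
}

#' Draw virome reads from genomes at a known abundance
#'
#' Reads are drawn from genome `i` with probability proportional to
#' `abundance[i] * length[i]`, so that the expected length-normalized
#' fractional abundance recovered downstream equals the input vector.
#' Circular genomes yield origin-spanning reads. Reads are error-free by
#' default; `error_rate` adds uniform substitutions.
#'
#' @param genomes named character vector
#' @param abundance abundance vector summing to 1 (recycled names from
#'   `genomes` if unnamed)
#' @param n_reads number of reads (> 0)
#' @param read_length read length; must not exceed the shortest genome
#' @param seed RNG seed
#' @param circular logical (recycled): whether each genome is circular
#' @param error_rate uniform substitution probability per base
#' @return list with `reads` (named character vector; names encode the
#'   source), `truth` (data frame: read_id, genome, start, strand)
#' @export
generate_reads <- function(genomes, abundance, n_reads,
                           read_length = 150, seed = 1, circular = TRUE,
                           error_rate = 0) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (abs(sum(abundance) - 1) > 1e-8)
    stop("abundance vector must sum to 1")
  lens <- nchar(genomes)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest genome")
  set.seed(seed)
  circular <- rep_len(circular, length(genomes))
  p <- abundance * lens
  p <- p / sum(p)
  src <- sample(seq_along(genomes), n_reads, replace = TRUE, prob = p)
  ext <- ifelse(circular,
                paste0(genomes, substr(genomes, 1, read_length - 1)),
                genomes)
  max_start <- ifelse(circular, lens, lens - read_length + 1L)
  starts <- 1L + floor(runif(n_reads) * max_start[src])
  reads <- substring(ext[src], starts, starts + read_length - 1L)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads[strands == "-"] <- revcomp(reads[strands == "-"])
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      v <- strsplit(r, "")[[1]]
      flip <- which(runif(length(v)) < error_rate)
      if (length(flip))
        v[flip] <- vapply(v[flip], function(b)
          sample(setdiff(DNA_BASES4, b), 1), "")
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  ids <- sprintf("read%06d|%s", seq_len(n_reads), names(genomes)[src])
  list(reads = stats::setNames(reads, ids),
       truth = data.frame(read_id = ids, genome = names(genomes)[src],
                          start = starts - 1L, strand = strands))
}
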
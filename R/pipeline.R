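# End-to-end orchestration: simulate -> circularity screen -> two-round
# marker classification -> dereplication -> host prediction -> DGR scan ->
# abundance, with plain-file stage handoff (FASTA/TSV), a funnel summary,
# and a reproducibility manifest of input/output digests.

#' Validate a pipeline configuration
#' @keywords internal
.check_pipeline_config <- function(cfg) {
  e1 <- cfg$e1 %||% 0.05
  e2 <- cfg$e2 %||% 0.01
  if (e2 > e1)
    stop("validation error: round-2 cutoff e2 (", e2,
         ") must not be looser than round-1 cutoff e1 (", e1, ")")
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full discovery pipeline on a synthetic community
#'
#' Stages run in dependency order: community simulation, circularity
#' screening, two-round marker classification, genome dereplication,
#' CRISPR-spacer host prediction (when the community has a spacer table),
#' DGR detection on genomes with a planted reverse transcriptase, read
#' simulation and abundance profiling. Outputs are written as FASTA/TSV
#' under `out_dir` along with `summary.tsv` (the per-stage survivor
#' funnel) and `manifest.yaml` (config snapshot, seeds, file digests,
#' stage timings).
#'
#' @param config list (or path to a YAML file) with optional entries
#'   `community` (arguments to [community_config()]), `e1`, `e2`,
#'   `min_len`, `n_reads`, `read_length`; seeds come from `seed`
#' @param out_dir output directory (created); NULL for no file output
#' @param seed integer seed overriding `config$seed`
#' @param profiles calibrated profiles; loaded from the package when NULL
#' @return list with all stage outputs, `summary` (funnel data frame) and
#'   `manifest`
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL,
                         profiles = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_pipeline_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage_files <- character(0)

  if (is.null(profiles)) profiles <- load_marker_profiles()

  # --- simulate ---------------------------------------------------------
  t0 <- tic()
  comm_args <- config$community %||% list()
  comm_args$seed <- seed
  cc <- do.call(community_config, comm_args)
  comm <- generate_community(cc, profiles = profiles)
  t_all$simulate <- tic() - t0

  # --- circular screen --------------------------------------------------
  t0 <- tic()
  screen <- screen_circular(comm$contigs)
  canonical <- attr(screen, "canonical")
  t_all$screen <- tic() - t0

  # --- classification ---------------------------------------------------
  t0 <- tic()
  calls <- classify_contigs(canonical, profiles,
                            e1 = config$e1 %||% 0.05,
                            e2 = config$e2 %||% 0.01,
                            min_len = config$min_len %||% 3000,
                            circular = TRUE)
  phage_ids <- calls$contig_id[calls$is_phage]
  phage_genomes <- canonical[phage_ids]
  t_all$classify <- tic() - t0

  # --- dereplication ----------------------------------------------------
  t0 <- tic()
  derep <- if (length(phage_genomes) >= 1)
    dereplicate_genomes(phage_genomes) else
      data.frame(member = character(0), representative = character(0))
  reps <- unique(derep$representative)
  t_all$dereplicate <- tic() - t0

  # --- host prediction --------------------------------------------------
  t0 <- tic()
  hosts <- NULL; matches <- NULL
  if (!is.null(comm$spacers) && length(phage_genomes)) {
    matches <- match_spacers(comm$spacers, phage_genomes)
    hosts <- predict_hosts(matches, comm$spacers)
  }
  t_all$hosts <- tic() - t0

  # --- DGR --------------------------------------------------------------
  t0 <- tic()
  dgr_reports <- list()
  for (id in names(comm$dgr_truth)) {
    if (!id %in% names(comm$contigs)) next
    tr_call <- find_terminal_repeat(comm$contigs[[id]])
    gseq <- if (tr_call$is_circular) tr_call$canonical_seq else
      comm$contigs[[id]]
    rp <- find_repeat_pairs(gseq, comm$dgr_truth[[id]]$rt)
    reps_id <- dgr_adenine_report(gseq, rp)
    if (length(reps_id)) dgr_reports[[id]] <- reps_id[[1]]
  }
  t_all$dgr <- tic() - t0

  # --- abundance --------------------------------------------------------
  t0 <- tic()
  abund <- NULL; recr <- NULL
  if (length(phage_genomes)) {
    ab_truth <- comm$abundance[phage_ids]
    ab_truth <- ab_truth / sum(ab_truth)
    sim <- generate_reads(phage_genomes, ab_truth,
                          n_reads = config$n_reads %||% 5000,
                          read_length = config$read_length %||% 150,
                          seed = seed + 7L)
    recr <- recruit_reads(sim$reads, phage_genomes)
    abund <- fractional_abundance(recr$counts, nchar(phage_genomes))
  }
  t_all$abundance <- tic() - t0

  funnel <- data.frame(
    stage = c("contigs", "circular", "round1_hit", "phage",
              "dereplicated"),
    n = c(nrow(screen), sum(screen$is_circular),
          sum(calls$round1_pass), length(phage_ids), length(reps)))

  manifest <- list(version = as.character(utils::packageVersion("phagering")),
                   seed = seed,
                   config = config,
                   timings = t_all)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(comm$contigs, file.path(out_dir, "contigs.fasta"))
    utils::write.table(screen, file.path(out_dir, "circular.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(calls, file.path(out_dir, "phage_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(derep, file.path(out_dir, "dereplication.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(matches))
      utils::write.table(matches, file.path(out_dir, "spacer_matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(abund))
      utils::write.table(abund, file.path(out_dir, "abundance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(funnel, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_files <- list.files(out_dir, full.names = TRUE)
    manifest$digests <- as.list(tools::md5sum(stage_files))
    names(manifest$digests) <- basename(stage_files)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  list(community = comm, screen = screen, calls = calls, derep = derep,
       hosts = hosts, spacer_matches = matches, dgr = dgr_reports,
       recruitment = recr, abundance = abund, summary = funnel,
       manifest = manifest)
}
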
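#' Run the full design-and-evaluation pipeline
#'
#' Wires the stages end to end on simulated inputs: genome and population
#' simulation, per-population site filtering, pooling, flank extraction and
#' probe screening, three-stage even-spacing selection, a simulated array
#' run over the selected panel, QC/polymorphism evaluation and an
#' identity-by-state neighbor-joining tree. Every stage's counts land in a
#' manifest (with the seed and a config digest) so that conservation across
#' stages can be audited; with `outdir` set, the per-stage artifacts are
#' written as FASTA / VCF / TSV / Newick files.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @param stages character subset of
#'   `c("simulate", "filter", "select", "evaluate", "phylo")`; later stages
#'   require the earlier ones.
#' @return list with the per-stage objects (`genome`, `truth`,
#'   `populations`, `kept_sets`, `pooled`, `candidates`, `panel`, `audit`,
#'   `array_run`, `qc`, `accounting`, `tree`) and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         stages = c("simulate", "filter", "select",
                                    "evaluate", "phylo")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  manifest <- list(seed = config$seed,
                   config_digest = config_digest(config),
                   counts = list())
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(outdir)) writer(file.path(outdir, name))
  }

  spec <- config$sim
  spec$seed <- config$seed
  out$genome <- simulate_genome(spec)
  sim <- simulate_populations(out$genome, spec)
  out$truth <- sim$truth
  out$populations <- sim$populations
  manifest$counts$simulated_sites <- nrow(sim$truth)
  emit("genome.fa", function(p) write_genome_fasta(out$genome, p))
  emit("truth.tsv", function(p) write_truth_table(out$truth, p))

  if (!"filter" %in% stages) {
    manifest$counts <- manifest$counts
    out$manifest <- manifest
    return(out)
  }
  out$kept_sets <- lapply(names(sim$populations), function(p) {
    stats <- site_stats(sim$populations[[p]], p)
    stats$n_alleles <- 2L  # simulated sites are biallelic
    filter_sites(stats, p, config$site_filter)$kept
  })
  names(out$kept_sets) <- names(sim$populations)
  manifest$counts$kept_per_population <-
    vapply(out$kept_sets, nrow, integer(1))
  out$pooled <- pool_unique(out$kept_sets)
  manifest$counts$pooled_unique <- nrow(out$pooled)
  flanked <- extract_flanks(out$pooled, out$genome,
                            config$probe_filter$flank_length)
  probe <- filter_probes(flanked, config$probe_filter)
  out$candidates <- probe$kept
  manifest$counts$probe_kept <- nrow(probe$kept)
  manifest$counts$probe_rejected <- nrow(probe$rejected)
  emit("candidates.tsv", function(p)
    write.table(out$candidates, p, sep = "\t", quote = FALSE,
                row.names = FALSE))

  if (!"select" %in% stages) {
    out$manifest <- manifest
    return(out)
  }
  sel <- select_panel(out$candidates, out$genome, config$select)
  out$panel <- sel$panel
  out$audit <- sel$audit
  manifest$counts$panel_size <- nrow(out$panel)
  manifest$counts$dropped <- sum(sel$audit$state == "dropped")
  emit("panel.tsv", function(p) write_panel(out$panel, p))
  emit("audit.tsv", function(p)
    write.table(sel$audit, p, sep = "\t", quote = FALSE, row.names = FALSE))

  if (!"evaluate" %in% stages) {
    out$manifest <- manifest
    return(out)
  }
  samples <- do.call(rbind, lapply(sim$populations, function(gm) gm$samples))
  rownames(samples) <- NULL
  out$array_run <- simulate_array_run(
    out$panel[, c("chrom", "pos", "ref", "alt")], samples, out$truth,
    missing_rate = spec$missing_rate,
    genotype_error_rate = spec$genotype_error_rate,
    seed = config$seed + 3L)
  out$qc <- marker_qc(out$array_run, config$eval)
  manifest$counts$qc_kept <- length(out$qc$kept)
  manifest$counts$qc_failed <- length(out$qc$failed)
  out$accounting <- polymorphic_accounting(out$array_run, config$eval)
  emit("marker_summary.tsv", function(p)
    write.table(out$qc$summary, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("genotypes.vcf", function(p)
    write_vcf(out$array_run, p, genome_index(out$genome)))

  if ("phylo" %in% stages) {
    keep_markers <- out$qc$kept
    gm_kept <- subset_genotypes(out$array_run, markers = keep_markers)
    dm <- allele_sharing_distance(gm_kept, permissive = TRUE)
    gdm <- group_mean_distance(dm, gm_kept$samples$group)
    out$tree <- neighbor_joining(gdm)
    emit("tree.nwk", function(p) write_newick(out$tree, p))
  }
  out$manifest <- manifest
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  out
}

config_digest <- function(config) {
  # order-stable digest of every numeric threshold; no external digest dep
  flat <- unlist(config, use.names = TRUE)
  paste0("cfg-", sum(seq_along(flat) *
                       as.integer(factor(paste(names(flat), flat)))) %%
           1000000L)
}
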
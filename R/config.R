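## Configuration objects. Defaults are the published array-design thresholds;
## every number is overridable so alternative designs remain expressible.

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Site-filter thresholds
#'
#' Population-level hard filters applied to called SNP sites. Two sequential
#' passes mirror the two filtering tools used after variant calling: the
#' primary pass keeps sites with minor allele frequency >= `min_maf` and
#' missing genotype count <= `max_missing_primary`; the secondary pass
#' additionally requires minor allele count >= `min_minor_allele_count`,
#' missing count <= `max_missing_secondary`, and observed allele number
#' <= `max_alleles`. Quality thresholds (`min_site_quality`,
#' `min_mapping_quality`, `min_base_quality`, `min_coverage`) apply only when
#' the corresponding fields are present in the input, since they are normally
#' enforced inside the variant caller.
#'
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param max_missing_primary maximum missing genotype count, primary pass
#'   (default 3).
#' @param min_minor_allele_count minimum minor allele count, secondary pass
#'   (default 2).
#' @param max_missing_secondary maximum missing genotype count, secondary pass
#'   (default 2).
#' @param max_alleles maximum number of observed alleles (default 3).
#' @param min_site_quality,min_mapping_quality,min_base_quality Phred-scaled
#'   minima (default 20), applied only if present in the input.
#' @param min_coverage minimum site coverage (default 10), applied only if
#'   present in the input.
#' @return an object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_maf = 0.05,
                               max_missing_primary = 3,
                               min_minor_allele_count = 2,
                               max_missing_secondary = 2,
                               max_alleles = 3,
                               min_site_quality = 20,
                               min_mapping_quality = 20,
                               min_base_quality = 20,
                               min_coverage = 10) {
  stopifnot_scalar(min_maf, "min_maf", 0, 1)
  stopifnot_scalar(max_missing_primary, "max_missing_primary", 0)
  stopifnot_scalar(min_minor_allele_count, "min_minor_allele_count", 0)
  stopifnot_scalar(max_missing_secondary, "max_missing_secondary", 0)
  stopifnot_scalar(max_alleles, "max_alleles", 1)
  stopifnot_scalar(min_site_quality, "min_site_quality", 0)
  stopifnot_scalar(min_mapping_quality, "min_mapping_quality", 0)
  stopifnot_scalar(min_base_quality, "min_base_quality", 0)
  stopifnot_scalar(min_coverage, "min_coverage", 0)
  structure(list(min_maf = min_maf,
                 max_missing_primary = max_missing_primary,
                 min_minor_allele_count = min_minor_allele_count,
                 max_missing_secondary = max_missing_secondary,
                 max_alleles = max_alleles,
                 min_site_quality = min_site_quality,
                 min_mapping_quality = min_mapping_quality,
                 min_base_quality = min_base_quality,
                 min_coverage = min_coverage),
            class = "site_filter_config")
}

#' Probe flank-screen thresholds
#'
#' Rules deciding whether the 35 bp flanks of a SNP are compatible with
#' hybridisation probe design: runs of G/C shorter than `max_gc_run`
#' (a run of length >= `max_gc_run` fails), runs of A/T shorter than
#' `max_at_run`, GC content of the probe context within
#' `[gc_min, gc_max]` (inclusive), no other known variant inside either
#' flank, and a biallelic SNP (no indel).
#'
#' @param flank_length flank length in bases (default 35).
#' @param max_gc_run exclusive G/C run bound: a run of this length fails
#'   (default 4, i.e. "fewer than four contiguous G or C").
#' @param max_at_run exclusive A/T run bound (default 6).
#' @param gc_min,gc_max inclusive GC-content bounds (defaults 0.30 and 0.70).
#' @param require_no_other_variant reject sites with another known variant in
#'   a flank (default TRUE).
#' @param require_no_indel reject non-SNP (indel) records (default TRUE).
#' @param combined_run_alphabet if TRUE (default) a "G or C" run is a run over
#'   the combined alphabet \{G,C\} so "GCGC" counts as one run of 4; if FALSE
#'   only same-base homopolymers count.
#' @param gc_window `"context"` (default) measures GC over the full
#'   71-base probe context, `"flanks"` over the two flanks only.
#' @return an object of class `probe_filter_config`.
#' @export
probe_filter_config <- function(flank_length = 35,
                                max_gc_run = 4,
                                max_at_run = 6,
                                gc_min = 0.30,
                                gc_max = 0.70,
                                require_no_other_variant = TRUE,
                                require_no_indel = TRUE,
                                combined_run_alphabet = TRUE,
                                gc_window = c("context", "flanks")) {
  stopifnot_scalar(flank_length, "flank_length", 1)
  stopifnot_scalar(max_gc_run, "max_gc_run", 1)
  stopifnot_scalar(max_at_run, "max_at_run", 1)
  stopifnot_scalar(gc_min, "gc_min", 0, 1)
  stopifnot_scalar(gc_max, "gc_max", 0, 1)
  if (gc_min > gc_max) stop("gc_min must be <= gc_max", call. = FALSE)
  gc_window <- match.arg(gc_window)
  structure(list(flank_length = flank_length,
                 max_gc_run = max_gc_run,
                 max_at_run = max_at_run,
                 gc_min = gc_min,
                 gc_max = gc_max,
                 require_no_other_variant = isTRUE(require_no_other_variant),
                 require_no_indel = isTRUE(require_no_indel),
                 combined_run_alphabet = isTRUE(combined_run_alphabet),
                 gc_window = gc_window),
            class = "probe_filter_config")
}

#' Even-spacing selection parameters
#'
#' Parameters of the three-stage binning selection: Stage I picks the two
#' edge-nearest SNPs per `small_bin`-sized bin, Stage II merges
#' `merge_factor` bins and adjusts density into the `[bin_floor, bin_target]`
#' band, Stage III back-fills inter-marker gaps larger than `max_gap` with
#' dropped SNPs nearest the gap midpoints.
#'
#' @param small_bin Stage-I bin size in bases (default 1000).
#' @param merge_factor number of adjacent small bins merged in Stage II
#'   (default 10, giving 10 kb bins).
#' @param bin_target maximum SNPs kept per merged bin (default 10).
#' @param bin_floor merged-bin count below which dropped SNPs are re-promoted
#'   (default 7).
#' @param max_gap largest tolerated adjacent-marker gap in bases
#'   (default 2000).
#' @param tie_break tie rule identifier; only `"lowest-coordinate"` is
#'   implemented.
#' @return an object of class `select_config`.
#' @export
select_config <- function(small_bin = 1000,
                          merge_factor = 10,
                          bin_target = 10,
                          bin_floor = 7,
                          max_gap = 2000,
                          tie_break = "lowest-coordinate") {
  stopifnot_scalar(small_bin, "small_bin", 1)
  stopifnot_scalar(merge_factor, "merge_factor", 1)
  stopifnot_scalar(bin_target, "bin_target", 1)
  stopifnot_scalar(bin_floor, "bin_floor", 0)
  stopifnot_scalar(max_gap, "max_gap", 1)
  if (bin_floor > bin_target)
    stop("bin_floor must be <= bin_target", call. = FALSE)
  tie_break <- match.arg(tie_break, "lowest-coordinate")
  structure(list(small_bin = as.integer(small_bin),
                 merge_factor = as.integer(merge_factor),
                 bin_target = as.integer(bin_target),
                 bin_floor = as.integer(bin_floor),
                 max_gap = as.integer(max_gap),
                 tie_break = tie_break),
            class = "select_config")
}

#' Post-genotyping evaluation parameters
#'
#' @param min_call_rate markers with call rate strictly greater than this are
#'   kept by QC (default 0.90).
#' @param min_maf markers with minor allele frequency strictly greater than
#'   this are kept by QC (default 0.02).
#' @param class_call_rate call-rate bound used by conversion-type
#'   classification (default 0.97).
#' @param density_bin bin width in bases for the genome density scan
#'   (default 100000).
#' @param low_density_threshold bins with fewer markers than this are counted
#'   as low-density (default 10).
#' @return an object of class `eval_config`.
#' @export
eval_config <- function(min_call_rate = 0.90,
                        min_maf = 0.02,
                        class_call_rate = 0.97,
                        density_bin = 100000,
                        low_density_threshold = 10) {
  stopifnot_scalar(min_call_rate, "min_call_rate", 0, 1)
  stopifnot_scalar(min_maf, "min_maf", 0, 1)
  stopifnot_scalar(class_call_rate, "class_call_rate", 0, 1)
  stopifnot_scalar(density_bin, "density_bin", 1)
  stopifnot_scalar(low_density_threshold, "low_density_threshold", 0)
  structure(list(min_call_rate = min_call_rate,
                 min_maf = min_maf,
                 class_call_rate = class_call_rate,
                 density_bin = as.integer(density_bin),
                 low_density_threshold = as.integer(low_density_threshold)),
            class = "eval_config")
}

#' Simulation specification
#'
#' Parameters of the synthetic-data generator. Defaults mirror a
#' multi-population marine-fish resequencing design at desk scale:
#' six populations, 14 diploid samples each, a SNP density of 14 per kb and a
#' pooled call set in which roughly 0.45% of sites segregate in a single
#' population only (`shared_fraction = 0.9955`); the genome itself is scaled
#' to a few hundred kilobases so that every pipeline stage runs in seconds.
#'
#' @param genome_length_per_chrom chromosome length in bases.
#' @param n_chromosomes number of chromosomes.
#' @param gc_fraction expected GC fraction of the simulated genome.
#' @param n_populations number of populations.
#' @param samples_per_population diploid samples per population.
#' @param snp_density expected SNPs per kb.
#' @param maf_distribution minor-allele-frequency spectrum; currently
#'   `"uniform"` on `[maf_min, maf_max]`.
#' @param maf_min,maf_max bounds of the uniform MAF spectrum
#'   (defaults 0.05 and 0.5).
#' @param shared_fraction proportion of sites segregating in all populations;
#'   the remainder segregate in exactly one.
#' @param missing_rate per-call missing probability (missing completely at
#'   random).
#' @param genotype_error_rate per-call probability of replacing the true
#'   genotype with one of the two other classes.
#' @param seed integer seed; identical spec and seed give byte-identical
#'   outputs.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(genome_length_per_chrom = 100000,
                     n_chromosomes = 3,
                     gc_fraction = 0.41,
                     n_populations = 6,
                     samples_per_population = 14,
                     snp_density = 14,
                     maf_distribution = "uniform",
                     maf_min = 0.05,
                     maf_max = 0.5,
                     shared_fraction = 0.9955,
                     missing_rate = 0.02,
                     genotype_error_rate = 0.005,
                     seed = 1L) {
  stopifnot_scalar(genome_length_per_chrom, "genome_length_per_chrom", 1)
  stopifnot_scalar(n_chromosomes, "n_chromosomes", 1)
  stopifnot_scalar(gc_fraction, "gc_fraction", 0, 1)
  stopifnot_scalar(n_populations, "n_populations", 1)
  stopifnot_scalar(samples_per_population, "samples_per_population", 1)
  if (!is.numeric(snp_density) || snp_density <= 0)
    stop("snp_density must be > 0", call. = FALSE)
  maf_distribution <- match.arg(maf_distribution, "uniform")
  stopifnot_scalar(maf_min, "maf_min", 0, 0.5)
  stopifnot_scalar(maf_max, "maf_max", 0, 0.5)
  stopifnot_scalar(shared_fraction, "shared_fraction", 0, 1)
  stopifnot_scalar(missing_rate, "missing_rate", 0, 1)
  stopifnot_scalar(genotype_error_rate, "genotype_error_rate", 0, 1)
  stopifnot_scalar(seed, "seed")
  structure(list(genome_length_per_chrom = as.integer(genome_length_per_chrom),
                 n_chromosomes = as.integer(n_chromosomes),
                 gc_fraction = gc_fraction,
                 n_populations = as.integer(n_populations),
                 samples_per_population = as.integer(samples_per_population),
                 snp_density = snp_density,
                 maf_distribution = maf_distribution,
                 maf_min = maf_min,
                 maf_max = maf_max,
                 shared_fraction = shared_fraction,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Composite pipeline configuration
#'
#' Bundles the per-stage configurations with a global seed. Defaults
#' reproduce the published design thresholds exactly.
#'
#' @param sim a [sim_spec()].
#' @param site_filter a [site_filter_config()].
#' @param probe_filter a [probe_filter_config()].
#' @param select a [select_config()].
#' @param eval a [eval_config()].
#' @param seed global seed for the simulation stages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_spec(),
                       site_filter = site_filter_config(),
                       probe_filter = probe_filter_config(),
                       select = select_config(),
                       eval = eval_config(),
                       seed = 1L) {
  stopifnot(inherits(sim, "sim_spec"),
            inherits(site_filter, "site_filter_config"),
            inherits(probe_filter, "probe_filter_config"),
            inherits(select, "select_config"),
            inherits(eval, "eval_config"))
  structure(list(sim = sim, site_filter = site_filter,
                 probe_filter = probe_filter, select = select,
                 eval = eval, seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline configuration (design defaults)\n")
  for (nm in c("site_filter", "probe_filter", "select", "eval")) {
    cat("--", nm, "--\n")
    cfg <- x[[nm]]
    for (f in names(cfg)) cat(sprintf("  %-24s %s\n", f, format(cfg[[f]])))
  }
  invisible(x)
}
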
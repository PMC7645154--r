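## Population-level hard filtering of called SNP sites and pooling of the
## per-population call sets into one unique candidate list.

PRIMARY_RULES <- c("min_site_quality", "min_mapping_quality",
                   "min_base_quality", "min_coverage", "min_maf",
                   "max_missing_primary")
SECONDARY_RULES <- c("min_minor_allele_count", "max_missing_secondary",
                     "max_alleles")

#' Filter SNP sites for one population
#'
#' Applies the post-calling hard filters to per-population site statistics.
#' The primary pass enforces MAF and missing-count thresholds (plus quality
#' and coverage thresholds whenever those columns are present); the
#' secondary pass enforces minor-allele count, a stricter missing-count
#' bound and the maximum observed allele number. A site is kept iff it
#' passes every applicable rule; the rejection log records the first failing
#' rule per site. Filtering is idempotent.
#'
#' @param sites data.frame of per-population site statistics
#'   (see [read_vcf()] or [site_stats()]).
#' @param population population label to filter; must match the `population`
#'   column.
#' @param config a [site_filter_config()].
#' @param stage `"both"` (default), `"primary"` or `"secondary"`.
#' @return list with `kept` (data.frame) and `log` (data.frame: `chrom`,
#'   `pos`, `population`, `rule` of first failure).
#' @export
filter_sites <- function(sites, population, config = site_filter_config(),
                         stage = c("both", "primary", "secondary")) {
  stopifnot(is.data.frame(sites), inherits(config, "site_filter_config"))
  stage <- match.arg(stage)
  if (!population %in% sites$population)
    stop("population label absent from site statistics: ", population,
         call. = FALSE)
  x <- sites[sites$population == population, , drop = FALSE]
  rules <- character(0)
  if (stage %in% c("both", "primary")) rules <- c(rules, PRIMARY_RULES)
  if (stage %in% c("both", "secondary")) rules <- c(rules, SECONDARY_RULES)

  fail_rule <- rep(NA_character_, nrow(x))
  mark <- function(bad, rule) {
    bad[is.na(bad)] <- FALSE
    fail_rule[is.na(fail_rule) & bad] <<- rule
  }
  for (rule in rules) {
    switch(rule,
      min_site_quality = if (!is.null(x$site_quality))
        mark(x$site_quality < config$min_site_quality, rule),
      min_mapping_quality = if (!is.null(x$mapping_quality))
        mark(x$mapping_quality < config$min_mapping_quality, rule),
      min_base_quality = if (!is.null(x$base_quality))
        mark(x$base_quality < config$min_base_quality, rule),
      min_coverage = if (!is.null(x$coverage))
        mark(x$coverage < config$min_coverage, rule),
      min_maf = mark(is.na(x$maf) | x$maf < config$min_maf, rule),
      max_missing_primary =
        mark(x$n_missing > config$max_missing_primary, rule),
      min_minor_allele_count =
        mark(x$mac < config$min_minor_allele_count, rule),
      max_missing_secondary =
        mark(x$n_missing > config$max_missing_secondary, rule),
      max_alleles = mark(x$n_alleles > config$max_alleles, rule))
  }
  kept <- x[is.na(fail_rule), , drop = FALSE]
  rownames(kept) <- NULL
  bad <- which(!is.na(fail_rule))
  log <- data.frame(chrom = x$chrom[bad], pos = x$pos[bad],
                    population = rep(population, length(bad)),
                    rule = fail_rule[bad], stringsAsFactors = FALSE)
  list(kept = kept, log = log)
}

#' Pool per-population kept sets into a unique candidate list
#'
#' Takes the union of per-population site sets keyed by
#' (chromosome, position, ref, alt), recording which populations carry each
#' site. Sites present in exactly one population are population-specific.
#' Two records at the same coordinate with different reference alleles are a
#' reference mismatch and raise an error.
#'
#' @param kept_sets named list of per-population site data.frames (each with
#'   `chrom`, `pos`, `ref`, `alt`).
#' @return data.frame with one row per unique site: `chrom`, `pos`, `ref`,
#'   `alt`, `n_alleles` (max observed), `populations`
#'   (comma-separated labels), `n_populations`, `specific` (logical), sorted
#'   by chromosome then position.
#' @export
pool_unique <- function(kept_sets) {
  stopifnot(is.list(kept_sets), length(kept_sets) >= 1)
  if (is.null(names(kept_sets)) || any(names(kept_sets) == ""))
    stop("kept_sets must be a named list (population labels)", call. = FALSE)
  all <- do.call(rbind, lapply(names(kept_sets), function(p) {
    x <- kept_sets[[p]]
    if (nrow(x) == 0) return(NULL)
    data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
               n_alleles = if (is.null(x$n_alleles)) 2L else x$n_alleles,
               population = p, stringsAsFactors = FALSE)
  }))
  if (is.null(all)) stop("all input sets are empty", call. = FALSE)
  coord <- paste(all$chrom, all$pos)
  ref_by_coord <- tapply(all$ref, coord, function(r) length(unique(r)))
  if (any(ref_by_coord > 1)) {
    bad <- names(ref_by_coord)[ref_by_coord > 1][1]
    stop("reference allele mismatch between populations at ", bad,
         call. = FALSE)
  }
  key <- paste(all$chrom, all$pos, all$ref, all$alt)
  first <- !duplicated(key)
  pooled <- all[first, c("chrom", "pos", "ref", "alt", "n_alleles")]
  pops <- tapply(all$population, key, function(p)
    paste(sort(unique(p)), collapse = ","))
  nall <- tapply(all$n_alleles, key, max)
  pooled$n_alleles <- as.integer(nall[key[first]])
  pooled$populations <- as.character(pops[key[first]])
  pooled$n_populations <- lengths(strsplit(pooled$populations, ","))
  pooled$specific <- pooled$n_populations == 1L
  pooled <- pooled[order(pooled$chrom, pooled$pos, pooled$alt), ]
  rownames(pooled) <- NULL
  pooled
}
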
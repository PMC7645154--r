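## Post-genotyping evaluation: QC, conversion classes, polymorphism
## accounting, feature density, spacing scans, concordance.

#' Per-marker quality control
#'
#' Call rate is called samples over total samples; MAF is computed over
#' called alleles. A marker is kept iff call rate is strictly greater than
#' `min_call_rate` and MAF strictly greater than `min_maf`.
#'
#' @param gm a `genotype_matrix`.
#' @param config an [eval_config()].
#' @return list with `summary` (per-marker data.frame: genotype counts,
#'   `call_rate`, `maf`, `polymorphic`, `kept`, `conversion_class`) and the
#'   `kept` / `failed` marker index partition.
#' @export
marker_qc <- function(gm, config = eval_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- ncol(gm$geno)
  if (ns == 0) stop("genotype matrix has zero samples", call. = FALSE)
  g <- gm$geno
  n_missing <- rowSums(is.na(g))
  n_called <- ns - n_missing
  n_hom_ref <- rowSums(g == 0L, na.rm = TRUE)
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_hom_alt <- rowSums(g == 2L, na.rm = TRUE)
  call_rate <- n_called / ns
  alt <- n_het + 2L * n_hom_alt
  called_alleles <- 2L * n_called
  maf <- ifelse(called_alleles > 0,
                pmin(alt, called_alleles - alt) / called_alleles, 0)
  summary <- data.frame(
    marker_id = marker_id(gm$markers),
    chrom = gm$markers$chrom, pos = gm$markers$pos,
    n_hom_ref = n_hom_ref, n_het = n_het, n_hom_alt = n_hom_alt,
    n_missing = as.integer(n_missing), call_rate = call_rate, maf = maf,
    polymorphic = (n_hom_ref > 0) + (n_het > 0) + (n_hom_alt > 0) >= 2,
    stringsAsFactors = FALSE)
  summary$kept <- call_rate > config$min_call_rate & maf > config$min_maf
  summary$conversion_class <- conversion_classify(summary, config)
  list(summary = summary, kept = which(summary$kept),
       failed = which(!summary$kept))
}

#' Conversion-type classification
#'
#' A simplified, deterministic stand-in for vendor cluster-geometry classes,
#' computed from genotype counts and call rate: call rate below
#' `class_call_rate` gives `OffRecommended`; all called samples in a single
#' homozygote class gives `MonoHighResolution`; heterozygotes present but no
#' minor homozygote gives `NoMinorHom`; all three genotype classes present
#' gives `PolyHighResolution`; anything else is `Other`. The five labels
#' partition the marker set.
#'
#' @param summary per-marker summary (from [marker_qc()], or any data.frame
#'   with `n_hom_ref`, `n_het`, `n_hom_alt`, `call_rate`).
#' @param config an [eval_config()].
#' @return character vector of class labels.
#' @export
conversion_classify <- function(summary, config = eval_config()) {
  n_classes <- (summary$n_hom_ref > 0) + (summary$n_het > 0) +
    (summary$n_hom_alt > 0)
  hom_classes <- (summary$n_hom_ref > 0) + (summary$n_hom_alt > 0)
  out <- rep("Other", nrow(summary))
  out[summary$call_rate < config$class_call_rate] <- "OffRecommended"
  ok <- summary$call_rate >= config$class_call_rate
  out[ok & hom_classes <= 1 & summary$n_het == 0] <- "MonoHighResolution"
  out[ok & hom_classes == 1 & summary$n_het > 0] <- "NoMinorHom"
  out[ok & n_classes == 3] <- "PolyHighResolution"
  out
}

#' Polymorphism accounting by group
#'
#' A marker is polymorphic within a group iff at least two genotype classes
#' are observed among that group's called samples; group-specific iff
#' polymorphic in exactly one group; overall polymorphic iff polymorphic in
#' at least one. Working SNPs per group are markers with within-group call
#' rate above `min_call_rate`.
#'
#' @param gm a `genotype_matrix` with group labels in `samples$group`.
#' @param config an [eval_config()].
#' @return list with `by_group` (data.frame: `group`, `n_samples`,
#'   `n_polymorphic`, `polymorphic_rate`, `n_working`, `working_rate`,
#'   `n_specific`), `overall` (list: `n_markers`, `n_polymorphic`,
#'   `polymorphic_rate`) and `polymorphic` (marker x group logical matrix).
#' @export
polymorphic_accounting <- function(gm, config = eval_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  groups <- unique(gm$samples$group)
  nm <- nrow(gm$geno)
  poly <- matrix(FALSE, nrow = nm, ncol = length(groups),
                 dimnames = list(rownames(gm$geno), groups))
  working <- poly
  for (k in seq_along(groups)) {
    cols <- gm$samples$group == groups[k]
    if (!any(cols)) stop("group with zero samples: ", groups[k],
                         call. = FALSE)
    g <- gm$geno[, cols, drop = FALSE]
    n_classes <- (rowSums(g == 0L, na.rm = TRUE) > 0) +
      (rowSums(g == 1L, na.rm = TRUE) > 0) +
      (rowSums(g == 2L, na.rm = TRUE) > 0)
    poly[, k] <- n_classes >= 2
    working[, k] <- rowMeans(!is.na(g)) > config$min_call_rate
  }
  n_groups_poly <- rowSums(poly)
  by_group <- data.frame(
    group = groups,
    n_samples = as.integer(table(gm$samples$group)[groups]),
    n_polymorphic = colSums(poly),
    polymorphic_rate = colSums(poly) / nm,
    n_working = colSums(working),
    working_rate = colSums(working) / nm,
    n_specific = vapply(seq_along(groups), function(k)
      sum(poly[, k] & n_groups_poly == 1L), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(by_group) <- NULL
  list(by_group = by_group,
       overall = list(n_markers = nm,
                      n_polymorphic = sum(n_groups_poly >= 1),
                      polymorphic_rate = mean(n_groups_poly >= 1)),
       polymorphic = poly)
}

#' Marker density by genomic feature class
#'
#' Assigns each marker to exactly one annotation class (exon / intron /
#' intergenic; the classes partition the genome) and reports count, percent
#' of classified markers, class length and markers per kb.
#'
#' @param markers data.frame with `chrom`, `pos` (a panel or kept-marker
#'   table).
#' @param annotation GRanges from [derive_annotation()].
#' @return data.frame with rows per class plus an `All` row: `category`,
#'   `n`, `percent`, `length_mb`, `density_per_kb`.
#' @export
feature_density <- function(markers, annotation) {
  stopifnot(is.data.frame(markers))
  gr <- GenomicRanges::GRanges(markers$chrom,
                               IRanges::IRanges(markers$pos, markers$pos))
  hits <- GenomicRanges::findOverlaps(gr, annotation)
  if (length(hits) < length(gr))
    stop("marker outside all annotation classes; annotation must ",
         "partition the genome", call. = FALSE)
  cls <- annotation$class[S4Vectors::subjectHits(hits)][
    match(seq_along(gr), S4Vectors::queryHits(hits))]
  class_levels <- c("exon", "intron", "intergenic")
  n <- vapply(class_levels, function(k) sum(cls == k), numeric(1))
  len <- vapply(class_levels, function(k)
    sum(GenomicRanges::width(annotation[annotation$class == k])),
    numeric(1))
  feature_density_from_counts(c(class_levels, "All"),
                              c(n, sum(n)), c(len, sum(len)) / 1e6)
}

#' Density table from per-class counts and lengths
#'
#' The arithmetic behind the feature-density report: percent of total count
#' and markers per kb for each category.
#'
#' @param category category labels.
#' @param n marker counts per category.
#' @param length_mb category lengths in megabases.
#' @return data.frame with `category`, `n`, `percent`, `length_mb`,
#'   `density_per_kb`.
#' @export
feature_density_from_counts <- function(category, n, length_mb) {
  total <- if ("All" %in% category) n[category == "All"][1] else sum(n)
  data.frame(category = category, n = n,
             percent = 100 * n / total,
             length_mb = length_mb,
             density_per_kb = n / (length_mb * 1000),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Marker spacing and genome-bin density scan
#'
#' Adjacent-marker spacing per chromosome and genome-wide, a census of gaps
#' above `max_gap`, and marker counts per `density_bin`-sized genome bin
#' with the fractions of low-density and empty bins.
#'
#' @param panel sorted marker table (`chrom`, `pos`).
#' @param genome DNAStringSet or [genome_index()].
#' @param config an [eval_config()].
#' @param max_gap gap threshold in bases for the gap census (default 2000).
#' @return list with `per_chrom` (data.frame: `chrom`, `n`, `mean_spacing`,
#'   `median_spacing`, `n_gaps_over`), `overall` (list: `n`, `mean_spacing`,
#'   `median_spacing`, `n_gaps_over`), and `bins` (data.frame: `chrom`,
#'   `bin_start`, `bin_end`, `n`) plus `frac_bins_low` / `frac_bins_empty`.
#' @export
spacing_scan <- function(panel, genome, config = eval_config(),
                         max_gap = 2000) {
  stopifnot(is.data.frame(panel))
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  index <- genome_index(genome)
  panel <- panel[order(panel$chrom, panel$pos), ]
  spac <- lapply(split(panel$pos, panel$chrom), function(p) diff(sort(p)))
  per_chrom <- data.frame(
    chrom = names(spac),
    n = as.integer(table(panel$chrom)[names(spac)]),
    mean_spacing = vapply(spac, function(d)
      if (length(d)) mean(d) else NA_real_, numeric(1)),
    median_spacing = vapply(spac, function(d)
      if (length(d)) median(d) else NA_real_, numeric(1)),
    n_gaps_over = vapply(spac, function(d) sum(d > max_gap), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  all_d <- unlist(spac, use.names = FALSE)
  bins <- do.call(rbind, lapply(seq_len(nrow(index)), function(i) {
    starts <- seq(0L, index$length[i] - 1L, by = config$density_bin)
    ends <- pmin(starts + config$density_bin, index$length[i])
    p <- panel$pos[panel$chrom == index$chrom[i]]
    cnt <- vapply(seq_along(starts), function(k)
      sum(p > starts[k] & p <= ends[k]), numeric(1))
    data.frame(chrom = index$chrom[i], bin_start = starts, bin_end = ends,
               n = as.integer(cnt), stringsAsFactors = FALSE)
  }))
  list(per_chrom = per_chrom,
       overall = list(n = nrow(panel),
                      mean_spacing = if (length(all_d)) mean(all_d) else
                        NA_real_,
                      median_spacing = if (length(all_d)) median(all_d) else
                        NA_real_,
                      n_gaps_over = sum(all_d > max_gap)),
       bins = bins,
       frac_bins_low = mean(bins$n < config$low_density_threshold),
       frac_bins_empty = mean(bins$n == 0))
}

#' Concordance between sequencing-derived and array genotypes
#'
#' Compares two genotype matrices over their shared marker x sample grid.
#' The missing-in-array rate divides genotypes called by sequencing but
#' missing on the array by the sequencing-called count. The recovered rate
#' (genotypes missing in sequencing but called by the array) is reported
#' under three normalisations since the natural denominator is debatable:
#' the whole shared grid (`recovered_rate`), the sequencing-missing count
#' (`recovered_rate_of_missing`) and the array-called count
#' (`recovered_rate_of_array_called`). Discordance is the mismatch fraction
#' among co-called genotypes. Every rate is reported with its denominator.
#'
#' @param wgs_gm,array_gm `genotype_matrix` objects.
#' @return list of named lists, each with `n` (numerator), `den`
#'   (denominator) and `rate`.
#' @export
concordance <- function(wgs_gm, array_gm) {
  stopifnot(inherits(wgs_gm, "genotype_matrix"),
            inherits(array_gm, "genotype_matrix"))
  mk <- intersect(rownames(wgs_gm$geno), rownames(array_gm$geno))
  sp <- intersect(colnames(wgs_gm$geno), colnames(array_gm$geno))
  if (length(mk) == 0 || length(sp) == 0)
    stop("no shared markers/samples between the two matrices",
         call. = FALSE)
  w <- wgs_gm$geno[mk, sp, drop = FALSE]
  a <- array_gm$geno[mk, sp, drop = FALSE]
  grid <- length(w)
  w_called <- !is.na(w)
  a_called <- !is.na(a)
  miss_in_array <- sum(w_called & !a_called)
  recovered <- sum(!w_called & a_called)
  co_called <- w_called & a_called
  discord <- sum(w[co_called] != a[co_called])
  rate <- function(n, den) list(n = n, den = den,
                                rate = if (den > 0) n / den else NA_real_)
  list(grid = rate(grid, grid),
       missing_in_array = rate(miss_in_array, sum(w_called)),
       recovered = rate(recovered, grid),
       recovered_of_missing = rate(recovered, sum(!w_called)),
       recovered_of_array_called = rate(recovered, sum(a_called)),
       discordance = rate(discord, sum(co_called)))
}
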
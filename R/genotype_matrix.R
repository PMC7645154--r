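#' Genotype matrix
#'
#' Markers-by-samples diploid genotype calls coded as minor/alt allele dosage:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing. Marker metadata (`chrom`, `pos`, `ref`, `alt`) and sample
#' metadata (`sample`, `group`) ride along.
#'
#' @param geno integer matrix, markers in rows, samples in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param markers data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per row of `geno`).
#' @param samples data.frame with columns `sample` and `group` (population or
#'   species label; one row per column of `geno`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, markers, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(markers), is.data.frame(samples),
            all(c("chrom", "pos") %in% names(markers)),
            "sample" %in% names(samples))
  if (nrow(markers) != nrow(geno))
    stop("marker table and genotype matrix disagree on marker count",
         call. = FALSE)
  if (nrow(samples) != ncol(geno))
    stop("sample table and genotype matrix disagree on sample count",
         call. = FALSE)
  if (!all(geno %in% c(0L, 1L, 2L, NA_integer_)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(samples$group)) samples$group <- "all"
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  rownames(geno) <- marker_id(markers)
  colnames(geno) <- samples$sample
  structure(list(geno = geno,
                 markers = as.data.frame(markers, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' Marker identifiers
#'
#' Canonical marker id `<chrom>_<pos>` used across files and matrices.
#'
#' @param x a data.frame with `chrom` and `pos` columns.
#' @return character vector of ids.
#' @export
marker_id <- function(x) paste(x$chrom, x$pos, sep = "_")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples (%d groups)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$samples$group))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param markers,samples logical, integer or character indices into markers
#'   and samples; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, markers = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  mi <- if (is.null(markers)) seq_len(nrow(x$geno)) else markers
  si <- if (is.null(samples)) seq_len(ncol(x$geno)) else samples
  if (is.character(mi)) mi <- match(mi, rownames(x$geno))
  if (is.character(si)) si <- match(si, colnames(x$geno))
  genotype_matrix(x$geno[mi, si, drop = FALSE],
                  x$markers[if (is.logical(mi)) which(mi) else mi, ,
                            drop = FALSE],
                  x$samples[if (is.logical(si)) which(si) else si, ,
                            drop = FALSE])
}

#' Per-site summary statistics for one population
#'
#' Computes, for each marker of a genotype matrix restricted to one group,
#' the minor allele frequency over called alleles, minor allele count,
#' missing genotype count and observed allele number.
#'
#' @param gm a `genotype_matrix`.
#' @param population group label; `NULL` uses all samples.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `population`, `maf`, `mac`, `n_missing`, `n_called`, `n_alleles`.
#' @export
site_stats <- function(gm, population = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(population)) {
    keep <- gm$samples$group == population
    if (!any(keep))
      stop("population label not present in samples: ", population,
           call. = FALSE)
    gm <- subset_genotypes(gm, samples = keep)
  } else {
    population <- "all"
  }
  g <- gm$geno
  n_missing <- rowSums(is.na(g))
  n_called <- ncol(g) - n_missing
  alt_count <- rowSums(g, na.rm = TRUE)
  called_alleles <- 2L * n_called
  ref_count <- called_alleles - alt_count
  mac <- pmin(alt_count, ref_count)
  maf <- ifelse(called_alleles > 0, mac / called_alleles, NA_real_)
  # observed allele number: ref and/or alt seen among called genotypes
  n_alleles <- (ref_count > 0) + (alt_count > 0)
  out <- gm$markers[, intersect(c("chrom", "pos", "ref", "alt"),
                                names(gm$markers)), drop = FALSE]
  out$population <- population
  out$maf <- maf
  out$mac <- as.integer(mac)
  out$n_missing <- as.integer(n_missing)
  out$n_called <- as.integer(n_called)
  out$n_alleles <- as.integer(n_alleles)
  rownames(out) <- NULL
  out
}
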
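## Seeded simulator of multi-population SNP call sets and array runs.
## Sites are diploid, autosomal and unlinked; population divergence is
## modelled by drawing per-population allele frequencies independently;
## missingness is missing-completely-at-random.

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate multi-population SNP call sets with a truth table
#'
#' Places SNP sites on a simulated genome at the requested density
#' (Poisson per chromosome), flags a `shared_fraction` of them as segregating
#' in every population (the rest segregate in exactly one), draws a true
#' alternate-allele frequency per segregating site and population from the
#' MAF spectrum, and samples per-individual genotypes, missingness and
#' genotyping errors.
#'
#' @param genome a DNAStringSet from [simulate_genome()].
#' @param spec the [sim_spec()] used to build the genome.
#' @return a list with elements
#'   \describe{
#'     \item{truth}{data.frame with `chrom`, `pos`, `ref`, `alt`, `shared`
#'       and one `freq_<population>` column per population (true alternate
#'       allele frequency; 0 where the site does not segregate).}
#'     \item{populations}{named list; per population a `genotype_matrix` of
#'       its segregating sites.}
#'   }
#' @export
simulate_populations <- function(genome, spec) {
  stopifnot(inherits(spec, "sim_spec"), inherits(genome, "DNAStringSet"))
  index <- genome_index(genome)
  set.seed(spec$seed + 1L)

  pops <- paste0("pop", seq_len(spec$n_populations))
  sites <- do.call(rbind, lapply(seq_len(nrow(index)), function(i) {
    len <- index$length[i]
    n <- rpois(1, spec$snp_density * len / 1000)
    if (n > len)
      stop("requested SNP density exceeds available positions on ",
           index$chrom[i], call. = FALSE)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n))
    data.frame(chrom = index$chrom[i], pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(sites) || nrow(sites) == 0)
    stop("no SNP sites simulated; increase snp_density or genome length",
         call. = FALSE)
  seqs <- as.character(genome)
  sites$ref <- vapply(seq_len(nrow(sites)), function(k)
    substr(seqs[[sites$chrom[k]]], sites$pos[k], sites$pos[k]), character(1))
  sites$alt <- vapply(sites$ref, function(r)
    sample(OTHER_BASES[[r]], 1), character(1), USE.NAMES = FALSE)

  n <- nrow(sites)
  sites$shared <- runif(n) < spec$shared_fraction
  home_pop <- sample.int(spec$n_populations, n, replace = TRUE)
  freq <- matrix(0, nrow = n, ncol = spec$n_populations,
                 dimnames = list(NULL, pops))
  for (j in seq_len(spec$n_populations)) {
    present <- sites$shared | home_pop == j
    freq[present, j] <- runif(sum(present), spec$maf_min, spec$maf_max)
  }
  truth <- cbind(sites, as.data.frame(freq))
  names(truth)[match(pops, names(truth))] <- paste0("freq_", pops)
  class(truth) <- c("snp_truth", "data.frame")

  populations <- setNames(lapply(seq_along(pops), function(j) {
    present <- which(freq[, j] > 0)
    samples <- data.frame(
      sample = sprintf("%s_s%02d", pops[j], seq_len(spec$samples_per_population)),
      group = pops[j], stringsAsFactors = FALSE)
    markers <- sites[present, c("chrom", "pos", "ref", "alt")]
    true_g <- draw_genotypes(freq[present, j], nrow(samples))
    g <- apply_call_errors(true_g, spec$missing_rate, spec$genotype_error_rate)
    gm <- genotype_matrix(g, markers, samples)
    attr(gm, "true_genotypes") <- genotype_matrix(true_g, markers, samples)
    gm
  }), pops)

  list(truth = truth, populations = populations)
}

## genotypes as alt-dosage draws: one binomial(2, p) per site x sample
draw_genotypes <- function(p, n_samples) {
  matrix(rbinom(length(p) * n_samples, 2, rep(p, n_samples)),
         nrow = length(p), ncol = n_samples)
}

apply_call_errors <- function(g, missing_rate, error_rate) {
  if (error_rate > 0) {
    err <- runif(length(g)) < error_rate
    if (any(err)) {
      # replace with one of the two other genotype classes, uniformly
      shift <- sample(1:2, sum(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) g[runif(length(g)) < missing_rate] <- NA_integer_
  g
}

#' Draw true genotypes for a marker panel
#'
#' For each sample, genotypes are drawn from the true allele frequency of the
#' sample's population in the truth table; markers absent from the truth
#' table (or not segregating in that population) are homozygous reference.
#'
#' @param markers data.frame with `chrom`, `pos` (and ideally `ref`, `alt`).
#' @param samples data.frame with `sample` and `group` columns; `group` must
#'   match the truth table's `freq_<group>` columns.
#' @param truth truth table from [simulate_populations()].
#' @param seed integer seed.
#' @return a `genotype_matrix` without missing calls.
#' @export
simulate_true_genotypes <- function(markers, samples, truth, seed = 1L) {
  if (nrow(samples) == 0) stop("empty sample list", call. = FALSE)
  if (nrow(markers) == 0) stop("empty marker panel", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- match(marker_id(markers), marker_id(truth))
  g <- matrix(0L, nrow = nrow(markers), ncol = nrow(samples))
  for (grp in unique(samples$group)) {
    col <- paste0("freq_", grp)
    p <- if (col %in% names(truth)) truth[[col]][idx] else rep(0, nrow(markers))
    p[is.na(p)] <- 0
    cols <- which(samples$group == grp)
    g[, cols] <- draw_genotypes(p, length(cols))
  }
  if (!all(c("ref", "alt") %in% names(markers))) {
    markers$ref <- truth$ref[idx]
    markers$alt <- truth$alt[idx]
  }
  genotype_matrix(g, markers, samples)
}

#' Simulate an array genotyping run
#'
#' Applies a per-call genotyping-error model and missing-completely-at-random
#' dropout to true genotypes, emulating a physical array run over a marker
#' panel. True genotypes are attached as attribute `true_genotypes` so
#' concordance against the truth remains computable.
#'
#' @param panel a panel data.frame (`chrom`, `pos`, ...) or a
#'   `genotype_matrix` of true genotypes.
#' @param samples data.frame with `sample`, `group`; required when `panel` is
#'   a marker table.
#' @param truth truth table from [simulate_populations()]; required when
#'   `panel` is a marker table.
#' @param missing_rate per-call missing probability.
#' @param genotype_error_rate per-call probability of a wrong genotype class.
#' @param seed integer seed.
#' @return a `genotype_matrix` with attribute `true_genotypes`.
#' @export
simulate_array_run <- function(panel, samples = NULL, truth = NULL,
                               missing_rate = 0, genotype_error_rate = 0,
                               seed = 1L) {
  if (inherits(panel, "genotype_matrix")) {
    true_gm <- panel
  } else {
    if (is.null(samples) || is.null(truth))
      stop("samples and truth are required when panel is a marker table",
           call. = FALSE)
    true_gm <- simulate_true_genotypes(panel, samples, truth, seed = seed)
  }
  if (nrow(true_gm$samples) == 0) stop("empty sample list", call. = FALSE)
  if (nrow(true_gm$markers) == 0) stop("empty marker panel", call. = FALSE)
  set.seed(as.integer(seed) + 2L)
  g <- apply_call_errors(true_gm$geno, missing_rate, genotype_error_rate)
  gm <- genotype_matrix(g, true_gm$markers, true_gm$samples)
  attr(gm, "true_genotypes") <- true_gm
  gm
}

#' Write / read a simulation truth table
#'
#' Plain TSV round trip for the truth table emitted by
#' [simulate_populations()].
#'
#' @param truth truth table.
#' @param path file path.
#' @return the path (write) or the truth table (read).
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  truth <- read.delim(path, stringsAsFactors = FALSE)
  truth$shared <- as.logical(truth$shared)
  class(truth) <- c("snp_truth", "data.frame")
  truth
}
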
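#' Bundled reference tables
#'
#' Two small published summary tables from the large yellow croaker
#' (*Larimichthys crocea*) 600K array design study ship with the package as
#' worked examples: the per-population resequencing / SNP-calling summary
#' (individuals, raw bases, depth, population-specific and total SNP counts
#' for the six populations plus their Total row) and the genome
#' feature-density table (SNP count, percent, class length and SNPs per kb
#' for exon / intron / intergenic classes).
#'
#' @param which `"resequencing"` or `"feature_density"`.
#' @return a data.frame.
#' @export
reference_table <- function(which = c("resequencing", "feature_density")) {
  which <- match.arg(which)
  file <- switch(which,
                 resequencing = "resequencing_summary.tsv",
                 feature_density = "feature_density_reference.tsv")
  path <- system.file("extdata", file, package = "snpanel")
  read.delim(path, stringsAsFactors = FALSE)
}
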
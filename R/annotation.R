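#' Read gene annotation intervals
#'
#' Loads gene and exon intervals from BED (0-based half-open) or GFF3
#' (1-based inclusive) and normalises them to 1-based inclusive coordinates.
#' For BED input the feature class is taken from the name column
#' (`gene`/`exon`); for GFF3 from the `type` column.
#'
#' @param path BED or GFF3 file; format inferred from the extension.
#' @return a [GenomicRanges::GRanges] with a `type` metadata column holding
#'   `gene` and `exon` intervals.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")  # converts to 1-based
    type <- gr$name
  } else {
    stop("unsupported annotation format: ", ext, call. = FALSE)
  }
  keep <- type %in% c("gene", "exon")
  gr <- gr[keep]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = type[keep])
  gr
}

#' Partition the genome into exon / intron / intergenic intervals
#'
#' Introns are gene bases not covered by an exon; intergenic is everything
#' outside genes. Exons are clipped to gene bodies. The three classes
#' partition the genome exactly: their total lengths sum to the genome
#' length.
#'
#' @param genes a GRanges with a `type` column (`gene`, `exon`), e.g. from
#'   [read_annotation()], or a data.frame with `chrom`, `start`, `end`,
#'   `type` (1-based inclusive).
#' @param genome a DNAStringSet or [genome_index()].
#' @return a GRanges with metadata column `class` in
#'   \{`exon`, `intron`, `intergenic`\}.
#' @export
derive_annotation <- function(genes, genome) {
  index <- genome_index(if (inherits(genome, "DNAStringSet"))
    genome else genome)
  if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end),
      type = genes$type)
  }
  seqlens <- setNames(index$length, index$chrom)
  if (!all(as.character(GenomicRanges::seqnames(genes)) %in% index$chrom))
    stop("annotation interval on unknown chromosome", call. = FALSE)
  if (any(GenomicRanges::end(genes) >
          seqlens[as.character(GenomicRanges::seqnames(genes))]) ||
      any(GenomicRanges::start(genes) < 1))
    stop("annotation interval exceeds chromosome bounds", call. = FALSE)
  genes <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes)),
    IRanges::ranges(genes), type = genes$type)  # drop strand
  GenomeInfoDb::seqlevels(genes) <- index$chrom
  GenomeInfoDb::seqlengths(genes) <- seqlens

  whole <- GenomicRanges::GRanges(index$chrom,
                                  IRanges::IRanges(1, index$length),
                                  seqlengths = seqlens)
  gene_iv <- GenomicRanges::reduce(genes[genes$type == "gene"])
  exon_iv <- GenomicRanges::reduce(
    GenomicRanges::intersect(genes[genes$type == "exon"], gene_iv))
  intron_iv <- GenomicRanges::setdiff(gene_iv, exon_iv)
  intergenic_iv <- GenomicRanges::setdiff(whole, gene_iv)
  out <- c(exon_iv, intron_iv, intergenic_iv)
  out$class <- rep(c("exon", "intron", "intergenic"),
                   c(length(exon_iv), length(intron_iv),
                     length(intergenic_iv)))
  total <- sum(GenomicRanges::width(out))
  if (total != sum(index$length))
    stop("annotation classes do not partition the genome", call. = FALSE)
  sort(out)
}

#' Write an annotation partition as GFF3
#'
#' @param annotation GRanges from [derive_annotation()] (or gene/exon GRanges
#'   with a `type` column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gff3")
  invisible(path)
}
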
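#' Genome index
#'
#' The coordinate frame used by binning and gap analysis: ordered chromosome
#' names with lengths.
#'
#' @param x a named numeric vector of chromosome lengths, a data.frame with
#'   columns `chrom` and `length`, or a [Biostrings::DNAStringSet].
#' @return a data.frame of class `genome_index` with columns `chrom`
#'   (character) and `length` (integer).
#' @export
genome_index <- function(x) {
  if (inherits(x, "genome_index")) return(x)
  if (inherits(x, "DNAStringSet")) {
    idx <- data.frame(chrom = names(x), length = Biostrings::width(x),
                      stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "length") %in% names(x)))
    idx <- data.frame(chrom = as.character(x$chrom),
                      length = as.integer(x$length),
                      stringsAsFactors = FALSE)
  } else if (is.numeric(x) && !is.null(names(x))) {
    idx <- data.frame(chrom = names(x), length = as.integer(x),
                      stringsAsFactors = FALSE)
  } else {
    stop("cannot build a genome_index from this object", call. = FALSE)
  }
  if (anyDuplicated(idx$chrom))
    stop("duplicate chromosome names in genome index", call. = FALSE)
  if (any(idx$length <= 0))
    stop("chromosome lengths must be > 0", call. = FALSE)
  class(idx) <- c("genome_index", "data.frame")
  idx
}

chrom_length <- function(index, chrom) {
  len <- index$length[match(chrom, index$chrom)]
  if (anyNA(len))
    stop("chromosome(s) absent from genome index: ",
         paste(unique(chrom[is.na(len)]), collapse = ", "), call. = FALSE)
  len
}

#' Simulate a random genome
#'
#' Draws `n_chromosomes` i.i.d. sequences over \{A,C,G,T\} with the requested
#' GC fraction. Deterministic under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return a [Biostrings::DNAStringSet] named `chr1`, `chr2`, ... with the
#'   genome index attached as attribute `index`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$genome_length_per_chrom <= 0)
    stop("genome length must be positive", call. = FALSE)
  set.seed(spec$seed)
  gc <- spec$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(spec$n_chromosomes), function(i) {
    paste(sample(names(p), spec$genome_length_per_chrom, replace = TRUE,
                 prob = p), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(spec$n_chromosomes))
  attr(genome, "index") <- genome_index(genome)
  genome
}

#' Write / read a genome FASTA
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()].
#'
#' @param genome a DNAStringSet.
#' @param path output file.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a DNAStringSet.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  # drop any FASTA description after the first whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  attr(genome, "index") <- genome_index(genome)
  genome
}
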
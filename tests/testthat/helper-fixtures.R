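# Shared fixture builders; everything is generated in code.

tiny_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- if (!is.null(names(seqs))) names(seqs) else
    paste0("chr", seq_along(seqs))
  attr(g, "index") <- genome_index(g)
  g
}

# repeatable pseudo-random sequence of given length and GC fraction
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_sites <- function(chrom, pos, ref = "A", alt = "G", ...) {
  if (length(pos) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             ..., stringsAsFactors = FALSE)
}

# write a VCF text fixture; body rows are tab-separated strings
write_vcf_fixture <- function(body, samples = character(0),
                              path = tempfile(fileext = ".vcf")) {
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", if (length(samples)) c("FORMAT", samples)),
                  collapse = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               header, body), path)
  path
}

# genotype matrix straight from a dosage matrix
gm_from <- function(g, groups = rep("all", ncol(g)), chrom = "chr1",
                    pos = NULL) {
  g <- as.matrix(g)
  if (is.null(pos)) pos <- seq_len(nrow(g)) * 100L
  nm <- if (!is.null(colnames(g))) colnames(g) else
    sprintf("s%d", seq_len(ncol(g)))
  genotype_matrix(g,
                  make_sites(chrom, pos),
                  data.frame(sample = nm, group = groups,
                             stringsAsFactors = FALSE))
}
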
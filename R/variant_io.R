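#' Read a VCF into SNP sites and a genotype matrix
#'
#' Loads a VCF v4.x file (biallelic and multiallelic records alike),
#' computes per-site statistics for one population from the GT fields, and
#' returns both a site table and the genotype matrix. Coordinates stay
#' 1-based. Genotypes are coded as non-reference allele dosage; records
#' without a GT field load with all calls missing. Site quality (QUAL) and,
#' when present in INFO, mapping quality (MQ) and depth (DP) are carried
#' through so that quality filters can apply.
#'
#' @param path VCF file (optionally gzipped).
#' @param population_label group label attached to the samples and to the
#'   per-site statistics.
#' @return list with elements `sites` (data.frame: `chrom`, `pos`, `ref`,
#'   `alt`, `is_snp`, `n_alleles`, `population`, `maf`, `mac`, `n_missing`,
#'   `n_called`, plus `site_quality`, `mapping_quality`, `coverage` when
#'   available) and `genotypes` (a [genotype_matrix()]).
#' @export
read_vcf <- function(path, population_label = "all") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  if (n == 0) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        is_snp = logical(), n_alleles = integer(),
                        population = character(), maf = numeric(),
                        mac = integer(), n_missing = integer(),
                        n_called = integer(), stringsAsFactors = FALSE)
    return(list(sites = empty, genotypes = NULL))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1], call. = FALSE)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  alts <- strsplit(alt, ",", fixed = TRUE)
  n_alleles <- 1L + lengths(alts)
  is_snp <- nchar(ref) == 1L &
    vapply(alts, function(a) length(a) > 0 && all(nchar(a) == 1L), logical(1))

  ## genotype calls
  has_gt <- nrow(vcf@gt) > 0 && "FORMAT" %in% colnames(vcf@gt)
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(gt)
    alleles <- gt_to_alleles(gt)      # n x (2*samples) allele index matrix
    dosage <- allele_dosage(alleles, ncol(gt))
  } else {
    samples <- character(0)
    alleles <- matrix(NA_integer_, nrow = n, ncol = 0)
    dosage <- matrix(NA_integer_, nrow = n, ncol = 0)
  }

  n_missing <- if (ncol(dosage) > 0) rowSums(is.na(dosage)) else
    rep(0L, n)
  n_called <- ncol(dosage) - n_missing
  stats <- site_stats_from_alleles(alleles)

  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos, ref = ref,
                      alt = alt, is_snp = is_snp, n_alleles = n_alleles,
                      population = population_label,
                      maf = stats$maf, mac = stats$mac,
                      n_missing = as.integer(n_missing),
                      n_called = as.integer(n_called),
                      stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  if (any(!is.na(qual))) sites$site_quality <- qual
  info <- fix[, "INFO"]
  mq <- info_field(info, "MQ")
  if (any(!is.na(mq))) sites$mapping_quality <- mq
  dp <- info_field(info, "DP")
  if (any(!is.na(dp))) sites$coverage <- dp

  gm <- NULL
  if (length(samples) > 0) {
    gm <- genotype_matrix(
      dosage,
      data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
                 stringsAsFactors = FALSE),
      data.frame(sample = samples, group = population_label,
                 stringsAsFactors = FALSE))
  }
  list(sites = sites, genotypes = gm)
}

## split GT strings into an integer allele-index matrix (n x 2*samples);
## missing alleles are NA; phased separators accepted
gt_to_alleles <- function(gt) {
  n <- nrow(gt)
  ns <- ncol(gt)
  out <- matrix(NA_integer_, nrow = n, ncol = 2L * ns)
  for (j in seq_len(ns)) {
    parts <- strsplit(gt[, j], "[/|]")
    a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".",
                 character(1))
    a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".",
                 character(1))
    out[, 2L * j - 1L] <- suppressWarnings(as.integer(a1))
    out[, 2L * j] <- suppressWarnings(as.integer(a2))
  }
  out
}

## dosage of non-reference alleles per sample; NA if either allele missing
allele_dosage <- function(alleles, ns) {
  n <- nrow(alleles)
  out <- matrix(NA_integer_, nrow = n, ncol = ns)
  for (j in seq_len(ns)) {
    a1 <- alleles[, 2L * j - 1L]
    a2 <- alleles[, 2L * j]
    out[, j] <- ifelse(is.na(a1) | is.na(a2), NA_integer_,
                       (a1 > 0L) + (a2 > 0L))
  }
  out
}

## MAF = frequency of the second most frequent allele among called alleles
site_stats_from_alleles <- function(alleles) {
  n <- nrow(alleles)
  maf <- rep(NA_real_, n)
  mac <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    a <- alleles[i, ]
    a <- a[!is.na(a)]
    if (length(a) == 0) { mac[i] <- 0L; maf[i] <- NA_real_; next }
    counts <- sort(tabulate(a + 1L), decreasing = TRUE)
    minor <- if (length(counts) >= 2) counts[2] else 0L
    mac[i] <- as.integer(minor)
    maf[i] <- minor / length(a)
  }
  list(maf = maf, mac = mac)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  out <- rep(NA_real_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "",
                                              m)))
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits CHROM/POS/ID/REF/ALT and one GT column per sample. Written plain
#' text unless `path` ends in `.gz`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param index optional [genome_index()] used to emit contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, index = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- gm$markers
  meta <- c("##fileformat=VCFv4.2",
            if (!is.null(index))
              sprintf("##contig=<ID=%s,length=%d>", index$chrom, index$length),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gm$samples$sample), collapse = "\t")
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$geno), ncol = ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[gm$geno[ok] + 1L]
  body <- paste(m$chrom, m$pos, marker_id(m), m$ref, m$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, header, body), con)
  invisible(path)
}

#' Write / read a genotype matrix as a TSV table
#'
#' Wide layout: marker metadata columns then one column per sample holding
#' the dosage code (0/1/2, `NA` missing). A companion two-column header
#' comment (`#group:`) preserves sample groups.
#'
#' @param gm a `genotype_matrix`.
#' @param path file path.
#' @return the path (write) or a `genotype_matrix` (read).
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#group:\t", paste(gm$samples$group, collapse = "\t")),
             con)
  df <- cbind(gm$markers[, c("chrom", "pos", "ref", "alt")],
              as.data.frame(gm$geno, check.names = FALSE))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  first <- readLines(path, n = 1)
  groups <- strsplit(sub("^#group:\\t", "", first), "\t")[[1]]
  df <- read.delim(path, skip = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta_cols <- c("chrom", "pos", "ref", "alt")
  geno <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  genotype_matrix(geno, df[, meta_cols],
                  data.frame(sample = colnames(geno), group = groups,
                             stringsAsFactors = FALSE))
}

#' Export a genotype matrix in PED/MAP format
#'
#' Writes PLINK-style `.ped` and `.map` text files for interoperability.
#' The group label is used as the family identifier.
#'
#' @param gm a `genotype_matrix`.
#' @param prefix output prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return character vector of the two paths, invisibly.
#' @export
write_ped_map <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- gm$markers
  map <- data.frame(chrom = m$chrom, id = marker_id(m), cm = 0, pos = m$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ref <- m$ref
  alt <- m$alt
  allele_pairs <- function(g, i) {
    switch(as.character(g),
           "0" = c(ref[i], ref[i]),
           "1" = c(ref[i], alt[i]),
           "2" = c(alt[i], alt[i]),
           c("0", "0"))
  }
  lines <- vapply(seq_len(ncol(gm$geno)), function(j) {
    gts <- unlist(lapply(seq_len(nrow(gm$geno)), function(i)
      allele_pairs(gm$geno[i, j], i)))
    paste(c(gm$samples$group[j], gm$samples$sample[j], 0, 0, 0, -9, gts),
          collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}
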
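# Readers/writers and the in-memory model: VCF parsing and statistics,
# flank extraction, panel and genotype round trips, annotation partition.

test_that("read_vcf loads records, stats and genotypes", {
  body <- c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tMQ=40;DP=20\tGT\t0/0\t0/1\t0/1\t./.",
    "chr1\t200\t.\tC\tT\t50\tPASS\tMQ=40;DP=20\tGT\t0/0\t0/0\t0/0\t0/0",
    "chr2\t300\t.\tG\tA,C\t50\tPASS\tMQ=40;DP=20\tGT\t0/1\t1/2\t0/0\t0/2")
  path <- write_vcf_fixture(body, samples = c("s1", "s2", "s3", "s4"))
  v <- read_vcf(path, "popX")
  expect_equal(nrow(v$sites), 3)
  expect_equal(dim(v$genotypes), c(3L, 4L))

  # hand count: alleles 0/0,0/1,0/1,./. give 2 alt of 6 called
  expect_equal(v$sites$maf[1], 2 / 6, tolerance = 1e-12)
  expect_equal(v$sites$n_missing[1], 1L)
  expect_equal(v$sites$mac[1], 2L)

  # monomorphic record: MAF 0
  expect_equal(v$sites$maf[2], 0)

  # multiallelic record: 3 alleles recorded; MAF is the second most
  # frequent allele's share (alleles 0:4, 1:2, 2:2 -> 2/8)
  expect_equal(v$sites$n_alleles[3], 3L)
  expect_equal(v$sites$maf[3], 2 / 8, tolerance = 1e-12)

  expect_equal(v$sites$population, rep("popX", 3))
  expect_true(all(c("site_quality", "mapping_quality", "coverage") %in%
                    names(v$sites)))
  expect_equal(v$genotypes$geno[1, ], c(s1 = 0L, s2 = 1L, s3 = 1L,
                                        s4 = NA_integer_))
})

test_that("empty and malformed VCF bodies behave as specified", {
  empty <- write_vcf_fixture(character(0), samples = c("s1"))
  v <- read_vcf(empty)
  expect_equal(nrow(v$sites), 0)

  bad <- write_vcf_fixture("chr1\tnotapos\t.\tA\tG\t.\t.\t.\tGT\t0/0",
                           samples = "s1")
  expect_error(read_vcf(bad), "line")
})

test_that("VCF round trip preserves the genotype matrix", {
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3)
  gm <- gm_from(g, groups = c("a", "b"))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path, genome_index(c(chr1 = 1000L)))
  back <- read_vcf(path)
  expect_identical(unname(back$genotypes$geno), unname(gm$geno))
  expect_equal(back$genotypes$markers$pos, gm$markers$pos)
})

test_that("flank extraction matches a substring oracle", {
  set.seed(7)
  seq1 <- random_seq(100)
  g <- tiny_genome(chr1 = seq1)
  sites <- make_sites("chr1", c(36, 10, 50))
  fl <- extract_flanks(sites, g, flank = 35)

  # position 36: left flank is bases 1-35
  expect_identical(fl$flank_left[1], substr(seq1, 1, 35))
  # position 10: insufficient left flank
  expect_identical(fl$state[2], "excluded")
  expect_identical(fl$exclude_reason[2], "insufficient_flank")
  # position 50: both flanks equal independent substring slices
  expect_identical(fl$flank_left[3], substr(seq1, 15, 49))
  expect_identical(fl$flank_right[3], substr(seq1, 51, 85))
  expect_equal(nchar(fl$flank_left[3]), 35)

  expect_error(extract_flanks(make_sites("chr1", 500), g), "bounds")
})

test_that("panel files round trip and use bracket probe contexts", {
  set.seed(21)
  seq1 <- random_seq(5000)
  g <- tiny_genome(chr1 = seq1)
  pos <- sort(sample(36:4965, 100))
  panel <- make_sites("chr1", pos, ref = substring(seq1, pos, pos),
                      alt = "A", stage = "stage1")
  panel$alt[panel$ref == "A"] <- "G"
  panel <- extract_flanks(panel, g)
  path <- tempfile(fileext = ".tsv")
  write_panel(panel, path)

  expect_length(readLines(path), 101)  # header + 100 rows
  ctx <- probe_context(panel)
  expect_true(all(nchar(ctx) == 75))   # 35 + 5 + 35 for single-base alleles

  back <- read_panel(path)
  cols <- c("chrom", "pos", "ref", "alt", "flank_left", "flank_right",
            "stage")
  expect_equal(as.data.frame(back)[cols],
               as.data.frame(panel[order(panel$chrom, panel$pos), ])[cols],
               ignore_attr = TRUE)

  # duplicate coordinates on read are an error
  dup <- rbind(back, back[1, ])
  path2 <- tempfile(fileext = ".tsv")
  write_panel(dup, path2)
  expect_error(read_panel(path2), "duplicate")
})

test_that("genotype TSV and PED/MAP exports are consistent", {
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L, 2L, 2L), nrow = 2)
  gm <- gm_from(g, groups = c("p1", "p1", "p2", "p2"))
  path <- tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, path)
  back <- read_genotype_tsv(path)
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_identical(back$samples$group, gm$samples$group)

  prefix <- tempfile()
  write_ped_map(gm, prefix)
  map <- read.delim(paste0(prefix, ".map"), header = FALSE)
  ped <- readLines(paste0(prefix, ".ped"))
  expect_equal(nrow(map), 2)        # one row per marker
  expect_length(ped, 4)             # one line per sample
  expect_equal(length(strsplit(ped[1], " ")[[1]]), 6 + 2 * 2)
})

test_that("annotation derivation partitions the genome", {
  idx <- genome_index(c(chr1 = 1000L))
  genes <- data.frame(chrom = "chr1", start = c(101, 101),
                      end = c(200, 150), type = c("gene", "exon"))
  ann <- derive_annotation(genes, idx)
  len <- tapply(GenomicRanges::width(ann), ann$class, sum)
  expect_equal(unname(len["exon"]), 50)
  expect_equal(unname(len["intron"]), 50)
  expect_equal(unname(len["intergenic"]), 900)
  expect_equal(sum(GenomicRanges::width(ann)), 1000)

  # no genes: everything intergenic
  none <- derive_annotation(
    data.frame(chrom = character(), start = integer(), end = integer(),
               type = character()), idx)
  expect_equal(sum(GenomicRanges::width(none[none$class == "intergenic"])),
               1000)

  # exons tiling the gene: zero intron
  tiled <- derive_annotation(
    data.frame(chrom = "chr1", start = c(101, 101), end = c(200, 200),
               type = c("gene", "exon")), idx)
  expect_equal(sum(GenomicRanges::width(tiled[tiled$class == "intron"])), 0)

  expect_error(derive_annotation(
    data.frame(chrom = "chr1", start = 900, end = 1100, type = "gene"),
    idx), "bounds")
})

test_that("BED and GFF3 annotation coordinates are normalised", {
  dir <- tempfile(); dir.create(dir)
  # same gene in both conventions: bases 101..200 (1-based inclusive)
  bed <- file.path(dir, "genes.bed")
  writeLines("chr1\t100\t200\tgene", bed)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t101\t200\t.\t+\t.\tID=g1"), gff)
  from_bed <- read_annotation(bed)
  from_gff <- read_annotation(gff)
  expect_equal(GenomicRanges::start(from_bed), 101)
  expect_equal(GenomicRanges::start(from_gff), 101)
  expect_equal(GenomicRanges::end(from_bed), 200)
  expect_equal(GenomicRanges::end(from_gff), 200)
})
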
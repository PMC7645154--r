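# Post-genotyping evaluation: QC, conversion classes, accounting,
# feature density, spacing and concordance.

test_that("marker QC applies strict call-rate and MAF bounds", {
  # 9/10 called (call rate exactly 0.9) fails the strict inequality
  g1 <- c(rep(0L, 4), rep(1L, 4), 2L, NA)
  # all hom-ref: MAF 0 fails
  g2 <- rep(0L, 10)
  # 10/10 called, 6 hom-ref + 4 het: MAF 4/20 = 0.2, kept
  g3 <- c(rep(0L, 6), rep(1L, 4))
  gm <- gm_from(rbind(g1, g2, g3))
  qc <- marker_qc(gm)
  expect_equal(qc$summary$call_rate, c(0.9, 1, 1))
  expect_equal(qc$summary$maf, c(6 / 18, 0, 0.2))
  expect_equal(qc$summary$kept, c(FALSE, FALSE, TRUE))
  expect_equal(qc$kept, 3L)

  expect_error(marker_qc(gm_from(matrix(integer(0), nrow = 2))),
               "zero samples")
})

test_that("conversion classes are deterministic and partition markers", {
  rows <- rbind(
    mono = rep(0L, 100),                          # all hom-ref
    nmh = c(rep(0L, 70), rep(1L, 30)),            # hom-ref + het only
    phr = c(rep(0L, 60), rep(1L, 30), rep(2L, 10)),
    offr = c(rep(0L, 95), rep(NA_integer_, 5)),   # call rate 0.95 < 0.97
    other = c(rep(1L, 100))                       # het only
  )
  gm <- gm_from(rows)
  cls <- marker_qc(gm)$summary$conversion_class
  expect_equal(cls, c("MonoHighResolution", "NoMinorHom",
                      "PolyHighResolution", "OffRecommended", "Other"))
  # each marker receives exactly one label
  expect_length(cls, nrow(rows))
  expect_false(anyNA(cls))
})

test_that("polymorphism accounting flags group-specific markers", {
  # marker 1 segregates only in group A; marker 2 nowhere; marker 3 in both
  gA <- rbind(c(0L, 1L, 0L), c(0L, 0L, 0L), c(0L, 1L, 1L))
  gB <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 2L, 0L))
  gm <- genotype_matrix(cbind(gA, gB), make_sites("chr1", c(100, 200, 300)),
                        data.frame(sample = paste0("s", 1:6),
                                   group = rep(c("A", "B"), each = 3)))
  acc <- polymorphic_accounting(gm)
  a <- acc$by_group[acc$by_group$group == "A", ]
  b <- acc$by_group[acc$by_group$group == "B", ]
  expect_equal(a$n_polymorphic, 2)
  expect_equal(a$n_specific, 1)     # marker 1
  expect_equal(b$n_polymorphic, 1)
  expect_equal(b$n_specific, 0)
  expect_equal(acc$overall$n_polymorphic, 2)
  # specific counts can never exceed the overall polymorphic count
  expect_lte(sum(acc$by_group$n_specific), acc$overall$n_polymorphic)
  expect_lte(acc$overall$n_polymorphic, acc$overall$n_markers)
})

test_that("feature density assigns markers and reports per-kb rates", {
  idx <- genome_index(c(chr1 = 1000L))
  ann <- derive_annotation(
    data.frame(chrom = "chr1", start = c(101, 101), end = c(200, 150),
               type = c("gene", "exon")), idx)
  markers <- make_sites("chr1", c(120, 140, 160, 500, 900))
  fd <- feature_density(markers, ann)
  expect_equal(fd$n[fd$category == "exon"], 2)
  expect_equal(fd$n[fd$category == "intron"], 1)
  expect_equal(fd$n[fd$category == "intergenic"], 2)
  expect_equal(fd$n[fd$category == "All"], 5)
  expect_equal(sum(fd$percent[fd$category != "All"]), 100, tolerance = 1e-9)
  # single class covering the genome: density = N / length
  only <- derive_annotation(
    data.frame(chrom = character(), start = integer(), end = integer(),
               type = character()), idx)
  fd2 <- feature_density(markers, only)
  expect_equal(fd2$percent[fd2$category == "intergenic"], 100)
  expect_equal(fd2$density_per_kb[fd2$category == "intergenic"], 5 / 1)
})

test_that("spacing scan reports means, gaps and bin occupancy", {
  idx <- genome_index(c(chr1 = 100000L))
  panel <- make_sites("chr1", c(1000, 2000, 3000))
  sc <- spacing_scan(panel, idx)
  expect_equal(sc$overall$mean_spacing, 1000)
  expect_equal(sc$overall$n_gaps_over, 0)

  # 5 markers all in the first 100 kb bin of a 100 kb chromosome
  p5 <- make_sites("chr1", c(100, 200, 300, 400, 500))
  sc5 <- spacing_scan(p5, idx)
  expect_equal(sc5$bins$n, 5L)
  expect_equal(sc5$frac_bins_low, 1)     # fewer than 10 markers
  expect_equal(sc5$frac_bins_empty, 0)

  # a panel built at 1.19 kb mean spacing is measured back as 1.19 kb
  pos <- cumsum(rep(1190, 80))
  scn <- spacing_scan(make_sites("chr1", pos),
                      genome_index(c(chr1 = 100000L)))
  expect_equal(scn$overall$mean_spacing, 1190)

  expect_error(spacing_scan(make_sites("chr1", integer(0)), idx), "empty")
})

test_that("concordance reports explicit denominators for every rate", {
  g <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 3)
  wgs <- gm_from(g)
  arr <- gm_from(g)
  same <- concordance(wgs, arr)
  expect_equal(same$missing_in_array$rate, 0)
  expect_equal(same$recovered$n, 0)
  expect_equal(same$discordance$rate, 0)
  expect_equal(same$discordance$den, 6)

  # array entirely missing: missing-in-array rate 1
  arr_na <- gm_from(matrix(NA_integer_, 3, 2))
  all_missing <- concordance(wgs, arr_na)
  expect_equal(all_missing$missing_in_array$rate, 1)
  expect_equal(all_missing$discordance$den, 0)

  # known 10% WGS dropout recovered by an error-free array
  set.seed(99)
  n <- 4000
  truth <- matrix(rbinom(n, 2, 0.3), ncol = 10)
  drop <- matrix(runif(n) < 0.1, ncol = 10)
  wgs2 <- truth; wgs2[drop] <- NA_integer_
  cc <- concordance(gm_from(wgs2), gm_from(truth))
  expect_equal(cc$recovered$den, n)
  expect_lt(abs(cc$recovered$rate - 0.1), 4 * sqrt(0.1 * 0.9 / n))
  expect_equal(cc$recovered_of_missing$rate, 1)
  expect_equal(cc$discordance$rate, 0)

  expect_error(concordance(wgs, gm_from(g, chrom = "chrX")), "shared")
})
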
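# Three-stage even-spacing selection: stage behaviour, invariants, and
# equivalence with the independently coded reference implementation.

idx1 <- function(len) genome_index(setNames(as.integer(len), "chr1"))

sel_pos <- function(state) sort(state$pos[state$state == "selected"])

test_that("stage 1 keeps the edge-nearest pair per small bin", {
  cfg <- select_config()
  st <- stage1_edge_pick(make_sites("chr1", c(100, 450, 900)), idx1(10000),
                         cfg)
  expect_equal(sel_pos(st), c(100, 900))
  expect_equal(st$state[st$pos == 450], "dropped")

  single <- stage1_edge_pick(make_sites("chr1", 500), idx1(10000), cfg)
  expect_equal(sel_pos(single), 500)

  two <- stage1_edge_pick(make_sites("chr1", c(400, 600)), idx1(10000), cfg)
  expect_equal(sel_pos(two), c(400, 600))

  # every 1 kb bin contributes at most two selections
  set.seed(31)
  many <- stage1_edge_pick(
    make_sites("chr1", sort(sample(1:20000, 500))), idx1(20000), cfg)
  per_bin <- table((many$pos[many$state == "selected"] - 1) %/% 1000)
  expect_true(all(per_bin <= 2))

  expect_error(stage1_edge_pick(make_sites("chr1", 30000), idx1(20000), cfg),
               "bounds")
})

test_that("stage 2 thins dense bins and tops up sparse ones", {
  cfg <- select_config()
  # 20 stage-1 survivors in one 10 kb bin: exactly 10 kept, chosen by the
  # uniform-target rule
  pos20 <- sort(c(seq_len(10) * 1000 - 900, seq_len(10) * 1000 - 100))
  st <- stage1_edge_pick(make_sites("chr1", pos20), idx1(10000), cfg)
  expect_equal(length(sel_pos(st)), 20)
  st2 <- stage2_density_adjust(st, cfg)
  kept <- sel_pos(st2)
  expect_length(kept, 10)
  expect_equal(kept, oracle_uniform_pick(pos20, 0, 10000, 10))

  # pass-through band: 8 markers stay untouched
  pos8 <- seq_len(8) * 1000 - 500
  st8 <- stage2_density_adjust(
    stage1_edge_pick(make_sites("chr1", pos8), idx1(10000), cfg), cfg)
  expect_equal(sel_pos(st8), pos8)

  # sparse bin with 3 selected and 2 dropped: the pool is exhausted at 5
  pos_sparse <- c(100, 250, 400, 900, 1500)  # bin 0 holds 4, bin 1 holds 1
  st_sp <- stage1_edge_pick(make_sites("chr1", pos_sparse), idx1(10000),
                            cfg)
  expect_length(sel_pos(st_sp), 3)
  st_sp2 <- stage2_density_adjust(st_sp, cfg)
  expect_equal(sel_pos(st_sp2), pos_sparse)  # all 5 kept, still under 7
})

test_that("uniform_pick matches its targets and tie rule", {
  # sites coinciding with the ten targets of [0, 10000) are all kept
  pos <- seq_len(10) * 1000 - 500
  expect_equal(uniform_pick(pos, 0, 10000, 10), 1:10)

  # clustered sites, k = 2: assignment found by enumerating both targets
  pos2 <- c(100, 200, 300)
  picked <- uniform_pick(pos2, 0, 10000, 2)
  expect_equal(sort(pos2[picked]), c(200, 300))
  # targets are 2500 and 7500; 300 is nearest 2500, then 200 nearest 7500

  # tie between two equidistant sites: the lower coordinate wins
  pos3 <- c(2400, 2602)  # 0-based 2399 and 2601: both 101 from target 2500
  picked3 <- uniform_pick(pos3, 0, 5000, 1)
  expect_equal(pos3[picked3], 2400)

  expect_error(uniform_pick(pos2, 0, 1000, 0), "positive")
  expect_error(uniform_pick(pos2, 0, 1000, 5), "fewer")
})

test_that("stage 3 fills oversized gaps from the dropped pool", {
  cfg <- select_config()
  # dropped SNP nearest the midpoint is promoted; residual gaps remain once
  # the pool is empty
  cand <- make_sites("chr1", c(1000, 3400, 6000))
  st <- stage1_edge_pick(cand, idx1(6500), cfg)
  st$state[st$pos == 3400] <- "dropped"   # force the published scenario
  st$stage[st$pos == 3400] <- NA_character_
  st3 <- stage3_gap_fill(st, cfg)
  expect_equal(sel_pos(st3), c(1000, 3400, 6000))
  expect_equal(st3$stage[st3$pos == 3400], "stage3")

  # gap of 1900 needs no action
  ok <- make_sites("chr1", c(1000, 2900))
  sto <- stage3_gap_fill(stage1_edge_pick(ok, idx1(3500), cfg), cfg)
  expect_equal(sort(sto$stage), c("stage1", "stage1"))

  # 5 kb gap with dropped SNPs every 500 bases: no residual gap > 2 kb
  dense <- make_sites("chr1", c(1000, seq(1500, 5500, by = 500), 6000))
  std <- stage1_edge_pick(dense, idx1(7000), cfg)
  # demote the interior so the gap spans 1000..6000
  interior <- std$pos > 1000 & std$pos < 6000
  std$state[interior] <- "dropped"
  std$stage[interior] <- NA_character_
  std3 <- stage3_gap_fill(std, cfg)
  expect_true(all(diff(c(0, sel_pos(std3), 7000)) <= 2000))
})

test_that("fixed trait and control markers join without displacement", {
  cfg <- select_config()
  g <- idx1(20000)
  sel <- select_panel(make_sites("chr1", c(500, 1500, 2500)), g, cfg)
  panel <- sel$panel
  n0 <- nrow(panel)

  # a trait SNP already on the panel only upgrades provenance
  trait <- make_sites("chr1", panel$pos[1])
  p2 <- add_fixed_markers(panel, trait_snps = trait)
  expect_equal(nrow(p2), n0)
  expect_equal(p2$stage[p2$pos == panel$pos[1]], "trait")

  # five novel control SNPs extend the panel by five
  controls <- make_sites("chr1", c(11000, 12000, 13000, 14000, 15000))
  p3 <- add_fixed_markers(panel, control_snps = controls)
  expect_equal(nrow(p3), n0 + 5)
  expect_true(all(p3$stage[p3$pos >= 11000] == "control"))

  # duplicates inside the trait list collapse to one entry
  dup <- make_sites("chr1", c(18000, 18000))
  p4 <- add_fixed_markers(panel, trait_snps = dup)
  expect_equal(nrow(p4), n0 + 1)

  expect_error(add_fixed_markers(panel, trait_snps =
    make_sites("chr1", 25000)), "bounds")

  # probe-incompatible fixed markers warn but are kept
  bad_flank <- make_sites("chr1", 16000,
                          flank_left = strrep("G", 35),
                          flank_right = strrep("C", 35))
  expect_warning(p5 <- add_fixed_markers(panel, trait_snps = bad_flank,
                                         probe_config =
                                           probe_filter_config()),
                 "kept")
  expect_true(16000 %in% p5$pos)
})

test_that("candidates are conserved across stages and order-independent", {
  set.seed(61)
  index <- genome_index(c(chr1 = 30000L, chr2 = 20000L))
  cand <- rbind(make_sites("chr1", sort(sample(1:30000, 300))),
                make_sites("chr2", sort(sample(1:20000, 40))))
  cfg <- select_config()
  sel <- select_panel(cand, index, cfg)

  # conservation: every candidate is selected or dropped, none lost
  expect_equal(nrow(sel$audit), nrow(cand))
  expect_true(all(sel$audit$state %in% c("selected", "dropped")))
  expect_setequal(marker_id(sel$audit), marker_id(cand))

  # stage-2 band: merged bins end at or below the target
  sel_bins <- table(paste(sel$panel$chrom,
                          (sel$panel$pos - 1) %/% 10000))
  expect_true(all(sel_bins <= cfg$bin_target))

  # record order does not matter
  shuffled <- cand[sample(nrow(cand)), ]
  sel2 <- select_panel(shuffled, index, cfg)
  expect_equal(sel2$panel$pos, sel$panel$pos)
  expect_equal(sel2$panel$stage, sel$panel$stage)
})

test_that("the full pipeline matches the reference implementation", {
  set.seed(71)
  for (rep in 1:25) {
    len <- sample(5000:50000, 1)
    n <- sample(5:60, 1)
    cfg <- select_config(
      small_bin = sample(c(500, 1000, 2000), 1),
      merge_factor = sample(c(5, 10), 1),
      bin_target = sample(6:12, 1),
      bin_floor = sample(3:6, 1),
      max_gap = sample(c(1000, 2000, 3000), 1))
    cand <- make_sites("chr1", sort(sample(seq_len(len), n)))
    index <- idx1(len)
    got <- select_panel(cand, index, cfg)
    want <- oracle_select(cand, index, cfg)$chr1
    expect_equal(got$panel$pos, want$selected)
    expect_equal(got$panel$stage, want$stage)
  }
})

test_that("a residual oversized gap never hides an unused dropped SNP", {
  set.seed(81)
  index <- idx1(100000)
  cand <- make_sites("chr1", sort(sample(1:100000, 60)))
  sel <- select_panel(cand, index, select_config())
  bounds <- c(0, sel$panel$pos, 100000)
  dropped <- sel$audit$pos[sel$audit$state == "dropped"]
  for (i in seq_len(length(bounds) - 1)) {
    if (bounds[i + 1] - bounds[i] > 2000) {
      inside <- dropped[dropped > bounds[i] & dropped < bounds[i + 1]]
      expect_length(inside, 0)
    }
  }
})
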
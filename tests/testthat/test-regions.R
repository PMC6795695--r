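test_that("core regions are maximal runs at or above the depth threshold", {
  cfg <- region_config()
  expect_equal(nrow(call_core_regions(coverage_track("c", rep(0L, 100)), cfg)), 0L)

  depth <- rep(0L, 100)
  depth[10:20] <- 17L                    # threshold is inclusive
  expect_equal(call_core_regions(coverage_track("c", depth), cfg),
               data.frame(start = 10L, end = 20L))
  depth[10:20] <- 16L
  expect_equal(nrow(call_core_regions(coverage_track("c", depth), cfg)), 0L)
})

test_that("flanking and merging follow the strict gap rule", {
  cfg <- region_config(min_depth = 17, flank = 500, merge_gap = 301)

  one <- flank_and_merge(data.frame(start = 1000L, end = 1100L), cfg, 10000L)
  expect_equal(one[, c("start", "end")], data.frame(start = 500L, end = 1600L))

  # extended gap 399 >= 301: kept apart
  two <- flank_and_merge(data.frame(start = c(1000L, 2500L),
                                    end = c(1100L, 2600L)), cfg, 10000L)
  expect_equal(two$start, c(500L, 2000L))
  expect_equal(two$end, c(1600L, 3100L))

  # extended gap 299 < 301: merged, core span covers both cores
  merged <- flank_and_merge(data.frame(start = c(1000L, 2400L),
                                       end = c(1100L, 2500L)), cfg, 10000L)
  expect_equal(merged[, c("start", "end")], data.frame(start = 500L, end = 3000L))
  expect_equal(merged[, c("core_start", "core_end")],
               data.frame(core_start = 1000L, core_end = 2500L))

  # boundary pair: extended gap exactly 300 merges, exactly 301 does not
  g300 <- flank_and_merge(data.frame(start = c(1000L, 2401L),
                                     end = c(1100L, 2501L)), cfg, 10000L)
  expect_equal(nrow(g300), 1L)
  g301 <- flank_and_merge(data.frame(start = c(1000L, 2402L),
                                     end = c(1100L, 2502L)), cfg, 10000L)
  expect_equal(nrow(g301), 2L)

  # flanks are clipped at chromosome ends
  clipped <- flank_and_merge(data.frame(start = 100L, end = 9900L), cfg, 10000L)
  expect_equal(clipped[, c("start", "end")], data.frame(start = 1L, end = 10000L))
})

test_that("region pipeline matches the dilate-and-union oracle on random tracks", {
  set.seed(21)
  cfg <- region_config(min_depth = 17, flank = 500, merge_gap = 301)
  for (rep_i in 1:200) {
    depth <- as.integer(rpois(5000, sample(c(2, 8, 14, 17, 20), 1)))
    track <- coverage_track("c", depth)
    got <- flank_and_merge(call_core_regions(track, cfg), cfg, 5000L)
    exp <- oracle_regions(depth, cfg)
    expect_equal(got[, c("start", "end")], exp, ignore_attr = TRUE)
    if (nrow(got) > 1L) {
      gaps <- got$start[-1] - got$end[-nrow(got)] - 1L
      expect_true(all(gaps >= cfg$merge_gap))
    }
  }
})

test_that("flank_and_merge with zero flank is idempotent on its own output", {
  set.seed(22)
  cfg <- region_config(min_depth = 5, flank = 120, merge_gap = 80)
  depth <- as.integer(rpois(3000, 4))
  regs <- flank_and_merge(call_core_regions(coverage_track("c", depth), cfg),
                          cfg, 3000L)
  cfg0 <- region_config(min_depth = cfg$min_depth, flank = 0,
                        merge_gap = cfg$merge_gap)
  again <- flank_and_merge(regs[, c("start", "end")], cfg0, 3000L)
  expect_equal(again[, c("start", "end")], regs[, c("start", "end")])
})

test_that("excise_contigs cuts sequences and assigns ordered ids", {
  asm <- c(chr1 = "ACGTACGTAC", chr2 = "TTTTGGGGCCCCAAAA")
  regs <- data.frame(chrom = c("chr1", "chr2", "chr1"),
                     start = c(5L, 1L, 1L), end = c(8L, 4L, 4L))
  ctg <- excise_contigs(regs, asm, "assembly_1")
  expect_equal(ctg$contig_id, sprintf("ctg%06d", 1:3))
  # (chrom, start) order: chr1:1-4, chr1:5-8, chr2:1-4
  expect_equal(ctg$sequence, c("ACGT", "ACGT", "TTTT"))
  expect_equal(ctg$source_chrom, c("chr1", "chr1", "chr2"))

  expect_error(excise_contigs(data.frame(chrom = "chr1", start = 5L, end = 12L),
                              asm, "assembly_1"), "outside the chromosome")
  expect_equal(nrow(excise_contigs(regs[0, ], asm, "assembly_1")), 0L)
})

test_that("build_reference combines assemblies and filters de-novo contigs", {
  set.seed(23)
  mkasm <- function(len) setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "chr1")
  asm1 <- mkasm(4000)
  asm2 <- mkasm(4000)
  d1 <- rep(0L, 4000); d1[1001:1200] <- 20L; d1[3001:3100] <- 20L
  d2 <- rep(0L, 4000); d2[2001:2300] <- 20L
  cfg <- region_config(min_depth = 17, flank = 100, merge_gap = 301)
  denovo <- reference_contigs(c("x1", "x2"),
                              c(strrep("A", 499), strrep("C", 500)))
  ref <- build_reference(list(list(coverage_track("chr1", d1)),
                              list(coverage_track("chr1", d2))),
                         list(asm1, asm2), denovo, cfg)
  # 499-bp de-novo contig excluded, 500-bp included
  expect_equal(nrow(ref), 4L)
  expect_equal(ref$contig_id, sprintf("ctg%06d", 1:4))
  expect_equal(ref$source, c("assembly_1", "assembly_1", "assembly_2", "denovo"))
  expect_equal(nchar(ref$sequence[4]), 500L)

  # total contig length equals the sum of region extents plus retained denovo
  spans <- ref[ref$source != "denovo", ]
  expect_equal(nchar(spans$sequence),
               spans$source_end - spans$source_start + 1L)
  summ <- attr(ref, "summary")
  expect_equal(sum(summ$total_bp), sum(nchar(ref$sequence)))
})
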
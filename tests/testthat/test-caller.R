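mut6 <- sprintf("line%03d", 1:6)

test_that("control concordance separates varietal SNPs from clean columns", {
  cfg <- caller_config()
  clean <- make_column("G", list(control = c(G = 30)))
  expect_true(control_is_concordant(clean, "control", cfg)$concordant)

  flipped <- make_column("G", list(control = c(A = 25, G = 5)))
  res <- control_is_concordant(flipped, "control", cfg)
  expect_false(res$concordant)
  expect_match(res$detail, "majority")

  # 3/23 = 13% minor fraction exceeds the 10% cap
  noisy <- make_column("G", list(control = c(G = 20, A = 3)))
  expect_false(control_is_concordant(noisy, "control", cfg)$concordant)
  # 2/22 = 9% passes
  ok <- make_column("G", list(control = c(G = 20, A = 2)))
  expect_true(control_is_concordant(ok, "control", cfg)$concordant)

  nocov <- make_column("G", list(control = c()))
  res <- control_is_concordant(nocov, "control", cfg)
  expect_false(res$concordant)
  expect_equal(res$detail, "no control coverage")
})

test_that("candidate alleles must be unique to one carrier", {
  cfg <- caller_config()
  counts <- list(control = c(G = 30), line001 = c(G = 10, A = 12),
                 line002 = c(G = 11), line003 = c(G = 9))
  col <- make_column("G", counts)
  cand <- candidate_alleles(col, cfg, names(counts)[-1])
  expect_equal(cand$carrier[cand$allele == "A"], "line001")
  expect_equal(cand$support[cand$allele == "A"], 12L)

  # same allele present in two lines: not a candidate
  counts$line002 <- c(G = 8, A = 3)
  cand <- candidate_alleles(make_column("G", counts), cfg, names(counts)[-1])
  expect_equal(cand$n_present[cand$allele == "A"], 2L)
  expect_true(is.na(cand$carrier[cand$allele == "A"]))

  # a single stray read below presence_min_reads does not veto the carrier
  counts$line002 <- c(G = 8, A = 1)
  cand <- candidate_alleles(make_column("G", counts), cfg, names(counts)[-1])
  expect_equal(cand$carrier[cand$allele == "A"], "line001")
})

test_that("population coverage requires enough informative other samples", {
  cfg <- caller_config(min_informative_samples = 50)
  counts <- c(list(control = c(G = 30), carrier = c(A = 12)),
              setNames(rep(list(c(G = 3)), 60), sprintf("s%02d", 1:60)),
              setNames(rep(list(c(G = 2)), 20), sprintf("t%02d", 1:20)))
  col <- make_column("G", counts)
  samples <- setdiff(names(counts), "control")
  res <- population_coverage_ok(col, "carrier", "G", cfg, samples)
  expect_true(res$ok)
  expect_equal(res$n_informative, 60L)

  # boundary: 49 informative < 50
  counts49 <- c(list(control = c(G = 30), carrier = c(A = 12)),
                setNames(rep(list(c(G = 3)), 49), sprintf("s%02d", 1:49)))
  col49 <- make_column("G", counts49)
  expect_false(population_coverage_ok(col49, "carrier", "G", cfg,
                                      setdiff(names(counts49), "control"))$ok)
  # a scaled threshold behaves identically
  cfg20 <- caller_config(min_informative_samples = 20)
  expect_true(population_coverage_ok(col49, "carrier", "G", cfg20,
                                     setdiff(names(counts49), "control"))$ok)
})

test_that("zygosity classification follows the allele-fraction bands", {
  cfg <- caller_config()
  expect_equal(classify_zygosity(12, 12, cfg), "homozygous")
  expect_equal(classify_zygosity(6, 12, cfg), "heterozygous")
  expect_true(is.na(classify_zygosity(1, 12, cfg)))     # f ~ 0.083 < 0.15
  expect_equal(classify_zygosity(11, 12, cfg), "homozygous")  # f ~ 0.92
  expect_error(classify_zygosity(1, 0, cfg), "positive")
})

test_that("call_position composes the criteria and audits rejections", {
  cfg <- caller_config(min_mut_support = 10, min_informative_samples = 3)
  base <- list(control = c(G = 30), line001 = c(G = 1, A = 12),
               line002 = c(G = 8), line003 = c(G = 7), line004 = c(G = 9),
               line005 = c(G = 5), line006 = c(G = 6))
  col <- make_column("G", base)
  res <- call_position(col, cfg, mut6, "control")
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$sample_id, "line001")
  expect_equal(res$calls$mutant_allele, "A")
  expect_equal(res$calls$zygosity, "homozygous")   # 12/13 = 0.92
  expect_true(res$calls$is_canonical_ems)          # G -> A
  expect_equal(res$verdicts$status, "called")

  # support 9 < 10: rejected at the support step
  base$line001 <- c(G = 1, A = 9)
  res <- call_position(make_column("G", base), cfg, mut6, "control")
  expect_equal(nrow(res$calls), 0L)
  expect_equal(res$verdicts$status, "insufficient_support")

  # reference N is never callable
  res <- call_position(make_column("N", base), cfg, mut6, "control")
  expect_equal(res$verdicts$status, "ref_is_N")

  # deletion alleles are called like substitutions
  base$line001 <- c(G = 2, DEL = 11)
  res <- call_position(make_column("G", base), cfg, mut6, "control")
  expect_equal(res$calls$mutation_kind, "deletion")
  expect_equal(res$calls$mutant_allele, "DEL")
  expect_false(res$calls$is_canonical_ems)
})

test_that("call_population matches call_position column by column", {
  set.seed(41)
  cfg <- caller_config(min_mut_support = 3, min_informative_samples = 3)
  pu <- random_pileup(n_pos = 300L, n_samples = 8L)
  fast <- call_population(pu, cfg, "control")
  slow <- call_population(pu, cfg, "control", verdicts = TRUE)
  expect_equal(sort_calls(fast$calls), sort_calls(slow$calls))
  expect_equal(fast$callable, slow$callable)
  expect_true(all(slow$verdicts$status %in%
                    c("called", "not_unique", "polymorphic_in_control",
                      "insufficient_support",
                      "insufficient_population_coverage", "ref_is_N")))
})

test_that("call_population matches the brute-force enumeration oracle", {
  set.seed(42)
  cfg <- caller_config(min_mut_support = 3, min_informative_samples = 3)
  for (rep_i in 1:25) {
    pu <- random_pileup(n_pos = 200L, n_samples = 8L)
    got <- sort_calls(call_population(pu, cfg, "control")$calls)
    exp <- sort_calls(oracle_call_pileup(pu, cfg, "control"))
    expect_equal(got[, names(exp)], exp)
  }
})

test_that("no (contig, pos, allele) is called in two different samples", {
  set.seed(43)
  cfg <- caller_config(min_mut_support = 3, min_informative_samples = 2)
  for (i in 1:10) {
    calls <- call_population(random_pileup(150L, 6L), cfg, "control")$calls
    key <- paste(calls$contig_id, calls$pos, calls$mutant_allele)
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("call counts are monotone non-increasing in stringency", {
  set.seed(44)
  pu <- random_pileup(n_pos = 800L, n_samples = 8L, mean_depth = 15)
  n_calls <- function(...) {
    cfg <- caller_config(min_informative_samples = 3, ...)
    nrow(call_population(pu, cfg, "control")$calls)
  }
  by_support <- vapply(c(3, 5, 8, 10), function(s)
    n_calls(min_mut_support = s), numeric(1))
  expect_true(all(diff(by_support) <= 0))

  base <- caller_config(min_informative_samples = 3, min_mut_support = 3)
  stricter <- caller_config(min_informative_samples = 6, min_mut_support = 3)
  expect_lte(nrow(call_population(pu, stricter, "control")$calls),
             nrow(call_population(pu, base, "control")$calls))
})

test_that("raising presence_min_reads can relax the uniqueness veto", {
  # 12 reads in X and exactly 2 in Y: two carriers at threshold 2 (vetoed),
  # one carrier at threshold 3 (called) — the presence threshold is not a
  # pure stringency knob because it gates the uniqueness test on both sides
  counts <- list(control = c(G = 30), line001 = c(G = 1, A = 12),
                 line002 = c(G = 8, A = 2), line003 = c(G = 7),
                 line004 = c(G = 9), line005 = c(G = 5), line006 = c(G = 6))
  col <- make_column("G", counts)
  mk <- function(p) caller_config(min_mut_support = 3,
                                  min_informative_samples = 3,
                                  presence_min_reads = p)
  vetoed <- call_position(col, mk(2), mut6, "control")
  expect_equal(nrow(vetoed$calls), 0L)
  expect_true("not_unique" %in% vetoed$verdicts$status)
  called <- call_position(col, mk(3), mut6, "control")
  expect_equal(called$calls$sample_id, "line001")
})

test_that("callable space counts positions at or above the depth threshold", {
  set.seed(45)
  pu <- random_pileup(n_pos = 100L, n_samples = 4L, mean_depth = 8)
  res <- call_population(pu, caller_config(min_mut_support = 10,
                                           min_informative_samples = 2),
                         "control")
  expect_equal(res$callable$min_depth, 10L)
  for (s in setdiff(pu$samples, "control")) {
    expect_equal(res$callable$per_sample[[s]],
                 sum(rowSums(pu$counts[[s]][, 1:5]) >= 10))
  }
  expect_equal(res$callable$total, sum(res$callable$per_sample))
})
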
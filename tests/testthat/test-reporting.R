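test_that("summarize_calls computes spectrum, ratio and rate identities", {
  calls <- data.frame(
    sample_id = c("a", "a", "b"), contig_id = "ctg000001", pos = 1:3,
    mutation_kind = c("substitution", "substitution", "deletion"),
    control_base = c("C", "T", "G"),
    mutant_allele = c("T", "A", "DEL"),
    zygosity = c("heterozygous", "heterozygous", "homozygous"),
    mut_support = c(12L, 5L, 8L), sample_depth = c(24L, 10L, 9L),
    is_canonical_ems = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  st <- summarize_calls(calls, callable_bp = 2e6)
  expect_equal(st$n_total, 3L)
  expect_equal(st$n_total, st$n_het + st$n_hom)
  expect_equal(sum(st$type_counts$n), st$n_total)
  expect_equal(st$cg_ta_fraction, 1 / 3)
  expect_equal(st$het_hom_ratio, 2)
  expect_equal(st$mutations_per_mbp, 1.5)

  # one call over 2 Mbp is 0.5 mutations per Mbp
  expect_equal(summarize_calls(calls[1, ], 2e6)$mutations_per_mbp, 0.5)

  # zero homozygous calls: ratio undefined, reported NA
  expect_true(is.na(summarize_calls(calls[1:2, ])$het_hom_ratio))
  expect_equal(summarize_calls(calls[0, ])$n_total, 0L)
})

test_that("calls_from_spectrum inverts the type-count summary", {
  spec <- data.frame(mutation_kind = c("substitution", "substitution", "deletion"),
                     control_base = c("C", "G", "A"),
                     mutant_allele = c("T", "A", "DEL"),
                     n = c(5L, 3L, 2L), stringsAsFactors = FALSE)
  calls <- calls_from_spectrum(spec, n_het = 6L, n_hom = 4L)
  expect_equal(nrow(calls), 10L)
  st <- summarize_calls(calls)
  expect_equal(st$n_het, 6L)
  expect_equal(st$n_hom, 4L)
  expect_equal(st$cg_ta_fraction, 0.8)
  got <- merge(spec, st$type_counts,
               by = c("mutation_kind", "control_base", "mutant_allele"))
  expect_equal(got$n.x, got$n.y)
})

test_that("coverage_sweep is non-increasing per zygosity series", {
  calls <- data.frame(mut_support = c(3L, 5L, 12L),
                      zygosity = c("heterozygous", "heterozygous", "homozygous"))
  sw <- coverage_sweep(calls, c(3, 10))
  expect_equal(sw$n_total, c(3L, 1L))
  expect_equal(sw$n_het, c(2L, 0L))
  expect_equal(sw$n_hom, c(1L, 1L))

  empty <- coverage_sweep(calls[0, ], c(3, 10))
  expect_equal(empty$n_total, c(0L, 0L))

  one <- coverage_sweep(data.frame(mut_support = 10L, zygosity = "homozygous"),
                        10)
  expect_equal(c(one$n_het, one$n_hom), c(0L, 1L))

  set.seed(51)
  rnd <- data.frame(mut_support = rpois(500, 8) + 1L,
                    zygosity = sample(c("heterozygous", "homozygous"), 500,
                                      replace = TRUE))
  sw <- coverage_sweep(rnd, 1:20)
  expect_true(all(diff(sw$n_het) <= 0))
  expect_true(all(diff(sw$n_hom) <= 0))
})

test_that("extract_flanks marks the mutation and respects boundaries", {
  set.seed(52)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  ctg <- reference_contigs("ctg000001", seq1)
  call <- data.frame(contig_id = "ctg000001", pos = 300L,
                     control_base = substr(seq1, 300, 300),
                     mutant_allele = "T", stringsAsFactors = FALSE)
  fl <- extract_flanks(call, ctg)
  expect_equal(fl$left_len, 200L)
  expect_equal(fl$right_len, 200L)
  expect_false(fl$short_flank)
  # 200 + marker + 200; the marker text replaces the single mutated base
  expect_equal(stringi::stri_count_fixed(fl$flanking_sequence, "["), 1L)
  expect_equal(nchar(fl$flanking_sequence),
               401L - 1L + nchar(sprintf("[%s/T]", call$control_base)))

  # marker stripped and control base restored gives an exact substring
  restored <- sub("\\[(.)/.+\\]", "\\1", fl$flanking_sequence)
  expect_equal(restored, substr(seq1, 100, 500))

  near <- call; near$pos <- 30L
  near$control_base <- substr(seq1, 30, 30)
  fl <- extract_flanks(near, ctg)
  expect_equal(fl$left_len, 29L)
  expect_true(fl$short_flank)

  del <- call; del$mutant_allele <- "DEL"
  expect_match(extract_flanks(del, ctg)$flanking_sequence,
               sprintf("\\[%s/-\\]", call$control_base))

  bad <- call; bad$pos <- 1001L
  expect_error(extract_flanks(bad, ctg), "outside contig")
})

test_that("mutation records export to CSV and SQLite and query back", {
  set.seed(53)
  ds <- simulate_dataset(sim_config(n_contigs = 10, contig_length_bp = 1500,
                                    n_lines = 8, mutant_depth_mean = 30,
                                    mutation_rate_per_mbp = 400, seed = 53))
  res <- call_population(ds$pileup,
                         caller_config(min_informative_samples = 4),
                         "control")
  expect_gt(nrow(res$calls), 5L)
  rec <- as_mutation_records(res$calls, ds$reference)
  expect_true(all(rec$chromosome_location == "unplaced"))
  expect_true(all(stringi::stri_count_fixed(rec$flanking_sequence, "[") == 1L))

  csv <- withr::local_tempfile(fileext = ".csv")
  db <- withr::local_tempfile(fileext = ".sqlite")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  export_mutation_csv(rec, csv)
  expect_identical(read_mutation_csv(csv), rec)

  export_sqlite(csv, db)
  sqlite_to_csv(db, csv2)
  back <- read_mutation_csv(csv2)
  expect_identical(back[order(back$contig_id, back$pos, back$mutant_id), ],
                   rec[order(rec$contig_id, rec$pos, rec$mutant_id), ],
                   ignore_attr = TRUE)

  # query by contig: every row on that contig, sorted by depth descending
  ctg <- rec$contig_id[1]
  q <- query_mutations(db, contig_id = ctg)
  expect_equal(sort(q$pos), sort(rec$pos[rec$contig_id == ctg]))
  expect_true(all(diff(q$mut_depth) <= 0))
  # query by mutant line
  line <- rec$mutant_id[1]
  q2 <- query_mutations(db, mutant_id = line)
  expect_equal(nrow(q2), sum(rec$mutant_id == line))
  expect_error(query_mutations(db), "exactly one")

  # empty record set still yields a valid header-only CSV and empty table
  export_mutation_csv(rec[0, ], csv)
  expect_equal(nrow(read_mutation_csv(csv)), 0L)
  export_sqlite(rec[0, ], db)
  expect_equal(nrow(query_mutations(db, contig_id = ctg)), 0L)
})
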
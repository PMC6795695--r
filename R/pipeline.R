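#' Run the simulate / dedup / call / report pipeline
#'
#' Composite entry point wiring the modules in pipeline order. Input is
#' either a simulation config (`sim`) or a pileup file plus sample manifest
#' (`pileup_path`, `samples`); the manifest must name exactly one control.
#' Stages: PCR-duplicate metrics (when read pairs are simulated or
#' supplied), population-scale mutation calling, spectrum summary, and
#' optional CSV/SQLite export.
#'
#' @param config a list with components:
#'   * `sim`: a [sim_config()] (simulation mode), or
#'   * `pileup_path` + `samples` (data.frame `sample_id`, `is_control`)
#'     (file mode);
#'   * `caller`: a [caller_config()] (default [caller_config()]);
#'   * `read_pairs`: logical, simulate and dedup read pairs (default FALSE);
#'   * `out_dir`: optional output directory for `calls.csv`,
#'     `mutations.csv`, `mutations.sqlite` and `summary.json`.
#' @return a summary list (`n_calls`, `cg_ta_fraction`, `het_hom_ratio`,
#'   `mutations_per_mbp`, `dedup_rate`, `per_sample`) with the full `calls`,
#'   `stats` and (simulation mode) `truth` attached.
#' @export
run_pipeline <- function(config) {
  cfg <- config$caller %||% caller_config()
  truth <- NULL
  pairs <- NULL
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim, read_pairs = isTRUE(config$read_pairs))
    pileup <- ds$pileup
    truth <- ds$truth
    pairs <- ds$pairs
    reference <- ds$reference
    control_id <- "control"
  } else {
    if (is.null(config$pileup_path) || is.null(config$samples)) {
      stop("config needs either 'sim' or 'pileup_path' + 'samples'")
    }
    manifest <- config$samples
    if (sum(manifest$is_control) != 1L) {
      stop("sample manifest must name exactly one control sample")
    }
    control_id <- manifest$sample_id[manifest$is_control]
    pileup <- read_pileup(config$pileup_path, manifest$sample_id,
                          min_mapq = cfg$min_mapq)
    reference <- if (!is.null(config$reference_path))
      read_contig_fasta(config$reference_path) else NULL
  }

  dd_rate <- NA_real_
  if (!is.null(pairs)) {
    marked <- mark_duplicates(pairs)
    dd_rate <- dedup_rate(marked)
  }

  res <- call_population(pileup, cfg, control_id)
  stats <- summarize_calls(res$calls, callable_bp = res$callable$total,
                           per_sample_callable = res$callable$per_sample)

  summary <- list(
    n_calls = stats$n_total,
    n_het = stats$n_het,
    n_hom = stats$n_hom,
    cg_ta_fraction = stats$cg_ta_fraction,
    het_hom_ratio = stats$het_hom_ratio,
    mutations_per_mbp = stats$mutations_per_mbp,
    dedup_rate = dd_rate,
    callable_bp = res$callable$total,
    per_sample = stats$per_sample)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$calls, file.path(config$out_dir, "calls.csv"),
              row.names = FALSE)
    if (!is.null(reference) && nrow(res$calls)) {
      rec <- as_mutation_records(res$calls, reference)
      export_mutation_csv(rec, file.path(config$out_dir, "mutations.csv"))
      export_sqlite(rec, file.path(config$out_dir, "mutations.sqlite"))
    }
    jsonlite::write_json(summary[names(summary) != "per_sample"],
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  c(summary, list(calls = res$calls, stats = stats, truth = truth))
}

#' Compare a call set with a simulation truth table
#'
#' Scores calls against induced (non-varietal) truth mutations whose carrier
#' support could plausibly reach the calling threshold. A call matches a
#' truth record on (line, contig, position, mutant allele).
#'
#' @param calls calls from [call_population()].
#' @param truth truth table from [simulate_population()].
#' @param min_support only truth mutations whose carrier support reached
#'   this many reads count toward recall; requires `pileup` (default 0:
#'   all truth records count).
#' @param pileup the simulated `tc_pileup`, needed when `min_support > 0`.
#' @return list `recall`, `precision`, `zygosity_accuracy`, `n_truth`,
#'   `n_calls`, `n_true_positive`.
#' @export
score_calls <- function(calls, truth, min_support = 0L, pileup = NULL) {
  tr <- truth[!truth$is_varietal_snp, , drop = FALSE]
  if (min_support > 0L) {
    stopifnot(!is.null(pileup))
    gidx <- setNames(seq_len(nrow(pileup$sites)),
                     paste(pileup$sites$contig_id, pileup$sites$pos))
    supp <- vapply(seq_len(nrow(tr)), function(k) {
      i <- gidx[[paste(tr$contig_id[k], tr$pos[k])]]
      pileup$counts[[tr$line_id[k]]][i, tr$mutant_allele[k]]
    }, integer(1))
    tr <- tr[supp >= min_support, , drop = FALSE]
  }
  key_t <- paste(tr$line_id, tr$contig_id, tr$pos, tr$mutant_allele)
  key_c <- paste(calls$sample_id, calls$contig_id, calls$pos,
                 calls$mutant_allele)
  tp <- key_c %in% key_t
  zyg_truth <- setNames(tr$zygosity, key_t)
  zacc <- if (any(tp))
    mean(calls$zygosity[tp] == zyg_truth[key_c[tp]]) else NA_real_
  list(recall = if (nrow(tr)) mean(key_t %in% key_c) else NA_real_,
       precision = if (nrow(calls)) mean(tp) else NA_real_,
       zygosity_accuracy = zacc,
       n_truth = nrow(tr), n_calls = nrow(calls),
       n_true_positive = sum(tp))
}
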
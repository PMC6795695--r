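#' Summarise a mutation call set into population statistics
#'
#' Computes the mutation spectrum (counts per kind / control base / mutant
#' allele), the canonical-EMS (CG-to-TA) fraction, heterozygous and
#' homozygous totals and their ratio, the mutation rate per Mbp, and
#' per-sample summaries. The rate denominator is the callable space: the
#' number of (sample, position) pairs covered deeply enough to call a
#' mutation, as returned by [call_population()].
#'
#' @param calls a mutation-call data.frame (see [call_position()]); an
#'   optional missing/`NA` `zygosity` is tolerated and excluded from the
#'   het/hom totals.
#' @param callable_bp callable denominator in bases (summed over mutant
#'   samples); `NULL` suppresses the rate.
#' @param per_sample_callable optional named vector of per-sample callable
#'   bases for per-sample rates.
#' @return a `population_stats` list: `type_counts` (data.frame
#'   `mutation_kind`, `control_base`, `mutant_allele`, `n`), `n_total`,
#'   `n_het`, `n_hom`, `cg_ta_fraction`, `het_hom_ratio`,
#'   `mutations_per_mbp`, `per_sample`.
#' @export
summarize_calls <- function(calls, callable_bp = NULL,
                            per_sample_callable = NULL) {
  n_total <- nrow(calls)
  if (n_total) {
    tc <- aggregate(list(n = rep(1L, n_total)),
                    by = list(mutation_kind = calls$mutation_kind,
                              control_base = calls$control_base,
                              mutant_allele = calls$mutant_allele),
                    FUN = sum)
    tc <- tc[order(tc$mutation_kind, tc$control_base, tc$mutant_allele), ]
    rownames(tc) <- NULL
  } else {
    tc <- data.frame(mutation_kind = character(), control_base = character(),
                     mutant_allele = character(), n = integer(),
                     stringsAsFactors = FALSE)
  }
  n_het <- sum(calls$zygosity == "heterozygous", na.rm = TRUE)
  n_hom <- sum(calls$zygosity == "homozygous", na.rm = TRUE)
  n_cgta <- sum(calls$mutation_kind == "substitution" &
                  ((calls$control_base == "C" & calls$mutant_allele == "T") |
                     (calls$control_base == "G" & calls$mutant_allele == "A")))
  per_sample <- NULL
  if (n_total) {
    per_sample <- aggregate(
      list(n_calls = rep(1L, n_total)),
      by = list(sample_id = calls$sample_id), FUN = sum)
    if (!is.null(per_sample_callable)) {
      per_sample$callable_bp <-
        as.numeric(per_sample_callable[per_sample$sample_id])
      per_sample$mutations_per_mbp <-
        per_sample$n_calls / (per_sample$callable_bp / 1e6)
    }
  }
  structure(list(
    type_counts = tc,
    n_total = n_total,
    n_het = n_het,
    n_hom = n_hom,
    cg_ta_fraction = if (n_total) n_cgta / n_total else NA_real_,
    het_hom_ratio = if (n_hom > 0) n_het / n_hom else NA_real_,
    mutations_per_mbp = if (!is.null(callable_bp) && callable_bp > 0)
      n_total / (callable_bp / 1e6) else NA_real_,
    per_sample = per_sample), class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("population_stats: %d mutations (%d het, %d hom)\n",
              x$n_total, x$n_het, x$n_hom))
  if (!is.na(x$cg_ta_fraction))
    cat(sprintf("  CG->TA fraction: %.1f%%\n", 100 * x$cg_ta_fraction))
  if (!is.na(x$het_hom_ratio))
    cat(sprintf("  het:hom ratio:   %.2f\n", x$het_hom_ratio))
  if (!is.na(x$mutations_per_mbp))
    cat(sprintf("  mutations/Mbp:   %.2f\n", x$mutations_per_mbp))
  invisible(x)
}

#' Expand a per-type spectrum table into a mutation-call skeleton
#'
#' Convenience inverse of the `type_counts` component of
#' [summarize_calls()]: repeats each (kind, from, to) row `n` times so that
#' published spectrum tables can be fed through the same summary code path.
#' Zygosity can be supplied as het/hom totals, assigned arbitrarily across
#' rows (the spectrum statistics do not depend on which rows are which).
#'
#' @param type_counts data.frame `mutation_kind`, `control_base`,
#'   `mutant_allele`, `n`.
#' @param n_het,n_hom optional zygosity totals (must sum to `sum(n)`).
#' @return a mutation-call data.frame accepted by [summarize_calls()].
#' @export
calls_from_spectrum <- function(type_counts, n_het = NA, n_hom = NA) {
  idx <- rep(seq_len(nrow(type_counts)), type_counts$n)
  n <- length(idx)
  zyg <- rep(NA_character_, n)
  if (!is.na(n_het) && !is.na(n_hom)) {
    stopifnot(n_het + n_hom == n)
    zyg <- rep(c("heterozygous", "homozygous"), c(n_het, n_hom))
  }
  data.frame(sample_id = NA_character_, contig_id = NA_character_,
             pos = NA_integer_,
             mutation_kind = type_counts$mutation_kind[idx],
             control_base = type_counts$control_base[idx],
             mutant_allele = type_counts$mutant_allele[idx],
             zygosity = zyg, mut_support = NA_integer_,
             sample_depth = NA_integer_,
             is_canonical_ems = type_counts$mutation_kind[idx] == "substitution" &
               ((type_counts$control_base[idx] == "C" &
                   type_counts$mutant_allele[idx] == "T") |
                  (type_counts$control_base[idx] == "G" &
                     type_counts$mutant_allele[idx] == "A")),
             stringsAsFactors = FALSE)
}

#' Count calls by zygosity across support thresholds
#'
#' The stringency sweep: for each minimum mutant-allele coverage, how many
#' heterozygous and homozygous calls survive. Raising the threshold trades
#' sensitivity for a lower false-positive rate, and the shape of these
#' curves (together with the CG-to-TA fraction) guides the choice of the
#' final cutoff.
#'
#' @param calls a mutation-call data.frame with `mut_support` and `zygosity`.
#' @param support_values integer thresholds to evaluate.
#' @return data.frame `min_support`, `n_het`, `n_hom`, `n_total`; both
#'   zygosity series are non-increasing in the threshold.
#' @export
coverage_sweep <- function(calls, support_values = 3:15) {
  res <- lapply(sort(support_values), function(t) {
    keep <- calls$mut_support >= t
    data.frame(min_support = t,
               n_het = sum(keep & calls$zygosity == "heterozygous", na.rm = TRUE),
               n_hom = sum(keep & calls$zygosity == "homozygous", na.rm = TRUE),
               n_total = sum(keep))
  })
  do.call(rbind, res)
}

#' Extract the flanking sequence around a mutation
#'
#' Returns up to `max_flank` reference bases on either side of the mutated
#' position, truncated at contig boundaries, with the position itself
#' rendered as a `[control/mutant]` marker (`[G/A]` for a substitution,
#' `[G/-]` for a deletion) — the form used for primer design and database
#' display.
#'
#' @param calls one or more mutation-call rows (`contig_id`, `pos`,
#'   `control_base`, `mutant_allele`).
#' @param contigs a reference-contig table.
#' @param min_flank sides shorter than this raise the `short_flank` flag
#'   (default 50).
#' @param max_flank maximum bases per side (default 200).
#' @return data.frame `flanking_sequence`, `left_len`, `right_len`,
#'   `short_flank`.
#' @export
extract_flanks <- function(calls, contigs, min_flank = 50L, max_flank = 200L) {
  seqs <- setNames(contigs$sequence, contigs$contig_id)
  s <- seqs[calls$contig_id]
  if (anyNA(s)) stop("unknown contig_id: ",
                     calls$contig_id[which(is.na(s))[1]])
  len <- nchar(s)
  if (any(calls$pos < 1L | calls$pos > len)) {
    bad <- which(calls$pos < 1L | calls$pos > len)[1]
    stop(sprintf("position %d outside contig %s (length %d)",
                 calls$pos[bad], calls$contig_id[bad], len[bad]))
  }
  left_start <- pmax(1L, calls$pos - max_flank)
  right_end <- pmin(len, calls$pos + max_flank)
  left <- stringi::stri_sub(s, left_start, calls$pos - 1L)
  right <- stringi::stri_sub(s, calls$pos + 1L, right_end)
  mut <- ifelse(calls$mutant_allele == "DEL", "-", calls$mutant_allele)
  data.frame(
    flanking_sequence = paste0(left, "[", calls$control_base, "/", mut, "]",
                               right),
    left_len = nchar(left),
    right_len = nchar(right),
    short_flank = nchar(left) < min_flank | nchar(right) < min_flank,
    stringsAsFactors = FALSE)
}

#' Build database-ready mutation records
#'
#' Joins calls with the reference to add flanking sequences and the
#' chromosome location carried in contig provenance (`unplaced` for de-novo
#' or simulated contigs).
#'
#' @param calls a mutation-call data.frame.
#' @param contigs a reference-contig table.
#' @param min_flank,max_flank see [extract_flanks()].
#' @return data.frame with columns `mutant_id`, `contig_id`, `pos`,
#'   `mutation_type`, `control_call`, `mutant_call`, `zygosity`,
#'   `chromosome_location`, `mut_depth`, `flanking_sequence`.
#' @export
as_mutation_records <- function(calls, contigs, min_flank = 50L,
                                max_flank = 200L) {
  fl <- extract_flanks(calls, contigs, min_flank, max_flank)
  loc <- setNames(ifelse(is.na(contigs$source_chrom) |
                           contigs$source %in% c("denovo", "simulated"),
                         "unplaced", contigs$source_chrom),
                  contigs$contig_id)
  data.frame(mutant_id = calls$sample_id,
             contig_id = calls$contig_id,
             pos = calls$pos,
             mutation_type = calls$mutation_kind,
             control_call = calls$control_base,
             mutant_call = ifelse(calls$mutant_allele == "DEL", "-",
                                  calls$mutant_allele),
             zygosity = calls$zygosity,
             chromosome_location = unname(loc[calls$contig_id]),
             mut_depth = calls$mut_support,
             flanking_sequence = fl$flanking_sequence,
             stringsAsFactors = FALSE)
}

MUTATION_RECORD_FIELDS <- c("mutant_id", "contig_id", "pos", "mutation_type",
                            "control_call", "mutant_call", "zygosity",
                            "chromosome_location", "mut_depth",
                            "flanking_sequence")

#' Write / read the mutation-record CSV
#'
#' Fixed header, comma separated, UTF-8, quoting only where needed — the
#' interchange format the SQLite loader consumes.
#'
#' @param records mutation records (see [as_mutation_records()]).
#' @param path output path.
#' @return `path` invisibly (`export_mutation_csv`); the records data.frame
#'   (`read_mutation_csv`).
#' @export
export_mutation_csv <- function(records, path) {
  miss <- setdiff(MUTATION_RECORD_FIELDS, names(records))
  if (length(miss)) stop("mutation records missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in MUTATION_RECORD_FIELDS) {
    bad <- which(is.na(records[[col]]))
    if (length(bad) && col != "zygosity") {
      stop(sprintf("missing value in row %d, column %s", bad[1], col))
    }
  }
  write.csv(records[, MUTATION_RECORD_FIELDS, drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_mutation_csv
#' @export
read_mutation_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(pos = "integer", mut_depth = "integer"))
}
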
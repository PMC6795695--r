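#' Simulation configuration for a synthetic M2 exome-capture population
#'
#' The defaults emulate the study conditions of a durum wheat EMS TILLING
#' population sequenced by exome capture: 40 mutant lines, a deeply
#' sequenced unmutagenized control (mean 29.5 reads/base), per-line mean
#' depths drawn from 1.2-11.3 (set `mutant_depth_mean` to a fixed value,
#' e.g. 30, for power analyses), a mutation rate of 20 per Mbp, 98%
#' canonical EMS transitions (C-to-T / G-to-A), a 2:1
#' heterozygous:homozygous expectation (`p_het = 2/3`), rare small
#' deletions, a 0.2% per-read sequencing error rate, 5% PCR duplicates and
#' 50 varietal SNPs per Mbp shared by the control and every line.
#'
#' @param n_contigs,contig_length_bp reference size (default 200 x 2000 bp).
#' @param n_lines number of mutant lines (default 40).
#' @param control_depth_mean mean control depth (default 29.5).
#' @param mutant_depth_mean fixed mean depth for every line, or `NULL`
#'   (default) to sample per-line means from `mutant_depth_mean_range`.
#' @param mutant_depth_mean_range range of per-line mean depths (default
#'   `c(1.2, 11.3)`).
#' @param mutation_rate_per_mbp induced mutations per line per Mbp
#'   (default 20).
#' @param p_canonical_ems probability a substitution is a canonical EMS
#'   transition (default 0.98).
#' @param p_het probability a mutation is heterozygous (default 2/3).
#' @param p_deletion probability a mutation is a small deletion
#'   (default 0.001).
#' @param seq_error_rate per-read miscall probability (default 0.002).
#' @param pcr_dup_rate PCR duplicate fraction for read-pair simulation
#'   (default 0.05).
#' @param varietal_snp_rate_per_mbp shared line-vs-reference SNPs per Mbp
#'   (default 50).
#' @param gc reference GC content (default 0.5).
#' @param seed RNG seed used by [simulate_dataset()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_contigs = 200L, contig_length_bp = 2000L,
                       n_lines = 40L, control_depth_mean = 29.5,
                       mutant_depth_mean = NULL,
                       mutant_depth_mean_range = c(1.2, 11.3),
                       mutation_rate_per_mbp = 20,
                       p_canonical_ems = 0.98, p_het = 2 / 3,
                       p_deletion = 0.001, seq_error_rate = 0.002,
                       pcr_dup_rate = 0.05,
                       varietal_snp_rate_per_mbp = 50,
                       gc = 0.5, seed = 1L) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length_bp = as.integer(contig_length_bp),
              n_lines = as.integer(n_lines),
              control_depth_mean = control_depth_mean,
              mutant_depth_mean = mutant_depth_mean,
              mutant_depth_mean_range = mutant_depth_mean_range,
              mutation_rate_per_mbp = mutation_rate_per_mbp,
              p_canonical_ems = p_canonical_ems, p_het = p_het,
              p_deletion = p_deletion, seq_error_rate = seq_error_rate,
              pcr_dup_rate = pcr_dup_rate,
              varietal_snp_rate_per_mbp = varietal_snp_rate_per_mbp,
              gc = gc, seed = as.integer(seed))
  probs <- c(cfg$p_canonical_ems, cfg$p_het, cfg$p_deletion,
             cfg$seq_error_rate, cfg$pcr_dup_rate, cfg$gc)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$mutation_rate_per_mbp >= 0,
            cfg$varietal_snp_rate_per_mbp >= 0)
  structure(cfg, class = "sim_config")
}

#' Expected CG-to-TA fraction among simulated substitutions
#'
#' Non-canonical substitutions pick a uniform site and a uniform non-reference
#' base, so they land on a canonical change with probability `gc / 3`;
#' deletions never count.
#'
#' @param cfg a [sim_config()].
#' @return expected fraction of all mutations that are canonical EMS
#'   transitions.
#' @export
expected_cg_ta <- function(cfg) {
  (1 - cfg$p_deletion) *
    (cfg$p_canonical_ems + (1 - cfg$p_canonical_ems) * cfg$gc / 3)
}

#' Simulate a random reference
#'
#' @param cfg a [sim_config()].
#' @return a reference-contig table with source `simulated`.
#' @export
simulate_reference <- function(cfg = sim_config()) {
  if (cfg$n_contigs == 0L) return(reference_contigs(character(), character()))
  p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
         T = (1 - cfg$gc) / 2)
  seqs <- vapply(seq_len(cfg$n_contigs), function(i) {
    paste(sample(BASES, cfg$contig_length_bp, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  reference_contigs(contig_id = sprintf("ctg%06d", seq_len(cfg$n_contigs)),
                    sequence = seqs, source = "simulated")
}

#' Simulate the mutation truth table of an M2 population
#'
#' Each line receives `Poisson(rate x genome_Mbp)` induced mutations at
#' unique positions. With probability `p_deletion` a mutation is a deletion
#' of the reference base; otherwise with probability `p_canonical_ems` it is
#' a canonical EMS transition placed on a C or G site (C-to-T / G-to-A), and
#' with the remaining probability a uniform substitution at a uniform site.
#' Zygosity is heterozygous with probability `p_het`. Varietal SNPs —
#' polymorphisms between the study line and the reference accession — are
#' placed once and shared by the control and every line (`line_id = NA`,
#' `is_varietal_snp = TRUE`).
#'
#' @param reference a reference-contig table.
#' @param cfg a [sim_config()].
#' @return a truth data.frame: `line_id`, `contig_id`, `pos`,
#'   `control_base`, `mutant_allele`, `zygosity`, `is_varietal_snp`.
#' @export
simulate_population <- function(reference, cfg = sim_config()) {
  seq_all <- paste(reference$sequence, collapse = "")
  total_bp <- nchar(seq_all)
  mbp <- total_bp / 1e6
  contig_of <- rep(reference$contig_id, nchar(reference$sequence))
  pos_of <- sequence(nchar(reference$sequence))
  base_of <- stringi::stri_sub(seq_all, 1:total_bp, 1:total_bp)
  cg_sites <- which(base_of %in% c("C", "G"))
  line_ids <- sprintf("line%03d", seq_len(cfg$n_lines))

  truth_row <- function(line, idx, allele, zyg, varietal = FALSE) {
    k <- length(idx)
    data.frame(line_id = rep_len(line, k), contig_id = contig_of[idx],
               pos = pos_of[idx], control_base = base_of[idx],
               mutant_allele = allele,
               zygosity = rep_len(zyg, k),
               is_varietal_snp = rep_len(varietal, k),
               stringsAsFactors = FALSE)
  }

  # shared varietal SNPs
  n_var <- rpois(1L, cfg$varietal_snp_rate_per_mbp * mbp)
  var_idx <- if (n_var > 0L) sample(total_bp, min(n_var, total_bp)) else integer()
  var_alt <- vapply(var_idx, function(i) sample(setdiff(BASES, base_of[i]), 1L),
                    character(1))
  out <- list()
  if (length(var_idx)) {
    out[[1L]] <- truth_row(NA_character_, var_idx, var_alt, "homozygous",
                           varietal = TRUE)
  }

  for (line in line_ids) {
    n_mut <- rpois(1L, cfg$mutation_rate_per_mbp * mbp)
    if (n_mut == 0L) next
    is_del <- runif(n_mut) < cfg$p_deletion
    is_can <- !is_del & runif(n_mut) < cfg$p_canonical_ems
    n_can <- sum(is_can)
    n_other <- n_mut - n_can
    if (n_can > length(cg_sites)) {
      stop("mutation rate exhausts the available C/G sites")
    }
    idx_can <- if (n_can) sample(cg_sites, n_can) else integer()
    idx_other <- if (n_other) sample(total_bp, n_other) else integer()
    # enforce unique positions per line (and avoid varietal sites)
    taken <- c(var_idx, idx_can)
    clash <- idx_other %in% taken | duplicated(idx_other)
    idx_other <- idx_other[!clash]
    can_clash <- idx_can %in% var_idx
    idx_can <- idx_can[!can_clash]

    allele_can <- ifelse(base_of[idx_can] == "C", "T", "A")
    allele_other <- character(length(idx_other))
    del_pool <- which(is_del)
    n_del <- min(length(del_pool), length(idx_other))
    if (length(idx_other)) {
      is_del_row <- seq_along(idx_other) <= n_del
      allele_other[is_del_row] <- "DEL"
      for (j in which(!is_del_row)) {
        allele_other[j] <- sample(setdiff(BASES, base_of[idx_other[j]]), 1L)
      }
    }
    idx <- c(idx_can, idx_other)
    allele <- c(allele_can, allele_other)
    zyg <- ifelse(runif(length(idx)) < cfg$p_het, "heterozygous", "homozygous")
    out[[length(out) + 1L]] <- truth_row(line, idx, allele, zyg)
  }
  truth <- if (length(out)) do.call(rbind, out) else
    truth_row(character(), integer(), character(), character())
  rownames(truth) <- NULL
  truth
}

#' Simulate a multi-sample pileup from a truth table
#'
#' Per position and sample, depth is Poisson with the sample's mean; allele
#' counts are multinomial around the truth: a homozygous carrier reads the
#' mutant allele at `1 - e`, a heterozygous carrier at 0.5, non-carriers
#' read the reference at `1 - e`, with the sequencing-error mass `e` spread
#' uniformly over the three other bases. Varietal SNPs are applied to the
#' control and all lines as homozygous alternate alleles. Sample order is
#' the control (`control`) followed by the mutant lines.
#'
#' @param reference a reference-contig table.
#' @param truth a truth table from [simulate_population()].
#' @param cfg a [sim_config()].
#' @return a `tc_pileup`; its `depth_means` attribute records the per-sample
#'   mean depths used.
#' @export
simulate_pileup <- function(reference, truth, cfg = sim_config()) {
  n <- sum(nchar(reference$sequence))
  sites <- data.frame(
    contig_id = rep(reference$contig_id, nchar(reference$sequence)),
    pos = sequence(nchar(reference$sequence)),
    ref_base = stringi::stri_sub(paste(reference$sequence, collapse = ""),
                                 1:n, 1:n),
    stringsAsFactors = FALSE)
  gidx <- seq_len(n)
  names(gidx) <- paste(sites$contig_id, sites$pos)
  line_ids <- sprintf("line%03d", seq_len(cfg$n_lines))
  samples <- c("control", line_ids)
  means <- c(cfg$control_depth_mean,
             if (!is.null(cfg$mutant_depth_mean))
               rep(cfg$mutant_depth_mean, cfg$n_lines)
             else runif(cfg$n_lines, cfg$mutant_depth_mean_range[1],
                        cfg$mutant_depth_mean_range[2]))
  names(means) <- samples
  ridx <- match(sites$ref_base, BASES)
  eps <- cfg$seq_error_rate

  var_rows <- which(truth$is_varietal_snp)
  var_gi <- gidx[paste(truth$contig_id[var_rows], truth$pos[var_rows])]

  counts <- vector("list", length(samples))
  names(counts) <- samples
  for (s in samples) {
    depth <- rpois(n, means[[s]])
    m <- matrix(0L, n, 6L, dimnames = list(NULL, ALLELES))
    # baseline: reference reads with uniform errors over the 3 other bases
    nerr <- rbinom(n, depth, eps)
    e1 <- rbinom(n, nerr, 1 / 3)
    e2 <- rbinom(n, nerr - e1, 1 / 2)
    e3 <- nerr - e1 - e2
    others <- matrix(0L, n, 4L)
    for (b in 1:4) {
      slot <- ((b - ridx) %% 4L)        # 1..3 index among the other bases
      others[cbind(which(slot == 1L), b)] <- e1[slot == 1L]
      others[cbind(which(slot == 2L), b)] <- e2[slot == 2L]
      others[cbind(which(slot == 3L), b)] <- e3[slot == 3L]
    }
    m[, 1:4] <- others
    m[cbind(gidx, ridx)] <- m[cbind(gidx, ridx)] + depth - nerr

    # varietal SNPs: every sample (control included) is homozygous alternate
    if (length(var_gi)) {
      for (k in seq_along(var_gi)) {
        i <- var_gi[k]
        m[i, ] <- sim_cell(depth[i], truth$mutant_allele[var_rows[k]],
                           sites$ref_base[i], "homozygous", eps)
      }
    }
    # this line's induced mutations
    if (s != "control") {
      rows <- which(!truth$is_varietal_snp & truth$line_id == s)
      gi <- gidx[paste(truth$contig_id[rows], truth$pos[rows])]
      for (k in seq_along(gi)) {
        i <- gi[k]
        m[i, ] <- sim_cell(depth[i], truth$mutant_allele[rows[k]],
                           sites$ref_base[i], truth$zygosity[rows[k]], eps)
      }
    }
    counts[[s]] <- m
  }
  pu <- new_pileup(sites, counts)
  attr(pu, "depth_means") <- means
  pu
}

# Multinomial allele counts for one carrier cell. True reads are mutant
# (fraction 1 for hom, 0.5 for het) or reference; each base read is misread
# with probability eps, uniformly over the three other bases. DEL reads are
# not subject to miscalls.
sim_cell <- function(depth, mut_allele, ref_base, zygosity, eps) {
  out <- setNames(integer(6L), ALLELES)
  if (depth == 0L) return(out)
  f <- if (zygosity == "homozygous") 1 else 0.5
  p <- setNames(numeric(6L), ALLELES)
  add_reads <- function(p, allele, mass) {
    if (allele == "DEL") {
      p[["DEL"]] <- p[["DEL"]] + mass
    } else {
      p[[allele]] <- p[[allele]] + mass * (1 - eps)
      for (b in setdiff(BASES, allele)) p[[b]] <- p[[b]] + mass * eps / 3
    }
    p
  }
  p <- add_reads(p, mut_allele, f)
  p <- add_reads(p, ref_base, 1 - f)
  setNames(as.integer(rmultinom(1L, depth, p)), ALLELES)
}

#' Simulate coordinate-sorted read pairs with injected PCR duplicates
#'
#' Unique fragments (~300 bp, the typical library insert) are laid at
#' distinct positions; each emitted pair is, with probability
#' `cfg$pcr_dup_rate`, a PCR copy of a previously emitted unique fragment
#' (same coordinates and orientation, fresh name and qualities). The truth
#' count of unique fragments is recorded in the `n_unique` attribute.
#'
#' @param reference a reference-contig table.
#' @param cfg a [sim_config()].
#' @param n_pairs total pairs to emit (default 10000).
#' @param read_len read length (default 100).
#' @return read-pair records sorted by `(contig_id, left_start_1)`.
#' @export
simulate_read_pairs <- function(reference, cfg = sim_config(),
                                n_pairs = 10000L, read_len = 100L) {
  if (n_pairs == 0L) {
    return(read_pair_records(character(), character(), integer(), integer(),
                             character(), integer()))
  }
  lens <- setNames(nchar(reference$sequence), reference$contig_id)
  is_dup <- runif(n_pairs) < cfg$pcr_dup_rate
  is_dup[1L] <- FALSE
  n_uniq <- sum(!is_dup)
  frag <- pmax(2L * read_len, as.integer(round(rnorm(n_uniq, 300, 30))))
  ctg <- sample(reference$contig_id, n_uniq, replace = TRUE)
  start <- vapply(seq_len(n_uniq), function(i) {
    sample.int(max(1L, lens[[ctg[i]]] - frag[i]), 1L)
  }, integer(1))
  # distinct duplicate keys for unique fragments: perturb collisions
  key <- paste(ctg, start, frag)
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))
    frag[i] <- frag[i] + 1L
    key <- paste(ctg, start, frag)
  }
  uniq <- data.frame(contig_id = ctg, left_start_1 = start,
                     left_start_2 = start + frag - read_len,
                     stringsAsFactors = FALSE)
  src <- integer(n_pairs)
  src[!is_dup] <- seq_len(n_uniq)
  for (i in which(is_dup)) {
    src[i] <- src[sample.int(i - 1L, 1L)]
  }
  pairs <- read_pair_records(
    query_name = sprintf("frag%06d", seq_len(n_pairs)),
    contig_id = uniq$contig_id[src],
    left_start_1 = uniq$left_start_1[src],
    left_start_2 = uniq$left_start_2[src],
    orientation = "FR",
    base_quality_sum = as.integer(round(runif(n_pairs, 2000, 8000))))
  pairs <- pairs[order(pairs$contig_id, pairs$left_start_1), ]
  rownames(pairs) <- NULL
  attr(pairs, "n_unique") <- n_uniq
  pairs
}

#' Simulate a complete dataset deterministically
#'
#' Seeds the RNG from `cfg$seed` and runs [simulate_reference()],
#' [simulate_population()], [simulate_pileup()] and (optionally)
#' [simulate_read_pairs()]; identical config and seed give byte-identical
#' outputs.
#'
#' @param cfg a [sim_config()].
#' @param read_pairs also simulate duplicated read pairs (default `FALSE`).
#' @param n_pairs pairs to simulate when `read_pairs` is `TRUE`.
#' @return list `reference`, `truth`, `pileup`, and optionally `pairs`.
#' @export
simulate_dataset <- function(cfg = sim_config(), read_pairs = FALSE,
                             n_pairs = 10000L) {
  set.seed(cfg$seed)
  reference <- simulate_reference(cfg)
  truth <- simulate_population(reference, cfg)
  pileup <- simulate_pileup(reference, truth, cfg)
  out <- list(reference = reference, truth = truth, pileup = pileup)
  if (read_pairs) out$pairs <- simulate_read_pairs(reference, cfg, n_pairs)
  out
}
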
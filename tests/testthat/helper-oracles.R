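# Independent brute-force reference implementations used as oracles.
# These deliberately re-derive results position by position / column by
# column, sharing no code with the package's vectorised paths.

# -- pileup: independent naive encoder of one column's counts ---------------
# Emits symbols in random order with random case, read start/end markers and
# indel tokens, exercising every token the dialect allows.
naive_encode_column <- function(counts, ref_base) {
  syms <- character(0)
  for (a in c("A", "C", "G", "T")) {
    k <- counts[[a]]
    if (k == 0L) next
    if (a == ref_base) {
      syms <- c(syms, sample(c(".", ","), k, replace = TRUE))
    } else {
      syms <- c(syms, sample(c(a, tolower(a)), k, replace = TRUE))
    }
  }
  syms <- c(syms, rep("*", counts[["DEL"]]))
  kN <- counts[["N"]]
  if (kN > 0L) {
    pool <- if (ref_base == "N") c(".", ",", "N", "n") else c("N", "n")
    syms <- c(syms, sample(pool, kN, replace = TRUE))
  }
  if (!length(syms)) return("")
  syms <- sample(syms)
  decorated <- vapply(syms, function(x) {
    pre <- if (runif(1) < 0.15) paste0("^", intToUtf8(sample(33:126, 1))) else ""
    ind <- if (runif(1) < 0.10) {
      n <- sample(1:3, 1)
      paste0(sample(c("+", "-"), 1), n,
             paste(sample(c("A", "C", "G", "T", "a", "t"), n, replace = TRUE),
                   collapse = ""))
    } else ""
    post <- if (runif(1) < 0.15) "$" else ""
    paste0(pre, x, ind, post)
  }, character(1), USE.NAMES = FALSE)
  paste(decorated, collapse = "")
}

# -- region builder: mark, dilate, union ------------------------------------
oracle_regions <- function(depth, cfg, chrom_length = length(depth)) {
  marked <- which(depth >= cfg$min_depth)
  if (!length(marked)) return(data.frame(start = integer(), end = integer()))
  covered <- logical(chrom_length)
  for (p in marked) {
    covered[max(1L, p - cfg$flank):min(chrom_length, p + cfg$flank)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    gap <- iv$start[i] - out$end[nrow(out)] - 1L
    if (gap < cfg$merge_gap) {
      out$end[nrow(out)] <- iv$end[i]
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

# -- caller: literal enumeration of every (position, allele, sample) --------
oracle_call_pileup <- function(pileup, cfg, control_id) {
  mutants <- setdiff(pileup$samples, control_id)
  cube <- simplify2array(pileup$counts)   # n x 6 x S
  ctrl_k <- match(control_id, pileup$samples)
  mut_k <- match(mutants, pileup$samples)
  acc <- list()
  for (i in seq_len(nrow(pileup$sites))) {
    ref <- pileup$sites$ref_base[i]
    if (ref == "N") next
    ctrl <- cube[i, , ctrl_k]
    d <- sum(ctrl[1:5])
    if (d == 0) next
    if (ctrl[[ref]] < max(ctrl[1:5])) next
    if ((d - ctrl[[ref]]) / d > cfg$control_max_minor_fraction) next
    for (a in setdiff(c("A", "C", "G", "T", "DEL"), ref)) {
      pres <- integer(0)
      for (k in seq_along(mut_k)) {
        if (cube[i, a, mut_k[k]] >= cfg$presence_min_reads) pres <- c(pres, k)
      }
      if (length(pres) != 1L) next
      supp <- cube[i, a, mut_k[pres]]
      if (supp < cfg$min_mut_support) next
      ninf <- 0L
      for (k in seq_along(mut_k)[-pres]) {
        if (cube[i, ref, mut_k[k]] >= cfg$min_other_depth) ninf <- ninf + 1L
      }
      if (ninf < cfg$min_informative_samples) next
      sd_ <- sum(cube[i, 1:5, mut_k[pres]])
      f <- supp / sd_
      if (f < cfg$het_min_fraction) next
      acc[[length(acc) + 1L]] <- list(
        sample_id = mutants[pres], contig_id = pileup$sites$contig_id[i],
        pos = pileup$sites$pos[i], mutant_allele = a,
        zygosity = if (f >= cfg$hom_min_fraction) "homozygous" else "heterozygous",
        mut_support = as.integer(supp), sample_depth = as.integer(sd_))
    }
  }
  if (!length(acc)) {
    return(data.frame(sample_id = character(), contig_id = character(),
                      pos = integer(), mutant_allele = character(),
                      zygosity = character(), mut_support = integer(),
                      sample_depth = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(acc, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
}

sort_calls <- function(df) {
  df <- df[order(df$contig_id, df$pos, df$mutant_allele, df$sample_id),
           c("sample_id", "contig_id", "pos", "mutant_allele", "zygosity",
             "mut_support", "sample_depth")]
  rownames(df) <- NULL
  df
}
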
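# Programmatic fixtures shared across test files.

# random count matrices with enough structure that candidate alleles,
# shared alleles and control discordance all occur
random_pileup <- function(n_pos = 200L, n_samples = 8L, mean_depth = 12,
                          contig = "ctg000001") {
  samples <- c("control", sprintf("line%03d", seq_len(n_samples - 1L)))
  ref <- sample(c("A", "C", "G", "T"), n_pos, replace = TRUE)
  sites <- data.frame(contig_id = contig, pos = seq_len(n_pos),
                      ref_base = ref, stringsAsFactors = FALSE)
  counts <- lapply(samples, function(s) {
    depth <- rpois(n_pos, mean_depth)
    m <- matrix(0L, n_pos, 6L,
                dimnames = list(NULL, c("A", "C", "G", "T", "DEL", "N")))
    ridx <- match(ref, c("A", "C", "G", "T"))
    m[cbind(seq_len(n_pos), ridx)] <- depth
    # perturb ~20% of cells: move a random share of reads to a random allele
    hit <- which(runif(n_pos) < 0.2 & depth > 0L)
    for (i in hit) {
      a <- sample(setdiff(1:5, ridx[i]), 1L)
      k <- rbinom(1L, depth[i], runif(1L))
      m[i, a] <- m[i, a] + k
      m[i, ridx[i]] <- m[i, ridx[i]] - k
    }
    m
  })
  names(counts) <- samples
  pileup_from_counts(sites, counts)
}

# a single pileup column as used by call_position()
make_column <- function(ref_base, counts_by_sample, contig = "ctg000001",
                        pos = 100L) {
  samples <- names(counts_by_sample)
  cnt <- matrix(0L, length(samples), 6L,
                dimnames = list(samples, c("A", "C", "G", "T", "DEL", "N")))
  for (s in samples) cnt[s, names(counts_by_sample[[s]])] <-
    as.integer(counts_by_sample[[s]])
  list(contig_id = contig, pos = pos, ref_base = ref_base, counts = cnt)
}
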
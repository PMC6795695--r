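#' Parse samtools text-pileup base strings into allele counts
#'
#' Decodes the base-string dialect emitted by `samtools mpileup` (one string
#' per sample per position): `.`/`,` match the reference on either strand,
#' `ACGTacgt` are mismatches, `*` is a deletion of the reference base, `^X`
#' marks a read start (the following character encodes the read's mapping
#' quality and is consumed, not counted), `$` marks a read end, and
#' `+NNseq`/`-NNseq` are indel tokens attached to the preceding read symbol
#' (consumed, never counted — insertions are not called). `<`/`>` (reference
#' skips) and `N`/`n` are tallied as `N`. Case is collapsed: calling is
#' strand-agnostic.
#'
#' @param bases character vector of base strings, one per pileup column.
#' @param depth integer vector of stated read depths, parallel to `bases`.
#' @param ref_base character vector of reference bases (`A`,`C`,`G`,`T`,`N`),
#'   parallel to `bases`; `.`/`,` symbols are credited to this allele (to `N`
#'   when the reference base is `N`).
#' @param line integer vector of source line numbers used in error messages.
#' @return an integer matrix with one row per element of `bases` and columns
#'   `A`, `C`, `G`, `T`, `DEL`, `N`. Per-sample depth in the calling sense is
#'   the row sum over `A`..`DEL` (`N` is excluded).
#' @export
parse_pileup_bases <- function(bases, depth, ref_base,
                               line = seq_along(bases)) {
  n <- length(bases)
  stopifnot(length(depth) == n, length(ref_base) == n)
  out <- matrix(0L, nrow = n, ncol = 6L, dimnames = list(NULL, ALLELES))
  if (n == 0L) return(out)

  s <- bases
  # depth-0 placeholder columns ("*" in both bases and quals)
  zero <- depth == 0L
  s[zero] <- ""
  # read-start markers: '^' plus the mapq character (which may itself be
  # '^', '$' or an indel sign, hence the explicit two-character consume)
  s <- stringi::stri_replace_all_regex(s, "\\^.", "")
  s <- stringi::stri_replace_all_fixed(s, "$", "")
  # indel tokens are rare; handle only the strings that contain them
  has_indel <- stringi::stri_detect_regex(s, "[+-][0-9]")
  if (any(has_indel)) s[has_indel] <- vapply(s[has_indel], strip_indel_tokens,
                                             character(1), USE.NAMES = FALSE)

  up <- stringi::stri_trans_toupper(s)
  nref <- stringi::stri_count_fixed(s, ".") + stringi::stri_count_fixed(s, ",")
  cnt <- sapply(BASES, function(b) stringi::stri_count_fixed(up, b))
  cnt <- matrix(as.integer(cnt), nrow = n, ncol = 4L,
                dimnames = list(NULL, BASES))
  ndel <- stringi::stri_count_fixed(s, "*")
  nn <- stringi::stri_count_fixed(up, "N") +
    stringi::stri_count_fixed(s, "<") + stringi::stri_count_fixed(s, ">")

  total <- as.integer(rowSums(cnt) + nref + ndel + nn)
  bad <- which(total != depth)
  if (length(bad)) {
    stop(sprintf(
      "malformed pileup base string at line %d: %d symbols parsed but stated depth is %d",
      line[bad[1]], total[bad[1]], depth[bad[1]]))
  }

  out[, BASES] <- cnt
  out[, "DEL"] <- ndel
  out[, "N"] <- nn
  # credit reference-matching symbols to the reference allele
  ridx <- match(ref_base, BASES)
  known <- !is.na(ridx)
  if (any(known)) {
    ij <- cbind(which(known), ridx[known])
    out[ij] <- out[ij] + nref[known]
  }
  out[!known, "N"] <- out[!known, "N"] + nref[!known]
  out
}

# Consume "+<len><seq>" / "-<len><seq>" indel tokens from one base string.
strip_indel_tokens <- function(s) {
  repeat {
    m <- stringi::stri_locate_first_regex(s, "[+-][0-9]+")
    if (is.na(m[1, 1])) return(s)
    len <- as.integer(stringi::stri_sub(s, m[1, 1] + 1L, m[1, 2]))
    stringi::stri_sub(s, m[1, 1], m[1, 2] + len) <- ""
  }
}

#' Read a multi-sample samtools text pileup
#'
#' Parses the tab-separated text-pileup form with three leading columns
#' (contig, 1-based position, reference base) followed by one
#' `depth / bases / qualities` triplet per sample. Base qualities are parsed
#' but not used downstream: mutation support is counted from reads alone.
#' Mapping-quality filtering happens when the pileup is generated (e.g.
#' `samtools mpileup -q 2`); the threshold is recorded on the returned object
#' as provenance.
#'
#' @param path path to the pileup file.
#' @param sample_order character vector of sample ids, one per column triplet,
#'   in file order.
#' @param min_mapq minimum mapping quality the pileup was generated with
#'   (metadata; default 2).
#' @return a `tc_pileup` object: a list with `sites` (data.frame `contig_id`,
#'   `pos`, `ref_base`), `counts` (one integer position-by-allele matrix per
#'   sample, columns `A,C,G,T,DEL,N`), `samples`, and `min_mapq`.
#' @export
read_pileup <- function(path, sample_order, min_mapq = 2L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_samples <- length(sample_order)
  if (length(lines) == 0L) {
    return(new_pileup(
      sites = data.frame(contig_id = character(), pos = integer(),
                         ref_base = character(), stringsAsFactors = FALSE),
      counts = setNames(replicate(n_samples, matrix(
        0L, 0L, 6L, dimnames = list(NULL, ALLELES)), simplify = FALSE),
        sample_order),
      min_mapq = min_mapq))
  }
  f <- stringi::stri_split_fixed(lines, "\t", simplify = TRUE)
  expected <- 3L + 3L * n_samples
  if (ncol(f) != expected) {
    stop(sprintf(
      "pileup has %d fields per line but %d samples imply %d (3 + 3 per sample)",
      ncol(f), n_samples, expected))
  }
  sites <- data.frame(contig_id = f[, 1L],
                      pos = as.integer(f[, 2L]),
                      ref_base = stringi::stri_trans_toupper(f[, 3L]),
                      stringsAsFactors = FALSE)
  counts <- vector("list", n_samples)
  names(counts) <- sample_order
  for (k in seq_len(n_samples)) {
    d <- as.integer(f[, 3L * k + 1L])
    counts[[k]] <- parse_pileup_bases(f[, 3L * k + 2L], d, sites$ref_base)
  }
  new_pileup(sites, counts, min_mapq)
}

new_pileup <- function(sites, counts, min_mapq = 2L) {
  structure(list(sites = sites, counts = counts,
                 samples = names(counts), min_mapq = as.integer(min_mapq)),
            class = "tc_pileup")
}

#' Assemble a pileup object from allele-count matrices
#'
#' @param sites data.frame `contig_id`, `pos`, `ref_base`.
#' @param counts named list (one element per sample) of integer matrices
#'   with `nrow(sites)` rows and columns `A,C,G,T,DEL,N`.
#' @param min_mapq mapping-quality provenance (default 2).
#' @return a `tc_pileup`.
#' @export
pileup_from_counts <- function(sites, counts, min_mapq = 2L) {
  stopifnot(is.data.frame(sites),
            all(c("contig_id", "pos", "ref_base") %in% names(sites)),
            length(names(counts)) == length(counts))
  for (m in counts) {
    stopifnot(is.matrix(m), nrow(m) == nrow(sites),
              identical(colnames(m), ALLELES))
  }
  new_pileup(sites, counts, min_mapq)
}

#' @export
print.tc_pileup <- function(x, ...) {
  cat(sprintf("tc_pileup: %d positions x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(head(x$samples, 5), collapse = ", ")))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pileup a `tc_pileup`.
#' @param i row index into `pileup$sites`.
#' @return a list with `contig_id`, `pos`, `ref_base` and `counts`, a
#'   samples-by-allele integer matrix.
#' @export
pileup_column <- function(pileup, i) {
  cnt <- t(vapply(pileup$counts, function(m) m[i, ], integer(6L)))
  colnames(cnt) <- ALLELES
  list(contig_id = pileup$sites$contig_id[i], pos = pileup$sites$pos[i],
       ref_base = pileup$sites$ref_base[i], counts = cnt)
}

#' Write a multi-sample text pileup
#'
#' Encodes a `tc_pileup` back into the text dialect [read_pileup()] parses.
#' Reference-matching reads are split between `.` and `,`, mismatches between
#' upper and lower case, and a fraction of columns carry `^]` read-start and
#' `$` read-end markers so downstream parsers are exercised realistically.
#' Symbol order within a column is arbitrary; counts round-trip exactly.
#' Base qualities are written as constant `I`.
#'
#' @param pileup a `tc_pileup`.
#' @param path output path.
#' @param decorate add read start/end markers to ~10% of sample columns
#'   (default `TRUE`). Uses the ambient RNG stream.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path, decorate = TRUE) {
  n <- nrow(pileup$sites)
  ref <- pileup$sites$ref_base
  cols <- vector("list", length(pileup$counts))
  for (k in seq_along(pileup$counts)) {
    m <- pileup$counts[[k]]
    depth <- as.integer(rowSums(m))          # stated depth includes N reads
    bases <- encode_bases(m, ref, decorate)
    quals <- stringi::stri_dup("I", depth)
    quals[depth == 0L] <- "*"
    bases[depth == 0L] <- "*"
    cols[[k]] <- paste(depth, bases, quals, sep = "\t")
  }
  body <- do.call(paste, c(list(pileup$sites$contig_id, pileup$sites$pos, ref),
                           cols, list(sep = "\t")))
  writeLines(body, path)
  invisible(path)
}

encode_bases <- function(m, ref, decorate) {
  n <- nrow(m)
  ridx <- match(ref, BASES)
  out <- character(n)
  parts <- matrix("", n, 6L)
  for (a in 1:4) {
    cnt <- m[, a]
    is_ref <- !is.na(ridx) & ridx == a
    # reference matches: mix of '.' (forward) and ',' (reverse)
    fwd <- ifelse(is_ref, cnt %/% 2L, 0L)
    rev_ <- ifelse(is_ref, cnt - fwd, 0L)
    mm <- ifelse(is_ref, 0L, cnt)
    mup <- mm %/% 2L
    parts[, a] <- paste0(stringi::stri_dup(".", fwd),
                         stringi::stri_dup(",", rev_),
                         stringi::stri_dup(BASES[a], mup),
                         stringi::stri_dup(tolower(BASES[a]), mm - mup))
  }
  parts[, 5L] <- stringi::stri_dup("*", m[, "DEL"])
  nref_n <- ifelse(is.na(ridx), m[, "N"], 0L)  # ref N: '.' symbols land on N
  other_n <- m[, "N"] - nref_n
  parts[, 6L] <- paste0(stringi::stri_dup(".", nref_n),
                        stringi::stri_dup("N", other_n))
  out <- paste0(parts[, 1L], parts[, 2L], parts[, 3L], parts[, 4L],
                parts[, 5L], parts[, 6L])
  if (decorate) {
    nonempty <- nzchar(out)
    deco <- nonempty & runif(n) < 0.1
    out[deco] <- paste0("^]", out[deco])
    deco2 <- nonempty & runif(n) < 0.1
    out[deco2] <- paste0(out[deco2], "$")
  }
  out
}
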
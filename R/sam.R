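#' Read paired-end alignments from SAM/BAM as read-pair records
#'
#' Thin adapter over Rsamtools: loads primary, mapped, paired alignments,
#' joins mates by query name, orders them canonically by leftmost position
#' and derives the pair orientation from the strand flags and the summed
#' base quality from the QUAL strings. SAM input is converted to BAM in a
#' temporary directory first.
#'
#' @param path a SAM or BAM file.
#' @return a read-pair record data.frame sorted by `(contig_id,
#'   left_start_1)`, ready for [mark_duplicates()].
#' @export
read_sam_pairs <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_sam_pairs() requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qual"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  hasUnmappedMate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  qsum <- vapply(as.character(b$qual),
                 function(q) sum(utf8ToInt(q)) - 33L * nchar(q),
                 integer(1), USE.NAMES = FALSE)
  strand <- ifelse(bitwAnd(b$flag, 16L) > 0L, "R", "F")
  first <- bitwAnd(b$flag, 64L) > 0L
  d <- data.frame(qname = b$qname, contig = as.character(b$rname),
                  pos = b$pos, strand = strand, qsum = qsum, first = first,
                  stringsAsFactors = FALSE)
  d <- d[order(d$qname, !d$first), ]
  m1 <- d[!duplicated(d$qname), ]
  m2 <- d[duplicated(d$qname), ]
  m2 <- m2[match(m1$qname, m2$qname), ]
  ok <- !is.na(m2$qname)
  m1 <- m1[ok, ]; m2 <- m2[ok, ]
  swap <- m2$pos < m1$pos
  ls1 <- ifelse(swap, m2$pos, m1$pos)
  ls2 <- ifelse(swap, m1$pos, m2$pos)
  s1 <- ifelse(swap, m2$strand, m1$strand)
  s2 <- ifelse(swap, m1$strand, m2$strand)
  out <- read_pair_records(query_name = m1$qname, contig_id = m1$contig,
                           left_start_1 = ls1, left_start_2 = ls2,
                           orientation = paste0(s1, s2),
                           base_quality_sum = m1$qsum + m2$qsum)
  out[order(out$contig_id, out$left_start_1), , drop = FALSE]
}

#' Write read-pair records as a minimal SAM file
#'
#' Emits two `read_len`-bp primary alignment lines per pair with flags
#' derived from the orientation and QUAL strings whose summed qualities
#' reproduce `base_quality_sum`. Intended for generating alignment fixtures;
#' not a general SAM writer.
#'
#' @param pairs read-pair records.
#' @param contig_lengths named integer vector for the `@SQ` header lines.
#' @param path output path.
#' @param read_len read length (default 100).
#' @return `path`, invisibly.
#' @export
write_sam_pairs <- function(pairs, contig_lengths, path, read_len = 100L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  n <- nrow(pairs)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  qual_str <- function(total) {
    total <- pmin(as.integer(total), 41L * read_len)
    base <- total %/% read_len
    extra <- total %% read_len
    vapply(seq_along(total), function(i) {
      q <- rep(base[i], read_len)
      if (extra[i] > 0L) q[seq_len(extra[i])] <- q[seq_len(extra[i])] + 1L
      intToUtf8(q + 33L)
    }, character(1))
  }
  q1 <- pairs$base_quality_sum - pairs$base_quality_sum %/% 2L
  q2 <- pairs$base_quality_sum %/% 2L
  rev1 <- substr(pairs$orientation, 1L, 1L) == "R"
  rev2 <- substr(pairs$orientation, 2L, 2L) == "R"
  flag1 <- 1L + 2L + 64L + ifelse(rev1, 16L, 0L) + ifelse(rev2, 32L, 0L)
  flag2 <- 1L + 2L + 128L + ifelse(rev2, 16L, 0L) + ifelse(rev1, 32L, 0L)
  tlen <- pairs$left_start_2 - pairs$left_start_1 + read_len
  seq_ <- strrep("A", read_len)
  cig <- paste0(read_len, "M")
  l1 <- paste(pairs$query_name, flag1, pairs$contig_id, pairs$left_start_1,
              60L, cig, "=", pairs$left_start_2, tlen, seq_, qual_str(q1),
              sep = "\t")
  l2 <- paste(pairs$query_name, flag2, pairs$contig_id, pairs$left_start_2,
              60L, cig, "=", pairs$left_start_1, -tlen, seq_, qual_str(q2),
              sep = "\t")
  body <- character(2L * n)
  body[seq(1L, 2L * n, 2L)] <- l1
  body[seq(2L, 2L * n, 2L)] <- l2
  ord <- order(rep(pairs$contig_id, each = 2L),
               as.vector(rbind(pairs$left_start_1, pairs$left_start_2)))
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Read a per-base coverage track from a depth TSV or bedGraph
#'
#' Accepts either the three-column `samtools depth` form
#' (`chrom<TAB>pos<TAB>depth`, 1-based) or bedGraph (via rtracklayer,
#' 0-based half-open). Positions absent from the file get depth 0.
#'
#' @param path input path; format inferred from the extension (`.bedgraph`
#'   or `.bg` vs anything else).
#' @param chrom chromosome to extract.
#' @param chrom_length track length.
#' @return a [coverage_track()].
#' @export
read_coverage <- function(path, chrom, chrom_length) {
  depth <- integer(chrom_length)
  if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("bedGraph input requires the rtracklayer package")
    }
    g <- rtracklayer::import(path, format = "bedGraph")
    g <- g[as.character(GenomeInfoDb::seqnames(g)) == chrom]
    st <- BiocGenerics::start(g); en <- BiocGenerics::end(g)
    sc <- as.integer(g$score)
    for (i in seq_along(g)) depth[st[i]:en[i]] <- sc[i]
  } else {
    f <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "pos", "depth"),
                    stringsAsFactors = FALSE)
    f <- f[f$chrom == chrom & f$pos >= 1L & f$pos <= chrom_length, ]
    depth[f$pos] <- as.integer(f$depth)
  }
  coverage_track(chrom, depth)
}
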
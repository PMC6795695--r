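#' Construct a reference-contig table
#'
#' A reference set is a plain data.frame with one row per contig and the
#' columns `contig_id` (pattern `ctgNNNNNN`), `sequence` (DNA over
#' `A,C,G,T,N`), `source` (`assembly_1`, `assembly_2`, `denovo` or
#' `simulated`), `source_chrom`, `source_start`, `source_end` (1-based
#' inclusive coordinates on the source assembly; `NA` for de-novo or
#' simulated contigs).
#'
#' @param contig_id,sequence,source,source_chrom,source_start,source_end
#'   parallel vectors; see Details.
#' @return a validated `data.frame`.
#' @export
reference_contigs <- function(contig_id, sequence, source = "denovo",
                              source_chrom = NA_character_,
                              source_start = NA_integer_,
                              source_end = NA_integer_) {
  n <- length(contig_id)
  df <- data.frame(contig_id = as.character(contig_id),
                   sequence = rep_len(toupper(as.character(sequence)),
                                      n)[seq_len(n)],
                   source = rep_len(as.character(source), n)[seq_len(n)],
                   source_chrom = rep_len(as.character(source_chrom),
                                          n)[seq_len(n)],
                   source_start = rep_len(as.integer(source_start),
                                          n)[seq_len(n)],
                   source_end = rep_len(as.integer(source_end), n)[seq_len(n)],
                   stringsAsFactors = FALSE)
  validate_contigs(df)
  df
}

validate_contigs <- function(df) {
  dup <- df$contig_id[duplicated(df$contig_id)]
  if (length(dup)) stop("duplicate contig_id: ", paste(unique(dup), collapse = ", "))
  ok_src <- df$source %in% c("assembly_1", "assembly_2", "denovo", "simulated")
  if (!all(ok_src)) stop("unknown contig source: ", df$source[!ok_src][1])
  bad <- stringi::stri_locate_first_regex(df$sequence, "[^ACGTN]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop(sprintf("contig %s contains non-ACGTN character '%s' at position %d",
                 df$contig_id[i],
                 stringi::stri_sub(df$sequence[i], bad[i], bad[i]), bad[i]))
  }
  from_asm <- df$source %in% c("assembly_1", "assembly_2") &
    !is.na(df$source_start)
  len <- nchar(df$sequence)
  mism <- from_asm & (df$source_end - df$source_start + 1L != len)
  if (any(mism)) {
    stop(sprintf("contig %s: sequence length %d disagrees with source span %d..%d",
                 df$contig_id[mism][1], len[mism][1],
                 df$source_start[mism][1], df$source_end[mism][1]))
  }
  invisible(df)
}

#' Write reference contigs to FASTA with provenance headers
#'
#' Headers follow `>ctgNNNNNN source=<s> chrom=<c> start=<i> end=<j>`;
#' [read_contig_fasta()] restores the table (modulo line wrapping).
#'
#' @param contigs a reference-contig table (see [reference_contigs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path) {
  validate_contigs(contigs)
  if (nrow(contigs) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(contigs$sequence)
  names(seqs) <- sprintf("%s source=%s chrom=%s start=%s end=%s",
                         contigs$contig_id, contigs$source,
                         ifelse(is.na(contigs$source_chrom), "", contigs$source_chrom),
                         ifelse(is.na(contigs$source_start), 0L, contigs$source_start),
                         ifelse(is.na(contigs$source_end), 0L, contigs$source_end))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read reference contigs from a provenance-tagged FASTA
#'
#' @param path FASTA path written by [write_contig_fasta()] (plain FASTA
#'   without the `key=value` tags is accepted; provenance fields are then
#'   `NA`/`denovo`).
#' @return a reference-contig table.
#' @export
read_contig_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    return(reference_contigs(character(), character()))
  }
  hdr <- names(seqs)
  id <- stringi::stri_extract_first_regex(hdr, "^\\S+")
  tag <- function(key) {
    v <- stringi::stri_match_first_regex(hdr, paste0("\\b", key, "=(\\S*)"))[, 2]
    v
  }
  src <- tag("source")
  chrom <- tag("chrom")
  st <- suppressWarnings(as.integer(tag("start")))
  en <- suppressWarnings(as.integer(tag("end")))
  chrom[!is.na(chrom) & chrom == ""] <- NA_character_
  st[!is.na(st) & st == 0L] <- NA_integer_
  en[!is.na(en) & en == 0L] <- NA_integer_
  reference_contigs(contig_id = id,
                    sequence = as.character(seqs),
                    source = ifelse(is.na(src), "denovo", src),
                    source_chrom = chrom,
                    source_start = st, source_end = en)
}
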
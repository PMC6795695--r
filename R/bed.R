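#' Write exome regions to BED6
#'
#' Internal coordinates are 1-based inclusive throughout the package (the
#' pileup / mutation-table convention); BED is 0-based half-open, so the
#' conversion `start - 1` happens here, at the I/O boundary, and nowhere
#' else. No merging is performed at this layer.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), sorted by `(chrom, start)`; an optional `name` column is
#'   used for BED column 4.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  o <- order(regions$chrom, regions$start)
  if (!identical(o, seq_len(nrow(regions)))) {
    stop("regions must be sorted by (chrom, start) before writing BED")
  }
  name <- regions$name %||% sprintf("region%05d", seq_len(nrow(regions)))
  writeLines(paste(regions$chrom, regions$start - 1L, regions$end,
                   name, 0L, ".", sep = "\t"), path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#'
#' @param path BED3+ path.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  f <- stringi::stri_split_fixed(lines, "\t", simplify = TRUE)
  data.frame(chrom = f[, 1L],
             start = as.integer(f[, 2L]) + 1L,
             end = as.integer(f[, 3L]),
             name = if (ncol(f) >= 4L) f[, 4L] else NA_character_,
             stringsAsFactors = FALSE)
}
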
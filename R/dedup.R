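#' Construct paired-end read-pair records
#'
#' The minimal representation of a coordinate-sorted paired-end alignment
#' used for PCR-duplicate detection: both mates' leftmost 1-based positions
#' (canonically ordered so `left_start_1 <= left_start_2`), the pair
#' orientation, and the summed base quality used to pick the representative
#' among duplicates.
#'
#' @param query_name,contig_id,left_start_1,left_start_2,orientation,base_quality_sum
#'   parallel vectors; `orientation` one of `FR`, `RF`, `FF`, `RR`.
#' @return a data.frame of read-pair records.
#' @export
read_pair_records <- function(query_name, contig_id, left_start_1,
                              left_start_2, orientation = "FR",
                              base_quality_sum = 0L) {
  n <- length(query_name)
  df <- data.frame(query_name = as.character(query_name),
                   contig_id = rep_len(as.character(contig_id), n),
                   left_start_1 = as.integer(left_start_1),
                   left_start_2 = as.integer(left_start_2),
                   orientation = rep_len(as.character(orientation), n),
                   base_quality_sum = rep_len(as.integer(base_quality_sum), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$orientation %in% c("FR", "RF", "FF", "RR")),
            all(df$left_start_1 <= df$left_start_2))
  df
}

#' Mark PCR duplicates among coordinate-sorted read pairs
#'
#' Two pairs are duplicates when they share contig, both mates' leftmost
#' positions and orientation (the standard coordinate-based criterion).
#' Within each duplicate group exactly one pair is kept: the one with the
#' highest base-quality sum, ties broken by lexicographically smallest query
#' name, so output is reproducible. Singleton groups are never flagged.
#'
#' @param pairs read-pair records sorted by `(contig_id, left_start_1)`.
#' @return `pairs` with a logical `is_duplicate` column appended, in input
#'   order.
#' @export
mark_duplicates <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    pairs$is_duplicate <- logical()
    return(pairs)
  }
  o <- order(pairs$contig_id, pairs$left_start_1)
  if (!identical(pairs$contig_id, pairs$contig_id[o]) ||
      !identical(pairs$left_start_1, pairs$left_start_1[o])) {
    stop("input pairs must be sorted by (contig_id, left_start_1)")
  }
  key <- paste(pairs$contig_id, pairs$left_start_1, pairs$left_start_2,
               pairs$orientation, sep = "\r")
  ord <- order(key, -pairs$base_quality_sum, pairs$query_name)
  dup_sorted <- duplicated(key[ord])
  is_dup <- logical(n)
  is_dup[ord] <- dup_sorted
  pairs$is_duplicate <- is_dup
  pairs
}

#' PCR-duplication rate of a marked pair set
#'
#' @param pairs output of [mark_duplicates()] (or any data.frame with an
#'   `is_duplicate` column).
#' @return `duplicates / total`; 0 for empty input.
#' @export
dedup_rate <- function(pairs) {
  if (nrow(pairs) == 0L) return(0)
  mean(pairs$is_duplicate)
}
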
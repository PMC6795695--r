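#' Region-extraction configuration
#'
#' Defaults follow the exome-reference construction used for durum wheat
#' TILLING: positions with control-sample coverage of 17 reads or more seed a
#' region, each region is retrieved with 500-bp flanks, and flank-extended
#' regions separated by a gap of less than 301 bp are merged.
#'
#' @param min_depth minimum per-position read depth (inclusive) for a
#'   high-coverage core; default 17.
#' @param flank bases added on either side of each core; default 500.
#' @param merge_gap regions whose gap is strictly less than this many bases
#'   are merged; default 301 (so a 300-bp gap merges, a 301-bp gap does not).
#' @return a `region_config` list.
#' @export
region_config <- function(min_depth = 17L, flank = 500L, merge_gap = 301L) {
  cfg <- list(min_depth = as.integer(min_depth), flank = as.integer(flank),
              merge_gap = as.integer(merge_gap))
  stopifnot(cfg$min_depth >= 0L, cfg$flank >= 0L, cfg$merge_gap >= 0L)
  structure(cfg, class = "region_config")
}

#' Per-base coverage track for one chromosome
#'
#' @param chrom chromosome name.
#' @param depth non-negative integer vector; `depth[i]` is the read depth at
#'   1-based position `i`. Length defines the chromosome length.
#' @return a `coverage_track` list.
#' @export
coverage_track <- function(chrom, depth) {
  depth <- as.integer(depth)
  stopifnot(all(depth >= 0L, na.rm = TRUE))
  depth[is.na(depth)] <- 0L
  structure(list(chrom = chrom, depth = depth,
                 chrom_length = length(depth)), class = "coverage_track")
}

#' Find maximal runs of high-coverage positions
#'
#' Marks every position whose depth is at or above `cfg$min_depth` and
#' returns the maximal runs as 1-based inclusive intervals, sorted and
#' non-overlapping.
#'
#' @param track a [coverage_track()].
#' @param cfg a [region_config()].
#' @return data.frame `start`, `end`.
#' @export
call_core_regions <- function(track, cfg = region_config()) {
  hit <- track$depth >= cfg$min_depth
  if (!any(hit)) return(data.frame(start = integer(), end = integer()))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Flank high-coverage cores and merge nearby regions
#'
#' Each core interval is extended by `cfg$flank` bases on both sides (exome
#' capture coverage does not drop abruptly at intron-exon boundaries, so the
#' flanks retain the poorly covered edges), clipped to `[1, chrom_length]`.
#' Flank-extended regions whose gap (`next$start - prev$end - 1`) is strictly
#' less than `cfg$merge_gap` are then merged transitively; adjacent or
#' overlapping extended regions always merge. Merging after flanking
#' guarantees the resulting contigs never overlap.
#'
#' @param cores data.frame `start`, `end`: sorted, non-overlapping 1-based
#'   inclusive core intervals (from [call_core_regions()]).
#' @param cfg a [region_config()].
#' @param chrom_length chromosome length for clipping.
#' @param chrom optional chromosome name carried into the output.
#' @return data.frame `chrom`, `start`, `end`, `core_start`, `core_end` where
#'   `core_start`/`core_end` span the first to last high-coverage core inside
#'   the (possibly merged) region.
#' @export
flank_and_merge <- function(cores, cfg = region_config(), chrom_length,
                            chrom = NA_character_) {
  if (nrow(cores) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      core_start = integer(), core_end = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(!is.unsorted(cores$start), all(cores$end >= cores$start),
            all(cores$end <= chrom_length))
  ext_start <- pmax(1L, cores$start - cfg$flank)
  ext_end <- pmin(as.integer(chrom_length), cores$end + cfg$flank)
  # merge extended intervals whose gap < merge_gap (gap <= 0 always merges)
  n <- nrow(cores)
  new_run <- c(TRUE, ext_start[-1L] - ext_end[-n] - 1L >= cfg$merge_gap)
  grp <- cumsum(new_run)
  data.frame(chrom = chrom,
             start = as.integer(tapply(ext_start, grp, min)),
             end = as.integer(tapply(ext_end, grp, max)),
             core_start = as.integer(tapply(cores$start, grp, min)),
             core_end = as.integer(tapply(cores$end, grp, max)),
             stringsAsFactors = FALSE)
}

#' Excise region sequences from an assembly as reference contigs
#'
#' @param regions data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   sorted by `(chrom, start)`.
#' @param assembly named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param source_tag provenance label (`assembly_1` or `assembly_2`).
#' @param first_id integer: number for the first contig id (`ctg%06d`),
#'   allowing ids to continue across assemblies.
#' @return a reference-contig table (see [reference_contigs()]).
#' @export
excise_contigs <- function(regions, assembly, source_tag = "assembly_1",
                           first_id = 1L) {
  if (nrow(regions) == 0L) return(reference_contigs(character(), character()))
  o <- order(regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  assembly_chr <- if (methods::is(assembly, "DNAStringSet"))
    as.character(assembly) else assembly
  miss <- setdiff(unique(regions$chrom), names(assembly_chr))
  if (length(miss)) stop("regions reference unknown chromosome(s): ",
                         paste(miss, collapse = ", "))
  lens <- nchar(assembly_chr)[regions$chrom]
  if (any(regions$start < 1L | regions$end > lens)) {
    bad <- which(regions$start < 1L | regions$end > lens)[1]
    stop(sprintf("region %s:%d-%d falls outside the chromosome (length %d)",
                 regions$chrom[bad], regions$start[bad], regions$end[bad],
                 lens[bad]))
  }
  seqs <- stringi::stri_sub(assembly_chr[regions$chrom],
                            regions$start, regions$end)
  ids <- sprintf("ctg%06d", seq(first_id, length.out = nrow(regions)))
  reference_contigs(contig_id = ids, sequence = seqs, source = source_tag,
                    source_chrom = regions$chrom,
                    source_start = regions$start, source_end = regions$end)
}

#' Build a combined exome reference from coverage tracks and de-novo contigs
#'
#' Runs [call_core_regions()] + [flank_and_merge()] + [excise_contigs()] per
#' assembly (assembly 1 first; the track against assembly 2 is expected to
#' come from reads that did not map to assembly 1 — that read partition is an
#' upstream alignment concern), appends de-novo contigs of at least
#' `min_denovo_len` bases, and assigns globally unique sequential contig ids.
#'
#' @param tracks list of lists of [coverage_track()]s, one inner list per
#'   assembly, in priority order.
#' @param assemblies list of named character vectors / `DNAStringSet`s,
#'   parallel to `tracks`.
#' @param denovo_contigs optional reference-contig table of externally
#'   assembled contigs.
#' @param cfg a [region_config()].
#' @param min_denovo_len minimum de-novo contig length retained (default 500).
#' @return a reference-contig table with attributes `summary` (a data.frame
#'   of contig counts and total bp per source).
#' @export
build_reference <- function(tracks, assemblies, denovo_contigs = NULL,
                            cfg = region_config(), min_denovo_len = 500L) {
  stopifnot(length(tracks) == length(assemblies), length(tracks) <= 2L)
  out <- list()
  next_id <- 1L
  for (k in seq_along(tracks)) {
    regs <- do.call(rbind, lapply(tracks[[k]], function(tr) {
      cores <- call_core_regions(tr, cfg)
      flank_and_merge(cores, cfg, tr$chrom_length, chrom = tr$chrom)
    }))
    regs <- regs[order(regs$chrom, regs$start), , drop = FALSE]
    ctg <- excise_contigs(regs, assemblies[[k]],
                          source_tag = paste0("assembly_", k),
                          first_id = next_id)
    next_id <- next_id + nrow(ctg)
    out[[k]] <- ctg
  }
  if (!is.null(denovo_contigs) && nrow(denovo_contigs) > 0L) {
    keep <- nchar(denovo_contigs$sequence) >= min_denovo_len
    dn <- denovo_contigs[keep, , drop = FALSE]
    if (nrow(dn) > 0L) {
      dn$contig_id <- sprintf("ctg%06d", seq(next_id, length.out = nrow(dn)))
      dn$source <- "denovo"
      out[[length(out) + 1L]] <- dn
    }
  }
  ref <- if (length(out)) do.call(rbind, out) else
    reference_contigs(character(), character())
  rownames(ref) <- NULL
  validate_contigs(ref)
  summ <- if (nrow(ref)) aggregate(nchar(ref$sequence),
                                   by = list(source = ref$source),
                                   FUN = function(x) c(n = length(x), bp = sum(x)))
  else NULL
  attr(ref, "summary") <- data.frame(
    source = if (is.null(summ)) character() else summ$source,
    n_contigs = if (is.null(summ)) integer() else summ$x[, "n"],
    total_bp = if (is.null(summ)) integer() else summ$x[, "bp"],
    stringsAsFactors = FALSE)
  ref
}
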
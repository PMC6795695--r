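#' Load a mutation-record CSV into an SQLite database
#'
#' Creates a single `mutations` table with the record fields, indexed on
#' `mutant_id` and `contig_id` — the two identifiers the mutation browser is
#' searched by.
#'
#' @param csv_path path to a CSV written by [export_mutation_csv()] (or a
#'   mutation-record data.frame).
#' @param db_path output SQLite file.
#' @return `db_path`, invisibly.
#' @export
export_sqlite <- function(csv_path, db_path) {
  records <- if (is.data.frame(csv_path)) csv_path else
    read_mutation_csv(csv_path)
  miss <- setdiff(MUTATION_RECORD_FIELDS, names(records))
  if (length(miss)) stop("mutation records missing column(s): ",
                         paste(miss, collapse = ", "))
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbWriteTable(con, "mutations",
                    records[, MUTATION_RECORD_FIELDS, drop = FALSE],
                    overwrite = TRUE)
  DBI::dbExecute(con, "CREATE INDEX idx_mutant ON mutations (mutant_id)")
  DBI::dbExecute(con, "CREATE INDEX idx_contig ON mutations (contig_id)")
  invisible(db_path)
}

#' Query a mutation database by contig or by mutant line
#'
#' The two search modes of the mutation browser: all mutations on one
#' reference contig (across every line), or all mutations of one mutant
#' line (across every contig). Results are sorted by mutant-allele depth,
#' descending, as a confidence ordering.
#'
#' @param db path to an SQLite file from [export_sqlite()], or a
#'   mutation-record data.frame.
#' @param contig_id,mutant_id exactly one must be given.
#' @return a mutation-record data.frame sorted by `mut_depth` descending.
#' @export
query_mutations <- function(db, contig_id = NULL, mutant_id = NULL) {
  if (is.null(contig_id) == is.null(mutant_id)) {
    stop("supply exactly one of contig_id or mutant_id")
  }
  if (is.data.frame(db)) {
    res <- if (!is.null(contig_id)) db[db$contig_id == contig_id, ] else
      db[db$mutant_id == mutant_id, ]
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), db)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    if (!is.null(contig_id)) {
      res <- DBI::dbGetQuery(
        con, "SELECT * FROM mutations WHERE contig_id = ?",
        params = list(contig_id))
    } else {
      res <- DBI::dbGetQuery(
        con, "SELECT * FROM mutations WHERE mutant_id = ?",
        params = list(mutant_id))
    }
  }
  res <- res[order(-res$mut_depth, res$contig_id, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export an SQLite mutation database back to CSV
#'
#' @param db_path SQLite file.
#' @param csv_path output CSV.
#' @return `csv_path`, invisibly.
#' @export
sqlite_to_csv <- function(db_path, csv_path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  records <- DBI::dbReadTable(con, "mutations")
  export_mutation_csv(records, csv_path)
}
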
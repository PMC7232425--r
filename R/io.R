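# Shared TSV I/O.  Dialect: tab-delimited, UTF-8, header row; feature tables
# have feature ids as the header and station ids in the first column.

check_rectangular <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged TSV '%s': line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  invisible(nf)
}

#' Read / write a station x feature abundance table
#'
#' The TSV has feature ids as the header row and station ids in the first
#' column (`station_id`).  Duplicate identifiers, missing values, ragged
#' rows and negative counts are rejected with named errors.
#'
#' @param path file path.
#' @return `read_feature_table` returns a stations x features numeric
#'   matrix; `write_feature_table` invisibly returns `path`.
#' @export
read_feature_table <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated station id '%s' in '%s'",
                 ids[anyDuplicated(ids)], path))
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x))
    stop(sprintf("non-numeric cell(s) in feature table '%s'", path))
  rownames(x) <- ids
  x <- as_feature_matrix(x)
  check_nonnegative(x, arg = sprintf("'%s'", path))
  x
}

#' @param x stations x features matrix.
#' @rdname read_feature_table
#' @export
write_feature_table <- function(x, path) {
  x <- as_feature_matrix(x)
  df <- data.frame(station_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a station covariate table
#'
#' Requires `station_id` and `region` columns; all other columns are read
#' as-is (covariates numeric).
#'
#' @param path file path.
#' @return `read_station_table` returns a data.frame;
#'   `write_station_table` invisibly returns `path`.
#' @export
read_station_table <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("station_id", "region") %in% names(df)))
    stop(sprintf("station table '%s' needs 'station_id' and 'region' columns",
                 path))
  if (anyDuplicated(df$station_id))
    stop(sprintf("duplicated station id '%s' in '%s'",
                 df$station_id[anyDuplicated(df$station_id)], path))
  df
}

#' @param x station covariate data.frame.
#' @rdname read_station_table
#' @export
write_station_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Pfam-to-KO mapping table
#'
#' Two tab-separated columns, `pfam_id` and `ko_id`; a header naming them is
#' optional.  Duplicate pairs are collapsed.
#'
#' @param path file path.
#' @return data.frame with columns `pfam_id`, `ko_id`.
#' @export
read_pfam_ko_map <- function(path) {
  check_rectangular(path)
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  has_header <- identical(tolower(first[1:2]), c("pfam_id", "ko_id"))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop(sprintf("mapping '%s' needs two columns", path))
  df <- df[, 1:2]
  names(df) <- c("pfam_id", "ko_id")
  unique(df)
}
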
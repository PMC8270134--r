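#' Construct a wildlife-tracking table
#'
#' A plain data frame with columns `species`, `individual_id`, `x`, `y` and
#' `timestamp` (Date or NA). Coordinates are planar metres in the analysis
#' CRS.
#'
#' @param species,individual_id Character vectors (non-empty strings).
#' @param x,y Finite planar coordinates (metres).
#' @param timestamp Optional `Date` vector.
#' @return A `tracking_table` data frame.
#' @export
tracking_table <- function(species, individual_id, x, y, timestamp = NULL) {
  n <- length(x)
  if (is.null(timestamp)) timestamp <- as.Date(rep(NA, n))
  df <- data.frame(species = as.character(species),
                   individual_id = as.character(individual_id),
                   x = as.numeric(x), y = as.numeric(y),
                   timestamp = as.Date(timestamp),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("coordinates must be finite")
  if (any(!nzchar(df$species)) || any(!nzchar(df$individual_id)))
    stop("species and individual_id must be non-empty")
  class(df) <- c("tracking_table", "data.frame")
  df
}

#' Read wildlife-tracking occurrences from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `species`,
#' `individual_id`, `x`, `y` and optionally `date` (ISO-8601). Rows with
#' unparseable coordinates or empty identifiers are dropped with a warning
#' reporting the count, exact duplicates (same species, individual,
#' coordinates and date) are removed, and non-ISO dates become NA timestamps
#' with a warning. Reading already-clean data is a no-op (deduplication is
#' idempotent).
#'
#' @param path CSV file path.
#' @return A [tracking_table()].
#' @export
read_tracking_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("species", "individual_id", "x", "y")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("tracking CSV is missing required column(s) ",
         paste(missing, collapse = ", "),
         "; required header: species,individual_id,x,y[,date]")
  n0 <- nrow(raw)
  if (n0 == 0L)
    return(tracking_table(character(), character(), numeric(), numeric()))
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  species <- trimws(raw$species)
  id <- trimws(raw$individual_id)
  keep <- is.finite(x) & is.finite(y) & nzchar(species) & nzchar(id)
  if (any(!keep))
    warning(sum(!keep), " record(s) dropped: unparseable coordinates or ",
            "missing identification")
  date_chr <- if ("date" %in% names(raw)) trimws(raw$date)
              else rep(NA_character_, n0)
  ts <- as.Date(rep(NA, n0))
  has_date <- !is.na(date_chr) & nzchar(date_chr)
  if (any(has_date)) {
    parsed <- as.Date(date_chr[has_date], format = "%Y-%m-%d",
                      optional = TRUE)
    if (anyNA(parsed))
      warning(sum(is.na(parsed)), " non-ISO-8601 date(s) set to NA")
    ts[has_date] <- parsed
  }
  df <- data.frame(species = species, id = id, x = x, y = y, ts = ts)[keep, ]
  dup <- duplicated(df)
  if (any(dup)) message(sum(dup), " duplicated record(s) removed")
  df <- df[!dup, ]
  tracking_table(df$species, df$id, df$x, df$y, df$ts)
}

#' Write a tracking table (or labelled point set) to CSV
#'
#' @param table A [tracking_table()] or any data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(table, path) {
  out <- as.data.frame(table)
  if ("timestamp" %in% names(out)) {
    names(out)[names(out) == "timestamp"] <- "date"
    out$date <- format(out$date, "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
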
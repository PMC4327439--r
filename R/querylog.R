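#' Construct a query log
#'
#' A query log is one record per search event: an opaque user identifier,
#' a 0-based day index within a shared observation window, the normalized
#' query text, and optionally the clicked page identifiers, a region code
#' and a year of birth. Timestamps below day resolution are deliberately
#' not represented: the downstream model only uses day-level co-occurrence.
#'
#' @param records data frame with columns `user_id`, `day`, `text`, and
#'   optionally `clicked_pages` (page ids separated by `|`), `region`,
#'   `birth_year`.
#' @param observation_length length of the shared observation window in
#'   days (default 183, about six months). Records with `day` outside
#'   `[0, observation_length)` are dropped with a warning giving the count.
#' @return object of class `query_log` (a data frame with attribute
#'   `observation_length`).
#' @export
query_log <- function(records, observation_length = 183L) {
  observation_length <- as.integer(observation_length)
  stopifnot(is.data.frame(records), observation_length >= 1L)
  need <- setdiff(c("user_id", "day", "text"), names(records))
  if (length(need))
    stop("query log is missing mandatory column(s): ",
         paste(need, collapse = ", "))
  n <- nrow(records)
  rec <- data.frame(
    user_id = as.character(records$user_id),
    day = as.integer(records$day),
    text = normalize_text(records$text),
    clicked_pages = if ("clicked_pages" %in% names(records))
      as.character(records$clicked_pages) else rep("", n),
    region = if ("region" %in% names(records))
      as.character(records$region) else rep(NA_character_, n),
    birth_year = if ("birth_year" %in% names(records))
      suppressWarnings(as.integer(records$birth_year)) else rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  rec <- rec[nzchar(rec$text), , drop = FALSE]
  bad <- is.na(rec$day) | rec$day < 0L | rec$day >= observation_length
  if (any(bad)) {
    warning(sum(bad), " record(s) outside the observation window [0, ",
            observation_length, ") were dropped")
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  structure(rec, observation_length = observation_length,
            class = c("query_log", "data.frame"))
}

#' @export
print.query_log <- function(x, ...) {
  cat("Query log:", nrow(x), "records,", length(unique(x$user_id)),
      "users, window", attr(x, "observation_length"), "days\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read and write a query log file
#'
#' The file format is tab-separated with a header; mandatory columns
#' `user_id`, `day`, `text`; optional `clicked_pages` (ids separated by
#' `|`), `region`, `birth_year`. Unknown columns are ignored. Rows whose
#' `day` falls outside the observation window are dropped and counted in a
#' warning.
#'
#' @param path file path.
#' @param observation_length window length in days (default 183).
#' @return `read_querylog()` returns a [query_log()].
#' @export
read_querylog <- function(path, observation_length = 183L) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  need <- setdiff(c("user_id", "day", "text"), names(d))
  if (length(need))
    stop("query log file is missing mandatory column(s): ",
         paste(need, collapse = ", "))
  query_log(d, observation_length)
}

#' @rdname read_querylog
#' @param log a [query_log()].
#' @export
write_querylog <- function(log, path) {
  stopifnot(inherits(log, "query_log"))
  utils::write.table(as.data.frame(log), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference incidence table
#'
#' Two tab-separated columns: `condition` (canonical term) and `incidence`
#' (fraction of the population in (0, 1)). Used to anchor self-identified
#' cohort rates against published population incidence.
#'
#' @param path file path.
#' @return data frame with columns `condition`, `incidence`.
#' @export
read_incidence_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- setdiff(c("condition", "incidence"), names(d))
  if (length(need))
    stop("incidence table is missing column(s): ", paste(need, collapse = ", "))
  incidence_table(d$condition, as.numeric(d$incidence))
}

#' @rdname read_incidence_table
#' @param condition character vector of canonical condition names.
#' @param incidence numeric vector of population fractions in (0, 1).
#' @export
incidence_table <- function(condition, incidence) {
  condition <- as.character(condition)
  incidence <- as.numeric(incidence)
  stopifnot(length(condition) == length(incidence))
  if (anyDuplicated(condition)) stop("conditions must be unique")
  if (any(!is.finite(incidence) | incidence <= 0 | incidence >= 1))
    stop("incidences must lie in (0, 1)")
  data.frame(condition = condition, incidence = incidence,
             stringsAsFactors = FALSE)
}

#' Published incidence versus self-identified rates for 29 diseases
#'
#' A published comparison of the per-condition share of self-identified
#' users in a large search-log population against US population incidence
#' for 29 diseases, shipped as a plain-text fixture. Used to validate the
#' assumption that self-identifying queries track real disease occurrence:
#' the Spearman rank correlation between the two columns is about 0.5.
#'
#' @return data frame with columns `condition`, `siu_percent` (share of
#'   self-identified users, percent) and `incidence` (US population
#'   fraction).
#' @seealso [siu_incidence_check()]
#' @export
incidence_benchmark <- function() {
  path <- system.file("extdata", "us_incidence_29.tsv", package = "searchsccs",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}
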
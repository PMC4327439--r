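#' Construct a query-to-category map
#'
#' Maps a normalized query text to the single encyclopedia page its clicks
#' most often landed on, and to that page's subject categories. Queries not
#' present in the map are not generalized downstream: their literal text is
#' used as a label of kind `"query"`.
#'
#' @param query character vector of query texts.
#' @param page character vector of page identifiers (one per query).
#' @param categories categories per query: either a character vector (one
#'   category per row, possibly `|`-separated) or a list of character
#'   vectors. Must be non-empty for every mapped query.
#' @return object of class `category_map`: data frame with columns
#'   `query`, `page`, `categories` (categories joined by `|`).
#' @export
category_map <- function(query, page, categories) {
  query <- normalize_text(query)
  if (is.list(categories))
    categories <- vapply(categories, paste, "", collapse = "|")
  stopifnot(length(query) == length(page), length(query) == length(categories))
  if (anyDuplicated(query)) stop("each query must map to exactly one page")
  if (any(!nzchar(categories)))
    stop("categories must be non-empty for every mapped query")
  structure(data.frame(query = query, page = as.character(page),
                       categories = as.character(categories),
                       stringsAsFactors = FALSE),
            class = c("category_map", "data.frame"))
}

#' @export
print.category_map <- function(x, ...) {
  cat("Category map:", nrow(x), "queries,", length(unique(x$page)), "pages,",
      length(unique(unlist(strsplit(x$categories, "|", fixed = TRUE)))),
      "categories\n")
  invisible(x)
}

#' Read and write a category map file
#'
#' Tab-separated with columns `query`, `page`, `categories`
#' (`|`-separated).
#'
#' @param path file path.
#' @return `read_category_map()` returns a [category_map()].
#' @export
read_category_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  need <- setdiff(c("query", "page", "categories"), names(d))
  if (length(need))
    stop("category map file is missing column(s): ", paste(need, collapse = ", "))
  category_map(d$query, d$page, d$categories)
}

#' @rdname read_category_map
#' @param map a [category_map()].
#' @export
write_category_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a category map from click records
#'
#' Keeps a (query, page) pair only if the page was clicked for that query
#' at least `min_monthly_clicks` times in every month of the span (the
#' strict reading of a per-month threshold; set `rule = "mean"` to require
#' only a per-month average). Among surviving pages per query, the page
#' with the highest total clicks wins, ties broken by lexicographically
#' smaller page id. Pages with no known categories cause the query to be
#' dropped from the map: such queries fall back to their raw text
#' downstream.
#'
#' @param clicks data frame with columns `query`, `page`, `month`
#'   (integer month index) and `clicks`.
#' @param page_categories named list: page id -> character vector of
#'   category names.
#' @param min_monthly_clicks per-month click threshold (default 10,
#'   boundary inclusive).
#' @param rule `"every_month"` (default): the threshold must hold in each
#'   month of the span; `"mean"`: the per-month average must meet it.
#' @return a [category_map()].
#' @export
build_category_map <- function(clicks, page_categories,
                               min_monthly_clicks = 10,
                               rule = c("every_month", "mean")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(clicks),
            all(c("query", "page", "month", "clicks") %in% names(clicks)))
  if (any(clicks$clicks < 0)) stop("click counts must be nonnegative")
  clicks$query <- normalize_text(clicks$query)
  months <- sort(unique(clicks$month))
  key <- paste(clicks$query, clicks$page, sep = "\r")
  # per (query, page, month) click sums
  agg <- stats::aggregate(clicks$clicks,
                          list(key = key, month = clicks$month), sum)
  total <- tapply(agg$x, agg$key, sum)
  keep <- if (rule == "mean") {
    total / length(months) >= min_monthly_clicks
  } else {
    # every month of the span must individually meet the threshold
    ok <- tapply(agg$x >= min_monthly_clicks, agg$key, all)
    n_months <- tapply(agg$month, agg$key, length)
    ok[names(total)] & n_months[names(total)] == length(months)
  }
  if (!any(keep)) {
    return(category_map(character(), character(), character()))
  }
  surv <- data.frame(key = names(total)[keep], total = as.numeric(total[keep]),
                     stringsAsFactors = FALSE)
  parts <- strsplit(surv$key, "\r", fixed = TRUE)
  surv$query <- vapply(parts, `[`, "", 1L)
  surv$page <- vapply(parts, `[`, "", 2L)
  # winner per query: max total clicks, tie -> lexicographic page id
  surv <- surv[order(surv$query, -surv$total, surv$page), , drop = FALSE]
  surv <- surv[!duplicated(surv$query), , drop = FALSE]
  cats <- lapply(surv$page, function(p) page_categories[[p]])
  has <- lengths(cats) > 0L
  category_map(surv$query[has], surv$page[has], cats[has])
}

#' Annotate a query with its labels
#'
#' Returns the query's mapped categories (kind `"category"`), plus the raw
#' normalized query text itself as a label of kind `"query"`. Unmapped
#' queries yield only the raw-text label, so every query contributes at
#' least one label and every downstream finding traces to either a
#' category or a literal query string.
#'
#' @param query a single query text.
#' @param map a [category_map()].
#' @return data frame with columns `label` and `kind`.
#' @export
#' @examples
#' m <- category_map("pre diabetes symptoms", "wiki/Pre-diabetes",
#'                   "diabetes|nutrition")
#' annotate("Pre-Diabetes  Symptoms", m)
annotate <- function(query, map) {
  stopifnot(length(query) == 1L)
  q <- normalize_text(query)
  i <- match(q, map$query)
  labels <- q; kinds <- "query"
  if (!is.na(i)) {
    cats <- strsplit(map$categories[i], "|", fixed = TRUE)[[1]]
    labels <- c(cats, labels)
    kinds <- c(rep("category", length(cats)), kinds)
  }
  data.frame(label = labels, kind = kinds, stringsAsFactors = FALSE)
}

#' Annotate every record of a query log
#'
#' Vectorized version of [annotate()] over a whole log: each record
#' produces one row per label (its mapped categories plus its raw text).
#'
#' @param log a [query_log()].
#' @param map a [category_map()].
#' @return data frame with columns `user_id`, `day`, `label`, `kind`;
#'   attribute `observation_length` is carried over from the log.
#' @export
annotate_log <- function(log, map) {
  stopifnot(inherits(log, "query_log"))
  texts <- unique(log$text)
  per_text <- lapply(texts, annotate, map = map)
  nlab <- vapply(per_text, nrow, 0L)
  lab <- do.call(rbind, per_text)
  # expand to records via the text -> labels relation
  ti <- match(log$text, texts)
  reps <- nlab[ti]
  row0 <- cumsum(c(0L, nlab))[ti]  # offset of each record's label block
  idx <- rep(row0, reps) + sequence(reps)
  out <- data.frame(
    user_id = rep(log$user_id, reps),
    day = rep(log$day, reps),
    label = lab$label[idx],
    kind = lab$kind[idx],
    stringsAsFactors = FALSE
  )
  attr(out, "observation_length") <- attr(log, "observation_length")
  out
}
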
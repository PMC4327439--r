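#' Detect self-identified users
#'
#' A query self-identifies a user as having a condition when it contains
#' one of the trigger phrases ("i have", "i suffer from", "living with",
#' "i was diagnosed with") together with at least one disease term from the
#' lexicon. The event day is the day of the user's FIRST self-identifying
#' query for that condition; when a trigger query names several diseases,
#' the longest token span wins, remaining ties broken lexicographically. A
#' user's primary condition is the one self-identified first (earliest
#' day; longest span on same-day ties).
#'
#' Negated statements ("i don't have cancer") are not handled; the method
#' deliberately takes self-identification at face value.
#'
#' @param log a [query_log()].
#' @param lexicon a [med_lexicon()].
#' @param trigger_phrases character vector of trigger phrases (normalized
#'   text); defaults to the four standard phrases.
#' @return data frame with columns `user_id`, `condition`, `event_day`,
#'   `primary` (logical: is this the user's primary condition), one row per
#'   (user, condition), ordered by `user_id` then `event_day`.
#' @export
#' @examples
#' log <- query_log(data.frame(user_id = "u1", day = 40,
#'                             text = "i was diagnosed with hiv"))
#' detect_sius(log, toy_lexicon())
detect_sius <- function(log, lexicon, trigger_phrases = siu_trigger_phrases()) {
  stopifnot(inherits(log, "query_log"))
  empty <- data.frame(user_id = character(), condition = character(),
                      event_day = integer(), primary = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(log)) return(empty)
  trig <- rep(FALSE, nrow(log))
  for (ph in normalize_text(trigger_phrases))
    trig <- trig | contains_phrase(log$text, ph)
  if (!any(trig)) return(empty)
  cand <- which(trig)
  m <- match_terms_batch(log$text[cand], lexicon)
  m <- m[m$kind == "disease", , drop = FALSE]
  if (!nrow(m)) return(empty)
  # match_terms_batch orders within record by span desc then surface; keep
  # the first disease per record as the deterministic pick
  m <- m[!duplicated(m$idx), , drop = FALSE]
  hits <- data.frame(
    user_id = log$user_id[cand[m$idx]],
    condition = m$canonical,
    event_day = log$day[cand[m$idx]],
    span = m$span,
    stringsAsFactors = FALSE
  )
  # earliest day per (user, condition); span desc breaks same-day ties for
  # the primary pick below
  hits <- hits[order(hits$user_id, hits$event_day, -hits$span, hits$condition), ,
               drop = FALSE]
  rec <- hits[!duplicated(hits[c("user_id", "condition")]), , drop = FALSE]
  rec$primary <- !duplicated(rec$user_id)
  rec$span <- NULL
  rownames(rec) <- NULL
  rec
}

#' Keep conditions with enough self-identified users
#'
#' Retains only conditions self-identified by at least `min_count` users
#' (boundary inclusive), and the SIU records for those conditions.
#'
#' @param sius output of [detect_sius()].
#' @param min_count minimum number of SIUs per condition (default 25).
#' @return list with `conditions` (character vector of retained
#'   conditions), `sius` (retained records), `counts` (named integer vector
#'   of SIU counts per input condition) and `n_dropped` (records dropped).
#' @export
filter_conditions <- function(sius, min_count = 25L) {
  stopifnot(min_count >= 1L)
  if (!nrow(sius))
    return(list(conditions = character(), sius = sius,
                counts = integer(), n_dropped = 0L))
  counts <- table(sius$condition)
  keep <- names(counts)[counts >= min_count]
  retained <- sius[sius$condition %in% keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(conditions = keep, sius = retained,
       counts = stats::setNames(as.integer(counts), names(counts)),
       n_dropped = nrow(sius) - nrow(retained))
}

#' Rank-correlate self-identified rates with reference incidence
#'
#' Computes the Spearman rank correlation (average-rank tie handling)
#' between the per-condition fraction of self-identified users and a
#' reference incidence table, over the conditions present in both. A high
#' correlation supports the assumption that self-identifying queries track
#' real disease occurrence.
#'
#' @param sius output of [detect_sius()] (or any data frame with columns
#'   `user_id`, `condition`).
#' @param n_users total number of users in the log population.
#' @param incidence an [incidence_table()] (or any data frame with columns
#'   `condition`, `incidence`).
#' @return list with `rho` (Spearman correlation), `p_value` (two-sided),
#'   `n` (number of overlapping conditions) and `table` (the merged data).
#' @export
siu_incidence_check <- function(sius, n_users, incidence) {
  counts <- table(sius$condition)
  common <- intersect(names(counts), incidence$condition)
  if (length(common) < 3L)
    stop("need at least 3 conditions present in both the SIU set and the ",
         "incidence table; got ", length(common))
  tab <- data.frame(
    condition = common,
    siu_fraction = as.numeric(counts[common]) / n_users,
    incidence = incidence$incidence[match(common, incidence$condition)],
    stringsAsFactors = FALSE
  )
  ct <- suppressWarnings(
    stats::cor.test(tab$siu_fraction, tab$incidence, method = "spearman",
                    exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(common), table = tab)
}
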
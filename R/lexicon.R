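#' Construct a medical lexicon
#'
#' A lexicon holds canonical medical terms, each of kind `"disease"`,
#' `"drug"` or `"symptom"`, together with surface synonyms that are folded
#' into the canonical term when queries are matched (for instance
#' "heart attack" into "myocardial infarction").
#'
#' @param terms data frame with columns `canonical` and `kind`
#'   (`disease`/`drug`/`symptom`); canonical names must be unique.
#' @param synonyms named character vector mapping synonym surface form to
#'   canonical term. Every value must be a canonical term in `terms`.
#'   Canonical surface forms themselves need not be listed; they always
#'   match.
#' @return object of class `med_lexicon` with components `terms` (data
#'   frame) and `synonym_map` (named character vector, surface form ->
#'   canonical, normalized, including the canonical forms themselves).
#' @seealso [toy_lexicon()], [match_terms()], [read_lexicon()]
#' @export
med_lexicon <- function(terms, synonyms = character()) {
  stopifnot(is.data.frame(terms), all(c("canonical", "kind") %in% names(terms)))
  terms$canonical <- as.character(terms$canonical)
  terms$kind <- as.character(terms$kind)
  if (anyDuplicated(terms$canonical))
    stop("canonical term names must be unique")
  bad <- setdiff(terms$kind, c("disease", "drug", "symptom"))
  if (length(bad))
    stop("unknown term kind(s): ", paste(bad, collapse = ", "))
  synonyms <- vapply(synonyms, as.character, "")
  if (length(synonyms) && is.null(names(synonyms)))
    stop("synonyms must be a named vector (surface form -> canonical)")
  missing <- setdiff(unname(synonyms), terms$canonical)
  if (length(missing))
    stop("synonym targets not in lexicon: ", paste(missing, collapse = ", "))
  map <- c(
    stats::setNames(terms$canonical, normalize_text(terms$canonical)),
    stats::setNames(unname(synonyms), normalize_text(names(synonyms)))
  )
  # a surface form must resolve to exactly one canonical term
  n_targets <- tapply(unname(map), names(map), function(v) length(unique(v)))
  if (any(n_targets > 1))
    stop("surface form(s) map to more than one canonical term: ",
         paste(names(n_targets)[n_targets > 1], collapse = ", "))
  map <- map[!duplicated(names(map))]
  structure(list(terms = terms[c("canonical", "kind")], synonym_map = map),
            class = "med_lexicon")
}

#' @export
print.med_lexicon <- function(x, ...) {
  tab <- table(x$terms$kind)
  cat("Medical lexicon:", nrow(x$terms), "canonical terms (",
      paste(names(tab), tab, sep = " ", collapse = ", "), ");",
      length(x$synonym_map) - nrow(x$terms), "synonyms\n")
  invisible(x)
}

#' Look up the kind of a canonical term
#' @param lexicon a [med_lexicon()].
#' @param canonical character vector of canonical term names.
#' @return character vector of kinds (`NA` for unknown terms).
#' @export
term_kind <- function(lexicon, canonical) {
  lexicon$terms$kind[match(canonical, lexicon$terms$canonical)]
}

#' Read and write a lexicon file
#'
#' The on-disk format is a tab-separated file with columns `canonical`,
#' `kind` and `synonyms`, where `synonyms` holds zero or more surface forms
#' separated by `|`.
#'
#' @param path file path.
#' @return `read_lexicon()` returns a [med_lexicon()].
#' @export
read_lexicon <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  need <- setdiff(c("canonical", "kind"), names(d))
  if (length(need))
    stop("lexicon file is missing column(s): ", paste(need, collapse = ", "))
  syn_col <- if ("synonyms" %in% names(d)) d$synonyms else rep("", nrow(d))
  syn_list <- strsplit(syn_col, "|", fixed = TRUE)
  syn <- stats::setNames(
    rep(d$canonical, lengths(syn_list)),
    unlist(syn_list)
  )
  syn <- syn[nzchar(names(syn))]
  med_lexicon(d[c("canonical", "kind")], stats::setNames(unname(syn), names(syn)))
}

#' @rdname read_lexicon
#' @param lexicon a [med_lexicon()].
#' @export
write_lexicon <- function(lexicon, path) {
  syn <- lexicon$synonym_map
  syn <- syn[!names(syn) %in% normalize_text(lexicon$terms$canonical)]
  by_canon <- split(names(syn), factor(unname(syn), levels = lexicon$terms$canonical))
  out <- data.frame(
    canonical = lexicon$terms$canonical,
    kind = lexicon$terms$kind,
    synonyms = vapply(by_canon, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A small fixed lexicon for simulation and tests
#'
#' Twenty diseases, ten drugs and ten symptoms, each with at least one
#' synonym (e.g. "heart attack" for "myocardial infarction"). The synthetic
#' query-log simulator draws condition names from this lexicon; it stands in
#' for the large encyclopedia-derived term lists a production analysis would
#' load with [read_lexicon()].
#'
#' @return a [med_lexicon()].
#' @export
#' @examples
#' match_terms("heart attack symptoms", toy_lexicon())
toy_lexicon <- function() {
  diseases <- c(
    "myocardial infarction", "hiv", "diabetes mellitus", "asthma",
    "hypertension", "migraine", "depression", "influenza", "pneumonia",
    "breast cancer", "epilepsy", "arthritis", "anemia", "psoriasis",
    "herpes simplex", "pregnancy", "allergy", "anorexia nervosa",
    "hypothyroidism", "gastritis"
  )
  drugs <- c(
    "aspirin", "metformin", "albuterol", "lisinopril", "sumatriptan",
    "fluoxetine", "oseltamivir", "amoxicillin", "tamoxifen", "ibuprofen"
  )
  symptoms <- c(
    "chest pain", "fever", "headache", "fatigue", "nausea", "cough",
    "rash", "shortness of breath", "dizziness", "joint pain"
  )
  terms <- data.frame(
    canonical = c(diseases, drugs, symptoms),
    kind = rep(c("disease", "drug", "symptom"),
               c(length(diseases), length(drugs), length(symptoms))),
    stringsAsFactors = FALSE
  )
  synonyms <- c(
    "heart attack" = "myocardial infarction",
    "human immunodeficiency virus" = "hiv",
    "aids virus" = "hiv",
    "sugar diabetes" = "diabetes mellitus",
    "bronchial asthma" = "asthma",
    "high blood pressure" = "hypertension",
    "migraine headache" = "migraine",
    "clinical depression" = "depression",
    "flu" = "influenza",
    "lung infection" = "pneumonia",
    "breast carcinoma" = "breast cancer",
    "seizure disorder" = "epilepsy",
    "joint inflammation" = "arthritis",
    "low iron" = "anemia",
    "plaque psoriasis" = "psoriasis",
    "genital herpes" = "herpes simplex",
    "expecting a baby" = "pregnancy",
    "allergies" = "allergy",
    "anorexia" = "anorexia nervosa",
    "underactive thyroid" = "hypothyroidism",
    "stomach inflammation" = "gastritis",
    "acetylsalicylic acid" = "aspirin",
    "glucophage" = "metformin",
    "salbutamol" = "albuterol",
    "zestril" = "lisinopril",
    "imitrex" = "sumatriptan",
    "prozac" = "fluoxetine",
    "tamiflu" = "oseltamivir",
    "amoxil" = "amoxicillin",
    "nolvadex" = "tamoxifen",
    "advil" = "ibuprofen",
    "angina" = "chest pain",
    "high temperature" = "fever",
    "head ache" = "headache",
    "tiredness" = "fatigue",
    "feeling sick" = "nausea",
    "dry cough" = "cough",
    "skin rash" = "rash",
    "breathlessness" = "shortness of breath",
    "vertigo" = "dizziness",
    "aching joints" = "joint pain"
  )
  med_lexicon(terms, synonyms)
}

# Batch matcher over many query strings. Returns one row per accepted match:
# (index into texts, canonical, kind, span = number of tokens matched).
# Longest token span wins on overlap; ties broken lexicographically on the
# surface form; each canonical reported at most once per query. Rows are
# ordered, within each query, by decreasing span then surface form, so the
# first disease row is the deterministic pick downstream.
match_terms_batch <- function(texts, lexicon) {
  texts <- normalize_text(texts)
  surfaces <- names(lexicon$synonym_map)
  surf_len <- lengths(strsplit(surfaces, " ", fixed = TRUE))
  max_n <- max(surf_len)
  toks <- strsplit(texts, " ", fixed = TRUE)
  nt <- lengths(toks)
  tok <- unlist(toks, use.names = FALSE)
  rid <- rep(seq_along(texts), nt)
  off <- cumsum(c(0L, nt))[seq_along(texts)]  # token offset per record
  hits <- vector("list", max_n)
  m <- length(tok)
  for (n in seq_len(max_n)) {
    if (m < n) break
    s <- seq_len(m - n + 1L)
    s <- s[rid[s] == rid[s + n - 1L]]
    if (!length(s)) next
    gram <- tok[s]
    if (n > 1L) for (k in seq_len(n - 1L)) gram <- paste(gram, tok[s + k])
    j <- match(gram, surfaces)
    ok <- !is.na(j)
    if (!any(ok)) next
    hits[[n]] <- data.frame(
      idx = rid[s[ok]],
      start = s[ok] - off[rid[s[ok]]],
      span = n,
      surface = surfaces[j[ok]],
      canonical = unname(lexicon$synonym_map[j[ok]]),
      stringsAsFactors = FALSE
    )
  }
  h <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  empty <- data.frame(idx = integer(), canonical = character(),
                      kind = character(), span = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(h) || !nrow(h)) return(empty)
  h <- h[order(h$idx, -h$span, h$surface), , drop = FALSE]
  # greedy overlap resolution within each record: longest span first
  keep <- logical(nrow(h))
  for (rows in split(seq_len(nrow(h)), h$idx)) {
    if (length(rows) == 1L) { keep[rows] <- TRUE; next }
    covered <- integer(0)
    for (r in rows) {
      pos <- h$start[r]:(h$start[r] + h$span[r] - 1L)
      if (!any(pos %in% covered)) {
        keep[r] <- TRUE
        covered <- c(covered, pos)
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[!duplicated(h[c("idx", "canonical")]), , drop = FALSE]
  data.frame(idx = h$idx, canonical = h$canonical,
             kind = term_kind(lexicon, h$canonical),
             span = h$span, stringsAsFactors = FALSE)
}

#' Match lexicon terms in query text
#'
#' Finds every canonical term whose surface form or synonym occurs in the
#' text as a whole-token subsequence ("hives" does not match "hiv"). When
#' candidate matches overlap, the longest token span wins and remaining
#' ties are broken lexicographically on the surface form; each canonical
#' term is reported at most once per query.
#'
#' @param text a single query string (normalized or not).
#' @param lexicon a [med_lexicon()].
#' @return data frame with columns `canonical`, `kind` and `span` (tokens
#'   matched), ordered by decreasing span then surface form; zero rows if
#'   nothing matches.
#' @export
#' @examples
#' match_terms("i was diagnosed with hiv", toy_lexicon())
match_terms <- function(text, lexicon) {
  stopifnot(length(text) == 1L)
  m <- match_terms_batch(text, lexicon)
  m[c("canonical", "kind", "span")]
}

#' Per-user medical term counts
#'
#' Counts, for every user in the log, the number of queries mentioning each
#' canonical term (synonyms folded in; a term is counted at most once per
#' query). This is the sparse analogue of representing each user by a
#' term-count vector over the full lexicon.
#'
#' @param log a [query_log()].
#' @param lexicon a [med_lexicon()].
#' @return object of class `term_counts`: data frame with columns
#'   `user_id`, `canonical`, `kind`, `count` (one row per user x term with
#'   a positive count), plus attribute `n_users` = number of distinct users
#'   in the log.
#' @export
build_term_vectors <- function(log, lexicon) {
  stopifnot(inherits(log, "query_log"))
  users <- unique(log$user_id)
  if (!nrow(log)) {
    out <- data.frame(user_id = character(), canonical = character(),
                      kind = character(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_users") <- 0L
    class(out) <- c("term_counts", "data.frame")
    return(out)
  }
  m <- match_terms_batch(log$text, lexicon)
  if (!nrow(m)) {
    out <- data.frame(user_id = character(), canonical = character(),
                      kind = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(log$user_id[m$idx], m$canonical, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(
      user_id = vapply(parts, `[`, "", 1L),
      canonical = vapply(parts, `[`, "", 2L),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
    out$kind <- term_kind(lexicon, out$canonical)
    out <- out[order(out$user_id, out$canonical), c("user_id", "canonical", "kind", "count")]
    rownames(out) <- NULL
  }
  attr(out, "n_users") <- length(users)
  attr(out, "users") <- users
  class(out) <- c("term_counts", "data.frame")
  out
}
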
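#' Benjamini-Hochberg rejection flags
#'
#' Standard step-up procedure at level `q`: sort the p-values ascending,
#' find the largest k with `p_(k) <= k q / m`, reject all hypotheses with
#' p-values up to `p_(k)`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return logical vector of rejection flags, aligned with `p_values`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.2, 0.9), q = 0.05)  # first three rejected
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical())
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(q > 0, q < 1)
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Select candidate labels queried by enough of the cohort
#'
#' A label (category or raw query text) is a candidate precursor for a
#' condition only if at least a fraction `min_fraction` of the cohort
#' users queried it (boundary inclusive).
#'
#' @param cohort a cohort data frame (`user_id`, `condition`, `event_day`).
#' @param annotated [annotate_log()] output restricted or not to the
#'   cohort; only cohort users' rows are counted.
#' @param min_fraction minimum fraction of cohort users (default 0.01).
#' @return data frame with columns `label`, `kind`, `n_users`, `fraction`,
#'   ordered by decreasing `n_users`.
#' @export
select_candidates <- function(cohort, annotated, min_fraction = 0.01) {
  if (!nrow(cohort)) stop("empty cohort")
  ann <- annotated[annotated$user_id %in% cohort$user_id, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(label = character(), kind = character(),
                      n_users = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(ann$label, ann$kind, sep = "\r")
  n_users <- tapply(ann$user_id, key, function(u) length(unique(u)))
  parts <- strsplit(names(n_users), "\r", fixed = TRUE)
  out <- data.frame(
    label = vapply(parts, `[`, "", 1L),
    kind = vapply(parts, `[`, "", 2L),
    n_users = as.integer(n_users),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$n_users / nrow(cohort)
  out <- out[out$fraction >= min_fraction, , drop = FALSE]
  out <- out[order(-out$n_users, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Temporal-confound filter
#'
#' A candidate label whose daily query counts in the cohort correlate with
#' its daily counts in a disjoint background user sample is driven by a
#' shared external clock (for instance a news spike) rather than by
#' individual risk, and is REJECTED. Per label, the Pearson (optionally
#' Spearman) correlation between the two daily series is tested against
#' the zero-correlation null; labels significant after Benjamini-Hochberg
#' correction at level `q` are rejected. Labels with a constant series in
#' either population carry no evidence of confounding and are kept.
#'
#' @param cohort_annotated [annotate_log()] rows for cohort users.
#' @param background_annotated [annotate_log()] rows for the background
#'   sample (must be disjoint from the cohort).
#' @param candidates data frame with columns `label`, `kind` (for instance
#'   [select_candidates()] output).
#' @param observation_length window length in days.
#' @param q FDR level (default 0.05).
#' @param method correlation type: `"pearson"` (default) or `"spearman"`.
#' @return list with `stats` (data frame `label`, `kind`, `cor`,
#'   `p_value`, `rejected`), `kept` and `rejected` (subsets of
#'   `candidates`).
#' @export
temporal_filter <- function(cohort_annotated, background_annotated,
                            candidates, observation_length, q = 0.05,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(intersect(cohort_annotated$user_id, background_annotated$user_id)))
    stop("background sample must be disjoint from the cohort")
  L <- observation_length
  daily <- function(ann, label, kind) {
    d <- ann$day[ann$label == label & ann$kind == kind]
    tabulate(d + 1L, nbins = L)
  }
  n <- nrow(candidates)
  cor_v <- rep(NA_real_, n); p_v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- daily(cohort_annotated, candidates$label[i], candidates$kind[i])
    y <- daily(background_annotated, candidates$label[i], candidates$kind[i])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # no evidence either way
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    cor_v[i] <- unname(ct$estimate); p_v[i] <- ct$p.value
  }
  rejected <- rep(FALSE, n)
  testable <- !is.na(p_v)
  if (any(testable)) rejected[testable] <- bh_fdr(p_v[testable], q)
  stats_df <- data.frame(label = candidates$label, kind = candidates$kind,
                         cor = cor_v, p_value = p_v, rejected = rejected,
                         stringsAsFactors = FALSE)
  list(stats = stats_df,
       kept = candidates[!rejected, , drop = FALSE],
       rejected = candidates[rejected, , drop = FALSE])
}

#' Screen one condition for precursor labels
#'
#' The per-condition discovery loop: select candidate labels queried by at
#' least `min_fraction` of the condition's cohort, drop labels that merely
#' name the condition itself (tautological self-association), reject
#' temporally confounded labels against the background sample, fit the
#' SCCS model to every surviving candidate, and control the FDR across the
#' candidates' likelihood-ratio p-values with Benjamini-Hochberg at level
#' `q`. Rows for significant candidates are returned sorted by decreasing
#' relative hazard.
#'
#' @param condition the condition (canonical disease name).
#' @param cohort cohort data frame; rows with other conditions are
#'   ignored.
#' @param annotated [annotate_log()] output for the whole log.
#' @param background_users character vector of background user ids
#'   (disjoint from the cohort).
#' @param q FDR level (default 0.05).
#' @param W risk-window length in days (default 15).
#' @param min_fraction candidate threshold (default 0.01).
#' @param lexicon optional [med_lexicon()]; when given, labels equal to
#'   the condition or one of its synonyms are excluded.
#' @param observation_length window length in days.
#' @param pre_event_only passed to [build_case_series()].
#' @return object of class `screen_result`: list with `condition`,
#'   `report` (significant rows: `condition`, `precursor`, `kind`,
#'   `relative_hazard`, `p_value`, `fdr_significant`, `n_users_exposed`),
#'   `fits` (the same columns for every fitted candidate), `candidates`,
#'   `temporal` (filter stats) and `skipped` (labels with a reason).
#' @export
run_screen <- function(condition, cohort, annotated, background_users,
                       q = 0.05, W = 15L, min_fraction = 0.01,
                       lexicon = NULL,
                       observation_length = attr(annotated, "observation_length"),
                       pre_event_only = FALSE) {
  co <- cohort[cohort$condition == condition, , drop = FALSE]
  if (!nrow(co)) stop("no cohort users for condition ", condition)
  ann_cohort <- annotated[annotated$user_id %in% co$user_id, , drop = FALSE]
  ann_bg <- annotated[annotated$user_id %in% background_users, , drop = FALSE]
  cand <- select_candidates(co, ann_cohort, min_fraction)
  skipped <- data.frame(label = character(), kind = character(),
                        reason = character(), stringsAsFactors = FALSE)
  # tautology guard: a label that names the condition itself
  if (!is.null(lexicon) && nrow(cand)) {
    canon <- unname(lexicon$synonym_map[normalize_text(cand$label)])
    taut <- !is.na(canon) & canon == condition
    if (any(taut)) {
      skipped <- rbind(skipped, data.frame(
        label = cand$label[taut], kind = cand$kind[taut],
        reason = "names the condition itself", stringsAsFactors = FALSE))
      cand <- cand[!taut, , drop = FALSE]
    }
  }
  tf <- temporal_filter(ann_cohort, ann_bg, cand, observation_length, q)
  if (nrow(tf$rejected))
    skipped <- rbind(skipped, data.frame(
      label = tf$rejected$label, kind = tf$rejected$kind,
      reason = "temporally confounded", stringsAsFactors = FALSE))
  kept <- tf$kept
  fits <- list()
  for (i in seq_len(nrow(kept))) {
    sel <- ann_cohort$label == kept$label[i] & ann_cohort$kind == kept$kind[i]
    exposures <- data.frame(user_id = ann_cohort$user_id[sel],
                            day = ann_cohort$day[sel],
                            stringsAsFactors = FALSE)
    fit <- tryCatch({
      series <- build_case_series(co, exposures, W, observation_length,
                                  pre_event_only = pre_event_only,
                                  label = kept$label[i])
      sccs(series)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- rbind(skipped, data.frame(
        label = kept$label[i], kind = kept$kind[i],
        reason = conditionMessage(fit), stringsAsFactors = FALSE))
      next
    }
    if (!fit$converged) {
      skipped <- rbind(skipped, data.frame(
        label = kept$label[i], kind = kept$kind[i],
        reason = "estimate did not converge (hit the |beta| cap)",
        stringsAsFactors = FALSE))
      next
    }
    fits[[length(fits) + 1L]] <- data.frame(
      condition = condition,
      precursor = kept$label[i],
      kind = kept$kind[i],
      relative_hazard = fit$relative_hazard,
      p_value = fit$p_value,
      n_users_exposed = fit$n_exposed_users,
      stringsAsFactors = FALSE
    )
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(condition = character(), precursor = character(),
               kind = character(), relative_hazard = numeric(),
               p_value = numeric(), n_users_exposed = integer(),
               stringsAsFactors = FALSE)
  fits$fdr_significant <- if (nrow(fits)) bh_fdr(fits$p_value, q) else logical()
  report <- fits[fits$fdr_significant, , drop = FALSE]
  report <- report[order(-report$relative_hazard, report$precursor), , drop = FALSE]
  rownames(report) <- rownames(fits) <- NULL
  structure(list(condition = condition, report = report, fits = fits,
                 candidates = cand, temporal = tf$stats, skipped = skipped,
                 q = q, W = W),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Precursor screen for '", x$condition, "': ", nrow(x$candidates),
      " candidates, ", sum(x$temporal$rejected),
      " temporally confounded, ", nrow(x$fits), " fitted, ",
      nrow(x$report), " significant at FDR ", x$q, "\n", sep = "")
  if (nrow(x$report)) print(x$report)
  invisible(x)
}

#' Dose-response (biological gradient) check for a precursor
#'
#' Stratifies all users who queried the label by how often they queried it
#' (1, 2, 3, 4-or-more by default) and computes the fraction of users in
#' each stratum identified as having the condition. A Spearman correlation
#' of at least 0.5 between stratum and fraction indicates a positive
#' gradient (more exposure, more risk); at most -0.5 a negative one;
#' anything else, or fewer than 3 populated strata, is undetermined.
#'
#' @param annotated [annotate_log()] output over all users.
#' @param label,kind the precursor label to check.
#' @param condition_users character vector of user ids identified with the
#'   condition.
#' @param max_stratum counts at or above this are pooled (default 4).
#' @return list with `direction` (`"positive"`, `"negative"` or
#'   `"undetermined"`), `rho` and `table` (per-stratum users and fraction
#'   with the condition).
#' @export
gradient_check <- function(annotated, label, kind, condition_users,
                           max_stratum = 4L) {
  sel <- annotated$label == label & annotated$kind == kind
  if (!any(sel))
    return(list(direction = "undetermined", rho = NA_real_, table = NULL))
  counts <- table(annotated$user_id[sel])
  stratum <- pmin(as.integer(counts), max_stratum)
  with_cond <- names(counts) %in% condition_users
  tab <- data.frame(
    stratum = sort(unique(stratum)),
    n_users = as.integer(table(stratum)),
    fraction = as.numeric(tapply(with_cond, stratum, mean)),
    stringsAsFactors = FALSE
  )
  if (nrow(tab) < 3L)
    return(list(direction = "undetermined", rho = NA_real_, table = tab))
  rho <- suppressWarnings(stats::cor(tab$stratum, tab$fraction,
                                     method = "spearman"))
  direction <- if (!is.na(rho) && rho >= 0.5) "positive"
  else if (!is.na(rho) && rho <= -0.5) "negative"
  else "undetermined"
  list(direction = direction, rho = rho, table = tab)
}
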
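#' Disease-drug co-occurrence matrix
#'
#' `M[i, j]` is the number of users who queried disease `i` and also drug
#' `j` (each at least once). Feeds the drug-relatedness feature of
#' [compute_features()].
#'
#' @param vectors a [build_term_vectors()] result.
#' @return integer matrix with disease row names and drug column names
#'   (observed terms only; absent pairs are zero).
#' @export
disease_drug_cooccurrence <- function(vectors) {
  dis <- vectors[vectors$kind == "disease", , drop = FALSE]
  drg <- vectors[vectors$kind == "drug", , drop = FALSE]
  diseases <- sort(unique(dis$canonical))
  drugs <- sort(unique(drg$canonical))
  M <- matrix(0L, length(diseases), length(drugs),
              dimnames = list(diseases, drugs))
  if (!length(diseases) || !length(drugs)) return(M)
  dis_by_user <- split(dis$canonical, dis$user_id)
  drg_by_user <- split(drg$canonical, drg$user_id)
  for (u in intersect(names(dis_by_user), names(drg_by_user))) {
    M[dis_by_user[[u]], drg_by_user[[u]]] <-
      M[dis_by_user[[u]], drg_by_user[[u]], drop = FALSE] + 1L
  }
  M
}

#' Per-user features for the cohort classifier
#'
#' The eight features predicting whether the disease a user queried most
#' often is the one afflicting them:
#' `f1` queries for the most common disease; `f2` for the second most
#' common; `f3 = f1 / max(f2, 1)`; `f4` fraction of all users who asked
#' about the user's most common disease; `f5`, `f6`, `f7` number of
#' diseases asked about more than 1, 5 and 10 times; `f8` drug-relatedness:
#' the user's binary drug-query indicator vector times the co-occurrence
#' matrix column for their most common disease.
#'
#' Users with no disease queries have no most-common disease and are
#' excluded from the output.
#'
#' @param vectors a [build_term_vectors()] result.
#' @param M co-occurrence matrix from [disease_drug_cooccurrence()];
#'   computed from `vectors` when omitted.
#' @return data frame with columns `user_id`, `most_common_disease` and
#'   `f1`..`f8`.
#' @export
compute_features <- function(vectors, M = disease_drug_cooccurrence(vectors)) {
  stopifnot(inherits(vectors, "term_counts"))
  n_users <- attr(vectors, "n_users")
  dis <- vectors[vectors$kind == "disease", , drop = FALSE]
  if (!nrow(dis))
    return(data.frame(user_id = character(), most_common_disease = character(),
                      f1 = numeric(), f2 = numeric(), f3 = numeric(),
                      f4 = numeric(), f5 = numeric(), f6 = numeric(),
                      f7 = numeric(), f8 = numeric(), stringsAsFactors = FALSE))
  # fraction of all users who asked about each disease
  users_per_disease <- tapply(dis$user_id, dis$canonical,
                              function(u) length(unique(u)))
  drg_by_user <- split(vectors$canonical[vectors$kind == "drug"],
                       vectors$user_id[vectors$kind == "drug"])
  # deterministic argmax: count desc, then canonical
  dis <- dis[order(dis$user_id, -dis$count, dis$canonical), , drop = FALSE]
  rows <- split(seq_len(nrow(dis)), dis$user_id)
  out <- lapply(names(rows), function(u) {
    ix <- rows[[u]]
    cnt <- dis$count[ix]
    top <- dis$canonical[ix[1]]
    f1 <- cnt[1]
    f2 <- if (length(cnt) > 1L) cnt[2] else 0
    drugs <- drg_by_user[[u]]
    f8 <- if (length(drugs) && top %in% rownames(M))
      sum(M[top, intersect(drugs, colnames(M))]) else 0
    data.frame(user_id = u, most_common_disease = top,
               f1 = f1, f2 = f2, f3 = f1 / max(f2, 1),
               f4 = unname(users_per_disease[top]) / n_users,
               f5 = sum(cnt > 1), f6 = sum(cnt > 5), f7 = sum(cnt > 10),
               f8 = f8, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Training labels from self-identified users
#'
#' Label 1 when the user's most frequently queried disease equals their
#' (primary) self-identified condition, 0 otherwise. Only SIUs that appear
#' in `features` (i.e. have at least one disease query) are labeled.
#'
#' @param sius output of [detect_sius()]; only primary records are used.
#' @param features output of [compute_features()].
#' @return data frame with columns `user_id`, `condition`, `label`,
#'   aligned with the rows of `features` that correspond to SIUs.
#' @export
label_training <- function(sius, features) {
  prim <- sius[sius$primary, , drop = FALSE]
  i <- match(prim$user_id, features$user_id)
  ok <- !is.na(i)
  data.frame(
    user_id = prim$user_id[ok],
    condition = prim$condition[ok],
    label = as.integer(features$most_common_disease[i[ok]] == prim$condition[ok]),
    stringsAsFactors = FALSE
  )
}

# stratified k-fold assignment, seeded
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

feature_cols <- function(features) grep("^f[0-9]+$", names(features), value = TRUE)

#' Train the linear cohort scorer with cross-validated AUC
#'
#' Fits a logistic regression (a linear margin scorer with outputs mapped
#' to probabilities in `[0, 1]`) on the labeled SIU feature vectors, and
#' reports the mean out-of-fold area under the ROC curve over seeded,
#' label-stratified folds.
#'
#' @param features output of [compute_features()] (or any data frame whose
#'   feature columns are named `f<number>`).
#' @param labels integer/logical vector of 0-1 labels aligned with
#'   `features` rows.
#' @param k_folds number of cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @param columns feature columns to use; default all `f*` columns.
#' @return list with `scorer` (a function mapping a feature data frame to
#'   scores in `[0, 1]`), `model` (the full-data glm), `auc` (mean
#'   out-of-fold AUC), `fold_aucs`, `columns`.
#' @export
train_and_cv <- function(features, labels, k_folds = 5L, seed = 1L,
                         columns = feature_cols(features)) {
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), length(columns) >= 1L)
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: both classes must be present")
  dat <- features[columns]
  dat$.y <- labels
  fold <- stratified_folds(labels, k_folds, seed)
  fold_aucs <- rep(NA_real_, k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    if (length(unique(labels[!tr])) < 2L || length(unique(labels[tr])) < 2L) next
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat[tr, , drop = FALSE],
                                       family = stats::binomial()))
    sc <- suppressWarnings(
      stats::predict(fit, newdata = dat[!tr, , drop = FALSE], type = "response"))
    fold_aucs[f] <- as.numeric(pROC::auc(pROC::roc(
      labels[!tr], sc, quiet = TRUE, direction = "<", levels = c(0, 1))))
  }
  model <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                       family = stats::binomial()))
  scorer <- function(newdata) {
    as.numeric(suppressWarnings(
      stats::predict(model, newdata = newdata[columns], type = "response")))
  }
  list(scorer = scorer, model = model, auc = mean(fold_aucs, na.rm = TRUE),
       fold_aucs = fold_aucs, columns = columns)
}

#' Sequential forward feature selection by cross-validated AUC
#'
#' Greedily adds the feature whose inclusion most improves the mean
#' out-of-fold AUC, stopping when no candidate improves it by more than
#' `tol`.
#'
#' @inheritParams train_and_cv
#' @param tol minimum AUC improvement to keep adding (default 1e-4).
#' @return list with `columns` (selected features, in order of selection),
#'   `auc` (CV AUC of the selected subset) and `trace` (data frame of the
#'   selection path).
#' @export
forward_select <- function(features, labels, k_folds = 5L, seed = 1L,
                           tol = 1e-4) {
  cand <- feature_cols(features)
  chosen <- character(0)
  best_auc <- -Inf
  trace <- list()
  repeat {
    remaining <- setdiff(cand, chosen)
    if (!length(remaining)) break
    aucs <- vapply(remaining, function(col) {
      train_and_cv(features, labels, k_folds, seed,
                   columns = c(chosen, col))$auc
    }, 0)
    top <- names(aucs)[which.max(aucs)]
    if (max(aucs) <= best_auc + tol) break
    best_auc <- max(aucs)
    chosen <- c(chosen, top)
    trace[[length(trace) + 1L]] <- data.frame(added = top, auc = best_auc,
                                              stringsAsFactors = FALSE)
  }
  if (!length(chosen)) {
    # even a single feature never improves on nothing; keep the best one
    chosen <- names(which.max(vapply(cand, function(col)
      train_and_cv(features, labels, k_folds, seed, columns = col)$auc, 0)))
    best_auc <- train_and_cv(features, labels, k_folds, seed, columns = chosen)$auc
  }
  list(columns = chosen, auc = best_auc,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Tune the classifier threshold against reference incidence
#'
#' For each threshold in the grid, users scoring above it are assigned the
#' disease they queried most often; the resulting per-condition cohort
#' fractions are rank-correlated (Spearman) with the reference incidence
#' table. Threshold 0 denotes the SIU-only cohort. The chosen threshold is
#' the smallest grid value (largest cohort) whose correlation still meets
#' `rho_target`; if none does, the threshold with the highest correlation
#' is returned.
#'
#' @param scorer scoring function from [train_and_cv()].
#' @param features [compute_features()] output for ALL users (not just
#'   SIUs).
#' @param sius [detect_sius()] output.
#' @param incidence an [incidence_table()].
#' @param n_users total number of users in the log population.
#' @param grid numeric vector of thresholds; must contain 0.
#' @param rho_target minimum acceptable Spearman correlation (default
#'   0.3).
#' @return list with `threshold`, `curve` (data frame `threshold`, `rho`,
#'   `cohort_size`) and `rho_target`.
#' @export
tune_threshold <- function(scorer, features, sius, incidence, n_users,
                           grid = c(0, 2^seq(-10, -1)), rho_target = 0.3) {
  if (!length(grid)) stop("empty threshold grid")
  if (!any(grid == 0)) stop("threshold grid must include 0 (the SIU-only point)")
  grid <- sort(unique(grid))
  scores <- scorer(features)
  prim <- sius[sius$primary, , drop = FALSE]
  rows <- lapply(grid, function(t) {
    if (t == 0) {
      cond <- prim$condition
      size <- nrow(prim)
    } else {
      sel <- scores > t & !features$user_id %in% prim$user_id
      cond <- c(prim$condition, features$most_common_disease[sel])
      size <- length(cond)
    }
    counts <- table(cond)
    common <- intersect(names(counts), incidence$condition)
    rho <- if (length(common) >= 3L) {
      suppressWarnings(stats::cor(
        as.numeric(counts[common]) / n_users,
        incidence$incidence[match(common, incidence$condition)],
        method = "spearman"))
    } else NA_real_
    data.frame(threshold = t, rho = rho, cohort_size = size)
  })
  curve <- do.call(rbind, rows)
  ok <- which(!is.na(curve$rho) & curve$rho >= rho_target)
  threshold <- if (length(ok)) {
    # largest admissible cohort; ties broken toward the smaller threshold
    best <- ok[order(-curve$cohort_size[ok], curve$threshold[ok])][1]
    curve$threshold[best]
  } else if (any(!is.na(curve$rho))) {
    curve$threshold[which.max(curve$rho)]
  } else {
    0  # correlation never computable (too few conditions): SIU-only cohort
  }
  list(threshold = threshold, curve = curve, rho_target = rho_target)
}

#' Expand the self-identified set into the event cohort
#'
#' Self-identified users enter with their self-identification day as the
#' event day. Non-SIU users scoring above the threshold enter with the
#' condition they queried most often; their event day is the day of their
#' FIRST query mentioning that condition (by analogy with the assumption
#' that self-identification happens at onset -- the source method leaves
#' this day undefined). The union is duplicate-free: a user who is both an
#' SIU and above threshold appears once, as an SIU.
#'
#' @param scorer scoring function from [train_and_cv()].
#' @param threshold score threshold; 0 means SIU-only.
#' @param features [compute_features()] output for all users.
#' @param sius [detect_sius()] output.
#' @param log the [query_log()].
#' @param lexicon the [med_lexicon()] used to match condition mentions.
#' @return object of class `cohort`: data frame `user_id`, `condition`,
#'   `event_day`, `source` (`"siu"` or `"classified"`).
#' @export
expand_cohort <- function(scorer, threshold, features, sius, log, lexicon) {
  prim <- sius[sius$primary, , drop = FALSE]
  out <- data.frame(user_id = prim$user_id, condition = prim$condition,
                    event_day = prim$event_day, source = "siu",
                    stringsAsFactors = FALSE)
  if (threshold > 0 && nrow(features)) {
    scores <- scorer(features)
    sel <- scores > threshold & !features$user_id %in% prim$user_id
    if (any(sel)) {
      cls <- features[sel, c("user_id", "most_common_disease")]
      # first day each classified user mentioned their assigned condition
      m <- match_terms_batch(log$text, lexicon)
      m <- m[m$kind == "disease", , drop = FALSE]
      mention <- data.frame(user_id = log$user_id[m$idx],
                            day = log$day[m$idx],
                            condition = m$canonical,
                            stringsAsFactors = FALSE)
      mention <- mention[paste(mention$user_id, mention$condition) %in%
                           paste(cls$user_id, cls$most_common_disease), ,
                         drop = FALSE]
      first <- stats::aggregate(day ~ user_id + condition, mention, min)
      i <- match(paste(cls$user_id, cls$most_common_disease),
                 paste(first$user_id, first$condition))
      out <- rbind(out, data.frame(
        user_id = cls$user_id,
        condition = cls$most_common_disease,
        event_day = first$day[i],
        source = "classified",
        stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[!is.na(out$event_day), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("Event cohort:", nrow(x), "users (",
      sum(x$source == "siu"), "self-identified,",
      sum(x$source == "classified"), "classified ) over",
      length(unique(x$condition)), "conditions\n")
  invisible(x)
}

#' Multi-class accuracy of condition prediction from term counts
#'
#' Cross-validated accuracy of a linear support vector machine predicting
#' each self-identified user's condition from their term-count vector,
#' restricted to the given attribute kinds (diseases, drugs, symptoms and
#' combinations). Measures which kinds of medical terms carry the signal.
#'
#' @param vectors a [build_term_vectors()] result.
#' @param sius [detect_sius()] output; primary records are the labels.
#' @param attribute_sets list of character vectors of kinds, e.g.
#'   `list("disease", "drug", c("disease", "drug"))`.
#' @param k_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @return named numeric vector of CV accuracies (names are the attribute
#'   sets joined with `+`).
#' @export
multiclass_accuracy <- function(vectors, sius,
                                attribute_sets = list(
                                  "disease", "drug", "symptom",
                                  c("disease", "drug"),
                                  c("disease", "drug", "symptom")),
                                k_folds = 5L, seed = 1L) {
  prim <- sius[sius$primary, , drop = FALSE]
  if (length(unique(prim$condition)) < 2L)
    stop("degenerate labels: need at least two conditions")
  y <- factor(prim$condition)
  fold <- stratified_folds(as.integer(y), k_folds, seed)
  sub <- vectors[vectors$user_id %in% prim$user_id, , drop = FALSE]
  res <- vapply(attribute_sets, function(kinds) {
    v <- sub[sub$kind %in% kinds, , drop = FALSE]
    terms <- sort(unique(v$canonical))
    X <- matrix(0, nrow(prim), max(length(terms), 1L),
                dimnames = list(prim$user_id,
                                if (length(terms)) terms else ".none"))
    if (length(terms))
      X[cbind(match(v$user_id, prim$user_id), match(v$canonical, terms))] <- v$count
    correct <- 0L
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      fit <- suppressWarnings(e1071::svm(
        X[tr, , drop = FALSE], droplevels(y[tr]), kernel = "linear",
        scale = FALSE))
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    correct / nrow(prim)
  }, 0)
  names(res) <- vapply(attribute_sets, paste, "", collapse = "+")
  res
}
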
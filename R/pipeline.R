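#' Run the full precursor-discovery pipeline
#'
#' The three-stage flow on any query log: (1) identify the event
#' population -- detect self-identified users, keep conditions with at
#' least `min_siu` of them, optionally expand the cohort with the linear
#' classifier tuned against the reference incidence table; (2) generalize
#' queries into labels through the category map; (3) per condition, screen
#' candidate labels with the temporal-confound filter, fit the SCCS model
#' to each survivor and control the FDR across candidates.
#'
#' All randomness (cross-validation folds, background sampling) flows from
#' `seed`; two runs with the same inputs and seed produce identical
#' reports.
#'
#' @param log a [query_log()].
#' @param lexicon a [med_lexicon()].
#' @param map a [category_map()].
#' @param incidence an [incidence_table()] used for the SIU sanity check
#'   and threshold tuning.
#' @param min_siu minimum self-identified users per condition (default
#'   25).
#' @param min_fraction candidate-label threshold (default 0.01).
#' @param W risk-window length in days (default 15).
#' @param q FDR level (default 0.05).
#' @param rho_target threshold-tuning correlation target (default 0.3).
#' @param threshold_grid grid for [tune_threshold()]; must contain 0.
#' @param background_multiple background sample size as a multiple of the
#'   cohort size (default 10).
#' @param use_classifier if `FALSE`, skip cohort expansion and screen the
#'   SIU-only cohort.
#' @param pre_event_only passed to [build_case_series()].
#' @param seed integer seed.
#' @param out_dir optional directory; when given, per-stage TSV artifacts
#'   (SIU records, cohort, candidate stats, the final report) are written
#'   there.
#' @return object of class `precursor_screen`: list with `report` (all
#'   conditions' significant rows, sorted by condition then decreasing
#'   relative hazard), `screens` (per-condition [run_screen()] results),
#'   `sius`, `conditions`, `cohort`, `siu_incidence` (the rank-correlation
#'   check, or NULL), `classifier` (AUC, threshold and tuning curve, or
#'   NULL), `stage_log` (character vector of counts in/out at each
#'   filter).
#' @export
run_all <- function(log, lexicon, map, incidence,
                    min_siu = 25L, min_fraction = 0.01, W = 15L, q = 0.05,
                    rho_target = 0.3, threshold_grid = c(0, 2^seq(-10, -1)),
                    background_multiple = 10L, use_classifier = TRUE,
                    pre_event_only = FALSE, seed = 1L, out_dir = NULL) {
  set.seed(seed)
  msgs <- character(0)
  note <- function(...) msgs <<- c(msgs, paste0(...))
  L <- attr(log, "observation_length")
  n_users_total <- length(unique(log$user_id))
  note("input: ", nrow(log), " records, ", n_users_total, " users")

  # stage 1a: self-identified users
  sius <- detect_sius(log, lexicon)
  note("SIU detection: ", sum(sius$primary), " users self-identified (",
       nrow(sius), " user-condition records)")
  fc <- filter_conditions(sius, min_siu)
  note("condition filter (>= ", min_siu, " SIUs): ",
       length(fc$conditions), " conditions retained, ",
       fc$n_dropped, " records dropped")
  sius_kept <- fc$sius

  siu_rho <- tryCatch(
    siu_incidence_check(sius_kept, n_users_total, incidence),
    error = function(e) NULL)
  if (!is.null(siu_rho))
    note("SIU incidence check: spearman rho = ", round(siu_rho$rho, 3),
         " over ", siu_rho$n, " conditions")

  empty_report <- data.frame(
    condition = character(), precursor = character(), kind = character(),
    relative_hazard = numeric(), p_value = numeric(),
    n_users_exposed = integer(), fdr_significant = logical(),
    stringsAsFactors = FALSE)

  if (!length(fc$conditions)) {
    note("no condition reached the SIU threshold; empty report")
    return(structure(list(report = empty_report, screens = list(),
                          sius = sius, conditions = character(),
                          cohort = NULL, siu_incidence = siu_rho,
                          classifier = NULL, stage_log = msgs),
                     class = "precursor_screen"))
  }

  # stage 1b: cohort expansion via the linear classifier
  vectors <- build_term_vectors(log, lexicon)
  classifier <- NULL
  cohort <- NULL
  if (use_classifier) {
    feats <- compute_features(vectors)
    labs <- label_training(sius_kept, feats)
    trainable <- nrow(labs) >= 20L && length(unique(labs$label)) == 2L &&
      min(table(labs$label)) >= 5L
    if (trainable) {
      tri <- match(labs$user_id, feats$user_id)
      tc <- train_and_cv(feats[tri, , drop = FALSE], labs$label, seed = seed)
      tt <- tryCatch(
        tune_threshold(tc$scorer, feats, sius_kept, incidence, n_users_total,
                       grid = threshold_grid, rho_target = rho_target),
        error = function(e) list(threshold = 0, curve = NULL))
      cohort <- expand_cohort(tc$scorer, tt$threshold, feats, sius_kept,
                              log, lexicon)
      classifier <- list(auc = tc$auc, threshold = tt$threshold,
                         curve = tt$curve)
      note("classifier: CV AUC = ", round(tc$auc, 3),
           ", threshold = ", signif(tt$threshold, 3),
           ", cohort = ", nrow(cohort), " users (",
           sum(cohort$source == "classified"), " classified)")
    } else {
      note("classifier skipped: training labels degenerate or too few; ",
           "using the SIU-only cohort")
    }
  }
  if (is.null(cohort))
    cohort <- expand_cohort(NULL, 0, NULL, sius_kept, log, lexicon)
  cohort <- cohort[cohort$condition %in% fc$conditions, , drop = FALSE]
  class(cohort) <- c("cohort", "data.frame")
  note("cohort: ", nrow(cohort), " users over ",
       length(unique(cohort$condition)), " retained conditions")

  # stage 2: label annotation
  annotated <- annotate_log(log, map)

  # stage 3: per-condition screening against a seeded background sample
  non_cohort <- setdiff(unique(log$user_id), cohort$user_id)
  bg_n <- min(length(non_cohort), background_multiple * nrow(cohort))
  background_users <- sort(sample(non_cohort, bg_n))
  note("background sample: ", bg_n, " users")

  screens <- list()
  for (cond in sort(intersect(fc$conditions, unique(cohort$condition)))) {
    scr <- run_screen(cond, cohort, annotated, background_users,
                      q = q, W = W, min_fraction = min_fraction,
                      lexicon = lexicon, observation_length = L,
                      pre_event_only = pre_event_only)
    screens[[cond]] <- scr
    note("screen '", cond, "': ", nrow(scr$candidates), " candidates, ",
         sum(scr$temporal$rejected), " confounded, ",
         nrow(scr$report), " significant")
  }
  report <- do.call(rbind, c(list(empty_report),
                             lapply(screens, function(s) s$report)))
  report <- report[order(report$condition, -report$relative_hazard,
                         report$precursor), , drop = FALSE]
  rownames(report) <- NULL

  res <- structure(list(report = report, screens = screens, sius = sius,
                        conditions = fc$conditions, cohort = cohort,
                        siu_incidence = siu_rho, classifier = classifier,
                        stage_log = msgs),
                   class = "precursor_screen")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sius, file.path(out_dir, "sius.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(cohort), file.path(out_dir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cond in names(screens))
      utils::write.table(screens[[cond]]$fits,
                         file.path(out_dir, paste0("fits_", gsub(" ", "_", cond), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(report, file.path(out_dir, "report.tsv"))
    writeLines(msgs, file.path(out_dir, "stages.log"))
  }
  res
}

#' @export
print.precursor_screen <- function(x, ...) {
  cat("Precursor screen over", length(x$screens), "condition(s);",
      nrow(x$report), "significant precursor(s)\n")
  for (m in x$stage_log) cat(" -", m, "\n")
  if (nrow(x$report)) {
    cat("\n")
    print(x$report)
  }
  invisible(x)
}

#' Write a precursor report file
#'
#' Tab-separated, one row per precursor, mirroring the standard report
#' layout: condition, precursor, kind (`Category` or `Query`), relative
#' hazard printed with two decimals, p-value, number of exposed users.
#'
#' @param report the `report` component of a [run_all()] or
#'   [run_screen()] result.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- data.frame(
    condition = report$condition,
    precursor = report$precursor,
    kind = ifelse(report$kind == "category", "Category", "Query"),
    relative_hazard = sprintf("%.2f", report$relative_hazard),
    p_value = signif(report$p_value, 4),
    n_users_exposed = report$n_users_exposed,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
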
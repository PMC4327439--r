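#' Configuration for the synthetic query-log simulator
#'
#' Collects every knob of the generative model realized by
#' [simulate_querylog()]. Defaults encode the study conditions the method
#' was designed for: a six-month (183-day) observation window; affected
#' users querying their own condition 6.8 times on average against 2.15 in
#' the general disease-querying population; and a 15-day post-exposure risk
#' window for planted precursor categories.
#'
#' @param n_users number of simulated users.
#' @param observation_length window length in days.
#' @param incidence an [incidence_table()]: condition names (which must be
#'   diseases in `lexicon`) and population fractions. Fractions must sum to
#'   at most 1; each user has at most one condition.
#' @param siu_fraction fraction of affected users who emit a
#'   self-identifying trigger query ("i was diagnosed with ...") on their
#'   event day.
#' @param mean_condition_queries_affected mean number of own-condition
#'   queries an affected user issues after the event (default 6.8).
#' @param mean_condition_queries_background mean number of disease queries
#'   for users querying a disease they do not have (default 2.15).
#' @param precursors data frame with columns `condition`, `category`,
#'   `relative_hazard` and `window`: planted precursor categories whose
#'   queries multiply the event hazard by `relative_hazard` for `window`
#'   days.
#' @param precursor_user_fraction fraction of affected users who receive
#'   extra planted exposure queries for their condition's precursor
#'   categories.
#' @param precursor_exposures_mean mean number of planted exposure queries
#'   per exposed user (Poisson, at least one).
#' @param background_categories data frame with columns `category` and
#'   `daily_prob`: per user-day query probability for globally neutral
#'   categories.
#' @param news_spikes data frame with columns `category`, `spike_day`,
#'   `spike_height` and `duration`: categories that spike for a few days in
#'   the whole population (emulating news-driven query bursts), the planted
#'   temporal confounders.
#' @param disease_query_fraction fraction of users who also query one
#'   random unrelated disease at the background mean.
#' @param lexicon a [med_lexicon()] supplying disease names (default
#'   [toy_lexicon()]).
#' @param seed integer seed; every random draw in the simulator flows from
#'   it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_users = 2000L,
                       observation_length = 183L,
                       incidence = incidence_table(
                         c("hypertension", "diabetes mellitus", "asthma", "migraine"),
                         c(0.03, 0.02, 0.015, 0.01)),
                       siu_fraction = 0.5,
                       mean_condition_queries_affected = 6.8,
                       mean_condition_queries_background = 2.15,
                       precursors = NULL,
                       precursor_user_fraction = 0.8,
                       precursor_exposures_mean = 2,
                       background_categories = data.frame(
                         category = paste("interest", letters[1:8]),
                         daily_prob = 0.004,
                         stringsAsFactors = FALSE),
                       news_spikes = NULL,
                       disease_query_fraction = 0.3,
                       lexicon = toy_lexicon(),
                       seed = 1L) {
  if (is.null(precursors))
    precursors <- data.frame(condition = character(), category = character(),
                             relative_hazard = numeric(), window = integer(),
                             stringsAsFactors = FALSE)
  if (is.null(news_spikes))
    news_spikes <- data.frame(category = character(), spike_day = integer(),
                              spike_height = numeric(), duration = integer(),
                              stringsAsFactors = FALSE)
  if (!"duration" %in% names(news_spikes) && nrow(news_spikes) >= 0)
    news_spikes$duration <- rep(3L, nrow(news_spikes))
  stopifnot(n_users >= 1L, observation_length >= 2L)
  if (sum(incidence$incidence) > 1)
    stop("incidence fractions sum to more than 1")
  diseases <- lexicon$terms$canonical[lexicon$terms$kind == "disease"]
  unknown <- setdiff(incidence$condition, diseases)
  if (length(unknown))
    stop("conditions not in the lexicon as diseases: ",
         paste(unknown, collapse = ", "))
  for (fr in c(siu_fraction, precursor_user_fraction, disease_query_fraction))
    stopifnot(fr >= 0, fr <= 1)
  if (nrow(precursors)) {
    stopifnot(all(precursors$relative_hazard > 0), all(precursors$window >= 1))
    if (!all(precursors$condition %in% incidence$condition))
      stop("precursor conditions must appear in the incidence table")
  }
  structure(list(
    n_users = as.integer(n_users),
    observation_length = as.integer(observation_length),
    incidence = incidence,
    siu_fraction = siu_fraction,
    mean_condition_queries_affected = mean_condition_queries_affected,
    mean_condition_queries_background = mean_condition_queries_background,
    precursors = precursors,
    precursor_user_fraction = precursor_user_fraction,
    precursor_exposures_mean = precursor_exposures_mean,
    background_categories = background_categories,
    news_spikes = news_spikes,
    disease_query_fraction = disease_query_fraction,
    lexicon = lexicon,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# trigger phrases users combine with a disease name to self-identify
siu_trigger_phrases <- function() {
  c("i have", "i suffer from", "living with", "i was diagnosed with")
}

# page id and query-text variants for a category
category_page <- function(category) {
  paste0("wiki/", gsub(" ", "_", category, fixed = TRUE))
}
category_query_variants <- function(category) {
  c(category, paste(category, "online"), paste("best", category))
}

#' Simulate a query log with planted ground truth
#'
#' Realizes the exact generative law the SCCS fit assumes: each affected
#' user's event day is drawn from the multinomial implied by the
#' non-homogeneous Poisson model, with day weights `exp(beta * r_d)` where
#' `r_d = 1` inside the risk window following one of the user's precursor
#' category queries. Because the generator and the fitted likelihood
#' coincide, parameter recovery is a sharp test of the estimator.
#'
#' On top of the planted precursor exposures the log contains: background
#' category queries (uniform user-day Bernoulli), news-spike category
#' bursts synchronized across the whole population, own-condition queries
#' (Poisson with the affected mean after the event day, the background mean
#' scaled to the pre-event span before it), unrelated disease queries, and
#' self-identifying trigger queries on the event day for a `siu_fraction`
#' subset of affected users.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result` with components:
#'   * `log`: the [query_log()];
#'   * `truth`: data frame `user_id`, `condition`, `event_day`, `is_siu`,
#'     `n_planted_exposures` for every affected user;
#'   * `category_map`: a [category_map()] covering every category query
#'     text the simulator can emit;
#'   * `lexicon`: the lexicon used;
#'   * `config`: the input configuration.
#' @export
#' @examples
#' sim <- simulate_querylog(sim_config(n_users = 200, seed = 7))
#' sim$log
simulate_querylog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_users
  L <- config$observation_length
  uid <- sprintf("u%06d", seq_len(n))

  # 1. condition assignment (single condition per user)
  conds <- config$incidence$condition
  probs <- c(config$incidence$incidence, 1 - sum(config$incidence$incidence))
  assign <- sample(c(conds, NA_character_), n, replace = TRUE, prob = probs)
  affected <- which(!is.na(assign))

  # 2. category universe: background + news-spike baselines + precursor
  cats <- config$background_categories
  extra <- setdiff(c(config$news_spikes$category, config$precursors$category),
                   cats$category)
  if (length(extra))
    cats <- rbind(cats, data.frame(category = extra, daily_prob = 0.004,
                                   stringsAsFactors = FALSE))

  hit_user <- integer(0); hit_day <- integer(0); hit_cat <- character(0)
  add_hits <- function(u, d, cat) {
    hit_user <<- c(hit_user, u); hit_day <<- c(hit_day, d)
    hit_cat <<- c(hit_cat, rep(cat, length(u)))
  }
  for (i in seq_len(nrow(cats))) {
    ndraw <- stats::rbinom(1L, n * L, cats$daily_prob[i])
    if (!ndraw) next
    idx <- sample.int(n * L, ndraw)  # without replacement: Bernoulli per user-day
    add_hits((idx - 1L) %/% L + 1L, (idx - 1L) %% L, cats$category[i])
  }
  # news spikes: extra bursts over the whole population
  for (i in seq_len(nrow(config$news_spikes))) {
    ns <- config$news_spikes[i, ]
    days <- ns$spike_day + seq_len(ns$duration) - 1L
    days <- days[days >= 0L & days < L]
    if (!length(days)) next
    ndraw <- stats::rbinom(1L, n * length(days), ns$spike_height)
    if (!ndraw) next
    idx <- sample.int(n * length(days), ndraw)
    add_hits((idx - 1L) %/% length(days) + 1L,
             days[(idx - 1L) %% length(days) + 1L], ns$category)
  }

  # 3. planted precursor exposures for affected users
  n_planted <- integer(n)
  if (nrow(config$precursors)) {
    for (i in seq_len(nrow(config$precursors))) {
      pr <- config$precursors[i, ]
      users_c <- affected[assign[affected] == pr$condition]
      exposed <- users_c[stats::runif(length(users_c)) < config$precursor_user_fraction]
      for (u in exposed) {
        k <- 1L + stats::rpois(1L, max(config$precursor_exposures_mean - 1, 0))
        d <- sample.int(L, min(k, L)) - 1L
        add_hits(rep(u, length(d)), d, pr$category)
        n_planted[u] <- n_planted[u] + length(d)
      }
    }
  }
  # dedupe repeated (user, day, category) hits
  if (length(hit_user)) {
    dup <- duplicated(paste(hit_user, hit_day, hit_cat, sep = "\r"))
    hit_user <- hit_user[!dup]; hit_day <- hit_day[!dup]; hit_cat <- hit_cat[!dup]
  }

  # 4. event day per affected user: multinomial implied by the SCCS model
  event_day <- rep(NA_integer_, n)
  pre_by_cond <- split(seq_len(nrow(config$precursors)), config$precursors$condition)
  # per precursor category: exposure days keyed by user index
  exp_lookup <- lapply(unique(config$precursors$category), function(cat) {
    sel <- hit_cat == cat
    split(hit_day[sel], hit_user[sel])
  })
  names(exp_lookup) <- unique(config$precursors$category)
  for (u in affected) {
    w <- rep(1, L)
    rows <- pre_by_cond[[assign[u]]]
    for (i in rows) {
      pr <- config$precursors[i, ]
      ed <- exp_lookup[[pr$category]][[as.character(u)]]
      if (!length(ed)) next
      r <- risk_days(ed, pr$window, L)
      w[r + 1L] <- w[r + 1L] * pr$relative_hazard
    }
    event_day[u] <- sample.int(L, 1L, prob = w) - 1L
  }

  chunks <- list()
  emit <- function(user, day, text, click) {
    chunks[[length(chunks) + 1L]] <<- data.frame(
      user_id = user, day = day, text = text, clicked_pages = click,
      stringsAsFactors = FALSE)
  }

  # category queries, with per-hit text variant and the clicked page
  if (length(hit_user)) {
    variant <- sample.int(3L, length(hit_user), replace = TRUE)
    txt <- ifelse(variant == 1L, hit_cat,
                  ifelse(variant == 2L, paste(hit_cat, "online"),
                         paste("best", hit_cat)))
    emit(uid[hit_user], hit_day, txt, category_page(hit_cat))
  }

  # 5. own-condition queries: affected mean after the event, background
  # mean (scaled to the pre-event span) before it
  for (u in affected) {
    ev <- event_day[u]
    n_post <- stats::rpois(1L, config$mean_condition_queries_affected)
    if (n_post)
      emit(rep(uid[u], n_post), ev + sample.int(L - ev, n_post, replace = TRUE) - 1L,
           rep(assign[u], n_post), rep("", n_post))
    if (ev > 0L) {
      n_pre <- stats::rpois(1L, config$mean_condition_queries_background * ev / L)
      if (n_pre)
        emit(rep(uid[u], n_pre), sample.int(ev, n_pre, replace = TRUE) - 1L,
             rep(assign[u], n_pre), rep("", n_pre))
    }
  }

  # 6. unrelated disease queries at the background mean
  diseases <- config$lexicon$terms$canonical[config$lexicon$terms$kind == "disease"]
  bg_users <- which(stats::runif(n) < config$disease_query_fraction)
  for (u in bg_users) {
    pool <- setdiff(diseases, assign[u])
    dis <- pool[sample.int(length(pool), 1L)]
    k <- stats::rpois(1L, config$mean_condition_queries_background)
    if (!k) next
    emit(rep(uid[u], k), sample.int(L, k, replace = TRUE) - 1L,
         rep(dis, k), rep("", k))
  }

  # 7. self-identifying trigger queries on the event day
  is_siu <- rep(FALSE, n)
  if (length(affected)) {
    siu_users <- affected[stats::runif(length(affected)) < config$siu_fraction]
    is_siu[siu_users] <- TRUE
    if (length(siu_users)) {
      phr <- sample(siu_trigger_phrases(), length(siu_users), replace = TRUE)
      emit(uid[siu_users], event_day[siu_users],
           paste(phr, assign[siu_users]), rep("", length(siu_users)))
    }
  }

  records <- do.call(rbind, chunks)
  records <- records[order(records$user_id, records$day, records$text,
                           records$clicked_pages), , drop = FALSE]
  log <- query_log(records, L)

  truth <- data.frame(
    user_id = uid[affected],
    condition = assign[affected],
    event_day = event_day[affected],
    is_siu = is_siu[affected],
    n_planted_exposures = n_planted[affected],
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$user_id), , drop = FALSE]
  rownames(truth) <- NULL

  map <- category_map(
    query = unlist(lapply(cats$category, category_query_variants)),
    page = rep(category_page(cats$category), each = 3L),
    categories = rep(cats$category, each = 3L)
  )

  structure(list(log = log, truth = truth, category_map = map,
                 lexicon = config$lexicon, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Synthetic query log: ", nrow(x$log), " records, ",
      x$config$n_users, " users, ", nrow(x$truth), " affected (",
      sum(x$truth$is_siu), " self-identified)\n", sep = "")
  if (nrow(x$config$precursors)) {
    cat("Planted precursors:\n")
    print(x$config$precursors)
  }
  invisible(x)
}

#' Simulate case series directly from the SCCS model
#'
#' Bypasses the query-log layer: draws per-user exposure days uniformly,
#' forms risk windows, and samples the single event day from the
#' multinomial with weights `exp(beta)` on risk days and 1 elsewhere --
#' the law under which the [sccs()] likelihood is exact. Used for
#' parameter-recovery and coverage experiments.
#'
#' @param n_users number of users.
#' @param relative_hazard true multiplicative effect `exp(beta)` on risk
#'   days.
#' @param W risk-window length in days.
#' @param observation_length window length in days.
#' @param exposures_mean mean number of exposure days per exposed user
#'   (at least one).
#' @param exposed_fraction fraction of users with any exposure.
#' @param seed optional integer seed.
#' @return a `case_series` (see [build_case_series()]).
#' @export
simulate_case_series <- function(n_users = 2000L, relative_hazard = 3,
                                 W = 15L, observation_length = 183L,
                                 exposures_mean = 2, exposed_fraction = 1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(relative_hazard > 0, W >= 1L)
  L <- as.integer(observation_length)
  n1 <- integer(n_users); e <- logical(n_users)
  for (i in seq_len(n_users)) {
    if (stats::runif(1) >= exposed_fraction) {
      # unexposed: event uniform, no risk days
      next
    }
    k <- 1L + stats::rpois(1L, max(exposures_mean - 1, 0))
    ed <- sample.int(L, min(k, L)) - 1L
    r <- risk_days(ed, W, L)
    n1[i] <- length(r)
    w <- rep(1, L); w[r + 1L] <- relative_hazard
    ev <- sample.int(L, 1L, prob = w) - 1L
    e[i] <- ev %in% r
  }
  case_series(n1, L - n1, e, W = W, observation_length = L)
}
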
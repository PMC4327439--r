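#' Risk days implied by exposure days
#'
#' The risk window after an exposure on day `d` is `(d, d + W]`: the
#' exposure day itself is excluded ("the W days following"), optionally
#' included via `include_exposure_day`. Windows from multiple exposures are
#' unioned and clipped to the observation window `[0, observation_length)`.
#'
#' @param exposure_days integer vector of days on which the exposure
#'   occurred (0-based).
#' @param W risk-window length in days (default 15).
#' @param observation_length observation window length in days.
#' @param include_exposure_day if `TRUE`, the exposure day itself is a risk
#'   day.
#' @return sorted integer vector of risk days.
#' @export
#' @examples
#' risk_days(10, W = 15, observation_length = 183)   # days 11..25
#' risk_days(180, W = 15, observation_length = 183)  # clipped: 181, 182
risk_days <- function(exposure_days, W = 15L, observation_length = 183L,
                      include_exposure_day = FALSE) {
  stopifnot(W >= 1L)
  exposure_days <- unique(as.integer(exposure_days))
  if (!length(exposure_days)) return(integer())
  lo <- if (include_exposure_day) 0L else 1L
  d <- unique(unlist(lapply(exposure_days, function(e) e + lo:W)))
  sort(d[d >= 0L & d < observation_length])
}

#' Build a case series for one candidate exposure label
#'
#' Reduces a cohort and its exposure days for one candidate label to the
#' per-user summaries the SCCS likelihood depends on: number of risk days,
#' number of baseline days, and whether the (single) event fell on a risk
#' day. Users with zero risk days (never exposed) or zero baseline days
#' (risk windows cover the whole observation window) carry no information
#' about the relative hazard and are flagged `informative = FALSE`.
#'
#' @param cohort data frame with columns `user_id` and `event_day` (one
#'   event per user).
#' @param exposures data frame with columns `user_id` and `day`: the days
#'   on which each user issued a query carrying the candidate label.
#'   Users absent from `exposures` are unexposed.
#' @param W risk-window length in days (default 15).
#' @param observation_length observation window length in days.
#' @param include_exposure_day passed to [risk_days()].
#' @param pre_event_only if `TRUE`, exposures on or after the event day are
#'   discarded before building risk windows. The default (`FALSE`) is the
#'   standard SCCS treatment: observation is not censored at the event, so
#'   post-event exposures still contribute risk time.
#' @param label optional label name stored on the result.
#' @return object of class `case_series`: data frame with one row per
#'   cohort user and columns `user_id`, `event_day`, `n_risk_days`,
#'   `n_baseline_days`, `event_in_risk`, `informative`; attributes `W` and
#'   `observation_length`.
#' @seealso [sccs()] which fits the model to a case series.
#' @export
build_case_series <- function(cohort, exposures, W = 15L,
                              observation_length = 183L,
                              include_exposure_day = FALSE,
                              pre_event_only = FALSE,
                              label = NULL) {
  stopifnot(is.data.frame(cohort), all(c("user_id", "event_day") %in% names(cohort)))
  if (!nrow(cohort)) stop("empty cohort")
  if (anyDuplicated(cohort$user_id)) stop("one event per user: duplicate user_id in cohort")
  stopifnot(all(cohort$event_day >= 0L & cohort$event_day < observation_length))
  exp_by_user <- if (!is.null(exposures) && nrow(exposures))
    split(as.integer(exposures$day), as.character(exposures$user_id))
  else list()
  n <- nrow(cohort)
  n_risk <- integer(n); in_risk <- logical(n)
  for (i in seq_len(n)) {
    ed <- exp_by_user[[as.character(cohort$user_id[i])]]
    if (pre_event_only && length(ed)) ed <- ed[ed < cohort$event_day[i]]
    if (!length(ed)) next
    r <- risk_days(ed, W, observation_length, include_exposure_day)
    n_risk[i] <- length(r)
    in_risk[i] <- cohort$event_day[i] %in% r
  }
  out <- data.frame(
    user_id = as.character(cohort$user_id),
    event_day = as.integer(cohort$event_day),
    n_risk_days = n_risk,
    n_baseline_days = as.integer(observation_length) - n_risk,
    event_in_risk = in_risk,
    stringsAsFactors = FALSE
  )
  out$informative <- out$n_risk_days > 0L & out$n_baseline_days > 0L
  structure(out, W = as.integer(W),
            observation_length = as.integer(observation_length),
            label = label,
            class = c("case_series", "data.frame"))
}

#' Assemble a case series from per-user summaries
#'
#' Constructs a `case_series` directly from the sufficient summaries the
#' SCCS likelihood depends on, bypassing the query-log layer. Used by the
#' simulator and wherever a series with known structure is needed.
#'
#' @param n_risk_days integer vector: risk days per user.
#' @param n_baseline_days integer vector: baseline days per user.
#' @param event_in_risk logical vector: did the user's event fall on a
#'   risk day.
#' @param W risk-window length the series was built with.
#' @param observation_length window length in days; defaults to the
#'   maximum of `n_risk_days + n_baseline_days`.
#' @param user_id optional user identifiers.
#' @param event_day optional event days (kept for bookkeeping only; the
#'   likelihood does not use them).
#' @param label optional label name.
#' @return a `case_series` (see [build_case_series()]).
#' @export
case_series <- function(n_risk_days, n_baseline_days, event_in_risk,
                        W = 15L, observation_length = NULL, user_id = NULL,
                        event_day = NA_integer_, label = NULL) {
  n <- length(n_risk_days)
  if (is.null(observation_length))
    observation_length <- max(n_risk_days + n_baseline_days)
  out <- data.frame(
    user_id = if (is.null(user_id)) sprintf("u%05d", seq_len(n)) else as.character(user_id),
    event_day = rep_len(as.integer(event_day), n),
    n_risk_days = as.integer(n_risk_days),
    n_baseline_days = as.integer(n_baseline_days),
    event_in_risk = as.logical(event_in_risk),
    stringsAsFactors = FALSE
  )
  out$informative <- out$n_risk_days > 0L & out$n_baseline_days > 0L
  structure(out, W = as.integer(W),
            observation_length = as.integer(observation_length),
            label = label,
            class = c("case_series", "data.frame"))
}

#' @export
print.case_series <- function(x, ...) {
  cat("SCCS case series: ", nrow(x), " users (",
      sum(x$informative), " informative, ",
      sum(x$n_risk_days > 0L), " exposed), W = ", attr(x, "W"),
      ", window ", attr(x, "observation_length"), " days\n", sep = "")
  invisible(x)
}

#' SCCS Poisson log-likelihood
#'
#' The model: each user i has one event in an observation window of
#' `D_i` days; the daily event rate is `exp(theta_i)` on baseline days and
#' `exp(theta_i + beta)` on risk days. The Poisson log-likelihood, up to an
#' additive constant, is
#' `sum_i [ (theta_i + beta * e_i) - exp(theta_i) * (n0_i + n1_i * exp(beta)) ]`
#' where `e_i` indicates an event on a risk day and `n1_i`, `n0_i` count
#' risk and baseline days.
#'
#' @param series a [build_case_series()] result.
#' @param beta log relative hazard.
#' @param thetas per-user baseline log rates, length `nrow(series)`.
#' @return scalar log-likelihood (up to an additive constant).
#' @export
sccs_loglik <- function(series, beta, thetas) {
  stopifnot(inherits(series, "case_series"), is.finite(beta))
  if (length(thetas) != nrow(series))
    stop("thetas must have one element per user (", nrow(series), ")")
  sum(thetas + beta * series$event_in_risk -
        exp(thetas) * (series$n_baseline_days + series$n_risk_days * exp(beta)))
}

# Profile log-likelihood in beta: theta_i maximized out in closed form.
# With one event per user, theta_hat_i(beta) = -log(n0_i + n1_i e^beta), and
# each user's profiled contribution (dropping constants) is
#   e_i * beta - log(n0_i + n1_i * e^beta).
# Aggregated over strata of identical (n1, n0): k users, k1 with the event
# in risk.
sccs_profile_loglik <- function(beta, n1, n0, k, k1) {
  sum(k1 * beta - k * log(n0 + n1 * exp(beta)))
}

#' Fit the self-controlled case series model
#'
#' Estimates the log relative hazard `beta` of the event during
#' post-exposure risk windows by maximum likelihood. The per-user baseline
#' rates are profiled out in closed form (for a single event per user the
#' profiled contribution is the conditional multinomial likelihood), leaving
#' a one-dimensional concave profile likelihood in `beta` that is maximized
#' numerically with the Nelder-Mead simplex by default. The profile
#' maximizer equals the joint maximizer over all baseline rates and `beta`;
#' [sccs_joint()] checks this directly on small series.
#'
#' The p-value is a likelihood-ratio test of `beta = 0` against the
#' chi-squared distribution with 1 degree of freedom. Estimates are capped
#' at `|beta| <= beta_cap`; a fit that hits the cap (all informative events
#' on risk days, or none) is flagged `converged = FALSE`.
#'
#' @param series a [build_case_series()] result.
#' @param method `"Nelder-Mead"` (default) or `"optimize"` (golden-section
#'   on the same profile likelihood).
#' @param beta_cap cap on `|beta|` (default 10).
#' @param tol convergence tolerance on the profile log-likelihood.
#' @param maxit maximum simplex iterations.
#' @return object of class `sccs` with components `coefficients` (named
#'   `log_relative_hazard`), `relative_hazard`, `se`, `loglik`,
#'   `loglik_null`, `lrt_stat`, `p_value`, `n_users`, `n_informative`,
#'   `n_exposed_users`, `converged`, `theta` (profiled baseline log rates at
#'   the estimate), `W`, `label`.
#' @export
#' @examples
#' # homogeneous design: 3 risk / 7 baseline days, 60 of 100 events in risk
#' s <- case_series(rep(3, 100), rep(7, 100),
#'                  rep(c(TRUE, FALSE), c(60, 40)), W = 3)
#' fit <- sccs(s)
#' fit$relative_hazard  # (60 * 7) / (40 * 3) = 3.5
sccs <- function(series, method = c("Nelder-Mead", "optimize"),
                 beta_cap = 10, tol = 1e-8, maxit = 500L) {
  method <- match.arg(method)
  stopifnot(inherits(series, "case_series"))
  inf <- series[series$informative, , drop = FALSE]
  if (!nrow(inf))
    stop("no informative users: every user lacks risk days or baseline days")
  # aggregate identical (n1, n0) strata; the likelihood depends on nothing else
  key <- paste(inf$n_risk_days, inf$n_baseline_days)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(inf)), key), function(ix) {
    data.frame(n1 = inf$n_risk_days[ix[1]], n0 = inf$n_baseline_days[ix[1]],
               k = length(ix), k1 = sum(inf$event_in_risk[ix]))
  }))
  tot_e <- sum(agg$k1); tot_k <- sum(agg$k)
  converged <- TRUE
  if (tot_e == 0L) {
    beta_hat <- -beta_cap; converged <- FALSE
  } else if (tot_e == tot_k) {
    beta_hat <- beta_cap; converged <- FALSE
  } else if (method == "optimize") {
    opt <- stats::optimize(function(b) sccs_profile_loglik(b, agg$n1, agg$n0, agg$k, agg$k1),
                           c(-beta_cap, beta_cap), maximum = TRUE, tol = 1e-10)
    beta_hat <- opt$maximum
  } else {
    opt <- suppressWarnings(stats::optim(
      0, function(b) -sccs_profile_loglik(b, agg$n1, agg$n0, agg$k, agg$k1),
      method = "Nelder-Mead",
      control = list(abstol = tol, reltol = 1e-12, maxit = maxit)
    ))
    beta_hat <- opt$par
    if (opt$convergence != 0L) converged <- FALSE
    # Newton polish on the analytic score: the profile likelihood is
    # smooth and concave, so a couple of steps pin the maximizer down to
    # machine precision regardless of simplex stopping noise
    for (it in 1:5) {
      p1 <- agg$n1 * exp(beta_hat) / (agg$n0 + agg$n1 * exp(beta_hat))
      score <- sum(agg$k1 - agg$k * p1)
      info <- sum(agg$k * p1 * (1 - p1))
      if (info <= 0) break
      step <- score / info
      beta_hat <- beta_hat + max(min(step, 1), -1)
      if (abs(step) < 1e-12) break
    }
  }
  if (abs(beta_hat) >= beta_cap) {
    beta_hat <- sign(beta_hat) * beta_cap
    converged <- FALSE
  }
  ll_hat <- sccs_profile_loglik(beta_hat, agg$n1, agg$n0, agg$k, agg$k1)
  ll_null <- sccs_profile_loglik(0, agg$n1, agg$n0, agg$k, agg$k1)
  lrt <- max(0, 2 * (ll_hat - ll_null))
  # observed information of the profile likelihood
  p1 <- agg$n1 * exp(beta_hat) / (agg$n0 + agg$n1 * exp(beta_hat))
  info <- sum(agg$k * p1 * (1 - p1))
  theta <- -log(series$n_baseline_days + series$n_risk_days * exp(beta_hat))
  structure(list(
    coefficients = c(log_relative_hazard = beta_hat),
    relative_hazard = exp(beta_hat),
    se = if (info > 0) 1 / sqrt(info) else NA_real_,
    loglik = ll_hat,
    loglik_null = ll_null,
    lrt_stat = lrt,
    p_value = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
    n_users = nrow(series),
    n_informative = nrow(inf),
    n_exposed_users = sum(series$n_risk_days > 0L),
    n_events_in_risk = tot_e,
    converged = converged,
    theta = stats::setNames(theta, series$user_id),
    W = attr(series, "W"),
    observation_length = attr(series, "observation_length"),
    label = attr(series, "label"),
    method = method,
    strata = agg,
    call = match.call()
  ), class = "sccs")
}

#' Joint maximum-likelihood oracle for small case series
#'
#' Maximizes the full Poisson log-likelihood over all per-user baseline
#' rates and `beta` simultaneously with the Nelder-Mead simplex, without
#' profiling. Exponentially slower than [sccs()] and intended as an
#' independent cross-check on small series (tens of users): the two
#' maximizers agree because profiling the baseline rates is exact.
#'
#' @inheritParams sccs
#' @param maxit maximum simplex iterations.
#' @return list with `beta_hat`, `relative_hazard`, `loglik` (full, up to
#'   the same additive constant as [sccs_loglik()]) and `convergence`.
#' @export
sccs_joint <- function(series, beta_cap = 10, maxit = 2000L) {
  stopifnot(inherits(series, "case_series"))
  inf <- series[series$informative, , drop = FALSE]
  if (!nrow(inf)) stop("no informative users")
  n <- nrow(series)
  par0 <- c(rep(-log(attr(series, "observation_length")), n), 0)
  negll <- function(par) {
    b <- par[n + 1L]
    if (abs(b) > beta_cap) return(1e10 + (abs(b) - beta_cap) * 1e6)
    -sccs_loglik(series, b, par[seq_len(n)])
  }
  neggr <- function(par) {
    b <- min(max(par[n + 1L], -beta_cap), beta_cap)
    th <- par[seq_len(n)]
    mu <- exp(th) * (series$n_baseline_days + series$n_risk_days * exp(b))
    g_th <- 1 - mu
    g_b <- sum(series$event_in_risk) - sum(exp(th) * series$n_risk_days * exp(b))
    -c(g_th, g_b)
  }
  # simplex search, restarted at the incumbent (Nelder-Mead stalls in many
  # dimensions), then a quasi-Newton polish with the analytic gradient --
  # the joint likelihood is smooth and concave, so the polish only sharpens
  # the simplex result
  par <- par0; val <- Inf; conv <- 1L
  for (r in 1:10) {
    opt <- suppressWarnings(stats::optim(
      par, negll, method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-10)
    ))
    improved <- val - opt$value
    par <- opt$par; val <- opt$value; conv <- opt$convergence
    if (r > 1L && improved < 1e-8) break
  }
  pol <- suppressWarnings(stats::optim(
    par, negll, neggr, method = "BFGS",
    control = list(maxit = 1000L, reltol = 1e-14)
  ))
  if (pol$value <= val) { par <- pol$par; val <- pol$value; conv <- pol$convergence }
  list(beta_hat = par[n + 1L],
       relative_hazard = exp(par[n + 1L]),
       loglik = -val,
       convergence = conv)
}

#' @export
print.sccs <- function(x, digits = 3, ...) {
  cat("Self-controlled case series fit",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  relative hazard: ", format(x$relative_hazard, digits = digits),
      "  (log RH = ", format(x$coefficients[[1]], digits = digits),
      ", SE = ", format(x$se, digits = digits), ")\n", sep = "")
  cat("  LRT vs beta = 0: chi2(1) = ", format(x$lrt_stat, digits = digits),
      ", p = ", format.pval(x$p_value, digits = digits), "\n", sep = "")
  cat("  users: ", x$n_users, " (", x$n_informative, " informative, ",
      x$n_exposed_users, " exposed); risk window W = ", x$W, " days\n", sep = "")
  if (!x$converged) cat("  WARNING: estimate hit the |beta| cap; not converged\n")
  invisible(x)
}

#' @export
coef.sccs <- function(object, ...) object$coefficients

#' @export
vcov.sccs <- function(object, ...) {
  matrix(object$se^2, 1, 1,
         dimnames = list("log_relative_hazard", "log_relative_hazard"))
}

#' @export
logLik.sccs <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_informative,
            class = "logLik")
}

#' @export
nobs.sccs <- function(object, ...) object$n_users

#' @export
confint.sccs <- function(object, parm = "log_relative_hazard", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[[1]]
  ci <- matrix(c(est - z * object$se, est + z * object$se), 1, 2,
               dimnames = list("log_relative_hazard",
                               paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")))
  ci
}

#' @export
summary.sccs <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  out <- list(fit = object,
              table = data.frame(
                estimate = object$coefficients[[1]],
                se = object$se,
                rel_hazard = object$relative_hazard,
                rh_lower = exp(ci[1, 1]), rh_upper = exp(ci[1, 2]),
                lrt = object$lrt_stat, p_value = object$p_value,
                row.names = "log_relative_hazard"))
  class(out) <- "summary.sccs"
  out
}

#' @export
print.summary.sccs <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(format(x$table, digits = digits))
  invisible(x)
}
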
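test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.2, 0.9), 0.05),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_equal(bh_fdr(numeric(), 0.05), logical())
})

test_that("bh_fdr agrees with brute-force enumeration on short vectors", {
  grid <- c(0, 0.004, 0.011, 0.02, 0.049, 0.2, 0.8, 1)
  set.seed(2)
  for (m in 1:8) {
    for (rep in 1:30) {
      p <- sample(grid, m, replace = TRUE)
      for (q in c(0.01, 0.05, 0.1))
        expect_equal(bh_fdr(p, q), bh_bruteforce(p, q),
                     info = paste("m =", m, "q =", q,
                                  "p =", paste(p, collapse = ",")))
    }
  }
})

test_that("candidate selection applies the cohort-fraction threshold", {
  cohort <- data.frame(user_id = paste0("u", 1:200),
                       condition = "asthma", event_day = 10L,
                       stringsAsFactors = FALSE)
  ann <- data.frame(
    user_id = c("u1", "u2", "u5", rep("u9", 3)),
    day = c(1L, 2L, 3L, 4:6),
    label = c("pollen", "pollen", "rare thing", rep("spam", 3)),
    kind = "category", stringsAsFactors = FALSE)
  cand <- select_candidates(cohort, ann, min_fraction = 0.01)
  # 2 of 200 users = exactly 1%: retained (boundary inclusive)
  expect_true("pollen" %in% cand$label)
  # 1 of 200 users: dropped, even with 3 queries
  expect_false("rare thing" %in% cand$label)
  expect_false("spam" %in% cand$label)
  expect_error(select_candidates(cohort[0, ], ann), "empty cohort")
})

test_that("temporal filter rejects shared-clock labels and keeps cohort-only ones", {
  L <- 100L
  mk_ann <- function(users, label, days) data.frame(
    user_id = rep(users, length.out = length(days)), day = days,
    label = rep(label, length(days)), kind = rep("category", length(days)),
    stringsAsFactors = FALSE)
  # news label: synchronized spike on days 40..42 in both populations
  spike_days <- rep(40:42, times = 20)
  # precursor label: cohort-only activity, flat background
  set.seed(4)
  co_ann <- rbind(mk_ann(paste0("c", 1:10), "news", spike_days),
                  mk_ann(paste0("c", 1:10), "precursor",
                         sample(0:(L - 1), 60, replace = TRUE)))
  bg_ann <- rbind(mk_ann(paste0("b", 1:50), "news", spike_days),
                  mk_ann(paste0("b", 1:50), "precursor",
                         sample(0:(L - 1), 60, replace = TRUE)))
  cand <- data.frame(label = c("news", "precursor"), kind = "category",
                     stringsAsFactors = FALSE)
  tf <- temporal_filter(co_ann, bg_ann, cand, L, q = 0.05)
  expect_equal(tf$rejected$label, "news")
  expect_equal(tf$kept$label, "precursor")

  # identical nonconstant series in both populations: r = 1, rejected
  tf2 <- temporal_filter(mk_ann("c1", "x", c(1L, 1L, 5L)),
                         mk_ann("b1", "x", c(1L, 1L, 5L)),
                         data.frame(label = "x", kind = "category"), L)
  expect_equal(tf2$stats$cor, 1)
  expect_true(tf2$stats$rejected)

  # constant series: correlation undefined, label kept
  tf3 <- temporal_filter(mk_ann("c1", "y", integer()),
                         mk_ann("b1", "y", 3L),
                         data.frame(label = "y", kind = "category"), L)
  expect_false(tf3$stats$rejected)

  expect_error(temporal_filter(mk_ann("c1", "x", 1L), mk_ann("c1", "x", 1L),
                               cand, L), "disjoint")
})

test_that("independent noise series are rejected at about the FDR level", {
  set.seed(12)
  L <- 120L
  n_labels <- 60
  rates <- vapply(1:20, function(r) {
    mk <- function(prefix) {
      n <- rpois(n_labels, 40) + 5L
      data.frame(
        user_id = paste0(prefix, unlist(lapply(n, seq_len))),
        day = unlist(lapply(n, function(k) sample(0:(L - 1), k, replace = TRUE))),
        label = rep(paste0("lab", seq_len(n_labels)), n),
        kind = "category", stringsAsFactors = FALSE)
    }
    cand <- data.frame(label = paste0("lab", seq_len(n_labels)),
                       kind = "category", stringsAsFactors = FALSE)
    tf <- temporal_filter(mk("c"), mk("b"), cand, L, q = 0.05)
    mean(tf$stats$rejected)
  }, 0)
  expect_lt(mean(rates), 0.05 + 0.02)
})

test_that("run_screen reports a planted precursor and only that", {
  set.seed(41)
  L <- 183L
  n_cohort <- 150L
  cohort <- data.frame(user_id = paste0("c", 1:n_cohort),
                       condition = "asthma", event_day = NA_integer_,
                       stringsAsFactors = FALSE)
  # planted precursor: exposures, then events drawn from the SCCS law
  ann <- list(); truth_rr <- 4
  for (i in seq_len(n_cohort)) {
    ed <- sample(0:(L - 1), 2)
    r <- risk_days(ed, 15, L)
    w <- rep(1, L); w[r + 1] <- truth_rr
    cohort$event_day[i] <- sample.int(L, 1, prob = w) - 1L
    ann[[i]] <- data.frame(user_id = cohort$user_id[i], day = ed,
                           label = "planted", kind = "category",
                           stringsAsFactors = FALSE)
  }
  # 20 null labels with random exposure days, independent of events
  for (lab in paste0("null", 1:20)) {
    n_u <- 60L
    u <- sample(cohort$user_id, n_u)
    ann[[length(ann) + 1L]] <- data.frame(
      user_id = u, day = sample(0:(L - 1), n_u, replace = TRUE),
      label = lab, kind = "category", stringsAsFactors = FALSE)
  }
  co_ann <- do.call(rbind, ann)
  # background sample with flat activity on the same labels
  bg_ann <- data.frame(
    user_id = paste0("b", 1:500),
    day = sample(0:(L - 1), 500, replace = TRUE),
    label = sample(c("planted", paste0("null", 1:20)), 500, replace = TRUE),
    kind = "category", stringsAsFactors = FALSE)
  annotated <- rbind(co_ann, bg_ann)
  attr(annotated, "observation_length") <- L
  scr <- run_screen("asthma", cohort, annotated, unique(bg_ann$user_id),
                    q = 0.05, W = 15)
  expect_true("planted" %in% scr$report$precursor)
  rr <- scr$report$relative_hazard[scr$report$precursor == "planted"]
  expect_gt(rr, 2); expect_lt(rr, 8)
  expect_lte(nrow(scr$report), 3)  # at most a stray false positive or two
})

test_that("gradient check classifies monotone dose-response patterns", {
  mk_ann <- function(counts, with_cond) {
    # one user per entry; counts[i] queries of the label
    u <- paste0(ifelse(with_cond, "c", "n"), seq_along(counts))
    data.frame(user_id = rep(u, counts), day = 1L, label = "lab",
               kind = "category", stringsAsFactors = FALSE)
  }
  # increasing fraction with condition by stratum 1, 2, 3, 4+
  ann <- rbind(mk_ann(c(rep(1, 99), rep(2, 49), rep(3, 24), rep(5, 9)), FALSE),
               mk_ann(c(1, 2, 2, 3, 3, 3, rep(5, 4)), TRUE))
  cond_users <- paste0("c", 1:10)
  g <- gradient_check(ann, "lab", "category", cond_users)
  expect_equal(g$direction, "positive")
  expect_gte(g$rho, 0.5)

  # reversed pattern
  ann2 <- rbind(mk_ann(c(rep(1, 9), rep(2, 49), rep(3, 74), rep(5, 99)), FALSE),
                mk_ann(c(rep(1, 6), 2, 2, 3, 5), TRUE))
  g2 <- gradient_check(ann2, "lab", "category", cond_users)
  expect_equal(g2$direction, "negative")

  # single populated stratum: undetermined
  ann3 <- mk_ann(rep(1, 10), TRUE)
  expect_equal(gradient_check(ann3, "lab", "category", cond_users)$direction,
               "undetermined")
})
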
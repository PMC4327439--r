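# small term_counts builder bypassing the log layer
tc <- function(df, n_users) {
  df$kind <- term_kind(toy_lexicon(), df$canonical)
  attr(df, "n_users") <- n_users
  class(df) <- c("term_counts", "data.frame")
  df
}

test_that("compute_features matches the attribute definitions", {
  v <- tc(data.frame(
    user_id = c("u1", "u1", "u2"),
    canonical = c("asthma", "migraine", "asthma"),
    count = c(10L, 2L, 1L), stringsAsFactors = FALSE), n_users = 4)
  f <- compute_features(v)
  r1 <- f[f$user_id == "u1", ]
  expect_equal(r1$most_common_disease, "asthma")
  expect_equal(c(r1$f1, r1$f2, r1$f3), c(10, 2, 5))
  expect_equal(r1$f4, 2 / 4)  # both users asked about asthma, 4 users total
  expect_equal(c(r1$f5, r1$f6, r1$f7), c(2, 1, 0))
  expect_equal(r1$f8, 0)  # no drug queries

  # degenerate user: one disease queried once -> denominator guard
  r2 <- f[f$user_id == "u2", ]
  expect_equal(c(r2$f1, r2$f2, r2$f3, r2$f5), c(1, 0, 1, 0))
})

test_that("the drug-relatedness feature is the D row times M", {
  v <- tc(data.frame(
    user_id = c("u1", "u1", "u2", "u2", "u3", "u3"),
    canonical = c("asthma", "albuterol", "asthma", "albuterol",
                  "asthma", "aspirin"),
    count = c(5L, 1L, 2L, 3L, 4L, 1L), stringsAsFactors = FALSE), n_users = 3)
  M <- disease_drug_cooccurrence(v)
  expect_equal(M["asthma", "albuterol"], 2L)  # u1 and u2
  expect_equal(M["asthma", "aspirin"], 1L)    # u3
  f <- compute_features(v, M)
  # u1 queried albuterol only: f8 = M[asthma, albuterol] = 2
  expect_equal(f$f8[f$user_id == "u1"], 2)
  # hand multiplication of the binary drug row by M's condition column
  expect_equal(f$f8[f$user_id == "u3"], 1)
})

test_that("training labels compare the argmax disease to the SIU condition", {
  v <- tc(data.frame(
    user_id = c("u1", "u1", "u2", "u2"),
    canonical = c("hiv", "influenza", "breast cancer", "hiv"),
    count = c(6L, 1L, 4L, 2L), stringsAsFactors = FALSE), n_users = 2)
  f <- compute_features(v)
  sius <- data.frame(user_id = c("u1", "u2"), condition = c("hiv", "hiv"),
                     event_day = 1L, primary = TRUE, stringsAsFactors = FALSE)
  labs <- label_training(sius, f)
  expect_equal(labs$label[labs$user_id == "u1"], 1L)
  expect_equal(labs$label[labs$user_id == "u2"], 0L)  # argmax is breast cancer
})

test_that("cross-validated AUC is 1 on separable features, 0.5 on noise", {
  set.seed(5)
  n <- 120
  feats <- data.frame(user_id = paste0("u", 1:n),
                      f1 = c(rnorm(n / 2, 4), rnorm(n / 2, 0)),
                      f2 = rnorm(n))
  y <- rep(1:0, each = n / 2)
  fit <- train_and_cv(feats, y, seed = 2)
  expect_equal(fit$auc, 1, tolerance = 0.02)
  expect_true(all(fit$scorer(feats) >= 0 & fit$scorer(feats) <= 1))

  # permuted labels: mean AUC over seeds near chance
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    train_and_cv(feats, sample(y), seed = s)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  expect_error(train_and_cv(feats, rep(1, n)), "degenerate")
})

test_that("forward selection finds the informative feature first", {
  set.seed(8)
  n <- 160
  y <- rep(1:0, each = n / 2)
  feats <- data.frame(user_id = paste0("u", 1:n),
                      f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                      f4 = y * 3 + rnorm(n),  # the signal
                      f5 = rnorm(n), f6 = rnorm(n), f7 = rnorm(n),
                      f8 = rnorm(n))
  sel <- forward_select(feats, y, seed = 3)
  expect_equal(sel$columns[1], "f4")
  expect_gt(sel$auc, 0.9)

  # all-noise features: small subset, chance-level AUC
  noise <- feats; noise$f4 <- rnorm(n)
  sel2 <- forward_select(noise, y, seed = 3)
  expect_lte(length(sel2$columns), 2L)
  expect_lt(sel2$auc, 0.62)
})

test_that("threshold tuning maximizes the cohort under the rho constraint", {
  # score = 1 for users whose argmax equals their condition, else 0:
  # any threshold in (0, 1) yields the identical cohort and rho
  set.seed(11)
  conds <- c("asthma", "migraine", "hypertension", "influenza")
  n_per <- c(40, 30, 20, 10)
  feats <- data.frame(
    user_id = paste0("u", 1:100),
    most_common_disease = rep(conds, n_per),
    f1 = 5, stringsAsFactors = FALSE)
  sius <- data.frame(user_id = paste0("s", 1:8),
                     condition = rep(conds, 2),
                     event_day = 1L, primary = TRUE, stringsAsFactors = FALSE)
  inc <- incidence_table(conds, c(0.04, 0.03, 0.02, 0.01))
  scorer <- function(f) rep(1, nrow(f))
  tt <- tune_threshold(scorer, feats, sius, inc, n_users = 1000,
                       grid = c(0, 0.25, 0.5, 0.75))
  curve <- tt$curve
  expect_equal(length(unique(curve$rho[curve$threshold > 0])), 1L)
  expect_equal(length(unique(curve$cohort_size[curve$threshold > 0])), 1L)
  # rho passes the target at every positive threshold: pick the biggest cohort
  expect_gt(tt$threshold, 0)
  # threshold 0 is the SIU-only cohort
  expect_equal(curve$cohort_size[curve$threshold == 0], nrow(sius))
  expect_error(tune_threshold(scorer, feats, sius, inc, 1000, grid = numeric()),
               "empty")
})

test_that("cohort expansion dedupes SIUs and is monotone in the threshold", {
  lex <- toy_lexicon()
  log <- tiny_log(
    list("u1", 10, "asthma attack"), list("u1", 30, "i have asthma"),
    list("u2", 20, "asthma inhaler"), list("u2", 40, "asthma"),
    list("u3", 50, "migraine"), list("u4", 60, "weather")
  )
  v <- build_term_vectors(log, lex)
  feats <- compute_features(v)
  sius <- detect_sius(log, lex)
  scores <- c(u1 = 0.9, u2 = 0.6, u3 = 0.2)
  scorer <- function(f) unname(scores[f$user_id])

  hi <- expand_cohort(scorer, 0.7, feats, sius, log, lexicon = lex)
  expect_equal(hi$user_id, "u1")          # u1 is an SIU, enters once
  expect_equal(hi$source, "siu")
  expect_equal(hi$event_day, 30L)         # the self-identification day

  lo <- expand_cohort(scorer, 0.5, feats, sius, log, lexicon = lex)
  expect_true(all(hi$user_id %in% lo$user_id))  # monotone: superset
  expect_equal(lo$event_day[lo$user_id == "u2"], 20L)  # first mention day
  expect_equal(lo$source[lo$user_id == "u2"], "classified")

  # threshold above every score: SIU set only
  top <- expand_cohort(scorer, 0.99, feats, sius, log, lexicon = lex)
  expect_equal(top$user_id, "u1")
})

test_that("multiclass accuracy separates conditions via disease terms only", {
  set.seed(17)
  conds <- c("asthma", "migraine", "hiv")
  n_per <- 15
  users <- paste0("u", 1:(3 * n_per))
  cond <- rep(conds, each = n_per)
  v <- tc(data.frame(
    user_id = rep(users, 2),
    canonical = c(cond, rep("fever", length(users))),
    count = c(rpois(length(users), 5) + 1L, rep(1L, length(users))),
    stringsAsFactors = FALSE), n_users = length(users))
  sius <- data.frame(user_id = users, condition = cond, event_day = 1L,
                     primary = TRUE, stringsAsFactors = FALSE)
  acc <- multiclass_accuracy(v, sius,
                             attribute_sets = list("disease", "symptom"))
  expect_equal(unname(acc["disease"]), 1)
  # symptom counts are identical across classes: accuracy near chance
  expect_lt(unname(acc["symptom"]), 0.55)
})

test_that("the scorer separates affected users in the simulated population", {
  # affected users query their condition ~Poisson(6.8) vs ~Poisson(2.15)
  # background: the features must carry signal
  cfg <- sim_config(n_users = 1500, siu_fraction = 1,
                    incidence = incidence_table("migraine", 0.1),
                    disease_query_fraction = 0.5, seed = 23)
  sim <- simulate_querylog(cfg)
  v <- build_term_vectors(sim$log, sim$lexicon)
  feats <- compute_features(v)
  sius <- detect_sius(sim$log, sim$lexicon)
  # label: is this user actually affected?
  y <- as.integer(feats$user_id %in% sim$truth$user_id)
  fit <- train_and_cv(feats, y, seed = 7)
  expect_gt(fit$auc, 0.75)
})
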
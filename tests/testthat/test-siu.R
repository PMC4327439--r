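test_that("detect_sius requires a trigger phrase plus a disease term", {
  lex <- toy_lexicon()
  log <- tiny_log(
    list("u1", 40, "i was diagnosed with hiv"),
    list("u2", 10, "living with my parents"),
    list("u3", 12, "hiv test locations"),
    list("u4", 60, "i have asthma"),
    list("u4", 20, "i suffer from asthma")
  )
  s <- detect_sius(log, lex)
  expect_equal(s$condition[s$user_id == "u1"], "hiv")
  expect_equal(s$event_day[s$user_id == "u1"], 40L)
  expect_false("u2" %in% s$user_id)  # no disease term
  expect_false("u3" %in% s$user_id)  # no trigger phrase
  # earliest self-identifying query defines the event day
  expect_equal(s$event_day[s$user_id == "u4"], 20L)
})

test_that("detect_sius picks the longest disease span and earliest condition", {
  lex <- toy_lexicon()
  # "heart attack" (2 tokens, -> myocardial infarction) beats "asthma"
  log <- tiny_log(list("u1", 5, "i have heart attack and asthma"))
  s <- detect_sius(log, lex)
  expect_equal(s$condition[s$primary], "myocardial infarction")

  # two conditions on different days: earliest defines the primary; both kept
  log2 <- tiny_log(
    list("u2", 50, "i have asthma"),
    list("u2", 30, "i have migraine")
  )
  s2 <- detect_sius(log2, lex)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$condition[s2$primary], "migraine")
})

test_that("detect_sius is invariant to record order", {
  lex <- toy_lexicon()
  rec <- data.frame(
    user_id = c("u1", "u2", "u1", "u3"),
    day = c(40L, 9L, 12L, 100L),
    text = c("i was diagnosed with hiv", "i have influenza",
             "i have hiv", "living with depression"),
    stringsAsFactors = FALSE
  )
  s1 <- detect_sius(query_log(rec), lex)
  s2 <- detect_sius(query_log(rec[c(4, 2, 3, 1), ]), lex)
  expect_equal(s1, s2)
})

test_that("filter_conditions keeps conditions at or above the threshold", {
  sius <- data.frame(
    user_id = paste0("u", 1:35),
    condition = rep(c("asthma", "migraine"), c(25, 10)),
    event_day = 1L, primary = TRUE, stringsAsFactors = FALSE
  )
  fc <- filter_conditions(sius, 25)
  expect_equal(fc$conditions, "asthma")  # exactly 25 retained ("at least")
  expect_equal(nrow(fc$sius), 25L)
  expect_equal(fc$n_dropped, 10L)
  expect_equal(nrow(fc$sius) + fc$n_dropped, nrow(sius))
  # min_count = 1 is the identity
  expect_equal(nrow(filter_conditions(sius, 1)$sius), nrow(sius))
})

test_that("siu_incidence_check computes Spearman rho with tie handling", {
  mk <- function(counts) data.frame(
    user_id = paste0("u", seq_len(sum(counts))),
    condition = rep(names(counts), counts), stringsAsFactors = FALSE)
  inc <- incidence_table(c("a", "b", "c", "d"), c(0.04, 0.03, 0.02, 0.01))
  # perfectly concordant
  chk <- siu_incidence_check(mk(c(a = 40, b = 30, c = 20, d = 10)), 1000, inc)
  expect_equal(chk$rho, 1)
  # perfectly reversed
  chk2 <- siu_incidence_check(mk(c(a = 10, b = 20, c = 30, d = 40)), 1000, inc)
  expect_equal(chk2$rho, -1)
  # fewer than 3 overlapping conditions
  expect_error(
    siu_incidence_check(mk(c(a = 5, b = 5)), 100, inc), "at least 3")
})

test_that("the published 29-disease comparison lands near rho = 0.5", {
  bench <- incidence_benchmark()
  expect_equal(nrow(bench), 29L)
  rho <- suppressWarnings(
    cor(bench$siu_percent, bench$incidence, method = "spearman"))
  expect_equal(rho, 0.5006, tolerance = 1e-3)
})

test_that("with universal self-identification every affected user is found", {
  cfg <- sim_config(n_users = 600, siu_fraction = 1, seed = 21)
  sim <- simulate_querylog(cfg)
  s <- detect_sius(sim$log, sim$lexicon)
  prim <- s[s$primary, ]
  expect_equal(sort(prim$user_id), sort(sim$truth$user_id))
  m <- merge(prim, sim$truth, by = "user_id")
  expect_equal(m$condition.x, m$condition.y)
  expect_equal(m$event_day.x, m$event_day.y)
})
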
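# Small builders shared across the test files. Everything is generated in
# code; no fixtures are read from disk except the shipped incidence table.

tiny_log <- function(...) {
  rows <- list(...)
  rec <- do.call(rbind, lapply(rows, function(r) {
    data.frame(user_id = r[[1]], day = as.integer(r[[2]]), text = r[[3]],
               stringsAsFactors = FALSE)
  }))
  query_log(rec)
}

# a deterministic homogeneous case series with known closed-form MLE
homog_series <- function(n = 100L, n_risk = 3L, n_base = 7L, k_risk = 60L) {
  case_series(rep(n_risk, n), rep(n_base, n),
              rep(c(TRUE, FALSE), c(k_risk, n - k_risk)),
              W = n_risk, observation_length = n_risk + n_base)
}

# brute-force Benjamini-Hochberg step-up, written independently of bh_fdr:
# enumerate every k and apply the textbook rule
bh_bruteforce <- function(p, q) {
  m <- length(p)
  if (!m) return(logical())
  o <- order(p)
  ps <- p[o]
  k_max <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_max <- k
  rej <- rep(FALSE, m)
  if (k_max > 0L) rej[o[seq_len(k_max)]] <- TRUE
  rej
}

# click records helper
clicks_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r[[1]], page = r[[2]], month = as.integer(r[[3]]),
               clicks = as.integer(r[[4]]), stringsAsFactors = FALSE)
  }))
}
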
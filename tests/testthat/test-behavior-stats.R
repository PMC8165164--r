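# spread a total over k cells as evenly as possible (integer counts)
spread_counts <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

test_that("ethogram summaries are totals and per-session means over the scored sessions", {
  tab <- tibble::tibble(
    bird_id = rep(sprintf("B%02d", 1:4), each = 3),
    condition = "Mirror",
    session = rep(1:3, 4),
    behavior = "preening",
    count = spread_counts(90, 12)
  )
  s <- summarize_ethogram(tab)
  expect_equal(s$sum, 90)
  expect_equal(s$mean, 90 / 12)
  expect_identical(s$n, 12L)
  expect_error(summarize_ethogram(dplyr::mutate(tab, count = count - 100)),
               class = "input_error")
})

test_that("kappa is 1 for perfect agreement and matches a hand-computed table", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  # classic 2x2 example: observed agreement 0.7, chance agreement 0.5
  a <- c(rep("x", 25), rep("y", 25))
  b <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.7)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.4)
  expect_true(is.finite(k$z))
})

test_that("kappa is near zero for independent raters and agrees with the e1071 oracle", {
  set.seed(123)
  n <- 10000
  labs <- letters[1:4]
  a <- sample(labs, n, replace = TRUE)
  b <- sample(labs, n, replace = TRUE)
  k <- cohens_kappa(a, b)
  expect_lt(abs(k$kappa), 0.05)
  # independent implementation on the same confusion matrix
  oracle <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(k$kappa, oracle, tolerance = 1e-10)
  # and on a structured table
  etho <- simulate_ethogram(tiny_cfg(rater_disagreement = 0.1, seed = 61))
  k2 <- cohens_kappa(etho$labels$rater_a, etho$labels$rater_b)
  oracle2 <- e1071::classAgreement(
    table(factor(etho$labels$rater_a, levels = behavior_catalogue()),
          factor(etho$labels$rater_b, levels = behavior_catalogue())))$kappa
  expect_equal(k2$kappa, oracle2, tolerance = 1e-10)
  expect_gt(k2$kappa, 0.7)
})

test_that("degenerate kappa input is flagged as undefined rather than erroring", {
  expect_warning(k <- cohens_kappa(rep("a", 10), rep("a", 10)), "undefined")
  expect_true(k$undefined)
  expect_true(is.na(k$kappa))
  expect_error(cohens_kappa("a", c("a", "b")), class = "input_error")
})

test_that("the repeated-measures ANOVA has the design's degrees of freedom", {
  cfg <- sim_config(session_length = 5, seed = 71)  # full 8 x 3 x 6 design
  etho <- simulate_ethogram(cfg)
  res <- rm_anova(etho$counts)
  a <- res$anova
  cond <- a[a$term == "condition", ]
  day <- a[a$term == "day", ]
  inter <- a[a$term == "condition:day", ]
  expect_identical(c(cond$df1, cond$df2), c(2, 14))
  expect_identical(c(day$df1, day$df2), c(5, 35))
  expect_identical(c(inter$df1, inter$df2), c(10, 70))
  expect_true(all(a$partial_eta_sq >= 0 & a$partial_eta_sq <= 1))
  expect_identical(nrow(res$posthoc), 3L)
  expect_true(all(res$posthoc$p_corrected >= 0 & res$posthoc$p_corrected <= 1))
})

test_that("the ANOVA rejects unbalanced designs and detects a strong condition effect", {
  cfg <- tiny_cfg(seed = 72)
  etho <- simulate_ethogram(cfg)
  # drop an entire bird x condition x session cell for the analysed rater
  unb <- dplyr::filter(etho$counts,
                       !(bird_id == "B01" & condition == "Wall" & session == 1))
  expect_error(rm_anova(unb), class = "input_error")

  # power: a large injected difference is detected in most replicates
  reps <- 40
  hits <- 0
  for (r in seq_len(reps)) {
    set.seed(500 + r)
    g <- expand.grid(bird_id = sprintf("B%02d", 1:8),
                     condition = c("Wall", "Mirror", "Stranger"),
                     session = 1:6, stringsAsFactors = FALSE)
    shift <- c(Wall = 0, Mirror = 3, Stranger = 6)[g$condition]
    g$behavior <- "preening"
    g$count <- pmax(0L, as.integer(round(5 + shift + rnorm(nrow(g), 0, 2))))
    p <- rm_anova(tibble::as_tibble(g))$anova
    if (p$p[p$term == "condition"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("mixed-model LRTs detect an injected condition effect and report bookkeeping", {
  set.seed(81)
  d <- null_latency_data(seed = 81)
  d$latency_s <- d$latency_s + c(Wall = 0, Mirror = 15, Stranger = -5)[d$condition]
  d$censored <- FALSE
  d$censored[1:3] <- TRUE
  res <- lmm_lrt(d, "latency_s")
  lrt <- res$lrt
  expect_setequal(lrt$term, c("condition", "session", "condition:session"))
  expect_lt(lrt$p[lrt$term == "condition"], 1e-4)
  expect_true(all(lrt$eta_sq_analog >= 0 & lrt$eta_sq_analog <= 1))
  expect_identical(res$n_censored, 3L)
  expect_identical(res$n, nrow(d) - 3L)
  expect_identical(nrow(res$posthoc), 3L)
})

test_that("session post-hocs within condition are available for the familiarisation question", {
  set.seed(82)
  d <- null_latency_data(seed = 82)
  # session-1 elevation, as in a familiarisation effect
  d$latency_s <- d$latency_s + ifelse(d$session == 1, 20, 0)
  res <- lmm_lrt(d, "latency_s", session_posthoc = TRUE)
  expect_lt(res$lrt$p[res$lrt$term == "session"], 0.01)
  ph <- res$posthoc_sessions
  expect_identical(nrow(ph), 15L * 3L)  # 15 session pairs per condition
  expect_error(lmm_lrt(d, "nope"), class = "input_error")
})
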
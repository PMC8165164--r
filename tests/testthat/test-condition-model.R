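test_that("binning averages within sessions first, then across sessions", {
  frames <- tibble::tibble(
    bird_id = rep(c("B01", "B02"), each = 4),
    condition = "Wall",
    session = 1L,
    time_s = rep(c(0.2, 0.7, 1.1, 1.6), 2),
    orientation = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.0, 0.0, 0.0)
  )
  b <- bin_series(frames, bin_width = 1)
  expect_identical(nrow(b), 2L)
  # bin 0: mean(session means) = mean(mean(0.2, 0.4), mean(1.0, 1.0))
  expect_equal(b$mean[b$bin == 0], mean(c(0.3, 1.0)))
  expect_equal(b$mean[b$bin == 1], mean(c(0.7, 0.0)))
  expect_identical(b$n_sessions, c(2L, 2L))
  expect_identical(b$n_frames, c(4L, 4L))
  expect_equal(b$bin_time, c(0.5, 1.5))
  expect_error(bin_series(frames, bin_width = 0), class = "config_error")
})

test_that("a constant orientation series bins to that constant in every bin", {
  frames <- tibble::tibble(
    bird_id = "B01", condition = "Mirror", session = 1L,
    time_s = seq(0, 9.9, by = 0.1), orientation = 0.42
  )
  b <- bin_series(frames, bin_width = 2)
  expect_true(all(b$mean == 0.42))
  expect_identical(nrow(b), 5L)
})

test_that("the condition model covers zero when the conditions are identical in law", {
  series <- make_series(n_bins = 150, delta = 0, noise = 0.05, seed = 11)
  post <- fit_condition_model(series, "A", "B", mcmc = quick_mcmc(seed = 21))
  expect_lte(post$summary$ci_low, 0)
  expect_gte(post$summary$ci_high, 0)
  expect_lt(abs(post$summary$mean), 0.1)
})

test_that("a constant injected offset is recovered with a CI excluding zero", {
  series <- make_series(n_bins = 200, delta = 0.2,
                        trend = function(t) 0.4 + 0.1 * sin(t / 30),
                        noise = 0.05, seed = 12)
  # the check is about recovery, not mixing; short chains may flag a scale Rhat
  post <- suppressWarnings(
    fit_condition_model(series, "A", "B",
                        mcmc = quick_mcmc(seed = 22, draws = 500,
                                          warmup = 500)))
  s <- post$summary
  expect_gt(s$ci_low, 0)
  half <- (s$ci_high - s$ci_low) / 2
  expect_lt(abs(s$mean - 0.2), half)
})

test_that("difference periods localise where the difference actually is", {
  n <- 180
  d <- c(rep(0.35, n / 3), rep(0, 2 * n / 3))
  series <- make_series(n_bins = n, delta = d, noise = 0.05, seed = 13)
  post <- fit_condition_model(series, "A", "B",
                              mcmc = quick_mcmc(seed = 23, draws = 500,
                                                warmup = 500))
  flagged <- post$difference_periods$bin
  expect_gt(length(flagged), 10)
  expect_gte(mean(flagged < n / 3), 0.8)
})

test_that("swapping reference and alternative exactly negates every draw", {
  series <- make_series(n_bins = 120, delta = 0.15, noise = 0.05, seed = 14)
  p1 <- fit_condition_model(series, "A", "B", mcmc = quick_mcmc(seed = 24))
  p2 <- fit_condition_model(series, "B", "A", mcmc = quick_mcmc(seed = 24))
  expect_identical(p1$delta_draws, -p2$delta_draws)
  expect_identical(p1$summary$mean, -p2$summary$mean)
  expect_identical(p1$summary$ci_low, -p2$summary$ci_high)
})

test_that("the inferred difference is invariant to a common constant shift", {
  series <- make_series(n_bins = 120, delta = 0.15, noise = 0.05, seed = 15)
  shifted <- series
  shifted$mean <- shifted$mean + 5
  p1 <- fit_condition_model(series, "A", "B", mcmc = quick_mcmc(seed = 25))
  p2 <- fit_condition_model(shifted, "A", "B", mcmc = quick_mcmc(seed = 25))
  expect_equal(p1$delta_draws, p2$delta_draws, tolerance = 1e-6)
  expect_equal(p1$summary$mean, p2$summary$mean, tolerance = 1e-6)
})

test_that("the Gibbs sampler agrees with an independent JAGS fit of the same model", {
  n <- 60
  series <- make_series(n_bins = n, delta = 0.25, noise = 0.08, seed = 16)
  post <- fit_condition_model(series, "A", "B",
                              mcmc = quick_mcmc(seed = 26, draws = 1500,
                                                warmup = 1000, chains = 2))

  yA <- series$mean[series$condition == "A"]
  yB <- series$mean[series$condition == "B"]
  m0 <- mean(c(yA, yB))
  model_str <- "
    model {
      mu[1] ~ dnorm(m0, 1)
      delta[1] ~ dnorm(0, 1)
      for (t in 2:T) {
        mu[t] ~ dnorm(mu[t-1], tau_mu)
        delta[t] ~ dnorm(delta[t-1], tau_del)
      }
      for (t in 1:T) {
        yA[t] ~ dnorm(mu[t], tau_obs)
        yB[t] ~ dnorm(mu[t] + delta[t], tau_obs)
      }
      sig_mu ~ dnorm(0, 1) T(0,)
      sig_del ~ dnorm(0, 1) T(0,)
      sig_obs ~ dnorm(0, 1) T(0,)
      tau_mu <- pow(sig_mu, -2)
      tau_del <- pow(sig_del, -2)
      tau_obs <- pow(sig_obs, -2)
      delta_bar <- mean(delta)
    }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(yA = yA, yB = yB, T = n, m0 = m0),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 99))
  update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, "delta_bar", n.iter = 4000,
                            progress.bar = "none")
  jd <- unlist(js)
  expect_lt(abs(mean(post$delta_bar) - mean(jd)), 0.03)
  expect_lt(abs(sd(post$delta_bar) - sd(jd)), 0.02)
})

test_that("convergence diagnostics are reported and inputs validated", {
  series <- make_series(n_bins = 120, delta = 0.1, noise = 0.05, seed = 17)
  post <- fit_condition_model(series, "A", "B",
                              mcmc = quick_mcmc(seed = 27, draws = 600,
                                                warmup = 600, chains = 4))
  expect_named(post$rhat, c("delta_bar", "sigma_mu", "sigma_delta", "sigma_obs"))
  expect_true(all(is.finite(post$rhat)))

  expect_error(fit_condition_model(series, "A", "C"), class = "input_error")
  expect_error(fit_condition_model(series, "A", "A"), class = "input_error")
  short <- make_series(n_bins = 10, seed = 18)
  expect_error(fit_condition_model(short, "A", "B"), class = "input_error")
})

test_that("the difference summary converts the index difference to degrees consistently", {
  series <- make_series(n_bins = 120, delta = 0.3, noise = 0.05, seed = 19)
  post <- fit_condition_model(series, "A", "B", mcmc = quick_mcmc(seed = 29))
  s <- summarize_difference(post)
  expect_identical(s$comparison, "B vs A")
  expect_equal(s$degrees, index_to_degrees(s$delta_mean))
  expect_identical(s$n_difference_bins, nrow(post$difference_periods))
})
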
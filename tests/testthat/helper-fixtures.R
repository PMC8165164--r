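# Shared builders for small, fast test fixtures.

# a reduced experiment: 2 birds x 3 conditions x 2 sessions, short sessions
tiny_cfg <- function(..., seed = 101) {
  args <- utils::modifyList(
    list(n_birds = 2, n_sessions = 2, session_length = 30, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# a binned two-condition series in the shape produced by bin_series():
# condition "A" follows `trend`, condition "B" follows `trend + delta`
make_series <- function(n_bins = 120, delta = 0, trend = function(t) 0.4,
                        noise = 0.05, seed = 1,
                        conditions = c("A", "B")) {
  set.seed(seed)
  tt <- seq_len(n_bins)
  base <- trend(tt)
  if (length(base) == 1) base <- rep(base, n_bins)
  d <- if (length(delta) == 1) rep(delta, n_bins) else delta
  tibble::tibble(
    bin = rep(0:(n_bins - 1L), 2),
    bin_time = rep(0:(n_bins - 1L) + 0.5, 2),
    condition = rep(conditions, each = n_bins),
    mean = c(base + rnorm(n_bins, 0, noise),
             base + d + rnorm(n_bins, 0, noise)),
    n_sessions = 1L, n_frames = 30L
  )
}

# fast MCMC settings for property tests (acceptance-style checks use larger runs)
quick_mcmc <- function(seed = 1, draws = 300, warmup = 300, chains = 2) {
  list(draws = draws, warmup = warmup, chains = chains, seed = seed)
}

# hand-built trajectory with head/body-center keypoints
make_traj <- function(head_x, head_y, body_x, body_y,
                      lik = 0.99, fps = 30, units = "cm") {
  n <- length(head_x)
  lk <- if (length(lik) == 1) rep(lik, n) else lik
  trajectory(
    x = cbind(head = head_x, `body-center` = body_x),
    y = cbind(head = head_y, `body-center` = body_y),
    likelihood = cbind(head = lk, `body-center` = lk),
    fps = fps, units = units
  )
}

# balanced latency-style dataset with a per-bird intercept and NO condition
# effect (for null calibration of the mixed-model LRT)
null_latency_data <- function(n_birds = 8, n_sessions = 6,
                              conditions = c("Wall", "Mirror", "Stranger"),
                              bird_sd = 5, resid_sd = 8, seed = 1) {
  set.seed(seed)
  g <- expand.grid(bird_id = sprintf("B%02d", seq_len(n_birds)),
                   condition = conditions,
                   session = seq_len(n_sessions),
                   stringsAsFactors = FALSE)
  b <- rnorm(n_birds, 0, bird_sd)
  names(b) <- sprintf("B%02d", seq_len(n_birds))
  g$latency_s <- 25 + b[g$bird_id] + rnorm(nrow(g), 0, resid_sd)
  tibble::as_tibble(g)
}

md5_of <- function(dir, pattern = "\\.csv$") {
  files <- sort(list.files(dir, pattern, recursive = TRUE, full.names = FALSE))
  vapply(files, function(f) unname(tools::md5sum(file.path(dir, f))),
         character(1))
}
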
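#' Simulate one arena-foraging session
#'
#' Generates a keypoint trajectory for one bird x condition x session with the
#' structure the downstream analysis assumes: the bird dwells at the entrance
#' for a condition/session-dependent time, approaches the feeder along a
#' curved path, then alternates feeding bouts at the feeder with short
#' excursions. The heading is the direction toward the feeder plus an
#' Ornstein-Uhlenbeck deviation whose stationary sd is chosen so that the
#' expected body-orientation index over the post-approach segment equals
#' `orientation_bias[condition]` (for a Gaussian deviation with sd s,
#' E cos(theta) = exp(-s^2/2)). The head keypoint sits `head_offset` cm from
#' body-center along the heading, so the orientation ground truth is known
#' analytically. Gaussian tracker jitter and low-likelihood dropout frames
#' with corrupted coordinates are added on top of the clean path.
#'
#' @param cfg a [sim_config()].
#' @param bird bird index (1-based) or an id of the form `"B03"`.
#' @param condition condition label; must be one of `cfg$conditions`.
#' @param session session number in `1:cfg$n_sessions`.
#'
#' @return A list with elements
#'   * `trajectory`: a [trajectory()] in pixel units (bodyparts `head`,
#'     `body-center`; likelihood 0.99 for clean frames, uniform on (0, 0.5)
#'     for dropouts),
#'   * `events`: ground truth — `latency_s` (first time the clean head enters
#'     the feeder zone; `NA` if never), `feeding_mask` (per-frame logical on
#'     the clean path), `clean_head`, `clean_body` (n x 2 matrices, cm),
#'     `heading` (radians), `dwell_s`, `speed_cms`, and the identifiers.
#' @export
simulate_session <- function(cfg, bird, condition, session) {
  stopifnot(inherits(cfg, "sim_config"))
  cond_i <- match(condition, cfg$conditions)
  if (is.na(cond_i))
    stop_mf("unknown condition label: ", condition, class = "config_error")
  if (!(session %in% seq_len(cfg$n_sessions)))
    stop_mf("session must be in 1..", cfg$n_sessions, class = "config_error")
  if (is.character(bird)) {
    bird_i <- as.integer(sub("^B0*", "", bird))
    bird_id <- bird
  } else {
    bird_i <- as.integer(bird)
    bird_id <- sprintf("B%02d", bird_i)
  }
  if (is.na(bird_i) || bird_i < 1)
    stop_mf("invalid bird identifier", class = "config_error")
  set.seed(derive_seed(cfg$seed, 1L, bird_i, cond_i, session))

  geom <- cfg$arena
  fps <- cfg$fps
  dt <- 1 / fps
  n <- round(cfg$session_length * fps)
  feeder <- geom$feeder_center
  entrance <- geom$entrance
  r_zone <- geom$feeder_zone_radius
  h_off <- cfg$head_offset

  # session movement speed with mild between-session variability
  v <- cfg$approach_speed_mean[[condition]] * exp(rnorm(1, 0, 0.08))

  # entrance dwell calibrated so that dwell + approach travel matches the
  # configured latency mean (head enters the zone when the body is roughly
  # r_zone + head_offset from the feeder; 1.05 covers path curvature)
  d0 <- sqrt(sum((feeder - entrance)^2))
  travel_est <- 1.05 * max(d0 - (r_zone + h_off), 1) / v
  dwell_mean <- max(cfg$latency_mean[condition, session] - travel_est, 0.5)
  dwell <- rgamma(1, shape = 9, scale = dwell_mean / 9)
  k_dwell <- max(1L, round(dwell * fps))

  # heading-deviation OU: stationary sd per phase; post-approach sd encodes
  # the configured orientation bias (E cos(theta) = exp(-sd^2 / 2))
  s_post <- sqrt(max(-2 * log(cfg$orientation_bias[[condition]]), 0))
  phi_th <- exp(-dt / 2)          # tau = 2 s
  innov <- function(sd) sd * sqrt(1 - phi_th^2)

  # feeding bout / excursion schedule
  bout_mean <- 4
  rate <- cfg$feeding_bout_rate
  gap_mean <- if (rate > 0) max(60 / rate - (bout_mean + 1), 2) else Inf
  u_in <- (c(geom$width, geom$depth) / 2 - feeder)
  u_in <- u_in / sqrt(sum(u_in^2))

  body <- matrix(NA_real_, n, 2)
  heading <- numeric(n)
  pos <- entrance
  theta <- rnorm(1, 0, 1.2)
  phase <- 1L                      # 1 dwell, 2 approach, 3 forage
  seg_left <- 0L
  in_bout <- FALSE
  anchor <- entrance
  spd_fac <- 0.3
  noise_fac <- 0.4

  for (t in seq_len(n)) {
    if (phase == 1L && t > k_dwell) phase <- 2L
    if (phase == 2L && sqrt(sum((pos - feeder)^2)) <= r_zone + h_off - 2) {
      phase <- 3L
      seg_left <- 0L
      in_bout <- FALSE
    }
    if (phase == 1L) {
      anchor <- entrance; spd_fac <- 0.3
      th_sd <- 1.2
    } else if (phase == 2L) {
      anchor <- feeder; spd_fac <- 1
      th_sd <- 0.2
    } else {
      if (seg_left <= 0L) {
        in_bout <- !in_bout
        if (in_bout) {
          dur <- 1 + rexp(1, 1 / bout_mean)
          anchor <- feeder + 2.5 * u_in + rnorm(2, 0, 0.5)
        } else {
          dur <- if (is.finite(gap_mean)) 0.5 + rexp(1, 1 / gap_mean) else Inf
          ang <- atan2(u_in[2], u_in[1]) + runif(1, -1.1, 1.1)
          anchor <- feeder + runif(1, 8, 18) * c(cos(ang), sin(ang))
        }
        anchor[1] <- min(max(anchor[1], 2), geom$width - 2)
        anchor[2] <- min(max(anchor[2], 2), geom$depth - 2)
        seg_left <- if (is.finite(dur)) max(1L, round(dur * fps)) else .Machine$integer.max
      }
      seg_left <- seg_left - 1L
      spd_fac <- if (in_bout) 0.25 else 1
      th_sd <- s_post
    }
    # pulled step toward the anchor plus isotropic movement noise, both
    # scaled by the session speed so mean non-feeding speed tracks v
    pull <- anchor - pos
    d <- sqrt(sum(pull^2))
    step <- if (d > 1e-9) pmin(v * spd_fac * dt, d) * pull / d else c(0, 0)
    pos <- pos + step + rnorm(2, 0, noise_fac * v * spd_fac * dt)
    pos[1] <- min(max(pos[1], 1), geom$width - 1)
    pos[2] <- min(max(pos[2], 1), geom$depth - 1)
    # heading deviation OU (exactly zero when the configured bias is 1)
    if (phase == 3L && s_post == 0) {
      theta <- 0
    } else {
      theta <- phi_th * theta + innov(th_sd) * rnorm(1)
    }
    to_feeder <- atan2(feeder[2] - pos[2], feeder[1] - pos[1])
    heading[t] <- to_feeder + theta
    body[t, ] <- pos
  }

  head <- body + h_off * cbind(cos(heading), sin(heading))
  feed_true <- sqrt((head[, 1] - feeder[1])^2 + (head[, 2] - feeder[2])^2) <= r_zone
  first_feed <- which(feed_true)[1]
  latency_true <- if (is.na(first_feed)) NA_real_ else (first_feed - 1) / fps

  # observation model: tracker jitter + dropouts with corrupted coordinates
  obs_body <- body + matrix(rnorm(2L * n, 0, cfg$tracker_noise_sd), n, 2)
  obs_head <- head + matrix(rnorm(2L * n, 0, cfg$tracker_noise_sd), n, 2)
  lik_head <- rep(0.99, n)
  lik_body <- rep(0.99, n)
  drop_head <- runif(n) < cfg$dropout_prob
  drop_body <- runif(n) < cfg$dropout_prob
  if (any(drop_head)) {
    k <- sum(drop_head)
    obs_head[drop_head, ] <- cbind(runif(k, 0, geom$width), runif(k, 0, geom$depth))
    lik_head[drop_head] <- runif(k, 0, 0.5)
  }
  if (any(drop_body)) {
    k <- sum(drop_body)
    obs_body[drop_body, ] <- cbind(runif(k, 0, geom$width), runif(k, 0, geom$depth))
    lik_body[drop_body] <- runif(k, 0, 0.5)
  }

  s <- geom$px_per_cm
  xm <- cbind(head = obs_head[, 1], `body-center` = obs_body[, 1]) * s
  ym <- cbind(head = obs_head[, 2], `body-center` = obs_body[, 2]) * s
  lm_ <- cbind(head = lik_head, `body-center` = lik_body)
  traj <- trajectory(x = xm, y = ym, likelihood = lm_, fps = fps, units = "px")

  list(
    trajectory = traj,
    events = list(bird_id = bird_id, condition = condition, session = session,
                  latency_s = latency_true, feeding_mask = feed_true,
                  clean_head = head, clean_body = body, heading = heading,
                  dwell_s = dwell, speed_cms = v)
  )
}

#' Simulate an ethogram with a second rater
#'
#' Draws per-session behaviour counts from a negative binomial with the
#' configured condition-specific means and overdispersion, then generates a
#' second rater by relabelling each scored event with probability
#' `cfg$rater_disagreement` to a different behaviour, which makes the expected
#' Cohen's kappa controllable.
#'
#' @param cfg a [sim_config()].
#' @return A list with
#'   * `counts`: tibble (`bird_id`, `condition`, `session`, `behavior`,
#'     `count`, `rater`) for raters `"A"` (primary) and `"B"`,
#'   * `labels`: tibble of event-level labels (`rater_a`, `rater_b`) for
#'     reliability analysis.
#' @export
simulate_ethogram <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  behaviors <- rownames(cfg$behavior_rates)
  grid <- tidyr::expand_grid(
    bird_id = sprintf("B%02d", seq_len(cfg$n_birds)),
    condition = cfg$conditions,
    session = seq_len(cfg$n_sessions),
    behavior = behaviors
  )
  mu <- cfg$behavior_rates[cbind(grid$behavior, grid$condition)]
  grid$count <- rnbinom(nrow(grid), mu = mu, size = cfg$overdispersion)

  # event-level labels: rater A scores the true behaviour; rater B relabels
  # each event with the configured disagreement probability
  ev <- grid[rep(seq_len(nrow(grid)), grid$count),
             c("bird_id", "condition", "session", "behavior")]
  names(ev)[names(ev) == "behavior"] <- "rater_a"
  n_ev <- nrow(ev)
  ev$rater_b <- ev$rater_a
  if (n_ev > 0 && cfg$rater_disagreement > 0 && length(behaviors) > 1) {
    flip <- runif(n_ev) < cfg$rater_disagreement
    if (any(flip)) {
      ev$rater_b[flip] <- vapply(ev$rater_a[flip], function(b)
        sample(setdiff(behaviors, b), 1L), character(1))
    }
  }
  ev <- tibble::as_tibble(ev)
  ev$event <- seq_len(nrow(ev))

  counts_a <- dplyr::mutate(grid, rater = "A")
  counts_b <- ev |>
    dplyr::count(bird_id, condition, session, behavior = .data$rater_b,
                 name = "count") |>
    tidyr::complete(bird_id = sprintf("B%02d", seq_len(cfg$n_birds)),
                    condition = cfg$conditions,
                    session = seq_len(cfg$n_sessions),
                    behavior = behaviors,
                    fill = list(count = 0L)) |>
    dplyr::mutate(rater = "B")
  counts <- dplyr::bind_rows(tibble::as_tibble(counts_a), counts_b) |>
    dplyr::arrange(rater, bird_id, condition, session, behavior)
  list(counts = counts, labels = ev)
}

#' Write a complete synthetic fixture set
#'
#' Emits one DeepLabCut-dialect trajectory CSV per bird x condition x session,
#' a session manifest, and ethogram tables, all derived deterministically from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest tibble, invisibly, with attribute `paths` naming the
#'   manifest, ethogram and rater-label files.
#' @export
write_fixture_set <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  traj_dir <- file.path(out_dir, "trajectories")
  ok <- dir.create(traj_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(traj_dir))
    stop_mf("cannot create output directory: ", traj_dir, class = "io_error")
  rows <- list()
  for (b in seq_len(cfg$n_birds)) {
    for (cond in cfg$conditions) {
      for (s in seq_len(cfg$n_sessions)) {
        sim <- simulate_session(cfg, b, cond, s)
        rel <- file.path("trajectories",
                         sprintf("%s_%s_s%02d.csv", sim$events$bird_id, cond, s))
        write_trajectory(sim$trajectory, file.path(out_dir, rel),
                         scorer = "mirrorforage-synthetic")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          bird_id = sim$events$bird_id, condition = cond, session = s,
          path = rel, fps = cfg$fps)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  man_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, man_path)
  etho <- simulate_ethogram(cfg)
  etho_path <- file.path(out_dir, "ethogram.csv")
  labels_path <- file.path(out_dir, "ethogram_labels.csv")
  readr::write_csv(etho$counts, etho_path)
  readr::write_csv(etho$labels, labels_path)
  attr(manifest, "paths") <- list(manifest = man_path, ethogram = etho_path,
                                  labels = labels_path)
  invisible(manifest)
}
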
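#' Behaviour catalogue used by the ethogram simulator
#'
#' @return Character vector of the six scored behaviours.
#' @export
behavior_catalogue <- function() {
  c("shaking", "preening", "head_scratching", "wing_flapping",
    "pecking_barrier", "attack")
}

default_latency_mean <- function(conditions, n_sessions) {
  base <- rbind(
    Wall     = c(25, 20, 18, 16, 15, 15),
    Mirror   = c(60, 35, 28, 24, 22, 20),
    Stranger = c(45, 25, 20, 16, 14, 13)
  )
  out <- matrix(20, nrow = length(conditions), ncol = n_sessions,
                dimnames = list(conditions, NULL))
  for (cond in intersect(conditions, rownames(base))) {
    cols <- pmin(seq_len(n_sessions), ncol(base))
    out[cond, ] <- base[cond, cols]
  }
  out
}

default_behavior_rates <- function(conditions) {
  # per-session mean counts; column order Wall, Mirror, Stranger
  base <- matrix(
    c(187, 183, 228,   # shaking
      246, 249, 359,   # preening
       10,   4,  12,   # head_scratching
       14,  17,   6,   # wing_flapping
        0,   9,  21,   # pecking_barrier
        0,  12,  10) / 48,  # attack; totals over 8 birds x 6 sessions
    nrow = 6, byrow = TRUE,
    dimnames = list(behavior_catalogue(), c("Wall", "Mirror", "Stranger"))
  )
  out <- matrix(1, nrow = 6, ncol = length(conditions),
                dimnames = list(behavior_catalogue(), conditions))
  for (cond in intersect(conditions, colnames(base))) out[, cond] <- base[, cond]
  out
}

#' Configuration of the synthetic arena-foraging experiment
#'
#' Defines the full design the generator emulates: 8 focal birds, three
#' conditions (Wall, Mirror, Stranger), 6 ten-minute sessions per condition at
#' 30 fps. Condition-level parameters encode the behavioural signatures the
#' analysis is meant to detect: mean body-orientation index toward the feeder
#' ordered Wall < Mirror < Stranger, non-feeding movement speed Stranger >
#' Wall > Mirror, latencies highest in Mirror with a strong session-1
#' elevation, and overdispersed per-session behaviour counts.
#'
#' @param n_birds number of focal birds.
#' @param conditions condition labels.
#' @param n_sessions sessions per condition.
#' @param session_length session duration in seconds.
#' @param fps camera frame rate (frames/second).
#' @param arena an [arena_geometry()].
#' @param approach_speed_mean named numeric, mean locomotion speed (cm/s) per
#'   condition.
#' @param orientation_bias named numeric in (0, 1], target time-mean
#'   body-orientation index per condition over the post-approach segment.
#' @param latency_mean condition x session matrix of mean latencies to reach
#'   the feeder (s); rownames must be the condition labels.
#' @param feeding_bout_rate feeding bouts per minute after the approach.
#' @param tracker_noise_sd sd (cm) of the Gaussian tracker jitter.
#' @param dropout_prob per-frame, per-bodypart probability of a low-likelihood
#'   dropout with corrupted coordinates.
#' @param behavior_rates behaviour x condition matrix of mean counts/session.
#' @param overdispersion negative-binomial size (shape) parameter for the
#'   behaviour counts; variance = mu (1 + mu / size), so smaller values give
#'   stronger overdispersion.
#' @param rater_disagreement probability that the second rater relabels an
#'   event to a different behaviour (controls the expected Cohen's kappa).
#' @param head_offset distance (cm) of the head keypoint from body-center
#'   along the heading.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_birds = 8,
                       conditions = c("Wall", "Mirror", "Stranger"),
                       n_sessions = 6,
                       session_length = 600,
                       fps = 30,
                       arena = arena_geometry(),
                       approach_speed_mean = c(Wall = 6, Mirror = 5, Stranger = 7),
                       orientation_bias = c(Wall = 0.35, Mirror = 0.51, Stranger = 0.67),
                       latency_mean = NULL,
                       feeding_bout_rate = 3,
                       tracker_noise_sd = 0.3,
                       dropout_prob = 0.02,
                       behavior_rates = NULL,
                       overdispersion = 5,
                       rater_disagreement = 0.05,
                       head_offset = 5,
                       seed = 20220101) {
  if (length(conditions) < 1) stop_mf("conditions must be nonempty", class = "config_error")
  if (anyDuplicated(conditions)) stop_mf("duplicate condition labels", class = "config_error")
  if (n_birds < 1 || n_sessions < 1) stop_mf("n_birds and n_sessions must be >= 1",
                                             class = "config_error")
  if (session_length <= 0) stop_mf("session_length must be > 0", class = "config_error")
  if (fps <= 0) stop_mf("fps must be > 0", class = "config_error")
  if (is.null(latency_mean)) latency_mean <- default_latency_mean(conditions, n_sessions)
  if (is.null(behavior_rates)) behavior_rates <- default_behavior_rates(conditions)
  need_named <- function(x, what) {
    if (is.null(names(x)) || !all(conditions %in% names(x)))
      stop_mf(what, " must be named for every condition", class = "config_error")
    x[conditions]
  }
  approach_speed_mean <- need_named(approach_speed_mean, "approach_speed_mean")
  orientation_bias <- need_named(orientation_bias, "orientation_bias")
  if (any(approach_speed_mean <= 0))
    stop_mf("approach_speed_mean must be > 0", class = "config_error")
  if (any(orientation_bias <= 0 | orientation_bias > 1))
    stop_mf("orientation_bias must lie in (0, 1]", class = "config_error")
  if (!is.matrix(latency_mean) || is.null(rownames(latency_mean)) ||
      !all(conditions %in% rownames(latency_mean)) ||
      ncol(latency_mean) < n_sessions)
    stop_mf("latency_mean must be a condition x session matrix", class = "config_error")
  latency_mean <- latency_mean[conditions, seq_len(n_sessions), drop = FALSE]
  if (any(latency_mean <= 0)) stop_mf("latency_mean must be > 0", class = "config_error")
  if (!is.matrix(behavior_rates) || is.null(rownames(behavior_rates)) ||
      !all(conditions %in% colnames(behavior_rates)))
    stop_mf("behavior_rates must be a behavior x condition matrix",
            class = "config_error")
  behavior_rates <- behavior_rates[, conditions, drop = FALSE]
  if (any(behavior_rates < 0))
    stop_mf("behavior_rates must be >= 0", class = "config_error")
  if (tracker_noise_sd < 0 || dropout_prob < 0 || dropout_prob > 1 ||
      feeding_bout_rate < 0 || overdispersion <= 0 ||
      rater_disagreement < 0 || rater_disagreement > 1 || head_offset <= 0)
    stop_mf("rates, probabilities and sds out of range", class = "config_error")
  structure(
    list(n_birds = as.integer(n_birds), conditions = conditions,
         n_sessions = as.integer(n_sessions), session_length = session_length,
         fps = fps, arena = arena,
         approach_speed_mean = approach_speed_mean,
         orientation_bias = orientation_bias,
         latency_mean = latency_mean,
         feeding_bout_rate = feeding_bout_rate,
         tracker_noise_sd = tracker_noise_sd,
         dropout_prob = dropout_prob,
         behavior_rates = behavior_rates,
         overdispersion = overdispersion,
         rater_disagreement = rater_disagreement,
         head_offset = head_offset,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d birds x {%s} x %d sessions, %g s @ %g fps, seed %d\n",
              x$n_birds, paste(x$conditions, collapse = ", "), x$n_sessions,
              x$session_length, x$fps, x$seed))
  invisible(x)
}

# deterministic per-unit seed derived from the master seed (kept < 2^31)
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in seq_along(ix)) s <- (s * 69069 + ix[k] * 2654435761) %% 2147483647
  as.integer(s) + 1L
}
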
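#' Summarise an ethogram table
#'
#' Per-behaviour, per-condition totals and per-session means with their
#' standard errors over the bird x session observations (the divisor for the
#' mean is the number of scored sessions per condition, e.g. 8 birds x 6
#' sessions = 48).
#'
#' @param tab ethogram tibble with columns `bird_id`, `condition`, `session`,
#'   `behavior`, `count` and optionally `rater`.
#' @param rater which rater's counts to summarise (default: first rater in the
#'   table, or all rows when no rater column exists).
#' @return Tibble `behavior`, `condition`, `sum`, `mean`, `sem`, `n`.
#' @export
summarize_ethogram <- function(tab, rater = NULL) {
  if (any(tab$count < 0)) stop_mf("counts must be >= 0", class = "input_error")
  if ("rater" %in% names(tab)) {
    if (is.null(rater)) rater <- sort(unique(tab$rater))[1]
    tab <- tab[tab$rater == rater, ]
  }
  out <- tab |>
    dplyr::group_by(behavior, condition) |>
    dplyr::summarise(sum = sum(count), mean = mean(count),
                     sem = if (dplyr::n() > 1) sd(count) / sqrt(dplyr::n()) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  ns <- unique(out$n)
  if (length(ns) > 1)
    warning("unequal numbers of scored sessions across cells: ",
            paste(ns, collapse = ", "))
  out
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with the
#' expected agreement \eqn{p_e} computed from the product of the raters'
#' marginal label frequencies. A large-sample z test against \eqn{\kappa = 0}
#' is included. When both raters assign a single identical label throughout,
#' \eqn{p_e = 1} and kappa is undefined (flagged, not an error).
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return List of class `kappa_result`: `kappa`, `p_o`, `p_e`, `se0`, `z`,
#'   `p_value`, `n`, `undefined`.
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y"), c("x", "x", "y"))$kappa  # 1
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_mf("label vectors must have equal length", class = "input_error")
  n <- length(labels_a)
  if (n < 2) stop_mf("need at least 2 paired labels", class = "input_error")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  p <- tab / n
  p_o <- sum(diag(p))
  pa <- rowSums(p); pb <- colSums(p)
  p_e <- sum(pa * pb)
  if (abs(1 - p_e) < .Machine$double.eps * 8) {
    warning("both raters constant with the same label; kappa undefined")
    return(structure(list(kappa = NA_real_, p_o = p_o, p_e = p_e,
                          se0 = NA_real_, z = NA_real_, p_value = NA_real_,
                          n = n, undefined = TRUE),
                     class = "kappa_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt (1969) null variance
  var0 <- (p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, se0 = se0, z = z,
                 p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                 n = n, undefined = FALSE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) cat("<kappa_result> undefined (p_e = 1)\n")
  else cat(sprintf("<kappa_result> kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d, p = %.3g)\n",
                   x$kappa, x$p_o, x$p_e, x$n, x$p_value))
  invisible(x)
}

#' Two-way repeated-measures ANOVA on behaviour counts
#'
#' Aggregates the counts of the selected behaviours per bird x condition x
#' session and fits the classical univariate repeated-measures ANOVA with
#' within-subject factors (condition, day, and their interaction when both are
#' given), using per-factor error strata. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the error from the matching
#' stratum. Tukey-adjusted pairwise comparisons are reported for `condition`
#' when present.
#'
#' @param tab ethogram tibble (`bird_id`, `condition`, `session`, `behavior`,
#'   `count`, optional `rater`; one rater's rows are used).
#' @param behaviors subset of behaviours to aggregate (default: all present).
#' @param factors within-subject factors: `c("condition", "day")` (day =
#'   session) or a single one.
#' @param rater rater whose counts are analysed.
#' @return List of class `test_result`: `anova` tibble (`term`, `df1`, `df2`,
#'   `F`, `p`, `partial_eta_sq`) and `posthoc` tibble of Tukey condition
#'   contrasts (or `NULL`).
#' @export
rm_anova <- function(tab, behaviors = NULL, factors = c("condition", "day"),
                     rater = NULL) {
  factors <- match.arg(factors, c("condition", "day"), several.ok = TRUE)
  if ("rater" %in% names(tab)) {
    if (is.null(rater)) rater <- sort(unique(tab$rater))[1]
    tab <- tab[tab$rater == rater, ]
  }
  if (is.null(behaviors)) behaviors <- unique(tab$behavior)
  d <- tab |>
    dplyr::filter(behavior %in% behaviors) |>
    dplyr::group_by(bird_id, condition, session) |>
    dplyr::summarise(y = sum(count), .groups = "drop") |>
    dplyr::mutate(bird = factor(bird_id), condition = factor(condition),
                  day = factor(session))
  cells <- table(d$bird, d$condition, d$day)
  if (length(unique(as.vector(cells))) != 1 || any(cells != 1))
    stop_mf("design must be balanced with one observation per bird x condition x day",
            class = "input_error")
  rhs <- paste(factors, collapse = " * ")
  err <- paste0("Error(bird/(", rhs, "))")
  fml <- as.formula(paste("y ~", rhs, "+", err))
  # build the call with the formula inlined so emmeans can re-evaluate it
  fit <- do.call(stats::aov, list(fml, data = d))
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- rownames(st)
    resid_i <- grep("^Residuals", trimws(terms))
    if (!length(resid_i)) next
    ss_err <- st[resid_i, "Sum Sq"]
    df_err <- st[resid_i, "Df"]
    for (i in setdiff(seq_along(terms), resid_i)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = trimws(terms[i]),
        df1 = st[i, "Df"], df2 = df_err,
        F = st[i, "F value"], p = st[i, "Pr(>F)"],
        partial_eta_sq = st[i, "Sum Sq"] / (st[i, "Sum Sq"] + ss_err))
    }
  }
  anova_tab <- dplyr::bind_rows(rows)
  posthoc <- NULL
  if ("condition" %in% factors && nlevels(d$condition) > 1) {
    em <- suppressMessages(emmeans::emmeans(fit, "condition", data = d))
    posthoc <- tibble::as_tibble(summary(emmeans::contrast(
      em, method = "pairwise", adjust = "tukey")))
    names(posthoc)[names(posthoc) == "p.value"] <- "p_corrected"
  }
  structure(list(anova = anova_tab, posthoc = posthoc,
                 n_subjects = nlevels(d$bird)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (!is.null(x$anova)) { cat("ANOVA:\n"); print(as.data.frame(x$anova)) }
  if (!is.null(x$lrt)) { cat("Likelihood-ratio tests:\n"); print(as.data.frame(x$lrt)) }
  if (!is.null(x$posthoc)) { cat("Post-hoc (Tukey):\n"); print(as.data.frame(x$posthoc)) }
  invisible(x)
}

#' Mixed-model likelihood-ratio tests with Tukey post-hocs
#'
#' Fits linear mixed models with a random intercept per bird (maximum
#' likelihood, as required for likelihood-ratio tests of fixed effects) to a
#' per-session scalar outcome and tests condition, session, and their
#' interaction by comparing nested fits. Pairwise condition contrasts are
#' Tukey-adjusted z tests on the additive model's estimated marginal means.
#' Right-censored sessions (e.g. a bird that never fed) are excluded, with the
#' number reported.
#'
#' @param data tibble with columns `bird_id`, `condition`, `session`, the
#'   outcome, and optionally logical `censored`.
#' @param outcome name of the outcome column.
#' @param interaction test the condition x session interaction (default TRUE).
#' @param session_posthoc also report Tukey-adjusted session contrasts within
#'   each condition (the familiarisation question).
#' @return List of class `test_result`: `lrt` tibble (`term`, `chisq`, `df`,
#'   `p`, `eta_sq_analog`), `posthoc` (condition contrasts),
#'   `posthoc_sessions` (optional), `n`, `n_censored`, `singular`.
#'   The effect-size analog is the Cox-Snell pseudo-R2 of the term,
#'   `1 - exp(-chisq / n)`.
#' @export
lmm_lrt <- function(data, outcome, interaction = TRUE,
                    session_posthoc = FALSE) {
  if (!outcome %in% names(data))
    stop_mf("outcome column '", outcome, "' not found", class = "input_error")
  n_censored <- 0L
  if ("censored" %in% names(data)) {
    n_censored <- sum(data$censored, na.rm = TRUE)
    data <- data[!data$censored, ]
  }
  d <- data.frame(y = data[[outcome]],
                  bird = factor(data$bird_id),
                  condition = factor(data$condition),
                  session = factor(data$session))
  d <- d[complete.cases(d), ]
  if (nlevels(d$bird) < 2 || nlevels(d$condition) < 2)
    stop_mf("need >= 2 birds and >= 2 condition levels", class = "input_error")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- function(f) suppressMessages(
    lme4::lmer(f, data = d, REML = FALSE, control = ctrl))
  m_add <- fit(y ~ condition + session + (1 | bird))
  m_nocond <- fit(y ~ session + (1 | bird))
  m_nosess <- fit(y ~ condition + (1 | bird))
  n <- nrow(d)
  lrt_row <- function(term, full, reduced) {
    chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
    df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
    tibble::tibble(term = term, chisq = chisq, df = df,
                   p = stats::pchisq(chisq, df, lower.tail = FALSE),
                   eta_sq_analog = 1 - exp(-chisq / n))
  }
  rows <- list(lrt_row("condition", m_add, m_nocond),
               lrt_row("session", m_add, m_nosess))
  singular <- lme4::isSingular(m_add)
  if (interaction && nlevels(d$session) > 1) {
    m_full <- fit(y ~ condition * session + (1 | bird))
    rows <- c(rows, list(lrt_row("condition:session", m_full, m_add)))
    singular <- singular || lme4::isSingular(m_full)
  }
  em <- suppressMessages(emmeans::emmeans(m_add, "condition", lmer.df = "asymptotic"))
  posthoc <- tibble::as_tibble(summary(emmeans::contrast(
    em, method = "pairwise", adjust = "tukey")))
  names(posthoc)[names(posthoc) == "p.value"] <- "p_corrected"
  posthoc_sessions <- NULL
  if (session_posthoc && nlevels(d$session) > 1) {
    m_full2 <- fit(y ~ condition * session + (1 | bird))
    ems <- emmeans::emmeans(m_full2, "session", by = "condition",
                            lmer.df = "asymptotic")
    posthoc_sessions <- tibble::as_tibble(summary(emmeans::contrast(
      ems, method = "pairwise", adjust = "tukey")))
    names(posthoc_sessions)[names(posthoc_sessions) == "p.value"] <- "p_corrected"
  }
  if (singular)
    warning("random-intercept variance estimated at the boundary (singular fit); ",
            "fixed-effect tests reported but interpret the random effect with care")
  structure(list(lrt = dplyr::bind_rows(rows), posthoc = posthoc,
                 posthoc_sessions = posthoc_sessions,
                 n = n, n_censored = n_censored, singular = singular),
            class = "test_result")
}
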
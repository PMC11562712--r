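#' Correct TEST series for dissipation in the sorption controls
#'
#' Sterile sorption controls (SC) capture the combined abiotic loss and
#' sorption-driven decline of the dissolved-phase signal. The SC relative
#' area curve \eqn{\hat S(t)} is estimated by a log-linear fit of the
#' pooled SC areas versus time (i.e. a first-order SC dissipation rate
#' constant, clamped at zero so \eqn{\hat S \le 1}), and each TEST area at
#' time t is divided by \eqn{\hat S(t)}, so the residual decay in the
#' corrected series reflects biodegradation only. Dividing by the fitted
#' curve rather than by the raw per-time SC ratios preserves the
#' point-level data for the break test while injecting far less
#' measurement noise; on exact exponentials the two are identical. The
#' sampling variance of the SC rate estimate (`se_sc`) is returned so the
#' cell-level fit can propagate it into the uncertainty of the corrected
#' rate constant. Censoring flags are carried forward unchanged.
#'
#' @param test_df long table of TEST points for one compound x site
#'   (`time_days`, `area`, `censored`, `replicate`).
#' @param sc_df matching SC points.
#' @return List with `series` (corrected TEST table), `k_sc` (SC
#'   dissipation rate, 1/day), `se_sc` (its standard error, 0 when the
#'   correction was skipped) and `status` (`"ok"`, or `"sc_censored"` when
#'   no usable SC data exist, in which case the TEST series is returned
#'   unchanged).
#' @export
correct_for_sc <- function(test_df, sc_df) {
  usable <- sc_df[!sc_df$censored & sc_df$area > 0, , drop = FALSE]
  t0 <- usable[usable$time_days == 0, , drop = FALSE]
  if (nrow(usable) == 0L || nrow(t0) == 0L) {
    warning("all sorption-control points censored; SC correction skipped")
    return(list(series = test_df, k_sc = NA_real_, se_sc = 0,
                status = "sc_censored"))
  }
  if (length(unique(usable$time_days)) < 2L) {
    # a lone t = 0 point fixes no curve: nothing to correct with
    return(list(series = test_df, k_sc = NA_real_, se_sc = 0,
                status = "sc_insufficient"))
  }
  fit <- stats::lm(log(area) ~ time_days, data = usable)
  cf <- suppressWarnings(summary(fit))$coefficients
  k_sc <- max(-cf["time_days", "Estimate"], 0)  # S(t) must not exceed 1
  se_sc <- cf["time_days", "Std. Error"]
  if (!is.finite(se_sc)) se_sc <- 0
  corrected <- test_df
  corrected$area <- test_df$area / exp(-k_sc * test_df$time_days)
  list(series = corrected, k_sc = k_sc, se_sc = se_sc, status = "ok")
}

#' Pooled log-linear first-order fit
#'
#' Ordinary least-squares regression of ln(peak area) on time over all
#' uncensored points, pooled across replicates. The observed rate constant
#' is minus the slope; confidence intervals come from the t distribution of
#' the slope, and the p-value is one-sided for a negative slope
#' (dissipation). An estimate is valid when it rests on at least
#' `min_points` data points and the slope is significantly below zero
#' (p < `alpha`); a significant *positive* slope is therefore invalid.
#'
#' @param df long table with `time_days`, `area`, `censored`.
#' @param min_points minimum number of points for a valid estimate
#'   (default 5).
#' @param alpha significance level for the slope test (default 0.05).
#' @return One-row data.frame: `k_observed`, `se`, `ci95_lo/hi`,
#'   `ci99_lo/hi`, `p_value`, `n_points`, `valid`, `reason_invalid`
#'   (`"none"`, `"too_few_points"`, `"not_significant"`), `status`
#'   (`"ok"` or `"not_available"` when fewer than 2 uncensored points
#'   remain).
#' @export
fit_pooled_loglinear <- function(df, min_points = 5L, alpha = 0.05) {
  use <- df[!df$censored & df$area > 0, , drop = FALSE]
  n <- nrow(use)
  na_row <- data.frame(
    k_observed = NA_real_, se = NA_real_,
    ci95_lo = NA_real_, ci95_hi = NA_real_,
    ci99_lo = NA_real_, ci99_hi = NA_real_,
    p_value = NA_real_, n_points = n, valid = FALSE,
    reason_invalid = "too_few_points", status = "not_available",
    stringsAsFactors = FALSE
  )
  if (n < 2L || length(unique(use$time_days)) < 2L) return(na_row)
  fit <- stats::lm(log(area) ~ time_days, data = use)
  # noiseless fixtures fit exactly; the perfect-fit warning is expected
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["time_days", "Estimate"]
  se <- cf["time_days", "Std. Error"]
  dfree <- fit$df.residual
  if (dfree < 1L || !is.finite(se)) return(na_row)
  k <- -slope
  t975 <- stats::qt(0.975, dfree)
  t995 <- stats::qt(0.995, dfree)
  # one-sided: evidence that the slope is negative
  p <- stats::pt(slope / se, dfree)
  valid <- n >= min_points && is.finite(p) && p < alpha
  reason <- if (valid) "none" else if (n < min_points) "too_few_points" else "not_significant"
  data.frame(
    k_observed = k, se = se,
    ci95_lo = k - t975 * se, ci95_hi = k + t975 * se,
    ci99_lo = k - t995 * se, ci99_hi = k + t995 * se,
    p_value = p, n_points = n, valid = valid, reason_invalid = reason,
    status = "ok", stringsAsFactors = FALSE
  )
}

# Folds the sampling variance of the SC dissipation rate into a cell
# estimate: the corrected rate is a difference of two independent slopes,
# so their variances add. CIs and the one-sided p are recomputed on the
# combined standard error (t distribution with the TEST fit's df).
propagate_sc_uncertainty <- function(est, se_sc, min_points = 5L,
                                     alpha = 0.05) {
  if (!identical(est$status, "ok") || !is.finite(est$se) || se_sc <= 0) {
    return(est)
  }
  dfree <- est$n_points - 2L
  se <- sqrt(est$se^2 + se_sc^2)
  est$se <- se
  est$ci95_lo <- est$k_observed - stats::qt(0.975, dfree) * se
  est$ci95_hi <- est$k_observed + stats::qt(0.975, dfree) * se
  est$ci99_lo <- est$k_observed - stats::qt(0.995, dfree) * se
  est$ci99_hi <- est$k_observed + stats::qt(0.995, dfree) * se
  est$p_value <- stats::pt(-est$k_observed / se, dfree)
  est$valid <- est$n_points >= min_points && est$p_value < alpha
  est$reason_invalid <- if (est$valid) "none" else
    if (est$n_points < min_points) "too_few_points" else "not_significant"
  est
}

# Residual sum of squares of ln(area) ~ time on a set of points.
.rss_loglinear <- function(tt, y) {
  X <- cbind(1, tt)
  b <- qr.coef(qr(X), y)
  r <- y - X %*% b
  sum(r^2)
}

#' Classify mono- vs biphasic dissipation with a Chow structural-break test
#'
#' Biphasic dissipation (fast initial phase, slower late phase) is detected
#' by a Chow F-test of the pooled ln-linear regression at every candidate
#' break placed at an interior scheduled sampling time with at least
#' `m_min` uncensored points and two distinct times on each side
#' (first segment: t <= break; second: t > break). The candidate with the
#' largest F (earliest time on ties) is retained, and its p-value is
#' Bonferroni-corrected for the number of candidates tested so that the
#' family-wise false-biphasic rate is controlled at `alpha_chow`. When the
#' corrected p falls below `alpha_chow` the series is classified biphasic
#' and the reported rate constant is the initial-segment fit; otherwise the
#' full-series fit is used.
#'
#' @param df pooled, SC-corrected TEST points (`time_days`, `area`,
#'   `censored`).
#' @param alpha_chow significance level of the break test (default 0.05).
#' @param m_min minimum uncensored points per segment (default 3).
#' @param min_points,alpha passed to [fit_pooled_loglinear()].
#' @return List: `kinetic_class` ("monophasic"/"biphasic"), `break_time`
#'   (NA when monophasic), `estimate` (the RateEstimate row used for
#'   k_observed), `full_estimate` (always the full-series fit), `chow_p`
#'   (Bonferroni-corrected minimal p, NA when no candidate was testable).
#' @export
classify_biphasic <- function(df, alpha_chow = 0.05, m_min = 3L,
                              min_points = 5L, alpha = 0.05) {
  full <- fit_pooled_loglinear(df, min_points = min_points, alpha = alpha)
  mono <- function(chow_p = NA_real_) {
    list(kinetic_class = "monophasic", break_time = NA_real_,
         estimate = full, full_estimate = full, chow_p = chow_p)
  }
  use <- df[!df$censored & df$area > 0, , drop = FALSE]
  n <- nrow(use)
  if (n < 2L * m_min) return(mono())
  tt <- use$time_days
  y <- log(use$area)
  times <- sort(unique(tt))
  cands <- times[vapply(times, function(tb) {
    i1 <- tt <= tb
    sum(i1) >= m_min && sum(!i1) >= m_min &&
      length(unique(tt[i1])) >= 2L && length(unique(tt[!i1])) >= 2L
  }, logical(1))]
  if (length(cands) == 0L) return(mono())

  rss_full <- .rss_loglinear(tt, y)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0 || rss_full / tss < 1e-15) return(mono())  # perfect single line

  stats_tab <- t(vapply(cands, function(tb) {
    i1 <- tt <= tb
    rss_split <- .rss_loglinear(tt[i1], y[i1]) + .rss_loglinear(tt[!i1], y[!i1])
    dfree <- n - 4L
    f <- ((rss_full - rss_split) / 2) / (rss_split / dfree)
    if (!is.finite(f)) f <- Inf  # split fits exactly
    p <- stats::pf(f, 2, dfree, lower.tail = FALSE)
    c(f = f, p = p)
  }, c(f = 0, p = 0)))

  best <- which(stats_tab[, "f"] == max(stats_tab[, "f"]))[1L]  # earliest tie
  p_adj <- min(1, stats_tab[best, "p"] * length(cands))
  if (!is.finite(p_adj) || p_adj >= alpha_chow) return(mono(p_adj))

  brk <- cands[best]
  initial <- fit_pooled_loglinear(df[df$time_days <= brk, , drop = FALSE],
                                  min_points = min_points, alpha = alpha)
  list(kinetic_class = "biphasic", break_time = brk, estimate = initial,
       full_estimate = full, chow_p = p_adj)
}

#' Fit one compound x site cell
#'
#' Runs the full per-cell chain: SC correction, biphasic classification,
#' and the pooled rate estimate with validity flags.
#'
#' @param test_df,sc_df long tables of TEST and SC points for the cell.
#' @param alpha_chow,m_min,min_points,alpha tuning parameters, see
#'   [classify_biphasic()] and [fit_pooled_loglinear()].
#' @return One-row data.frame combining the RateEstimate fields with
#'   `kinetic_class`, `break_time`, `chow_p` and `sc_status`.
#' @export
fit_cell <- function(test_df, sc_df, alpha_chow = 0.05, m_min = 3L,
                     min_points = 5L, alpha = 0.05) {
  corr <- if (is.null(sc_df) || nrow(sc_df) == 0L) {
    list(series = test_df, status = "no_sc")
  } else {
    correct_for_sc(test_df, sc_df)
  }
  cls <- classify_biphasic(corr$series, alpha_chow = alpha_chow,
                           m_min = m_min, min_points = min_points,
                           alpha = alpha)
  out <- propagate_sc_uncertainty(cls$estimate, corr$se_sc %||% 0,
                                  min_points = min_points, alpha = alpha)
  out$kinetic_class <- cls$kinetic_class
  out$break_time <- cls$break_time
  out$chow_p <- cls$chow_p
  out$sc_status <- corr$status
  out
}

#' Fit rate constants for every compound x site cell of an experiment
#'
#' Pools the TEST replicates per cell (all uncensored points enter one
#' regression), corrects for the sorption controls, classifies kinetics,
#' and additionally fits each TEST replicate separately (used for the
#' between-site ANOVA). Replicate-level fits inherit the pooled cell's
#' kinetic class: when the pooled fit is biphasic, replicates are fitted on
#' the initial segment only. The dissolved fraction f_Dis is estimated per
#' cell from the SC and HC areas at t = 0.
#'
#' @param areas long area table as produced by [generate_experiment()] (or
#'   read with [read_incubation_csv()]).
#' @param alpha_chow,m_min,min_points,alpha tuning parameters.
#' @return List of data.frames: `rates` (one row per cell, scope "pooled"),
#'   `replicate_rates` (one row per cell x TEST replicate), `f_dis` (per
#'   cell dissolved fraction and status).
#' @export
fit_rates <- function(areas, alpha_chow = 0.05, m_min = 3L,
                      min_points = 5L, alpha = 0.05) {
  cells <- unique(areas[, c("site", "country", "compound")])
  rates <- vector("list", nrow(cells))
  reps <- vector("list", nrow(cells))
  fdis <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    si <- cells$site[i]; cp <- cells$compound[i]
    cell <- areas[areas$site == si & areas$compound == cp, , drop = FALSE]
    test <- cell[cell$vessel_type == "TEST", , drop = FALSE]
    sc <- cell[cell$vessel_type == "SC", , drop = FALSE]
    hc <- cell[cell$vessel_type == "HC", , drop = FALSE]

    row <- fit_cell(test, sc, alpha_chow = alpha_chow, m_min = m_min,
                    min_points = min_points, alpha = alpha)
    row <- cbind(cells[i, , drop = FALSE], scope = "pooled", row,
                 row.names = NULL)
    rates[[i]] <- row

    corr <- if (nrow(sc)) suppressWarnings(correct_for_sc(test, sc)$series) else test
    rr <- lapply(split(corr, corr$replicate), function(d) {
      dd <- if (row$kinetic_class == "biphasic" && is.finite(row$break_time)) {
        d[d$time_days <= row$break_time, , drop = FALSE]
      } else d
      est <- fit_pooled_loglinear(dd, min_points = min_points, alpha = alpha)
      cbind(cells[i, , drop = FALSE], scope = "replicate",
            replicate = d$replicate[1], est, row.names = NULL)
    })
    reps[[i]] <- do.call(rbind, rr)

    sc0 <- sc[sc$time_days == 0 & !sc$censored, "area"]
    hc0 <- hc[hc$time_days == 0 & !hc$censored, "area"]
    fd <- estimate_f_dis(sc0, hc0)
    fdis[[i]] <- data.frame(
      site = si, compound = cp, f_dis = as.numeric(fd),
      f_dis_status = if (is.na(fd)) attr(fd, "reason") else "estimated",
      stringsAsFactors = FALSE
    )
  }
  list(
    rates = do.call(rbind, c(rates, list(make.row.names = FALSE))),
    replicate_rates = do.call(rbind, c(reps, list(make.row.names = FALSE))),
    f_dis = do.call(rbind, c(fdis, list(make.row.names = FALSE)))
  )
}
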
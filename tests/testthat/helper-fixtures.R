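# Shared fixtures, all built in code.

design_times <- function() c(c(0, 2, 5, 9, 18) / 24, 1, 2, 4, 7, 10)

# Noiseless exponential series in the long dialect.
make_series <- function(k, times = design_times(), a0 = 1e6, f_dis = 1,
                        reps = 1L, vessel = "TEST", loq = 0,
                        compound = "X", site = "S1") {
  do.call(rbind, lapply(seq_len(reps), function(r) {
    a <- a0 * f_dis * exp(-k * times)
    data.frame(site = site, country = "AA", compound = compound,
               vessel_type = vessel, replicate = paste0(vessel, r),
               time_days = times, area = a, censored = a < loq,
               stringsAsFactors = FALSE)
  }))
}

# Piecewise-exponential (biphasic) series, continuous at the break.
make_biphasic_series <- function(k1, k2, brk, times = design_times(),
                                 a0 = 1e6, reps = 1L, loq = 0) {
  do.call(rbind, lapply(seq_len(reps), function(r) {
    a <- a0 * ifelse(times <= brk, exp(-k1 * times),
                     exp(-k1 * brk - k2 * (times - brk)))
    data.frame(site = "S1", country = "AA", compound = "X",
               vessel_type = "TEST", replicate = paste0("TEST", r),
               time_days = times, area = a, censored = a < loq,
               stringsAsFactors = FALSE)
  }))
}

# Multiply areas by seeded lognormal noise with the given RSD.
add_noise <- function(df, rsd, seed) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + rsd^2))
  df$area <- df$area * exp(rnorm(nrow(df), -sdlog^2 / 2, sdlog))
  df
}

# Rate table row in the layout rate_matrix() expects.
rate_row <- function(compound, site, k, valid, ci99 = c(NA, NA),
                     country = "AA", status = "ok") {
  data.frame(site = site, country = country, compound = compound,
             k_observed = k, ci99_lo = ci99[1], ci99_hi = ci99[2],
             valid = valid, status = status, stringsAsFactors = FALSE)
}

# Small experiment reused by several files (built once per test run).
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- simulate_site_env(n_per_country = c(SE = 2, DE = 2, CH = 2),
                               seed = 42)
      cmp <- default_compound_panel()[c(1, 3, 6, 10)]
      cache <<- generate_experiment(study_design(seed = 42), cmp,
                                    site_model(env))
    }
    cache
  }
})

# Independent brute-force RDA: explicit normal equations + eigen
# decomposition of the fitted covariance. Returns per-axis shares of total
# variance and the total R^2.
brute_rda_shares <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xm <- as.matrix(X)
  B <- solve(crossprod(Xm), crossprod(Xm, Yc))
  fitted <- Xm %*% B
  ev <- eigen(crossprod(fitted) / (nrow(Yc) - 1), symmetric = TRUE)$values
  tot <- sum(diag(crossprod(Yc) / (nrow(Yc) - 1)))
  list(shares = ev[ev > 1e-12] / tot, r2 = sum(fitted^2) / sum(Yc^2))
}
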
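test_that("stddev of log10 and its fold conversion behave as stated", {
  expect_equal(stddev_log(c(0.2, 0.2, 0.2)),
               list(stddev_log10 = 0, fold = 1))
  out <- stddev_log(c(0.1, 1, 10))
  expect_equal(out$stddev_log10, 1.0, tolerance = 1e-12)
  expect_equal(out$fold, 10, tolerance = 1e-12)
  expect_error(stddev_log(c(0.1, -1)), "non-positive")
  expect_error(stddev_log(0.1), "at least 2")
})

test_that("spread statistics are invariant to rescaling", {
  set.seed(3)
  v <- 10^rnorm(10, -0.5, 0.4)
  a <- stddev_log(v)
  b <- stddev_log(v * 123.4)
  expect_equal(a$stddev_log10, b$stddev_log10, tolerance = 1e-12)
  expect_equal(a$fold, b$fold, tolerance = 1e-12)
})

test_that("half-life conversion is ln(2)/k", {
  expect_equal(half_life(0.14), log(2) / 0.14, tolerance = 1e-12)
  expect_equal(round(half_life(0.14)), 5)
})

test_that("ANOVA F matches the hand-computed mean-square ratio", {
  d <- data.frame(
    site = rep(c("A", "B", "C"), each = 3),
    k = c(0.10, 0.12, 0.11, 0.30, 0.28, 0.33, 0.55, 0.60, 0.50)
  )
  out <- anova_across_sites(d)
  # textbook oracle on log10 k
  y <- log10(d$k); g <- d$site
  gm <- tapply(y, g, mean); n_g <- tapply(y, g, length)
  ss_b <- sum(n_g * (gm - mean(y))^2)
  ss_w <- sum((y - gm[g])^2)
  f_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(out$F, f_oracle, tolerance = 1e-10)
  expect_equal(out$p, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA degenerate and separated limits behave", {
  flat <- data.frame(site = rep(c("A", "B"), each = 3), k = rep(0.2, 6))
  out <- anova_across_sites(flat)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  jit <- c(1, 1, 1, 10, 10, 10) * (1 + 1e-9 * c(1, -1, 2, 1, -2, 1))
  sep <- data.frame(site = rep(c("A", "B"), each = 3), k = jit)
  expect_lt(anova_across_sites(sep)$p, 0.05)
  one <- data.frame(site = "A", k = c(1, 2))
  expect_identical(anova_across_sites(one)$status, "not_computable")
})

test_that("scope summaries report medians and group sizes correctly", {
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i) {
      rate_row("C1", paste0("S", i), c(0.1, 0.2, 0.1, 0.2)[i], valid = TRUE)
    })),
    do.call(rbind, lapply(1:4, function(i) {
      rate_row("C2", paste0("S", i), c(0.1, 0.5, 0.1, 0.5)[i], valid = TRUE)
    }))
  )
  rm <- rate_matrix(rows)
  out <- summarize_scope(rm)
  bc <- out$by_compound
  expect_equal(nrow(bc), 2)
  expect_equal(out$by_scope$median_stddev_log10,
               median(bc$stddev_log10), tolerance = 1e-12)
  expect_equal(bc$fold, 10^bc$stddev_log10, tolerance = 1e-12)
  expect_equal(bc$n_sites_used, c(4L, 4L))
})

test_that("site groups are honored and small scopes are skipped", {
  ex <- small_experiment()
  fits <- fit_rates(ex$areas)
  rm <- gap_fill_chain(rate_matrix(fits$rates))
  env <- ex$truth_sites
  groups <- list(
    all_sites = env$site_id,
    contaminated = env$site_id[env$contamination == "contaminated"],
    tiny = env$site_id[1]
  )
  expect_message(out <- summarize_scope(rm, groups), "tiny")
  expect_setequal(unique(out$by_compound$scope),
                  c("all_sites", "contaminated"))
  n_cont <- sum(env$contamination == "contaminated")
  expect_true(all(out$by_compound$n_sites_used[
    out$by_compound$scope == "contaminated"] <= n_cont))
})

test_that("median rate constants recover the generated variability level", {
  env <- simulate_site_env(seed = 21)
  cmps <- lapply(1:20, function(i) {
    true_compound(sprintf("N%02d", i), runif(1, -1, 0.5))
  })
  set.seed(21)
  ex <- generate_experiment(study_design(seed = 21), cmps,
                            site_model(env, sigma_site = 0.46))
  truth_rm <- rate_matrix(do.call(rbind, lapply(
    seq_len(nrow(ex$truth_cells)), function(i) {
      tc <- ex$truth_cells[i, ]
      rate_row(tc$compound, tc$site, tc$k_true, valid = TRUE,
               country = tc$country)
    })))
  out <- summarize_scope(truth_rm)
  tol <- 3 * 0.46 / sqrt(2 * (18 - 1))
  expect_lt(abs(out$by_scope$median_stddev_log10 - 0.46), tol)
})

test_that("environmental correlation finds a built-in linear relation", {
  env <- simulate_site_env(n_per_country = c(SE = 3, DE = 3), seed = 2)
  rows <- do.call(rbind, lapply(seq_len(nrow(env)), function(i) {
    rate_row("C1", env$site_id[i], 0.05 * log10(env$toc[i]) + 0.2,
             valid = TRUE)
  }))
  out <- correlate_with_env(rate_matrix(rows), env, "toc")
  expect_equal(out$r, 1, tolerance = 1e-10)
  const <- env; const$toc <- 2
  expect_identical(correlate_with_env(rate_matrix(rows), const, "toc")$status,
                   "not_computable")
})
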
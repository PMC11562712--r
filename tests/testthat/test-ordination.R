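test_that("predictor preparation transforms, drops silt, and standardizes", {
  env <- simulate_site_env(seed = 13)
  pred <- prepare_predictors(env)
  expect_setequal(colnames(pred), c("longitude", "latitude", "tcc", "toc",
                                    "ec", "do", "ph", "inv_t", "clay",
                                    "sand"))
  expect_equal(ncol(pred), 10)
  expect_false("silt" %in% colnames(pred))
  expect_true(all(abs(colMeans(pred)) < 1e-12))
  expect_true(all(abs(apply(pred, 2, sd) - 1) < 1e-12))
  # 1/T enters before scaling: check ordering is preserved through scale()
  expect_equal(order(pred$inv_t), order(1 / env$temperature_k))
  bad <- env; bad$toc[1] <- -1
  expect_error(prepare_predictors(bad), "toc")
})

test_that("one response and one predictor reduce to simple regression", {
  set.seed(5)
  x <- data.frame(x = rnorm(20))
  y <- matrix(2 * x$x + rnorm(20), ncol = 1, dimnames = list(NULL, "c1"))
  out <- run_rda(y, x, permutations = 99, seed = 1)
  expect_equal(out$r2_total, cor(y[, 1], x$x)^2, tolerance = 1e-10)
})

test_that("an exactly linear response is fully explained", {
  set.seed(6)
  x <- data.frame(a = rnorm(15), b = rnorm(15))
  y <- cbind(r1 = x$a + 2 * x$b, r2 = x$a - x$b)
  out <- run_rda(y, x, permutations = 999, seed = 2)
  expect_equal(out$r2_total, 1, tolerance = 1e-10)
  expect_equal(out$p_model, 1 / 1000)  # (b+1)/(B+1) floor at B = 999
})

test_that("axis shares match a brute-force normal-equations ordination", {
  set.seed(7)
  env <- simulate_site_env(seed = 7)
  pred <- prepare_predictors(env)[, c("toc", "ph", "inv_t")]
  y <- matrix(rnorm(18 * 5), 18, 5,
              dimnames = list(env$site_id, paste0("c", 1:5)))
  y[, 1] <- y[, 1] + 2 * pred$toc
  out <- run_rda(y, pred, permutations = 99, seed = 3)
  oracle <- brute_rda_shares(y, pred)
  expect_equal(unname(out$axis_shares),
               oracle$shares[seq_along(out$axis_shares)],
               tolerance = 1e-8)
  expect_equal(out$r2_total, oracle$r2, tolerance = 1e-10)
})

test_that("adjusted R2 applies the Ezekiel correction and its bounds", {
  set.seed(8)
  x <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  y <- cbind(r1 = x$a + rnorm(15), r2 = rnorm(15))
  out <- run_rda(y, x, permutations = 99, seed = 4)
  n <- 15; m <- 3
  expect_equal(out$r2_adjusted,
               1 - (1 - out$r2_total) * (n - 1) / (n - m - 1),
               tolerance = 1e-10)
  expect_lt(out$r2_adjusted, out$r2_total)
  expect_true(all(diff(out$axis_shares) <= 1e-12))
  expect_lte(sum(out$axis_shares), out$r2_total + 1e-9)
})

test_that("envfit scores a variable aligned with an axis as r2 = 1", {
  set.seed(9)
  scores <- cbind(RDA1 = rnorm(18), RDA2 = rnorm(18))
  vars <- data.frame(aligned = scores[, 1] * 3 + 1, noise = rnorm(18))
  out <- envfit_variables(scores, vars, n_perm = 199)
  expect_equal(out$r2_envfit[out$name == "aligned"], 1, tolerance = 1e-10)
  expect_lt(out$p_envfit[out$name == "aligned"], 0.05)
  expect_lt(out$r2_envfit[out$name == "noise"], 0.5)
  expect_equal(out$r2_envfit_adjusted,
               1 - (1 - out$r2_envfit) * 17 / 15, tolerance = 1e-10)
})

test_that("envfit orders strong vs weak generating effects correctly", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    strong <- rnorm(18)
    y <- cbind(c1 = 2 * strong + 0.3 * rnorm(18),
               c2 = strong + 0.3 * rnorm(18))
    vars <- data.frame(strong = strong, weak = 0.2 * strong + rnorm(18))
    pred <- as.data.frame(scale(vars))
    out <- run_rda(y, pred, permutations = 99, seed = s)
    pv <- out$per_variable
    pv$r2_envfit_adjusted[pv$name == "strong"] >
      pv$r2_envfit_adjusted[pv$name == "weak"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the ordination response refuses data gaps", {
  rows <- rbind(
    rate_row("C1", "S1", 0.1, valid = TRUE),
    rate_row("C1", "S2", 0.2, valid = TRUE),
    rate_row("C2", "S1", 0.3, valid = TRUE),
    rate_row("C2", "S2", NA, valid = FALSE, status = "not_available")
  )
  rm <- rate_matrix(rows)
  expect_error(ordination_response(rm), "empty cells")
  expect_silent(resp <- ordination_response(rm, "C1"))
  expect_equal(dim(resp), c(2, 1))
  expect_equal(resp["S1", "C1"], log10(0.1))
})
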
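# Build a rate matrix holding one invalid target cell at site S0 plus valid
# peers for the same compound at other sites, and one unrelated compound
# fixing the global minimum.
chain_fixture <- function(ci99, peers = c(0.1, 0.2, 0.4), global_min = 0.001) {
  rows <- list(rate_row("C1", "S0", 0.05, valid = FALSE, ci99 = ci99))
  for (i in seq_along(peers)) {
    rows[[length(rows) + 1L]] <-
      rate_row("C1", paste0("S", i), peers[i], valid = TRUE)
  }
  rows[[length(rows) + 1L]] <- rate_row("C2", "S0", global_min, valid = TRUE)
  rate_matrix(do.call(rbind, rows))
}

test_that("step 1: CI containing the peer median fills with the median", {
  rm <- gap_fill_chain(chain_fixture(ci99 = c(-0.1, 0.3)))
  expect_equal(rm$values["C1", "S0"], 0.2)
  expect_identical(rm$status["C1", "S0"], "gapfilled_median")
})

test_that("step 2: CI containing only the peer minimum fills with the minimum", {
  rm <- gap_fill_chain(chain_fixture(ci99 = c(-0.01, 0.04),
                                     peers = c(0.03, 0.2, 0.4)))
  expect_equal(rm$values["C1", "S0"], 0.03)
  expect_identical(rm$status["C1", "S0"], "gapfilled_min_compound")
})

test_that("step 3: CI excluding both falls back to the global minimum", {
  rm <- gap_fill_chain(chain_fixture(ci99 = c(0.5, 0.9),
                                     peers = c(0.03, 0.2, 0.4)))
  expect_equal(rm$values["C1", "S0"], 0.001)
  expect_identical(rm$status["C1", "S0"], "gapfilled_global_min")
})

test_that("CI containment is closed: a boundary hit counts", {
  rm <- gap_fill_chain(chain_fixture(ci99 = c(0.2, 0.5)))  # lo == median
  expect_identical(rm$status["C1", "S0"], "gapfilled_median")
})

test_that("a compound with no valid peers anywhere falls to the global min", {
  rows <- rbind(
    rate_row("C1", "S0", 0.05, valid = FALSE, ci99 = c(-0.1, 0.3)),
    rate_row("C2", "S0", 0.007, valid = TRUE)
  )
  rm <- gap_fill_chain(rate_matrix(rows))
  expect_equal(rm$values["C1", "S0"], 0.007)
  expect_identical(rm$status["C1", "S0"], "gapfilled_global_min")
})

test_that("gap-filling is idempotent and leaves valid cells untouched", {
  ex <- small_experiment()
  fits <- fit_rates(ex$areas)
  rm0 <- rate_matrix(fits$rates)
  rm1 <- gap_fill_chain(rm0)
  rm2 <- gap_fill_chain(rm1)
  expect_identical(rm1, rm2)
  valid <- rm0$status == "valid"
  expect_identical(rm1$values[valid], rm0$values[valid])
  filled <- grepl("^gapfilled", rm1$status)
  if (any(filled)) {
    expect_true(all(rm1$values[filled] >= min(rm0$values[valid])))
    expect_true(all(rm1$values[filled] <= max(rm0$values[valid])))
  }
})

test_that("country medians fill not-available cells only under low spread", {
  mk <- function(vals, na_site = "S9") {
    rows <- list(rate_row("C1", na_site, NA, valid = FALSE,
                          status = "not_available"))
    for (i in seq_along(vals)) {
      rows[[length(rows) + 1L]] <- rate_row("C1", paste0("S", i), vals[i],
                                            valid = TRUE)
    }
    rate_matrix(do.call(rbind, rows))
  }
  # tight spread (stddev log10 ~ 0.035): filled with the median
  rm <- country_median_fill(mk(c(0.10, 0.12, 0.11)))
  expect_equal(rm$values["C1", "S9"], 0.11)
  expect_identical(rm$status["C1", "S9"], "gapfilled_country_median")
  # wild spread (stddev log10 ~ 1.41): left alone
  rm <- country_median_fill(mk(c(0.01, 1.0)))
  expect_identical(rm$status["C1", "S9"], "not_available")
  # degenerate threshold: nothing ever fills
  rm <- country_median_fill(mk(c(0.10, 0.12, 0.11)), stddev_threshold = 0)
  expect_identical(rm$status["C1", "S9"], "not_available")
})

test_that("the inclusion criterion keeps compounds valid at >= 12 of 18 sites", {
  mk_compound <- function(id, n_valid, n_sites = 18) {
    do.call(rbind, lapply(seq_len(n_sites), function(i) {
      rate_row(id, sprintf("S%02d", i), 0.1,
               valid = i <= n_valid,
               ci99 = c(-0.1, 0.3))
    }))
  }
  rm <- rate_matrix(rbind(mk_compound("KEEP", 12), mk_compound("DROP", 11)))
  expect_identical(apply_inclusion_criterion(rm), "KEEP")
  expect_setequal(apply_inclusion_criterion(rm, min_valid = 0),
                  c("KEEP", "DROP"))
})

test_that("corrections applied after filling preserve statuses", {
  ex <- small_experiment()
  fits <- fit_rates(ex$areas)
  rm <- gap_fill_chain(rate_matrix(fits$rates))
  props <- compound_properties(default_compound_panel()[c(1, 3, 6, 10)])
  rm7 <- correct_rate_matrix(rm, fits$f_dis, props, ex$truth_sites)
  expect_identical(rm7$status, rm$status)
  # neutral, non-sorbing compounds are unchanged by the corrections
  expect_equal(rm7$values["CPD01", ], rm$values["CPD01", ], tolerance = 0.2)
})
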
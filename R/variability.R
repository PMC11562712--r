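#' Standard deviation of log10 rate constants and its fold equivalent
#'
#' The spatial-variability metric: the sample standard deviation (n-1
#' denominator) of log10 of the rate constants, together with its base-10
#' antilog, which expresses the spread as a fold difference (e.g. a stddev
#' of 0.46 log10 units is a factor of about 3).
#'
#' @param values positive rate constants (at least 2).
#' @return Named list `stddev_log10`, `fold`.
#' @export
#' @examples
#' stddev_log(c(0.1, 1, 10))  # stddev 1, fold 10
stddev_log <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("non-positive rate constant at position ", bad[1L])
  }
  s <- stats::sd(log10(values))
  list(stddev_log10 = s, fold = 10^s)
}

#' First-order half-life
#'
#' @param k first-order rate constant (1/day).
#' @return Half-life `ln(2)/k` in days.
#' @export
#' @examples
#' half_life(0.14)  # about 5 days
half_life <- function(k) log(2) / k

#' One-way ANOVA of replicate-level rate constants across sites
#'
#' Tests whether a compound's rate constant differs between sites, using
#' the per-replicate fits. By default the response is log10 k (the scale on
#' which the variability metric lives and on which replicate noise is
#' approximately homoscedastic); `log = FALSE` runs on linear k.
#'
#' @param replicate_k data.frame with columns `site` and `k` (one row per
#'   replicate incubation).
#' @param log analyze log10-transformed rate constants (default `TRUE`).
#' @return Named list `F`, `p`, `df_between`, `df_within`; `NA`s with
#'   `status = "not_computable"` when fewer than 2 sites have 2 or more
#'   replicates or the response is degenerate.
#' @export
anova_across_sites <- function(replicate_k, log = TRUE) {
  d <- replicate_k[is.finite(replicate_k$k), , drop = FALSE]
  if (log) {
    d <- d[d$k > 0, , drop = FALSE]
    d$y <- log10(d$k)
  } else {
    d$y <- d$k
  }
  counts <- table(d$site)
  not_comp <- list(F = NA_real_, p = NA_real_, df_between = NA_integer_,
                   df_within = NA_integer_, status = "not_computable")
  if (sum(counts >= 2L) < 2L || length(counts) < 2L) return(not_comp)
  if (stats::var(d$y) == 0) {
    # no variance at all: groups indistinguishable
    return(list(F = 0, p = 1, df_between = length(counts) - 1L,
                df_within = nrow(d) - length(counts), status = "ok"))
  }
  fit <- stats::aov(y ~ factor(site), data = d)
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df_between = tab[1L, "Df"], df_within = tab[2L, "Df"],
       status = "ok")
}

#' Per-compound spatial-variability summary over site groups
#'
#' For each compound and each site group (scope), computes the standard
#' deviation of log10 of the matrix values, its fold equivalent, and the
#' across-site ANOVA on replicate-level fits; per scope it also reports the
#' median stddev across compounds and the percentage of compounds with a
#' significant site effect (p < 0.05).
#'
#' @param rm a [rate_matrix()] (typically gap-filled and corrected).
#' @param site_groups named list of site-label vectors; default is a single
#'   `all_sites` scope over every site in the matrix.
#' @param replicate_rates replicate-level table from [fit_rates()]
#'   (columns `compound`, `site`, `k_observed`); optional -- without it the
#'   ANOVA columns are `NA`.
#' @param valid_only use only cells with status `"valid"` (default `FALSE`:
#'   all finite cells, i.e. including gap-fills).
#' @return List: `by_compound` (one row per compound x scope) and
#'   `by_scope` (median stddev and percent significant per scope).
#' @export
summarize_scope <- function(rm, site_groups = NULL, replicate_rates = NULL,
                            valid_only = FALSE) {
  stopifnot(inherits(rm, "rate_matrix"))
  if (is.null(site_groups)) site_groups <- list(all_sites = rm$sites)
  rows <- list()
  for (scope in names(site_groups)) {
    sites <- intersect(site_groups[[scope]], rm$sites)
    if (length(sites) < 2L) {
      message("scope '", scope, "' has fewer than 2 sites; skipped")
      next
    }
    cols <- match(sites, rm$sites)
    for (ci in seq_along(rm$compounds)) {
      vals <- rm$values[ci, cols]
      st <- rm$status[ci, cols]
      use <- is.finite(vals) & vals > 0 &
        (if (valid_only) st == "valid" else st != "not_available")
      sl <- if (sum(use) >= 2L) stddev_log(vals[use]) else
        list(stddev_log10 = NA_real_, fold = NA_real_)
      an <- list(F = NA_real_, p = NA_real_)
      if (!is.null(replicate_rates)) {
        rr <- replicate_rates[
          replicate_rates$compound == rm$compounds[ci] &
            replicate_rates$site %in% sites, , drop = FALSE]
        if (nrow(rr)) {
          an <- anova_across_sites(
            data.frame(site = rr$site, k = rr$k_observed)
          )
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        compound = rm$compounds[ci], scope = scope,
        stddev_log10 = sl$stddev_log10, fold = sl$fold,
        n_sites_used = sum(use), anova_F = an$F, anova_p = an$p,
        significant = is.finite(an$p) && an$p < 0.05,
        stringsAsFactors = FALSE
      )
    }
  }
  by_compound <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  by_scope <- do.call(rbind, lapply(split(by_compound, by_compound$scope),
    function(d) {
      data.frame(
        scope = d$scope[1L],
        median_stddev_log10 = stats::median(d$stddev_log10, na.rm = TRUE),
        median_fold = 10^stats::median(d$stddev_log10, na.rm = TRUE),
        pct_significant = 100 * mean(d$significant[is.finite(d$anova_p)]),
        n_compounds = nrow(d), stringsAsFactors = FALSE
      )
    }))
  rownames(by_scope) <- NULL
  list(by_compound = by_compound, by_scope = by_scope)
}

#' Correlate per-site median rate constants with an environmental variable
#'
#' Pearson correlation between the per-site median (across compounds) of
#' the matrix values and an environmental covariate, by default on the
#' median k vs log10 of the variable (the scale used for TOC).
#'
#' @param rm a [rate_matrix()].
#' @param env environment table with `site_id` and the variable column.
#' @param variable column name in `env` (default `"toc"`).
#' @param log_variable log10-transform the covariate (default `TRUE`).
#' @param log_values use log10 of the per-site medians (default `FALSE`).
#' @return Named list `r`, `p`, `n`; `status = "not_computable"` when the
#'   covariate is constant.
#' @export
correlate_with_env <- function(rm, env, variable = "toc",
                               log_variable = TRUE, log_values = FALSE) {
  stopifnot(inherits(rm, "rate_matrix"), variable %in% names(env))
  med <- apply(rm$values, 2, function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v)) stats::median(v) else NA_real_
  })
  x <- env[[variable]][match(rm$sites, env$site_id)]
  if (log_variable) x <- log10(x)
  y <- if (log_values) log10(med) else med
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                status = "not_computable"))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), status = "ok")
}
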
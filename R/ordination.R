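#' Build the standardized predictor matrix for ordination
#'
#' Applies the transformations used for the environmental factors before
#' redundancy analysis: concentration-like variables (TOC, TCC, EC, DO,
#' clay, sand) are log10-transformed, temperature enters as 1/T in Kelvin
#' (an Arrhenius-consistent distance scale), pH and the geographic
#' coordinates enter untransformed, and silt is dropped because the
#' particle-size fractions close to 100% make it collinear with clay and
#' sand. All columns are then centered and scaled to unit variance,
#' yielding 10 predictors.
#'
#' @param env environment table from [simulate_site_env()] (columns
#'   `longitude`, `latitude`, `ph`, `temperature_k`, `do`, `ec`, `toc`,
#'   `tcc`, `clay`, `sand`, `silt`).
#' @return data.frame of 10 standardized predictors, rownames = site ids.
#' @export
prepare_predictors <- function(env) {
  logged <- c("tcc", "toc", "ec", "do", "clay", "sand")
  for (v in logged) {
    if (any(env[[v]] <= 0)) {
      stop("non-positive value in log-transformed variable '", v, "'")
    }
  }
  out <- data.frame(
    longitude = env$longitude,
    latitude = env$latitude,
    tcc = log10(env$tcc),
    toc = log10(env$toc),
    ec = log10(env$ec),
    do = log10(env$do),
    ph = env$ph,
    inv_t = 1 / env$temperature_k,
    clay = log10(env$clay),
    sand = log10(env$sand),
    row.names = env$site_id
  )
  as.data.frame(scale(out))
}

# Ezekiel small-sample adjustment of R^2.
adjust_r2 <- function(r2, n, m) {
  if (n - m - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Redundancy analysis of the rate matrix on environmental predictors
#'
#' Constrained ordination: the site x compound response matrix (log10
#' rate constants, sites as observations) is regressed on the standardized
#' predictors; the principal axes of the fitted values are the constrained
#' axes. Reports the total and Ezekiel-adjusted ("unbiased") fraction of
#' variance explained, per-axis shares, a global permutation test
#' (unrestricted permutation of sites, pseudo-F, `(b+1)/(B+1)` p-value),
#' and per-variable envfit statistics on the first `axes` constrained axes.
#'
#' @param response numeric matrix, sites in rows (rownames = site ids),
#'   compounds in columns; no missing cells.
#' @param predictors standardized predictor data.frame from
#'   [prepare_predictors()], same row order as `response`.
#' @param permutations number of permutations for the global test and
#'   envfit (default 999).
#' @param axes number of constrained axes used for envfit (default 2).
#' @param seed optional integer seed for the permutation draws.
#' @return Object of class `rda_result`: `r2_total`, `r2_adjusted`,
#'   `axis_shares`, `pseudo_F`, `p_model`, `per_variable`, `site_scores`,
#'   `compound_scores`, `biplot_arrows`, plus the underlying vegan model
#'   (`model`).
#' @export
run_rda <- function(response, predictors, permutations = 999, axes = 2,
                    seed = NULL) {
  response <- as.matrix(response)
  stopifnot(nrow(response) == nrow(predictors))
  if (anyNA(response)) stop("response matrix must not contain missing cells")
  if (!is.null(seed)) set.seed(seed)
  if (nrow(response) < ncol(predictors) + 2) {
    message("fewer sites than predictors + 2: fit is rank-deficient")
  }
  mod <- vegan::rda(response ~ ., data = predictors)
  r2 <- vegan::RsquareAdj(mod)
  shares <- mod$CCA$eig / mod$tot.chi
  if (1 - r2$r.squared < 1e-12) {
    # exact fit: no residual to form F against; the observed statistic beats
    # every permutation, so p sits at the (b+1)/(B+1) floor
    an <- data.frame(F = Inf, check.names = FALSE)
    an[["Pr(>F)"]] <- 1 / (permutations + 1)
  } else {
    an <- vegan::anova.cca(mod, permutations = permutations)
  }
  n_axes <- min(axes, length(shares))
  site_scores <- vegan::scores(mod, display = "sites", choices = seq_len(n_axes))
  per_var <- envfit_variables(site_scores, predictors, n_perm = permutations)
  structure(
    list(
      r2_total = r2$r.squared,
      r2_adjusted = r2$adj.r.squared,
      axis_shares = shares,
      pseudo_F = an$F[1L],
      p_model = an[["Pr(>F)"]][1L],
      per_variable = per_var,
      site_scores = site_scores,
      compound_scores = vegan::scores(mod, display = "species",
                                      choices = seq_len(n_axes)),
      biplot_arrows = vegan::scores(mod, display = "bp",
                                    choices = seq_len(n_axes)),
      model = mod
    ),
    class = "rda_result"
  )
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.3f (adjusted %.3f), pseudo-F = %.2f, p = %.4g\n",
              x$r2_total, x$r2_adjusted, x$pseudo_F, x$p_model))
  cat("axis shares:", paste(sprintf("%.3f", x$axis_shares[seq_len(min(4,
      length(x$axis_shares)))]), collapse = ", "), "\n")
  invisible(x)
}

#' Per-variable fit onto ordination axes
#'
#' Fits each environmental variable as a vector onto the given ordination
#' scores (envfit): the squared correlation of the variable with its
#' projection on the score plane, an Ezekiel-adjusted version of it, and a
#' permutation p-value obtained by permuting the variable across sites.
#'
#' @param scores matrix of site scores (sites x axes).
#' @param predictors data.frame of numeric variables, same row order.
#' @param n_perm permutations (default 999).
#' @return data.frame: `name`, `r2_envfit`, `r2_envfit_adjusted`,
#'   `p_envfit`.
#' @export
envfit_variables <- function(scores, predictors, n_perm = 999) {
  ef <- vegan::envfit(scores, predictors, permutations = n_perm)
  r2 <- ef$vectors$r
  n <- nrow(scores)
  m <- ncol(scores)
  data.frame(
    name = names(r2),
    r2_envfit = unname(r2),
    r2_envfit_adjusted = vapply(r2, adjust_r2, numeric(1), n = n, m = m),
    p_envfit = unname(ef$vectors$pvals),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Response matrix for ordination
#'
#' Transposes a (fully densified) rate matrix into the sites x compounds
#' log10 response used by [run_rda()].
#'
#' @param rm a [rate_matrix()] with no remaining `not_available` cells
#'   among the selected compounds.
#' @param compounds optional compound subset.
#' @return numeric matrix, sites in rows, log10 values.
#' @export
ordination_response <- function(rm, compounds = NULL) {
  stopifnot(inherits(rm, "rate_matrix"))
  if (!is.null(compounds)) rm <- subset_compounds(rm, compounds)
  if (anyNA(rm$values)) {
    stop("rate matrix still has empty cells; densify with the gap-filling ",
         "rules first")
  }
  t(log10(rm$values))
}
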
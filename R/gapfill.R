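#' Compounds x sites rate matrix
#'
#' Reshapes a long rate-estimate table into the matrix form used by the
#' gap-filling chain and the spatial summaries: one value matrix, one
#' status matrix and the 99% confidence bounds of each estimate. Initial
#' statuses are `"valid"`, `"invalid"` (an estimate exists but failed the
#' validity rules and still carries its CI) or `"not_available"` (no data
#' above the LOQ, or too few uncensored points to regress).
#'
#' @param rates pooled rate table from [fit_rates()] (or any table with
#'   `compound`, `site`, `country`, `k_observed`, `ci99_lo`, `ci99_hi`,
#'   `valid`, `status`), filtered to one row per compound x site.
#' @param value_col column holding the cell value (default `"k_observed"`).
#' @return Object of class `rate_matrix`: list with matrices `values`,
#'   `status`, `ci99_lo`, `ci99_hi` (compounds in rows, sites in columns)
#'   and the `countries` vector named by site.
#' @export
rate_matrix <- function(rates, value_col = "k_observed") {
  if ("scope" %in% names(rates)) {
    rates <- rates[rates$scope == "pooled", , drop = FALSE]
  }
  compounds <- sort(unique(rates$compound))
  sites <- sort(unique(rates$site))
  shape <- function(init) {
    matrix(init, nrow = length(compounds), ncol = length(sites),
           dimnames = list(compounds, sites))
  }
  values <- shape(NA_real_)
  status <- shape("not_available")
  lo <- shape(NA_real_)
  hi <- shape(NA_real_)
  for (i in seq_len(nrow(rates))) {
    r <- rates[i, ]
    cell <- cbind(match(r$compound, compounds), match(r$site, sites))
    if (identical(r$status, "not_available")) next
    values[cell] <- r[[value_col]]
    status[cell] <- if (isTRUE(r$valid)) "valid" else "invalid"
    lo[cell] <- r$ci99_lo
    hi[cell] <- r$ci99_hi
  }
  countries <- stats::setNames(
    rates$country[match(sites, rates$site)], sites
  )
  structure(
    list(values = values, status = status, ci99_lo = lo, ci99_hi = hi,
         compounds = compounds, sites = sites, countries = countries),
    class = "rate_matrix"
  )
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Rate matrix:", length(x$compounds), "compounds x",
      length(x$sites), "sites\n")
  print(table(x$status))
  invisible(x)
}

#' Gap-fill invalid rate estimates with the confidence-interval chain
#'
#' Replaces every invalid estimate by walking a three-step decision chain
#' anchored on its own 99% confidence interval, so that the substituted
#' value is consistent with what the (noisy, non-significant) regression
#' allowed: (1) if the CI contains the median valid value for the same
#' compound at the other sites, fill with that median; (2) else if the CI
#' contains the minimum of those valid values, fill with that minimum;
#' (3) else fill with the minimum valid value over all compounds and sites.
#' CI containment is closed (a boundary hit counts). Cells with no estimate
#' at all (`"not_available"`) are left untouched; valid cells are never
#' modified; the chain is idempotent.
#'
#' @param rm a [rate_matrix()].
#' @return The matrix with invalid cells filled and statuses set to
#'   `"gapfilled_median"`, `"gapfilled_min_compound"` or
#'   `"gapfilled_global_min"`.
#' @export
gap_fill_chain <- function(rm) {
  stopifnot(inherits(rm, "rate_matrix"))
  valid_mask <- rm$status == "valid"
  if (!any(valid_mask)) stop("gap-filling requires at least one valid cell")
  global_min <- min(rm$values[valid_mask])
  contains <- function(lo, hi, x) {
    is.finite(lo) && is.finite(hi) && lo <= x && x <= hi
  }
  for (ci in seq_along(rm$compounds)) {
    for (si in seq_along(rm$sites)) {
      if (rm$status[ci, si] != "invalid") next
      peers <- rm$values[ci, valid_mask[ci, ] & seq_along(rm$sites) != si]
      lo <- rm$ci99_lo[ci, si]; hi <- rm$ci99_hi[ci, si]
      if (length(peers) > 0 && contains(lo, hi, stats::median(peers))) {
        rm$values[ci, si] <- stats::median(peers)
        rm$status[ci, si] <- "gapfilled_median"
      } else if (length(peers) > 0 && contains(lo, hi, min(peers))) {
        rm$values[ci, si] <- min(peers)
        rm$status[ci, si] <- "gapfilled_min_compound"
      } else {
        rm$values[ci, si] <- global_min
        rm$status[ci, si] <- "gapfilled_global_min"
      }
    }
  }
  rm
}

#' Fill not-available cells with within-country medians
#'
#' Densification rule used before ordination (which accepts no data gaps):
#' a `"not_available"` cell is filled with the median of the compound's
#' available values (valid or gap-filled) within the same country, but only
#' when the within-country standard deviation of their log10 values is
#' below `stddev_threshold` -- i.e. only where the country's sites agree
#' well enough for the median to be a defensible stand-in.
#'
#' @param rm a [rate_matrix()].
#' @param stddev_threshold log10-units threshold (default 0.4).
#' @return The matrix with qualifying cells filled
#'   (`"gapfilled_country_median"`).
#' @export
country_median_fill <- function(rm, stddev_threshold = 0.4) {
  stopifnot(inherits(rm, "rate_matrix"))
  filled <- c("valid", "gapfilled_median", "gapfilled_min_compound",
              "gapfilled_global_min")
  for (ci in seq_along(rm$compounds)) {
    for (si in seq_along(rm$sites)) {
      if (rm$status[ci, si] != "not_available") next
      same_country <- rm$countries == rm$countries[si]
      avail <- rm$status[ci, ] %in% filled & same_country
      vals <- rm$values[ci, avail]
      vals <- vals[is.finite(vals) & vals > 0]
      if (length(vals) < 2L) next
      if (stats::sd(log10(vals)) < stddev_threshold) {
        rm$values[ci, si] <- stats::median(vals)
        rm$status[ci, si] <- "gapfilled_country_median"
      }
    }
  }
  rm
}

#' Compound inclusion criterion
#'
#' Keeps the compounds whose estimates are trustworthy enough for spatial
#' comparison: at least `min_valid` valid (not gap-filled) cells, i.e.
#' gap-filling for less than one-third of the sites at the default 12 of
#' 18.
#'
#' @param rm a [rate_matrix()].
#' @param min_valid minimum number of valid cells per compound (default 12).
#' @return Character vector of retained compound labels.
#' @export
apply_inclusion_criterion <- function(rm, min_valid = 12L) {
  stopifnot(inherits(rm, "rate_matrix"))
  n_valid <- rowSums(rm$status == "valid")
  rm$compounds[n_valid >= min_valid]
}

#' Subset a rate matrix by compound
#'
#' @param rm a [rate_matrix()].
#' @param compounds compound labels to keep.
#' @return The subsetted `rate_matrix`.
#' @export
subset_compounds <- function(rm, compounds) {
  keep <- rm$compounds %in% compounds
  rm$values <- rm$values[keep, , drop = FALSE]
  rm$status <- rm$status[keep, , drop = FALSE]
  rm$ci99_lo <- rm$ci99_lo[keep, , drop = FALSE]
  rm$ci99_hi <- rm$ci99_hi[keep, , drop = FALSE]
  rm$compounds <- rm$compounds[keep]
  rm
}

#' Apply sorption and speciation corrections to a (gap-filled) rate matrix
#'
#' The gap-filling chain operates on observed rate constants; corrected
#' values inherit the fills by applying the sorption (dissolved-fraction)
#' and reference-pH corrections cell-wise to the filled matrix. Cells whose
#' dissolved fraction is not estimable keep `k = k_observed` for that step.
#'
#' @param rm a [rate_matrix()] of observed rate constants.
#' @param f_dis_table per-cell dissolved fractions (`site`, `compound`,
#'   `f_dis`).
#' @param properties compound-property table ([compound_properties()]).
#' @param env environment table with `site_id` and `ph`.
#' @param ref_ph reference pH (default 7).
#' @param target `"k"` (sorption-corrected) or `"k_ph7"` (additionally
#'   pH-normalized; default).
#' @return A `rate_matrix` of corrected values with unchanged statuses.
#' @export
correct_rate_matrix <- function(rm, f_dis_table, properties, env,
                                ref_ph = 7, target = c("k_ph7", "k")) {
  target <- match.arg(target)
  key <- function(s, c) paste(s, c, sep = "\r")
  fd <- stats::setNames(f_dis_table$f_dis,
                        key(f_dis_table$site, f_dis_table$compound))
  ph_by_site <- stats::setNames(env$ph, env$site_id)
  for (ci in seq_along(rm$compounds)) {
    sp <- pka_spec_from_row(
      properties[properties$compound == rm$compounds[ci], , drop = FALSE]
    )
    f_n_ref <- neutral_fraction(sp, ref_ph)
    for (si in seq_along(rm$sites)) {
      v <- rm$values[ci, si]
      if (!is.finite(v)) next
      f <- fd[key(rm$sites[si], rm$compounds[ci])]
      if (is.finite(f) && f > 0) v <- v / f
      if (target == "k_ph7") {
        f_n_site <- neutral_fraction(sp, ph_by_site[[rm$sites[si]]])
        v <- v * f_n_ref / f_n_site
      }
      rm$values[ci, si] <- v
    }
  }
  rm
}
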
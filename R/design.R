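#' Incubation study design
#'
#' Describes one batch of water-sediment incubation experiments following the
#' modified OECD 309 layout: test vessels (TEST, live sediment suspension),
#' azide-sterilized sorption controls (SC, with sediment) and an
#' azide-sterilized sediment-free hydrolysis control (HC). The default
#' sampling schedule is 0, 2, 5, 9, 18 hours and 1, 2, 4, 7, 10 days, stored
#' in days.
#'
#' @param sampling_times numeric vector of sampling times in days, strictly
#'   increasing and starting at 0.
#' @param n_test_reps number of TEST replicates (default 3).
#' @param n_sc_reps number of sorption-control replicates (default 2).
#' @param n_hydrolysis_reps number of hydrolysis-control replicates (default 1).
#' @param spike_concentration nominal spike level in ug/L (default 1). Carried
#'   as metadata; peak areas are expressed relative to `area_t0`.
#' @param area_t0 expected chromatographic peak area at t = 0 for a fully
#'   dissolved compound at the spike concentration (arbitrary area units).
#' @param loq limit of quantification in the same area units. Points below the
#'   LOQ are flagged censored by the generator and excluded from fitting.
#' @param duplicate_subsamples if `TRUE`, two analytical subsamples are drawn
#'   per vessel and time point (independent measurement noise).
#' @param seed integer seed used by [generate_experiment()] when none is
#'   passed explicitly.
#'
#' @return An object of class `study_design` (a list of the above fields).
#' @export
#' @examples
#' d <- study_design()
#' d$sampling_times
study_design <- function(sampling_times = c(c(0, 2, 5, 9, 18) / 24,
                                            1, 2, 4, 7, 10),
                         n_test_reps = 3L,
                         n_sc_reps = 2L,
                         n_hydrolysis_reps = 1L,
                         spike_concentration = 1,
                         area_t0 = 1e6,
                         loq = 1e3,
                         duplicate_subsamples = FALSE,
                         seed = 1L) {
  sampling_times <- as.numeric(sampling_times)
  if (length(sampling_times) < 2L || any(diff(sampling_times) <= 0)) {
    stop("sampling_times must be strictly increasing")
  }
  if (sampling_times[1L] != 0) {
    stop("sampling_times must start at 0")
  }
  if (n_test_reps < 1L) stop("at least one TEST replicate is required")
  if (loq <= 0) stop("loq must be positive")
  if (area_t0 <= 0) stop("area_t0 must be positive")
  structure(
    list(
      sampling_times = sampling_times,
      n_test_reps = as.integer(n_test_reps),
      n_sc_reps = as.integer(n_sc_reps),
      n_hydrolysis_reps = as.integer(n_hydrolysis_reps),
      spike_concentration = spike_concentration,
      area_t0 = area_t0,
      loq = loq,
      duplicate_subsamples = isTRUE(duplicate_subsamples),
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Incubation study design\n")
  cat("  sampling times (d):", paste(signif(x$sampling_times, 4), collapse = ", "), "\n")
  cat("  replicates: TEST =", x$n_test_reps, "| SC =", x$n_sc_reps,
      "| HC =", x$n_hydrolysis_reps, "\n")
  cat("  spike:", x$spike_concentration, "ug/L; area(t=0) =", x$area_t0,
      "; LOQ =", x$loq, "\n")
  invisible(x)
}
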
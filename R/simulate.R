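#' Generate a synthetic incubation experiment
#'
#' Renders peak-area time series for every compound x site combination under
#' the study design: `n_test_reps` TEST vessels (live sediment suspension),
#' `n_sc_reps` sorption controls (sterilized, with sediment) and
#' `n_hydrolysis_reps` hydrolysis controls (sterilized, sediment-free).
#'
#' The dissolved-phase area signals are
#' \deqn{TEST: A_0 f_{Dis} e^{-(k_{site}+k_{abiotic})t}, \quad
#'       SC: A_0 f_{Dis} e^{-k_{abiotic}t}, \quad
#'       HC: A_0 e^{-k_{abiotic}t},}
#' each multiplied by mean-preserving lognormal measurement noise with the
#' compound's relative standard deviation. Biphasic compounds decay piecewise
#' with a continuous transition at the break time. The per-site rate constant
#' combines the compound mean, the site model's TOC component and residual
#' site noise, and (for ionizable compounds, when `apply_speciation = TRUE`)
#' scales with the neutral fraction at the site pH relative to the reference
#' pH, so that rate constants normalized back to the reference pH recover the
#' compound's intrinsic value. Areas below the design LOQ are kept but
#' flagged censored; exclusion is owned by the fitting step.
#'
#' @param design a [study_design()].
#' @param compounds list of [true_compound()] objects.
#' @param sites a [site_model()].
#' @param seed integer seed; identical seeds give identical output tables.
#' @param apply_speciation logical; make the realized biodegradation rate
#'   proportional to the neutral fraction at the site pH (default `TRUE`).
#' @param ref_ph reference pH anchoring compound means (default 7).
#'
#' @return List with elements
#'   \describe{
#'     \item{areas}{long table: `site`, `country`, `compound`, `vessel_type`
#'       (TEST/SC/HC), `replicate`, `time_days`, `area`, `censored`.}
#'     \item{truth_cells}{per compound x site truth: realized `k_true`
#'       (initial-phase biodegradation rate at site pH), `k_late`,
#'       `break_time`, `k_ph7_true`, `f_dis_true`, `abiotic_rate`,
#'       `f_n_site`.}
#'     \item{truth_sites}{the environment table with model parameters.}
#'     \item{design}{the design used.}
#'   }
#' @export
generate_experiment <- function(design, compounds, sites, seed = design$seed,
                                apply_speciation = TRUE, ref_ph = 7) {
  stopifnot(inherits(design, "study_design"), inherits(sites, "site_model"))
  if (length(compounds) < 1L) stop("need at least one compound")
  if (inherits(compounds, "true_compound")) compounds <- list(compounds)
  env <- sites$env
  set.seed(as.integer(seed))
  tt <- design$sampling_times
  nsub <- if (design$duplicate_subsamples) 2L else 1L

  areas <- vector("list", length(compounds) * nrow(env))
  truth <- vector("list", length(compounds) * nrow(env))
  idx <- 0L

  for (si in seq_len(nrow(env))) {
    site <- env$site_id[si]
    for (cp in compounds) {
      idx <- idx + 1L
      # per-site deviation on log10 k: TOC component + residual site noise
      dev <- sites$toc_slope * sites$toc_centered[si] +
        stats::rnorm(1, 0, sites$sigma_resid)
      f_n_site <- if (apply_speciation && !is.null(cp$pka_spec)) {
        neutral_fraction(cp$pka_spec, env$ph[si])
      } else 1
      f_n_ref <- if (apply_speciation && !is.null(cp$pka_spec)) {
        neutral_fraction(cp$pka_spec, ref_ph)
      } else 1
      spec_factor <- f_n_site / f_n_ref

      if (is.null(cp$biphasic)) {
        k_ph7 <- 10^(cp$log10_k_mean + dev)
        k_init <- k_ph7 * spec_factor
        k_late <- k_init
        brk <- NA_real_
      } else {
        site_factor <- 10^dev
        k_init <- cp$biphasic$k_initial * site_factor * spec_factor
        k_late <- cp$biphasic$k_late * site_factor * spec_factor
        brk <- cp$biphasic$break_time
        k_ph7 <- k_init / spec_factor
      }
      if (any(c(k_init, k_late, cp$abiotic_rate) < 0)) {
        stop(sprintf("negative rate for compound %s at site %s", cp$id, site))
      }

      bio_decay <- if (is.na(brk)) {
        exp(-k_init * tt)
      } else {
        ifelse(tt <= brk, exp(-k_init * tt),
               exp(-k_init * brk - k_late * (tt - brk)))
      }
      abio_decay <- exp(-cp$abiotic_rate * tt)
      sdlog <- sqrt(log(1 + cp$noise_rsd^2))

      emit <- function(vessel, rep_id, mu) {
        n <- length(mu) * nsub
        noise <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
        a <- rep(mu, each = nsub) * noise
        data.frame(
          site = site, country = env$country[si], compound = cp$id,
          vessel_type = vessel, replicate = rep_id,
          time_days = rep(tt, each = nsub), area = a,
          censored = a < design$loq, stringsAsFactors = FALSE
        )
      }

      ser <- list()
      for (r in seq_len(design$n_test_reps)) {
        mu <- design$area_t0 * cp$f_dis_true * bio_decay * abio_decay
        ser[[length(ser) + 1L]] <- emit("TEST", paste0("TEST", r), mu)
      }
      for (r in seq_len(design$n_sc_reps)) {
        mu <- design$area_t0 * cp$f_dis_true * abio_decay
        ser[[length(ser) + 1L]] <- emit("SC", paste0("SC", r), mu)
      }
      for (r in seq_len(design$n_hydrolysis_reps)) {
        mu <- design$area_t0 * abio_decay
        ser[[length(ser) + 1L]] <- emit("HC", paste0("HC", r), mu)
      }
      areas[[idx]] <- do.call(rbind, ser)

      truth[[idx]] <- data.frame(
        site = site, country = env$country[si], compound = cp$id,
        k_true = k_init, k_late_true = k_late, break_time = brk,
        k_ph7_true = k_ph7, f_dis_true = cp$f_dis_true,
        abiotic_rate = cp$abiotic_rate, f_n_site = f_n_site,
        site_dev_log10 = dev, stringsAsFactors = FALSE
      )
    }
  }

  truth_sites <- env
  truth_sites$sigma_site <- sites$sigma_site
  truth_sites$toc_slope <- sites$toc_slope

  list(
    areas = do.call(rbind, c(areas, list(make.row.names = FALSE))),
    truth_cells = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    truth_sites = truth_sites,
    design = design
  )
}
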
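#' Neutral fraction of an ionizable compound
#'
#' Henderson-Hasselbalch speciation. For a monoprotic acid the neutral
#' (protonated) fraction is \eqn{1/(1+10^{pH-pKa})}; for a monoprotic base
#' (neutral form deprotonated) it is \eqn{1/(1+10^{pKa-pH})}. Multiple
#' ionization sites are treated as independent, so the fully neutral
#' fraction is the product of the per-site neutral-form probabilities
#' (zwitterionic microstates are not resolved -- pKa values alone cannot
#' identify them). Neutral compounds return 1.
#'
#' @param pka_spec `NULL` (neutral compound) or a data.frame with columns
#'   `pka` and `type` ("acid"/"base"); a [true_compound()] is also accepted.
#' @param ph pH value(s) in `[0, 14]`; vectorized.
#' @return Neutral fraction in (0, 1], same length as `ph`.
#' @export
#' @examples
#' neutral_fraction(data.frame(pka = 4.2, type = "acid"), 7)   # weak acid
#' neutral_fraction(NULL, 8)                                   # neutral: 1
neutral_fraction <- function(pka_spec, ph) {
  if (inherits(pka_spec, "true_compound")) pka_spec <- pka_spec$pka_spec
  if (any(ph < 0 | ph > 14)) stop("ph must be within [0, 14]")
  if (is.null(pka_spec) || nrow(pka_spec) == 0L) {
    return(rep(1, length(ph)))
  }
  out <- rep(1, length(ph))
  for (i in seq_len(nrow(pka_spec))) {
    pka <- pka_spec$pka[i]
    out <- out * switch(pka_spec$type[i],
      acid = 1 / (1 + 10^(ph - pka)),
      base = 1 / (1 + 10^(pka - ph)),
      stop("ionization site type must be 'acid' or 'base'")
    )
  }
  out
}

#' Dissolved fraction from control vessels at t = 0
#'
#' The dissolved fraction f_Dis is estimated as the quotient of the mean
#' t = 0 peak area in the sorption controls (sterilized, with sediment)
#' and the hydrolysis control (sterilized, sediment-free): sorption to the
#' sediment lowers the dissolved-phase signal in the SC relative to the
#' sediment-free control. The quotient is clamped to
#' `(f_dis_floor, 1]` so that measurement noise cannot produce unphysical
#' values or an unbounded sorption correction.
#'
#' @param sc_t0_areas uncensored t = 0 peak areas from the sorption
#'   controls.
#' @param hc_t0_areas uncensored t = 0 peak areas from the hydrolysis
#'   control.
#' @param f_dis_floor lower clamp (default 0.01).
#' @return Scalar dissolved fraction, or `NA` with attribute
#'   `reason = "hc_censored"` when no hydrolysis-control area is available.
#' @export
estimate_f_dis <- function(sc_t0_areas, hc_t0_areas, f_dis_floor = 0.01) {
  sc_t0_areas <- sc_t0_areas[is.finite(sc_t0_areas)]
  hc_t0_areas <- hc_t0_areas[is.finite(hc_t0_areas)]
  if (length(hc_t0_areas) == 0L || length(sc_t0_areas) == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "hc_censored"
    return(out)
  }
  q <- mean(sc_t0_areas) / mean(hc_t0_areas)
  min(max(q, f_dis_floor), 1)
}

#' Sorption correction of the observed rate constant
#'
#' When part of the compound is sorbed, only the dissolved fraction is
#' degraded, so the observed decline of the dissolved concentration is
#' slower than it would be if the compound were fully dissolved. Dividing
#' by the dissolved fraction yields `k`, the rate constant that would
#' hypothetically be observed with all of the chemical dissolved.
#'
#' @param k_observed observed first-order rate constant (1/day).
#' @param f_dis dissolved fraction in (0, 1].
#' @return Corrected rate constant `k = k_observed / f_dis` (1/day).
#' @export
#' @examples
#' apply_eq1(0.2, 0.4)  # 0.5
apply_eq1 <- function(k_observed, f_dis) {
  if (any(f_dis <= 0, na.rm = TRUE)) stop("f_dis must be positive")
  k_observed / f_dis
}

#' Normalize a rate constant to a reference pH
#'
#' Under the assumption that the biodegradation rate is proportional to the
#' neutral fraction f_N of the compound (uptake of the neutral species
#' limits degradation), the rate constant measured at the site pH is
#' rescaled to the neutral fraction at the reference pH:
#' `k_ph7 = k * f_n_ref / f_n_site`. With site pH equal to the reference pH
#' this is the identity.
#'
#' @param k sorption-corrected rate constant (1/day).
#' @param f_n_site neutral fraction at the site pH, in (0, 1].
#' @param f_n_ref neutral fraction at the reference pH, in (0, 1].
#' @return Rate constant normalized to the reference pH (1/day).
#' @export
#' @examples
#' apply_eq2(0.5, f_n_site = 0.25, f_n_ref = 0.5)  # 1.0
apply_eq2 <- function(k, f_n_site, f_n_ref) {
  if (any(f_n_site <= 0, na.rm = TRUE)) stop("f_n_site must be positive")
  if (any(f_n_ref <= 0, na.rm = TRUE)) stop("f_n_ref must be positive")
  k * f_n_ref / f_n_site
}

#' Apply sorption and speciation corrections to a rate table
#'
#' Adds `f_dis`, `k`, `f_n_site`, `f_n_ref` and `k_ph7` columns to a rate
#' estimate table. f_Dis is taken from the supplied per-cell table (as
#' estimated from the control vessels); when it is not estimable the
#' sorption correction is skipped (`k = k_observed`) and flagged in
#' `f_dis_status`. Neutral fractions come from the compound-property table
#' and the per-site pH.
#'
#' @param rates rate table with at least `site`, `compound`, `k_observed`.
#' @param f_dis_table data.frame `site`, `compound`, `f_dis` (NA allowed).
#' @param properties compound-property table from [compound_properties()].
#' @param env environment table with `site_id` and `ph`.
#' @param ref_ph reference pH (default 7).
#' @return `rates` with appended correction columns.
#' @export
correct_rates <- function(rates, f_dis_table, properties, env, ref_ph = 7) {
  key <- function(s, c) paste(s, c, sep = "\r")
  fd <- stats::setNames(f_dis_table$f_dis,
                        key(f_dis_table$site, f_dis_table$compound))
  ph_by_site <- stats::setNames(env$ph, env$site_id)
  specs <- stats::setNames(
    lapply(seq_len(nrow(properties)), function(i) {
      pka_spec_from_row(properties[i, , drop = FALSE])
    }),
    properties$compound
  )

  n <- nrow(rates)
  rates$f_dis <- unname(fd[key(rates$site, rates$compound)])
  rates$f_dis_status <- ifelse(is.na(rates$f_dis), "not_estimable", "estimated")
  rates$k <- ifelse(is.na(rates$f_dis), rates$k_observed,
                    rates$k_observed / rates$f_dis)
  rates$site_ph <- unname(ph_by_site[rates$site])
  rates$ref_ph <- ref_ph
  f_n_site <- numeric(n)
  f_n_ref <- numeric(n)
  for (i in seq_len(n)) {
    sp <- specs[[rates$compound[i]]]
    f_n_site[i] <- neutral_fraction(sp, rates$site_ph[i])
    f_n_ref[i] <- neutral_fraction(sp, ref_ph)
  }
  rates$f_n_site <- f_n_site
  rates$f_n_ref <- f_n_ref
  rates$k_ph7 <- rates$k * rates$f_n_ref / rates$f_n_site
  rates
}
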
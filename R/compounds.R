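#' Ground-truth compound for the experiment generator
#'
#' Defines the true kinetic and physicochemical behaviour of one test
#' compound. The generator draws per-site rate constants around
#' `log10_k_mean` and renders TEST, SC and HC peak-area series from them,
#' so downstream estimates can be checked against the emitted truth table.
#'
#' @param id compound label.
#' @param log10_k_mean mean of log10 of the biodegradation rate constant
#'   (1/day) across sites, before site effects.
#' @param f_dis_true true fraction of the compound in the dissolved phase in
#'   sediment-containing vessels, in (0, 1].
#' @param abiotic_rate first-order abiotic (hydrolysis) dissipation rate
#'   constant in 1/day, acting in all vessel types.
#' @param pka_spec ionization sites: a data.frame with columns `pka`
#'   (numeric) and `type` ("acid" or "base"), or `NULL` for a neutral
#'   compound.
#' @param biphasic `NULL` for monophasic kinetics, or a list with elements
#'   `k_initial`, `k_late` (1/day, `k_initial >= k_late >= 0`) and
#'   `break_time` (days). When biphasic, `log10_k_mean` is ignored and the
#'   site effect scales both phase rates.
#' @param noise_rsd relative standard deviation of multiplicative
#'   (lognormal) measurement noise on peak areas. Default 0.09, the typical
#'   between-sample RSD of internal-standard peak areas in this assay.
#'
#' @return An object of class `true_compound`.
#' @export
true_compound <- function(id,
                          log10_k_mean,
                          f_dis_true = 1,
                          abiotic_rate = 0,
                          pka_spec = NULL,
                          biphasic = NULL,
                          noise_rsd = 0.09) {
  if (f_dis_true <= 0 || f_dis_true > 1) {
    stop(sprintf("compound %s: f_dis_true must be in (0, 1]", id))
  }
  if (abiotic_rate < 0) {
    stop(sprintf("compound %s: abiotic_rate must be non-negative", id))
  }
  if (noise_rsd < 0) {
    stop(sprintf("compound %s: noise_rsd must be non-negative", id))
  }
  if (!is.null(biphasic)) {
    stopifnot(all(c("k_initial", "k_late", "break_time") %in% names(biphasic)))
    if (biphasic$k_late < 0 || biphasic$k_initial < biphasic$k_late) {
      stop(sprintf("compound %s: need k_initial >= k_late >= 0", id))
    }
  }
  if (!is.null(pka_spec)) {
    pka_spec <- as.data.frame(pka_spec)
    stopifnot(all(c("pka", "type") %in% names(pka_spec)))
    if (any(!is.finite(pka_spec$pka))) {
      stop(sprintf("compound %s: pKa values must be finite", id))
    }
    if (!all(pka_spec$type %in% c("acid", "base"))) {
      stop(sprintf("compound %s: site type must be 'acid' or 'base'", id))
    }
    if (nrow(pka_spec) == 0L) pka_spec <- NULL
  }
  structure(
    list(
      id = as.character(id),
      log10_k_mean = log10_k_mean,
      f_dis_true = f_dis_true,
      abiotic_rate = abiotic_rate,
      pka_spec = pka_spec,
      biphasic = biphasic,
      noise_rsd = noise_rsd
    ),
    class = "true_compound"
  )
}

#' Default synthetic compound panel
#'
#' A 12-compound panel covering the behaviours observed in river
#' biodegradation screens: rate constants spanning roughly 0.03-10 /day
#' (half-lives of hours to weeks), a mix of neutral compounds, monoprotic
#' acids and bases and one zwitterion, two sorbing bases (dissolved
#' fraction < 0.5), slow background hydrolysis for two compounds, and two
#' compounds with biphasic (fast-then-slow) dissipation.
#'
#' @param noise_rsd measurement noise RSD shared by all compounds
#'   (default 0.09).
#' @return List of [true_compound()] objects.
#' @export
default_compound_panel <- function(noise_rsd = 0.09) {
  acid <- function(pka) data.frame(pka = pka, type = "acid")
  base <- function(pka) data.frame(pka = pka, type = "base")
  list(
    true_compound("CPD01", log10_k_mean = -1.5, noise_rsd = noise_rsd),
    true_compound("CPD02", log10_k_mean = -1.0, pka_spec = acid(4.2),
                  noise_rsd = noise_rsd),
    true_compound("CPD03", log10_k_mean = -0.8, abiotic_rate = 0.02,
                  noise_rsd = noise_rsd),
    true_compound("CPD04", log10_k_mean = -0.6, pka_spec = base(9.5),
                  f_dis_true = 0.4, noise_rsd = noise_rsd),
    true_compound("CPD05", log10_k_mean = -0.4, pka_spec = acid(7.4),
                  noise_rsd = noise_rsd),
    true_compound("CPD06", log10_k_mean = -0.2, noise_rsd = noise_rsd),
    true_compound("CPD07", log10_k_mean = 0.0, pka_spec = base(7.8),
                  noise_rsd = noise_rsd),
    true_compound("CPD08", log10_k_mean = 0.2,
                  pka_spec = rbind(acid(3.0), base(9.8)),
                  noise_rsd = noise_rsd),
    true_compound("CPD09", log10_k_mean = 0.5, pka_spec = base(8.6),
                  f_dis_true = 0.3, abiotic_rate = 0.05,
                  noise_rsd = noise_rsd),
    true_compound("CPD10", log10_k_mean = 1.0, noise_rsd = noise_rsd),
    true_compound("CPD11", log10_k_mean = NA,
                  biphasic = list(k_initial = 1.0, k_late = 0.05,
                                  break_time = 2),
                  noise_rsd = noise_rsd),
    true_compound("CPD12", log10_k_mean = NA, pka_spec = acid(4.8),
                  biphasic = list(k_initial = 2.0, k_late = 0.1,
                                  break_time = 1),
                  noise_rsd = noise_rsd)
  )
}

#' Monophasic panel for parameter-recovery studies
#'
#' The [default_compound_panel()] with its two biphasic members replaced by
#' monophasic compounds of comparable magnitude. Used for recovery studies,
#' where the estimand must be well defined for every cell: when an initial
#' fast phase is statistically invisible at a site (e.g. a strongly
#' speciated biphasic acid at low pH), the blended single-slope fit has no
#' unambiguous true value to recover, which is a property of break
#' detection (assessed separately), not of the regression machinery.
#'
#' @inheritParams default_compound_panel
#' @return List of [true_compound()] objects, all monophasic.
#' @export
monophasic_compound_panel <- function(noise_rsd = 0.09) {
  panel <- default_compound_panel(noise_rsd = noise_rsd)
  panel[[11]] <- true_compound("CPD11", log10_k_mean = 0.0,
                               noise_rsd = noise_rsd)
  panel[[12]] <- true_compound("CPD12", log10_k_mean = 0.3,
                               pka_spec = data.frame(pka = 4.8,
                                                     type = "acid"),
                               noise_rsd = noise_rsd)
  panel
}

#' Compound-property table for speciation corrections
#'
#' Flattens a list of [true_compound()] objects (or builds from scratch)
#' into the wide compound-property layout used on disk: one row per
#' compound with columns `pka1..pkaN` and `type1..typeN`.
#'
#' @param compounds list of `true_compound` objects.
#' @return data.frame with columns `compound`, `pka1..`, `type1..`.
#' @export
compound_properties <- function(compounds) {
  nmax <- max(c(1L, vapply(compounds, function(cp) {
    if (is.null(cp$pka_spec)) 0L else nrow(cp$pka_spec)
  }, integer(1))))
  rows <- lapply(compounds, function(cp) {
    row <- list(compound = cp$id)
    for (i in seq_len(nmax)) {
      has <- !is.null(cp$pka_spec) && nrow(cp$pka_spec) >= i
      row[[paste0("pka", i)]] <- if (has) cp$pka_spec$pka[i] else NA_real_
      row[[paste0("type", i)]] <- if (has) cp$pka_spec$type[i] else NA_character_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Inverse of compound_properties(): wide row -> pka_spec data.frame or NULL.
pka_spec_from_row <- function(row) {
  pk_cols <- grep("^pka[0-9]+$", names(row), value = TRUE)
  pkas <- unlist(row[pk_cols], use.names = FALSE)
  types <- unlist(row[sub("pka", "type", pk_cols)], use.names = FALSE)
  keep <- !is.na(pkas)
  if (!any(keep)) return(NULL)
  data.frame(pka = as.numeric(pkas[keep]), type = as.character(types[keep]),
             stringsAsFactors = FALSE)
}
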
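#' Logarithmic partition (or distribution) coefficient
#'
#' log10 of the ratio of organic- to aqueous-phase molar concentrations.
#' Applied to neutral-species concentrations this is log P; applied to total
#' (neutral + charged) concentrations it is log D. The same contract serves
#' both because routine concentration analytics cannot distinguish charged
#' from neutral species; the species-resolved version lives only inside the
#' forward simulator.
#'
#' @param c_org,c_aq Molar concentrations (mol/L) in the organic and aqueous
#'   phase; both strictly positive. Vectorized.
#' @return log10(c_org / c_aq).
#' @examples
#' log_partition(100, 1)  # 2
#' @export
log_partition <- function(c_org, c_aq) {
  if (any(!is.finite(c_org)) || any(!is.finite(c_aq)) ||
      any(c_org <= 0) || any(c_aq <= 0)) {
    stop("phase concentrations must be finite and > 0", call. = FALSE)
  }
  log10(c_org / c_aq)
}

#' Mole fraction from molar concentration (dilute regime)
#'
#' x = v_n * c, using the molar volume v_n (L/mol) of the phase. This linear
#' conversion is a dilute-solution approximation: a warning is issued above
#' x = 0.1 and values above 1 are rejected as outside the formula's validity.
#'
#' @param molar_volume Molar volume of the phase, L/mol, > 0.
#' @param c Molar concentration, mol/L, >= 0.
#' @return Mole fraction (dimensionless).
#' @export
mole_fraction_from_conc <- function(molar_volume, c) {
  stopifnot(is.numeric(molar_volume), is.numeric(c))
  if (any(!is.finite(molar_volume)) || any(molar_volume <= 0)) {
    stop("molar_volume must be > 0", call. = FALSE)
  }
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  x <- molar_volume * c
  if (any(x > 1)) {
    stop("mole fraction > 1: dilute-regime conversion not applicable",
         call. = FALSE)
  }
  if (any(x > 0.1)) {
    warning("mole fraction above 0.1; dilute-regime conversion is approximate",
            call. = FALSE)
  }
  x
}

#' Convert log D to log P (and back) via the ionization correction
#'
#' For an acid, P = D * (1 + 10^(pH - pKa)); for a base (conjugate-acid pKa),
#' P = D * (1 + 10^(pKa - pH)). On the log scale the correction is additive
#' and non-negative, so log P >= log D always: log P is the upper limit of
#' log D. The relation assumes dilute species concentrations with the
#' charged species confined to the aqueous phase. For a neutral solute the
#' conversion is the identity (log D = log P) and a warning is issued.
#'
#' @param logD Measured log distribution coefficient. Vectorized with `pH`.
#' @param pH Aqueous-phase pH at which `logD` was measured, in (0, 14).
#' @param solute A [solute].
#' @return log P (for `logp_from_logd`) or log D (for `logd_from_logp`).
#' @examples
#' nap <- solute("naproxen", "acid", 4.18)
#' logp_from_logd(0.33, 7.4, nap)  # 3.5503
#' @export
logp_from_logd <- function(logD, pH, solute) {
  stopifnot(inherits(solute, "solute"))
  if (!is_ionizable(solute)) {
    warning("neutral solute: log D and log P coincide", call. = FALSE)
    return(logD)
  }
  logD + ionization_correction(pH, solute)
}

#' @rdname logp_from_logd
#' @param logP log partition coefficient of the neutral species.
#' @export
logd_from_logp <- function(logP, pH, solute) {
  stopifnot(inherits(solute, "solute"))
  if (!is_ionizable(solute)) {
    warning("neutral solute: log D and log P coincide", call. = FALSE)
    return(logP)
  }
  logP - ionization_correction(pH, solute)
}

# log10(1 + 10^(pH - pKa)) for acids, log10(1 + 10^(pKa - pH)) for bases;
# computed via log1p for accuracy in both tails
ionization_correction <- function(pH, solute) {
  stopifnot(is.numeric(pH), all(is.finite(pH)))
  if (any(pH <= 0) || any(pH >= 14)) {
    stop("pH must lie in (0, 14)", call. = FALSE)
  }
  expo <- switch(solute$ionization_class,
                 acid = pH - solute$pKa,
                 base = solute$pKa - pH)
  log1p(10^expo) / log(10)
}

#' Solubility-ratio pseudo-partition coefficient (diagnostic only)
#'
#' log10 of the ratio of a solute's solubility in pure octanol to its
#' solubility in pure water. This quantity is sometimes used as a proxy for
#' lipophilicity but refers to solid-liquid equilibria in the two binary
#' systems, not to the ternary liquid-liquid system at zero solute
#' concentration, and must never be reported as K_OW; it is labelled as
#' diagnostic in all outputs.
#'
#' @param c_sle_org,c_sle_aq Saturation solubilities (mol/L), > 0.
#' @return log P^SLE (dimensionless), with attribute `diagnostic_only = TRUE`.
#' @export
logp_sle <- function(c_sle_org, c_sle_aq) {
  if (any(!is.finite(c_sle_org)) || any(!is.finite(c_sle_aq)) ||
      any(c_sle_org <= 0) || any(c_sle_aq <= 0)) {
    stop("solubilities must be finite and > 0", call. = FALSE)
  }
  structure(log10(c_sle_org / c_sle_aq), diagnostic_only = TRUE)
}

#' Phase thermodynamics at infinite dilution
#'
#' Container for the molar volumes of the two saturated phases and the
#' infinite-dilution activity coefficients of the neutral species, the
#' charged species, and hydronium, in each phase. The molar volumes refer to
#' the water-saturated octanol phase and the octanol-saturated water phase;
#' pure-solvent molar volumes are an approximation the caller may choose.
#'
#' @param molar_volume_aq,molar_volume_org Phase molar volumes, L/mol, > 0.
#' @param gamma_inf_neutral_aq,gamma_inf_neutral_org Infinite-dilution
#'   activity coefficients of the neutral solute species, > 0.
#' @param gamma_inf_charged_aq,gamma_inf_charged_org Same for the charged
#'   solute species.
#' @param gamma_inf_hydronium_aq,gamma_inf_hydronium_org Same for hydronium.
#' @return An object of class `phase_thermo`.
#' @export
phase_thermo <- function(molar_volume_aq, molar_volume_org,
                         gamma_inf_neutral_aq = 1, gamma_inf_neutral_org = 1,
                         gamma_inf_charged_aq = 1, gamma_inf_charged_org = 1,
                         gamma_inf_hydronium_aq = 1,
                         gamma_inf_hydronium_org = 1) {
  v <- c(molar_volume_aq, molar_volume_org, gamma_inf_neutral_aq,
         gamma_inf_neutral_org, gamma_inf_charged_aq, gamma_inf_charged_org,
         gamma_inf_hydronium_aq, gamma_inf_hydronium_org)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("molar volumes and activity coefficients must be finite and > 0",
         call. = FALSE)
  }
  structure(list(molar_volume_aq = molar_volume_aq,
                 molar_volume_org = molar_volume_org,
                 gamma_inf_neutral_aq = gamma_inf_neutral_aq,
                 gamma_inf_neutral_org = gamma_inf_neutral_org,
                 gamma_inf_charged_aq = gamma_inf_charged_aq,
                 gamma_inf_charged_org = gamma_inf_charged_org,
                 gamma_inf_hydronium_aq = gamma_inf_hydronium_aq,
                 gamma_inf_hydronium_org = gamma_inf_hydronium_org),
            class = "phase_thermo")
}

#' Partition coefficient from infinite-dilution activity coefficients
#'
#' K_OW = (v_aq / v_org) * (gamma_neutral_aq / gamma_neutral_org): the
#' activity-coefficient route to the partition coefficient, requiring no
#' extrapolation of measurements.
#'
#' @param thermo A [phase_thermo].
#' @return K_OW (dimensionless, linear scale).
#' @export
kow_from_activity <- function(thermo) {
  stopifnot(inherits(thermo, "phase_thermo"))
  (thermo$molar_volume_aq / thermo$molar_volume_org) *
    (thermo$gamma_inf_neutral_aq / thermo$gamma_inf_neutral_org)
}

#' Distribution coefficient from infinite-dilution activity coefficients
#'
#' D_OW = (v_aq / v_org) * (gamma_charged_aq / gamma_charged_org) *
#' (gamma_hydronium_aq / gamma_hydronium_org). At zero solute concentration
#' an ionizable solute is fully ionized, so D_OW depends only on the charged
#' species and its counterion, never on the neutral-species activity
#' coefficients.
#'
#' @param thermo A [phase_thermo].
#' @return D_OW (dimensionless, linear scale).
#' @export
dow_from_activity <- function(thermo) {
  stopifnot(inherits(thermo, "phase_thermo"))
  (thermo$molar_volume_aq / thermo$molar_volume_org) *
    (thermo$gamma_inf_charged_aq / thermo$gamma_inf_charged_org) *
    (thermo$gamma_inf_hydronium_aq / thermo$gamma_inf_hydronium_org)
}

#' OECD concentration-limit quality control
#'
#' The OECD shake-flask guidance recommends keeping the solute concentration
#' at or below 0.01 mol/L in each phase so that measurements stay close to
#' the zero-concentration state. This check flags (but never removes) every
#' measurement exceeding the limit in either phase; the comparison is
#' inclusive, so a measurement at exactly 0.01 mol/L passes.
#'
#' @param series A [measurement_series].
#' @param limit Per-phase concentration ceiling, mol/L. Default 0.01.
#' @return A data frame with one row per flag: columns `measurement`
#'   (row index), `phase` (`"org"` or `"aq"`), `concentration`, `limit`.
#'   Zero rows when all measurements pass.
#' @export
oecd_qc <- function(series, limit = 0.01) {
  stopifnot(inherits(series, "measurement_series"))
  d <- series$measurements
  flags <- data.frame(measurement = integer(), phase = character(),
                      concentration = numeric(), limit = numeric(),
                      stringsAsFactors = FALSE)
  for (ph in c("org", "aq")) {
    conc <- d[[paste0("c_", ph)]]
    hit <- which(conc > limit)
    if (length(hit)) {
      flags <- rbind(flags, data.frame(
        measurement = hit, phase = ph, concentration = conc[hit],
        limit = limit, stringsAsFactors = FALSE))
    }
  }
  flags <- flags[order(flags$measurement, flags$phase), , drop = FALSE]
  rownames(flags) <- NULL
  flags
}
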
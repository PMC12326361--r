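#' Ionization constant of water
#'
#' Autoprotolysis constant \eqn{K_w = c_{H_3O^+} \cdot c_{OH^-}} at 25 degC,
#' fixed at 1.0e-14 (concentration basis, mol^2/L^2). All speciation in the
#' package works at 20-30 degC where this value is the conventional reference;
#' it is deliberately a named constant, not a per-call argument.
#'
#' @format A length-one numeric.
#' @export
KW <- 1.0e-14

#' Define a solute
#'
#' Creates a `solute` object carrying the ionization class and, for ionizable
#' solutes, the acid dissociation constant of the (conjugate) acid.
#' For a base the pKa always refers to the conjugate acid BH+, so literature
#' values such as lidocaine's 7.92 are used unchanged.
#'
#' @param name Substance name.
#' @param ionization_class One of `"acid"`, `"base"`, `"neutral"`.
#' @param pKa Acid dissociation constant (-log10 scale). Required for acids
#'   and bases, must be absent (`NULL`/`NA`) for neutral solutes. Values
#'   outside `[2, 12]` trigger a warning; values outside `(0, 14)` are errors.
#' @param pKa_temperature Temperature (degC) at which the pKa was determined.
#'   Metadata only; no van 't Hoff correction is applied.
#' @param pKa_ionic_strength Ionic strength (mol/L) of the pKa determination.
#'   Metadata only.
#' @return An object of class `solute`.
#' @examples
#' naproxen  <- solute("naproxen",  "acid", 4.18)
#' lidocaine <- solute("lidocaine", "base", 7.92)
#' griseofulvin <- solute("griseofulvin", "neutral")
#' @export
solute <- function(name, ionization_class = c("acid", "base", "neutral"),
                   pKa = NULL, pKa_temperature = 25,
                   pKa_ionic_strength = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ionization_class <- match.arg(ionization_class)
  if (is.null(pKa) || (length(pKa) == 1L && is.na(pKa))) pKa <- NA_real_
  if (ionization_class == "neutral") {
    if (!is.na(pKa)) {
      stop("a neutral solute must not carry a pKa", call. = FALSE)
    }
  } else {
    if (is.na(pKa)) {
      stop("an ionizable solute requires a pKa", call. = FALSE)
    }
    if (!is.finite(pKa) || pKa <= 0 || pKa >= 14) {
      stop("pKa must lie in (0, 14)", call. = FALSE)
    }
    if (pKa < 2 || pKa > 12) {
      warning("pKa ", pKa, " is outside [2, 12]; check units/assignment",
              call. = FALSE)
    }
  }
  structure(
    list(name = name, ionization_class = ionization_class, pKa = pKa,
         pKa_temperature = pKa_temperature,
         pKa_ionic_strength = pKa_ionic_strength),
    class = "solute")
}

#' @export
print.solute <- function(x, ...) {
  cat("Solute:", x$name, sprintf("(%s)", x$ionization_class), "\n")
  if (!is.na(x$pKa)) {
    cat("  pKa:", x$pKa,
        sprintf("(%g degC, I = %s mol/L)", x$pKa_temperature,
                format(x$pKa_ionic_strength)), "\n")
  }
  invisible(x)
}

is_ionizable <- function(solute) solute$ionization_class != "neutral"

#' Aqueous speciation state
#'
#' Bundle of aqueous-phase species concentrations (mol/L) for one
#' equilibrium: hydronium, hydroxide, and the neutral and charged forms of
#' the solute. The hydronium/hydroxide pair must satisfy the water
#' autoprotolysis product [KW] to within a relative tolerance of 1e-9.
#'
#' @param c_hydronium,c_hydroxide,c_neutral_solute,c_charged_solute
#'   Species concentrations in mol/L, all non-negative.
#' @return An object of class `aqueous_state`.
#' @export
aqueous_state <- function(c_hydronium, c_hydroxide,
                          c_neutral_solute, c_charged_solute) {
  v <- c(c_hydronium = c_hydronium, c_hydroxide = c_hydroxide,
         c_neutral_solute = c_neutral_solute,
         c_charged_solute = c_charged_solute)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  if (abs(c_hydronium * c_hydroxide - KW) > 1e-9 * KW) {
    stop("c_hydronium * c_hydroxide violates the autoprotolysis product K_w",
         call. = FALSE)
  }
  structure(as.list(v), class = "aqueous_state")
}

#' pH from hydronium concentration
#'
#' `ph_from_hydronium()` computes pH = -log10(c_H3O+); `hydronium_from_ph()`
#' is its inverse. The pair round-trips to better than 1e-12 relative over
#' the whole bracket `[1e-14, 1]` mol/L.
#'
#' @param c_hydronium Hydronium concentration, mol/L, strictly positive.
#' @return pH (dimensionless).
#' @examples
#' ph_from_hydronium(1e-7)   # 7
#' hydronium_from_ph(4.18)   # 10^-4.18
#' @export
ph_from_hydronium <- function(c_hydronium) {
  if (any(!is.finite(c_hydronium)) || any(c_hydronium <= 0)) {
    stop("c_hydronium must be > 0", call. = FALSE)
  }
  -log10(c_hydronium)
}

#' @rdname ph_from_hydronium
#' @param pH pH value.
#' @export
hydronium_from_ph <- function(pH) {
  stopifnot(is.numeric(pH), all(is.finite(pH)))
  10^(-pH)
}

#' Ionized fraction of a monoprotic solute
#'
#' Henderson-Hasselbalch degree of ionization at a given aqueous pH:
#' acids ionize as AH + H2O <-> A- + H3O+, giving
#' \eqn{1/(1 + 10^{pKa - pH})}; bases (conjugate acid BH+) give
#' \eqn{1/(1 + 10^{pH - pKa})}. Strictly increasing in pH for acids and
#' decreasing for bases; at pH = pKa the fraction is exactly 1/2.
#'
#' @param solute A [solute] with `ionization_class` `"acid"` or `"base"`.
#' @param pH Aqueous pH (may be a vector).
#' @return Fraction ionized in `[0, 1]`.
#' @examples
#' fraction_ionized(solute("naproxen", "acid", 4.18), 7)    # ~0.9985
#' fraction_ionized(solute("lidocaine", "base", 7.92), 7)   # ~0.8927
#' @export
fraction_ionized <- function(solute, pH) {
  stopifnot(inherits(solute, "solute"))
  if (!is_ionizable(solute)) {
    stop("fraction_ionized is undefined for a neutral solute", call. = FALSE)
  }
  stopifnot(is.numeric(pH), all(is.finite(pH)))
  expo <- switch(solute$ionization_class,
                 acid = solute$pKa - pH,
                 base = pH - solute$pKa)
  1 / (1 + 10^expo)
}

#' Apparent dissociation quotient of an aqueous state
#'
#' Concentration-based mass-action quotient of the dissociation reaction,
#' -log10(c_deprotonated * c_hydronium / c_protonated). For an acid
#' (AH + H2O <-> A- + H3O+) the deprotonated form is the charged species;
#' for a base the protonated form BH+ is charged and the neutral B is
#' deprotonated. For any state produced by [solve_equilibrium] this
#' reproduces the solute pKa to better than 1e-9 (activity corrections are
#' ignored, valid at small species concentrations).
#'
#' @param state An [aqueous_state].
#' @param ionization_class `"acid"` (default) or `"base"`; decides which
#'   solute pool is the protonated form.
#' @return Apparent pKa (dimensionless).
#' @export
dissociation_quotient <- function(state,
                                  ionization_class = c("acid", "base")) {
  stopifnot(inherits(state, "aqueous_state"))
  ionization_class <- match.arg(ionization_class)
  if (state$c_neutral_solute <= 0) {
    stop("dissociation quotient undefined at zero neutral-species concentration",
         call. = FALSE)
  }
  if (state$c_charged_solute <= 0 || state$c_hydronium <= 0) {
    stop("charged-species and hydronium concentrations must be > 0",
         call. = FALSE)
  }
  deprot <- switch(ionization_class, acid = state$c_charged_solute,
                   base = state$c_neutral_solute)
  prot <- switch(ionization_class, acid = state$c_neutral_solute,
                 base = state$c_charged_solute)
  -log10(deprot * state$c_hydronium / prot)
}
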
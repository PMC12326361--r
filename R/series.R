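#' A series of biphasic partition measurements for one solute
#'
#' One equilibrium observation consists of the overall solute concentration
#' (total solute moles over total liquid volume V_org + V_aq), the measured
#' solute concentration in each phase, the aqueous-phase pH and the
#' temperature. A series collects several such observations for the same
#' solute at the same phase-volume ratio; this is the input unit of the
#' data-reduction fits.
#'
#' @param solute A [solute].
#' @param measurements A data frame with columns `c_total`, `c_org`, `c_aq`
#'   (mol/L), `pH` (may be `NA` only for neutral solutes), `temperature`
#'   (degC), and optionally `c_org_sd`, `c_aq_sd` (replicate standard
#'   deviations, mol/L).
#' @param volume_ratio_org_to_aq Phase volume ratio V_org / V_aq
#'   (dimensionless); the shake-flask design here uses 1:3 by default.
#' @param ionic_strength Aqueous ionic strength, mol/L; metadata only.
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(solute, measurements,
                               volume_ratio_org_to_aq = 1 / 3,
                               ionic_strength = 0) {
  stopifnot(inherits(solute, "solute"), is.data.frame(measurements))
  need <- c("c_total", "c_org", "c_aq", "pH", "temperature")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(measurements) < 1L) {
    stop("a measurement series needs at least one measurement", call. = FALSE)
  }
  for (col in c("c_org_sd", "c_aq_sd")) {
    if (is.null(measurements[[col]])) measurements[[col]] <- NA_real_
  }
  d <- measurements
  if (any(!is.finite(d$c_aq)) || any(d$c_aq <= 0) ||
      any(!is.finite(d$c_org)) || any(d$c_org < 0)) {
    stop("require c_org >= 0 and c_aq > 0 for every measurement",
         call. = FALSE)
  }
  if (any(is.na(d$pH)) && is_ionizable(solute)) {
    stop("pH is mandatory for ionizable solutes", call. = FALSE)
  }
  ok_ph <- is.na(d$pH) | (d$pH > 0 & d$pH < 14)
  if (!all(ok_ph)) stop("pH values must lie in (0, 14)", call. = FALSE)
  if (diff(range(d$temperature)) > 1) {
    stop("measurements in one series must share temperature within 1 degC",
         call. = FALSE)
  }
  if (!is.finite(volume_ratio_org_to_aq) || volume_ratio_org_to_aq <= 0) {
    stop("volume_ratio_org_to_aq must be > 0", call. = FALSE)
  }
  rownames(d) <- NULL
  structure(list(solute = solute, measurements = d,
                 volume_ratio_org_to_aq = volume_ratio_org_to_aq,
                 ionic_strength = ionic_strength),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("Measurement series: %s (%s), %d measurement(s), V_org/V_aq = %g\n",
              x$solute$name, x$solute$ionization_class,
              nrow(x$measurements), x$volume_ratio_org_to_aq))
  print(x$measurements, ...)
  invisible(x)
}

#' @export
as.data.frame.measurement_series <- function(x, ...) {
  d <- x$measurements
  data.frame(substance = x$solute$name,
             ionization_class = x$solute$ionization_class,
             pka = x$solute$pKa,
             c_total_mol_L = d$c_total,
             c_org_mol_L = d$c_org,
             c_aq_mol_L = d$c_aq,
             ph_aq = d$pH,
             temp_C = d$temperature,
             c_org_sd = d$c_org_sd,
             c_aq_sd = d$c_aq_sd,
             volume_ratio_org_aq = x$volume_ratio_org_to_aq,
             ionic_strength_mol_L = x$ionic_strength,
             stringsAsFactors = FALSE)
}

MEASUREMENT_COLUMNS <- c("substance", "ionization_class", "pka",
                         "c_total_mol_L", "c_org_mol_L", "c_aq_mol_L",
                         "ph_aq", "temp_C", "c_org_sd", "c_aq_sd",
                         "volume_ratio_org_aq", "ionic_strength_mol_L")

#' Read and write measurement CSV files
#'
#' The on-disk schema has one row per measurement with columns
#' `substance, ionization_class, pka, c_total_mol_L, c_org_mol_L,
#' c_aq_mol_L, ph_aq, temp_C, c_org_sd, c_aq_sd, volume_ratio_org_aq,
#' ionic_strength_mol_L` (decimal point, UTF-8, mandatory header). Lines
#' starting with `#` are metadata comments and are skipped on read;
#' `write_measurements()` emits such a header recording the tool version and
#' any supplied metadata (e.g. seed, config hash). A file may hold several
#' substances; `read_measurements()` returns a named list of
#' [measurement_series], one per substance.
#'
#' @param path File path.
#' @return For `read_measurements()`, a named list of `measurement_series`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(MEASUREMENT_COLUMNS, c("c_org_sd", "c_aq_sd")),
                  names(d))
  if (length(miss)) {
    stop("measurement CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (sub in unique(d$substance)) {
    rows <- d[d$substance == sub, , drop = FALSE]
    cls <- unique(rows$ionization_class)
    pka <- unique(rows$pka)
    if (length(cls) != 1L || length(pka) != 1L) {
      stop("inconsistent solute metadata for substance ", sub, call. = FALSE)
    }
    sol <- solute(sub, cls, if (cls == "neutral") NULL else pka)
    meas <- data.frame(c_total = rows$c_total_mol_L,
                       c_org = rows$c_org_mol_L,
                       c_aq = rows$c_aq_mol_L,
                       pH = rows$ph_aq,
                       temperature = rows$temp_C,
                       c_org_sd = if (is.null(rows$c_org_sd)) NA_real_ else rows$c_org_sd,
                       c_aq_sd = if (is.null(rows$c_aq_sd)) NA_real_ else rows$c_aq_sd)
    out[[sub]] <- measurement_series(
      sol, meas,
      volume_ratio_org_to_aq = rows$volume_ratio_org_aq[1L],
      ionic_strength = rows$ionic_strength_mol_L[1L])
  }
  out
}

#' @rdname read_measurements
#' @param series A [measurement_series] or list of them.
#' @param metadata Named character/numeric vector written into the `#`
#'   comment header (e.g. `c(seed = 42)`).
#' @export
write_measurements <- function(series, path, metadata = NULL) {
  if (inherits(series, "measurement_series")) series <- list(series)
  d <- do.call(rbind, lapply(series, as.data.frame))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# kowtools %s",
                     as.character(utils::packageVersion("kowtools"))), con)
  if (length(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, format, "")), con)
  }
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
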
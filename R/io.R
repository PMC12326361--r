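#' kowtools: determination of octanol-water partition coefficients
#'
#' See [kow_fit] for the central estimator, [simulate.biphasic_system] for
#' the forward equilibrium simulator, and [kow_reduce]/[kow_simulate]/
#' [kow_convert]/[kow_screen] for the file-based tool surface.
#'
#' @importFrom stats lm predict coef residuals qt rnorm uniroot simulate
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom graphics plot abline points
#' @keywords internal
"_PACKAGE"

#' Convert log D to log P in a table
#'
#' Appends a `logp` column to a measurement-style table. Input rows must
#' carry either a `logd` column or the phase concentrations
#' (`c_org_mol_L`, `c_aq_mol_L`), plus `substance`, `ionization_class`,
#' `pka` and `ph_aq`. Conversion alone is not extrapolation, so the output
#' column is deliberately named `logp`, never a K_OW label. Ionizable rows
#' without a pH cannot be converted and are returned in the error report.
#'
#' @param input A data frame or path to a CSV file in the measurement
#'   schema (see [read_measurements]).
#' @param output Optional path; when given the converted table is written
#'   as CSV.
#' @return A list with `table` (the input with `logp` appended) and
#'   `errors` (data frame of row indices and reasons; zero rows when clean).
#' @export
kow_convert <- function(input, output = NULL) {
  d <- if (is.character(input)) {
    utils::read.csv(input, comment.char = "#", stringsAsFactors = FALSE)
  } else as.data.frame(input)
  if (is.null(d$logd)) {
    if (is.null(d$c_org_mol_L) || is.null(d$c_aq_mol_L)) {
      stop("input needs either a logd column or both phase concentrations",
           call. = FALSE)
    }
    d$logd <- log_partition(d$c_org_mol_L, d$c_aq_mol_L)
  }
  errors <- data.frame(row = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  d$logp <- NA_real_
  d$note <- NA_character_
  for (i in seq_len(nrow(d))) {
    cls <- d$ionization_class[i]
    if (cls == "neutral") {
      d$logp[i] <- d$logd[i]
      d$note[i] <- "neutral: log P = log D"
      next
    }
    if (is.null(d$ph_aq) || is.na(d$ph_aq[i])) {
      errors <- rbind(errors, data.frame(
        row = i, reason = "ionizable row without pH",
        stringsAsFactors = FALSE))
      next
    }
    sol <- solute(d$substance[i], cls, d$pka[i])
    d$logp[i] <- logp_from_logd(d$logd[i], d$ph_aq[i], sol)
  }
  if (!is.null(output)) {
    utils::write.csv(d, output, row.names = FALSE)
  }
  list(table = d, errors = errors)
}

kow_estimate_record <- function(fit, substance) {
  data.frame(substance = substance,
             method = fit$method,
             log_value = fit$log_value,
             std_error = fit$std_error,
             intermediate_logDow = fit$intermediate_logDow,
             fit_slope = fit$fit_slope,
             fit_intercept = fit$fit_intercept,
             n_points = fit$n_points,
             r_squared = fit$r_squared,
             extrapolation_span_warning = fit$extrapolation_span_warning,
             n_qc_flags = nrow(fit$qc_flags),
             error = NA_character_,
             stringsAsFactors = FALSE)
}

empty_estimate_record <- function(substance, method, msg) {
  data.frame(substance = substance, method = method, log_value = NA_real_,
             std_error = NA_real_, intermediate_logDow = NA_real_,
             fit_slope = NA_real_, fit_intercept = NA_real_,
             n_points = NA_integer_, r_squared = NA_real_,
             extrapolation_span_warning = NA, n_qc_flags = NA_integer_,
             error = msg, stringsAsFactors = FALSE)
}

#' Reduce measurement series to log K_OW estimates
#'
#' Runs the requested data-reduction method(s) on every series of a
#' measurement file (or list of [measurement_series]), attaching OECD QC
#' flag counts and fit diagnostics. With `method = "all"`, both routes are
#' run for ionizable solutes and their absolute difference - the headline
#' consistency statistic of the approach - is reported per substance. Fit
#' failures are recorded per series (`error` column) and do not abort the
#' batch.
#'
#' @param input Path to a measurement CSV (see [read_measurements]), a
#'   [measurement_series], or a list of them.
#' @param method One of `"all"`, `"method1"` (pH extrapolation),
#'   `"method2"` (conversion + concentration extrapolation), `"neutral"`
#'   (log P vs concentration, neutral solutes).
#' @param output Optional path stem; estimates are written to
#'   `<output>.csv` and `<output>.json`.
#' @return A list with `estimates` (one row per substance x method) and
#'   `differences` (per-substance |method1 - method2|; zero rows unless
#'   `method = "all"`).
#' @export
kow_reduce <- function(input, method = c("all", "method1", "method2",
                                         "neutral"),
                       output = NULL) {
  method <- match.arg(method)
  series_list <- if (is.character(input)) {
    read_measurements(input)
  } else if (inherits(input, "measurement_series")) {
    stats::setNames(list(input), input$solute$name)
  } else input
  run <- function(f, ser, sub, label) {
    tryCatch(kow_estimate_record(f(ser), sub),
             error = function(e) empty_estimate_record(sub, label,
                                                       conditionMessage(e)))
  }
  est <- list(); dif <- list()
  for (sub in names(series_list)) {
    ser <- series_list[[sub]]
    ionizable <- is_ionizable(ser$solute)
    recs <- switch(method,
      method1 = run(fit_method1, ser, sub, "ph_extrapolation"),
      method2 = run(fit_method2, ser, sub, "conc_extrapolation"),
      neutral = run(fit_logp_vs_conc, ser, sub, "conc_extrapolation"),
      all = {
        if (ionizable) {
          r1 <- run(fit_method1, ser, sub, "ph_extrapolation")
          r2 <- run(fit_method2, ser, sub, "conc_extrapolation")
          if (!is.na(r1$log_value) && !is.na(r2$log_value)) {
            dif[[sub]] <- data.frame(
              substance = sub,
              method1 = r1$log_value, method2 = r2$log_value,
              abs_difference = abs(r1$log_value - r2$log_value),
              stringsAsFactors = FALSE)
          }
          rbind(r1, r2)
        } else {
          run(fit_logp_vs_conc, ser, sub, "conc_extrapolation")
        }
      })
    est[[sub]] <- recs
  }
  out <- list(estimates = do.call(rbind, unname(est)),
              differences = if (length(dif)) do.call(rbind, unname(dif))
              else data.frame(substance = character(), method1 = numeric(),
                              method2 = numeric(), abs_difference = numeric(),
                              stringsAsFactors = FALSE))
  rownames(out$estimates) <- NULL
  if (!is.null(output)) write_results(out$estimates, output)
  out
}

#' Serialize estimate records
#'
#' Writes a flat record table both as CSV and as JSON next to each other;
#' `read_results()` reads either back. The JSON round-trips all values at
#' full double precision.
#'
#' @param records A data frame of flat records.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_results <- function(records, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(records, csv, row.names = FALSE)
  jsonlite::write_json(records, js, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = js))
}

#' @rdname write_results
#' @param path Path to a `.csv` or `.json` written by `write_results()`.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

parse_scenario <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config), !is.null(config$solute), !is.null(config$system))
  config
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Run a simulation scenario
#'
#' Binds the forward simulator to a scenario configuration (YAML or JSON
#' file, or an equivalent list): a `solute` block (`name`,
#' `ionization_class`, `pka`), a `system` block ([biphasic_system]
#' arguments), an optional `grid` (overall concentrations in mol/L; the
#' designed grid of [design_concentration_grid] when absent), an optional
#' `noise` block ([noise_model] arguments) and a `seed`. Outputs are
#' deterministic under a fixed seed; the measurement CSV header records the
#' tool version, the seed and a hash of the canonicalized configuration.
#'
#' @param config Path to a YAML/JSON scenario file, or a list.
#' @param output Optional path for the measurement CSV.
#' @param species_output Optional path for the species-resolved companion
#'   CSV (noiseless speciation per grid point).
#' @param seed Optional integer overriding the configured seed.
#' @return A list with `series` ([measurement_series]), `species` (data
#'   frame), `seed`, and `config_hash`.
#' @export
kow_simulate <- function(config, output = NULL, species_output = NULL,
                         seed = NULL) {
  cfg <- parse_scenario(config)
  sol <- solute(cfg$solute$name, cfg$solute$ionization_class,
                cfg$solute$pka)
  sys <- do.call(biphasic_system, cfg$system)
  noise <- if (is.null(cfg$noise)) noise_model() else
    do.call(noise_model, cfg$noise)
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(seed)) seed <- 1L
  seed <- as.integer(seed)
  grid <- if (is.null(cfg$grid)) design_concentration_grid(sol, sys) else
    as.numeric(unlist(cfg$grid))
  ser <- simulate(sys, nsim = 1, seed = seed, solute = sol,
                  c_total_grid = grid, noise = noise)
  spc <- species_table(sol, sys, grid)
  hash <- config_hash(cfg)
  if (!is.null(output)) {
    write_measurements(ser, output,
                       metadata = c(seed = seed, config_hash = hash))
  }
  if (!is.null(species_output)) {
    con <- file(species_output, "wt")
    writeLines(sprintf("# kowtools %s; seed: %s; config_hash: %s",
                       as.character(utils::packageVersion("kowtools")),
                       seed, hash), con)
    utils::write.csv(spc, con, row.names = FALSE)
    close(con)
  }
  list(series = ser, species = spc, seed = seed, config_hash = hash)
}

#' Screen literature values
#'
#' Computes the per-substance spread (highest minus lowest reported value)
#' and the class-mean spreads over a literature curation, plus the pairwise
#' method differences of the method-comparison table for ionizable
#' substances.
#'
#' @param fixtures `"builtin"` for the packaged tables (see
#'   [kow_literature]) or a path to a CSV in the same layout.
#' @param output Optional path stem; the per-substance report is written as
#'   CSV and a human-readable text summary as `<output>.txt`.
#' @return A list with `per_substance`, `class_means` (see
#'   [class_spread_summary]) and `method_differences` (per ionizable
#'   substance of the comparison table: method 1, method 2 and their
#'   absolute difference).
#' @export
kow_screen <- function(fixtures = "builtin", output = NULL) {
  lit <- if (identical(fixtures, "builtin")) kow_literature() else
    utils::read.csv(fixtures, comment.char = "#", stringsAsFactors = FALSE)
  sm <- class_spread_summary(lit)
  t3 <- kow_method_comparison()
  t3i <- t3[!is.na(t3$method1) & !is.na(t3$method2), , drop = FALSE]
  md <- data.frame(substance = t3i$substance, method1 = t3i$method1,
                   method2 = t3i$method2,
                   abs_difference = abs(t3i$method1 - t3i$method2),
                   stringsAsFactors = FALSE)
  rownames(md) <- NULL
  out <- list(per_substance = sm$per_substance, class_means = sm$class_means,
              method_differences = md)
  if (!is.null(output)) {
    utils::write.csv(sm$per_substance, paste0(output, ".csv"),
                     row.names = FALSE)
    txt <- c("Literature screening summary",
             sprintf("  %s (n = %d substances): mean spread %.3f log units",
                     sm$class_means$class, sm$class_means$n_substances,
                     sm$class_means$mean_spread),
             "Method 1 vs Method 2 (comparison table):",
             sprintf("  %s: |%.2f - %.2f| = %.2f", md$substance, md$method1,
                     md$method2, md$abs_difference))
    writeLines(txt, paste0(output, ".txt"))
  }
  out
}
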
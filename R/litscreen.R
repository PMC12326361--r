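#' Curated literature values of partition/distribution coefficients
#'
#' `kow_literature()` loads the packaged curation of published partition and
#' distribution coefficients for 18 APIs (LLE-based determinations at
#' 20-30 degC), with the property each source *stated*, the property its
#' methods actually *reported*, the determination route (experimental,
#' converted, calculated, or unknown), and, where available, pH,
#' concentration range and ionic strength. `kow_method_comparison()` loads the
#' method-comparison table for the four example APIs (naproxen, ibuprofen,
#' lidocaine, griseofulvin): the solubility-ratio diagnostic and the
#' log K_OW values from the pH-extrapolation route (method 1), the
#' conversion/concentration route (method 2) and the activity-coefficient
#' route (method 3), next to the most reliable literature value.
#'
#' @return A data frame.
#' @examples
#' lit <- kow_literature()
#' spread(lit$value[lit$substance == "glibenclamide"])  # 4.5
#' @export
kow_literature <- function() {
  path <- system.file("extdata", "literature_partition_values.csv",
                      package = "kowtools", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(conc_range_mmol_L = "character"))
}

#' @rdname kow_literature
#' @export
kow_method_comparison <- function() {
  path <- system.file("extdata", "method_comparison.csv",
                      package = "kowtools", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Spread of reported values
#'
#' Difference between the highest and lowest value of a set of reported
#' partition coefficients for one substance; 0 for a single value.
#' Permutation- and duplication-invariant and non-negative.
#'
#' @param values Numeric vector with at least one finite value.
#' @return max(values) - min(values).
#' @export
spread <- function(values) {
  if (length(values) < 1L) stop("spread of an empty set", call. = FALSE)
  values <- values[!is.na(values)]
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("spread requires finite values", call. = FALSE)
  }
  max(values) - min(values)
}

#' Per-class mean spread of literature values
#'
#' For every substance, pools all reported values (optionally restricted to
#' experimentally determined ones) and computes the spread
#' (highest - lowest); then averages the per-substance spreads separately
#' for ionizable and nonionizable substances. The determination routes are
#' pooled by default because published compilations rarely state a
#' defensible exclusion rule.
#'
#' @param entries A data frame in the layout of [kow_literature].
#' @param determination `"all"` (default) or `"exp"` to keep only rows whose
#'   determination is experimental.
#' @return A list with `per_substance` (substance, class, n values, spread)
#'   and `class_means` (class, number of substances, mean spread). Classes
#'   without substances are omitted.
#' @export
class_spread_summary <- function(entries, determination = c("all", "exp")) {
  determination <- match.arg(determination)
  stopifnot(is.data.frame(entries),
            all(c("substance", "ionizable", "value") %in% names(entries)))
  if (determination == "exp") {
    entries <- entries[entries$determination == "exp", , drop = FALSE]
  }
  subs <- unique(entries$substance)
  per <- do.call(rbind, lapply(subs, function(s) {
    rows <- entries[entries$substance == s, , drop = FALSE]
    data.frame(substance = s,
               class = if (rows$ionizable[1L]) "ionizable" else "nonionizable",
               n_values = nrow(rows),
               spread = spread(rows$value),
               stringsAsFactors = FALSE)
  }))
  cls <- unique(per$class)
  means <- do.call(rbind, lapply(cls, function(cl) {
    p <- per[per$class == cl, , drop = FALSE]
    data.frame(class = cl, n_substances = nrow(p),
               mean_spread = mean(p$spread), stringsAsFactors = FALSE)
  }))
  list(per_substance = per, class_means = means)
}

#' Audit one literature entry for internal consistency
#'
#' Flags entries whose stated property disagrees with the property the
#' source actually reported (e.g. "log P" stated for a measured log D), and,
#' when the entry carries a pH and the solute a pKa, computes the
#' ionization-corrected companion value (log D -> log P or log P -> log D)
#' for cross-source comparison. For a neutral substance the two properties
#' coincide and no conversion is attempted.
#'
#' @param entry A one-row data frame (or list) with at least
#'   `property_stated`, `property_reported`, `value`; optionally `ph`.
#' @param solute A [solute] for the entry's substance.
#' @return A list with `mismatch` (logical; `NA` when the reported property
#'   is unknown), `companion_property`, `companion_value`, and
#'   `skipped_reason` (`NULL` unless the conversion was skipped).
#' @export
consistency_check <- function(entry, solute) {
  stopifnot(inherits(solute, "solute"))
  stated <- as.character(entry$property_stated)
  reported <- as.character(entry$property_reported)
  mismatch <- if (is.na(reported) || reported == "unknown") {
    NA
  } else !identical(stated, reported)

  out <- list(mismatch = mismatch, companion_property = NA_character_,
              companion_value = NA_real_, skipped_reason = NULL)
  if (!is_ionizable(solute)) {
    out$skipped_reason <- "neutral substance: log D and log P coincide"
    return(out)
  }
  ph <- suppressWarnings(as.numeric(entry$ph))
  if (is.na(ph)) {
    out$skipped_reason <- "no pH available for conversion"
    return(out)
  }
  prop <- if (!is.na(mismatch) && !mismatch) reported else stated
  if (prop %in% c("logD", "logDow")) {
    out$companion_property <- "logP"
    out$companion_value <- logp_from_logd(entry$value, ph, solute)
  } else if (prop %in% c("logP", "logKow")) {
    out$companion_property <- "logD"
    out$companion_value <- logd_from_logp(entry$value, ph, solute)
  } else {
    out$skipped_reason <- "property not convertible"
  }
  out
}
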
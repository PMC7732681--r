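#' Read a gas-exchange record table
#'
#' Ingests a CSV of instrument observations (comma-separated, header
#' row, '.' decimal) into the validated record table the fitting
#' functions consume. Declared units are converted at ingest; rows that
#' fail validation (non-finite numerics, Ca <= 0, RH outside \[0, 1\]
#' after conversion, gs below the -0.005 mol m-2 s-1 instrument
#' tolerance) are dropped with a message stating the count and reason,
#' never silently imputed. Small negative gs values above the tolerance
#' are kept and flagged in the `gs_flagged` column.
#'
#' @param path CSV file with columns `species`, `light`, `water`,
#'   `period`, `PAR_umol`, `A_umol`, `gs_mol`, `Ca_umol`, `RH_frac`,
#'   `D_kPa`, `T_C` and optionally `role`.
#' @param units List of unit declarations: `RH` (`"fraction"` or
#'   `"percent"`), `gs` (`"mol"` or `"mmol"`).
#' @return Validated records data.frame.
#' @export
read_gas_exchange_table <- function(path,
                                    units = list(RH = "fraction",
                                                 gs = "mol")) {
  if (!file.exists(path)) {
    stop("read_gas_exchange_table: no such file: ", path, call. = FALSE)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "light", "water", "period", "PAR_umol", "A_umol",
            "gs_mol", "Ca_umol", "RH_frac", "D_kPa", "T_C")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols) > 0) {
    stop("read_gas_exchange_table: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("PAR_umol", "A_umol", "gs_mol", "Ca_umol", "RH_frac",
                "D_kPa", "T_C")
  for (cc in num_cols) {
    dat[[cc]] <- suppressWarnings(as.numeric(as.character(dat[[cc]])))
  }
  if (identical(units$RH, "percent")) dat$RH_frac <- dat$RH_frac / 100
  if (identical(units$gs, "mmol")) dat$gs_mol <- mmol_to_mol(dat$gs_mol)

  finite <- vapply(dat[num_cols], function(v) is.finite(v),
                   logical(nrow(dat)))
  if (is.null(dim(finite))) finite <- matrix(finite, nrow = nrow(dat))
  bad_numeric <- rowSums(!finite) > 0
  bad_range <- dat$Ca_umol <= 0 | dat$RH_frac < 0 | dat$RH_frac > 1 |
    dat$PAR_umol < 0 | dat$gs_mol <= -0.005
  bad_range[is.na(bad_range)] <- TRUE
  drop <- bad_numeric | bad_range
  if (any(drop)) {
    message("read_gas_exchange_table: dropped ", sum(drop), " row(s): ",
            sum(bad_numeric), " unparseable/non-finite, ",
            sum(bad_range & !bad_numeric), " out of range")
  }
  out <- dat[!drop, , drop = FALSE]
  out$gs_flagged <- out$gs_mol < 0
  rownames(out) <- NULL
  out
}

#' Write a gas-exchange record table
#'
#' Canonical CSV writer (comma-separated, UTF-8, '.' decimal); a
#' write/read round trip through [read_gas_exchange_table()] with the
#' default units is lossless.
#'
#' @param records Records data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_table <- function(records, path) {
  cols <- intersect(c("species", "light", "water", "period", "role",
                      "PAR_umol", "A_umol", "gs_mol", "Ca_umol", "RH_frac",
                      "D_kPa", "T_C"), names(records))
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drying-curve weighing log
#'
#' Reads `time_s`, `mass_g` columns and combines them with the sidecar
#' metadata (leaf area and the lab air state) into a
#' [mass_loss_series()]. Declared units are converted at ingest.
#'
#' @param path CSV with columns `time_s`, `mass_g`.
#' @param area Leaf area in the declared area unit.
#' @param air An [air_state()] for the drying environment.
#' @param units List with `mass` (`"g"` or `"kg"`) and `area` (`"m2"` or
#'   `"cm2"`).
#' @return A [mass_loss_series()].
#' @export
read_mass_loss_csv <- function(path, area, air,
                               units = list(mass = "g", area = "m2")) {
  if (!file.exists(path)) {
    stop("read_mass_loss_csv: no such file: ", path, call. = FALSE)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "mass_g") %in% names(dat))) {
    stop("read_mass_loss_csv: need columns time_s, mass_g", call. = FALSE)
  }
  mass <- dat$mass_g
  if (identical(units$mass, "kg")) mass <- mass * 1000
  if (identical(units$area, "cm2")) area <- area / 1e4
  mass_loss_series(dat$time_s, mass, area, air)
}

#' Read an A/Ci response curve
#'
#' @param path CSV with columns `Ca_set_umol`, `Ci_umol`, `A_umol`,
#'   `PAR_umol`, `T_C`.
#' @return Curve data.frame suitable for [fit_aci()].
#' @export
read_aci_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_aci_csv: no such file: ", path, call. = FALSE)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Ca_set_umol", "Ci_umol", "A_umol", "PAR_umol", "T_C")
  if (!all(need %in% names(dat))) {
    stop("read_aci_csv: missing column(s): ",
         paste(setdiff(need, names(dat)), collapse = ", "), call. = FALSE)
  }
  dat
}

#' Published model-comparison table
#'
#' The transcribed per-species comparison of the five Ball-Berry-family
#' calibrations (AIC, delta-AIC, R2, observed-vs-predicted slope and
#' intercept with SEs; floors/intercepts in mmol m-2 s-1) for the two
#' oak species QF and QI. Shipped as package data so delta-AIC
#' arithmetic and the simulation floor values can be driven from the
#' printed numbers without the (unpublished) raw measurements.
#'
#' @return data.frame of the printed comparison table.
#' @export
published_comparison_table <- function() {
  utils::read.csv(system.file("extdata", "published_model_comparison.csv",
                              package = "stomres", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Model-comparison table
#'
#' Renders a list of fits as the conventional comparison layout: the
#' intercept-or-floor column in mmol m-2 s-1, AIC, delta-AIC, R2, and
#' the observed-vs-predicted slope and intercept with their standard
#' errors, rows sorted by AIC. With `pretty = TRUE` the slope/intercept
#' columns are formatted as "estimate (SE)" strings.
#'
#' @param fits Named list of [fit_model()] results on the same records
#'   (names become the model labels).
#' @param path Optional CSV output path.
#' @param pretty Return presentation strings instead of numeric columns.
#' @return data.frame, one row per model.
#' @export
emit_comparison_table <- function(fits, path = NULL, pretty = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$form, character(1))
  }
  gint_mmol <- vapply(fits, function(f) {
    g <- if (f$spec$form %in% c("BBD", "BB_MIN")) spec_floor(f$spec)
         else f$spec$gint
    mol_to_mmol(g)
  }, numeric(1))
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  d <- delta_aic(aics)
  tab <- data.frame(
    model = names(fits),
    gint_mmol = round(gint_mmol, 1),
    AIC = round(aics, 2),
    dAIC = round(d$dAIC, 2),
    R2 = round(vapply(fits, function(f) f$obs_pred$r_squared, numeric(1)), 2),
    slope = vapply(fits, function(f) f$obs_pred$slope, numeric(1)),
    slope_se = vapply(fits, function(f) f$obs_pred$slope_se, numeric(1)),
    intercept = vapply(fits, function(f) f$obs_pred$intercept, numeric(1)),
    intercept_se = vapply(fits, function(f) f$obs_pred$intercept_se,
                          numeric(1))
  )
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  if (pretty) {
    fmt <- function(est, se) sprintf("%.3g (%.2g)", est, se)
    tab$slope <- fmt(tab$slope, tab$slope_se)
    tab$intercept <- fmt(tab$intercept, tab$intercept_se)
    tab$slope_se <- tab$intercept_se <- NULL
  }
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  tab
}
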
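# Delimited-table exchange format for rheometer records. One dialect:
#   test_type, abscissa, abscissa_units, Gp_Pa, Gpp_Pa, eta_Pa_s, temp_C

.rheo_units <- c(time_sweep = "min", freq_sweep = "Hz",
                 amplitude_sweep = "Pa", recovery = "s",
                 flow_curve = "1/s")

.rheo_columns <- c("test_type", "abscissa", "abscissa_units",
                   "Gp_Pa", "Gpp_Pa", "eta_Pa_s", "temp_C")

#' Write a rheometer record as CSV
#'
#' @param x a [rheo_sweep()] or [flow_curve()].
#' @param path output CSV path.
#' @param temperature temperature column for flow curves, degrees C.
#' @return `path`, invisibly.
#' @export
write_rheo_table <- function(x, path, temperature = 37) {
  if (inherits(x, "rheo_sweep")) {
    df <- data.frame(test_type = x$test_type, abscissa = x$abscissa,
                     abscissa_units = .rheo_units[[x$test_type]],
                     Gp_Pa = x$Gp, Gpp_Pa = x$Gpp, eta_Pa_s = NA_real_,
                     temp_C = x$temperature)
  } else if (inherits(x, "flow_curve")) {
    df <- data.frame(test_type = "flow_curve", abscissa = x$shear_rate,
                     abscissa_units = "1/s", Gp_Pa = NA_real_,
                     Gpp_Pa = NA_real_, eta_Pa_s = x$viscosity,
                     temp_C = temperature)
  } else stop("x must be a rheo_sweep or flow_curve")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a rheometer record from CSV
#'
#' Expects the dialect written by [write_rheo_table()]. Rows are sorted
#' by abscissa (with a warning if they were shuffled); unit strings must
#' match the test type; sweeps missing a modulus column are rejected.
#'
#' @param path CSV path.
#' @return a [rheo_sweep()] or [flow_curve()] according to `test_type`.
#' @export
read_rheo_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), .rheo_columns)
  if (length(unknown))
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  missing <- setdiff(.rheo_columns, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  tt <- unique(df$test_type)
  if (length(tt) != 1L) stop("file must contain exactly one test_type")
  if (!tt %in% names(.rheo_units)) stop("unknown test_type: ", tt)
  un <- unique(df$abscissa_units)
  if (length(un) != 1L || un != .rheo_units[[tt]])
    stop(sprintf("unit mismatch: expected '%s' for %s", .rheo_units[[tt]], tt))
  if (is.unsorted(df$abscissa, strictly = FALSE)) {
    warning("rows were not sorted by abscissa; sorting")
    df <- df[order(df$abscissa), , drop = FALSE]
  }
  if (anyDuplicated(df$abscissa)) stop("duplicated abscissa values")
  if (tt == "flow_curve") {
    if (any(is.na(df$eta_Pa_s))) stop("missing viscosity values in flow curve")
    return(flow_curve(df$abscissa, df$eta_Pa_s))
  }
  if (any(is.na(df$Gp_Pa)) || any(is.na(df$Gpp_Pa)))
    stop("missing Gp_Pa/Gpp_Pa values for a ", tt)
  rheo_sweep(tt, df$abscissa, df$Gp_Pa, df$Gpp_Pa,
             temperature = df$temp_C[1])
}
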
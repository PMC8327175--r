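# File formats. Canonical internal units: cmH2O, ml, ml/s, seconds;
# conversions happen here and only here.

.flow_factors <- c("ml/s" = 1, "L/s" = 1000, "l/s" = 1000,
                   "L/min" = 1000 / 60, "l/min" = 1000 / 60)
.pressure_factors <- c("cmH2O" = 1, "cmh2o" = 1)

unit_factor <- function(unit, table, what) {
  if (!unit %in% names(table))
    stopf("unknown %s unit '%s' (supported: %s)", what, unit,
          paste(unique(names(table)), collapse = ", "))
  unname(table[[unit]])
}

#' Read a ventilator waveform CSV
#'
#' Expects a header `t,paw,flow[,peso]`. Flow may be declared in `ml/s`,
#' `L/s` or `L/min` and is converted to ml/s on load; pressures must be in
#' cmH2O. Rows with missing `t`, `paw` or `flow` are rejected; their line
#' numbers are attached as attribute `"bad_rows"`.
#'
#' @param path CSV path.
#' @param flow_unit Unit of the `flow` column in the file.
#' @param pressure_unit Unit of the pressure columns.
#' @return data.frame `t`, `paw`, `flow` (ml/s) and `peso` if present.
#' @export
read_waveforms <- function(path, flow_unit = "ml/s", pressure_unit = "cmH2O") {
  ff <- unit_factor(flow_unit, .flow_factors, "flow")
  pf <- unit_factor(pressure_unit, .pressure_factors, "pressure")
  d <- read.csv(path)
  need <- c("t", "paw", "flow")
  miss <- setdiff(need, names(d))
  extra <- setdiff(names(d), c(need, "peso"))
  if (length(miss) || length(extra))
    stopf("waveform schema mismatch in %s: missing [%s], unexpected [%s]",
          path, paste(miss, collapse = ", "), paste(extra, collapse = ", "))
  bad <- which(!stats::complete.cases(d[, need]))
  if (length(bad)) {
    warnf("%d malformed waveform row(s) rejected (lines %s)", length(bad),
          paste(bad + 1L, collapse = ", "))   # +1 for the header line
    d <- d[-bad, , drop = FALSE]
  }
  d$flow <- d$flow * ff
  d$paw <- d$paw * pf
  if ("peso" %in% names(d)) d$peso <- d$peso * pf
  attr(d, "bad_rows") <- bad
  d
}

#' Write a ventilator waveform CSV
#'
#' @param bundle A `signal_bundle` or a waveform data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_waveforms <- function(bundle, path) {
  sig <- as_signal_df(bundle)
  write.csv(sig, path, row.names = FALSE)
  invisible(path)
}

#' Write / read EIT frames as CSV
#'
#' Columns are `t` plus `roi1..roi4` (pre-summed bands) or `px0001..px1024`
#' (row-major 32x32 image, row 1 most ventral).
#'
#' @param frames Frame matrix with attribute `"t"` (see [simulate_eit()]).
#' @param path CSV path.
#' @return `write_eit_frames`: invisibly, `path`; `read_eit_frames`: the
#'   frame matrix with attribute `"t"`.
#' @export
write_eit_frames <- function(frames, path) {
  d <- data.frame(t = attr(frames, "t"), as.data.frame(unclass(frames)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eit_frames
#' @export
read_eit_frames <- function(path) {
  d <- read.csv(path)
  if (!"t" %in% names(d)) stopf("EIT frame file %s lacks a 't' column", path)
  m <- as.matrix(d[, setdiff(names(d), "t"), drop = FALSE])
  m <- check_frames(m)
  attr(m, "t") <- d$t
  m
}

#' Write / read a cohort table CSV
#'
#' One row per measurement (patient x condition panel).
#'
#' @param cohort A `cohort_table` data.frame.
#' @param path CSV path.
#' @return `write_cohort`: invisibly, `path`; `read_cohort`: a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("cohort_table", class(d))
  d
}

#' Serialize / deserialize a DP_L model as JSON
#'
#' @param model A `dpl_model`.
#' @param path JSON path.
#' @return `write_model_json`: invisibly, `path`; `read_model_json`: a
#'   `dpl_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "dpl_model"))
  obj <- list(coefficients = list(k = model$k, alpha = model$alpha,
                                  beta = model$beta, gamma = model$gamma,
                                  delta = model$delta, eps = model$eps),
              r2 = model$r2, fitted_on = model$fitted_on)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_dpl_model(unlist(obj$coefficients), r2 = obj$r2 %||% NA_real_,
                fitted_on = obj$fitted_on %||% "published")
}
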
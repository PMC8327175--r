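# End-to-end pipeline: simulate (optional) -> per-measurement analysis ->
# cohort assembly -> model fit / prediction -> agreement report, with a
# manifest that reconciles generated = analyzed + excluded.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed); `NULL` keeps all
#'   artifacts in memory.
#' @param cohort A [cohort_spec()] describing the synthetic cohort, or an
#'   existing `cohort_table` / `mechanistic_cohort` to analyze.
#' @param model `"refit"` (pooled OLS on the analyzed cohort) or
#'   `"published"` (fixed published coefficients).
#' @param loa_mult Limits-of-agreement multiplier.
#' @param verbose Log per-stage progress messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = NULL, cohort = cohort_spec(),
                       model = c("refit", "published"), loa_mult = 2,
                       verbose = FALSE) {
  model <- match.arg(model)
  structure(list(out_dir = out_dir, cohort = cohort, model = model,
                 loa_mult = loa_mult, verbose = verbose),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `out_dir`, `model`, `loa_mult`, `verbose`, and a
#' `cohort:` block whose entries are passed to [cohort_spec()].
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(cohort_spec, y$cohort %||% list())
  run_config(out_dir = y$out_dir, cohort = spec,
             model = y$model %||% "refit",
             loa_mult = y$loa_mult %||% 2,
             verbose = isTRUE(y$verbose))
}

pipe_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

# Analyze one mechanistic measurement into a cohort row.
analyze_measurement <- function(m) {
  br <- analyze_breaths(m$bundle)
  mech <- summarize_mechanics(br, with_peso = TRUE)
  roi <- roi_tidal(m$eit, m$bundle, tv_ml = mech$tv_ml, dp = mech$dp,
                   ibw_kg = m$patient$ibw_kg)
  data.frame(
    patient_id = m$patient$patient_id, condition = m$condition,
    peep = m$peep, ibw_kg = m$patient$ibw_kg,
    tv_ml = mech$tv_ml, ppeak = mech$ppeak, pplat = mech$pplat,
    peep_tot = mech$peep_tot, dp = mech$dp, ers = mech$ers,
    pl_insp = mech$pl_insp, pl_exp = mech$pl_exp,
    dpl = mech$dpl, el = mech$el, ecw = mech$ecw, pi = mech$pi,
    roi1_pct = unname(roi$roi_pct[1L]), roi2_pct = unname(roi$roi_pct[2L]),
    roi3_pct = unname(roi$roi_pct[3L]), roi4_pct = unname(roi$roi_pct[4L]),
    rc_roi1 = unname(roi$rc_roi[1L]), rc_roi2 = unname(roi$rc_roi[2L]),
    rc_roi3 = unname(roi$rc_roi[3L]), rc_roi4 = unname(roi$rc_roi[4L]),
    usable = TRUE
  )
}

# Derive the measured/predicted esophageal-chain columns an equation-mode
# cohort needs for the agreement report.
complete_equation_cohort <- function(co) {
  tv_l <- co$tv_ml / 1000
  co$dp <- co$ers * tv_l
  co$pplat <- co$peep + co$dp
  co$el <- co$dpl / tv_l
  co$ecw <- co$ers - co$el
  co$pi <- co$pplat * (co$el / co$ers)
  co
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, analyzes every measurement, fits or loads
#' the DP_L prediction model, derives the EIT-based DP_L / EL / PI for each
#' row, computes the agreement report, and writes the artifacts
#' (`cohort.csv`, `model.json`, `agreement.json`, `manifest.json`) when
#' `out_dir` is set. A failing measurement is excluded with its reason
#' recorded (not fatal) unless more than half of the measurements fail. Runs
#' are deterministic given the seeds inside the cohort specification.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `cohort` (analyzed table with
#'   `dpl_eit`, `el_eit`, `pi_eit` columns), `model`, `agreement`,
#'   `manifest`.
#' @examples
#' res <- run_pipeline(run_config(cohort = cohort_spec(n_patients = 5, seed = 9)))
#' res$manifest$counts
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  co_in <- config$cohort
  if (inherits(co_in, "cohort_spec")) {
    pipe_log(config, "simulating %d x %d cohort (%s mode, seed %d)",
             co_in$n_patients, co_in$conditions_per_patient,
             co_in$generation_mode, co_in$seed)
    co_in <- make_cohort(co_in)
  }

  excluded <- data.frame(measurement = character(), reason = character())
  if (inherits(co_in, "mechanistic_cohort")) {
    rows <- list()
    for (m in co_in$measurements) {
      id <- sprintf("%s/c%d", m$patient$patient_id, m$condition)
      row <- tryCatch(analyze_measurement(m), error = function(e) {
        conditionMessage(e)
      })
      if (is.character(row)) {
        pipe_log(config, "excluding %s: %s", id, row)
        excluded <- rbind(excluded,
                          data.frame(measurement = id, reason = row))
      } else {
        rows[[length(rows) + 1L]] <- row
      }
    }
    n_gen <- length(co_in$measurements)
    if (length(rows) < n_gen / 2)
      stopf("more than half of the measurements failed analysis (%d of %d)",
            n_gen - length(rows), n_gen)
    cohort <- do.call(rbind, rows)
    class(cohort) <- c("cohort_table", class(cohort))
  } else {
    cohort <- complete_equation_cohort(as.data.frame(co_in))
    n_gen <- nrow(cohort)
  }

  model <- if (config$model == "published") published_dpl_model()
           else fit_dpl_model(cohort)
  pipe_log(config, "model: %s (R^2 = %.3f)", model$fitted_on, model$r2)

  cohort$dpl_eit <- predict_dpl(model, cohort$ibw_kg, cohort$ers,
                                cohort$roi1_pct, cohort$roi2_pct,
                                cohort$roi3_pct, warn = FALSE)
  cohort$el_eit <- derive_el_eit(cohort$dpl_eit, cohort$tv_ml)
  cohort$pi_eit <- suppressWarnings(
    derive_pi_eit(cohort$pplat, cohort$ers, cohort$el_eit))

  agreement <- agreement_report(cohort, loa_mult = config$loa_mult)

  n_analyzed <- sum(cohort$usable %in% TRUE)
  manifest <- list(
    tool = "ventdp", version = as.character(packageVersion("ventdp")),
    config_hash = config_hash(config),
    seeds = pipeline_seeds(config),
    counts = list(generated = n_gen, analyzed = n_analyzed,
                  excluded = n_gen - n_analyzed),
    excluded = excluded
  )
  stopifnot(manifest$counts$generated ==
              manifest$counts$analyzed + manifest$counts$excluded)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    write_model_json(model, file.path(config$out_dir, "model.json"))
    jsonlite::write_json(unclass_report(agreement),
                         file.path(config$out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(cohort = cohort, model = model, agreement = agreement,
                 manifest = manifest), class = "pipeline_result")
}

# Strip S3 classes so jsonlite serializes the report plainly.
unclass_report <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_report)
  else if (is.object(x)) unclass(x)
  else x
}

# Stable hash of the configuration (md5 of its canonical JSON).
config_hash <- function(config) {
  obj <- list(model = config$model, loa_mult = config$loa_mult,
              cohort = if (inherits(config$cohort, "cohort_spec"))
                unclass(config$cohort) else "external")
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

pipeline_seeds <- function(config) {
  if (inherits(config$cohort, "cohort_spec"))
    list(cohort = config$cohort$seed)
  else list()
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("ventdp pipeline: %d generated, %d analyzed, %d excluded\n",
              x$manifest$counts$generated, x$manifest$counts$analyzed,
              x$manifest$counts$excluded))
  print(x$model)
  print(x$agreement)
  invisible(x)
}
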
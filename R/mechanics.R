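# Ventilator-waveform mechanics: breath segmentation, occlusion-pause
# detection, and airway / esophageal (transpulmonary) mechanics for one
# measurement.
#
# Conventions: pressures cmH2O, flow ml/s (positive = inspiratory),
# volumes ml, elastances cmH2O/L. PEEPtot is the expiratory-pause airway
# pressure, i.e. it includes intrinsic PEEP by construction.

as_signal_df <- function(bundle) {
  if (inherits(bundle, "signal_bundle")) return(bundle$signals)
  stopifnot(is.data.frame(bundle), all(c("t", "flow", "paw") %in% names(bundle)))
  bundle
}

#' Segment ventilator waveforms into breaths
#'
#' A breath starts at a flow zero-upcrossing above `min_insp_flow` and ends
#' just before the next one (the final breath ends at the end of the record).
#' Inspired volume is the trapezoidal integral of positive flow over the
#' breath.
#'
#' @param bundle A `signal_bundle` or a data.frame with columns `t`, `paw`,
#'   `flow` (and optionally `peso`).
#' @param min_insp_flow Threshold (ml/s) a flow upcrossing must exceed to
#'   open a breath; inter-breath noise below it is ignored.
#' @return data.frame with one row per breath: `breath`, `start`, `end`
#'   (sample indices), `tv_ml`, `ppeak`. Zero rows (with a warning) if no
#'   breath is detectable.
#' @export
segment_breaths <- function(bundle, min_insp_flow = 100) {
  sig <- as_signal_df(bundle)
  fl <- sig$flow
  n <- length(fl)
  up <- which(fl[-1L] >= min_insp_flow & fl[-n] < min_insp_flow) + 1L
  if (length(up) == 0L) {
    warnf("no breath detected (no flow upcrossing above %g ml/s)", min_insp_flow)
    return(data.frame(breath = integer(), start = integer(), end = integer(),
                      tv_ml = numeric(), ppeak = numeric()))
  }
  starts <- up
  ends <- c(up[-1L] - 1L, n)
  tv <- vapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    trapz(sig$t[idx], pmax(fl[idx], 0))
  }, numeric(1))
  ppk <- vapply(seq_along(starts), function(i)
    max(sig$paw[starts[i]:ends[i]]), numeric(1))
  data.frame(breath = seq_along(starts), start = starts, end = ends,
             tv_ml = tv, ppeak = ppk)
}

#' Locate occlusion pauses within one breath
#'
#' Pauses are runs where `|flow| < flow_eps` lasting at least `min_dur_s`.
#' The inspiratory pause is the first such run after the peak inspiratory
#' flow; the expiratory pause is the last run of the breath (the passive
#' expiratory tail merges into it, which is why pause pressures are read as
#' the median over the final half of the window — that portion lies inside
#' the true occlusion and the median also suppresses the cardiac artifact on
#' Peso). A breath lacking two distinct windows is reported unusable.
#'
#' @param bundle A `signal_bundle` or signal data.frame (see
#'   [segment_breaths()]).
#' @param breath One row of the [segment_breaths()] output (or any list with
#'   `start`/`end` indices).
#' @param flow_eps Zero-flow threshold (ml/s).
#' @param min_dur_s Minimum pause duration (s).
#' @return List with `insp` and `exp` (each `c(start, end)` sample indices,
#'   or `NULL`) and `usable` (logical).
#' @export
detect_pauses <- function(bundle, breath, flow_eps = 10, min_dur_s = 0.2) {
  sig <- as_signal_df(bundle)
  idx <- breath$start:breath$end
  fl <- sig$flow[idx]
  fs <- 1 / median(diff(sig$t[idx]))
  min_len <- max(2L, ceiling(min_dur_s * fs))
  runs <- true_runs(abs(fl) < flow_eps)
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  pk <- which.max(fl)
  runs <- runs[runs$start > pk, , drop = FALSE]
  if (nrow(runs) < 2L)
    return(list(insp = NULL, exp = NULL, usable = FALSE))
  insp <- c(runs$start[1L], runs$end[1L]) + breath$start - 1L
  m <- nrow(runs)
  expw <- c(runs$start[m], runs$end[m]) + breath$start - 1L
  list(insp = insp, exp = expw, usable = TRUE)
}

# Median of a signal over the final half of a window (robust plateau readout).
pause_pressure <- function(x, window) {
  idx <- window[1L]:window[2L]
  half <- idx[(floor(length(idx) / 2) + 1L):length(idx)]
  median(x[half])
}

#' Extract per-breath landmarks from a measurement
#'
#' Runs [segment_breaths()] and [detect_pauses()] and reads the plateau
#' (Pplat), total PEEP, and the esophageal pressures at both pauses for every
#' breath. Breaths without both occlusion windows are flagged unusable;
#' breaths where noise inverts `ppeak >= pplat >= peep_tot` are flagged (not
#' dropped) via `ordered_ok`.
#'
#' @inheritParams segment_breaths
#' @inheritParams detect_pauses
#' @return data.frame of breath records: `breath`, `start`, `end`, `tv_ml`,
#'   `ppeak`, `pplat`, `peep_tot`, `peso_insp`, `peso_exp`, `usable`,
#'   `ordered_ok`.
#' @export
analyze_breaths <- function(bundle, min_insp_flow = 100, flow_eps = 10,
                            min_dur_s = 0.2) {
  sig <- as_signal_df(bundle)
  br <- segment_breaths(bundle, min_insp_flow)
  has_peso <- "peso" %in% names(sig)
  br$pplat <- br$peep_tot <- br$peso_insp <- br$peso_exp <- NA_real_
  br$usable <- FALSE
  for (i in seq_len(nrow(br))) {
    pw <- detect_pauses(bundle, br[i, ], flow_eps, min_dur_s)
    if (!pw$usable) next
    br$pplat[i] <- pause_pressure(sig$paw, pw$insp)
    br$peep_tot[i] <- pause_pressure(sig$paw, pw$exp)
    if (has_peso) {
      br$peso_insp[i] <- pause_pressure(sig$peso, pw$insp)
      br$peso_exp[i] <- pause_pressure(sig$peso, pw$exp)
    }
    br$usable[i] <- TRUE
  }
  br$ordered_ok <- !br$usable | (br$ppeak >= br$pplat - 1e-9 &
                                   br$pplat >= br$peep_tot - 1e-9)
  br
}

#' Summarize respiratory mechanics over a measurement
#'
#' Averages per-breath landmark pressures and inspired volume over up to the
#' last `n_breaths` usable breaths, then applies the standard partitioning
#' formulas to the averages:
#' \deqn{DP = Pplat - PEEPtot, \quad Ers = DP / TV}
#' \deqn{P_L = Paw - Peso \; (at each pause), \quad DP_L = P_{L,insp} - P_{L,exp}}
#' \deqn{EL = DP_L / TV, \quad Ecw = Ers - EL, \quad PI = Pplat \cdot EL / Ers}
#' with TV in litres for the elastances. Setting `per_breath = TRUE` instead
#' computes the mechanics per breath and averages those (a second-order
#' difference).
#'
#' @param breaths Output of [analyze_breaths()] (or a compatible data.frame
#'   with the landmark columns).
#' @param with_peso Compute the esophageal (transpulmonary) chain; requires
#'   `peso_insp`/`peso_exp`.
#' @param n_breaths Maximum number of (most recent) usable breaths averaged.
#' @param per_breath Average per-breath mechanics instead of landmarks.
#' @return An object of class `mechanics_summary`: list with `tv_ml`,
#'   `ppeak`, `pplat`, `peep_tot`, `dp`, `ers`, and (with Peso) `pl_insp`,
#'   `pl_exp`, `dpl`, `el`, `ecw`, `pi`; plus `n_breaths_used`.
#' @examples
#' p <- patient_params(el_true = 18, ecw_true = 9)
#' b <- simulate_vcv(p, vcv_scenario(peep_set = 10))
#' summarize_mechanics(analyze_breaths(b))
#' @export
summarize_mechanics <- function(breaths, with_peso = TRUE, n_breaths = 10,
                                per_breath = FALSE) {
  use <- breaths[breaths$usable & breaths$tv_ml > 0, , drop = FALSE]
  if (nrow(use) == 0L) stopf("no usable breath (need detectable pauses)")
  use <- tail(use, n_breaths)
  if (with_peso && anyNA(c(use$peso_insp, use$peso_exp)))
    stopf("with_peso = TRUE but esophageal landmarks are missing")

  one <- function(d) {
    tv_l <- d$tv_ml / 1000
    out <- list(tv_ml = d$tv_ml, ppeak = d$ppeak, pplat = d$pplat,
                peep_tot = d$peep_tot,
                dp = d$pplat - d$peep_tot,
                ers = (d$pplat - d$peep_tot) / tv_l)
    if (with_peso) {
      out$pl_insp <- d$pplat - d$peso_insp
      out$pl_exp <- d$peep_tot - d$peso_exp
      out$dpl <- out$pl_insp - out$pl_exp
      out$el <- out$dpl / tv_l
      out$ecw <- out$ers - out$el
      out$pi <- d$pplat * (out$el / out$ers)
    }
    out
  }

  if (per_breath) {
    per <- lapply(seq_len(nrow(use)), function(i) one(use[i, ]))
    res <- lapply(setNames(nm = names(per[[1L]])), function(f)
      mean(vapply(per, `[[`, numeric(1), f)))
  } else {
    cols <- intersect(c("tv_ml", "ppeak", "pplat", "peep_tot",
                        "peso_insp", "peso_exp"), names(use))
    res <- one(as.list(colMeans(use[, cols])))
  }
  if (res$ers <= 0) stopf("non-physiologic Ers <= 0 (%.3f cmH2O/L)", res$ers)
  res$n_breaths_used <- nrow(use)
  structure(res, class = "mechanics_summary")
}

#' @export
print.mechanics_summary <- function(x, ...) {
  cat("Respiratory mechanics (", x$n_breaths_used, " breaths averaged)\n", sep = "")
  cat(sprintf("  TV %.0f ml | Ppeak %.1f | Pplat %.1f | PEEPtot %.1f cmH2O\n",
              x$tv_ml, x$ppeak, x$pplat, x$peep_tot))
  cat(sprintf("  DP %.2f cmH2O | Ers %.1f cmH2O/L\n", x$dp, x$ers))
  if (!is.null(x$dpl))
    cat(sprintf("  DP_L %.2f cmH2O | EL %.1f | Ecw %.1f cmH2O/L | PI %.2f cmH2O\n",
                x$dpl, x$el, x$ecw, x$pi))
  invisible(x)
}

#' Baydur occlusion test
#'
#' Validity check of esophageal balloon positioning: during an end-expiratory
#' airway occlusion with respiratory efforts, the esophageal pressure swing
#' should track the airway pressure swing. Returns the ratio of peak-to-trough
#' Peso swing to peak-to-trough Paw swing; ratios within \[0.8, 1.2\] are
#' conventionally considered valid.
#'
#' @param paw,peso Paired pressure series over the occlusion segment (cmH2O).
#' @param valid_range Acceptance band for the ratio.
#' @return List with `ratio`, `paw_swing`, `peso_swing`, `valid`.
#' @examples
#' occ <- simulate_occlusion(paw_swing = 5, ratio = 1)
#' occlusion_test(occ$paw, occ$peso)$valid
#' @export
occlusion_test <- function(paw, peso, valid_range = c(0.8, 1.2)) {
  stopifnot(length(paw) == length(peso), length(paw) >= 2L)
  paw_swing <- max(paw) - min(paw)
  peso_swing <- max(peso) - min(peso)
  if (paw_swing < 1e-9 || peso_swing < 1e-9)
    stopf("no oscillation detected in the occlusion segment")
  ratio <- peso_swing / paw_swing
  list(ratio = ratio, paw_swing = paw_swing, peso_swing = peso_swing,
       valid = ratio >= valid_range[1L] && ratio <= valid_range[2L])
}
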
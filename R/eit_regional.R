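# EIT regional analysis: ensemble tidal image, four ventral-to-dorsal
# regions of interest (ROI), and IBW-weighted regional compliance.

# Accepts a frame matrix of width 4 (pre-summed bands, ventral to dorsal) or
# 1024 (row-major 32x32 image, row 1 most ventral).
check_frames <- function(frames) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1L)
  if (!ncol(frames) %in% c(4L, 1024L))
    stopf("EIT frames must have 4 (band sums) or 1024 (32x32 image) columns, got %d",
          ncol(frames))
  frames
}

#' Ensemble tidal image over the last breaths of a measurement
#'
#' For each annotated breath, the tidal impedance change is the per-pixel
#' (or per-band) median frame over the end-inspiratory pause window minus the
#' median frame over the end-expiratory pause window — the same landmarks the
#' pressure mechanics use. The ensemble image is the mean tidal change over
#' the last `min(n_breaths, available)` breaths. Pixels with negative tidal
#' change (pendelluft or artifact) are floored at zero; the count is attached
#' as attribute `"n_floored"`.
#'
#' @param frames Matrix of EIT frames, one row per frame, 4 or 1024 columns.
#' @param t_frames Frame time stamps (s); defaults to `attr(frames, "t")`.
#' @param windows data.frame with one row per breath and columns
#'   `insp_start_t`, `insp_end_t`, `exp_start_t`, `exp_end_t` (seconds), e.g.
#'   from [pause_windows_times()].
#' @param n_breaths Number of most recent breaths to average (default 10).
#' @return Numeric vector (length 4 or 1024): the ensemble tidal impedance
#'   change, with attributes `n_breaths_used` and `n_floored`.
#' @export
ensemble_tidal_image <- function(frames, windows, t_frames = attr(frames, "t"),
                                 n_breaths = 10) {
  frames <- check_frames(frames)
  if (is.null(t_frames) || length(t_frames) != nrow(frames))
    stopf("frame time stamps missing or wrong length")
  per_breath <- list()
  for (i in seq_len(nrow(windows))) {
    ii <- which(t_frames >= windows$insp_start_t[i] &
                  t_frames <= windows$insp_end_t[i])
    ie <- which(t_frames >= windows$exp_start_t[i] &
                  t_frames <= windows$exp_end_t[i])
    if (length(ii) == 0L || length(ie) == 0L) next
    med <- function(ix) apply(frames[ix, , drop = FALSE], 2L, median)
    per_breath[[length(per_breath) + 1L]] <- med(ii) - med(ie)
  }
  if (length(per_breath) == 0L)
    stopf("no annotated breath overlaps the EIT frame series")
  per_breath <- tail(per_breath, n_breaths)
  dz <- Reduce(`+`, per_breath) / length(per_breath)
  n_floored <- sum(dz < 0)
  dz <- pmax(dz, 0)
  attr(dz, "n_breaths_used") <- length(per_breath)
  attr(dz, "n_floored") <- n_floored
  dz
}

#' Pause-window times for EIT alignment
#'
#' Converts the sample-index pause windows found on the waveform time base by
#' [detect_pauses()] into the time windows [ensemble_tidal_image()] needs.
#'
#' @inheritParams analyze_breaths
#' @return data.frame with one row per usable breath: `breath`,
#'   `insp_start_t`, `insp_end_t`, `exp_start_t`, `exp_end_t`.
#' @export
pause_windows_times <- function(bundle, min_insp_flow = 100, flow_eps = 10,
                                min_dur_s = 0.2) {
  sig <- as_signal_df(bundle)
  br <- segment_breaths(bundle, min_insp_flow)
  out <- list()
  for (i in seq_len(nrow(br))) {
    pw <- detect_pauses(bundle, br[i, ], flow_eps, min_dur_s)
    if (!pw$usable) next
    out[[length(out) + 1L]] <- data.frame(
      breath = br$breath[i],
      insp_start_t = sig$t[pw$insp[1L]], insp_end_t = sig$t[pw$insp[2L]],
      exp_start_t = sig$t[pw$exp[1L]], exp_end_t = sig$t[pw$exp[2L]])
  }
  if (length(out) == 0L)
    return(data.frame(breath = integer(), insp_start_t = numeric(),
                      insp_end_t = numeric(), exp_start_t = numeric(),
                      exp_end_t = numeric()))
  do.call(rbind, out)
}

#' Percentage of tidal ventilation in four ventral-to-dorsal ROIs
#'
#' The 32x32 tidal image is divided into four equal-height horizontal bands
#' (rows 1-8, 9-16, 17-24, 25-32; row 1 most ventral, so ROI1 is the ventral
#' band and ROI4 the dorsal band) and each band's share of the total tidal
#' impedance change is expressed in percent. Length-4 input (pre-summed
#' bands) is normalized directly.
#'
#' @param tidal Tidal image: numeric vector of length 1024 (row-major 32x32)
#'   or 4, or a 32x32 matrix (row 1 ventral).
#' @return Named length-4 vector `roi1..roi4` summing to 100.
#' @examples
#' roi_fractions(c(19, 37, 31, 13))
#' @export
roi_fractions <- function(tidal) {
  if (is.matrix(tidal) && all(dim(tidal) == c(32L, 32L)))
    tidal <- as.vector(t(tidal))          # row-major flattening
  tidal <- as.numeric(tidal)
  if (length(tidal) == 1024L) {
    band <- rep(1:4, each = 256L)         # 8 image rows of 32 px per band
    sums <- tapply(tidal, band, sum)
  } else if (length(tidal) == 4L) {
    sums <- tidal
  } else {
    stopf("tidal image must have length 4 or 1024 (got %d)", length(tidal))
  }
  if (any(sums < 0)) stopf("tidal image has negative band sums")
  total <- sum(sums)
  if (total <= 0) stopf("no tidal signal (total impedance change is zero)")
  setNames(100 * as.numeric(sums) / total, paste0("roi", 1:4))
}

#' IBW-weighted regional compliance
#'
#' \deqn{RC_{ROI,i} = \frac{TV \cdot ROI\%_i / 100}{DP \cdot IBW}}
#' in ml/cmH2O/kg of ideal body weight. The four values sum to the specific
#' compliance `(TV/DP)/IBW`.
#'
#' @param tv_ml Tidal volume (ml).
#' @param roi_pct Length-4 ROI percentages (summing to 100).
#' @param dp Driving pressure (cmH2O), must be positive.
#' @param ibw_kg Ideal body weight (kg), must be positive.
#' @return Named length-4 vector of regional compliances.
#' @examples
#' regional_compliance(375, c(19, 37, 31, 13), dp = 10, ibw_kg = 60)
#' @export
regional_compliance <- function(tv_ml, roi_pct, dp, ibw_kg) {
  if (!is_number(dp) || dp <= 0) stopf("dp must be a positive number")
  if (!is_number(ibw_kg) || ibw_kg <= 0) stopf("ibw_kg must be positive")
  stopifnot(length(roi_pct) == 4L)
  setNames(tv_ml * (roi_pct / 100) / dp / ibw_kg, paste0("rc_roi", 1:4))
}

#' Regional tidal analysis of one measurement
#'
#' Convenience wrapper chaining [pause_windows_times()],
#' [ensemble_tidal_image()], [roi_fractions()] and [regional_compliance()].
#'
#' @param frames EIT frame matrix (see [ensemble_tidal_image()]).
#' @param bundle Waveform bundle for breath/pause annotation.
#' @param tv_ml,dp,ibw_kg Mechanics inputs for the compliance weighting.
#' @param n_breaths Breaths averaged in the ensemble.
#' @return List of class `roi_tidal`: `roi_pct`, `rc_roi`, `n_breaths_used`,
#'   `n_floored`.
#' @export
roi_tidal <- function(frames, bundle, tv_ml, dp, ibw_kg, n_breaths = 10) {
  win <- pause_windows_times(bundle)
  dz <- ensemble_tidal_image(frames, win, n_breaths = n_breaths)
  pct <- roi_fractions(as.numeric(dz))
  structure(list(roi_pct = pct,
                 rc_roi = regional_compliance(tv_ml, pct, dp, ibw_kg),
                 n_breaths_used = attr(dz, "n_breaths_used"),
                 n_floored = attr(dz, "n_floored")),
            class = "roi_tidal")
}
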
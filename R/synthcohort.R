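# Synthetic ARDS cohort generation: virtual patients, ventilator / esophageal
# waveforms under volume-controlled ventilation (VCV), EIT band signals, and
# cohort tables with the panel structure (patient x PEEP condition) the
# downstream analysis assumes.

# Severity strata for lung elastance (EL, cmH2O/L). Chosen to bracket a
# typical ARDS cohort whose median EL is ~18 (IQR 14-23); chest-wall
# elastance (Ecw) is drawn from [5, 15] cmH2O/L for every stratum.
.severity_el_ranges <- list(
  mild     = c(8, 15),
  moderate = c(12, 30),
  severe   = c(25, 45)
)
.ecw_range <- c(5, 15)
.rrs_range <- c(8, 15)          # airway resistance, cmH2O.s/L
.roi_base_median <- c(0.19, 0.37, 0.31, 0.13)   # ventral -> dorsal
.roi_slope_base <- c(-0.004, -0.002, 0.003, 0.003)  # per cmH2O PEEP

#' Ideal body weight by the Devine formula
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height in centimetres.
#' @return Ideal body weight in kg.
#' @examples
#' devine_ibw("male", 175)
#' @export
devine_ibw <- function(sex, height_cm) {
  sex <- match.arg(sex, c("male", "female"))
  base <- if (sex == "male") 50 else 45.5
  base + 0.91 * (height_cm - 152.4)
}

#' Construct a virtual-patient parameter set
#'
#' Lower-level constructor used by [make_patient()]; all respiratory-mechanics
#' parameters can be supplied directly, which is convenient for closed-form
#' checks. `roi_base` is the ventral-to-dorsal 4-vector of tidal-ventilation
#' fractions at zero PEEP; `roi_peep_slope` shifts the fractions linearly with
#' PEEP (they are clamped to be non-negative and renormalized to sum to 1 at
#' every PEEP).
#'
#' @param patient_id Character id.
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height (cm).
#' @param el_true Lung elastance (cmH2O/L).
#' @param ecw_true Chest-wall elastance (cmH2O/L).
#' @param rrs Airway resistance (cmH2O.s/L).
#' @param roi_base Length-4 non-negative vector summing to 1.
#' @param roi_peep_slope Length-4 vector, change in fraction per cmH2O PEEP.
#' @param pleural_baseline End-expiratory pleural (esophageal) pressure at
#'   zero lung volume above FRC (cmH2O).
#' @param ibw_kg Ideal body weight; defaults to the Devine formula.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(patient_id = "P01", sex = "male", height_cm = 175,
                           el_true = 18, ecw_true = 9, rrs = 10,
                           roi_base = .roi_base_median,
                           roi_peep_slope = .roi_slope_base,
                           pleural_baseline = 5,
                           ibw_kg = devine_ibw(sex, height_cm)) {
  stopifnot(el_true > 0, ecw_true > 0, rrs > 0, ibw_kg > 0,
            length(roi_base) == 4L, all(roi_base >= 0),
            length(roi_peep_slope) == 4L)
  if (abs(sum(roi_base) - 1) > 1e-8)
    stopf("roi_base must sum to 1 (got %.6f)", sum(roi_base))
  structure(list(
    patient_id = patient_id, sex = sex, height_cm = height_cm,
    ibw_kg = ibw_kg, el_true = el_true, ecw_true = ecw_true,
    ers_true = el_true + ecw_true, rrs = rrs,
    roi_base = roi_base / sum(roi_base),
    roi_peep_slope = roi_peep_slope,
    pleural_baseline = pleural_baseline
  ), class = "patient_params")
}

#' Draw a virtual ARDS patient
#'
#' Draws patient covariates and true mechanics from severity-stratified
#' ranges: EL uniform on \[8,15\] (mild), \[12,30\] (moderate) or \[25,45\]
#' (severe) cmH2O/L, Ecw uniform on \[5,15\] cmH2O/L, resistance uniform on
#' \[8,15\] cmH2O.s/L; baseline ROI fractions are perturbed around the
#' ventral-to-dorsal profile (0.19, 0.37, 0.31, 0.13) and redistribute
#' dorsally with PEEP. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param patient_id Optional id (default derived from the seed).
#' @return A [patient_params()] object.
#' @examples
#' p <- make_patient(1, "moderate")
#' p$ers_true
#' @export
make_patient <- function(seed, severity = c("moderate", "mild", "severe"),
                         patient_id = sprintf("P%04d", seed %% 10000L)) {
  severity <- match.arg(severity)
  el_range <- .severity_el_ranges[[severity]]
  local_seed(seed, {
    sex <- sample(c("male", "female"), 1L, prob = c(13, 7))
    height_cm <- rnorm(1L, if (sex == "male") 175 else 162, 7)
    height_cm <- min(max(height_cm, 145), 200)
    el <- runif(1L, el_range[1L], el_range[2L])
    ecw <- runif(1L, .ecw_range[1L], .ecw_range[2L])
    rrs <- runif(1L, .rrs_range[1L], .rrs_range[2L])
    roi <- pmax(.roi_base_median + rnorm(4L, 0, 0.04), 0.01)
    roi <- roi / sum(roi)
    slope <- .roi_slope_base + rnorm(4L, 0, 0.001)
    pb <- runif(1L, 3, 8)
    patient_params(patient_id = patient_id, sex = sex, height_cm = height_cm,
                   el_true = el, ecw_true = ecw, rrs = rrs,
                   roi_base = roi, roi_peep_slope = slope,
                   pleural_baseline = pb)
  })
}

#' Ventilation fractions at a given PEEP
#'
#' Applies the patient's linear PEEP-dependent redistribution to the baseline
#' ROI fractions, clamps at zero and renormalizes so the four fractions stay
#' in \[0,1\] and sum to 1.
#'
#' @param params A [patient_params()] object.
#' @param peep PEEP (cmH2O).
#' @return Length-4 fraction vector (ventral to dorsal).
#' @export
fractions_at_peep <- function(params, peep) {
  f <- pmax(params$roi_base + params$roi_peep_slope * peep, 0)
  if (sum(f) <= 0) stopf("degenerate ROI fractions at PEEP %.1f", peep)
  f / sum(f)
}

#' Ventilator scenario for VCV simulation
#'
#' Defaults reflect lung-protective ventilation in a sedated, paralyzed ARDS
#' cohort: tidal volume 6 ml/kg IBW delivered as a square inspiratory flow
#' wave, respiratory rate 19/min, end-inspiratory and end-expiratory
#' occlusion pauses of 0.5 s on every breath, waveforms sampled at 100 Hz and
#' EIT at 20 Hz.
#'
#' @param peep_set Set PEEP (cmH2O).
#' @param tv_per_kg Tidal volume per kg IBW (ml/kg).
#' @param resp_rate Breaths per minute.
#' @param insp_flow Square-wave inspiratory flow (ml/s).
#' @param pause_insp_s,pause_exp_s Occlusion pause durations (s).
#' @param n_breaths Number of breaths simulated (>= 12 so that 10 remain
#'   after edge trimming).
#' @param fs_waveform Waveform sampling rate (Hz).
#' @param fs_eit EIT frame rate (Hz); must satisfy `fs_waveform >= 4 * fs_eit`.
#' @param noise_sd_paw,noise_sd_peso Gaussian noise SD on Paw / Peso (cmH2O).
#' @param cardiac_amp Amplitude of the 1.3 Hz cardiac artifact on Peso
#'   (cmH2O).
#' @param seed Integer seed for the noise draws (`NULL` = noiseless streams
#'   still deterministic).
#' @return An object of class `vcv_scenario`.
#' @export
vcv_scenario <- function(peep_set = 13, tv_per_kg = 6, resp_rate = 19,
                         insp_flow = 1000, pause_insp_s = 0.5,
                         pause_exp_s = 0.5, n_breaths = 14,
                         fs_waveform = 100, fs_eit = 20,
                         noise_sd_paw = 0, noise_sd_peso = 0,
                         cardiac_amp = 0, seed = NULL) {
  stopifnot(tv_per_kg >= 0, resp_rate > 0, insp_flow > 0,
            pause_insp_s >= 0, pause_exp_s >= 0, n_breaths >= 1)
  if (fs_waveform < 4 * fs_eit)
    stopf("fs_waveform (%g Hz) must be >= 4 x fs_eit (%g Hz)",
          fs_waveform, fs_eit)
  structure(as.list(environment()), class = "vcv_scenario")
}

#' Simulate ventilator and esophageal waveforms under VCV
#'
#' Single-compartment equation of motion with the elastance partitioned into
#' lung and chest wall:
#' \deqn{Paw(t) = PEEP + Rrs \dot V(t) + Ers V(t)}
#' \deqn{Peso(t) = baseline + Ecw V(t) + cardiac + noise}
#' Inspiration is a square flow wave delivering TV = `tv_per_kg * ibw_kg`;
#' expiration is passive with time constant `Rrs/Ers` (so that Paw relaxes to
#' PEEP while flow is negative); during occlusion pauses flow is exactly
#' zero. Breaths start from the steady-state residual volume, so the flow
#' integral over any complete cycle is zero and
#' `Pplat - PEEPtot = Ers * TV` holds exactly in the noiseless case.
#'
#' @param params A [patient_params()] object.
#' @param scenario A [vcv_scenario()] object.
#' @return A `signal_bundle`: list with `signals` (data.frame `t`, `paw`,
#'   `flow`, `peso`), `volume_ml` (true volume above end-expiratory lung
#'   volume at PEEP), `annotations` (per-breath sample and pause-window index
#'   ranges), `fs`, and the generating `params`/`scenario`.
#' @examples
#' p <- patient_params(el_true = 18, ecw_true = 9)
#' b <- simulate_vcv(p, vcv_scenario(peep_set = 10, n_breaths = 12))
#' range(b$signals$paw)
#' @export
simulate_vcv <- function(params, scenario) {
  stopifnot(inherits(params, "patient_params"),
            inherits(scenario, "vcv_scenario"))
  s <- scenario
  tv_ml <- s$tv_per_kg * params$ibw_kg
  t_cycle <- 60 / s$resp_rate
  t_insp <- tv_ml / s$insp_flow
  t_exp <- t_cycle - t_insp - s$pause_insp_s - s$pause_exp_s
  if (t_exp <= 0)
    stopf(paste0("infeasible timing: inspiratory time (%.2f s) + pauses ",
                 "(%.2f s) leave no expiratory time in a %.2f s cycle"),
          t_insp, s$pause_insp_s + s$pause_exp_s, t_cycle)
  ers <- params$ers_true
  tau <- params$rrs / ers
  # steady-state residual volume above relaxation volume at PEEP
  q <- exp(-t_exp / tau)
  v_res <- if (tv_ml > 0) tv_ml * q / (1 - q) else 0

  fs <- s$fs_waveform
  n <- round(s$n_breaths * t_cycle * fs)
  t <- (seq_len(n) - 1L) / fs

  # volume above the relaxation volume at PEEP; periodic in the cycle since
  # every breath starts from the steady-state residual volume
  v_of <- function(tt) {
    tl <- ((tt %% t_cycle) + t_cycle) %% t_cycle
    v <- rep(v_res, length(tl))
    if (tv_ml > 0) {
      ii <- tl < t_insp
      v[ii] <- v_res + s$insp_flow * tl[ii]
      ip <- !ii & tl < t_insp + s$pause_insp_s
      v[ip] <- v_res + tv_ml
      ie <- !ii & !ip & tl < t_insp + s$pause_insp_s + t_exp
      v[ie] <- (v_res + tv_ml) * exp(-(tl[ie] - t_insp - s$pause_insp_s) / tau)
    }
    v
  }
  v <- v_of(t)
  # flow as the sample-window mean of dV/dt (a real flow sensor averages over
  # its sampling interval); keeps the trapezoidal integral consistent with
  # the volume trace across the square-wave edges
  h <- 1 / fs
  flow <- (v_of(t + h / 2) - v_of(t - h / 2)) / h
  # force exact zeros inside the occlusion pauses
  tl <- t %% t_cycle
  pause_mask <- (tl >= t_insp + h / 2 & tl < t_insp + s$pause_insp_s - h / 2) |
    (tl >= t_insp + s$pause_insp_s + t_exp + h / 2)
  flow[pause_mask] <- 0
  if (tv_ml == 0) flow[] <- 0

  paw <- s$peep_set + params$rrs * (flow / 1000) + ers * (v / 1000)
  peso <- params$pleural_baseline + params$ecw_true * (v / 1000)
  if (s$cardiac_amp > 0)
    peso <- peso + s$cardiac_amp * sin(2 * pi * 1.3 * t)
  if (s$noise_sd_paw > 0 || s$noise_sd_peso > 0) {
    noise <- local_seed(s$seed %||% 0L, list(
      paw = rnorm(n, 0, s$noise_sd_paw),
      peso = rnorm(n, 0, s$noise_sd_peso)
    ))
    paw <- paw + noise$paw
    peso <- peso + noise$peso
  }

  idx_at <- function(tt) pmin(pmax(floor(tt * fs) + 1L, 1L), n)
  k <- seq_len(s$n_breaths) - 1L
  ann <- data.frame(
    breath = k + 1L,
    start = idx_at(k * t_cycle),
    end = idx_at((k + 1L) * t_cycle) - 1L,
    insp_start = idx_at(k * t_cycle + t_insp),
    insp_end = idx_at(k * t_cycle + t_insp + s$pause_insp_s) - 1L,
    exp_start = idx_at(k * t_cycle + t_insp + s$pause_insp_s + t_exp),
    exp_end = idx_at((k + 1L) * t_cycle) - 1L
  )
  ann$end[nrow(ann)] <- n
  ann$exp_end[nrow(ann)] <- n

  structure(list(
    signals = data.frame(t = t, paw = paw, flow = flow, peso = peso),
    volume_ml = v,
    annotations = ann,
    fs = fs,
    tv_ml = tv_ml,
    params = params,
    scenario = s
  ), class = "signal_bundle")
}

#' Simulate EIT band signals from a volume trace
#'
#' Each ventral-to-dorsal band carries an impedance signal proportional to
#' its share of the regional volume: `band_i(t) = f_i(PEEP) * V(t)` resampled
#' to the EIT frame rate, plus optional Gaussian noise. With `as_image =
#' TRUE` each band's signal is spread uniformly over its 8 rows of a 32x32
#' image (row-major, row 1 most ventral), so band sums reproduce the
#' generating fractions.
#'
#' @param params A [patient_params()] object.
#' @param volume_ml Volume trace (ml) at times `t`.
#' @param t Time stamps of `volume_ml` (s).
#' @param peep PEEP used for the fraction shift (cmH2O).
#' @param fs_eit EIT frame rate (Hz).
#' @param noise_sd Gaussian noise SD added per band (ml-equivalent impedance
#'   units).
#' @param as_image Return (n_frames x 1024) images instead of (n_frames x 4)
#'   band sums.
#' @param seed Seed for the noise draws.
#' @return Numeric matrix with attribute `"t"` (frame times); columns
#'   `roi1..roi4` or `px0001..px1024`.
#' @export
simulate_eit <- function(params, volume_ml, t, peep, fs_eit = 20,
                         noise_sd = 0, as_image = FALSE, seed = NULL) {
  stopifnot(length(volume_ml) == length(t), all(volume_ml >= -1e-9))
  f <- fractions_at_peep(params, peep)
  t_eit <- seq(t[1L], t[length(t)], by = 1 / fs_eit)
  v_eit <- approx(t, volume_ml, xout = t_eit)$y
  bands <- outer(v_eit, f)
  if (noise_sd > 0)
    bands <- bands + local_seed(seed %||% 0L,
                                matrix(rnorm(length(bands), 0, noise_sd),
                                       nrow = nrow(bands)))
  if (as_image) {
    img <- matrix(0, nrow = length(t_eit), ncol = 1024L)
    for (i in 1:4) {
      px <- ((i - 1L) * 256L + 1L):(i * 256L)
      img[, px] <- bands[, i] / 256
    }
    colnames(img) <- sprintf("px%04d", 1:1024)
    bands <- img
  } else {
    colnames(bands) <- paste0("roi", 1:4)
  }
  attr(bands, "t") <- t_eit
  bands
}

#' Simulate an end-expiratory occlusion with respiratory-effort oscillations
#'
#' Generates the paired Paw/Peso segment used for the Baydur occlusion test:
#' during an airway occlusion, inspiratory efforts swing both pressures; a
#' well-positioned esophageal balloon transmits the swing with a ratio near
#' 1. `ratio` is the simulated Peso/Paw swing ratio.
#'
#' @param paw_swing Peak-to-trough airway pressure swing (cmH2O).
#' @param ratio Simulated transmission ratio Peso swing / Paw swing.
#' @param peep Airway pressure baseline (cmH2O).
#' @param peso_baseline Esophageal baseline (cmH2O).
#' @param duration_s,fs Segment length and sampling rate.
#' @param f_effort Effort frequency (Hz).
#' @return data.frame with columns `t`, `paw`, `peso`.
#' @export
simulate_occlusion <- function(paw_swing = 5, ratio = 1, peep = 5,
                               peso_baseline = 8, duration_s = 6, fs = 100,
                               f_effort = 0.4) {
  t <- seq(0, duration_s, by = 1 / fs)
  effort <- -(paw_swing / 2) * (1 - cos(2 * pi * f_effort * t))
  data.frame(t = t, paw = peep + effort, peso = peso_baseline + ratio * effort)
}

#' Cohort specification
#'
#' Covariate centers default to the pooled-measurement medians of a typical
#' 20-patient ARDS panel (IBW 65 kg, Ers 27 cmH2O/L, ROI1-3 tidal fractions
#' 19/37/31 %, TV 375 ml); spreads are calibrated so the interquartile ranges
#' match that panel (IQR/1.349 for a normal). In `"equation"` mode the
#' measured DP_L of every row is the five-regressor linear prediction
#' evaluated at the drawn covariates plus `N(0, dpl_noise_sd)`; in
#' `"mechanistic"` mode full waveforms and EIT frames are simulated per
#' measurement and DP_L is left to the analysis chain.
#'
#' @param n_patients Number of patients (>= 2).
#' @param conditions_per_patient PEEP conditions per patient (default 3).
#' @param peep_levels PEEP values cycled across conditions (cmH2O).
#' @param ibw_center,ibw_spread IBW draw (kg).
#' @param ers_center,ers_spread Ers draw (cmH2O/L), truncated to \[5, 80\].
#' @param roi_centers,roi_spreads Length-3 centers/spreads for ROI1-3 (%),
#'   truncated to \[0, 100\].
#' @param tv_center,tv_spread Tidal volume draw (ml).
#' @param dpl_noise_sd SD of the Gaussian noise added to the equation-mode
#'   DP_L (cmH2O).
#' @param generation_mode `"equation"` or `"mechanistic"`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20, conditions_per_patient = 3,
                        peep_levels = c(9, 13, 15),
                        ibw_center = 65, ibw_spread = 10,
                        ers_center = 27, ers_spread = 8.9,
                        roi_centers = c(19, 37, 31),
                        roi_spreads = c(5.2, 6.7, 5.9),
                        tv_center = 375, tv_spread = 40,
                        dpl_noise_sd = 1.2,
                        generation_mode = c("equation", "mechanistic"),
                        seed = 1L) {
  generation_mode <- match.arg(generation_mode)
  stopifnot(n_patients >= 2, conditions_per_patient >= 1, dpl_noise_sd >= 0,
            length(roi_centers) == 3L, length(roi_spreads) == 3L)
  structure(as.list(environment()), class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort table
#'
#' Equation mode draws a patient-by-condition panel of covariates (a
#' patient-level and a condition-level normal component, each carrying half
#' the stated variance) and sets the measured DP_L to the published
#' five-regressor equation plus noise; the noiseless value is retained in
#' `dpl_true` for recovery tests. Mechanistic mode simulates full waveform
#' and EIT data per measurement (see [simulate_vcv()]); severities are
#' assigned in the 6/9/5 mild/moderate/severe proportion.
#'
#' @param spec A [cohort_spec()].
#' @return Equation mode: a `cohort_table` data.frame with one row per
#'   measurement (`patient_id`, `condition`, `peep`, `ibw_kg`, `tv_ml`,
#'   `ers`, `roi1_pct..roi4_pct`, `dpl_true`, `dpl`, `usable`). Mechanistic
#'   mode: a `mechanistic_cohort` list of measurements each holding the
#'   generating patient, scenario, signal bundle, EIT frames and ground
#'   truth.
#' @examples
#' co <- make_cohort(cohort_spec(n_patients = 4, seed = 2))
#' nrow(co)
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  switch(spec$generation_mode,
         equation = make_cohort_equation(spec),
         mechanistic = make_cohort_mechanistic(spec),
         stopf("unknown generation_mode '%s'", spec$generation_mode))
}

make_cohort_equation <- function(spec) {
  np <- spec$n_patients
  k <- spec$conditions_per_patient
  m <- published_dpl_model()
  local_seed(spec$seed, {
    ibw <- clamp(rnorm(np, spec$ibw_center, spec$ibw_spread), 35, 120)
    tv <- clamp(rnorm(np, spec$tv_center, spec$tv_spread), 250, 600)
    b_sd <- sqrt(0.5)   # between-patient share of the covariate variance
    w_sd <- sqrt(0.5)
    ers_b <- rnorm(np, 0, b_sd * spec$ers_spread)
    roi_b <- sapply(1:3, function(j) rnorm(np, 0, b_sd * spec$roi_spreads[j]))
    rows <- do.call(rbind, lapply(seq_len(np), function(i) {
      ers <- clamp(spec$ers_center + ers_b[i] +
                     rnorm(k, 0, w_sd * spec$ers_spread), 5, 80)
      roi <- sapply(1:3, function(j)
        clamp(spec$roi_centers[j] + roi_b[i, j] +
                rnorm(k, 0, w_sd * spec$roi_spreads[j]), 0, 100))
      roi4 <- pmax(100 - rowSums(roi), 0)
      data.frame(
        patient_id = sprintf("P%02d", i),
        condition = seq_len(k),
        peep = rep_len(spec$peep_levels, k),
        ibw_kg = ibw[i], tv_ml = tv[i],
        ers = ers,
        roi1_pct = roi[, 1], roi2_pct = roi[, 2], roi3_pct = roi[, 3],
        roi4_pct = roi4
      )
    }))
    rows$dpl_true <- predict_dpl(m, rows$ibw_kg, rows$ers, rows$roi1_pct,
                                 rows$roi2_pct, rows$roi3_pct, warn = FALSE)
    rows$dpl <- rows$dpl_true + rnorm(nrow(rows), 0, spec$dpl_noise_sd)
    rows$usable <- TRUE
    class(rows) <- c("cohort_table", class(rows))
    attr(rows, "spec") <- spec
    rows
  })
}

make_cohort_mechanistic <- function(spec) {
  np <- spec$n_patients
  k <- spec$conditions_per_patient
  sev_counts <- round(np * c(mild = 6, moderate = 9, severe = 5) / 20)
  sev_counts["moderate"] <- np - sev_counts["mild"] - sev_counts["severe"]
  severities <- rep(names(sev_counts), times = sev_counts)
  subseeds <- local_seed(spec$seed,
                         sample.int(.Machine$integer.max - 1L, np * (k + 1L)))
  meas <- list()
  idx <- 0L
  for (i in seq_len(np)) {
    p <- make_patient(subseeds[i], severities[i],
                      patient_id = sprintf("P%02d", i))
    for (j in seq_len(k)) {
      idx <- idx + 1L
      peep <- rep_len(spec$peep_levels, k)[j]
      sc <- vcv_scenario(peep_set = peep, seed = subseeds[np + idx],
                         noise_sd_paw = 0.05, noise_sd_peso = 0.05,
                         cardiac_amp = 1)
      bundle <- simulate_vcv(p, sc)
      eit <- simulate_eit(p, bundle$volume_ml, bundle$signals$t, peep,
                          fs_eit = sc$fs_eit, noise_sd = 0.5,
                          seed = subseeds[np + idx])
      meas[[idx]] <- list(patient = p, condition = j, peep = peep,
                          scenario = sc, bundle = bundle, eit = eit,
                          truth = list(el = p$el_true, ecw = p$ecw_true,
                                       ers = p$ers_true, tv_ml = bundle$tv_ml,
                                       roi = fractions_at_peep(p, peep)))
    }
  }
  structure(list(measurements = meas, spec = spec), class = "mechanistic_cohort")
}

#' Simulate repeated-measures panel data with a set within-subject correlation
#'
#' Each subject receives independent normal random intercepts for `x` and
#' `y`; within-subject deviations are bivariate normal with correlation
#' `r_within`. Used to validate the repeated-measures correlation estimator
#' ([rmcorr()]), which should recover `r_within` regardless of the
#' between-subject structure.
#'
#' @param n_subjects Number of subjects.
#' @param k Observations per subject.
#' @param r_within Generating within-subject correlation, in (-1, 1).
#' @param sd_between Length-2 SDs of the subject intercepts (x, y).
#' @param sd_within Length-2 SDs of the within-subject deviations.
#' @param seed Integer seed.
#' @return data.frame with columns `subject`, `x`, `y`.
#' @export
simulate_rm_panel <- function(n_subjects, k = 3, r_within = -0.68,
                              sd_between = c(1, 1), sd_within = c(1, 1),
                              seed = 1L) {
  stopifnot(n_subjects >= 2, k >= 2, abs(r_within) < 1)
  local_seed(seed, {
    n <- n_subjects * k
    mu_x <- rep(rnorm(n_subjects, 0, sd_between[1L]), each = k)
    mu_y <- rep(rnorm(n_subjects, 0, sd_between[2L]), each = k)
    z1 <- rnorm(n)
    z2 <- r_within * z1 + sqrt(1 - r_within^2) * rnorm(n)
    data.frame(subject = rep(seq_len(n_subjects), each = k),
               x = mu_x + sd_within[1L] * z1,
               y = mu_y + sd_within[2L] * z2)
  })
}
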
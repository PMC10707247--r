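# Audiology layer: decibel loss curves from mechanical output, audiometric
# summaries and scenario ranking against a measured air-bone gap.

#' Construct a measured audiogram
#'
#' @param frequencies Test frequencies in Hz, strictly increasing, within
#'   125-8000 Hz.
#' @param air_db_hl Air-conduction thresholds in dB HL, one per frequency,
#'   within -10..120.
#' @param bone_db_hl Optional bone-conduction thresholds in dB HL.
#' @param ear `"left"` or `"right"`.
#' @return An object of class `ear_audiogram`.
#' @export
audiogram <- function(frequencies, air_db_hl, bone_db_hl = NULL,
                      ear = c("left", "right")) {
  ear <- match.arg(ear)
  if (!is.numeric(frequencies) || !length(frequencies) ||
      any(!is.finite(frequencies)) ||
      is.unsorted(frequencies, strictly = TRUE) ||
      any(frequencies < 125) || any(frequencies > 8000)) {
    abort_data("'frequencies' must be strictly increasing within [125, 8000] Hz")
  }
  check_thr <- function(x, what) {
    if (!is.numeric(x) || length(x) != length(frequencies) ||
        any(!is.finite(x)) || any(x < -10) || any(x > 120)) {
      abort_data(sprintf("'%s' must match the frequency grid with values in [-10, 120] dB HL", what))
    }
  }
  check_thr(air_db_hl, "air_db_hl")
  if (!is.null(bone_db_hl)) check_thr(bone_db_hl, "bone_db_hl")
  structure(list(ear = ear, frequencies = as.numeric(frequencies),
                 air_db_hl = as.numeric(air_db_hl),
                 bone_db_hl = if (!is.null(bone_db_hl)) as.numeric(bone_db_hl)),
            class = "ear_audiogram")
}

#' Simulated hearing loss from volume-velocity curves
#'
#' `loss(f) = 20 log10(|V_SF normal| / |V_SF diseased|)`: the decibel ratio of
#' normal to diseased stapes-footplate volume velocity. Positive values mean
#' loss. The ratio is invariant to the drive level (the mechanics are linear).
#' A zero diseased magnitude yields a `+Inf` sentinel with a warning.
#'
#' @param normal_curve,diseased_curve Transmission curves from
#'   [transmission_curve()] on matching frequency grids.
#' @param scenario_name Optional label attached to the curve.
#' @return A `data.frame` of class `ear_loss_curve` with columns
#'   `frequency_hz`, `loss_db` and attribute `scenario`.
#' @export
vsf_ratio_db <- function(normal_curve, diseased_curve, scenario_name = "") {
  for (cv in list(normal_curve, diseased_curve)) {
    if (!is.data.frame(cv) || !all(c("frequency_hz", "vsf_abs") %in% names(cv))) {
      abort_data("curves must be data.frames with columns 'frequency_hz' and 'vsf_abs'")
    }
  }
  if (nrow(normal_curve) != nrow(diseased_curve) ||
      max(abs(normal_curve$frequency_hz - diseased_curve$frequency_hz)) > 1e-9) {
    abort_data("normal and diseased curves must share one frequency grid")
  }
  if (any(normal_curve$vsf_abs <= 0)) {
    abort_data("normal-ear volume velocity must be positive at every frequency")
  }
  dis <- diseased_curve$vsf_abs
  if (any(dis == 0)) {
    warn_earmech("diseased volume velocity is zero at some frequencies; loss reported as +Inf",
                 "earmech_sentinel_warning")
  }
  loss <- ifelse(dis == 0, Inf, 20 * log10(normal_curve$vsf_abs / dis))
  out <- data.frame(frequency_hz = normal_curve$frequency_hz, loss_db = loss)
  attr(out, "scenario") <- scenario_name
  class(out) <- c("ear_loss_curve", "data.frame")
  out
}

threshold_at <- function(aud, f) {
  i <- which(abs(aud$frequencies - f) < 0.5)
  if (!length(i)) abort_data(sprintf("audiogram has no threshold at %g Hz", f))
  aud$air_db_hl[i[1]]
}

#' Four-frequency pure-tone average
#'
#' `mean4` is the unweighted mean of the 500/1000/2000/4000 Hz air thresholds
#' (the default); `japanese_weighted` is `(a500 + 2 a1000 + a2000) / 4`.
#'
#' @param aud An [audiogram()].
#' @param convention `"mean4"` or `"japanese_weighted"`.
#' @return PTA in dB HL.
#' @export
pta4 <- function(aud, convention = c("mean4", "japanese_weighted")) {
  stopifnot(inherits(aud, "ear_audiogram"))
  convention <- match.arg(convention)
  if (convention == "mean4") {
    mean(vapply(c(500, 1000, 2000, 4000), threshold_at, numeric(1), aud = aud))
  } else {
    (threshold_at(aud, 500) + 2 * threshold_at(aud, 1000) +
       threshold_at(aud, 2000)) / 4
  }
}

#' Air-bone gap of an audiogram
#'
#' `gap(f) = air(f) - bone(f)`, the audiometric signature of conductive
#' (middle-ear) hearing loss; negative gaps are reported, not clipped.
#'
#' @param aud An [audiogram()] with bone-conduction thresholds.
#' @return List with `per_frequency` (data.frame `frequency_hz`, `gap_db`) and
#'   `mean_db`.
#' @export
ab_gap <- function(aud) {
  stopifnot(inherits(aud, "ear_audiogram"))
  if (is.null(aud$bone_db_hl)) {
    abort_data("audiogram carries no bone-conduction thresholds")
  }
  gap <- aud$air_db_hl - aud$bone_db_hl
  list(per_frequency = data.frame(frequency_hz = aud$frequencies, gap_db = gap),
       mean_db = mean(gap))
}

curve_values <- function(curve) {
  if (inherits(curve, "ear_loss_curve")) {
    list(f = curve$frequency_hz, v = curve$loss_db)
  } else if (is.data.frame(curve)) {
    vcol <- intersect(c("loss_db", "gap_db", "value"), names(curve))
    if (!("frequency_hz" %in% names(curve)) || !length(vcol)) {
      abort_data("curve data.frame needs 'frequency_hz' and one of 'loss_db', 'gap_db', 'value'")
    }
    list(f = curve$frequency_hz, v = curve[[vcol[1]]])
  } else if (is.list(curve) && !is.null(curve$per_frequency)) {
    curve_values(curve$per_frequency)
  } else {
    abort_data("unsupported curve object")
  }
}

#' Classify the shape of a loss or air-bone-gap curve
#'
#' Fits the curve value against log2(frequency) by least squares.
#' `down_sloping` (loss concentrated at high frequencies, the partial
#' discontinuity pattern) when the slope is at least `s0` dB/octave;
#' `up_sloping` (loss concentrated at low frequencies, the stiffness /
#' otosclerosis pattern) when the slope is at most `-s0`; otherwise `flat`.
#' An interior point deviating more than `d0` dB from the mean of its
#' neighbours overrides the slope class as `peaked` (above) or `dipped`
#' (below).
#'
#' @param curve An `ear_loss_curve`, an air-bone-gap result, or a data.frame
#'   with `frequency_hz` and a value column; at least 4 frequencies.
#' @param s0 Slope threshold in dB/octave (default 3).
#' @param d0 Peak/dip threshold in dB (default 10).
#' @return One of `"up_sloping"`, `"down_sloping"`, `"flat"`, `"peaked"`,
#'   `"dipped"`.
#' @export
classify_slope <- function(curve, s0 = 3, d0 = 10) {
  cv <- curve_values(curve)
  n <- length(cv$f)
  if (n < 4L) abort_data("slope classification needs at least 4 frequencies")
  if (any(!is.finite(cv$v))) abort_data("curve values must be finite for classification")

  dev <- cv$v[2:(n - 1)] - (cv$v[1:(n - 2)] + cv$v[3:n]) / 2
  if (any(abs(dev) > d0)) {
    worst <- which.max(abs(dev))
    return(if (dev[worst] > 0) "peaked" else "dipped")
  }
  slope <- stats::coef(stats::lm(cv$v ~ log2(cv$f)))[[2]]
  if (slope >= s0) "down_sloping" else if (slope <= -s0) "up_sloping" else "flat"
}

#' Compare a simulated loss curve with a measured air-bone gap
#'
#' Residuals, root-mean-square misfit and Pearson correlation on the common
#' frequency grid, plus slope classes of both curves.
#'
#' @param simulated An `ear_loss_curve`.
#' @param measured_gap A data.frame with `frequency_hz` and `gap_db` (or the
#'   result of [ab_gap()]).
#' @param s0,d0 Shape thresholds passed to [classify_slope()].
#' @return Object of class `ear_comparison`: `rms_db`, `pearson_r`,
#'   `slope_class_sim`, `slope_class_meas`, `per_frequency_residual`.
#' @export
compare_curves <- function(simulated, measured_gap, s0 = 3, d0 = 10) {
  sim <- curve_values(simulated)
  meas <- curve_values(measured_gap)
  common <- intersect(round(sim$f, 6), round(meas$f, 6))
  if (length(common) < 4L) {
    abort_data("curves overlap on fewer than 4 frequencies")
  }
  si <- match(common, round(sim$f, 6))
  mi <- match(common, round(meas$f, 6))
  s <- sim$v[si]; m <- meas$v[mi]
  res <- s - m
  r <- if (stats::sd(s) == 0 || stats::sd(m) == 0) {
    if (max(abs(res - mean(res))) < 1e-12) 1 else NA_real_
  } else {
    stats::cor(s, m)
  }
  structure(
    list(rms_db = sqrt(mean(res^2)),
         pearson_r = r,
         slope_class_sim = classify_slope(data.frame(frequency_hz = common, value = s),
                                          s0 = s0, d0 = d0),
         slope_class_meas = classify_slope(data.frame(frequency_hz = common, value = m),
                                           s0 = s0, d0 = d0),
         per_frequency_residual = data.frame(frequency_hz = common,
                                             residual_db = res)),
    class = "ear_comparison"
  )
}

#' @export
print.ear_comparison <- function(x, ...) {
  cat(sprintf("Curve comparison: rms %.2f dB, pearson r %.3f, shapes sim=%s meas=%s\n",
              x$rms_db, x$pearson_r, x$slope_class_sim, x$slope_class_meas))
  print(x$per_frequency_residual, row.names = FALSE)
  invisible(x)
}

#' Simulated loss curve of one scenario
#'
#' Convenience pipeline: compose the scenario on the normal model, sweep the
#' transmission and take the decibel ratio against the normal curve.
#'
#' @param model The normal `middle_ear_model`.
#' @param scenario An [pathology_scenario()].
#' @param frequencies Frequencies in Hz (default: the model grid).
#' @param normal_curve Optional precomputed normal transmission curve on the
#'   same grid (saves re-solving when ranking many scenarios).
#' @return An `ear_loss_curve`.
#' @export
scenario_loss_curve <- function(model, scenario,
                                frequencies = model$frequency_grid,
                                normal_curve = NULL) {
  frequencies <- sort(frequencies)
  if (is.null(normal_curve)) {
    normal_curve <- transmission_curve(model, frequencies)
  }
  diseased <- compose_scenario(model, scenario)
  vsf_ratio_db(normal_curve, transmission_curve(diseased, frequencies),
               scenario_name = scenario$name)
}

#' Rank pathology scenarios against a measured air-bone gap
#'
#' Simulates every scenario (compose, transmission sweep, decibel ratio) on
#' the measured frequency grid and sorts by ascending root-mean-square misfit;
#' ties break toward higher Pearson correlation, then catalog order. Scenarios
#' that fail to compose are excluded and listed in the `failed` attribute.
#'
#' @param measured_gap Data.frame with `frequency_hz`, `gap_db` (or an
#'   [ab_gap()] result).
#' @param scenarios List of [pathology_scenario()] (default: the full
#'   [scenario_catalog()]).
#' @param model The normal `middle_ear_model`.
#' @return A `data.frame` with columns `rank`, `scenario`, `rms_db`,
#'   `pearson_r`, `slope_class_sim`; attributes `reports` (named list of
#'   `ear_comparison`), `curves` (named list of loss curves) and `failed`.
#' @export
#' @examples
#' model <- build_normal_model()
#' gap <- scenario_loss_curve(model, scenario_catalog()[["patient2"]])
#' names(gap)[2] <- "gap_db"
#' rank_scenarios(gap, model = model)[1, "scenario"] # "patient2"
rank_scenarios <- function(measured_gap, scenarios = scenario_catalog(), model) {
  if (!length(scenarios)) abort_data("'scenarios' must be non-empty")
  if (inherits(scenarios, "ear_scenario")) scenarios <- list(scenarios)
  meas <- curve_values(measured_gap)
  freqs <- sort(meas$f)
  normal_curve <- transmission_curve(model, freqs)

  nm <- vapply(scenarios, `[[`, "", "name")
  reports <- list(); curves <- list(); failed <- character(0)
  for (i in seq_along(scenarios)) {
    res <- tryCatch({
      lc <- scenario_loss_curve(model, scenarios[[i]], freqs,
                                normal_curve = normal_curve)
      list(curve = lc, report = compare_curves(lc, measured_gap))
    }, earmech_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed[nm[i]] <- res
    } else {
      reports[[nm[i]]] <- res$report
      curves[[nm[i]]] <- res$curve
    }
  }
  if (!length(reports)) abort_data("no scenario could be simulated")

  rms <- vapply(reports, `[[`, numeric(1), "rms_db")
  r <- vapply(reports, function(x) {
    if (is.na(x$pearson_r)) -Inf else x$pearson_r
  }, numeric(1))
  ord <- order(rms, -r, seq_along(rms))
  out <- data.frame(
    rank = seq_along(ord),
    scenario = names(reports)[ord],
    rms_db = unname(rms[ord]),
    pearson_r = vapply(reports[ord], `[[`, numeric(1), "pearson_r"),
    slope_class_sim = vapply(reports[ord], `[[`, "", "slope_class_sim"),
    row.names = NULL
  )
  attr(out, "reports") <- reports
  attr(out, "curves") <- curves
  attr(out, "failed") <- failed
  out
}
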
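#' Build the airway-opening drive for a ventilator mode
#'
#' Converts [ventilator_settings()] into the inspiratory boundary condition
#' applied at the airway opening:
#' \describe{
#'   \item{CF}{constant flow, `Q_aw(t) = q_aw`.}
#'   \item{DF}{decelerating (triangular) flow, `Q_aw(t) = q_max (1 - t/ti)`,
#'     reaching exactly zero at end-inspiration.}
#'   \item{SF}{half-sinusoidal flow, `Q_aw(t) = q_max sin(pi t / ti)`, zero at
#'     both onset and end of inspiration.}
#'   \item{CP}{constant pressure, `P_aw(t) = p_set` (ideal source, no
#'     rise-time ramp; the circuit resistances alone shape the flow).}
#' }
#'
#' @param settings a [ventilator_settings()] with a concrete amplitude
#'   (`target_vt` settings must pass through [calibrate_drive_to_vt()] first).
#' @return object of class `airway_drive`: list with `kind`
#'   (`"flow_controlled"` or `"pressure_controlled"`), vectorised `waveform(t)`
#'   over `[0, ti]` (l/s or cmH2O), `ti` and `mode`.
#' @export
#' @examples
#' d <- make_drive(ventilator_settings("SF", peep = 2, ti = 1, ttot = 3,
#'                                     q_max = 2.670))
#' d$waveform(0.5)
make_drive <- function(settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (settings$amplitude_kind == "target_vt")
    stop("settings carry target_vt; calibrate with calibrate_drive_to_vt() first")
  ti <- settings$ti
  amp <- settings$amplitude
  wf <- switch(settings$mode,
    CF = function(t) rep_len(amp, length(t)),
    DF = function(t) amp * (1 - t / ti),
    SF = function(t) amp * sin(pi * t / ti),
    CP = function(t) rep_len(amp, length(t)),
    stop("unknown mode: ", settings$mode)
  )
  kind <- if (settings$mode == "CP") "pressure_controlled" else "flow_controlled"
  structure(list(kind = kind, waveform = wf, ti = ti, mode = settings$mode,
                 amplitude = amp),
            class = "airway_drive")
}

#' Tidal volume delivered by a flow-controlled drive
#'
#' The inspired volume at the airway opening, `integral of Q_aw over [0, ti]`,
#' in closed form: `q_aw * ti` (CF), `q_max * ti / 2` (DF),
#' `2 * q_max * ti / pi` (SF).
#'
#' @param drive an [make_drive()] result with `kind == "flow_controlled"`.
#' @return tidal volume (l).
#' @export
vt_of_drive <- function(drive) {
  stopifnot(inherits(drive, "airway_drive"))
  if (drive$kind != "flow_controlled")
    stop("tidal volume of a pressure-controlled drive emerges from the ",
         "circuit; simulate the cycle instead")
  switch(drive$mode,
    CF = drive$amplitude * drive$ti,
    DF = drive$amplitude * drive$ti / 2,
    SF = 2 * drive$amplitude * drive$ti / pi
  )
}

#' Calibrate the drive amplitude to a target tidal volume
#'
#' For the flow-controlled modes the amplitude is the closed-form inverse of
#' [vt_of_drive()]. For CP, the set pressure is found by bracketing root
#' search so that the periodic-steady-state inspired volume at the airway
#' opening matches `target_vt` to within `tol` (the steady-state tidal volume
#' is monotone increasing in `p_set`). Calibration is against the periodic
#' steady state, after auto-PEEP has settled, because the strain formulas use
#' steady-state end-expiratory pressures.
#'
#' @param net a valid [lung_network()].
#' @param settings [ventilator_settings()]; if its amplitude kind is not
#'   `target_vt`, `target_vt` must be given explicitly.
#' @param target_vt target tidal volume (l); defaults to the settings'
#'   `target_vt` amplitude.
#' @param tol absolute tolerance on the achieved tidal volume (l), CP only.
#' @param p_max upper limit for the CP bracket expansion (cmH2O).
#' @return a [ventilator_settings()] with a concrete amplitude.
#' @export
#' @examples
#' sc <- baseline_scenario()
#' s <- ventilator_settings("DF", peep = 2, ti = 1, ttot = 3, target_vt = 1.7)
#' calibrate_drive_to_vt(sc$network, s)$amplitude  # 3.4 l/s
calibrate_drive_to_vt <- function(net, settings, target_vt = NULL,
                                  tol = 1e-4, p_max = 1000) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (is.null(target_vt)) {
    if (settings$amplitude_kind != "target_vt")
      stop("settings carry no target_vt and none was given")
    target_vt <- settings$amplitude
  }
  stopifnot(target_vt > 0)
  remake <- function(key, val) {
    args <- list(mode = settings$mode, peep = settings$peep,
                 ti = settings$ti, ttot = settings$ttot)
    args[[key]] <- val
    do.call(ventilator_settings, args)
  }
  ti <- settings$ti
  if (settings$mode == "CF") return(remake("q_aw", target_vt / ti))
  if (settings$mode == "DF") return(remake("q_max", 2 * target_vt / ti))
  if (settings$mode == "SF") return(remake("q_max", pi * target_vt / (2 * ti)))

  # CP: root search on the steady-state airway tidal volume
  stop_if_invalid(net)
  vt_at <- function(p_set) {
    s <- remake("p_set", p_set)
    ss <- periodic_state_core(net, s)
    sum(ss$v_ti - ss$v_star)
  }
  lo <- settings$peep + 1e-6
  hi <- settings$peep + 5
  f_hi <- vt_at(hi) - target_vt
  while (f_hi < 0 && hi < p_max) {
    hi <- min(2 * (hi - settings$peep) + settings$peep, p_max)
    f_hi <- vt_at(hi) - target_vt
  }
  if (f_hi < 0)
    stop(sprintf(paste0("target tidal volume %.4g l unreachable: at p_set = ",
                        "%.4g cmH2O the steady state delivers only %.4g l"),
                 target_vt, hi, f_hi + target_vt))
  root <- stats::uniroot(function(p) vt_at(p) - target_vt,
                         lower = lo, upper = hi, tol = 1e-9)
  cal <- remake("p_set", root$root)
  achieved <- vt_at(root$root)
  if (abs(achieved - target_vt) > tol)
    stop(sprintf("CP calibration missed target: achieved %.6g l vs %.6g l",
                 achieved, target_vt))
  cal
}
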
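# one steady-state run reduced to a per-compartment record
sweep_point <- function(net, settings, dt = 1e-3) {
  traj <- find_periodic_steady_state(net, settings, dt = dt)
  ms <- max_strain(traj)
  ni <- traj$ti_index
  msr <- vapply(seq_len(ncol(traj$Q)), function(j)
    max(traj$Q[seq_len(ni), j]) / net$compartments$V_rest[j], numeric(1))
  data.frame(mode = settings$mode, compartment = ms$compartment,
             S_max = ms$S_max, max_strain_rate = msr,
             P_ex = ms$P_ex, V_T_comp = ms$V_T_comp,
             v_peak = ms$v_peak, t_peak = ms$t_peak,
             V_T = traj$V_T, stringsAsFactors = FALSE)
}

as_sweep_result <- function(df, variable, grid, scenario) {
  structure(df, class = c("sweep_result", "data.frame"),
            variable = variable, grid = grid,
            scenario_hash = scenario_hash(scenario))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> swept %s over %d point(s); %d records\n",
              attr(x, "variable"), length(attr(x, "grid")), nrow(x)))
  cat("  scenario:", attr(x, "scenario_hash"), "\n")
  NextMethod()
}

#' Amplitude-matched settings for several modes
#'
#' Builds one [ventilator_settings()] per requested mode, all delivering the
#' same tidal volume at the same inspiratory time (flow-mode amplitudes in
#' closed form; CP set pressure by steady-state root search against `net`).
#' The default target is the tidal volume delivered by `settings` itself.
#'
#' @param net a valid [lung_network()].
#' @param settings reference [ventilator_settings()] supplying PEEP, timing
#'   and (by default) the target tidal volume.
#' @param modes character vector of modes to match.
#' @param target_vt target tidal volume (l); default: the volume `settings`
#'   delivers (closed form for flow modes, steady-state volume for CP).
#' @return named list of calibrated settings, one per mode.
#' @export
matched_settings <- function(net, settings,
                             modes = c("CF", "DF", "SF", "CP"),
                             target_vt = NULL) {
  modes <- match.arg(modes, c("CF", "DF", "SF", "CP"), several.ok = TRUE)
  if (is.null(target_vt)) {
    target_vt <- if (settings$mode == "CP" ||
                     settings$amplitude_kind == "target_vt") {
      if (settings$amplitude_kind == "target_vt") settings$amplitude
      else find_periodic_steady_state(net, settings)$V_T
    } else vt_of_drive(make_drive(settings))
  }
  out <- lapply(modes, function(m) {
    s <- ventilator_settings(m, peep = settings$peep, ti = settings$ti,
                             ttot = settings$ttot, target_vt = target_vt)
    calibrate_drive_to_vt(net, s)
  })
  stats::setNames(out, modes)
}

#' Run several modes at matched tidal volume
#'
#' Simulates the periodic steady state for each mode at the same tidal volume
#' and inspiratory time and derives the energetics of each, for side-by-side
#' comparison of how the flow profile partitions volume, power and strain
#' among compartments.
#'
#' @inheritParams matched_settings
#' @param dt output grid step (s).
#' @param ... passed to [compute_energetics()].
#' @return list with `settings` (per-mode calibrated settings),
#'   `trajectories`, `energetics` (per-mode lists) and `summary` (long
#'   data.frame across modes and compartments).
#' @export
#' @examples
#' sc <- baseline_scenario()
#' mc <- mode_comparison(sc$network, sc$ventilator, modes = c("CF", "DF"))
#' mc$summary
mode_comparison <- function(net, settings,
                            modes = c("CF", "DF", "SF", "CP"),
                            target_vt = NULL, dt = 1e-3, ...) {
  cal <- matched_settings(net, settings, modes, target_vt)
  trajs <- lapply(cal, function(s) find_periodic_steady_state(net, s, dt = dt))
  ens <- lapply(trajs, compute_energetics, ...)
  summary <- do.call(rbind, lapply(names(trajs), function(m) {
    cbind(mode = m, ens[[m]]$summary, V_T = trajs[[m]]$V_T,
          stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(settings = cal, trajectories = trajs, energetics = ens,
       summary = summary)
}

#' Maximal strain across a PEEP sweep
#'
#' Recomputes the periodic steady state and per-compartment maximal strain
#' over a grid of applied PEEPs for each mode. Amplitudes are calibrated once
#' at the reference settings' PEEP and then held fixed across the sweep: the
#' flow modes keep their set flow (hence tidal volume), while CP keeps its
#' set pressure (so its tidal volume shrinks as PEEP rises) — mirroring how
#' each mode is set clinically. PEEP points at or above a CP set pressure are
#' marked infeasible (`NA` records) rather than simulated.
#'
#' @inheritParams mode_comparison
#' @param peep_grid strictly increasing PEEP grid (cmH2O).
#' @return a `sweep_result` data.frame, long format: one row per
#'   (PEEP, mode, compartment) with `S_max`, `max_strain_rate`, `P_ex`,
#'   `V_T_comp`, `v_peak`, `t_peak`, `V_T`.
#' @export
peep_sweep <- function(net, settings, peep_grid = seq(0, 12.75, by = 0.25),
                       modes = c("CF", "DF", "SF", "CP"),
                       target_vt = NULL, dt = 1e-3) {
  stopifnot(all(diff(peep_grid) > 0), all(peep_grid >= 0))
  cal <- matched_settings(net, settings, modes, target_vt)
  rows <- list()
  for (m in names(cal)) {
    s0 <- cal[[m]]
    for (p in peep_grid) {
      feasible <- !(m == "CP" && s0$amplitude <= p)
      if (feasible) {
        args <- list(mode = m, peep = p, ti = s0$ti, ttot = s0$ttot)
        args[[s0$amplitude_kind]] <- s0$amplitude
        rec <- sweep_point(net, do.call(ventilator_settings, args), dt = dt)
      } else {
        rec <- data.frame(mode = m, compartment = net$compartments$label,
                          S_max = NA_real_, max_strain_rate = NA_real_,
                          P_ex = NA_real_, V_T_comp = NA_real_,
                          v_peak = NA_real_, t_peak = NA_real_,
                          V_T = NA_real_, stringsAsFactors = FALSE)
      }
      rec <- cbind(peep = p, rec, feasible = feasible)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  as_sweep_result(df, "peep", peep_grid,
                  list(network = net, ventilator = settings))
}

#' Maximal strain over a tidal-volume by peak-flow grid
#'
#' For each cell of a tidal-volume x peak-flow grid, sets the inspiratory
#' time demanded by the flow profile (`ti = V_T/Q` for CF, `2 V_T/Q_max` for
#' DF, `pi V_T/(2 Q_max)` for SF), keeps PEEP and the cycle length from the
#' reference settings, and records the steady-state maximal strain per
#' compartment. Cells whose required `ti` reaches the cycle length are marked
#' infeasible, not computed. Cells where any compartment's end-expiratory
#' pressure exceeds set PEEP by more than 0.1 cmH2O are flagged
#' (`auto_peep = TRUE`) — longer inspirations shorten expiration and trap
#' gas.
#'
#' @inheritParams mode_comparison
#' @param vt_grid strictly increasing tidal volumes (l).
#' @param qmax_grid strictly increasing peak flows (l/s).
#' @return a `sweep_result` data.frame with one row per
#'   (V_T, Q_max, mode, compartment), columns as in [peep_sweep()] plus
#'   `ti`, `feasible` and `auto_peep`.
#' @export
vt_qmax_grid <- function(net, settings,
                         vt_grid = seq(0.3, 1.4, length.out = 20),
                         qmax_grid = seq(0.6, 3.4, length.out = 20),
                         modes = c("CF", "DF", "SF"), dt = 1e-3) {
  stopifnot(all(diff(vt_grid) > 0), all(diff(qmax_grid) > 0))
  modes <- match.arg(modes, c("CF", "DF", "SF"), several.ok = TRUE)
  labels <- net$compartments$label
  rows <- list()
  for (m in modes) for (q in qmax_grid) for (vt in vt_grid) {
    ti <- switch(m, CF = vt / q, DF = 2 * vt / q, SF = pi * vt / (2 * q))
    feasible <- ti > 0 && ti < settings$ttot
    if (feasible) {
      args <- list(mode = m, peep = settings$peep, ti = ti,
                   ttot = settings$ttot)
      args[[if (m == "CF") "q_aw" else "q_max"]] <- q
      rec <- sweep_point(net, do.call(ventilator_settings, args), dt = dt)
      auto_peep <- any(rec$P_ex > settings$peep + 0.1)
    } else {
      rec <- data.frame(mode = m, compartment = labels,
                        S_max = NA_real_, max_strain_rate = NA_real_,
                        P_ex = NA_real_, V_T_comp = NA_real_,
                        v_peak = NA_real_, t_peak = NA_real_,
                        V_T = NA_real_, stringsAsFactors = FALSE)
      auto_peep <- NA
    }
    rows[[length(rows) + 1L]] <-
      cbind(vt_set = vt, q_max = q, ti = ti, rec,
            feasible = feasible, auto_peep = auto_peep)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  as_sweep_result(df, "vt_set", vt_grid,
                  list(network = net, ventilator = settings))
}

#' Maximal strain across a resting-volume sweep
#'
#' Applies a common resting volume to every compartment over a grid and
#' reports the resulting maximal strains. The resting volume enters only the
#' strain formula, not the circuit, so the steady state is computed once per
#' mode and reused across the grid.
#'
#' @inheritParams mode_comparison
#' @param vrest_grid strictly increasing resting volumes (l).
#' @return a `sweep_result` data.frame with one row per
#'   (V_rest, mode, compartment).
#' @export
vrest_sweep <- function(net, settings, vrest_grid = seq(0.2, 1.2, by = 0.05),
                        modes = c("CF", "CP"), target_vt = NULL, dt = 1e-3) {
  stopifnot(all(diff(vrest_grid) > 0), all(vrest_grid > 0))
  cal <- matched_settings(net, settings, modes, target_vt)
  rows <- list()
  for (m in names(cal)) {
    base <- sweep_point(net, cal[[m]], dt = dt)
    # S_max - 1 and strain rate scale as 1/V_rest at fixed circuit behaviour
    base_vrest <- net$compartments$V_rest
    for (vr in vrest_grid) {
      rec <- base
      rec$S_max <- 1 + (base$S_max - 1) * base_vrest / vr
      rec$max_strain_rate <- base$max_strain_rate * base_vrest / vr
      rows[[length(rows) + 1L]] <- cbind(v_rest = vr, rec)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  as_sweep_result(df, "v_rest", vrest_grid,
                  list(network = net, ventilator = settings))
}

#' Documented preset of unequal resting volumes
#'
#' A synthetic assignment of per-compartment resting volumes (small for the
#' high-compliance compartment A, large for the high-resistance compartment
#' D) under which, on the baseline scenario with constant flow, compartment A
#' attains the highest maximal strain and compartment D the lowest. The
#' specific values are a package choice (no canonical set exists); they are
#' fixed here so results are reproducible.
#'
#' @return named numeric vector of resting volumes (l) for A..E.
#' @export
vrest_map_preset <- function() {
  c(A = 0.5, B = 0.75, C = 0.95, D = 1.2, E = 1.0)
}

#' Maximal strain with heterogeneous resting volumes
#'
#' Assigns a different resting volume to each compartment and reports the
#' per-compartment maximal strains at the periodic steady state. Resting
#' volumes do not feed back into the circuit, only into the strain mapping.
#'
#' @inheritParams mode_comparison
#' @param vrest_map named numeric vector of resting volumes (l), one per
#'   compartment label; see [vrest_map_preset()].
#' @param mode ventilation mode to run (default constant flow).
#' @return the [max_strain()] data.frame for the modified network.
#' @export
heterogeneous_vrest <- function(net, settings, vrest_map = vrest_map_preset(),
                                mode = "CF", target_vt = NULL, dt = 1e-3) {
  stopifnot(all(vrest_map > 0))
  labels <- net$compartments$label
  if (!setequal(names(vrest_map), labels))
    stop("vrest_map must name every compartment exactly once")
  net2 <- net
  net2$compartments$V_rest <- unname(vrest_map[labels])
  cal <- matched_settings(net2, settings, mode, target_vt)[[1]]
  traj <- find_periodic_steady_state(net2, cal, dt = dt)
  max_strain(traj)
}
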
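#' Intracycle elastic power
#'
#' The instantaneous rate of elastic energy delivery to a compartment,
#' `Q (V/C + P_ex)`: flow into the compartment times its absolute alveolar
#' elastic pressure (incremental elastic pressure plus the end-expiratory
#' residual pressure, i.e. total PEEP). Vectorised over trajectory samples.
#'
#' @param Q compartmental flow (l/s).
#' @param V compartmental volume above end-expiratory residual (l).
#' @param C compartmental compliance (l/cmH2O), > 0.
#' @param P_ex end-expiratory compartmental pressure (cmH2O).
#' @return power in cmH2O.l/s.
#' @export
icp_elastic <- function(Q, V, C, P_ex) {
  stopifnot(C > 0)
  Q * (V / C + P_ex)
}

#' Cumulative elastic energy
#'
#' Cumulative integral of an intracycle-power trace,
#' `A(t) = integral of ICP from 0 to t`, with `A(0) = 0`. The default is a
#' cumulative Simpson rule on the uniform part of the grid (fourth-order,
#' which keeps the energy-volume identity tight through the fast initial
#' transient of pressure-controlled inspiration); any trailing non-uniform
#' step, and the `"trapezoid"` method, use the trapezoidal rule.
#'
#' @param icp power samples (cmH2O.l/s) on the grid `t`.
#' @param t time grid (s), strictly increasing.
#' @param method `"simpson"` (default) or `"trapezoid"`.
#' @return cumulative energy (cmH2O.l), same length as `t`.
#' @export
cumulative_energy <- function(icp, t, method = c("simpson", "trapezoid")) {
  stopifnot(length(icp) == length(t), all(diff(t) > 0))
  method <- match.arg(method)
  n <- length(t)
  if (method == "trapezoid" || n < 3) return(drop(pracma::cumtrapz(t, icp)))
  h <- diff(t)
  # longest uniform prefix of the grid
  m <- n
  if (max(abs(h - h[1])) > 1e-9 * h[1]) {
    m <- which(abs(h - h[1]) > 1e-9 * h[1])[1]   # t[1..m] uniform
    if (m < 3) return(drop(pracma::cumtrapz(t, icp)))
  }
  A <- numeric(n)
  hh <- h[1]
  # quadratic (Newton) start for the first half-panel
  A[2] <- hh / 12 * (5 * icp[1] + 8 * icp[2] - icp[3])
  for (k in 3:m) A[k] <- A[k - 2] + hh / 3 *
      (icp[k - 2] + 4 * icp[k - 1] + icp[k])
  if (m < n) for (k in (m + 1):n)
    A[k] <- A[k - 1] + (t[k] - t[k - 1]) * (icp[k - 1] + icp[k]) / 2
  A
}

#' Strain from delivered elastic energy
#'
#' `strain(t) = 1 + sqrt(2 C A(t) + C^2 P_ex^2) / V_rest`. Along any
#' trajectory of the linear compartment this coincides with the volume form
#' [strain_from_volume()], via the identity
#' `2 C A + C^2 P_ex^2 = (V + C P_ex)^2`.
#'
#' @param A cumulative elastic energy (cmH2O.l).
#' @param C compliance (l/cmH2O).
#' @param P_ex end-expiratory pressure (cmH2O).
#' @param V_rest resting (unstressed) volume (l).
#' @return unitless strain.
#' @export
strain_from_energy <- function(A, C, P_ex, V_rest) {
  rad <- 2 * C * A + C^2 * P_ex^2
  if (any(rad < -1e-12 * max(1, C^2 * P_ex^2)))
    stop("negative radicand in strain_from_energy: inconsistent inputs")
  rad[rad < 0] <- 0
  1 + sqrt(rad) / V_rest
}

#' Strain from compartmental volume
#'
#' `strain(t) = 1 + (V(t) + C P_ex) / V_rest`: the expansion of the
#' compartment relative to its unstressed resting volume, with the
#' end-expiratory distension `C P_ex` included.
#'
#' @inheritParams strain_from_energy
#' @param V volume above end-expiratory residual (l).
#' @return unitless strain.
#' @export
strain_from_volume <- function(V, C, P_ex, V_rest) {
  1 + (V + C * P_ex) / V_rest
}

#' Strain rate, literal energy form
#'
#' `strain'(t) = ICP(t) / (V_rest sqrt(2 C A(t) + C^2 P_ex^2))`, implemented
#' exactly as stated. Note: along a trajectory this evaluates to
#' `Q / (C V_rest)`, whereas differentiating [strain_from_volume()] gives
#' `Q / V_rest` — the two differ by the constant factor `1/C` (see
#' [strain_rate_consistent()], the package default). Both are kept and
#' exported side by side; neither is silently corrected.
#'
#' @param icp intracycle elastic power (cmH2O.l/s).
#' @inheritParams strain_from_energy
#' @return strain rate (nominally 1/s).
#' @export
strain_rate_printed <- function(icp, A, C, P_ex, V_rest) {
  rad <- 2 * C * A + C^2 * P_ex^2
  if (any(rad <= 0))
    stop("zero or negative radicand in strain_rate_printed (e.g. t = 0 with ",
         "P_ex = 0): the limit is unavailable at a singular point")
  icp / (V_rest * sqrt(rad))
}

#' Strain rate, volume-consistent form
#'
#' The exact time derivative of [strain_from_volume()]:
#' `d/dt [1 + (V + C P_ex)/V_rest] = Q / V_rest`. This is the strain rate
#' reported in summaries by default.
#'
#' @param Q compartmental flow (l/s).
#' @param V_rest resting volume (l), > 0.
#' @return strain rate (1/s).
#' @export
strain_rate_consistent <- function(Q, V_rest) {
  stopifnot(V_rest > 0)
  Q / V_rest
}

#' Per-compartment energetics of a steady-state breath
#'
#' Computes, on the inspiration grid of a [find_periodic_steady_state()]
#' trajectory, each compartment's intracycle elastic power, cumulative
#' elastic energy `A(t)`, strain and strain rate, plus the scalar summaries
#' `S_max` (maximal strain over the whole cycle, see [max_strain()]) and
#' `A(ti)`. Optionally also the driving power `Q V/C` and the total
#' (resistive-inclusive) power `Q (V/C + P_ex + R_path Q)`, where `R_path` is
#' the series resistance from the airway opening to the compartment; only the
#' elastic component feeds strain.
#'
#' @param traj a `cycle_trajectory`.
#' @param strain_rate `"consistent"` (default, `Q/V_rest`) or `"printed"`
#'   (the literal energy form, smaller by the factor `C`).
#' @param components if `TRUE`, include `ICP_driving` and `ICP_total`
#'   matrices.
#' @return object of class `energetics_trace`: inspiration-grid matrices
#'   `ICP`, `A`, `strain`, `strain_rate` (one column per compartment), the
#'   summary data.frame `summary` (per compartment `S_max`, `t_peak`, `A_ti`,
#'   `V_T_comp`, `P_ex`) and metadata.
#' @export
#' @examples
#' sc <- baseline_scenario()
#' traj <- find_periodic_steady_state(sc$network, sc$ventilator)
#' en <- compute_energetics(traj)
#' en$summary
compute_energetics <- function(traj,
                               strain_rate = c("consistent", "printed"),
                               components = FALSE) {
  stopifnot(inherits(traj, "cycle_trajectory"))
  strain_rate <- match.arg(strain_rate)
  ni <- traj$ti_index
  t_in <- traj$time[seq_len(ni)]
  cp <- traj$net$compartments
  labels <- cp$label
  n <- length(labels)

  ICP <- Amat <- Smat <- SR <- matrix(0, ni, n, dimnames = list(NULL, labels))
  for (j in seq_len(n)) {
    Qj <- traj$Q[seq_len(ni), j]
    Vj <- traj$V[seq_len(ni), j]
    ICP[, j] <- icp_elastic(Qj, Vj, cp$C[j], traj$P_ex[j])
    Amat[, j] <- cumulative_energy(ICP[, j], t_in)
    Smat[, j] <- strain_from_volume(Vj, cp$C[j], traj$P_ex[j], cp$V_rest[j])
    SR[, j] <- if (strain_rate == "consistent")
      strain_rate_consistent(Qj, cp$V_rest[j])
    else
      strain_rate_printed(ICP[, j], Amat[, j], cp$C[j], traj$P_ex[j],
                          cp$V_rest[j])
  }

  summary <- max_strain(traj)
  summary$A_ti <- Amat[ni, ]
  summary$max_strain_rate <- apply(SR, 2, max)

  out <- list(time = t_in, ICP = ICP, A = Amat, strain = Smat,
              strain_rate = SR, strain_rate_kind = strain_rate,
              summary = summary, mode = traj$settings$mode)
  if (components) {
    circ <- circuit_matrices(traj$net)
    drv <- tot <- matrix(0, ni, n, dimnames = list(NULL, labels))
    for (j in seq_len(n)) {
      Qj <- traj$Q[seq_len(ni), j]
      Vj <- traj$V[seq_len(ni), j]
      drv[, j] <- Qj * Vj / cp$C[j]
      tot[, j] <- Qj * (Vj / cp$C[j] + traj$P_ex[j] + circ$R_path[j] * Qj)
    }
    out$ICP_driving <- drv
    out$ICP_total <- tot
  }
  structure(out, class = "energetics_trace")
}

#' @export
print.energetics_trace <- function(x, ...) {
  cat(sprintf("<energetics_trace> mode=%s, strain rate: %s form\n",
              x$mode, x$strain_rate_kind))
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
as.data.frame.energetics_trace <- function(x, ...) {
  df <- data.frame(t = x$time)
  for (lb in colnames(x$ICP)) {
    df[[paste0("ICP_", lb)]] <- x$ICP[, lb]
    df[[paste0("A_", lb)]] <- x$A[, lb]
    df[[paste0("strain_", lb)]] <- x$strain[, lb]
    df[[paste0("strainrate_", lb)]] <- x$strain_rate[, lb]
  }
  df
}

#' Maximal compartmental strain over a breath
#'
#' Per compartment, the maximum of `strain(t) = 1 + (V + C P_ex)/V_rest` over
#' the whole cycle, reported with the time and volume at the peak. For
#' monotone filling the peak sits at end-inspiration and `S_max` reduces to
#' `1 + (V_T_comp + C P_ex)/V_rest`; the maximum is taken over the full cycle
#' so that compartments that keep filling briefly into expiration
#' (pendelluft) are still captured.
#'
#' @param traj a `cycle_trajectory`.
#' @return data.frame with one row per compartment: `compartment`, `S_max`,
#'   `t_peak` (s), `v_peak` (l, above residual), `V_T_comp` (l,
#'   end-inspiratory volume above residual), `P_ex` (cmH2O).
#' @export
max_strain <- function(traj) {
  stopifnot(inherits(traj, "cycle_trajectory"))
  cp <- traj$net$compartments
  n <- nrow(cp)
  out <- data.frame(compartment = cp$label,
                    S_max = NA_real_, t_peak = NA_real_, v_peak = NA_real_,
                    V_T_comp = NA_real_, P_ex = unname(traj$P_ex),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    s <- strain_from_volume(traj$V[, j], cp$C[j], traj$P_ex[j], cp$V_rest[j])
    k <- which.max(s)
    out$S_max[j] <- s[k]
    out$t_peak[j] <- traj$time[k]
    out$v_peak[j] <- traj$V[k, j]
    out$V_T_comp[j] <- traj$V[traj$ti_index, j]
  }
  out
}
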
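#' Lung network: airway tree with elastic compartments
#'
#' A `lung_network` describes a rooted airway tree. The root is the airway
#' opening (node `"AO"`); internal edges carry named shared resistances
#' (conventionally `R0`, `R1`, ...); every leaf is an elastic compartment
#' reached through exactly one terminal edge whose resistance is the
#' compartment's own. Compartments are linear: alveolar elastic pressure is
#' `v / C` where `v` is the absolute elastic volume above the zero-pressure
#' relaxation point.
#'
#' Units throughout the package are the clinical ones: pressure in cmH2O,
#' volume in litres, time in seconds; hence resistance in cmH2O.s/l and
#' compliance in l/cmH2O. There is no unit-conversion layer.
#'
#' @param shared_resistances named numeric vector of proximal shared
#'   resistances (cmH2O.s/l), e.g. `c(R0 = 1, R1 = 1, R2 = 2, R3 = 1)`.
#' @param topology data.frame with columns `from`, `to` and `r`. Each row is
#'   one edge. `from`/`to` name nodes; the airway opening is `"AO"`. For an
#'   internal edge, `r` names the shared resistance on that edge; for a
#'   terminal edge (into a compartment) `r` is `NA` and the compartment's own
#'   resistance applies.
#' @param compartments data.frame with columns `label`, `R` (cmH2O.s/l),
#'   `C` (l/cmH2O) and `V_rest` (l, unstressed resting volume).
#' @return An object of class `lung_network`.
#' @seealso [baseline_scenario()], [validate_network()]
#' @export
#' @examples
#' net <- baseline_scenario()$network
#' validate_network(net)
lung_network <- function(shared_resistances, topology, compartments) {
  stopifnot(is.numeric(shared_resistances), !is.null(names(shared_resistances)))
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  if (!("r" %in% names(topology))) topology$r <- NA_character_
  topology$from <- as.character(topology$from)
  topology$to <- as.character(topology$to)
  topology$r <- as.character(topology$r)
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "R", "C", "V_rest") %in% names(compartments)))
  compartments$label <- as.character(compartments$label)
  net <- structure(
    list(
      shared_resistances = shared_resistances,
      topology = topology[, c("from", "to", "r")],
      compartments = compartments[, c("label", "R", "C", "V_rest")]
    ),
    class = "lung_network"
  )
  net
}

#' @export
print.lung_network <- function(x, ...) {
  cat("<lung_network>", nrow(x$compartments), "compartments,",
      nrow(x$topology), "edges\n")
  cat("  shared resistances:",
      paste(sprintf("%s=%g", names(x$shared_resistances), x$shared_resistances),
            collapse = ", "), "\n")
  print(x$compartments, row.names = FALSE)
  invisible(x)
}

#' Ventilator settings
#'
#' Bundles the inspiratory drive profile and breath timing. Exactly one drive
#' amplitude must be supplied and it must match the mode: `q_aw` (l/s) for
#' constant flow (CF), `q_max` (l/s) for decelerating (DF) or sinusoidal (SF)
#' flow, `p_set` (cmH2O) for constant inspiratory pressure (CP), or
#' `target_vt` (l) for any mode, which defers the amplitude to
#' [calibrate_drive_to_vt()].
#'
#' @param mode one of `"CF"`, `"DF"`, `"SF"`, `"CP"`.
#' @param peep applied end-expiratory pressure at the airway opening (cmH2O).
#' @param ti inspiratory time (s); must satisfy `0 < ti < ttot`.
#' @param ttot total cycle time (s).
#' @param q_aw,q_max,p_set,target_vt drive amplitude; supply exactly one.
#' @return An object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(mode, peep, ti, ttot,
                                q_aw = NULL, q_max = NULL, p_set = NULL,
                                target_vt = NULL) {
  mode <- match.arg(mode, c("CF", "DF", "SF", "CP"))
  amps <- list(q_aw = q_aw, q_max = q_max, p_set = p_set, target_vt = target_vt)
  given <- names(amps)[!vapply(amps, is.null, logical(1))]
  if (length(given) != 1L)
    stop("supply exactly one of q_aw, q_max, p_set, target_vt (got: ",
         paste(given, collapse = ", "), ")")
  expected <- switch(mode, CF = "q_aw", DF = "q_max", SF = "q_max", CP = "p_set")
  if (given != "target_vt" && given != expected)
    stop(sprintf("mode %s takes amplitude '%s', not '%s'", mode, expected, given))
  amp <- amps[[given]]
  if (!is.numeric(amp) || length(amp) != 1L || amp <= 0)
    stop("drive amplitude must be a single positive number")
  if (!is.numeric(peep) || peep < 0) stop("peep must be >= 0")
  if (!(is.numeric(ti) && is.numeric(ttot) && ti > 0 && ti < ttot))
    stop("timing must satisfy 0 < ti < ttot")
  if (mode == "CP" && given == "p_set" && p_set <= peep)
    stop("CP requires p_set > peep")
  structure(
    list(mode = mode, peep = peep, ti = ti, ttot = ttot,
         amplitude = amp, amplitude_kind = given),
    class = "ventilator_settings"
  )
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf("<ventilator_settings> mode=%s PEEP=%g ti=%g ttot=%g %s=%g\n",
              x$mode, x$peep, x$ti, x$ttot, x$amplitude_kind, x$amplitude))
  invisible(x)
}

#' Baseline five-compartment scenario
#'
#' The reference scenario used throughout: compartments A..E with resistances
#' (1, 15, 11, 15, 7) cmH2O.s/l, compliances (0.08, 0.06, 0.05, 0.02, 0.02)
#' l/cmH2O and a common resting volume of 1 l; a serial airway backbone
#' AO -R0- n1 -R1- n2 -R2- n3 -R3- n4 with branches n1 to A, n2 to B, n3 to C
#' and n4 to both D and E; ventilation at PEEP 2 cmH2O, ti 1 s, ttot 3 s,
#' constant flow 1.7 l/s by default.
#'
#' Two published variants of the shared resistances circulate: the values
#' quoted alongside the reference simulations (R0=1, R1=1, R2=2, R3=1; the
#' default) and a variant with R1=3. `shared = "alt"` selects the latter.
#'
#' Compartment A has the highest compliance and D the highest resistance;
#' the remaining compartments are intermediate, so the network mixes fast and
#' slow time constants deliberately.
#'
#' @param shared `"default"` (R1 = 1) or `"alt"` (R1 = 3).
#' @param mode,q_aw ventilator mode and constant-flow amplitude for the
#'   bundled settings.
#' @return list with elements `network` ([lung_network]) and `ventilator`
#'   ([ventilator_settings]).
#' @export
#' @examples
#' sc <- baseline_scenario()
#' sc$network$compartments
baseline_scenario <- function(shared = c("default", "alt"),
                              mode = "CF", q_aw = 1.7) {
  shared <- match.arg(shared)
  sr <- if (shared == "default") c(R0 = 1, R1 = 1, R2 = 2, R3 = 1)
        else                  c(R0 = 1, R1 = 3, R2 = 2, R3 = 1)
  topo <- data.frame(
    from = c("AO", "n1", "n2", "n3", "n1", "n2", "n3", "n4", "n4"),
    to   = c("n1", "n2", "n3", "n4", "A",  "B",  "C",  "D",  "E"),
    r    = c("R0", "R1", "R2", "R3", NA,   NA,   NA,   NA,   NA),
    stringsAsFactors = FALSE
  )
  comps <- data.frame(
    label  = c("A", "B", "C", "D", "E"),
    R      = c(1, 15, 11, 15, 7),
    C      = c(0.08, 0.06, 0.05, 0.02, 0.02),
    V_rest = c(1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  net <- lung_network(sr, topo, comps)
  vent <- ventilator_settings(mode = mode, peep = 2, ti = 1, ttot = 3,
                              q_aw = q_aw)
  list(network = net, ventilator = vent)
}

#' Validate a lung network
#'
#' Checks the structural and physical invariants of a [lung_network]:
#' positive resistances, compliances and resting volumes; unique compartment
#' labels; a rooted tree anchored at the airway opening `"AO"` through a
#' single root edge; each compartment a leaf reached through exactly one
#' terminal edge; every shared resistance on exactly one internal edge.
#'
#' @param net a [lung_network].
#' @return character vector of human-readable violations; empty iff valid.
#' @export
validate_network <- function(net) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  cp <- net$compartments
  topo <- net$topology
  sr <- net$shared_resistances

  if (anyDuplicated(cp$label))
    say("duplicate compartment labels: %s",
        paste(unique(cp$label[duplicated(cp$label)]), collapse = ", "))
  for (i in seq_len(nrow(cp))) {
    if (!is.finite(cp$R[i]) || cp$R[i] <= 0)
      say("compartment %s: resistance must be > 0 (got %s)", cp$label[i], cp$R[i])
    if (!is.finite(cp$C[i]) || cp$C[i] <= 0)
      say("compartment %s: compliance must be > 0 (got %s)", cp$label[i], cp$C[i])
    if (!is.finite(cp$V_rest[i]) || cp$V_rest[i] <= 0)
      say("compartment %s: rest volume must be > 0 (got %s)", cp$label[i], cp$V_rest[i])
  }
  if (anyDuplicated(names(sr)))
    say("duplicate shared resistance names")
  bad <- !is.finite(sr) | sr <= 0
  if (any(bad))
    say("shared resistance(s) must be > 0: %s", paste(names(sr)[bad], collapse = ", "))

  # structural checks
  if (anyDuplicated(topo$to))
    say("node(s) with more than one parent: %s",
        paste(unique(topo$to[duplicated(topo$to)]), collapse = ", "))
  if ("AO" %in% topo$to) say("the airway opening AO cannot have a parent")
  root_edges <- which(topo$from == "AO")
  if (length(root_edges) != 1L)
    say("exactly one edge must leave the airway opening AO (found %d)",
        length(root_edges))

  leaves <- setdiff(topo$to, topo$from)
  internal <- setdiff(unique(c(topo$from, topo$to)), c("AO", cp$label))
  orphans <- setdiff(cp$label, topo$to)
  for (o in orphans) say("compartment %s is not connected to the tree", o)
  for (lf in setdiff(leaves, cp$label))
    say("leaf node %s is not a declared compartment", lf)
  for (lb in intersect(cp$label, topo$from))
    say("compartment %s must be a leaf but has outgoing edges", lb)
  if (length(setdiff(cp$label, leaves)) == 0 &&
      length(setdiff(leaves, cp$label)) == 0 &&
      length(leaves) != nrow(cp))
    say("number of leaves (%d) != number of compartments (%d)",
        length(leaves), nrow(cp))

  # reachability from AO (tree connectivity)
  if (length(root_edges) == 1L) {
    reach <- "AO"
    repeat {
      nxt <- topo$to[topo$from %in% reach & !(topo$to %in% reach)]
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    unreach <- setdiff(unique(c(topo$from, topo$to)), reach)
    if (length(unreach))
      say("node(s) not reachable from AO: %s", paste(unreach, collapse = ", "))
  }

  # shared resistance <-> internal edge bijection
  internal_edges <- topo[!(topo$to %in% cp$label), , drop = FALSE]
  terminal_edges <- topo[topo$to %in% cp$label, , drop = FALSE]
  if (any(!is.na(terminal_edges$r)))
    say("terminal edges must not name a shared resistance (compartment R applies)")
  if (any(is.na(internal_edges$r)))
    say("internal edge(s) without a shared resistance name")
  used <- internal_edges$r[!is.na(internal_edges$r)]
  for (nm in setdiff(used, names(sr)))
    say("edge references undefined shared resistance %s", nm)
  if (anyDuplicated(used))
    say("shared resistance(s) on more than one edge: %s",
        paste(unique(used[duplicated(used)]), collapse = ", "))
  for (nm in setdiff(names(sr), used))
    say("shared resistance %s is not placed on any edge", nm)

  v
}

stop_if_invalid <- function(net) {
  v <- validate_network(net)
  if (length(v)) stop("invalid lung network:\n  ", paste(v, collapse = "\n  "),
                      call. = FALSE)
  invisible(net)
}
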
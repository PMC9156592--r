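# Independent oracles used across the suite. These deliberately take a
# different route from the package implementation: the Kirchhoff oracle
# assembles the FULL node system (airway opening included as an unknown) from
# the raw edge list; the steady-state oracle iterates the cycle map instead
# of solving its fixed point; the single-compartment oracles are closed-form
# RC solutions.

# Dense Kirchhoff solve over all node pressures, straight from the edge list.
# boundary: list(p_aw = ...) or list(q_aw = ...).
oracle_kirchhoff <- function(net, v, boundary) {
  cp <- net$compartments
  topo <- net$topology
  nodes <- setdiff(unique(c(topo$from, topo$to)), cp$label)  # AO + internal
  nn <- length(nodes)
  idx <- setNames(seq_len(nn), nodes)
  G <- matrix(0, nn, nn)
  rhs <- numeric(nn)
  p_leaf <- v / cp$C
  g_of <- function(e) {
    if (topo$to[e] %in% cp$label) 1 / cp$R[match(topo$to[e], cp$label)]
    else 1 / net$shared_resistances[[topo$r[e]]]
  }
  # conservation row for every node (AO's row later replaced/used by boundary)
  for (e in seq_len(nrow(topo))) {
    g <- g_of(e); u <- idx[[topo$from[e]]]
    if (topo$to[e] %in% cp$label) {
      i <- match(topo$to[e], cp$label)
      G[u, u] <- G[u, u] + g
      rhs[u] <- rhs[u] + g * p_leaf[i]
    } else {
      w <- idx[[topo$to[e]]]
      G[u, u] <- G[u, u] + g; G[w, w] <- G[w, w] + g
      G[u, w] <- G[u, w] - g; G[w, u] <- G[w, u] - g
    }
  }
  ao <- idx[["AO"]]
  if (!is.null(boundary$p_aw)) {
    G[ao, ] <- 0; G[ao, ao] <- 1; rhs[ao] <- boundary$p_aw
  } else {
    # AO conservation row currently reads: sum_out g (p_AO - p_child) = 0;
    # prescribe that net outflow instead
    rhs[ao] <- rhs[ao] + boundary$q_aw
  }
  p <- solve(G, rhs)
  names(p) <- nodes
  Q <- vapply(seq_len(nrow(cp)), function(i) {
    e <- which(topo$to == cp$label[i])
    (p[[topo$from[e]]] - p_leaf[i]) / cp$R[i]
  }, numeric(1))
  list(p = p, Q = setNames(Q, cp$label), P_aw = p[["AO"]])
}

# 200-cycle brute-force iteration of the cycle map via the phase simulator.
oracle_iterate_cycles <- function(net, settings, n_cycles = 200) {
  drive <- make_drive(settings)
  te <- settings$ttot - settings$ti
  v <- rep(0, nrow(net$compartments))
  for (k in seq_len(n_cycles)) {
    ph1 <- simulate_phase(net, drive, v, settings$ti, dt = settings$ti)
    ph2 <- simulate_phase(net, list(p_aw = settings$peep), ph1$end_state,
                          te, dt = te)
    v <- ph2$end_state
  }
  v
}

# two-edge degenerate network: AO -R0- n1 -R_A- single compartment
single_comp_net <- function(R0 = 1, R_A = 2, C = 0.05, V_rest = 1) {
  lung_network(
    shared_resistances = c(R0 = R0),
    topology = data.frame(from = c("AO", "n1"), to = c("n1", "A"),
                          r = c("R0", NA), stringsAsFactors = FALSE),
    compartments = data.frame(label = "A", R = R_A, C = C, V_rest = V_rest,
                              stringsAsFactors = FALSE)
  )
}

# randomized valid network: random tree of internal nodes with compartments
# attached, positive parameters in physiological-ish ranges
random_network <- function(n_comp = sample(2:6, 1)) {
  n_int <- sample(seq_len(min(3, n_comp)), 1)
  internal <- paste0("n", seq_len(n_int))
  edges <- data.frame(from = "AO", to = "n1", r = "R0",
                      stringsAsFactors = FALSE)
  if (n_int > 1) for (i in 2:n_int) {
    edges <- rbind(edges, data.frame(from = internal[sample(i - 1, 1)],
                                     to = internal[i],
                                     r = paste0("R", i - 1)))
  }
  labels <- LETTERS[seq_len(n_comp)]
  # every internal node must end up with at least one child
  childless <- setdiff(internal, edges$from)
  host <- c(childless, internal[sample.int(n_int, n_comp - length(childless),
                                           replace = TRUE)])
  for (i in seq_along(labels)) {
    edges <- rbind(edges, data.frame(from = host[i], to = labels[i], r = NA))
  }
  sr <- setNames(runif(n_int, 0.5, 4), paste0("R", seq_len(n_int) - 1))
  comps <- data.frame(label = labels,
                      R = runif(n_comp, 1, 20),
                      C = runif(n_comp, 0.01, 0.1),
                      V_rest = runif(n_comp, 0.3, 1.5),
                      stringsAsFactors = FALSE)
  lung_network(sr, edges, comps)
}

baseline_traj <- local({
  cache <- new.env(parent = emptyenv())
  function(mode = "CF", dt = 1e-3) {
    key <- paste(mode, dt)
    if (is.null(cache[[key]])) {
      sc <- baseline_scenario()
      s <- matched_settings(sc$network, sc$ventilator, modes = mode)[[1]]
      cache[[key]] <- find_periodic_steady_state(sc$network, s, dt = dt)
    }
    cache[[key]]
  }
})
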
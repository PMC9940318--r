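## Steady-state (0D) solution of a network: nodal analysis with Poiseuille
## segment resistances (consistent with the 1D solver's friction closure),
## nonlinear lumped stenosis resistances handled by damped fixed-point
## iteration, Windkessel terminals as series resistors to their mean
## intramyocardial back-pressure, and inflow ends held at the mean aortic
## pressure. Used by terminal calibration and as an independent low-frequency
## oracle for the pulsatile solver.

## Poiseuille resistance of a linearly tapered segment (CGS), for the
## axisymmetric profile of order zeta: dP/dx = -2(zeta+2) mu Q / (pi r^4).
segment_poiseuille_R <- function(length_cm, r_prox, r_dist, mu = blood_viscosity,
                                 zeta = 2) {
  int_r4 <- if (abs(r_dist - r_prox) < 1e-12) {
    length_cm / r_prox^4
  } else {
    length_cm / (r_dist - r_prox) * (1 / r_prox^3 - 1 / r_dist^3) / 3
  }
  2 * (zeta + 2) * mu / pi * int_r4
}

## stenosis linear + turbulent resistance coefficients (CGS):
## dP = Rv * Q + Rt * Q|Q| (+ inertance, zero in steady state)
stenosis_R_coefs <- function(sten, host_r) {
  D0 <- 2 * host_r
  A0 <- pi * host_r^2
  frac <- 1 - sten$percent_diameter / 100
  if (frac <= 0) stop("stenosis ", sten$id,
                      ": 100% diameter is an occlusion, not a stenosis")
  As <- A0 * frac^2
  Kv <- sten$K_v
  if (is.na(Kv)) Kv <- 32 * (sten$lesion_length_cm / D0) * (A0 / As)^2
  list(Rv = Kv * blood_viscosity / D0^3,
       Rt = sten$K_t * blood_density / (2 * A0^2) * (A0 / As - 1)^2,
       Lu = sten$K_u * blood_density * sten$lesion_length_cm / A0)
}

host_radius_at <- function(seg_row, pos)
  seg_row$radius_prox_cm +
    (seg_row$radius_dist_cm - seg_row$radius_prox_cm) * pos / seg_row$length_cm

## Build node indices: one node per junction, one per free (inflow/terminal)
## segment end. Returns list(node_of, n_nodes) with node_of a named vector
## over "seg|end" keys.
steady_nodes <- function(net) {
  key <- function(s, e) paste(s, e, sep = "|")
  node_of <- integer(0)
  n <- 0L
  for (j in unique(net$junctions$junction)) {
    n <- n + 1L
    rows <- net$junctions[net$junctions$junction == j, ]
    node_of[key(rows$segment, rows$end)] <- n
  }
  for (s in net$segments$id) for (e in c("proximal", "distal")) {
    k <- key(s, e)
    if (is.na(node_of[k])) { n <- n + 1L; node_of[k] <- n }
  }
  list(node_of = node_of, n_nodes = n)
}

#' Steady-state network solution
#'
#' Solves the network at the mean aortic pressure with purely resistive
#' elements (terminal compliances drop out in steady state).
#'
#' @param net a `coronary_network`.
#' @param zeta velocity-profile order for the Poiseuille friction closure.
#' @param mu blood viscosity (poise).
#' @param max_iter,tol fixed-point controls for the nonlinear stenosis
#'   resistances.
#' @return list with `segment_flows` (named, ml/s, positive proximal to
#'   distal), `terminal_flows` (named, ml/s), `territory_flows_ml_min`
#'   (named, ml/min), and `node_pressures_mmHg` at segment ends (named by
#'   `"segment|end"`).
#' @export
solve_steady <- function(net, zeta = 2, mu = blood_viscosity,
                         max_iter = 60L, tol = 1e-10) {
  stopifnot(inherits(net, "coronary_network"))
  g <- net$globals
  tgrid <- seq(0, g$period, length.out = 2048L)
  Pa <- mmHg_to_cgs(mean(eval_waveform(g$aortic, tgrid)))
  Plv <- mmHg_to_cgs(mean(eval_waveform(g$lv, tgrid)))

  nd <- steady_nodes(net)
  node_of <- nd$node_of
  key <- function(s, e) paste(s, e, sep = "|")

  seg <- net$segments
  ns <- nrow(seg)
  Rseg <- vapply(seq_len(ns), function(i)
    segment_poiseuille_R(seg$length_cm[i], seg$radius_prox_cm[i],
                         seg$radius_dist_cm[i], mu, zeta), numeric(1))
  sten_by_seg <- vector("list", ns)
  if (nrow(net$stenoses)) {
    for (i in seq_len(nrow(net$stenoses))) {
      st <- net$stenoses[i, ]
      si <- match(st$host_segment, seg$id)
      r <- host_radius_at(seg[si, ], st$position_cm)
      sten_by_seg[[si]] <- c(sten_by_seg[[si]],
                             list(stenosis_R_coefs(st, r)))
    }
  }
  a_node <- node_of[key(seg$id, "proximal")]
  b_node <- node_of[key(seg$id, "distal")]

  fixed <- rep(NA_real_, nd$n_nodes)
  for (i in seq_len(nrow(net$inflows)))
    fixed[node_of[key(net$inflows$segment[i], net$inflows$end[i])]] <- Pa

  term_node <- node_of[key(net$terminals$segment, "distal")]
  term_R <- res_to_cgs(net$terminals$R1 + net$terminals$R2)
  term_Pback <- net$terminals$gamma_im * Plv

  Q <- rep(1e-3, ns)  # ml/s, initial guess for stenosis linearisation
  P <- NULL
  for (it in seq_len(max_iter)) {
    Reff <- Rseg
    for (i in seq_len(ns)) {
      for (stc in sten_by_seg[[i]])
        Reff[i] <- Reff[i] + stc$Rv + stc$Rt * abs(Q[i])
    }
    G <- matrix(0, nd$n_nodes, nd$n_nodes)
    b <- rep(0, nd$n_nodes)
    add_edge <- function(a, bn, g_) {
      G[a, a] <<- G[a, a] + g_
      G[bn, bn] <<- G[bn, bn] + g_
      G[a, bn] <<- G[a, bn] - g_
      G[bn, a] <<- G[bn, a] - g_
    }
    for (i in seq_len(ns)) add_edge(a_node[i], b_node[i], 1 / Reff[i])
    for (i in seq_along(term_node)) {
      nn <- term_node[i]
      G[nn, nn] <- G[nn, nn] + 1 / term_R[i]
      b[nn] <- b[nn] + term_Pback[i] / term_R[i]
    }
    free <- is.na(fixed)
    if (!any(!free)) stop("steady solve needs at least one fixed-pressure inflow")
    bf <- b[free] - G[free, !free, drop = FALSE] %*% fixed[!free]
    Pfree <- solve(G[free, free, drop = FALSE], bf)
    P <- fixed
    P[free] <- Pfree
    Qnew <- (P[a_node] - P[b_node]) / Reff
    if (max(abs(Qnew - Q)) < tol * (1 + max(abs(Qnew)))) { Q <- Qnew; break }
    Q <- 0.5 * Q + 0.5 * Qnew
  }
  names(Q) <- seg$id
  qt <- (P[term_node] - term_Pback) / term_R
  names(qt) <- net$terminals$id
  terr <- tapply(qt * 60, net$terminals$territory, sum)
  node_p <- cgs_to_mmHg(P)
  names(node_p) <- names(node_of)[match(seq_along(P), node_of)]
  list(segment_flows = Q, terminal_flows = qt,
       territory_flows_ml_min = terr,
       node_pressures_mmHg = node_p[names(node_of)][order(node_of)] ,
       node_pressure_by_end = stats::setNames(cgs_to_mmHg(P[node_of]),
                                              names(node_of)))
}
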
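## Pulsatile 1D-0D solver front end: solver configuration, flattening of a
## coronary_network into the compiled core's mesh/boundary structures,
## periodic-cycle driver, and accessors over the returned cycle.

#' Solver configuration
#'
#' @param dx_cm target mesh spacing (each segment uses the nearest spacing
#'   that divides its length; at least 3 nodes per segment).
#' @param dt_s time step in seconds. Must satisfy the CFL bound
#'   `dt <= dx / max(|u| + c)` everywhere; the solver aborts naming the
#'   offending segment if it is violated.
#' @param max_cycles maximum cardiac cycles to run.
#' @param periodicity_tol relative cycle-to-cycle L2 change of all terminal
#'   flows below which the run is declared periodic.
#' @param rho blood density, g/ml.
#' @param mu blood viscosity, poise.
#' @param zeta velocity-profile order (friction `-2(zeta+2) pi mu Q / (rho A)`;
#'   2 = parabolic/Poiseuille).
#' @param dec_samples approximate number of stored samples per cycle.
#' @param profile `"standard"` (dx 0.1 cm, dt 2.95e-5 s) or `"fast"`
#'   (dx 0.5 cm, dt 2e-4 s), a coarse profile for quick runs whose time
#'   step keeps a CFL margin on the short mesh pieces created by
#'   anastomoses and stenosis interfaces; explicit `dx_cm`/`dt_s` override
#'   the profile.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(profile = c("standard", "fast"),
                          dx_cm = NULL, dt_s = NULL,
                          max_cycles = 20L, periodicity_tol = 1e-3,
                          rho = blood_density, mu = blood_viscosity,
                          zeta = 2, dec_samples = 1024L) {
  profile <- match.arg(profile)
  if (is.null(dx_cm)) dx_cm <- if (profile == "fast") 0.5 else 0.1
  if (is.null(dt_s)) dt_s <- if (profile == "fast") 2e-4 else 2.95e-5
  stopifnot(dx_cm > 0, dt_s > 0, max_cycles >= 1, periodicity_tol > 0)
  structure(list(profile = profile, dx_cm = dx_cm, dt_s = dt_s,
                 max_cycles = as.integer(max_cycles),
                 periodicity_tol = periodicity_tol, rho = rho, mu = mu,
                 zeta = zeta, dec_samples = as.integer(dec_samples)),
            class = "solver_config")
}

#' Read a solver configuration from YAML
#'
#' Expects a top-level `solver:` mapping, e.g.
#' `solver: {dx_cm: 0.1, dt_s: 2.95e-5, max_cycles: 20}`.
#'
#' @param path YAML file path.
#' @return a [solver_config()].
#' @export
read_solver_config <- function(path) {
  y <- yaml::read_yaml(path)
  s <- if (!is.null(y$solver)) y$solver else y
  args <- s[intersect(names(s),
                      setdiff(names(formals(solver_config)), "profile"))]
  if (!is.null(s$profile)) args$profile <- s$profile
  do.call(solver_config, args)
}

#' Tube law: transmural pressure from cross-sectional area
#'
#' `p = p_ref + beta (sqrt(A) - sqrt(A0)) / A0 + p_ext`; monotone
#' increasing in `A`.
#'
#' @param A_cm2 cross-sectional area, cm^2 (> 0).
#' @param beta_mmHg_cm tube-law stiffness, mmHg cm.
#' @param A0_cm2 reference area at `p_ref`.
#' @param p_ref_mmHg reference pressure.
#' @param p_ext_mmHg external (e.g. intramyocardial) pressure.
#' @return pressure in mmHg.
#' @export
tube_law <- function(A_cm2, beta_mmHg_cm, A0_cm2, p_ref_mmHg = 0,
                     p_ext_mmHg = 0) {
  if (any(A_cm2 <= 0)) stop("non-positive area in tube law (solver instability)")
  p_ref_mmHg + beta_mmHg_cm * (sqrt(A_cm2) - sqrt(A0_cm2)) / A0_cm2 +
    p_ext_mmHg
}

#' Tube-law pulse-wave speed
#'
#' `c = sqrt(beta sqrt(A) / (2 rho A0))` in cm/s.
#'
#' @inheritParams tube_law
#' @param rho blood density, g/ml.
#' @return wave speed, cm/s.
#' @export
wave_speed <- function(A_cm2, beta_mmHg_cm, A0_cm2, rho = blood_density) {
  sqrt(mmHg_to_cgs(beta_mmHg_cm) / A0_cm2 * sqrt(A_cm2) / (2 * rho))
}

#' Lumped stenosis pressure drop
#'
#' `dP = Kv mu Q / D0^3 + Kt rho/(2 A0^2) (A0/As - 1)^2 Q|Q| +
#'  Ku rho Ls/A0 dQ/dt`, with the stenotic area `As` from the percent
#' diameter reduction and, when `K_v` is `NA`, the length-scaled viscous
#' default `Kv = 32 (Ls/D0) (A0/As)^2`.
#'
#' @param Q_ml_s flow through the element, ml/s.
#' @param dQdt_ml_s2 flow time-derivative, ml/s^2.
#' @param stn one-row data.frame from [stenosis_element()].
#' @param host_radius_cm host vessel radius at the element, cm.
#' @return pressure drop in mmHg (odd in Q when the inertance term is off).
#' @export
stenosis_dp <- function(Q_ml_s, dQdt_ml_s2, stn, host_radius_cm) {
  coef <- stenosis_R_coefs(stn, host_radius_cm)
  cgs_to_mmHg(coef$Rv * Q_ml_s + coef$Rt * Q_ml_s * abs(Q_ml_s) +
              coef$Lu * dQdt_ml_s2)
}

#' One backward-Euler step of the RCR terminal ODE
#'
#' Advances `C dPc/dt = Q_in - (Pc - P_im)/R2 + C dP_im/dt`; the outlet
#' pressure seen by the 1D domain is `p = Pc + Q_in R1`. The compliance
#' stores volume against transmural pressure, so the `dP_im/dt` term
#' transmits ventricular contraction to the inlet flow (the diastolic-
#' dominant coronary signature); it averages to zero over a cycle and so
#' leaves the mean (DC) behaviour of the plain RCR unchanged. With
#' `P_im_prev_mmHg = P_im_mmHg` (default) the update is the plain RCR
#' step.
#'
#' @param Q_in_ml_s inflow into the terminal, ml/s.
#' @param terminal one-row data.frame from [windkessel_terminal()].
#' @param P_im_mmHg intramyocardial back-pressure at the new time level.
#' @param dt_s time step, s (> 0).
#' @param Pc_mmHg compliance-node pressure at the old time level.
#' @param P_im_prev_mmHg back-pressure at the old time level.
#' @return list with `p_mmHg` (outlet pressure) and `Pc_mmHg` (updated
#'   state).
#' @export
terminal_step <- function(Q_in_ml_s, terminal, P_im_mmHg, dt_s, Pc_mmHg,
                          P_im_prev_mmHg = P_im_mmHg) {
  stopifnot(dt_s > 0)
  a <- dt_s / terminal$C
  Pc_new <- (Pc_mmHg + (P_im_mmHg - P_im_prev_mmHg) +
             a * (Q_in_ml_s + P_im_mmHg / terminal$R2)) /
    (1 + a / terminal$R2)
  list(p_mmHg = Pc_new + Q_in_ml_s * terminal$R1, Pc_mmHg = Pc_new)
}

#' One interior Richtmyer two-step Lax-Wendroff update (reference version)
#'
#' Advances the interior nodes of a single uniform-geometry segment by one
#' time step (boundary nodes are left untouched); the compiled solver uses
#' the identical scheme. Exposed for verification: a uniform steady state
#' is an exact fixed point, and smooth pulses converge at second order.
#'
#' @param A,Q state vectors (cm^2, ml/s) on a uniform grid.
#' @param beta_mmHg_cm,A0_cm2 segment tube-law parameters (uniform).
#' @param dx_cm,dt_s grid spacing and time step.
#' @param rho blood density, g/ml; `mu` viscosity (poise); `zeta` profile
#'   order (friction off when `mu = 0`).
#' @param mu,zeta friction closure parameters.
#' @return list with updated `A`, `Q` (interior nodes advanced).
#' @export
lax_wendroff_step <- function(A, Q, beta_mmHg_cm, A0_cm2, dx_cm, dt_s,
                              rho = blood_density, mu = 0, zeta = 2) {
  n <- length(A)
  stopifnot(length(Q) == n, n >= 3)
  bh <- mmHg_to_cgs(beta_mmHg_cm) / A0_cm2
  cfun <- function(a) sqrt(bh * sqrt(a) / (2 * rho))
  smax <- max(abs(Q / A) + cfun(A))
  if (dt_s > dx_cm / smax)
    stop(sprintf("CFL violated: dt = %g exceeds dx/max(|u|+c) = %g",
                 dt_s, dx_cm / smax))
  fr <- 2 * (zeta + 2) * pi * mu / rho
  lam <- dt_s / dx_cm
  sa0 <- sqrt(A0_cm2)
  Fadv <- Q^2 / A
  p_n <- bh * (sqrt(A) - sa0)
  i <- seq_len(n - 1L)
  Aavg <- (A[i] + A[i + 1L]) / 2
  Qavg <- (Q[i] + Q[i + 1L]) / 2
  Ah <- Aavg - lam / 2 * (Q[i + 1L] - Q[i])
  src <- -(Aavg / rho) * (p_n[i + 1L] - p_n[i]) / dx_cm - fr * Qavg / Aavg
  Qh <- Qavg - lam / 2 * (Fadv[i + 1L] - Fadv[i]) + dt_s / 2 * src
  if (any(Ah <= 0)) stop("non-positive half-step area (solver instability)")
  Fh <- Qh^2 / Ah
  ph <- bh * (sqrt(Ah) - sa0)
  j <- seq(2L, n - 1L)
  An <- A; Qn <- Q
  An[j] <- A[j] - lam * (Qh[j] - Qh[j - 1L])
  Atil <- (Ah[j] + Ah[j - 1L]) / 2
  Qn[j] <- Q[j] - lam * (Fh[j] - Fh[j - 1L]) -
    dt_s / rho * Atil * (ph[j] - ph[j - 1L]) / dx_cm -
    dt_s * fr * Q[j] / A[j]
  list(A = An, Q = Qn)
}

## ---- mesh construction ----------------------------------------------------

## Split every stenosed segment at its element position; the split junction
## becomes a lumped-stenosis coupling rather than a plain junction. Also
## tracks, per stenosed input-level vessel, the mesh piece holding the
## vessel's distal end (the iFR measurement site, distal to all lesions).
## Returns list(net, stenosis_junctions, sites).
embed_stenoses <- function(net) {
  st_j <- data.frame(junction = character(), Rv = numeric(), Rt = numeric(),
                     Lu = numeric())
  hosts <- unique(net$stenoses$host_segment)
  vessel_of <- stats::setNames(hosts, hosts)       # current piece -> vessel
  distal_piece <- stats::setNames(hosts, hosts)    # vessel -> distal piece
  site_rows <- if (nrow(net$stenoses))
    data.frame(stenosis = net$stenoses$id, vessel = net$stenoses$host_segment)
  else data.frame(stenosis = character(), vessel = character())
  k <- 0L
  while (nrow(net$stenoses) > 0L) {
    st <- net$stenoses[1L, ]
    k <- k + 1L
    host <- st$host_segment
    vessel <- vessel_of[[host]]
    hrow <- net$segments[match(host, net$segments$id), ]
    coef <- stenosis_R_coefs(st, host_radius_at(hrow, st$position_cm))
    jid <- paste0("Jsten.", st$id)
    sp <- split_segment_at(net, host, st$position_cm,
                           prox_id = paste0(host, ".s", k, "p"),
                           dist_id = paste0(host, ".s", k, "d"),
                           junction_id = jid)
    net <- sp$net
    vessel_of[sp$prox_id] <- vessel
    vessel_of[sp$dist_id] <- vessel
    if (identical(distal_piece[[vessel]], host))
      distal_piece[vessel] <- sp$dist_id
    ## the element replaces the split junction; drop its row so later
    ## splits do not re-embed it
    net$stenoses <- net$stenoses[net$stenoses$id != st$id, ]
    st_j <- rbind(st_j, data.frame(junction = jid, Rv = coef$Rv,
                                   Rt = coef$Rt, Lu = coef$Lu))
  }
  site_rows$mesh_segment <- unname(distal_piece[site_rows$vessel])
  list(net = net, stenosis_junctions = st_j, sites = site_rows)
}

build_solver_mesh <- function(net, config) {
  emb <- embed_stenoses(net)
  wnet <- emb$net
  stenosis_sites <- emb$sites
  seg <- wnet$segments
  ns <- nrow(seg)
  n_nodes <- pmax(3L, as.integer(round(seg$length_cm / config$dx_cm)) + 1L)
  dx <- seg$length_cm / (n_nodes - 1L)
  off <- c(0L, cumsum(n_nodes))[seq_len(ns)]
  ntot <- sum(n_nodes)
  A0 <- bh <- numeric(ntot)
  for (s in seq_len(ns)) {
    x <- seq(0, seg$length_cm[s], length.out = n_nodes[s])
    drdx <- (seg$radius_dist_cm[s] - seg$radius_prox_cm[s]) / seg$length_cm[s]
    r <- seg$radius_prox_cm[s] + drdx * x
    idx <- off[s] + seq_len(n_nodes[s])
    A0[idx] <- pi * r^2
    bh[idx] <- mmHg_to_cgs(seg$beta_mmHg_cm[s]) / A0[idx]
  }
  seg_index <- function(ids) match(ids, seg$id) - 1L
  end01 <- function(e) ifelse(e == "distal", 1L, 0L)

  jn <- wnet$junctions
  st_ids <- emb$stenosis_junctions$junction
  plain_ids <- setdiff(unique(jn$junction), st_ids)
  junction_list <- lapply(plain_ids, function(j) {
    rows <- jn[jn$junction == j, ]
    cbind(seg_index(rows$segment), end01(rows$end))
  })
  stenosis_list <- lapply(seq_along(st_ids), function(k) {
    rows <- jn[jn$junction == st_ids[k], ]
    list(segL = seg_index(rows$segment[rows$end == "distal"]),
         segR = seg_index(rows$segment[rows$end == "proximal"]),
         Rv = emb$stenosis_junctions$Rv[k],
         Rt = emb$stenosis_junctions$Rt[k],
         Lu = emb$stenosis_junctions$Lu[k])
  })

  g <- wnet$globals
  nsteps <- as.integer(round(g$period / config$dt_s))
  dt <- g$period / nsteps
  tk <- (seq_len(nsteps) - 1L) * dt
  pref <- mmHg_to_cgs(g$reference_pressure_mmHg)

  ter <- wnet$terminals
  list(
    net = wnet,
    mesh = list(off = off, n = n_nodes, dx = dx, A0 = A0, bh = bh,
                gamma_ext = seg$gamma_ext,
                rho = config$rho,
                fr = 2 * (config$zeta + 2) * pi * config$mu / config$rho,
                pref = pref, seg_ids = seg$id),
    bc = list(
      pa = mmHg_to_cgs(eval_waveform(g$aortic, tk)),
      plv = mmHg_to_cgs(eval_waveform(g$lv, tk)),
      inflows = cbind(seg_index(wnet$inflows$segment),
                      end01(wnet$inflows$end)),
      junctions = junction_list,
      stenoses = stenosis_list,
      terminals = list(seg = seg_index(ter$segment),
                       R1 = res_to_cgs(ter$R1), R2 = res_to_cgs(ter$R2),
                       C = cap_to_cgs(ter$C), gamma_im = ter$gamma_im,
                       Pc0 = rep(mmHg_to_cgs(eval_waveform(g$aortic, 0)),
                                 nrow(ter)))),
    ctrl = list(dt = dt, nsteps = nsteps, max_cycles = config$max_cycles,
                tol = config$periodicity_tol,
                stride = max(1L, nsteps %/% config$dec_samples)),
    dt = dt, nsteps = nsteps, stenosis_sites = stenosis_sites
  )
}

#' Solve a network to a periodic state
#'
#' Runs whole cardiac cycles of the 1D-0D system, driven by the aortic
#' pressure waveform at every inflow attachment, until the relative
#' cycle-to-cycle L2 change of all terminal flows drops below the
#' configured tolerance (or `max_cycles` is reached, in which case the
#' result is flagged non-periodic). Deterministic given its inputs.
#'
#' @param net a valid `coronary_network`.
#' @param config a [solver_config()].
#' @return object of class `cycle_result`: decimated `(A, Q)` fields over
#'   the final cycle for all mesh nodes, full-resolution terminal flow
#'   series, the mesh-level network (stenoses embedded as interfaces), and
#'   convergence diagnostics.
#' @export
run_to_periodic <- function(net, config = solver_config()) {
  stopifnot(inherits(net, "coronary_network"))
  v <- validate_network(net)
  if (length(v)) stop("invalid network:\n  ", paste(v, collapse = "\n  "))
  built <- build_solver_mesh(net, config)
  out <- .lw_solve(built$mesh, built$bc, built$ctrl)
  if (!out$converged)
    warning(sprintf(
      "run did not reach periodicity in %d cycles (last residual %.3g)",
      out$cycles, tail(out$residuals, 1)))
  structure(list(
    time = as.numeric(out$time), A = out$A, Q = out$Q,
    terminal_Q = out$terminal_Q, Pc_mmHg = cgs_to_mmHg(out$Pc),
    dt = built$dt, nsteps = built$nsteps,
    net = built$net, mesh = built$mesh, config = config,
    input_net = net, stenosis_sites = built$stenosis_sites,
    converged = out$converged, cycles = out$cycles,
    residuals = as.numeric(out$residuals)), class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf(
    "cycle_result: %d segments / %d nodes, %d cycles (%s), residual %.2e\n",
    length(x$mesh$n), sum(x$mesh$n), x$cycles,
    if (x$converged) "periodic" else "NOT periodic",
    tail(x$residuals, 1)))
  invisible(x)
}

## ---- result accessors -----------------------------------------------------

mesh_node_index <- function(res, segment, position_cm) {
  s <- match(segment, res$mesh$seg_ids)
  if (is.na(s)) stop("unknown mesh segment '", segment, "'")
  n <- res$mesh$n[s]
  i <- round(position_cm / res$mesh$dx[s])
  i <- max(0L, min(n - 1L, i))
  as.integer(res$mesh$off[s] + i + 1L)
}

#' Extract a time series from a cycle result
#'
#' @param res a `cycle_result`.
#' @param segment mesh segment id (see `res$net$segments`; stenosis
#'   embedding splits host segments into `.s<k>p` / `.s<k>d` pieces).
#' @param position_cm position along the segment (clamped to the grid).
#' @param what `"Q"` (ml/s), `"A"` (cm^2) or `"p"` (mmHg).
#' @return data.frame with `t_s` and the requested series.
#' @export
result_series <- function(res, segment, position_cm,
                          what = c("Q", "A", "p")) {
  what <- match.arg(what)
  idx <- mesh_node_index(res, segment, position_cm)
  t <- res$time
  if (what == "Q") return(data.frame(t_s = t, Q_ml_s = res$Q[, idx]))
  if (what == "A") return(data.frame(t_s = t, A_cm2 = res$A[, idx]))
  s <- match(segment, res$mesh$seg_ids)
  g <- res$net$globals
  p_cgs <- res$mesh$pref +
    res$mesh$bh[idx] * (sqrt(res$A[, idx]) - sqrt(res$mesh$A0[idx])) +
    res$mesh$gamma_ext[s] * mmHg_to_cgs(eval_waveform(g$lv, t))
  data.frame(t_s = t, p_mmHg = cgs_to_mmHg(p_cgs))
}

#' Mean terminal and territory flows of a converged cycle
#'
#' @param res a `cycle_result`.
#' @return list with `terminal_ml_min` (named by terminal id) and
#'   `territory_ml_min` (named by territory; exact sums of their
#'   terminals).
#' @export
terminal_mean_flows <- function(res) {
  qbar <- rowMeans(res$terminal_Q) * 60
  names(qbar) <- res$net$terminals$id
  list(terminal_ml_min = qbar,
       territory_ml_min = tapply(qbar, res$net$terminals$territory, sum))
}

#' Junction mass-balance residuals over the stored cycle
#'
#' For each plain junction, the maximum over stored samples of
#' `|sum of signed end flows|` relative to the mean absolute through-flow.
#'
#' @param res a `cycle_result`.
#' @return named numeric vector of relative residuals.
#' @export
junction_mass_residuals <- function(res) {
  jn <- res$net$junctions
  plain <- setdiff(unique(jn$junction),
                   grep("^Jsten\\.", unique(jn$junction), value = TRUE))
  out <- vapply(plain, function(j) {
    rows <- jn[jn$junction == j, ]
    sgn <- ifelse(rows$end == "distal", 1, -1)
    idx <- vapply(seq_len(nrow(rows)), function(i) {
      s <- match(rows$segment[i], res$mesh$seg_ids)
      pos <- if (rows$end[i] == "distal") res$net$segments$length_cm[
        match(rows$segment[i], res$net$segments$id)] else 0
      mesh_node_index(res, rows$segment[i], pos)
    }, integer(1))
    qs <- res$Q[, idx, drop = FALSE]
    net_q <- as.numeric(qs %*% sgn)
    thr <- mean(abs(qs))
    max(abs(net_q)) / max(thr, 1e-12)
  }, numeric(1))
  names(out) <- plain
  out
}

#' Cyclic volume conservation check
#'
#' Compares inflow volume with total terminal outflow volume over the
#' stored cycle (both from full-resolution boundary series where
#' available).
#'
#' @param res a `cycle_result`.
#' @return list with `inflow_ml`, `outflow_ml` and `relative_error`.
#' @export
volume_conservation <- function(res) {
  inf <- res$net$inflows
  q_in <- 0
  for (i in seq_len(nrow(inf))) {
    s <- match(inf$segment[i], res$net$segments$id)
    pos <- if (inf$end[i] == "distal") res$net$segments$length_cm[s] else 0
    idx <- mesh_node_index(res, inf$segment[i], pos)
    sgn <- if (inf$end[i] == "distal") -1 else 1
    q_in <- q_in + sgn * mean(res$Q[, idx]) * res$nsteps * res$dt
  }
  q_out <- sum(rowMeans(res$terminal_Q)) * res$nsteps * res$dt
  list(inflow_ml = q_in, outflow_ml = q_out,
       relative_error = abs(q_in - q_out) / max(abs(q_in), 1e-12))
}
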
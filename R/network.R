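## Domain model of a coronary circulation: 1D vessel segments joined at
## junctions, lumped stenosis elements embedded in host segments, three-element
## Windkessel (RCR) terminals with intramyocardial back-pressure, inflow
## attachments driven by the aortic waveform, and named grafting-target
## markers. A network is a plain list of data.frames plus a `globals` list,
## with class "coronary_network".

SEGMENT_COLS <- c("id", "name", "length_cm", "radius_prox_cm", "radius_dist_cm",
                  "beta_mmHg_cm", "gamma_ext", "territory")
TERRITORIES <- c("LAD", "CIRC", "RCA", "graft", "systemic")

blood_density <- 1.06     # g/ml
blood_viscosity <- 0.035  # poise

#' Tube-law stiffness from a reference pulse-wave speed
#'
#' The tube law used throughout is `p = p_ref + beta * (sqrt(A) - sqrt(A0)) / A0`,
#' giving wave speed `c = sqrt(beta * sqrt(A) / (2 * rho * A0))`. This helper
#' returns the `beta` (mmHg cm) that yields wave speed `c0` at the reference
#' area of a vessel of radius `radius_cm`.
#'
#' @param radius_cm vessel radius (cm) at which `c0` should hold.
#' @param c0 pulse-wave speed in cm/s.
#' @param rho blood density (g/ml).
#' @return stiffness coefficient beta in mmHg cm.
#' @export
beta_from_wave_speed <- function(radius_cm, c0 = 900, rho = blood_density) {
  A0 <- pi * radius_cm^2
  cgs_to_mmHg(2 * rho * c0^2 * sqrt(A0))
}

#' Vessel segment constructor
#'
#' @param id unique segment identifier.
#' @param length_cm segment length (> 0), cm.
#' @param radius_prox_cm,radius_dist_cm proximal/distal lumen radius, cm
#'   (linear taper; either direction, both > 0).
#' @param beta_mmHg_cm tube-law stiffness (mmHg cm); default derived from a
#'   900 cm/s reference wave speed at the mean radius.
#' @param territory one of `LAD`, `CIRC`, `RCA`, `graft`, `systemic`.
#' @param gamma_ext fraction of the LV waveform applied as external pressure
#'   on the vessel wall (0 for epicardial vessels).
#' @param name display name.
#' @return one-row data.frame with the segment columns.
#' @export
vessel_segment <- function(id, length_cm, radius_prox_cm, radius_dist_cm,
                           beta_mmHg_cm = NULL, territory = "systemic",
                           gamma_ext = 0, name = id) {
  if (is.null(beta_mmHg_cm))
    beta_mmHg_cm <- beta_from_wave_speed((radius_prox_cm + radius_dist_cm) / 2)
  data.frame(id = id, name = name, length_cm = length_cm,
             radius_prox_cm = radius_prox_cm, radius_dist_cm = radius_dist_cm,
             beta_mmHg_cm = beta_mmHg_cm, gamma_ext = gamma_ext,
             territory = territory)
}

#' Lumped stenosis element constructor
#'
#' Pressure-drop model across the element (internal interface in its host
#' segment): `dP = Kv * mu * Q / D0^3 + Kt * rho / (2 A0^2) * (A0/As - 1)^2 *
#' Q|Q| + Ku * rho * Ls / A0 * dQ/dt`, with `As` the stenotic lumen area
#' implied by the percent diameter reduction. When `K_v` is `NA` it defaults
#' to `32 * (Ls/D0) * (A0/As)^2` at mesh time (viscous coefficient scaled
#' with lesion length and severity).
#'
#' @param id identifier.
#' @param host_segment id of the segment the element is embedded in.
#' @param position_cm distance of the element from the host's proximal end.
#' @param percent_diameter diameter reduction in percent, `0 <= x < 100`
#'   (100% is an occlusion and must be modelled as such, not as a stenosis).
#' @param lesion_length_cm lesion length (> 0), cm.
#' @param K_v,K_t,K_u viscous/turbulent/inertance coefficients
#'   (dimensionless; `K_v = NA` for the length-scaled default).
#' @return one-row data.frame.
#' @export
stenosis_element <- function(id, host_segment, position_cm, percent_diameter,
                             lesion_length_cm, K_v = NA_real_, K_t = 1.52,
                             K_u = 1.2) {
  data.frame(id = id, host_segment = host_segment, position_cm = position_cm,
             percent_diameter = percent_diameter,
             lesion_length_cm = lesion_length_cm,
             K_v = K_v, K_t = K_t, K_u = K_u)
}

#' Windkessel (RCR) terminal constructor
#'
#' @param id identifier.
#' @param segment id of the segment whose distal end carries this terminal.
#' @param R1,R2 proximal/distal resistance, mmHg s/ml (> 0).
#' @param C compliance, ml/mmHg (> 0).
#' @param territory perfusion territory label.
#' @param gamma_im fraction (0-1) of the LV pressure applied as
#'   intramyocardial back-pressure on the compliance.
#' @return one-row data.frame.
#' @export
windkessel_terminal <- function(id, segment, R1, R2, C, territory = "systemic",
                                gamma_im = 0) {
  data.frame(id = id, segment = segment, R1 = R1, R2 = R2, C = C,
             territory = territory, gamma_im = gamma_im)
}

#' Global haemodynamic settings
#'
#' @param aortic aortic root [pressure_waveform()] (inflow boundary).
#' @param lv left-ventricular [pressure_waveform()] (intramyocardial
#'   coupling).
#' @param heart_rate bpm.
#' @param period cardiac period in seconds (defaults to the aortic
#'   waveform's period).
#' @param cardiac_output_l_min cardiac output, L/min.
#' @param myocardial_fraction fraction of cardiac output perfusing the
#'   myocardium (in (0, 0.1)).
#' @param total_arterial_compliance_ml_mmHg systemic arterial compliance;
#'   the coronary share (scaled by `myocardial_fraction`) is distributed
#'   over the terminals at calibration.
#' @param territory_split named fractions of myocardial flow per territory.
#' @param reference_pressure_mmHg tube-law reference pressure at which the
#'   segment radii are defined; defaults to the mean aortic pressure.
#' @return a list with class `global_hemodynamics`.
#' @export
global_hemodynamics <- function(aortic = aortic_waveform(),
                                lv = lv_waveform(),
                                heart_rate = 65,
                                period = aortic$period,
                                cardiac_output_l_min = 5,
                                myocardial_fraction = 0.045,
                                total_arterial_compliance_ml_mmHg = 1.15,
                                territory_split = c(LAD = 0.40, CIRC = 0.30,
                                                    RCA = 0.30),
                                reference_pressure_mmHg = NULL) {
  stopifnot(inherits(aortic, "pressure_waveform"),
            inherits(lv, "pressure_waveform"))
  if (abs(period - 60 / heart_rate) > 0.05 * period)
    warning("period differs from 60/heart_rate by more than 5%")
  if (!(myocardial_fraction > 0 && myocardial_fraction < 0.1))
    stop("myocardial_fraction must lie in (0, 0.1)")
  if (abs(sum(territory_split) - 1) > 1e-6)
    stop("territory_split must sum to 1")
  if (is.null(reference_pressure_mmHg))
    reference_pressure_mmHg <- mean(eval_waveform(
      aortic, seq(0, period, length.out = 2048L)))
  structure(list(aortic = aortic, lv = lv, heart_rate = heart_rate,
                 period = period, cardiac_output_l_min = cardiac_output_l_min,
                 myocardial_fraction = myocardial_fraction,
                 total_arterial_compliance_ml_mmHg = total_arterial_compliance_ml_mmHg,
                 territory_split = territory_split,
                 reference_pressure_mmHg = reference_pressure_mmHg),
            class = "global_hemodynamics")
}

empty_junctions <- function()
  data.frame(junction = character(), segment = character(), end = character())
empty_stenoses <- function()
  data.frame(id = character(), host_segment = character(),
             position_cm = numeric(), percent_diameter = numeric(),
             lesion_length_cm = numeric(), K_v = numeric(), K_t = numeric(),
             K_u = numeric())
empty_markers <- function()
  data.frame(site = character(), segment = character(), position_cm = numeric())
empty_grafts <- function()
  data.frame(label = character(), conduit = character(), kind = character(),
             origin = character(), segment = character(),
             target_site = character(), target_side = character())

#' Assemble a coronary network
#'
#' @param segments data.frame of [vessel_segment()] rows.
#' @param junctions data.frame with columns `junction`, `segment`, `end`
#'   (`"proximal"`/`"distal"`); one row per segment end attached to a
#'   junction.
#' @param stenoses data.frame of [stenosis_element()] rows.
#' @param terminals data.frame of [windkessel_terminal()] rows.
#' @param inflows data.frame with columns `segment`, `end`: segment ends
#'   driven by the aortic pressure waveform.
#' @param markers data.frame with columns `site`, `segment`, `position_cm`:
#'   named grafting-target points (sites `LAD`, `OM`, `PDA`).
#' @param globals a [global_hemodynamics()] object.
#' @param grafts bookkeeping data.frame for applied grafts (created by
#'   [apply_configuration()]; leave default when building native anatomy).
#' @return object of class `coronary_network`.
#' @export
coronary_network <- function(segments, junctions = empty_junctions(),
                             stenoses = empty_stenoses(), terminals,
                             inflows, markers = empty_markers(),
                             globals = global_hemodynamics(),
                             grafts = empty_grafts()) {
  tidy <- function(d) { rownames(d) <- NULL; d }
  net <- structure(list(segments = tidy(segments), junctions = tidy(junctions),
                        stenoses = tidy(stenoses), terminals = tidy(terminals),
                        inflows = tidy(inflows), markers = tidy(markers),
                        grafts = tidy(grafts), globals = globals),
                   class = "coronary_network")
  v <- validate_network(net)
  if (length(v)) stop("invalid network:\n  ", paste(v, collapse = "\n  "))
  net
}

#' @export
print.coronary_network <- function(x, ...) {
  cat(sprintf(paste0("coronary_network: %d segments, %d junctions, ",
                     "%d stenoses, %d terminals, %d inflows, %d grafts\n"),
              nrow(x$segments),
              length(unique(x$junctions$junction)),
              nrow(x$stenoses), nrow(x$terminals), nrow(x$inflows),
              length(unique(x$grafts$label))))
  ter <- table(x$terminals$territory)
  cat("  terminals by territory:",
      paste(sprintf("%s=%d", names(ter), as.integer(ter)), collapse = ", "),
      "\n")
  invisible(x)
}

## all (segment, end) attachment records across junctions/inflows/terminals
attachment_table <- function(net) {
  nj <- nrow(net$junctions); ni <- nrow(net$inflows); nt <- nrow(net$terminals)
  rbind(
    data.frame(segment = net$junctions$segment, end = net$junctions$end,
               kind = rep("junction", nj)),
    data.frame(segment = net$inflows$segment, end = net$inflows$end,
               kind = rep("inflow", ni)),
    data.frame(segment = net$terminals$segment, end = rep("distal", nt),
               kind = rep("terminal", nt))
  )
}

#' Validate a coronary network
#'
#' Checks every structural invariant (positivity of geometry, stenosis and
#' terminal parameters, referential integrity of junctions/terminals/
#' markers, exactly one attachment per segment end, full connectivity from
#' the inflows) and returns descriptions of all violations; an empty
#' character vector means the network is simulatable.
#'
#' @param net a `coronary_network` (or plain list with the same fields).
#' @return character vector of violation descriptions (empty if valid).
#' @export
validate_network <- function(net) {
  v <- character()
  seg <- net$segments
  if (nrow(seg) == 0L) return("network has no segments")
  if (anyDuplicated(seg$id)) v <- c(v, "duplicate segment ids")
  bad <- seg$length_cm <= 0
  if (any(bad)) v <- c(v, sprintf("segment %s: non-positive length", seg$id[bad]))
  bad <- seg$radius_prox_cm <= 0 | seg$radius_dist_cm <= 0
  if (any(bad)) v <- c(v, sprintf("segment %s: non-positive radius", seg$id[bad]))
  bad <- seg$beta_mmHg_cm <= 0
  if (any(bad)) v <- c(v, sprintf("segment %s: non-positive beta", seg$id[bad]))
  bad <- !seg$territory %in% TERRITORIES
  if (any(bad)) v <- c(v, sprintf("segment %s: unknown territory '%s'",
                                  seg$id[bad], seg$territory[bad]))

  sten <- net$stenoses
  if (nrow(sten)) {
    bad <- !sten$host_segment %in% seg$id
    if (any(bad)) v <- c(v, sprintf("stenosis %s: unknown host segment '%s'",
                                    sten$id[bad], sten$host_segment[bad]))
    ok <- !bad
    if (any(ok)) {
      L <- seg$length_cm[match(sten$host_segment[ok], seg$id)]
      out <- sten$position_cm[ok] <= 0 | sten$position_cm[ok] >= L
      if (any(out)) v <- c(v, sprintf(
        "stenosis %s: position outside host segment", sten$id[ok][out]))
    }
    bad <- sten$percent_diameter < 0 | sten$percent_diameter >= 100
    if (any(bad)) v <- c(v, sprintf(
      "stenosis %s: percent_diameter must be in [0, 100)", sten$id[bad]))
    bad <- sten$lesion_length_cm <= 0
    if (any(bad)) v <- c(v, sprintf("stenosis %s: non-positive lesion length",
                                    sten$id[bad]))
    bad <- (!is.na(sten$K_v) & sten$K_v < 0) | sten$K_t < 0
    if (any(bad)) v <- c(v, sprintf("stenosis %s: negative K coefficient",
                                    sten$id[bad]))
  }

  ter <- net$terminals
  if (nrow(ter)) {
    bad <- !ter$segment %in% seg$id
    if (any(bad)) v <- c(v, sprintf("terminal %s: unknown segment '%s'",
                                    ter$id[bad], ter$segment[bad]))
    bad <- ter$R1 <= 0 | ter$R2 <= 0 | ter$C <= 0
    if (any(bad)) v <- c(v, sprintf("terminal %s: R1, R2, C must be positive",
                                    ter$id[bad]))
    bad <- ter$gamma_im < 0 | ter$gamma_im > 1
    if (any(bad)) v <- c(v, sprintf("terminal %s: gamma_im outside [0, 1]",
                                    ter$id[bad]))
  }

  jn <- net$junctions
  if (nrow(jn)) {
    bad <- !jn$segment %in% seg$id
    if (any(bad)) v <- c(v, sprintf("junction %s: unknown segment '%s'",
                                    jn$junction[bad], jn$segment[bad]))
    n_ends <- table(jn$junction)
    if (any(n_ends < 2)) v <- c(v, sprintf(
      "junction %s: fewer than two segment ends", names(n_ends)[n_ends < 2]))
  }

  att <- attachment_table(net)
  key <- paste(att$segment, att$end)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) v <- c(v, sprintf(
    "segment end %s attached more than once", unique(key[dup])))
  ## every segment end must be attached to exactly one of
  ## junction / inflow / terminal
  for (s in seg$id) for (e in c("proximal", "distal")) {
    if (!paste(s, e) %in% key)
      v <- c(v, sprintf("segment %s: %s end unattached (leaf needs an inflow or terminal)",
                        s, e))
  }
  if (nrow(net$inflows) == 0L) v <- c(v, "network has no inflow attachment")

  mk <- net$markers
  if (nrow(mk)) {
    bad <- !mk$segment %in% seg$id
    if (any(bad)) v <- c(v, sprintf("marker %s: unknown segment '%s'",
                                    mk$site[bad], mk$segment[bad]))
    ok <- !bad
    if (any(ok)) {
      L <- seg$length_cm[match(mk$segment[ok], seg$id)]
      out <- mk$position_cm[ok] < 0 | mk$position_cm[ok] > L
      if (any(out)) v <- c(v, sprintf("marker %s: position outside segment",
                                      mk$site[ok][out]))
    }
  }

  ## connectivity: every segment reachable from an inflow through junctions
  if (nrow(net$inflows) && !anyDuplicated(seg$id)) {
    adj <- split(jn$segment, jn$junction)
    reach <- unique(net$inflows$segment)
    repeat {
      grow <- unique(unlist(adj[vapply(adj, function(m) any(m %in% reach),
                                       logical(1))]))
      new <- setdiff(grow, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    orphan <- setdiff(seg$id, reach)
    if (length(orphan)) v <- c(v, sprintf(
      "segment %s: not connected to any inflow", orphan))
  }
  v
}

## --- internal topology surgery -------------------------------------------

## canonicalise row names after rbind-heavy surgery
tidy_network <- function(net) {
  for (nm in setdiff(names(net), "globals")) rownames(net[[nm]]) <- NULL
  net
}

new_junction_id <- function(net, stem = "J") {
  existing <- unique(net$junctions$junction)
  i <- 1L
  repeat {
    id <- sprintf("%s%d", stem, i)
    if (!id %in% existing) return(id)
    i <- i + 1L
  }
}

## Split a segment at an interior position. The two pieces are joined by a
## new junction (to which callers may attach further segment ends, e.g. a
## side branch or graft conduit). All references (junctions, inflows,
## terminals, stenoses, markers, graft bookkeeping) are remapped. Returns
## list(net, prox_id, dist_id, junction_id).
split_segment_at <- function(net, seg_id, pos, prox_id = NULL, dist_id = NULL,
                             junction_id = NULL) {
  i <- match(seg_id, net$segments$id)
  if (is.na(i)) stop("unknown segment '", seg_id, "'")
  s <- net$segments[i, ]
  if (pos <= 0 || pos >= s$length_cm)
    stop(sprintf("split position %.3f outside segment %s (length %.3f)",
                 pos, seg_id, s$length_cm))
  if (is.null(prox_id)) prox_id <- paste0(seg_id, ".p")
  if (is.null(dist_id)) dist_id <- paste0(seg_id, ".d")
  if (any(c(prox_id, dist_id) %in% net$segments$id))
    stop("split ids already in use")
  r_cut <- s$radius_prox_cm +
    (s$radius_dist_cm - s$radius_prox_cm) * pos / s$length_cm
  prox <- s; dist <- s
  prox$id <- prox_id; prox$name <- paste0(s$name, " (prox)")
  prox$length_cm <- pos; prox$radius_dist_cm <- r_cut
  dist$id <- dist_id; dist$name <- paste0(s$name, " (dist)")
  dist$length_cm <- s$length_cm - pos; dist$radius_prox_cm <- r_cut
  net$segments <- rbind(net$segments[-i, ], prox, dist)

  remap_end <- function(df) {
    if (!nrow(df)) return(df)
    hit <- df$segment == seg_id
    df$segment[hit & df$end == "proximal"] <- prox_id
    df$segment[hit & df$end == "distal"] <- dist_id
    df
  }
  net$junctions <- remap_end(net$junctions)
  net$inflows <- remap_end(net$inflows)
  if (nrow(net$terminals)) {
    hit <- net$terminals$segment == seg_id
    net$terminals$segment[hit] <- dist_id
  }
  remap_pos <- function(df) {
    if (!nrow(df)) return(df)
    hit <- df$segment == seg_id
    on_prox <- hit & df$position_cm <= pos
    on_dist <- hit & df$position_cm > pos
    df$segment[on_prox] <- prox_id
    df$segment[on_dist] <- dist_id
    df$position_cm[on_dist] <- df$position_cm[on_dist] - pos
    df
  }
  if (nrow(net$stenoses)) {
    hit <- net$stenoses$host_segment == seg_id
    on_prox <- hit & net$stenoses$position_cm <= pos
    on_dist <- hit & net$stenoses$position_cm > pos
    net$stenoses$host_segment[on_prox] <- prox_id
    net$stenoses$host_segment[on_dist] <- dist_id
    net$stenoses$position_cm[on_dist] <- net$stenoses$position_cm[on_dist] - pos
  }
  net$markers <- remap_pos(net$markers)
  if (nrow(net$grafts)) {
    hit <- net$grafts$segment == seg_id
    net$grafts$segment[hit] <- dist_id   # metric site is a distal end
  }
  if (is.null(junction_id)) junction_id <- new_junction_id(net, "Jsplit")
  net$junctions <- rbind(net$junctions,
                         data.frame(junction = junction_id,
                                    segment = c(prox_id, dist_id),
                                    end = c("distal", "proximal")))
  list(net = net, prox_id = prox_id, dist_id = dist_id,
       junction_id = junction_id)
}
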
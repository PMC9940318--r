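## Synthetic patient archetypes: five triple-vessel-disease coronary
## circulations with the published stenosis patterns (location class,
## percent diameter, lesion length), patient-specific branch plans (ramus
## intermedius for patients 1-2, additional milder lesions for 3-4, an
## in-stent restenosis for 5), three perfusion territories, side branches,
## calibrated terminals and LAD/OM/PDA grafting-target markers. The
## epicardial dimensions are literature-typical stand-ins, so downstream
## flow predictions are qualitative, not reconstructions of any real
## patient.

## stenosis plans: host segment, position (cm), percent diameter, length
## (cm). Positions sit at the centres of the 1.5 cm inter-branch intervals
## so stenosis interfaces never create mesh pieces shorter than 0.75 cm.
ARCHETYPE_STENOSES <- list(
  `1` = data.frame(
    id = c("LAD-mid-90", "CIRC-prox-95", "RCA-ostial-99"),
    host = c("LAD", "CIRCa", "RCA"),
    pos = c(3.75, 0.75, 0.75),
    pct = c(90, 95, 99),
    len = c(2.2, 0.7, 0.6)),
  `2` = data.frame(
    id = c("LAD-prox-95", "OM1-prox-75", "RCA-prox-99"),
    host = c("LAD", "OM", "RCA"),
    pos = c(0.75, 0.75, 0.75),
    pct = c(95, 75, 99),
    len = c(0.9, 2.0, 1.8)),
  `3` = data.frame(
    id = c("LAD1-40", "LAD2-mid-85", "CIRC1-30", "CIRC2-prox-75",
           "RCA1-45", "RCA2-mid-90"),
    host = c("LAD", "LAD", "CIRCa", "CIRCa", "RCA", "RCA"),
    pos = c(0.75, 3.75, 0.75, 2.25, 2.25, 5.25),
    pct = c(40, 85, 30, 75, 45, 90),
    len = c(0.5, 1.1, 0.4, 0.8, 0.9, 2.0)),
  `4` = data.frame(
    id = c("LMCA-mid-80", "LAD-prox-75", "RCA-mid-95", "PLB-30"),
    host = c("LM", "LAD", "RCA", "PLB"),
    pos = c(0.5, 0.75, 5.25, 0.75),
    pct = c(80, 75, 95, 30),
    len = c(1.2, 0.8, 1.5, 1.0)),
  `5` = data.frame(
    id = c("LAD-ISR-90", "OM2-prox-99", "RCA-mid-90"),
    host = c("LAD", "OM", "RCA"),
    pos = c(0.75, 0.75, 5.25),
    pct = c(90, 99, 90),
    len = c(1.6, 1.2, 1.5))
)

archetype_base_tree <- function(patient_id) {
  has_ramus <- patient_id %in% c(1L, 2L)
  om2 <- patient_id %in% c(4L, 5L)       # patients 4-5 graft the OM2
  circ_a_len <- if (om2) 4.5 else 3.0    # OM take-off along the circumflex
  circ_len <- 7.5
  r_circ_cut <- 0.15 + (0.10 - 0.15) * circ_a_len / circ_len

  segs <- rbind(
    vessel_segment("LM", 1.0, 0.20, 0.19, territory = "LAD",
                   name = "left main"),
    vessel_segment("LAD", 10, 0.16, 0.10, territory = "LAD",
                   name = "left anterior descending"),
    vessel_segment("CIRCa", circ_a_len, 0.15, r_circ_cut, territory = "CIRC",
                   name = "circumflex (proximal)"),
    vessel_segment("CIRCb", circ_len - circ_a_len, r_circ_cut, 0.10,
                   territory = "CIRC", name = "circumflex (distal)"),
    vessel_segment("OM", 6, 0.12, 0.07, territory = "CIRC",
                   name = if (om2) "second obtuse marginal"
                          else "first obtuse marginal"),
    vessel_segment("RCA", 12, 0.17, 0.10, territory = "RCA",
                   name = "right coronary artery"),
    vessel_segment("PDA", 4, 0.11, 0.07, territory = "RCA",
                   name = "posterior descending"),
    vessel_segment("PLB", 3, 0.09, 0.06, territory = "RCA",
                   name = "posterolateral branch"))
  lm_children <- c("LAD", "CIRCa")
  if (has_ramus) {
    segs <- rbind(segs,
      vessel_segment("RAMUS", 4.5, 0.10, 0.06, territory = "CIRC",
                     name = "ramus intermedius"))
    lm_children <- c(lm_children, "RAMUS")
  }
  jn <- rbind(
    data.frame(junction = "Jlm",
               segment = c("LM", lm_children),
               end = c("distal", rep("proximal", length(lm_children)))),
    data.frame(junction = "Jom", segment = c("CIRCa", "CIRCb", "OM"),
               end = c("distal", "proximal", "proximal")),
    data.frame(junction = "Jpda", segment = c("RCA", "PDA", "PLB"),
               end = c("distal", "proximal", "proximal")))
  leaves <- c(LAD = "LAD", CIRCb = "CIRC", OM = "CIRC", PDA = "RCA",
              PLB = "RCA")
  if (has_ramus) leaves <- c(leaves, RAMUS = "CIRC")
  ter <- do.call(rbind, lapply(names(leaves), function(s)
    windkessel_terminal(paste0("t.", s), s, R1 = 1, R2 = 100, C = 1e-3,
                        territory = leaves[[s]],
                        gamma_im = GAMMA_IM_DEFAULTS[[leaves[[s]]]])))
  coronary_network(
    segments = segs, junctions = jn, terminals = ter,
    inflows = data.frame(segment = c("LM", "RCA"),
                         end = c("proximal", "proximal")),
    markers = data.frame(site = c("LAD", "OM", "PDA"),
                         segment = c("LAD", "OM", "PDA"),
                         position_cm = c(6.75, 3.75, 2.25)))
}

#' Build a synthetic patient archetype network
#'
#' Constructs the epicardial tree (with the patient-specific branch plan),
#' populates side branches, calibrates the terminals on the healthy tree,
#' and finally installs the patient's stenoses. Deterministic.
#'
#' @param patient_id integer 1-5.
#' @param diseased if `FALSE`, return the calibrated healthy
#'   (stenosis-free) circulation.
#' @param side_branches insert side branches before calibration.
#' @return a calibrated `coronary_network` with target markers.
#' @export
patient_archetype <- function(patient_id, diseased = TRUE,
                              side_branches = TRUE) {
  patient_id <- as.integer(patient_id)
  if (!patient_id %in% 1:5) stop("unknown patient archetype id (need 1-5)")
  cache_key <- sprintf("archetype.%d.%d", patient_id, side_branches)
  healthy <- .graftflow_cache[[cache_key]]
  if (is.null(healthy)) {
    net <- archetype_base_tree(patient_id)
    if (side_branches) net <- populate_side_branches(net)
    healthy <- calibrate_terminals(net)
    .graftflow_cache[[cache_key]] <- healthy
  }
  net <- healthy
  if (diseased) {
    plan <- ARCHETYPE_STENOSES[[as.character(patient_id)]]
    st <- stenosis_element(plan$id, plan$host, plan$pos, plan$pct, plan$len)
    ## hosts may have been split by side-branch insertion (pieces
    ## <host>.m<k> every 1.5 cm): remap each element onto the piece
    ## covering its position
    spacing <- 1.5
    for (i in seq_len(nrow(st))) {
      host <- st$host_segment[i]
      if (host %in% net$segments$id) next
      k <- floor(st$position_cm[i] / spacing)
      piece <- sprintf("%s.m%d", host, k)
      if (!piece %in% net$segments$id)
        stop("internal: cannot remap stenosis host ", host)
      st$host_segment[i] <- piece
      st$position_cm[i] <- st$position_cm[i] - k * spacing
    }
    net$stenoses <- rbind(net$stenoses, st)
    v <- validate_network(net)
    if (length(v)) stop("archetype stenoses invalid:\n  ",
                        paste(v, collapse = "\n  "))
  }
  tidy_network(net)
}

#' Random disease scenario generator
#'
#' Places reproducible random stenoses on a base network: same seed, same
#' network.
#'
#' @param base_net a `coronary_network` (typically a healthy archetype).
#' @param scenario list with `seed`, `n_stenoses`, optional `hosts`
#'   (candidate segment ids; defaults to all non-graft segments at least
#'   2 cm long), `severity_range` (percent diameter, within `[0, 100)`)
#'   and `length_range` (cm).
#' @return a `coronary_network` with the drawn stenoses added.
#' @export
random_disease <- function(base_net, scenario) {
  stopifnot(inherits(base_net, "coronary_network"))
  if (is.null(scenario$seed)) stop("scenario needs a seed")
  n <- scenario$n_stenoses
  if (is.null(n)) stop("scenario needs n_stenoses")
  if (n == 0) return(base_net)
  sev <- scenario$severity_range %||% c(70, 95)
  len <- scenario$length_range %||% c(0.5, 2)
  if (sev[1] < 0 || sev[2] >= 100 || sev[1] > sev[2])
    stop("severity_range must lie within [0, 100)")
  hosts <- scenario$hosts
  if (is.null(hosts)) {
    s <- base_net$segments
    hosts <- s$id[s$territory != "graft" & s$length_cm >= 1.2]
  }
  if (length(hosts) == 0L) stop("no eligible host segments for stenoses")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(scenario$seed)
  pick <- sample(hosts, n, replace = n > length(hosts))
  seg <- base_net$segments
  st <- do.call(rbind, lapply(seq_len(n), function(i) {
    L <- seg$length_cm[match(pick[i], seg$id)]
    stenosis_element(sprintf("rand-%d", i), pick[i],
                     position_cm = stats::runif(1, 0.15 * L, 0.85 * L),
                     percent_diameter = stats::runif(1, sev[1], sev[2]),
                     lesion_length_cm = stats::runif(1, len[1], len[2]))
  }))
  base_net$stenoses <- rbind(base_net$stenoses, st)
  v <- validate_network(base_net)
  if (length(v)) stop("random disease produced an invalid network:\n  ",
                      paste(v, collapse = "\n  "))
  tidy_network(base_net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
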
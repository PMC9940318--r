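## Graft configurator: builds each of the twelve total-arterial grafting
## topologies (A-L) on any coronary network carrying LAD/OM/PDA target
## markers. Conduits are 1D segments; anastomoses are junctions (no
## anastomotic loss element - the model addresses flow competition, not
## technical error). Configurations A-D involve an aorto-coronary graft
## ("aortic"); E-L have no aortic anastomosis ("anaortic").
##
##   A: in situ LIMA-LAD; free RIMA Y (off LIMA)-OM; free RIMA (off aorta)-PDA
##   B: in situ LIMA-LAD; in situ RIMA (transverse sinus)-OM; RA (aorta)-PDA
##   C: in situ LIMA-LAD; RA (aorta)-OM; in situ RIMA-PDA
##   D: in situ RIMA-LAD; in situ LIMA-OM; RA (aorta)-PDA
##   E: in situ LIMA-LAD; RA Y (off LIMA)-OM; in situ RIMA-PDA
##   F: in situ LIMA-LAD; in situ RIMA-OM; RA Y (off RIMA)-PDA
##   G: in situ LIMA-LAD; free RIMA Y (off LIMA)-OM; RA Y (off RIMA)-PDA
##   H: in situ LIMA-LAD; free RIMA Y (off LIMA)-OM sequential to PDA
##   I: in situ LIMA-LAD; in situ RIMA-PDA, RA I-extension sequential to OM
##   J: in situ LIMA-LAD; in situ RIMA (transverse sinus)-OM, RA I-extension
##      sequential to PDA
##   K: in situ LIMA-OM; free RIMA Y (off LIMA)-LAD, RA I-extension
##      sequential to PDA
##   L: in situ LIMA-LAD; in situ RIMA-OM; RA jump graft (off distal LAD)-PDA

GRAFT_CONFIG_IDS <- LETTERS[1:12]

CONDUIT_DEFAULTS <- list(
  LIMA = list(diameter_cm = 0.20, length_cm = 17, c0 = 1100,
              origin = "in_situ_subclavian"),
  RIMA = list(diameter_cm = 0.20, length_cm = 19, c0 = 1100,
              origin = "in_situ_subclavian"),
  RA   = list(diameter_cm = 0.27, length_cm = 20, c0 = 1300,
              origin = "aorta")
)

#' Construct a graft conduit description
#'
#' Defaults: internal mammary arteries 2.0 mm diameter (LIMA 17 cm, RIMA
#' 19 cm, 21 cm via the transverse sinus), radial artery 2.7 mm and
#' stiffer wall; `in_situ_subclavian` origin is only valid for the IMAs.
#'
#' @param kind `"LIMA"`, `"RIMA"` or `"RA"`.
#' @param diameter_cm,length_cm,origin,beta_mmHg_cm overrides (positive).
#' @return one-row data.frame describing the conduit.
#' @export
make_conduit <- function(kind = c("LIMA", "RIMA", "RA"), diameter_cm = NULL,
                         length_cm = NULL, origin = NULL,
                         beta_mmHg_cm = NULL) {
  kind <- match.arg(kind)
  def <- CONDUIT_DEFAULTS[[kind]]
  if (is.null(diameter_cm)) diameter_cm <- def$diameter_cm
  if (is.null(length_cm)) length_cm <- def$length_cm
  if (is.null(origin)) origin <- def$origin
  if (diameter_cm <= 0 || length_cm <= 0)
    stop("conduit diameter and length must be positive")
  if (origin == "in_situ_subclavian" && kind == "RA")
    stop("the radial artery is a free conduit: in situ origin is invalid")
  if (is.null(beta_mmHg_cm))
    beta_mmHg_cm <- beta_from_wave_speed(diameter_cm / 2, c0 = def$c0)
  data.frame(kind = kind, diameter_cm = diameter_cm, length_cm = length_cm,
             origin = origin, beta_mmHg_cm = beta_mmHg_cm)
}

target_side_of <- function(site) if (site %in% c("LAD", "OM")) "left" else "right"

## builder state helpers ----------------------------------------------------

marker_row <- function(net, site) {
  i <- match(site, net$markers$site)
  if (is.na(i)) stop("configuration error: missing '", site,
                     "' grafting-target marker")
  net$markers[i, ]
}

## add a conduit segment; attach = "inflow" (aortic/subclavian pressure
## source) or a junction id
add_conduit_piece <- function(net, id, conduit, length_cm, attach) {
  r <- conduit$diameter_cm / 2
  net$segments <- rbind(net$segments,
    vessel_segment(id, length_cm, r, r,
                   beta_mmHg_cm = conduit$beta_mmHg_cm,
                   territory = "graft", name = id))
  if (identical(attach, "inflow")) {
    net$inflows <- rbind(net$inflows,
                         data.frame(segment = id, end = "proximal"))
  } else {
    net$junctions <- rbind(net$junctions,
      data.frame(junction = attach, segment = id, end = "proximal"))
  }
  net
}

## anastomose the distal end of a conduit piece onto a marker site;
## returns list(net, junction) - the junction can take a continuation piece
## for a side-to-side (sequential) touchdown
anastomose_at_marker <- function(net, piece_id, site) {
  mk <- marker_row(net, site)
  sp <- split_segment_at(net, mk$segment, mk$position_cm,
                         junction_id = paste0("Jgraft.", site))
  net <- sp$net
  net$junctions <- rbind(net$junctions,
    data.frame(junction = sp$junction_id, segment = piece_id, end = "distal"))
  list(net = net, junction = sp$junction_id)
}

## split a conduit at a Y-origin point; returns list(net, junction)
y_split <- function(net, piece_id, at_cm = 10) {
  L <- net$segments$length_cm[match(piece_id, net$segments$id)]
  pos <- if (at_cm < L) at_cm else 0.6 * L
  sp <- split_segment_at(net, piece_id, pos,
                         junction_id = paste0("Jy.", piece_id))
  list(net = sp$net, junction = sp$junction_id)
}

register_graft <- function(net, label, conduit_kind, origin, piece_id, site) {
  net$grafts <- rbind(net$grafts, data.frame(
    label = label, conduit = conduit_kind, kind = conduit_kind,
    origin = origin, segment = piece_id, target_site = site,
    target_side = target_side_of(site)))
  net
}

## one simple end-to-side graft: conduit from its origin to a marker
simple_graft <- function(net, id, kind, site, length_cm = NULL,
                         origin = NULL) {
  cd <- make_conduit(kind, length_cm = length_cm, origin = origin)
  net <- add_conduit_piece(net, id, cd, cd$length_cm, "inflow")
  an <- anastomose_at_marker(net, id, site)
  net <- register_graft(an$net, paste(graft_name(kind), "to", site), kind,
                        cd$origin, id, site)
  list(net = net, junction = an$junction, conduit = cd)
}

graft_name <- function(kind) if (kind == "RA") "Radial" else kind

#' Apply a grafting configuration to a network
#'
#' Builds the conduits and anastomoses of configuration `config_id` on a
#' copy of `net` (native stenoses untouched; target-vessel runoff
#' preserved). The input must carry `LAD`, `OM` and `PDA` markers.
#'
#' @param net a `coronary_network` with grafting-target markers.
#' @param config_id one of `"A"`..`"L"`.
#' @return a new, valid `coronary_network` with the grafts installed and
#'   bookkeeping rows in `net$grafts`.
#' @export
apply_configuration <- function(net, config_id) {
  stopifnot(inherits(net, "coronary_network"))
  if (!config_id %in% GRAFT_CONFIG_IDS)
    stop("config_id must be one of A-L")
  for (s in c("LAD", "OM", "PDA")) marker_row(net, s)
  if (nrow(net$grafts) > 0L) stop("network already carries grafts")

  lima_lad <- function(net) simple_graft(net, "LIMA", "LIMA", "LAD")

  net <- switch(config_id,
    A = {
      g <- lima_lad(net); net <- g$net
      y <- y_split(net, "LIMA"); net <- y$net
      cd <- make_conduit("RIMA", length_cm = 14, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RIMAy", cd, 14, y$junction)
      an <- anastomose_at_marker(net, "RIMAy", "OM")
      net <- register_graft(an$net, "RIMA to OM", "RIMA", "parent_conduit",
                            "RIMAy", "OM")
      cd2 <- make_conduit("RIMA", length_cm = 12, origin = "aorta")
      net <- add_conduit_piece(net, "RIMAao", cd2, 12, "inflow")
      an <- anastomose_at_marker(net, "RIMAao", "PDA")
      register_graft(an$net, "RIMA to PDA", "RIMA", "aorta", "RIMAao", "PDA")
    },
    B = {
      net <- lima_lad(net)$net
      net <- simple_graft(net, "RIMA", "RIMA", "OM", length_cm = 21)$net
      simple_graft(net, "RA", "RA", "PDA", length_cm = 14)$net
    },
    C = {
      net <- lima_lad(net)$net
      net <- simple_graft(net, "RA", "RA", "OM", length_cm = 12)$net
      simple_graft(net, "RIMA", "RIMA", "PDA")$net
    },
    D = {
      net <- simple_graft(net, "RIMA", "RIMA", "LAD")$net
      net <- simple_graft(net, "LIMA", "LIMA", "OM")$net
      simple_graft(net, "RA", "RA", "PDA", length_cm = 14)$net
    },
    E = {
      g <- lima_lad(net); net <- g$net
      y <- y_split(net, "LIMA"); net <- y$net
      cd <- make_conduit("RA", length_cm = 12, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RAy", cd, 12, y$junction)
      an <- anastomose_at_marker(net, "RAy", "OM")
      net <- register_graft(an$net, "Radial to OM", "RA", "parent_conduit",
                            "RAy", "OM")
      simple_graft(net, "RIMA", "RIMA", "PDA")$net
    },
    F = {
      net <- lima_lad(net)$net
      g <- simple_graft(net, "RIMA", "RIMA", "OM"); net <- g$net
      y <- y_split(net, "RIMA"); net <- y$net
      cd <- make_conduit("RA", length_cm = 12, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RAy", cd, 12, y$junction)
      an <- anastomose_at_marker(net, "RAy", "PDA")
      register_graft(an$net, "Radial to PDA", "RA", "parent_conduit",
                     "RAy", "PDA")
    },
    G = {
      g <- lima_lad(net); net <- g$net
      y <- y_split(net, "LIMA"); net <- y$net
      cd <- make_conduit("RIMA", length_cm = 14, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RIMAy", cd, 14, y$junction)
      an <- anastomose_at_marker(net, "RIMAy", "OM")
      net <- register_graft(an$net, "RIMA to OM", "RIMA", "parent_conduit",
                            "RIMAy", "OM")
      y2 <- y_split(net, "RIMAy"); net <- y2$net
      cd2 <- make_conduit("RA", length_cm = 12, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RAy", cd2, 12, y2$junction)
      an <- anastomose_at_marker(net, "RAy", "PDA")
      register_graft(an$net, "Radial to PDA", "RA", "parent_conduit",
                     "RAy", "PDA")
    },
    H = {
      g <- lima_lad(net); net <- g$net
      y <- y_split(net, "LIMA"); net <- y$net
      cd <- make_conduit("RIMA", length_cm = 14, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RIMAy", cd, 14, y$junction)
      an <- anastomose_at_marker(net, "RIMAy", "OM")   # side-to-side
      net <- register_graft(an$net, "RIMA to OM", "RIMA", "parent_conduit",
                            "RIMAy", "OM")
      net <- add_conduit_piece(net, "RIMAseq", cd, 8, an$junction)
      an2 <- anastomose_at_marker(net, "RIMAseq", "PDA")
      register_graft(an2$net, "RIMA to PDA", "RIMA", "parent_conduit",
                     "RIMAseq", "PDA")
    },
    I = {
      net <- lima_lad(net)$net
      g <- simple_graft(net, "RIMA", "RIMA", "PDA")   # side-to-side first
      net <- g$net
      cd <- make_conduit("RA", length_cm = 8, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RAext", cd, 8, g$junction)
      an <- anastomose_at_marker(net, "RAext", "OM")
      register_graft(an$net, "Radial to OM", "RA", "parent_conduit",
                     "RAext", "OM")
    },
    J = {
      net <- lima_lad(net)$net
      g <- simple_graft(net, "RIMA", "RIMA", "OM", length_cm = 21)
      net <- g$net
      cd <- make_conduit("RA", length_cm = 8, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RAext", cd, 8, g$junction)
      an <- anastomose_at_marker(net, "RAext", "PDA")
      register_graft(an$net, "Radial to PDA", "RA", "parent_conduit",
                     "RAext", "PDA")
    },
    K = {
      g <- simple_graft(net, "LIMA", "LIMA", "OM"); net <- g$net
      y <- y_split(net, "LIMA"); net <- y$net
      cd <- make_conduit("RIMA", length_cm = 14, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RIMAy", cd, 14, y$junction)
      an <- anastomose_at_marker(net, "RIMAy", "LAD")  # side-to-side
      net <- register_graft(an$net, "RIMA to LAD", "RIMA", "parent_conduit",
                            "RIMAy", "LAD")
      cd2 <- make_conduit("RA", length_cm = 8, origin = "parent_conduit")
      net <- add_conduit_piece(net, "RAext", cd2, 8, an$junction)
      an2 <- anastomose_at_marker(net, "RAext", "PDA")
      register_graft(an2$net, "Radial to PDA", "RA", "parent_conduit",
                     "RAext", "PDA")
    },
    L = {
      g <- lima_lad(net); net <- g$net
      net <- simple_graft(net, "RIMA", "RIMA", "OM")$net
      ## jump graft off the LAD just beyond the LIMA touchdown: split the
      ## runoff piece when it is long enough, otherwise take off at its
      ## distal junction (still downstream of the touchdown)
      rows <- net$junctions[net$junctions$junction == "Jgraft.LAD", ]
      runoff <- rows$segment[rows$end == "proximal"]
      Lr <- net$segments$length_cm[match(runoff, net$segments$id)]
      jn_dist <- net$junctions$junction[net$junctions$segment == runoff &
                                          net$junctions$end == "distal"]
      if (Lr >= 1.6) {
        sp <- split_segment_at(net, runoff, 0.8, junction_id = "Jjump.LAD")
        net <- sp$net
        jump_j <- sp$junction_id
      } else if (length(jn_dist) == 1L) {
        jump_j <- jn_dist
      } else {
        sp <- split_segment_at(net, runoff, Lr / 2, junction_id = "Jjump.LAD")
        net <- sp$net
        jump_j <- sp$junction_id
      }
      cd <- make_conduit("RA", length_cm = 12, origin = "host_artery")
      net <- add_conduit_piece(net, "RAjump", cd, 12, jump_j)
      an <- anastomose_at_marker(net, "RAjump", "PDA")
      register_graft(an$net, "Radial to PDA", "RA", "host_artery",
                     "RAjump", "PDA")
    })

  v <- validate_network(net)
  if (length(v)) stop("configuration ", config_id,
                      " produced an invalid network:\n  ",
                      paste(v, collapse = "\n  "))
  tidy_network(net)
}

#' Number of graft inflow sources of a configuration
#'
#' Counted from the built graph (inflow attachments on graft segments: in
#' situ IMA subclavian origins and aortic conduit origins), not from a
#' lookup table.
#'
#' @param x a configuration letter (`"A"`..`"L"`, built on a reference
#'   target network) or an already grafted `coronary_network`.
#' @return integer inflow count.
#' @export
inflow_count <- function(x) {
  net <- if (inherits(x, "coronary_network")) x
         else apply_configuration(reference_target_network(), x)
  if (nrow(net$grafts) == 0L) stop("network has no grafts")
  graft_segs <- net$segments$id[net$segments$territory == "graft"]
  sum(net$inflows$segment %in% graft_segs)
}

#' Aortic or anaortic category of a configuration
#'
#' Derived from the built conduit origins: `"aortic"` iff any conduit
#' originates from the ascending aorta.
#'
#' @inheritParams inflow_count
#' @return `"aortic"` or `"anaortic"`.
#' @export
graft_category <- function(x) {
  net <- if (inherits(x, "coronary_network")) x
         else apply_configuration(reference_target_network(), x)
  if (nrow(net$grafts) == 0L) stop("network has no grafts")
  if (any(net$grafts$origin == "aorta")) "aortic" else "anaortic"
}

.graftflow_cache <- new.env(parent = emptyenv())

## minimal three-territory network with LAD/OM/PDA markers, used for
## topology-only queries about the twelve configurations
reference_target_network <- function() {
  if (!is.null(.graftflow_cache$ref_net)) return(.graftflow_cache$ref_net)
  segs <- rbind(
    vessel_segment("LM", 1.0, 0.20, 0.19, territory = "LAD"),
    vessel_segment("LAD", 10, 0.16, 0.10, territory = "LAD"),
    vessel_segment("CIRC", 8, 0.15, 0.10, territory = "CIRC"),
    vessel_segment("OM", 6, 0.12, 0.07, territory = "CIRC"),
    vessel_segment("RCA", 11, 0.17, 0.10, territory = "RCA"),
    vessel_segment("PDA", 4, 0.10, 0.06, territory = "RCA"))
  jn <- rbind(
    data.frame(junction = "Jlm", segment = c("LM", "LAD", "CIRC"),
               end = c("distal", "proximal", "proximal")),
    data.frame(junction = "Jom", segment = c("CIRC", "OM"),
               end = c("distal", "proximal")),
    data.frame(junction = "Jpda", segment = c("RCA", "PDA"),
               end = c("distal", "proximal")))
  ter <- rbind(
    windkessel_terminal("tLAD", "LAD", 1, 60, 0.01, "LAD", 0.75),
    windkessel_terminal("tOM", "OM", 1, 80, 0.01, "CIRC", 0.75),
    windkessel_terminal("tPDA", "PDA", 1, 80, 0.01, "RCA", 0.5))
  net <- coronary_network(
    segments = segs, junctions = jn, terminals = ter,
    inflows = data.frame(segment = c("LM", "RCA"),
                         end = c("proximal", "proximal")),
    markers = data.frame(site = c("LAD", "OM", "PDA"),
                         segment = c("LAD", "OM", "PDA"),
                         position_cm = c(6.75, 3.75, 2.25)))
  .graftflow_cache$ref_net <- net
  net
}

#' The twelve standard configurations with derived metadata
#'
#' Category and inflow count per configuration letter, derived by building
#' each topology on a reference target network (cached per session).
#'
#' @return data.frame with columns `config`, `category`, `inflows`.
#' @export
configuration_table <- function() {
  if (!is.null(.graftflow_cache$config_table))
    return(.graftflow_cache$config_table)
  ref <- reference_target_network()
  tab <- do.call(rbind, lapply(GRAFT_CONFIG_IDS, function(id) {
    built <- apply_configuration(ref, id)
    data.frame(config = id, category = graft_category(built),
               inflows = inflow_count(built))
  }))
  .graftflow_cache$config_table <- tab
  tab
}
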
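## Side-branch population. The epicardial vessels segmented from imaging
## omit the many small branches that drain flow along their length; without
## them the 1D model shows no physiological proximal-to-distal pressure
## decline. Branches are inserted deterministically: a short terminal
## segment every `spacing_cm` along each epicardial vessel, with radius a
## fixed ratio of the local parent radius, each carrying its own Windkessel
## outlet (resistances are placeholders until [calibrate_terminals()]).

GAMMA_IM_DEFAULTS <- c(LAD = 0.75, CIRC = 0.75, RCA = 0.5,
                       graft = 0, systemic = 0)

#' Populate side branches along the epicardial vessels
#'
#' @param net a `coronary_network` whose main vessels have no side branches
#'   yet.
#' @param spacing_cm distance between consecutive branch origins along a
#'   parent vessel; branches sit at `k * spacing_cm` strictly inside the
#'   vessel.
#' @param radius_ratio branch radius as a fraction of the local parent
#'   radius (must be < 1).
#' @param branch_length_cm length of each branch segment.
#' @param territories territories whose segments receive branches.
#' @return a new `coronary_network` (the input is not modified).
#' @export
populate_side_branches <- function(net, spacing_cm = 1.5, radius_ratio = 0.4,
                                   branch_length_cm = 1.0,
                                   territories = c("LAD", "CIRC", "RCA")) {
  stopifnot(inherits(net, "coronary_network"))
  if (!(radius_ratio > 0 && radius_ratio < 1))
    stop("radius_ratio must be in (0, 1): branch radius must stay below the parent's")
  if (!(spacing_cm > 0)) stop("spacing_cm must be positive")
  if (!(branch_length_cm > 0)) stop("branch_length_cm must be positive")
  eps <- 1e-9
  parents <- net$segments[net$segments$territory %in% territories, ]
  for (k in seq_len(nrow(parents))) {
    s <- parents[k, ]
    n_br <- floor((s$length_cm - eps) / spacing_cm)
    if (n_br < 1L) next
    positions <- spacing_cm * seq_len(n_br)
    positions <- positions[positions < s$length_cm - eps]
    ## split from the distal end inward so earlier positions stay valid on
    ## the successively renamed proximal piece
    cur <- s$id
    for (j in rev(seq_along(positions))) {
      pos <- positions[j]
      r_here <- s$radius_prox_cm +
        (s$radius_dist_cm - s$radius_prox_cm) * pos / s$length_cm
      br_id <- sprintf("%s.b%d", s$id, j)
      ## pieces end up named <id>.m0 .. <id>.m<n_br> from proximal to distal
      sp <- split_segment_at(net, cur, pos,
                             prox_id = if (j > 1L) sprintf("%s.tmp%d", s$id, j)
                                       else sprintf("%s.m0", s$id),
                             dist_id = sprintf("%s.m%d", s$id, j),
                             junction_id = sprintf("Jb.%s.%d", s$id, j))
      net <- sp$net
      r_br <- radius_ratio * r_here
      net$segments <- rbind(net$segments,
        vessel_segment(br_id, branch_length_cm, r_br, 0.7 * r_br,
                       territory = s$territory,
                       name = sprintf("%s side branch %d", s$name, j)))
      net$junctions <- rbind(net$junctions,
        data.frame(junction = sp$junction_id, segment = br_id,
                   end = "proximal"))
      gim <- GAMMA_IM_DEFAULTS[[s$territory]]
      net$terminals <- rbind(net$terminals,
        windkessel_terminal(paste0("t.", br_id), br_id,
                            R1 = 1, R2 = 100, C = 1e-3,
                            territory = s$territory, gamma_im = gim))
      cur <- sp$prox_id
    }
  }
  v <- validate_network(net)
  if (length(v)) stop("side-branch population produced an invalid network:\n  ",
                      paste(v, collapse = "\n  "))
  tidy_network(net)
}
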
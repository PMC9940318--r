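## Network serialisation: a single versioned JSON document holding segment,
## junction, stenosis, terminal, inflow and marker tables plus the global
## haemodynamic settings (waveforms inlined as sample arrays). CSV import of
## segment/relations tables is supported for spreadsheet-style input. The
## JSON schema is documented in inst/schema/network.schema.json.

NETWORK_FORMAT_VERSION <- "1.0"

wf_to_list <- function(wf)
  list(t_s = wf$samples$t_s, p_mmHg = wf$samples$p_mmHg, period = wf$period)
wf_from_list <- function(x)
  pressure_waveform(x$t_s, x$p_mmHg, x$period)

#' Save a coronary network to JSON
#'
#' Lossless (full double precision); [load_network()] restores a field-wise
#' identical network.
#'
#' @param net a `coronary_network`.
#' @param path output file path (UTF-8 JSON).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "coronary_network"))
  v <- validate_network(net)
  if (length(v)) stop("refusing to save invalid network:\n  ",
                      paste(v, collapse = "\n  "))
  g <- net$globals
  doc <- list(
    format = "graftflow-network",
    version = NETWORK_FORMAT_VERSION,
    segments = net$segments,
    junctions = net$junctions,
    stenoses = net$stenoses,
    terminals = net$terminals,
    inflows = net$inflows,
    markers = net$markers,
    grafts = net$grafts,
    globals = list(
      aortic = wf_to_list(g$aortic),
      lv = wf_to_list(g$lv),
      heart_rate = g$heart_rate,
      period = g$period,
      cardiac_output_l_min = g$cardiac_output_l_min,
      myocardial_fraction = g$myocardial_fraction,
      total_arterial_compliance_ml_mmHg = g$total_arterial_compliance_ml_mmHg,
      territory_split = as.list(g$territory_split),
      reference_pressure_mmHg = g$reference_pressure_mmHg
    )
  )
  json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

df_or_empty <- function(x, empty) {
  if (is.null(x) || length(x) == 0L) return(empty)
  d <- as.data.frame(x)
  if (nrow(d) == 0L) empty else d
}

#' Load a coronary network from JSON
#'
#' @param path path to a network JSON file written by [save_network()] (or
#'   conforming to the documented schema).
#' @return a validated `coronary_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(doc$format, "graftflow-network"))
    stop("not a graftflow network file (missing format tag): ", path)
  for (f in c("segments", "terminals", "inflows", "globals"))
    if (is.null(doc[[f]])) stop("network file missing required field '", f, "'")
  g <- doc$globals
  for (f in c("aortic", "lv", "heart_rate", "period"))
    if (is.null(g[[f]])) stop("network globals missing field '", f, "'")
  globals <- global_hemodynamics(
    aortic = wf_from_list(g$aortic),
    lv = wf_from_list(g$lv),
    heart_rate = g$heart_rate,
    period = g$period,
    cardiac_output_l_min = g$cardiac_output_l_min,
    myocardial_fraction = g$myocardial_fraction,
    total_arterial_compliance_ml_mmHg = g$total_arterial_compliance_ml_mmHg,
    territory_split = unlist(g$territory_split),
    reference_pressure_mmHg = g$reference_pressure_mmHg
  )
  sten <- df_or_empty(doc$stenoses, empty_stenoses())
  if (nrow(sten) && !"K_v" %in% names(sten)) sten$K_v <- NA_real_
  if (nrow(sten)) sten$K_v <- as.numeric(sten$K_v)
  coronary_network(
    segments = as.data.frame(doc$segments),
    junctions = df_or_empty(doc$junctions, empty_junctions()),
    stenoses = sten,
    terminals = as.data.frame(doc$terminals),
    inflows = as.data.frame(doc$inflows),
    markers = df_or_empty(doc$markers, empty_markers()),
    globals = globals,
    grafts = df_or_empty(doc$grafts, empty_grafts())
  )
}

#' Import segment and relation tables from CSV
#'
#' Spreadsheet-style input: a segment table (columns as in
#' [vessel_segment()]) and a relations table (`junction,segment,end`).
#' Terminals, inflows, stenoses and markers may be given as additional CSVs;
#' globals use the package defaults unless supplied programmatically.
#'
#' @param segments_csv path to the segment table.
#' @param relations_csv path to the junction relations table.
#' @param terminals_csv,inflows_csv,stenoses_csv,markers_csv optional paths.
#' @param globals a [global_hemodynamics()].
#' @return a validated `coronary_network`.
#' @export
import_network_csv <- function(segments_csv, relations_csv,
                               terminals_csv = NULL, inflows_csv = NULL,
                               stenoses_csv = NULL, markers_csv = NULL,
                               globals = global_hemodynamics()) {
  read_or <- function(p, empty) if (is.null(p)) empty else read.csv(p)
  segments <- read.csv(segments_csv)
  if (is.null(segments$beta_mmHg_cm))
    segments$beta_mmHg_cm <- beta_from_wave_speed(
      (segments$radius_prox_cm + segments$radius_dist_cm) / 2)
  if (is.null(segments$gamma_ext)) segments$gamma_ext <- 0
  if (is.null(segments$name)) segments$name <- segments$id
  sten <- read_or(stenoses_csv, empty_stenoses())
  if (nrow(sten) && is.null(sten$K_v)) sten$K_v <- NA_real_
  if (nrow(sten) && is.null(sten$K_t)) sten$K_t <- 1.52
  if (nrow(sten) && is.null(sten$K_u)) sten$K_u <- 1.2
  coronary_network(
    segments = segments[SEGMENT_COLS],
    junctions = read_or(relations_csv, empty_junctions()),
    stenoses = sten,
    terminals = read_or(terminals_csv,
                        windkessel_terminal(character(), character(),
                                            numeric(), numeric(), numeric())),
    inflows = read_or(inflows_csv,
                      data.frame(segment = character(), end = character())),
    markers = read_or(markers_csv, empty_markers()),
    globals = globals
  )
}
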
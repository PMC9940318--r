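## Reference cohort: the published per-graft hemodynamic predictions for
## five triple-vessel-disease patients across the twelve grafting
## configurations, shipped as plain-text CSVs. These printed values are
## the desk-scale evaluation surface for the classification and
## statistics layers (the simulation layer reproduces them only
## qualitatively, since the underlying patient geometries are not public).

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "graftflow")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' Reference cohort tables
#'
#' @return `reference_graft_grid()`: per-(patient, configuration, graft)
#'   MGF/PI/regional-perfusion values (180 grafts);
#'   `reference_stenosis_table()`: per-stenosis length, percent diameter,
#'   iFR and printed FFR; `reference_perfusion_table()`: per-territory
#'   diseased and non-diseased perfusion; `reference_selection_counts()`:
#'   configuration-selection counts under standard and computer-informed
#'   decision-making with the published p-values.
#' @export
reference_graft_grid <- function() {
  d <- read.csv(fixture_path("cohort_graft_metrics.csv"))
  d$target_side <- ifelse(d$target_site == "PDA", "right", "left")
  d
}

#' @rdname reference_graft_grid
#' @export
reference_stenosis_table <- function()
  read.csv(fixture_path("cohort_stenoses.csv"))

#' @rdname reference_graft_grid
#' @export
reference_perfusion_table <- function()
  read.csv(fixture_path("cohort_perfusion.csv"))

#' @rdname reference_graft_grid
#' @export
reference_selection_counts <- function()
  read.csv(fixture_path("selection_counts.csv"))

#' Classify every (patient, configuration) cell of a graft-metric grid
#'
#' Applies [classify_configuration()] to each cell of a long-format grid
#' such as [reference_graft_grid()].
#'
#' @param grid data.frame with columns `patient`, `config`, `graft`,
#'   `mgf_ml_min`, `pi`, `target_side`.
#' @return data.frame with one row per (patient, config): `patient`,
#'   `config`, `label`.
#' @export
classify_grid <- function(grid) {
  req <- c("patient", "config", "graft", "mgf_ml_min", "pi", "target_side")
  if (!all(req %in% names(grid)))
    stop("grid needs columns: ", paste(req, collapse = ", "))
  cells <- unique(grid[c("patient", "config")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- grid[grid$patient == cells$patient[i] &
                  grid$config == cells$config[i], ]
    m <- data.frame(graft = sub$graft, MGF_ml_min = sub$mgf_ml_min,
                    PI = sub$pi, target_side = sub$target_side)
    data.frame(patient = cells$patient[i], config = cells$config[i],
               label = classify_configuration(m)$value)
  }))
  rownames(out) <- NULL
  out
}
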
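## End-to-end orchestration: healthy / diseased / grafted runs for a
## patient, paper-style per-patient tables, cohort summaries and run
## manifests.

SITE_REGION <- c(LAD = "LAD", OM = "CIRC", PDA = "RCA")

#' Run the full prediction pipeline for one patient
#'
#' Solves the theoretical non-diseased circulation, the diseased
#' circulation, and each requested grafted circulation; derives stenosis
#' metrics (iFR/FFR), graft metrics (MGF/PI/DF/BF), regional perfusion and
#' the configuration classification.
#'
#' @param patient a patient archetype id (1-5) or a diseased
#'   `coronary_network` carrying target markers.
#' @param configs configuration letters to build (default all twelve).
#' @param config a [solver_config()].
#' @param out_dir optional directory: per-stage CSV/JSON artefacts and a
#'   run manifest are written there.
#' @return list of class `pipeline_result`: `stenoses` (iFR/FFR table),
#'   `perfusion` (per scenario), `grafts` (per-configuration metric rows),
#'   `labels` (classification per configuration), `diagnostics`, and the
#'   `cycle_result`s in `runs`.
#' @export
run_pipeline <- function(patient, configs = GRAFT_CONFIG_IDS,
                         config = solver_config("fast"), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  if (inherits(patient, "coronary_network")) {
    diseased <- patient
    healthy <- patient
    healthy$stenoses <- empty_stenoses()
    patient_id <- NA
  } else {
    patient_id <- as.integer(patient)
    healthy <- patient_archetype(patient_id, diseased = FALSE)
    diseased <- patient_archetype(patient_id, diseased = TRUE)
  }
  stopifnot(all(configs %in% GRAFT_CONFIG_IDS))

  runs <- list()
  tic <- function() proc.time()[["elapsed"]]
  t <- tic(); runs$healthy <- run_to_periodic(healthy, config)
  timings$healthy <- tic() - t
  t <- tic(); runs$diseased <- run_to_periodic(diseased, config)
  timings$diseased <- tic() - t

  perfusion <- list(
    healthy = regional_perfusion(runs$healthy),
    diseased = regional_perfusion(runs$diseased))
  stenoses <- stenosis_metrics_from_result(runs$diseased)

  grafts <- NULL
  labels <- NULL
  for (cf in configs) {
    t <- tic()
    grafted <- apply_configuration(diseased, cf)
    res <- run_to_periodic(grafted, config)
    runs[[cf]] <- res
    gm <- graft_metrics_from_result(res)
    gm$region <- SITE_REGION[gm$target_site]
    perf <- regional_perfusion(res)
    gm$regional_perfusion_ml_min <-
      perf$perfusion_ml_min[match(gm$region, perf$region)]
    gm <- cbind(config = cf, gm)
    grafts <- rbind(grafts, gm)
    cls <- classify_configuration(data.frame(
      graft = gm$graft, MGF_ml_min = gm$MGF_ml_min, PI = gm$PI,
      target_side = gm$target_side))
    labels <- rbind(labels, data.frame(config = cf, label = cls$value))
    perfusion[[cf]] <- perf
    timings[[cf]] <- tic() - t
  }

  diagnostics <- data.frame(
    scenario = names(runs),
    cycles = vapply(runs, function(r) r$cycles, numeric(1)),
    converged = vapply(runs, function(r) r$converged, logical(1)),
    residual = vapply(runs, function(r) tail(r$residuals, 1), numeric(1)))
  pr <- structure(list(
    patient = patient_id, configs = configs, stenoses = stenoses,
    perfusion = perfusion, grafts = grafts, labels = labels,
    diagnostics = diagnostics, runs = runs, solver_config = config,
    elapsed_s = tic() - t0, timings = timings), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(pr, out_dir)
  pr
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: patient %s, %d scenario runs\n",
              ifelse(is.na(x$patient), "<custom>", x$patient),
              length(x$runs)))
  if (!is.null(x$labels)) print(x$labels)
  invisible(x)
}

#' Per-patient results table in the published layout
#'
#' One row per (configuration, graft) with region, MGF, PI and regional
#' perfusion, plus a `total` row per configuration; a stenosis block
#' precedes the graft rows.
#'
#' @param pr a `pipeline_result`.
#' @param path optional CSV path; a full-precision sibling
#'   `<path>.full.csv` is written alongside (main CSV at 2 decimals,
#'   mirroring the published tables).
#' @return invisible list with `stenosis_table` and `graft_table`.
#' @export
emit_patient_table <- function(pr, path = NULL) {
  stopifnot(inherits(pr, "pipeline_result"))
  missing <- setdiff(pr$configs, pr$labels$config)
  if (length(missing))
    stop("incomplete run; missing configurations: ",
         paste(missing, collapse = ", "))
  st <- pr$stenoses
  dis <- pr$perfusion$diseased
  hea <- pr$perfusion$healthy
  stenosis_table <- data.frame(
    stenosis = st$stenosis, vessel = st$vessel,
    pct_diameter = st$percent_diameter,
    lesion_length_cm = st$lesion_length_cm,
    iFR = st$iFR, FFR = st$FFR)
  perfusion_table <- data.frame(
    region = dis$region, diseased_ml_min = dis$perfusion_ml_min,
    no_disease_ml_min = hea$perfusion_ml_min,
    total = dis$total)
  rows <- NULL
  for (cf in pr$configs) {
    g <- pr$grafts[pr$grafts$config == cf, ]
    rows <- rbind(rows, data.frame(
      config = cf, region = g$region, graft = g$graft,
      MGF_ml_min = g$MGF_ml_min, PI = g$PI,
      regional_perfusion_ml_min = g$regional_perfusion_ml_min,
      total = FALSE))
    perf <- pr$perfusion[[cf]]
    rows <- rbind(rows, data.frame(
      config = cf, region = "total", graft = "",
      MGF_ml_min = NA, PI = NA,
      regional_perfusion_ml_min =
        perf$perfusion_ml_min[perf$region == "total"],
      total = TRUE))
  }
  if (!is.null(path)) {
    full <- rows
    num <- vapply(rows, is.numeric, logical(1))
    rows2 <- rows
    rows2[num] <- lapply(rows2[num], function(x) round(x, 2))
    write.csv(rows2, path, row.names = FALSE, na = "")
    write.csv(full, sub("\\.csv$", ".full.csv", path), row.names = FALSE,
              na = "")
  }
  invisible(list(stenosis_table = stenosis_table,
                 perfusion_table = perfusion_table, graft_table = rows))
}

#' Cohort summary with optional selection statistics
#'
#' @param labels a complete (patient, config, label) grid as accepted by
#'   [summarize_cohort()].
#' @param selection optional selection-count table (columns as in
#'   [reference_selection_counts()]): each row is tested with
#'   [compare_proportions()].
#' @param path_prefix optional path prefix: writes `<prefix>.json` and
#'   `<prefix>.csv`.
#' @return list with the [summarize_cohort()] summary and, if requested,
#'   `selection_tests`.
#' @export
emit_summary <- function(labels, selection = NULL, path_prefix = NULL) {
  summary <- summarize_cohort(labels)
  out <- list(summary = summary)
  if (!is.null(selection)) {
    out$selection_tests <- do.call(rbind, lapply(seq_len(nrow(selection)),
      function(i) {
        r <- selection[i, ]
        cp <- compare_proportions(r$standard_x, r$standard_n,
                                  r$computer_x, r$computer_n)
        data.frame(section = r$section, row = r$row, test = cp$test,
                   p = cp$p)
      }))
  }
  if (!is.null(path_prefix)) {
    jsonlite::write_json(
      list(counts = as.list(summary$counts),
           per_config = summary$per_config,
           category_rates = summary$category_rates,
           inflow_cell_rates = summary$inflow_cell_rates,
           selection_tests = out$selection_tests),
      paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write.csv(summary$per_config, paste0(path_prefix, ".csv"),
              row.names = FALSE)
  }
  out
}

write_pipeline_artifacts <- function(pr, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- emit_patient_table(pr, file.path(out_dir, "graft_metrics.csv"))
  write.csv(tabs$stenosis_table, file.path(out_dir, "stenosis_metrics.csv"),
            row.names = FALSE)
  write.csv(tabs$perfusion_table, file.path(out_dir, "perfusion.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(pr$labels)), function(i) list(
      patient = ifelse(is.na(pr$patient), "custom", pr$patient),
      config = pr$labels$config[i], label = pr$labels$label[i])),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE,
    pretty = TRUE)
  manifest <- list(
    package = "graftflow",
    version = as.character(utils::packageVersion("graftflow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    patient = ifelse(is.na(pr$patient), "custom", pr$patient),
    configs = pr$configs,
    solver = unclass(pr$solver_config),
    timings_s = pr$timings,
    convergence = pr$diagnostics,
    elapsed_s = pr$elapsed_s,
    output_md5 = as.list(tools::md5sum(list.files(out_dir,
                                                  full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
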
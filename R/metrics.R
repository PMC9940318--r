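## Functional metrics: iFR over the diastolic wave-free window, the affine
## iFR -> FFR map, transit-time-flowmetry graft indices (MGF, PI, DF, BF),
## regional perfusion, and the unsatisfactory / satisfactory / ideal
## classification of a grafting configuration.

#' Diastolic wave-free window of an aortic waveform
#'
#' Standard resting-window definition: diastole runs from the dicrotic
#' notch to end-diastole (located as the diastolic pressure minimum, i.e.
#' the next systolic onset); the wave-free window starts 25% into diastole
#' and ends 5 ms before end-diastole. The window is phase-equivariant:
#' `t_end` may exceed the period, in which case it wraps into the next
#' cycle.
#'
#' @param wf aortic [pressure_waveform()] (must show a dicrotic notch).
#' @return numeric `c(t_start, t_end)` in seconds from cycle start
#'   (`t_end` possibly `> period`, meaning periodic wrap).
#' @export
wave_free_window <- function(wf) {
  t_notch <- dicrotic_notch(wf)
  T <- wf$period
  t <- wf$samples$t_s
  p <- wf$samples$p_mmHg
  t_end <- t[which.min(p)]
  if (t_end <= t_notch) t_end <- t_end + T
  w <- c(t_notch + 0.25 * (t_end - t_notch), t_end - 0.005)
  if (diff(w) <= 0) stop("degenerate wave-free window")
  w
}

#' Instantaneous wave-free ratio from distal and aortic pressure series
#'
#' `iFR = mean(Pd) / mean(Pa)` over the wave-free window.
#'
#' @param t_s sample times (s), one cycle, same sampling for both series.
#' @param Pd distal pressure series (mmHg).
#' @param Pa aortic pressure series (mmHg).
#' @param window `c(t_start, t_end)` from [wave_free_window()].
#' @return iFR (dimensionless).
#' @export
compute_iFR <- function(t_s, Pd, Pa, window) {
  stopifnot(length(t_s) == length(Pd), length(t_s) == length(Pa))
  period <- max(t_s) - min(t_s) + diff(t_s[1:2])
  in_w <- if (window[2] > max(t_s)) {
    ## wrapped window: [w1, end-of-cycle] plus [0, w2 mod cycle]
    t_s >= window[1] | t_s <= (window[2] - period)
  } else {
    t_s >= window[1] & t_s <= window[2]
  }
  if (!any(in_w)) stop("no samples inside the wave-free window")
  mPa <- mean(Pa[in_w])
  if (abs(mPa) < 1e-12) stop("zero mean aortic pressure in window")
  mean(Pd[in_w]) / mPa
}

#' Map iFR to an equivalent FFR
#'
#' The resting-to-hyperaemic conversion `FFR = 0.68 * iFR + 0.18`.
#'
#' @param iFR iFR value(s).
#' @return FFR value(s).
#' @export
iFR_to_FFR <- function(iFR) {
  stopifnot(all(is.finite(iFR)))
  0.68 * iFR + 0.18
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Transit-time-flowmetry metrics of a graft flow series
#'
#' Computed at the distal end of a graft over one periodic cycle:
#' mean graft flow `MGF = 60 * mean(Q)` (ml/min, sign preserved),
#' pulsatility index `PI = (max Q - min Q) / mean Q`, diastolic filling
#' `DF = 100 * integral of Q over diastole / integral over the cycle` (%),
#' and backward flow `BF = 100 * integral of |min(Q, 0)| / integral of
#' |Q|` (%). Integrals are trapezoidal with periodic closure.
#'
#' @param t_s sample times (s) covering one cycle.
#' @param Q_ml_s flow series (ml/s).
#' @param period cycle length (s).
#' @param diastole `c(t_start, t_end)`: the diastolic interval (from the
#'   dicrotic notch to end-cycle); `NULL` leaves DF as `NA`.
#' @return one-row data.frame with `MGF_ml_min`, `PI`, `DF_pct`, `BF_pct`.
#' @export
graft_metrics <- function(t_s, Q_ml_s, period, diastole = NULL) {
  stopifnot(length(t_s) == length(Q_ml_s), period > 0)
  ## periodic closure
  tt <- c(t_s, t_s[1] + period)
  qq <- c(Q_ml_s, Q_ml_s[1])
  span <- tt[length(tt)] - tt[1]
  qbar <- trapz(tt, qq) / span
  if (abs(qbar) < 1e-12)
    stop("zero mean flow: pulsatility index undefined")
  PI <- (max(Q_ml_s) - min(Q_ml_s)) / qbar
  BF <- 100 * trapz(tt, abs(pmin(qq, 0))) / max(trapz(tt, abs(qq)), 1e-300)
  DF <- NA_real_
  if (!is.null(diastole)) {
    in_d <- tt >= diastole[1] & tt <= diastole[2]
    if (sum(in_d) >= 2)
      DF <- 100 * trapz(tt[in_d], qq[in_d]) / trapz(tt, qq)
  }
  data.frame(MGF_ml_min = 60 * qbar, PI = PI, DF_pct = DF, BF_pct = BF)
}

#' Classify a grafting configuration from its graft metrics
#'
#' Rules: *unsatisfactory* if any graft has `MGF < 15` ml/min or `PI > 5`;
#' otherwise *ideal* if every left-sided graft (LAD/OM targets) has
#' `PI < 3` (right-sided grafts need only `PI < 5`); otherwise
#' *satisfactory*. The side-specific ideal threshold reflects the higher
#' pulsatility tolerated in grafts to the right coronary territory.
#'
#' @param metrics data.frame with one row per graft: columns `graft`
#'   (label), `MGF_ml_min`, `PI`, and `target_side` (`"left"` or
#'   `"right"`).
#' @return list of class `graft_classification`: `value` (one of
#'   `"unsatisfactory"`, `"satisfactory"`, `"ideal"`) and `reasons`
#'   (data.frame `graft`, `rule`; empty for ideal).
#' @export
classify_configuration <- function(metrics) {
  req <- c("graft", "MGF_ml_min", "PI", "target_side")
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("metrics must be a non-empty data.frame (one row per graft)")
  if (!all(req %in% names(metrics)))
    stop("metrics needs columns: ", paste(req, collapse = ", "))
  if (!all(metrics$target_side %in% c("left", "right")))
    stop("target_side must be 'left' or 'right'")
  reasons <- data.frame(graft = character(), rule = character())
  low <- metrics$MGF_ml_min < 15
  high <- metrics$PI > 5
  if (any(low)) reasons <- rbind(reasons, data.frame(
    graft = metrics$graft[low], rule = "MGF < 15 ml/min"))
  if (any(high)) reasons <- rbind(reasons, data.frame(
    graft = metrics$graft[high], rule = "PI > 5"))
  if (nrow(reasons)) {
    value <- "unsatisfactory"
  } else {
    marg <- metrics$target_side == "left" & metrics$PI >= 3
    if (any(marg)) {
      value <- "satisfactory"
      reasons <- data.frame(graft = metrics$graft[marg],
                            rule = "PI in [3, 5] to left-sided target")
    } else {
      value <- "ideal"
    }
  }
  structure(list(value = value, reasons = reasons),
            class = "graft_classification")
}

#' @export
print.graft_classification <- function(x, ...) {
  cat("configuration:", x$value, "\n")
  if (nrow(x$reasons))
    for (i in seq_len(nrow(x$reasons)))
      cat(sprintf("  - %s: %s\n", x$reasons$graft[i], x$reasons$rule[i]))
  invisible(x)
}

#' Summarise a patient-by-configuration label grid
#'
#' @param labels data.frame with columns `patient`, `config`, `label`
#'   (values `unsatisfactory`/`satisfactory`/`ideal`); must form a
#'   complete rectangular grid.
#' @param config_info optional data.frame with columns `config`,
#'   `category` (`aortic`/`anaortic`) and `inflows` (integer); defaults to
#'   the twelve standard configurations via [configuration_table()].
#' @return list with `counts` (named: unsatisfactory, satisfactory,
#'   ideal), `per_config` (config, n_unsatisfactory, flagged),
#'   `category_rates` (flagged-in-at-least-one-patient rates by category)
#'   and `inflow_cell_rates` (unsatisfactory cell rates by inflow count).
#' @export
summarize_cohort <- function(labels, config_info = NULL) {
  req <- c("patient", "config", "label")
  if (!all(req %in% names(labels)))
    stop("labels needs columns: ", paste(req, collapse = ", "))
  pats <- unique(labels$patient)
  cfgs <- unique(labels$config)
  grid <- expand.grid(patient = pats, config = cfgs,
                      stringsAsFactors = FALSE)
  key <- paste(labels$patient, labels$config)
  missing <- setdiff(paste(grid$patient, grid$config), key)
  if (length(missing) || anyDuplicated(key))
    stop("label grid is not a complete rectangle; missing/duplicated cells: ",
         paste(head(c(missing, key[duplicated(key)]), 10), collapse = ", "))
  lv <- c("unsatisfactory", "satisfactory", "ideal")
  if (!all(labels$label %in% lv)) stop("unknown label value")
  counts <- vapply(lv, function(l) sum(labels$label == l), integer(1))

  per_config <- do.call(rbind, lapply(cfgs, function(cf) {
    n_u <- sum(labels$label[labels$config == cf] == "unsatisfactory")
    data.frame(config = cf, n_unsatisfactory = n_u, flagged = n_u > 0)
  }))

  if (is.null(config_info)) config_info <- configuration_table()
  pc <- merge(per_config, config_info, by = "config", all.x = TRUE)
  cat_rates <- do.call(rbind, lapply(unique(pc$category[!is.na(pc$category)]),
    function(cc) {
      sub <- pc[!is.na(pc$category) & pc$category == cc, ]
      data.frame(category = cc, flagged = sum(sub$flagged),
                 n_configs = nrow(sub),
                 rate = sum(sub$flagged) / nrow(sub))
    }))
  n_pat <- length(pats)
  ## inflow-count rates are an anaortic grouping: composite/sequential
  ## anaortic strategies are compared by their number of inflow sources
  an <- pc[!is.na(pc$category) & pc$category == "anaortic" &
             !is.na(pc$inflows), ]
  infl <- do.call(rbind, lapply(sort(unique(an$inflows)), function(k) {
    sub <- an[an$inflows == k, ]
    cells <- nrow(sub) * n_pat
    u <- sum(sub$n_unsatisfactory)
    data.frame(inflows = k, unsatisfactory_cells = u, cells = cells,
               rate = u / cells)
  }))
  list(counts = counts, per_config = per_config,
       category_rates = cat_rates, inflow_cell_rates = infl)
}

## ---- metrics straight from a cycle_result ---------------------------------

#' Regional perfusion report from a converged cycle
#'
#' @param res a `cycle_result`.
#' @param territories territories to report.
#' @return data.frame with one row per territory plus a `total` row whose
#'   flow is the exact sum.
#' @export
regional_perfusion <- function(res, territories = c("LAD", "CIRC", "RCA")) {
  fl <- terminal_mean_flows(res)$territory_ml_min
  missing <- setdiff(territories, names(fl))
  if (length(missing)) stop("no terminals mapped to territory: ",
                            paste(missing, collapse = ", "))
  v <- as.numeric(fl[territories])
  data.frame(region = c(territories, "total"),
             perfusion_ml_min = c(v, sum(v)),
             total = c(rep(FALSE, length(v)), TRUE))
}

#' Graft metrics (TTFM) for every graft in a solved configuration
#'
#' MGF/PI/DF/BF measured at the distal end of each graft conduit (the
#' piece arriving at its coronary touchdown).
#'
#' @param res a `cycle_result` of a grafted network.
#' @return data.frame with one row per graft: `graft`, `target_site`,
#'   `target_side`, and the [graft_metrics()] columns.
#' @export
graft_metrics_from_result <- function(res) {
  gr <- res$net$grafts
  if (nrow(gr) == 0L) stop("network has no grafts")
  g <- res$net$globals
  dia <- c(dicrotic_notch(g$aortic), g$period)
  out <- do.call(rbind, lapply(seq_len(nrow(gr)), function(i) {
    seg <- gr$segment[i]
    L <- res$net$segments$length_cm[match(seg, res$net$segments$id)]
    q <- result_series(res, seg, L, "Q")
    m <- graft_metrics(q$t_s, q$Q_ml_s, g$period, diastole = dia)
    cbind(data.frame(graft = gr$label[i], target_site = gr$target_site[i],
                     target_side = gr$target_side[i]), m)
  }))
  rownames(out) <- NULL
  out
}

#' Stenosis functional metrics (iFR, FFR) from a diseased-network cycle
#'
#' iFR is measured just distal to each lesion (at the distal end of the
#' vessel piece hosting it), with the aortic root waveform as Pa, over the
#' wave-free window; FFR via [iFR_to_FFR()]. With serial lesions this is
#' the per-lesion reading (the proximal lesion is assessed between the
#' lesions), mirroring how serial disease is reported clinically.
#'
#' @param res a `cycle_result` whose input network carried stenoses.
#' @return data.frame: `vessel`, `iFR`, `FFR` (one row per stenosed
#'   vessel).
#' @export
stenosis_metrics_from_result <- function(res) {
  sm <- res$stenosis_sites
  if (is.null(sm) || nrow(sm) == 0L) stop("network has no stenoses")
  g <- res$net$globals
  w <- wave_free_window(g$aortic)
  Pa <- eval_waveform(g$aortic, res$time)
  vessels <- unique(sm$vessel)
  per_vessel <- do.call(rbind, lapply(vessels, function(v) {
    seg <- sm$mesh_segment[match(v, sm$vessel)]
    L <- res$net$segments$length_cm[match(seg, res$net$segments$id)]
    Pd <- result_series(res, seg, L, "p")$p_mmHg
    ifr <- compute_iFR(res$time, Pd, Pa, w)
    data.frame(vessel = v, iFR = ifr, FFR = iFR_to_FFR(ifr))
  }))
  sten <- res$input_net$stenoses
  out <- data.frame(
    stenosis = sm$stenosis, vessel = sm$vessel,
    percent_diameter = sten$percent_diameter[match(sm$stenosis, sten$id)],
    lesion_length_cm = sten$lesion_length_cm[match(sm$stenosis, sten$id)],
    iFR = per_vessel$iFR[match(sm$vessel, per_vessel$vessel)],
    FFR = per_vessel$FFR[match(sm$vessel, per_vessel$vessel)])
  rownames(out) <- NULL
  out
}
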
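## Generic pressure waveform templates and waveform plumbing.
##
## The aortic template is a systolic rise/fall (sinusoidal arc), an explicit
## dicrotic-notch dip at end-ejection, and an exponential diastolic decay that
## returns exactly to the diastolic pressure at end-cycle, so the sampled
## waveform is C0-periodic. The LV template is a smooth systolic bump
## synchronised with aortic ejection over a near-zero diastolic baseline.

#' Construct a periodic pressure waveform
#'
#' @param t_s sample times in seconds, strictly increasing, starting at 0 and
#'   all `< period` (periodic continuation is implied).
#' @param p_mmHg pressures at `t_s`, in mmHg.
#' @param period cardiac period in seconds.
#' @return A `pressure_waveform`: list with `samples` (data.frame `t_s`,
#'   `p_mmHg`) and `period`.
#' @export
pressure_waveform <- function(t_s, p_mmHg, period) {
  stopifnot(is.numeric(t_s), is.numeric(p_mmHg), length(t_s) == length(p_mmHg))
  if (length(t_s) < 8L) stop("waveform needs at least 8 samples")
  if (!isTRUE(period > 0)) stop("period must be positive")
  if (any(diff(t_s) <= 0)) stop("waveform times must be strictly increasing")
  if (t_s[1] < 0 || t_s[length(t_s)] >= period)
    stop("waveform times must lie in [0, period)")
  structure(list(samples = data.frame(t_s = t_s, p_mmHg = p_mmHg),
                 period = period),
            class = "pressure_waveform")
}

#' Evaluate a waveform at arbitrary times (periodic linear interpolation)
#'
#' @param wf a [pressure_waveform()].
#' @param t times in seconds (any real values; reduced modulo the period).
#' @return pressures in mmHg.
#' @export
eval_waveform <- function(wf, t) {
  stopifnot(inherits(wf, "pressure_waveform"))
  tt <- wf$samples$t_s
  pp <- wf$samples$p_mmHg
  T <- wf$period
  ## wrap the first sample to t = T so interpolation covers the whole cycle
  tm <- t %% T
  approx(c(tt, tt[1] + T), c(pp, pp[1]), xout = tm, rule = 2)$y
}

#' @export
print.pressure_waveform <- function(x, ...) {
  p <- x$samples$p_mmHg
  cat(sprintf("pressure_waveform: %d samples, period %.4f s, %.1f/%.1f mmHg (max/min)\n",
              nrow(x$samples), x$period, max(p), min(p)))
  invisible(x)
}

#' Generic aortic root pressure waveform
#'
#' Template waveform scaled so that the maximum equals `systolic` and the
#' minimum equals `diastolic`, with one dicrotic notch at end-ejection.
#' The default period is `60/hr`; pass `period` explicitly to use a rounded
#' value (e.g. 0.917 s at 65 bpm).
#'
#' @param systolic,diastolic systolic/diastolic pressure in mmHg
#'   (`systolic > diastolic > 0`).
#' @param hr heart rate in beats per minute.
#' @param period cardiac period in seconds; default `60/hr`.
#' @param n_samples number of samples over one period.
#' @return A [pressure_waveform()].
#' @export
aortic_waveform <- function(systolic = 120, diastolic = 77, hr = 65,
                            period = 60 / hr, n_samples = 512L) {
  if (!(systolic > diastolic && diastolic > 0))
    stop("need systolic > diastolic > 0")
  if (!(hr > 0)) stop("heart rate must be positive")
  T <- period
  ts <- 0.36 * T          # end of ejection (notch onset)
  tn <- 0.04 * T          # notch dip width
  notch <- 0.40           # notch shoulder level (fraction of pulse)
  dip <- 0.08             # notch dip depth below shoulder
  th_end <- pi - asin(notch)
  t <- seq(0, T, length.out = n_samples + 1L)[seq_len(n_samples)]
  shape <- numeric(n_samples)
  i1 <- t < ts
  shape[i1] <- sin(th_end * t[i1] / ts)
  i2 <- !i1 & t < ts + tn
  shape[i2] <- notch - dip * sin(pi * (t[i2] - ts) / tn)
  i3 <- !i1 & !i2
  tau <- (T - ts - tn) / 2.5
  E <- exp(-(T - ts - tn) / tau)
  shape[i3] <- notch * (exp(-(t[i3] - ts - tn) / tau) - E) / (1 - E)
  p <- diastolic + (systolic - diastolic) * shape / max(shape)
  pressure_waveform(t, p, T)
}

#' Generic left-ventricular pressure waveform
#'
#' A smooth systolic bump (squared half-sine) synchronised with aortic
#' ejection, over a low diastolic baseline.
#'
#' @param peak peak LV pressure in mmHg.
#' @param hr heart rate in beats per minute.
#' @param period cardiac period in seconds; default `60/hr`.
#' @param baseline diastolic LV pressure in mmHg.
#' @param n_samples number of samples over one period.
#' @return A [pressure_waveform()].
#' @export
lv_waveform <- function(peak = 120, hr = 65, period = 60 / hr,
                        baseline = 2, n_samples = 512L) {
  if (!(peak > 0)) stop("peak must be positive")
  T <- period
  ts <- 0.40 * T          # LV systole spans ejection plus the notch interval
  t <- seq(0, T, length.out = n_samples + 1L)[seq_len(n_samples)]
  p <- rep(baseline, n_samples)
  i <- t < ts
  p[i] <- baseline + (peak - baseline) * sin(pi * t[i] / ts)^2
  pressure_waveform(t, p, T)
}

#' Locate the dicrotic notch of an aortic waveform
#'
#' The notch is identified as the first local pressure minimum after the
#' systolic peak (searching up to 60% of a cycle beyond the peak, with
#' periodic wrap), which makes the detection independent of where the
#' cycle nominally starts.
#'
#' @param wf a [pressure_waveform()].
#' @return notch time in seconds from cycle start (in `[0, period)`).
#' @export
dicrotic_notch <- function(wf) {
  stopifnot(inherits(wf, "pressure_waveform"))
  t <- wf$samples$t_s
  p <- wf$samples$p_mmHg
  n <- length(p)
  ipk <- which.max(p)
  ord <- ((ipk - 1L + 0:(n - 1L)) %% n) + 1L   # reorder, peak first
  pp <- p[ord]
  i <- 2:(n - 1L)
  loc <- i[pp[i] < pp[i - 1L] & pp[i] <= pp[i + 1L]]
  loc <- loc[loc <= 0.6 * n]
  if (length(loc) == 0L)
    stop("no dicrotic notch found in waveform")
  t[ord[loc[1L]]]
}

#' Read / write a waveform CSV (`t_s,p_mmHg` header)
#'
#' @param path file path.
#' @param period cardiac period in seconds (the CSV stores one period of
#'   samples).
#' @return `read_waveform_csv` returns a [pressure_waveform()];
#'   `write_waveform_csv` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- read.csv(path)
  if (!all(c("t_s", "p_mmHg") %in% names(d)))
    stop("waveform CSV must have header t_s,p_mmHg")
  if (is.null(period)) {
    dt <- diff(d$t_s)
    period <- d$t_s[nrow(d)] + stats::median(dt)
  }
  pressure_waveform(d$t_s, d$p_mmHg, period)
}

#' @rdname read_waveform_csv
#' @param wf a [pressure_waveform()].
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "pressure_waveform"))
  write.csv(wf$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
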
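test_that("iFR is the ratio of window means and is scale invariant", {
  wf <- aortic_waveform()
  w <- wave_free_window(wf)
  t <- seq(0, wf$period, length.out = 512L)
  Pa <- eval_waveform(wf, t)
  expect_equal(compute_iFR(t, Pa, Pa, w), 1.0)
  expect_equal(compute_iFR(t, 0.5 * Pa, Pa, w), 0.5)
  ## scaling Pd and Pa together changes nothing
  Pd <- 0.83 * Pa
  expect_equal(compute_iFR(t, 3 * Pd, 3 * Pa, w),
               compute_iFR(t, Pd, Pa, w), tolerance = 1e-12)
  expect_error(compute_iFR(t, Pa, 0 * Pa, w), "zero mean")
})

test_that("shifting the waveform phase shifts the wave-free window equally", {
  wf <- aortic_waveform()
  shift <- 0.11
  t2 <- (wf$samples$t_s + shift) %% wf$period
  o <- order(t2)
  wf2 <- pressure_waveform(t2[o], wf$samples$p_mmHg[o], wf$period)
  w1 <- wave_free_window(wf)
  w2 <- wave_free_window(wf2)
  expect_equal((w2[1] - w1[1]) %% wf$period, shift, tolerance = 0.01)
})

test_that("the iFR to FFR map is the exact affine conversion", {
  expect_equal(iFR_to_FFR(0.73), 0.6764)
  expect_equal(iFR_to_FFR(0.50), 0.52)
  expect_equal(iFR_to_FFR(1.00), 0.86)
  x <- runif(20)
  expect_equal(iFR_to_FFR(x), 0.68 * x + 0.18)
})

test_that("the affine map reproduces the published iFR/FFR pairs at 2 dp", {
  st <- reference_stenosis_table()
  ffr <- round(iFR_to_FFR(st$ifr), 2)
  mismatch <- which(abs(ffr - st$ffr) > 0.005)
  ## a single cell differs: its printed FFR was rounded from an unrounded
  ## iFR (0.68 * 0.86 + 0.18 = 0.7648 prints as 0.77 in the source table)
  expect_length(mismatch, 1L)
  expect_equal(st$patient[mismatch], 2)
  expect_equal(st$location[mismatch], "OM1")
})

test_that("graft metrics have their closed-form values on analytic flows", {
  T <- 0.8
  t <- seq(0, T, length.out = 400L)[1:399]
  ## constant flow: PI = 0, BF = 0, MGF = 60 Q
  m <- graft_metrics(t, rep(1.5, 399), T)
  expect_equal(m$MGF_ml_min, 90, tolerance = 1e-9)
  expect_equal(m$PI, 0)
  expect_equal(m$BF_pct, 0)
  ## sinusoidal modulation: PI = (max-min)/mean = 2 * amplitude ratio
  q <- 2 * (1 + 0.5 * sin(2 * pi * t / T))
  m2 <- graft_metrics(t, q, T)
  expect_equal(m2$PI, 1.0, tolerance = 1e-4)
  expect_equal(m2$MGF_ml_min, 120, tolerance = 0.01)
  ## mean-zero flow has no defined pulsatility index
  expect_error(graft_metrics(t, sin(2 * pi * t / T), T), "undefined")
})

test_that("graft metrics agree with an independent trapezoid oracle", {
  set.seed(7)
  t <- sort(runif(60, 0, 0.9))
  q <- 1 + 0.8 * sin(2 * pi * t / 0.9) + 0.2 * cos(4 * pi * t / 0.9)
  m <- graft_metrics(t, q, 0.9, diastole = c(0.4, 0.9))
  tt <- c(t, t[1] + 0.9)
  qq <- c(q, q[1])
  span <- tt[length(tt)] - tt[1]
  mgf <- 60 * trapz_oracle(tt, qq) / span
  bf <- 100 * trapz_oracle(tt, abs(pmin(qq, 0))) / trapz_oracle(tt, abs(qq))
  ind <- tt >= 0.4 & tt <= 0.9
  df <- 100 * trapz_oracle(tt[ind], qq[ind]) / trapz_oracle(tt, qq)
  expect_equal(m$MGF_ml_min, mgf, tolerance = 1e-10)
  expect_equal(m$BF_pct, bf, tolerance = 1e-10)
  expect_equal(m$DF_pct, df, tolerance = 1e-10)
})

test_that("classification reproduces the published example configurations", {
  mk <- function(mgf, pi, side) data.frame(
    graft = as.character(seq_along(mgf)), MGF_ml_min = mgf, PI = pi,
    target_side = side)
  ## reversed jump-graft flow: unsatisfactory
  c1 <- classify_configuration(mk(c(23.83, 42.79, -2.99), c(3.05, 1.68, 9.80),
                                  c("left", "left", "right")))
  expect_equal(c1$value, "unsatisfactory")
  expect_true(any(grepl("MGF", c1$reasons$rule)))
  ## marginal left-sided pulsatility: satisfactory
  c2 <- classify_configuration(mk(c(40.61, 19.57, 51.12), c(1.48, 3.58, 0.85),
                                  c("left", "left", "right")))
  expect_equal(c2$value, "satisfactory")
  expect_equal(c2$reasons$graft, "2")
  ## all quiet: ideal, no reasons
  c3 <- classify_configuration(mk(c(21.47, 44.99, 64.99), c(1.30, 1.52, 1.46),
                                  c("left", "left", "right")))
  expect_equal(c3$value, "ideal")
  expect_equal(nrow(c3$reasons), 0L)
  ## right-sided grafts tolerate PI in (3, 5) and stay ideal
  c4 <- classify_configuration(mk(c(24.47, 54.85, 15.29), c(2.98, 1.16, 3.04),
                                  c("left", "left", "right")))
  expect_equal(c4$value, "ideal")
  expect_error(classify_configuration(mk(numeric(), numeric(), character())),
               "non-empty")
})

test_that("classification is monotone in MGF and PI", {
  set.seed(42)
  rank <- c(unsatisfactory = 1L, satisfactory = 2L, ideal = 3L)
  for (rep in 1:40) {
    n <- sample(2:4, 1)
    m <- data.frame(graft = paste0("g", 1:n),
                    MGF_ml_min = runif(n, 0, 60),
                    PI = runif(n, 0.3, 8),
                    target_side = sample(c("left", "right"), n,
                                         replace = TRUE))
    base <- rank[classify_configuration(m)$value]
    better <- m
    i <- sample(n, 1)
    better$MGF_ml_min[i] <- better$MGF_ml_min[i] + runif(1, 0, 30)
    better$PI[i] <- better$PI[i] * runif(1, 0.3, 1)
    expect_gte(rank[classify_configuration(better)$value], base)
  }
})

test_that("cohort summaries count labels and demand a complete grid", {
  grid <- expand.grid(patient = 1:5, config = LETTERS[1:12],
                      stringsAsFactors = FALSE)
  grid$label <- "ideal"
  s <- summarize_cohort(grid)
  expect_equal(unname(s$counts), c(0L, 0L, 60L))
  expect_false(any(s$per_config$flagged))
  expect_error(summarize_cohort(grid[-1, ]), "complete")
})
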
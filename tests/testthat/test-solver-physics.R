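test_that("steady single-vessel flow matches the series-resistance oracle", {
  net <- single_vessel_net()
  res <- run_to_periodic(net, solver_config("fast"))
  expect_true(res$converged)
  Pa <- mean_aortic_pressure(net)
  Rseg <- graftflow:::segment_poiseuille_R(10, 0.3, 0.3) / 1333.22
  oracle <- Pa / (Rseg + 55)
  q <- mean(rowMeans(res$terminal_Q))
  expect_lt(abs(q / oracle - 1), 0.01)
})

test_that("the low-Reynolds steady limit reproduces Poiseuille's law", {
  ## steady driving pressure, narrow vessel: dP = 8 mu L Q / (pi r^4)
  T <- 0.92
  t <- seq(0, T, length.out = 64L)[1:63]
  wf <- pressure_waveform(t, rep(20, 63), T)
  g <- suppressWarnings(global_hemodynamics(aortic = wf, lv = lv_waveform(peak = 1e-6),
                                            heart_rate = 65, period = T))
  net <- coronary_network(
    segments = vessel_segment("V", 10, 0.1, 0.1, territory = "systemic"),
    terminals = windkessel_terminal("t", "V", 50, 500, 0.001, "systemic", 0),
    inflows = data.frame(segment = "V", end = "proximal"), globals = g)
  res <- run_to_periodic(net, solver_config("fast", zeta = 2, max_cycles = 30))
  q <- mean(rowMeans(res$terminal_Q))
  p_in <- 20
  p_out <- mean(result_series(res, "V", 10, "p")$p_mmHg)
  dp_poiseuille <- 8 * 0.035 * 10 * q / (pi * 0.1^4) / 1333.22
  expect_lt(abs((p_in - p_out) / dp_poiseuille - 1), 0.01)
})

test_that("small pulses travel at the analytic tube-law wave speed", {
  T <- 0.9230769
  t <- seq(0, T, length.out = 2049L)[1:2048]
  wf <- pressure_waveform(t, 80 + 2 * exp(-((t - 0.06) / 0.008)^2), T)
  A0 <- pi * 0.09
  Zc <- 1.06 * 900 / A0 / 1333.22
  g <- global_hemodynamics(aortic = wf, lv = lv_waveform(), heart_rate = 65,
                           period = T)
  net <- coronary_network(
    segments = vessel_segment("W", 40, 0.3, 0.3, territory = "systemic"),
    terminals = windkessel_terminal("t", "W", Zc, 1e9, 0.01, "systemic", 0),
    inflows = data.frame(segment = "W", end = "proximal"), globals = g)
  res <- suppressWarnings(run_to_periodic(
    net, solver_config("fast", mu = 1e-9, max_cycles = 1,
                       dec_samples = 8192L)))
  peak_t <- function(pos) {
    s <- result_series(res, "W", pos, "p")
    keep <- s$t_s < 0.25
    i <- which.max(s$p_mmHg[keep])
    y <- s$p_mmHg[(i - 1):(i + 1)]
    tt <- s$t_s[(i - 1):(i + 1)]
    tt[2] + 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3]) * (tt[2] - tt[1])
  }
  c_meas <- 24 / (peak_t(32) - peak_t(8))
  c_theory <- wave_speed(A0, net$segments$beta_mmHg_cm, A0)
  expect_lt(abs(c_meas / c_theory - 1), 0.02)
})

test_that("a symmetric bifurcation splits flow exactly evenly", {
  res <- run_to_periodic(symmetric_bifurcation_net(), solver_config("fast"))
  tm <- terminal_mean_flows(res)$terminal_ml_min
  expect_lt(abs(diff(tm)) / mean(tm), 1e-10)
})

test_that("junction mass balance is exact at every stored sample", {
  res <- run_to_periodic(trifurcation_net(), solver_config("fast"))
  expect_lt(max(junction_mass_residuals(res)), 1e-10)
})

test_that("cyclic volume is conserved from inflow to terminals", {
  for (net in list(single_vessel_net(), trifurcation_net())) {
    res <- run_to_periodic(net, solver_config("fast"))
    expect_lt(volume_conservation(res)$relative_error, 0.005)
  }
})

test_that("pulsatile flow through a lumped stenosis follows the steady oracle", {
  net <- single_vessel_net(radius = 0.25)
  net$stenoses <- stenosis_element("s1", "V", 5, 75, 1.0)
  ss <- solve_steady(net)
  res <- run_to_periodic(net, solver_config("fast"))
  q <- mean(rowMeans(res$terminal_Q))
  ## nonlinear element rectifies slightly under pulsation; agreement is
  ## looser than the linear case but the operating point must match
  expect_lt(abs(q / ss$terminal_flows - 1), 0.05)
  expect_lt(volume_conservation(res)$relative_error, 0.005)
})

test_that("solver aborts with a CFL diagnostic naming the segment", {
  net <- single_vessel_net()
  expect_error(run_to_periodic(net, solver_config(dx_cm = 0.5, dt_s = 1e-2)),
               "CFL.*'V'")
})

test_that("non-periodic runs are flagged with their residual history", {
  net <- single_vessel_net()
  expect_warning(res <- run_to_periodic(net, solver_config("fast", max_cycles = 1)),
                 "periodicity")
  expect_false(res$converged)
  expect_length(res$residuals, 1L)
})

test_that("solver configuration reads from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("solver:", "  dx_cm: 0.2", "  dt_s: 1.0e-4",
               "  max_cycles: 7"), f)
  cfg <- read_solver_config(f)
  expect_equal(cfg$dx_cm, 0.2)
  expect_equal(cfg$dt_s, 1e-4)
  expect_equal(cfg$max_cycles, 7L)
})
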
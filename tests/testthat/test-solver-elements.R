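test_that("tube law is exact at the reference state and linear in beta", {
  A0 <- pi * 0.15^2
  expect_equal(tube_law(A0, 400, A0, p_ref_mmHg = 91), 91)
  p1 <- tube_law(1.1 * A0, 400, A0)
  p2 <- tube_law(1.1 * A0, 800, A0)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  ## monotone increasing in A
  A <- seq(0.5, 1.5, by = 0.1) * A0
  expect_true(all(diff(tube_law(A, 400, A0)) > 0))
  expect_error(tube_law(-1, 400, A0), "non-positive")
  ## closed form against hand evaluation
  expect_equal(tube_law(0.09, 400, 0.0625),
               400 * (0.3 - 0.25) / 0.0625, tolerance = 1e-12)
})

test_that("wave speed follows the tube-law closed form", {
  A0 <- pi * 0.2^2
  beta <- beta_from_wave_speed(0.2, c0 = 900)
  expect_equal(wave_speed(A0, beta, A0), 900, tolerance = 1e-10)
  ## c scales as A^(1/4)
  expect_equal(wave_speed(2 * A0, beta, A0) / wave_speed(A0, beta, A0),
               2^0.25, tolerance = 1e-12)
})

test_that("stenosis pressure drop matches the hand-evaluated closed form", {
  stn <- stenosis_element("s", "V", 5, 90, 1.5)
  r <- 0.15
  ## independent arithmetic: Kv = 32*(Ls/D0)*(A0/As)^2, viscous + turbulent
  D0 <- 0.3; A0 <- pi * r^2; As <- A0 * 0.1^2
  Kv <- 32 * (1.5 / 0.3) * (A0 / As)^2
  dp_cgs <- Kv * 0.035 * 1 / D0^3 +
    1.52 * 1.06 / (2 * A0^2) * (A0 / As - 1)^2 * 1 * abs(1)
  expect_equal(stenosis_dp(1, 0, stn, r), dp_cgs / 1333.22,
               tolerance = 1e-10)
})

test_that("stenosis drop is zero at rest and odd in flow without inertance", {
  stn <- stenosis_element("s", "V", 5, 75, 1.0, K_u = 0)
  expect_equal(stenosis_dp(0, 0, stn, 0.2), 0)
  for (q in c(0.3, 1, 2.5))
    expect_equal(stenosis_dp(-q, 0, stn, 0.2), -stenosis_dp(q, 0, stn, 0.2))
  ## inertance term adds Ku*rho*Ls/A0 * dQdt
  stn2 <- stenosis_element("s", "V", 5, 75, 1.0)
  extra <- stenosis_dp(1, 10, stn2, 0.2) - stenosis_dp(1, 0, stn2, 0.2)
  expect_equal(extra, 1.2 * 1.06 * 1.0 / (pi * 0.04) * 10 / 1333.22,
               tolerance = 1e-10)
})

test_that("a total occlusion is rejected as a stenosis", {
  stn <- stenosis_element("s", "V", 5, 100, 1.0)
  expect_error(stenosis_dp(1, 0, stn, 0.2), "occlusion")
})

test_that("terminal step has the resistive DC limit and RC relaxation", {
  ter <- windkessel_terminal("t", "V", R1 = 5, R2 = 50, C = 0.01)
  ## steady flow, no back-pressure: p -> Q (R1 + R2)
  Pc <- 0
  for (i in 1:20000) {
    s <- terminal_step(2, ter, 0, 1e-3, Pc)
    Pc <- s$Pc_mmHg
  }
  expect_equal(s$p_mmHg, 2 * 55, tolerance = 1e-6)
  ## C -> 0: instantaneous resistive response
  ter0 <- windkessel_terminal("t", "V", R1 = 5, R2 = 50, C = 1e-12)
  expect_equal(terminal_step(2, ter0, 0, 1e-3, 0)$p_mmHg, 110,
               tolerance = 1e-6)
  ## step response relaxes with time constant R2 C (compare analytic decay)
  dt <- 1e-4
  tau <- ter$R2 * ter$C
  Pc <- 80
  n <- round(tau / dt)          # one time constant
  for (i in seq_len(n)) Pc <- terminal_step(0, ter, 0, dt, Pc)$Pc_mmHg
  expect_equal(Pc, 80 * exp(-1), tolerance = 0.01)
})

test_that("intramyocardial squeezing enters through the dPim/dt term", {
  ter <- windkessel_terminal("t", "V", R1 = 5, R2 = 50, C = 0.01,
                             gamma_im = 1)
  ## a rising back-pressure raises Pc even with zero inflow
  s <- terminal_step(0, ter, P_im_mmHg = 40, dt_s = 1e-3, Pc_mmHg = 80,
                     P_im_prev_mmHg = 20)
  s0 <- terminal_step(0, ter, P_im_mmHg = 40, dt_s = 1e-3, Pc_mmHg = 80)
  expect_gt(s$Pc_mmHg, s0$Pc_mmHg)
  expect_equal(s$Pc_mmHg - s0$Pc_mmHg, 20 / (1 + 1e-3 / 0.5),
               tolerance = 1e-9)
})

test_that("a uniform steady state is an exact fixed point of the interior step", {
  n <- 21
  A0 <- pi * 0.2^2
  A <- rep(1.05 * A0, n)
  Q <- rep(1.3, n)
  out <- lax_wendroff_step(A, Q, 400, A0, dx_cm = 0.1, dt_s = 5e-5, mu = 0)
  expect_equal(out$A, A, tolerance = 1e-14)
  expect_equal(out$Q, Q, tolerance = 1e-12)
})

test_that("the interior scheme is second-order on a smooth pulse", {
  ## Richardson: error ratio between successive grid halvings ~ 4
  run_grid <- function(dx) {
    L <- 20
    n <- round(L / dx) + 1L
    x <- seq(0, L, length.out = n)
    A0 <- pi * 0.2^2
    beta <- beta_from_wave_speed(0.2, c0 = 900)
    A <- A0 * (1 + 0.02 * exp(-((x - 10) / 1)^2))^2
    Q <- rep(0, n)
    dt <- 0.4 * dx / 1000
    nstep <- round(0.002 / dt)
    for (k in seq_len(nstep)) {
      st <- lax_wendroff_step(A, Q, beta, A0, dx, dt, mu = 0)
      A <- st$A; Q <- st$Q
    }
    list(x = x, A = A)
  }
  g1 <- run_grid(0.2); g2 <- run_grid(0.1); g3 <- run_grid(0.05)
  keep <- function(g, dx) {
    i <- seq(1L, length(g$x), by = as.integer(round(0.2 / dx)))
    g$A[i][g$x[i] >= 6 & g$x[i] <= 14]
  }
  e1 <- sqrt(mean((keep(g1, 0.2) - keep(g3, 0.05))^2))
  e2 <- sqrt(mean((keep(g2, 0.1) - keep(g3, 0.05))^2))
  order <- log2(e1 / e2)
  expect_gt(order, 1.6)
})

test_that("the interior step enforces the CFL bound", {
  A0 <- pi * 0.2^2
  expect_error(
    lax_wendroff_step(rep(A0, 11), rep(0, 11), 400, A0, dx_cm = 0.1,
                      dt_s = 1),
    "CFL")
})
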
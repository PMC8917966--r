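test_that("electrolytic gas generation follows the Nernst mole count", {
  op <- operating_conditions(i = 0.5e-3, V0 = 1.58e-9)
  n0 <- op$P0 * op$V0 / (physical_constants$R_gas * op$T)
  expect_equal(moles_of_gas(0, op), n0)
  expect_equal(moles_of_gas(60, op) - n0, 2.332e-7, tolerance = 1e-3)
  # linear in current
  op2 <- operating_conditions(i = 1e-3, V0 = 1.58e-9)
  expect_equal(moles_of_gas(60, op2) - n0, 2 * (moles_of_gas(60, op) - n0))
  expect_error(moles_of_gas(-1, op), "non-negative")
})

test_that("numerical solution starts at rest and delivers monotonically", {
  g <- fig_groups(0.5)
  prof <- solve_governing_ode(g, t2_model, fast_settings)
  expect_identical(prof$t_star[1], 0)
  expect_identical(prof$V_star[1], 0)
  expect_identical(prof$q_star[1], 0)
  expect_true(all(diff(prof$V_star) >= 0))
  expect_true(all(prof$q_star >= 0))
  # single interior maximum: rises then decays
  k <- which.max(prof$q_star)
  expect_gt(k, 1)
  expect_lt(k, nrow(prof))
  expect_true(all(diff(prof$q_star[1:k]) >= -1e-9))
})

test_that("ideal-gas balance holds along every numerical solution", {
  for (Ms in c(2e-4, 1e-3)) {
    g <- groups_with_M(Ms)
    prof <- solve_governing_ode(g, t2_model, fast_settings)
    # P*(V* + V0*) = t* + P0* V0*: the nondimensional gas law with the
    # Nernst mole count substituted
    P <- pressure_profile(prof, g, t2_model)$P_star
    resid <- P * (prof$V_star + g$V0star) - (prof$t_star + g$P0star * g$V0star)
    expect_lt(max(abs(resid)), 10 * fast_settings$rtol)
    expect_equal(P[1], g$P0star)
    # flowrate consistency of the stored derivative against finite
    # differences of the volume on the uniform part of the grid
    mid <- which(prof$t_star > 0.2 * max(prof$t_star) &
                   prof$t_star < 0.8 * max(prof$t_star))
    i <- mid[seq(2, length(mid) - 1, by = 50)]
    fd <- (prof$V_star[i + 1] - prof$V_star[i - 1]) /
      (prof$t_star[i + 1] - prof$t_star[i - 1])
    expect_equal(fd, prof$q_star[i], tolerance = 1e-5)
  }
})

test_that("dimensional and nondimensional routes agree with an SI oracle", {
  op <- operating_conditions(i = 0.5e-3, V0star = 0.9162, t_end = 600)
  prof <- solve_dimensional(t2_dev, op, settings = fast_settings)
  # independent oracle: integrate the balance directly in SI units
  dev <- t2_dev
  Rg <- physical_constants$R_gas; Fd <- physical_constants$F
  cgen <- op$stoich * (op$i / Fd) * Rg * op$T          # d(nRT)/dt, Pa m^3/s
  Rh <- 32 * dev$mu * dev$L / dev$a^4                  # rounded square duct
  V0 <- op$V0star * dev$R0^3
  rhs <- function(t, y, p) {
    V <- y[1]
    list((cgen * t - op$P0 * V - bending_f(V, dev) * (V + V0)) / (Rh * (V + V0)))
  }
  sol <- deSolve::ode(c(V = 0), times = prof$t_s, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-21)
  Vref <- sol[, "V"] / dev$R0^3
  scale <- max(prof$V_star)
  expect_lt(max(abs(prof$V_star - Vref)) / scale, 1e-6)
})

test_that("output grid plumbing and the zero-current case behave", {
  g <- fig_groups(0.5)
  s <- solver_settings(n_intervals = 500, refine_start = FALSE)
  prof <- solve_governing_ode(g, t2_model, s, t_end_star = 5)
  expect_identical(nrow(prof), 501L)
  expect_equal(diff(prof$t_star), rep(5 / 500, 500), tolerance = 1e-12)
  # no current: nothing is delivered
  p0 <- solve_dimensional(t2_dev, operating_conditions(i = 0, V0star = 0.9162, t_end = 10),
                          settings = s)
  expect_true(all(p0$V_star == 0))
  expect_true(all(p0$q_star == 0))
})

test_that("halving the tolerances leaves the peak unchanged to 0.1%", {
  g <- groups_with_M(9.13e-4)
  p1 <- solve_governing_ode(g, t2_model, fast_settings)
  s2 <- solver_settings(rtol = fast_settings$rtol / 2, atol = fast_settings$atol / 2,
                        n_intervals = 2000L, n_layer = 800L)
  p2 <- solve_governing_ode(g, t2_model, s2)
  expect_lt(abs(max_flowrate_numeric(p1)$q_star - max_flowrate_numeric(p2)$q_star) /
              max_flowrate_numeric(p2)$q_star, 0.001)
})

test_that("vanishing resistance recovers the leading-order balance", {
  g <- groups_with_M(1e-6)
  prof <- solve_governing_ode(g, t2_model, fast_settings, t_end_star = 2)
  # at M* = 0 the balance is algebraic: t* = P0* V* + G(V*)(V* + V0*);
  # invert it by root finding as an independent reference
  idx <- seq(101, nrow(prof), by = 200)
  Vref <- vapply(prof$t_star[idx], function(tt) {
    stats::uniroot(function(V) g$P0star * V + t2_model$G(V) * (V + g$V0star) - tt,
                   c(0, 50), tol = 1e-14)$root
  }, numeric(1))
  expect_equal(prof$V_star[idx], Vref, tolerance = 1e-4)
})

test_that("a completely full reservoir (V0* = 0) integrates through the start", {
  g <- nondimensional_groups(P0star = 0.101325, V0star = 0, Mstar = 1e-3,
                             Gprime0 = gprime0(t2_dev))
  prof <- solve_governing_ode(g, t2_model, fast_settings)
  expect_true(all(is.finite(prof$q_star)))
  expect_true(all(diff(prof$V_star) >= 0))
  # flowrate is bounded by the resistance-free limit 1/P0*
  expect_lt(max(prof$q_star), 1 / g$P0star)
})

test_that("the relaxed nonzero initial-flowrate convention is exposed", {
  g <- fig_groups(0.5)
  q0 <- slow_flowrate(0, g, t2_model)
  prof <- solve_governing_ode(g, t2_model, fast_settings, t_end_star = 1, qdot0 = q0)
  expect_equal(prof$q_star[1], q0)
  # no start-up layer: the early flowrate stays near the slow solution
  early <- prof$t_star > 0 & prof$t_star < 0.005
  expect_lt(max(abs(prof$q_star[early] - q0)) / q0, 0.05)
})
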
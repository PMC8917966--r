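test_that("slow time-of-volume starts at zero and reduces to the M* = 0 form", {
  g <- fig_groups(0.5)
  expect_identical(slow_time_of_volume(0, g, t2_model), 0)
  Vs <- seq(0, 3, by = 0.1)
  expect_true(all(diff(slow_time_of_volume(Vs, g, t2_model)) > 0))
  # leading order: t* = P0* V* + G'(0) V* (V* + V0*)
  g0 <- nondimensional_groups(g$P0star, g$V0star, 0, Gprime0 = g$Gprime0)
  k <- gprime0(t2_dev)
  expect_equal(slow_time_of_volume(Vs, g0, t2_model),
               g0$P0star * Vs + k * Vs * (Vs + g0$V0star), tolerance = 1e-14)
})

test_that("slow flowrate matches its closed forms and stays positive at start", {
  g <- fig_groups(0.5)
  k <- gprime0(t2_dev)
  q0 <- slow_flowrate(0, g, t2_model)
  expect_gt(q0, 0)
  # leading-order initial flowrate 1/(P0* + G'(0) V0*), correction O(M*)
  D0 <- g$P0star + k * g$V0star
  expect_equal(q0, 1 / D0, tolerance = 2 * g$Mstar / D0)
  # initial value agrees with the printed closed form (bending: G'' = 0)
  expect_equal(q0, 1 / (D0 + g$Mstar * (g$P0star - k * g$V0star) / D0^2),
               tolerance = 1e-14)
  # M* = 0, bending: dV*/dt* = 1 / (P0* + G'(0) (2 V* + V0*))
  g0 <- nondimensional_groups(g$P0star, g$V0star, 0, Gprime0 = k)
  Vs <- seq(0, 2, by = 0.25)
  expect_equal(slow_flowrate(Vs, g0, t2_model),
               1 / (g0$P0star + k * (2 * Vs + g0$V0star)), tolerance = 1e-14)
})

test_that("implicit differentiation reproduces the printed flowrate expression", {
  # the printed slow-flowrate formula is the exact implicit derivative of
  # the time-of-volume relation; both code paths must agree to rounding,
  # including on a curved (nonzero G'') model
  models <- list(t2_model, synthesize_fea_like_curve(t2_dev, stiffening = 1.2))
  set.seed(7)
  for (m in models) {
    for (rep in 1:20) {
      g <- nondimensional_groups(P0star = runif(1, 0.02, 0.3),
                                 V0star = runif(1, 0.05, 1.3),
                                 Mstar = runif(1, 1e-5, 5e-3),
                                 Gprime0 = m$Gprime(0))
      Vs <- seq(0, 1, by = 0.125)
      expect_equal(slow_flowrate(Vs, g, m, method = "implicit"),
                   slow_flowrate(Vs, g, m, method = "printed"),
                   tolerance = 1e-12)
    }
  }
})

test_that("initial slow curvature agrees with finite differences", {
  for (m in list(t2_model, synthesize_fea_like_curve(t2_dev, stiffening = 0.9))) {
    g <- nondimensional_groups(0.101325, 0.9162, 9.13e-4, Gprime0 = m$Gprime(0))
    d2 <- ecpump:::slow_curvature0(g, m)
    # d2V/dt2 = (dq/dV) q; dq/dV at 0 from a second-order one-sided stencil
    q <- function(V) slow_flowrate(V, g, m)
    h <- 1e-5
    dqdV <- (4 * q(h) - 3 * q(0) - q(2 * h)) / (2 * h)
    expect_equal(d2, dqdV * q(0), tolerance = 1e-6)
    expect_lt(d2, 0)
  }
})

test_that("fast correction cancels the initial flowrate and then decays", {
  g <- fig_groups(0.5)
  slow0 <- slow_flowrate(0, g, t2_model)
  lambda <- fast_decay_rate(g, t2_model)
  expect_identical(fast_volume(0, g, t2_model), 0)
  expect_equal(fast_flowrate(0, g, t2_model), -slow0)
  # algebraic identity V0*/(P0* + G'(0)V0*) = 1/lambda for random groups
  set.seed(11)
  for (rep in 1:25) {
    gr <- nondimensional_groups(runif(1, 0.02, 0.4), runif(1, 0.05, 1.5),
                                runif(1, 1e-5, 3e-3), Gprime0 = runif(1, 0.02, 0.4))
    m <- pv_model(function(V) gr$Gprime0 * V,
                  function(V) rep_len(gr$Gprime0, length(V)),
                  function(V) rep_len(0, length(V)), "bending")
    expect_equal(gr$V0star / (gr$P0star + gr$Gprime0 * gr$V0star),
                 1 / fast_decay_rate(gr, m), tolerance = 1e-13)
  }
  # exponential saturation of the volume deficit at M* slow0 / lambda
  plateau <- fast_volume(50 * g$Mstar / lambda, g, t2_model)
  expect_equal(plateau, -g$Mstar * slow0 / lambda, tolerance = 1e-12)
  # flowrate correction is negligible once lambda t*/M* > 30
  expect_lt(abs(fast_flowrate(31 * g$Mstar / lambda, g, t2_model)), 1e-12 * slow0)
})

test_that("slow-time inversion is exact on round trips and against brute force", {
  g <- fig_groups(0.5)
  expect_identical(invert_slow_time(0, g, t2_model), 0)
  Vs <- c(1e-6, 0.01, 0.3, 1.7, 12)
  ts <- slow_time_of_volume(Vs, g, t2_model)
  expect_equal(invert_slow_time(ts, g, t2_model), Vs, tolerance = 1e-8)
  # brute-force grid search refined by bisection on a tabulated model
  m <- synthesize_fea_like_curve(t2_dev, stiffening = 0.7, Vstar_max = 3, n = 120)
  tt <- 0.15
  grid <- seq(0, 2, length.out = 2001)
  tg <- slow_time_of_volume(grid, g, m)
  k <- max(which(tg <= tt))
  lo <- grid[k]; hi <- grid[k + 1]
  for (j in 1:60) {
    mid <- (lo + hi) / 2
    if (slow_time_of_volume(mid, g, m) < tt) lo <- mid else hi <- mid
  }
  expect_equal(invert_slow_time(tt, g, m), (lo + hi) / 2, tolerance = 1e-9)
})

test_that("combined flowrate is zero at start and rejoins the slow solution", {
  g <- fig_groups(0.5)
  expect_identical(combined_flowrate(0, g, t2_model), 0)
  lambda <- fast_decay_rate(g, t2_model)
  tlate <- 40 * g$Mstar / lambda
  expect_equal(combined_flowrate(tlate, g, t2_model),
               slow_flowrate(invert_slow_time(tlate, g, t2_model), g, t2_model),
               tolerance = 1e-12)
  # at small M* the combined profile tracks the numerical ODE closely up
  # to the peak (the agreement degrades linearly as M* grows)
  gs <- groups_with_M(2e-4)
  prof <- solve_governing_ode(gs, t2_model, fast_settings)
  kpk <- which.max(prof$q_star)
  upto <- prof$t_star[2:kpk]
  qc <- combined_flowrate(upto, gs, t2_model)
  expect_lt(max(abs(qc - prof$q_star[2:kpk])) / max(prof$q_star), 0.01)
})

test_that("explicit peak formula matches its limits and flags strained inputs", {
  g <- fig_groups(0.5)
  D0 <- g$P0star + g$Gprime0 * g$V0star
  pk <- max_flowrate_explicit(g)
  expect_equal(pk$q_star, 4.9202, tolerance = 1e-4)
  expect_false(pk$strained)
  # resistance-free limit
  g0 <- nondimensional_groups(g$P0star, g$V0star, 0, Gprime0 = g$Gprime0)
  expect_equal(max_flowrate_explicit(g0)$q_star, 1 / D0, tolerance = 1e-13)
  gbad <- nondimensional_groups(g$P0star, g$V0star, 0.3 * D0^2, Gprime0 = g$Gprime0)
  expect_warning(pkb <- max_flowrate_explicit(gbad), "strained")
  expect_true(pkb$strained)
})

test_that("the predicted peak time sits at the true combined maximum", {
  g <- fig_groups(0.5)
  em <- eta_at_max(g, t2_model)
  expect_false(em$at_boundary)
  # dense search around the boundary layer
  tt <- seq(1e-6, 20 * em$t_star_max, length.out = 4000)
  qq <- combined_flowrate(tt, g, t2_model)
  expect_lt(abs(combined_flowrate(em$t_star_max, g, t2_model) - max(qq)) / max(qq),
            0.005)
  # derivative changes sign across the peak
  eps <- 0.2 * em$t_star_max
  expect_gt(combined_flowrate(em$t_star_max, g, t2_model),
            combined_flowrate(em$t_star_max - eps, g, t2_model))
  expect_gt(combined_flowrate(em$t_star_max, g, t2_model),
            combined_flowrate(em$t_star_max + 3 * eps, g, t2_model))
  # shrinking M*: the layer-scaled peak time grows, the physical one shrinks
  ems <- lapply(c(9e-4, 3e-4, 1e-4), function(Ms)
    eta_at_max(groups_with_M(Ms), t2_model))
  expect_true(all(diff(vapply(ems, `[[`, 1, "eta_max")) > 0))
  expect_true(all(diff(vapply(ems, `[[`, 1, "t_star_max")) < 0))
})

test_that("numeric peak detection refines the grid maximum and warns at edges", {
  # on an exact parabola the refinement recovers vertex and height
  tt <- seq(0, 1, by = 0.05)
  qq <- 3 - 10 * (tt - 0.5123)^2
  prof <- structure(data.frame(t_star = tt, V_star = cumsum(qq) * 0.05,
                               q_star = qq, P_star = qq),
                    groups = nondimensional_groups(0.1, 0.9, 1e-3),
                    provenance = "numerical",
                    class = c("delivery_profile", "data.frame"))
  pk <- max_flowrate_numeric(prof)
  expect_equal(pk$t_star, 0.5123, tolerance = 1e-10)
  expect_equal(pk$q_star, 3, tolerance = 1e-10)
  # monotone-decreasing profile: boundary warning, no interior peak
  prof2 <- prof; prof2$q_star <- rev(sort(qq))
  expect_warning(max_flowrate_numeric(prof2), "first")
  prof3 <- prof; prof3$q_star <- sort(qq)
  expect_warning(pk3 <- max_flowrate_numeric(prof3), "final")
  expect_true(pk3$at_end)
})

test_that("peaks with a stiffening membrane stay in the bending regime", {
  m <- synthesize_fea_like_curve(t2_dev, stiffening = 2.5, Vstar_max = 3, n = 300)
  g <- fig_groups(0.5)
  prof <- solve_governing_ode(g, m, fast_settings, t_end_star = 5)
  pk <- max_flowrate_numeric(prof)
  Vpk <- prof$V_star[which.max(prof$q_star)]
  regime <- apex_height_from_volume(Vpk * t2_dev$R0^3, t2_dev)
  expect_identical(regime$regime, "bending")
})
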
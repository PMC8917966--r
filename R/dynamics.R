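#' Solver settings for the governing ODE
#'
#' @param rtol,atol Relative/absolute tolerances of the adaptive
#'   integrator (defaults 1e-8 / 1e-12, on the nondimensional scale).
#' @param n_intervals Number of uniform output intervals over the
#'   simulated window (default 10000, i.e. a step of 1/10000th of the
#'   total time).
#' @param refine_start Also resolve the start-up boundary layer with a
#'   dense auxiliary grid (default `TRUE`). The flowrate peak sits inside
#'   a layer of nondimensional width `Mstar / lambda` near `t* = 0`, far
#'   below the uniform output spacing; peak detection needs the extra
#'   points. Set to `FALSE` for a strictly uniform grid.
#' @param n_layer Number of points in the start-up refinement window.
#' @param max_step Maximum internal step (nondimensional), default
#'   unrestricted.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-12, n_intervals = 10000L,
                            refine_start = TRUE, n_layer = 1500L, max_step = Inf) {
  check_positive(rtol, "rtol"); check_positive(atol, "atol")
  check_positive(n_intervals, "n_intervals")
  structure(list(rtol = rtol, atol = atol, n_intervals = as.integer(n_intervals),
                 refine_start = isTRUE(refine_start), n_layer = as.integer(n_layer),
                 max_step = max_step),
            class = "solver_settings")
}

#' Moles of gas generated by electrolysis
#'
#' The Nernst mole-count relation for water electrolysis: the current `i`
#' converts charge to gas at `stoich` (default 3/4) moles of gas per 4
#' faradays, on top of the initial trapped moles
#' `n0 = P0 V0 / (R_gas T)` from the ideal gas law.
#'
#' @param t Time (s), `>= 0`.
#' @param op An [operating_conditions()] object (must carry a dimensional
#'   `V0` unless `n0` is given).
#' @param n0 Initial moles; default derived from `P0 V0 / (R_gas T)`.
#' @return Moles of gas at time `t`.
#' @export
moles_of_gas <- function(t, op, n0 = NULL) {
  stopifnot(inherits(op, "operating_conditions"))
  if (any(t < 0)) stop_invalid("t", "time must be non-negative")
  if (is.null(n0)) {
    if (is.null(op$V0)) stop_invalid("n0", "needs a dimensional V0 or explicit n0")
    n0 <- op$P0 * op$V0 / (physical_constants$R_gas * op$T)
  }
  op$stoich * (op$i / physical_constants$F) * t + n0
}

delivery_profile <- function(t_star, V_star, q_star, P_star, groups,
                             provenance, model_label = NA_character_) {
  df <- data.frame(t_star = t_star, V_star = V_star,
                   q_star = q_star, P_star = P_star)
  if (is.finite(groups$time_scale) && groups$time_scale > 0) {
    df$t_s <- t_star / groups$time_scale
    df$V_m3 <- V_star * groups$volume_scale
    df$Q_m3_s <- q_star * groups$flow_scale
    df$Q_ul_min <- m3s_to_ulmin(df$Q_m3_s)
    df$P_Pa <- P_star * groups$pressure_scale
  }
  structure(df, groups = groups, provenance = provenance,
            model_label = model_label,
            class = c("delivery_profile", "data.frame"))
}

#' @export
print.delivery_profile <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Delivery profile (%s), %d points, t* in [0, %.4g]\n",
              attr(x, "provenance"), nrow(x), max(x$t_star)))
  cat(sprintf("  groups: P0* = %.4g, V0* = %.4g, M* = %.4g\n",
              g$P0star, g$V0star, g$Mstar))
  pk <- max(x$q_star)
  cat(sprintf("  peak flowrate: %.4g (nondimensional)", pk))
  if (!is.null(x$Q_ul_min)) cat(sprintf(" = %.4g ul/min", max(x$Q_ul_min)))
  cat("\n")
  invisible(x)
}

# right-hand side of the nondimensional governing equation,
#   dV*/dt* = (t* + M* qdot0 V0* - P0* V* - G(V*) (V* + V0*)) / (M* (V* + V0*)),
# the ideal-gas balance with linear-in-time gas generation, membrane
# back-pressure G and channel resistance M*. qdot0 is the initial-flowrate
# value entering the balance through the initial chamber pressure; the
# default zero-initial-flowrate convention (qdot0 = 0) removes the term.
governing_rhs <- function(g, model, qdot0 = 0) {
  force(g); force(model); force(qdot0)
  shift <- g$Mstar * qdot0 * g$V0star
  function(t, y, parms) {
    V <- y[1]
    denom <- g$Mstar * (V + g$V0star)
    q <- (t + shift - g$P0star * V - model$G(V) * (V + g$V0star)) / denom
    list(q)
  }
}

#' Default nondimensional end time of a simulation
#'
#' The delivery has no sharp end; by default integration stops when the
#' analytic slow flowrate has decayed to 1% of its initial (maximal)
#' value, or when a target volume `Vstar_target` has been delivered,
#' whichever is earlier.
#'
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @param Vstar_target Optional delivered-volume target.
#' @param frac Decay fraction defining the end (default 0.01).
#' @return Nondimensional end time `t_end*`.
#' @export
default_t_end_star <- function(g, model, Vstar_target = NULL, frac = 0.01) {
  q0 <- slow_flowrate(0, g, model)
  f <- function(V) slow_flowrate(V, g, model) - frac * q0
  Vhi <- max(1, g$V0star)
  while (f(Vhi) > 0 && Vhi < 1e8) Vhi <- Vhi * 2
  Vend <- stats::uniroot(f, c(0, Vhi), tol = 1e-10)$root
  if (!is.null(Vstar_target)) Vend <- min(Vend, Vstar_target)
  slow_time_of_volume(Vend, g, model)
}

#' Integrate the nondimensional governing equation
#'
#' Solves the first-order ODE for the delivered nondimensional volume,
#'
#' `dV*/dt* = (t* - P0* V* - G(V*) (V* + V0*)) / (M* (V* + V0*))`,
#'
#' with `V*(0) = 0`, using an adaptive stiff-capable integrator
#' ([deSolve::ode()], `lsoda`). The small factor `M*` in the denominator
#' makes the start-up layer stiff; the layer is resolved on an auxiliary
#' dense output grid when `settings$refine_start` is `TRUE`.
#'
#' With a completely full electrolyte reservoir (`V0star = 0`) the
#' denominator vanishes at the start; integration then begins from a short
#' asymptotic step `V* = c t*` with `M* c^2 + P0* c - 1 = 0` taken over
#' `1e-6` of the simulated window.
#'
#' @param g Nondimensional groups (`Mstar > 0` required).
#' @param model A [pv_model()].
#' @param settings A [solver_settings()] object.
#' @param t_end_star Nondimensional end time; default
#'   [default_t_end_star()].
#' @param Vstar_target Optional delivered-volume target used by the
#'   default end-time rule.
#' @param qdot0 Initial flowrate entering the governing balance through
#'   the initial chamber pressure. The default 0 reproduces the
#'   zero-initial-flowrate start; a nonzero value (e.g. the initial slow
#'   flowrate) yields the relaxed variant without a start-up layer.
#' @return A `delivery_profile` (data frame of `t_star`, `V_star`,
#'   `q_star`, `P_star` plus dimensional columns when scales are known)
#'   with provenance `"numerical"`.
#' @export
solve_governing_ode <- function(g, model, settings = solver_settings(),
                                t_end_star = NULL, Vstar_target = NULL,
                                qdot0 = 0) {
  stopifnot(inherits(g, "nondimensional_groups"), inherits(model, "pv_model"))
  if (!is.finite(g$Mstar) || g$Mstar <= 0)
    stop_invalid("Mstar", "the governing ODE requires Mstar > 0")
  if (is.null(t_end_star)) t_end_star <- default_t_end_star(g, model, Vstar_target)

  # output grid: uniform 1/n_intervals steps, plus a dense start-up window
  times <- seq(0, t_end_star, length.out = settings$n_intervals + 1L)
  lambda <- if (g$V0star > 0) g$P0star / g$V0star + model$Gprime(0) else NA_real_
  if (settings$refine_start) {
    t_layer <- if (is.finite(lambda)) 60 * g$Mstar / lambda else 60 * g$Mstar
    t_layer <- min(t_layer, t_end_star)
    times <- sort(unique(c(times, seq(0, t_layer, length.out = settings$n_layer))))
  }

  rhs <- governing_rhs(g, model, qdot0)
  if (g$V0star > 0) {
    t0 <- 0; V0 <- 0
  } else {
    # asymptotic start V* = c t* to step over the vanishing denominator
    cc <- (-g$P0star + sqrt(g$P0star^2 + 4 * g$Mstar)) / (2 * g$Mstar)
    t0 <- 1e-6 * t_end_star
    V0 <- cc * t0
    times <- times[times > t0]
  }
  sol <- deSolve::ode(y = c(V = V0), times = c(t0, times[times > t0]),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = settings$rtol, atol = settings$atol,
                      hmax = if (is.finite(settings$max_step)) settings$max_step else NULL)
  if (attr(sol, "istate")[1] < 0 || anyNA(sol[, "V"]))
    stop("governing ODE integration failed (non-finite state); check parameters",
         call. = FALSE)
  tt <- sol[, "time"]; VV <- sol[, "V"]
  if (g$V0star > 0) { # re-attach the exact initial point
    keep <- tt > 0
    tt <- c(0, tt[keep]); VV <- c(0, VV[keep])
  }
  qq <- vapply(seq_along(tt), function(k) {
    if (tt[k] == 0 && g$V0star > 0) return(qdot0)
    rhs(tt[k], VV[k], NULL)[[1]]
  }, numeric(1))
  PP <- model$G(VV) + g$P0star + g$Mstar * qq
  delivery_profile(tt, VV, qq, PP, g, "numerical", model$label)
}

#' Pressure series along a delivery profile
#'
#' Recovers the chamber pressure from mechanical equilibrium: the membrane
#' back-pressure plus the environmental pressure plus the viscous channel
#' drop, `P* = G(V*) + P0* + M* dV*/dt*` (dimensionally
#' `P = f(V) + P0 + R_h V-dot`).
#'
#' @param profile A `delivery_profile`.
#' @param g Nondimensional groups (default: taken from the profile).
#' @param model The [pv_model()] used to produce the profile.
#' @return A data frame with `t_star`, `P_star` and, when scales are
#'   known, `P_Pa`.
#' @export
pressure_profile <- function(profile, g = attr(profile, "groups"), model) {
  P <- model$G(profile$V_star) + g$P0star + g$Mstar * profile$q_star
  out <- data.frame(t_star = profile$t_star, P_star = P)
  if (is.finite(g$pressure_scale)) out$P_Pa <- P * g$pressure_scale
  out
}

#' Solve the governing equation in dimensional form
#'
#' Nondimensionalizes the inputs via [compute_groups()], integrates with
#' [solve_governing_ode()] and converts back to physical units; the
#' returned profile carries both views. For `i = 0` no gas is generated
#' and the profile is identically zero.
#'
#' @param dev A [device_parameters()] object.
#' @param op An [operating_conditions()] object.
#' @param model A [pv_model()]; default the bending-plate model of `dev`.
#' @param settings A [solver_settings()] object.
#' @param resistance Passed to [compute_groups()].
#' @return A `delivery_profile`.
#' @export
solve_dimensional <- function(dev, op, model = bending_plate_model(dev),
                              settings = solver_settings(),
                              resistance = c("rounded", "exact")) {
  g <- compute_groups(dev, op, match.arg(resistance))
  if (op$i == 0) {
    t_end <- if (!is.null(op$t_end)) op$t_end else 1
    tt <- seq(0, t_end, length.out = settings$n_intervals + 1L)
    pr <- delivery_profile(tt * 0, tt * 0, tt * 0, rep(g$P0star, length(tt)),
                           g, "numerical", model$label)
    pr$t_s <- tt
    return(pr)
  }
  t_end_star <- if (!is.null(op$t_end)) op$t_end * g$time_scale else NULL
  solve_governing_ode(g, model, settings, t_end_star = t_end_star)
}
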
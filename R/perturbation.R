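#' Slow-variable delivery time of a volume
#'
#' First-order regular-perturbation solution of the governing equation in
#' the small resistance parameter `M*`, written explicitly as the
#' nondimensional time needed to deliver a nondimensional volume `V*`:
#'
#' `t* = P0* V* + G(V*) (V* + V0*) +
#'   M* ((V* + V0*) / (P0* + G(V*) + G'(V*) (V* + V0*)) -
#'       V0* / (P0* + G'(0) V0*))`
#'
#' The first two terms are the time for the membrane to deform against the
#' environmental pressure; the `M*` term is the viscous delay of the drug
#' travelling through the microchannel (the leading-order flowrate
#' `1/A(V*)`, with `A = P0* + G + G'(V*+V0*)`, times the resistance). The
#' constant makes `t*(0) = 0` exactly and corresponds to the slow
#' solution's nonzero initial flowrate `~1/(P0* + G'(0) V0*)` entering the
#' governing balance.
#'
#' @param Vstar Nondimensional volume(s), `>= 0`.
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @return Nondimensional time(s) `t*`; strictly increasing in `Vstar`,
#'   `t*(0) = 0` exactly.
#' @export
slow_time_of_volume <- function(Vstar, g, model) {
  if (any(Vstar < 0)) stop_invalid("Vstar", "volume must be non-negative")
  G <- model$G(Vstar); Gp <- model$Gprime(Vstar)
  W <- Vstar + g$V0star
  A <- g$P0star + G + Gp * W
  D0 <- g$P0star + model$Gprime(0) * g$V0star
  g$P0star * Vstar + G * W + g$Mstar * (W / A - g$V0star / D0)
}

# dt*/dV* of the slow solution: exact derivative of slow_time_of_volume,
# assembled by the quotient rule d/dV [W/A] = (A - W A') / A^2 with
# A = P0 + G + G' W and A' = 2 G' + G'' W.
slow_dt_dV <- function(Vstar, g, model) {
  G <- model$G(Vstar); Gp <- model$Gprime(Vstar); Gpp <- model$Gdprime(Vstar)
  W <- Vstar + g$V0star
  A <- g$P0star + G + Gp * W
  Aprime <- 2 * Gp + Gpp * W
  dWoA <- (A - W * Aprime) / A^2
  list(A = A, dWoA = dWoA, dtdV = A + g$Mstar * dWoA)
}

#' Slow-variable flowrate
#'
#' Flowrate of the slow solution, `dV*_slow/dt*`. The canonical
#' implementation (`method = "implicit"`) differentiates the explicit
#' time-of-volume relation exactly, `dV*/dt* = 1 / (dt*/dV*)`, assembling
#' the derivative by the quotient rule. The `"printed"` variant evaluates
#' the conventional closed form
#' `[A + M* (P0* + G - G'(V*+V0*) - G''(V*+V0*)^2) / A^2]^(-1)` with
#' `A = P0* + G + G'(V*+V0*)`; the two are algebraically identical and
#' serve as mutual cross-checks.
#'
#' At `V* = 0` the slow flowrate is strictly positive,
#' `[P0* + G'(0)V0* + M*(P0* - G'(0)V0* - G''(0)V0*^2)/(P0* + G'(0)V0*)^2]^(-1)`
#' — the slow solution alone does not satisfy the zero-initial-flowrate
#' condition; that is the role of the fast boundary-layer correction.
#'
#' @param Vstar Nondimensional volume(s), `>= 0`.
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @param method `"implicit"` (default) or `"printed"`.
#' @return Nondimensional flowrate(s).
#' @export
slow_flowrate <- function(Vstar, g, model, method = c("implicit", "printed")) {
  method <- match.arg(method)
  if (any(Vstar < 0)) stop_invalid("Vstar", "volume must be non-negative")
  if (method == "implicit") {
    d <- slow_dt_dV(Vstar, g, model)
    if (any(d$dtdV <= 0))
      stop("dt*/dV* <= 0: volume outside the model's monotone range", call. = FALSE)
    return(1 / d$dtdV)
  }
  G <- model$G(Vstar); Gp <- model$Gprime(Vstar); Gpp <- model$Gdprime(Vstar)
  W <- Vstar + g$V0star
  A <- g$P0star + G + Gp * W
  1 / (A + g$Mstar * (g$P0star + G - Gp * W - Gpp * W^2) / A^2)
}

# second derivative of the slow volume with respect to slow time at t*=0,
# d2V*_slow/dt*^2|0 = -T''(0)/T'(0)^3 where T(V) is the slow time.
# T'' = A' + M* (N' A - 2 N A') / A^3 with N = P0 + G - G' W - G'' W^2,
# N' = -3 G'' W - G''' W^2, A' = 2 G' + G'' W; G''' is obtained by
# one-sided differencing of G'' (exact for the linear bending model).
slow_curvature0 <- function(g, model) {
  V0 <- g$V0star
  Gp <- model$Gprime(0); Gpp <- model$Gdprime(0)
  hstep <- 1e-5 * max(1, V0)
  Gppp <- (model$Gdprime(hstep) - model$Gdprime(0)) / hstep
  A <- g$P0star + Gp * V0
  Aprime <- 2 * Gp + Gpp * V0
  N <- g$P0star - Gp * V0 - Gpp * V0^2
  Nprime <- -3 * Gpp * V0 - Gppp * V0^2
  Tp <- A + g$Mstar * (A - V0 * Aprime) / A^2
  Tpp <- Aprime + g$Mstar * (Nprime * A - 2 * N * Aprime) / A^3
  -Tpp / Tp^3
}

#' Fast boundary-layer decay rate
#'
#' `lambda = P0*/V0* + G'(0)`, the exponential rate (in the fast variable
#' `eta = t*/M*`) at which the start-up correction decays. Equals
#' `(P0* + G'(0) V0*) / V0*`.
#'
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @return Positive decay rate; `Inf` when `V0star = 0` (the layer
#'   collapses).
#' @export
fast_decay_rate <- function(g, model) {
  if (g$V0star == 0) return(Inf)
  g$P0star / g$V0star + model$Gprime(0)
}

#' Fast-variable volume correction
#'
#' The boundary-layer contribution to the delivered volume,
#' `M* V*_fast(eta)` with
#' `V*_fast = -(V0*/(P0* + G'(0) V0*)) (dV*_slow/dt*)|0 (1 - exp(-lambda t*/M*))`.
#' It is bounded by `M* slow0 / lambda` and therefore negligible for the
#' volume profile, but its derivative cancels the slow solution's spurious
#' initial flowrate.
#'
#' @param tstar Nondimensional time(s), `>= 0`.
#' @param g Nondimensional groups (`V0star > 0`).
#' @param model A [pv_model()].
#' @param slow0 Initial slow flowrate; default computed via
#'   [slow_flowrate()] at `V* = 0`.
#' @return The volume contribution `M* V*_fast(t*/M*)` (non-positive).
#' @export
fast_volume <- function(tstar, g, model, slow0 = slow_flowrate(0, g, model)) {
  if (g$V0star == 0) return(rep_len(0, length(tstar)))
  lambda <- fast_decay_rate(g, model)
  g$Mstar * (-(1 / lambda) * slow0 * (1 - exp(-lambda * tstar / g$Mstar)))
}

#' Fast-variable flowrate correction
#'
#' `dV*_fast/deta = -(dV*_slow/dt*)|0 exp(-lambda t*/M*)`: at `t* = 0` it
#' exactly cancels the slow solution's initial flowrate; it decays on the
#' fast scale `M*/lambda`.
#'
#' @inheritParams fast_volume
#' @return Flowrate correction (non-positive).
#' @export
fast_flowrate <- function(tstar, g, model, slow0 = slow_flowrate(0, g, model)) {
  if (g$V0star == 0) return(rep_len(0, length(tstar))) # layer collapsed
  lambda <- fast_decay_rate(g, model)
  -slow0 * exp(-lambda * tstar / g$Mstar)
}

#' Invert the slow time-of-volume relation
#'
#' Finds the unique `V*` with `slow_time_of_volume(V*) = t*` by
#' safeguarded root bracketing on the strictly increasing map.
#'
#' @param tstar Nondimensional time(s), `>= 0`.
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @return `V*_slow(t*)`, with residual below `1e-10` (relative to
#'   `max(1, t*)`).
#' @export
invert_slow_time <- function(tstar, g, model) {
  if (any(tstar < 0)) stop_invalid("tstar", "time must be non-negative")
  one <- function(tt) {
    if (tt == 0) return(0)
    Vhi <- max(1, g$V0star)
    it <- 0L
    while (slow_time_of_volume(Vhi, g, model) < tt) {
      Vhi <- Vhi * 2; it <- it + 1L
      if (it > 200L)
        stop(sprintf("cannot bracket V* for t* = %g (model range exceeded)", tt),
             call. = FALSE)
    }
    r <- stats::uniroot(function(V) slow_time_of_volume(V, g, model) - tt,
                        c(0, Vhi), tol = 1e-13 * max(1, Vhi))
    r$root
  }
  vapply(tstar, one, numeric(1))
}

#' Combined slow + fast flowrate
#'
#' The matched singular-perturbation flowrate
#' `dV*/dt* = dV*_slow/dt*(V*_slow(t*)) + dV*_fast/deta(t*/M*)`. It is
#' exactly zero at `t* = 0` and converges to the slow flowrate once the
#' boundary layer has decayed (`t* >> M*/lambda`). With `V0star = 0` the
#' layer collapses and the combined solution is the slow solution with the
#' flowrate set to 0 at `t* = 0`.
#'
#' @param tstar Nondimensional time(s), `>= 0`.
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @return Nondimensional flowrate(s).
#' @export
combined_flowrate <- function(tstar, g, model) {
  Vslow <- invert_slow_time(tstar, g, model)
  qs <- slow_flowrate(Vslow, g, model)
  if (g$V0star == 0) { qs[tstar == 0] <- 0; return(qs) }
  slow0 <- slow_flowrate(0, g, model)
  qs + fast_flowrate(tstar, g, model, slow0)
}

#' Analytical profiles on a time grid
#'
#' Evaluates the slow or slow+fast analytical solution on a grid,
#' returning the same `delivery_profile` structure as the numerical
#' solver so the solutions can be compared directly.
#'
#' @param g Nondimensional groups.
#' @param model A [pv_model()].
#' @param tstar Time grid (nondimensional, starting at 0).
#' @param kind `"slow+fast"` (default) or `"slow"`.
#' @return A `delivery_profile` with matching provenance.
#' @export
analytic_profile <- function(g, model, tstar, kind = c("slow+fast", "slow")) {
  kind <- match.arg(kind)
  Vslow <- invert_slow_time(tstar, g, model)
  if (kind == "slow") {
    V <- Vslow
    q <- slow_flowrate(Vslow, g, model)
  } else {
    slow0 <- slow_flowrate(0, g, model)
    V <- Vslow + fast_volume(tstar, g, model, slow0)
    q <- slow_flowrate(Vslow, g, model) + fast_flowrate(tstar, g, model, slow0)
    if (g$V0star == 0) q[tstar == 0] <- 0
  }
  P <- model$G(pmax(V, 0)) + g$P0star + g$Mstar * q
  delivery_profile(tstar, V, q, P, g, kind, model$label)
}

#' Explicit maximum-flowrate formula
#'
#' Closed-form peak of the delivery flowrate in the bending-dominated
#' regime:
#'
#' `max dV*/dt* = (1 - M* / (P0* + G'(0) V0*)^2) / (P0* + G'(0) V0*)`
#'
#' with `G'(0) = (64 / 3 pi) (h/R0)^2` for an incompressible membrane.
#' The leading factor is the resistance-free peak set by the environmental
#' pressure and the trapped gas; the `M*` term is the viscous delay of the
#' microchannel. The formula assumes `M*` is a small perturbation; a
#' `strained` flag is raised when `M* / (P0* + G'(0) V0*)^2 > 0.2`.
#'
#' @param g Nondimensional groups (uses the `Gprime0` field).
#' @return A list with `q_star`, and, when the flow scale is known,
#'   `q_m3_s` and `q_ul_min`; plus the logical `strained`.
#' @export
max_flowrate_explicit <- function(g) {
  stopifnot(inherits(g, "nondimensional_groups"))
  D0 <- g$P0star + g$Gprime0 * g$V0star
  ratio <- g$Mstar / D0^2
  strained <- ratio > 0.2
  if (strained)
    warning(sprintf("M*/(P0* + G'(0) V0*)^2 = %.3g > 0.2: perturbation assumption strained",
                    ratio), call. = FALSE)
  q_star <- (1 - ratio) / D0
  out <- list(q_star = q_star, strained = strained)
  if (is.finite(g$flow_scale)) {
    out$q_m3_s <- q_star * g$flow_scale
    out$q_ul_min <- m3s_to_ulmin(out$q_m3_s)
  }
  out
}

#' Boundary-layer time of the flowrate peak
#'
#' The peak of the combined flowrate sits inside the start-up layer, where
#' the decaying fast correction crosses the slowly falling slow flowrate.
#' Setting the second derivative of the combined volume to zero, with the
#' slow curvature frozen at its initial value, gives the closed form
#'
#' `eta_max = (1/lambda) log(lambda slow0 / (M* |d2V*_slow/dt*^2|0|))`,
#'
#' and the peak time `t*_max = M* eta_max`.
#'
#' @param g Nondimensional groups (`V0star > 0`).
#' @param model A [pv_model()].
#' @return A list with `eta_max`, `t_star_max`, the ingredients `lambda`,
#'   `slow0`, `curvature0`, and logical `at_boundary` (`TRUE` when the
#'   logarithm's argument is not positive, i.e. the peak sits at the layer
#'   edge).
#' @export
eta_at_max <- function(g, model) {
  if (g$V0star <= 0) stop_invalid("V0star", "the boundary layer requires V0star > 0")
  lambda <- fast_decay_rate(g, model)
  slow0 <- slow_flowrate(0, g, model)
  d2 <- slow_curvature0(g, model)
  arg <- lambda * slow0 / (g$Mstar * abs(d2))
  if (!is.finite(arg) || arg <= 1) {
    return(list(eta_max = 0, t_star_max = 0, lambda = lambda, slow0 = slow0,
                curvature0 = d2, at_boundary = TRUE))
  }
  eta <- log(arg) / lambda
  list(eta_max = eta, t_star_max = g$Mstar * eta, lambda = lambda,
       slow0 = slow0, curvature0 = d2, at_boundary = FALSE)
}

#' Peak flowrate of a computed profile
#'
#' Locates the discrete argmax of the flowrate series and refines it by a
#' local parabolic fit through the three neighbouring samples. Warns if
#' the maximum sits on the final grid point (simulation too short) and
#' flags a degenerate profile whose maximum is at the first point.
#'
#' @param profile A `delivery_profile`.
#' @return A list with `q_star`, `t_star`, logical `at_end`, and, when
#'   scales are known, `q_ul_min`, `q_m3_s` and `t_s`.
#' @export
max_flowrate_numeric <- function(profile) {
  q <- profile$q_star; tt <- profile$t_star
  k <- which.max(q)
  at_end <- k == length(q)
  if (at_end)
    warning("flowrate maximum at the final grid point; t_end was probably too short",
            call. = FALSE)
  if (k == 1L)
    warning("flowrate maximum at the first grid point; profile has no interior peak",
            call. = FALSE)
  qpk <- q[k]; tpk <- tt[k]
  if (k > 1 && k < length(q)) {
    # parabola through (t_{k-1}, q_{k-1}), (t_k, q_k), (t_{k+1}, q_{k+1})
    t1 <- tt[k - 1] - tt[k]; t2 <- 0; t3 <- tt[k + 1] - tt[k]
    y1 <- q[k - 1]; y2 <- q[k]; y3 <- q[k + 1]
    denom <- (t1 - t2) * (t1 - t3) * (t2 - t3)
    aa <- (t3 * (y2 - y1) + t2 * (y1 - y3) + t1 * (y3 - y2)) / denom
    bb <- (t3^2 * (y1 - y2) + t2^2 * (y3 - y1) + t1^2 * (y2 - y3)) / denom
    if (aa < 0) {
      dt <- -bb / (2 * aa)
      if (dt > t1 && dt < t3) {
        tpk <- tt[k] + dt
        qpk <- y2 + bb * dt + aa * dt^2
      }
    }
  }
  g <- attr(profile, "groups")
  out <- list(q_star = qpk, t_star = tpk, at_end = at_end)
  if (!is.null(g) && is.finite(g$flow_scale)) {
    out$q_m3_s <- qpk * g$flow_scale
    out$q_ul_min <- m3s_to_ulmin(out$q_m3_s)
    out$t_s <- tpk / g$time_scale
  }
  out
}
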
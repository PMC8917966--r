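#' Physical constants used throughout the package
#'
#' Ideal gas constant and Faraday's constant, the two universal constants
#' entering the electrolytic gas-generation model.
#'
#' @format A named list with elements `R_gas` (8.3144 J mol^-1 K^-1) and
#'   `F` (96485 C mol^-1).
#' @export
physical_constants <- list(R_gas = 8.3144, F = 96485)

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, strict = TRUE) {
  if (length(x) != 1L || !is.finite(x)) stop_invalid(field, "must be a finite scalar")
  if (strict && x <= 0) stop_invalid(field, "must be strictly positive")
  if (!strict && x < 0) stop_invalid(field, "must be non-negative")
  invisible(x)
}

#' Device geometry and material parameters
#'
#' Bundles the dimensional parameters of the pump hardware: the flexible
#' membrane that separates the electrolyte chamber from the drug reservoir,
#' and the rectangular microchannel the drug is pushed through. All values
#' are in SI units.
#'
#' @param R0 Membrane radius (m).
#' @param h Membrane thickness (m).
#' @param E Young's modulus of the membrane (Pa).
#' @param v Poisson ratio of the membrane (dimensionless, in \[0, 0.5\]).
#'   Defaults to 0.5 (incompressible elastomer).
#' @param a Microchannel width (m).
#' @param b Microchannel height (m). Defaults to `a` (square cross section).
#'   By the convention of the rectangular-duct resistance formula `b <= a`.
#' @param L Microchannel length (m).
#' @param mu Drug dynamic viscosity (Pa s).
#'
#' @return An object of class `device_parameters`.
#' @seealso [table2_device()] for the representative preset,
#'   [operating_conditions()], [compute_groups()].
#' @export
device_parameters <- function(R0, h, E, v = 0.5, a, b = a, L, mu) {
  check_positive(R0, "R0"); check_positive(h, "h"); check_positive(E, "E")
  check_positive(a, "a"); check_positive(b, "b")
  check_positive(L, "L"); check_positive(mu, "mu")
  if (length(v) != 1L || !is.finite(v) || v < 0 || v > 0.5)
    stop_invalid("v", "Poisson ratio must lie in [0, 0.5]")
  if (b > a) stop_invalid("b", "channel height must not exceed width (b <= a)")
  structure(list(R0 = R0, h = h, E = E, v = v, a = a, b = b, L = L, mu = mu),
            class = "device_parameters")
}

#' Operating conditions of a delivery run
#'
#' @param i Electrical current through the electrolysis electrodes (A).
#' @param T Electrolyte temperature (K). Default 310 K (core body
#'   temperature).
#' @param P0 Initial environmental pressure at the delivery target (Pa).
#'   Default 101325 Pa (atmospheric); about 117 kPa is a representative
#'   alternative when the target-site blood pressure matters.
#' @param V0 Initial gas volume trapped in the electrolyte reservoir (m^3),
#'   or `NULL` if `V0star` is given instead. When both are supplied the
#'   dimensional `V0` wins and `V0star` is derived from it.
#' @param V0star Nondimensional initial gas volume `V0 / R0^3`, the form in
#'   which the quantity is usually reported.
#' @param stoich Moles of gas generated per 4 faradays of charge. The
#'   default 3/4 is the value for water electrolysis (2 H2O -> 2 H2 + O2);
#'   other electrolytes require the ratio of their redox reaction.
#' @param t_end Simulated duration (s), or `NULL` to let the solver pick an
#'   end time from the decay of the flowrate.
#'
#' @return An object of class `operating_conditions`.
#' @export
operating_conditions <- function(i, T = 310, P0 = 101325, V0 = NULL,
                                 V0star = NULL, stoich = 3 / 4, t_end = NULL) {
  check_positive(i, "i", strict = FALSE)
  check_positive(T, "T"); check_positive(P0, "P0"); check_positive(stoich, "stoich")
  if (!is.null(V0)) check_positive(V0, "V0", strict = FALSE)
  if (!is.null(V0star)) check_positive(V0star, "V0star", strict = FALSE)
  if (is.null(V0) && is.null(V0star))
    stop_invalid("V0", "either V0 or V0star must be supplied")
  if (!is.null(t_end)) check_positive(t_end, "t_end")
  structure(list(i = i, T = T, P0 = P0, V0 = V0, V0star = V0star,
                 stoich = stoich, t_end = t_end),
            class = "operating_conditions")
}

#' Representative device preset
#'
#' The membrane and channel parameters of a compact bioelectronic device
#' used for drug delivery in the mouse brain: membrane radius 1.2 mm,
#' thickness 150 um, Young's modulus 8 MPa (SIS block copolymer), square
#' 50 um microchannel of length 20 mm, aqueous drug viscosity 0.89 mPa s.
#'
#' @param a Channel width override (m); default 50 um.
#' @return A [device_parameters()] object.
#' @export
table2_device <- function(a = 50e-6) {
  device_parameters(R0 = 1.2e-3, h = 150e-6, E = 8e6, v = 0.5,
                    a = a, b = a, L = 20e-3, mu = 0.89e-3)
}

#' Nondimensional groups of the governing equation
#'
#' Reduces the dimensional device and operating parameters to the three
#' groups that fully determine the nondimensional delivery dynamics:
#'
#' * `P0star = (R0 / (E h)) P0` — environmental pressure relative to the
#'   membrane bending stiffness;
#' * `V0star = V0 / R0^3` — initial trapped gas volume;
#' * `Mstar` — microfluidic resistance of the channel relative to the
#'   membrane stiffness; proportional to the electrical current.
#'
#' Together with the time scale `t* = t (3/4)(R T / F) i / (E h R0^2)` and
#' the flow scale `flow_scale = 3 R T i R0 / (4 F E h)` (m^3/s per unit of
#' nondimensional flowrate) these map any nondimensional result back to
#' physical units.
#'
#' @param dev A [device_parameters()] object.
#' @param op An [operating_conditions()] object.
#' @param resistance Which hydraulic-resistance coefficient to use for a
#'   square channel: `"rounded"` (default) uses the conventional rounded
#'   form `32 mu L / a^4`, i.e. the factor 24 in `Mstar`; `"exact"` uses
#'   the full rectangular-duct expression
#'   `12 mu L / (a b^3 (1 - 0.63 b/a))`. For `a != b` the exact form is
#'   always used (the rounded one is a square-only simplification). The
#'   two differ by under 2% for a square duct.
#'
#' @return An object of class `nondimensional_groups`: a list with
#'   `P0star`, `V0star`, `Mstar`, `time_scale` (1/s), `flow_scale`
#'   (m^3/s), `pressure_scale` (`E h / R0`, Pa), `volume_scale` (`R0^3`,
#'   m^3), and `Gprime0` (initial nondimensional membrane stiffness
#'   derivative).
#' @export
compute_groups <- function(dev, op, resistance = c("rounded", "exact")) {
  stopifnot(inherits(dev, "device_parameters"), inherits(op, "operating_conditions"))
  resistance <- match.arg(resistance)
  Rg <- physical_constants$R_gas
  Fd <- physical_constants$F

  P0star <- dev$R0 * op$P0 / (dev$E * dev$h)
  V0star <- if (!is.null(op$V0)) op$V0 / dev$R0^3 else op$V0star

  # hydraulic resistance R_h such that dP = R_h * Qdot; exact rectangular
  # duct or the rounded square simplification (32/a^4 vs 12/(a b^3 (1-0.63)))
  R_h <- if (resistance == "rounded" && dev$a == dev$b) {
    32 * dev$mu * dev$L / dev$a^4
  } else {
    12 * dev$mu * dev$L / (dev$a * dev$b^3 * (1 - 0.63 * dev$b / dev$a))
  }
  time_scale <- op$stoich * (Rg * op$T / Fd) * op$i / (dev$E * dev$h * dev$R0^2)
  flow_scale <- time_scale * dev$R0^3
  Mstar <- op$stoich * R_h * (Rg * op$T / Fd) * dev$R0^2 / (dev$E^2 * dev$h^2) * op$i

  structure(list(
    P0star = P0star, V0star = V0star, Mstar = Mstar,
    time_scale = time_scale, flow_scale = flow_scale,
    pressure_scale = dev$E * dev$h / dev$R0, volume_scale = dev$R0^3,
    Gprime0 = gprime0(dev)
  ), class = "nondimensional_groups")
}

#' Construct nondimensional groups directly
#'
#' For parametric studies it is often convenient to prescribe the three
#' groups themselves rather than derive them from hardware parameters.
#' Scales default to `NA`, in which case results stay nondimensional.
#'
#' @param P0star,V0star,Mstar The three nondimensional groups.
#' @param Gprime0 Initial membrane stiffness derivative `G'(0)`; default is
#'   the incompressible bending-plate value for `h/R0 = 0.125`.
#' @param time_scale,flow_scale,pressure_scale,volume_scale Optional
#'   dimensional scales (see [compute_groups()]).
#' @return A `nondimensional_groups` object.
#' @export
nondimensional_groups <- function(P0star, V0star, Mstar,
                                  Gprime0 = 64 / (3 * pi) * 0.125^2,
                                  time_scale = NA_real_, flow_scale = NA_real_,
                                  pressure_scale = NA_real_, volume_scale = NA_real_) {
  check_positive(P0star, "P0star", strict = FALSE)
  check_positive(V0star, "V0star", strict = FALSE)
  check_positive(Mstar, "Mstar", strict = FALSE)
  structure(list(P0star = P0star, V0star = V0star, Mstar = Mstar,
                 time_scale = time_scale, flow_scale = flow_scale,
                 pressure_scale = pressure_scale, volume_scale = volume_scale,
                 Gprime0 = Gprime0),
            class = "nondimensional_groups")
}

#' @export
print.nondimensional_groups <- function(x, ...) {
  cat("Nondimensional groups\n")
  cat(sprintf("  P0star = %.4g  V0star = %.4g  Mstar = %.4g\n",
              x$P0star, x$V0star, x$Mstar))
  cat(sprintf("  G'(0) = %.4g\n", x$Gprime0))
  if (is.finite(x$time_scale))
    cat(sprintf("  time scale = %.4g 1/s, flow scale = %.4g m^3/s (%.4g ul/min)\n",
                x$time_scale, x$flow_scale, m3s_to_ulmin(x$flow_scale)))
  invisible(x)
}

#' Convert a volumetric flowrate from m^3/s to ul/min
#' @param q Flowrate (m^3/s).
#' @return Flowrate in microlitres per minute.
#' @export
m3s_to_ulmin <- function(q) q * 6e10

#' Map a nondimensional flowrate to physical units
#'
#' @param q_star Nondimensional flowrate `dV*/dt*`.
#' @param g A `nondimensional_groups` object with a finite `flow_scale`.
#' @param units `"m3_s"` (default) or `"ul_min"`.
#' @return Numeric flowrate in the requested units. Exactly inverse to
#'   dividing a dimensional flowrate by `flow_scale`.
#' @export
to_dimensional_flowrate <- function(q_star, g, units = c("m3_s", "ul_min")) {
  units <- match.arg(units)
  stopifnot(inherits(g, "nondimensional_groups"))
  q <- q_star * g$flow_scale
  if (units == "ul_min") m3s_to_ulmin(q) else q
}

#' Apex displacement of the inflated membrane
#'
#' The membrane inflates into a spherical cap; the displaced volume and the
#' apex height `H` are related by `V = (pi H / 6) (3 R0^2 + H^2)`. This
#' solves that cubic for its unique positive root and classifies the
#' deformation regime: bending-dominated while `H` is small compared to the
#' membrane thickness `h`, stretching-dominated beyond.
#'
#' @param V Displaced volume (m^3), scalar or vector, `>= 0`.
#' @param dev A [device_parameters()] object.
#' @param threshold Regime boundary as a multiple of `h` (default 1: the
#'   regime flips where `H = h`).
#' @return A data frame with columns `V`, `H` (m), `H_over_h` and `regime`
#'   (`"bending"` or `"stretching"`).
#' @export
apex_height_from_volume <- function(V, dev, threshold = 1) {
  stopifnot(inherits(dev, "device_parameters"))
  if (any(V < 0)) stop_invalid("V", "displaced volume must be non-negative")
  # depressed cubic H^3 + p H + q = 0 with p = 3 R0^2 > 0 (one real root)
  p <- 3 * dev$R0^2
  q <- -6 * V / pi
  s <- sqrt(q^2 / 4 + p^3 / 27)
  cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
  H <- cbrt(-q / 2 + s) + cbrt(-q / 2 - s)
  # one Newton polish against the original relation
  H <- H - (H^3 + p * H + q) / (3 * H^2 + p)
  H[V == 0] <- 0
  data.frame(V = V, H = H, H_over_h = H / dev$h,
             regime = ifelse(H < threshold * dev$h, "bending", "stretching"))
}

#' Published safe-flowrate ranges for targeted drug delivery
#'
#' Loads the packaged table of flowrate ranges reported across targeted
#' drug-delivery applications (intracerebral, inner-ear, convection-
#' enhanced, lymphatic, transdermal, ...), used to screen a predicted
#' maximum flowrate against practice.
#'
#' @return A data frame with columns `application`, `flow_min`, `flow_max`
#'   (ul/min), `units` and `reference`.
#' @export
reference_flowrate_ranges <- function() {
  path <- system.file("extdata", "reference_flowrate_ranges.tsv",
                      package = "ecpump", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Screen a maximum flowrate against published application ranges
#'
#' @param q_max Maximum flowrate in ul/min, `>= 0`.
#' @return The subset of [reference_flowrate_ranges()] whose
#'   `[flow_min, flow_max]` interval contains `q_max` (inclusive).
#' @export
check_against_reference_ranges <- function(q_max) {
  check_positive(q_max, "q_max", strict = FALSE)
  tab <- reference_flowrate_ranges()
  tab[tab$flow_min <= q_max & q_max <= tab$flow_max, , drop = FALSE]
}
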
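#' Pressure-volume constitutive models for the flexible membrane
#'
#' A pressure-volume (PV) model describes the elastic response of the pump
#' membrane: the nondimensional pressure differential `G(V*)` needed to
#' inflate it by a nondimensional volume `V* = V / R0^3`, together with its
#' first two derivatives. The dimensional response is
#' `f(V) = (E h / R0) G(V / R0^3)`.
#'
#' Two implementations are provided: the linear bending-plate closed form
#' ([bending_plate_model()]), valid while the apex displacement is small
#' compared to the membrane thickness, and a monotone-cubic interpolant of
#' tabulated data ([tabulated_curve()]) standing in for a numerically
#' computed (e.g. finite-element) curve that also captures the
#' stretching-dominated stiffening at large inflation.
#'
#' @param G,Gprime,Gdprime Vectorized functions of `V*`.
#' @param label Short description used in printing and provenance.
#' @param Vstar_max Upper end of the validated `V*` range (`Inf` for closed
#'   forms).
#' @return An object of class `pv_model`.
#' @export
pv_model <- function(G, Gprime, Gdprime, label, Vstar_max = Inf) {
  stopifnot(is.function(G), is.function(Gprime), is.function(Gdprime))
  structure(list(G = G, Gprime = Gprime, Gdprime = Gdprime,
                 label = label, Vstar_max = Vstar_max),
            class = "pv_model")
}

#' @export
print.pv_model <- function(x, ...) {
  cat(sprintf("Pressure-volume model: %s  (G'(0) = %.5g, valid V* range [0, %g])\n",
              x$label, x$Gprime(0), x$Vstar_max))
  invisible(x)
}

#' Dimensional membrane pressure differential of a PV model
#'
#' @param model A `pv_model`.
#' @param V Displaced volume (m^3).
#' @param dev A [device_parameters()] object supplying the scales.
#' @return Pressure differential `f(V)` in Pa.
#' @export
dimensional_f <- function(model, V, dev) {
  (dev$E * dev$h / dev$R0) * model$G(V / dev$R0^3)
}

#' Bending-plate pressure-volume relation
#'
#' Small-deflection plate theory gives a linear relation between the
#' pressure differential across a clamped circular membrane and the volume
#' it displaces:
#' `f(V) = 16 E h^3 V / (pi R0^6 (1 - v^2))`.
#'
#' @param V Displaced volume (m^3), `>= 0`.
#' @param dev A [device_parameters()] object.
#' @return Pressure differential in Pa, linear in `V`.
#' @export
bending_f <- function(V, dev) {
  stopifnot(inherits(dev, "device_parameters"))
  if (any(V < 0)) stop_invalid("V", "volume must be non-negative")
  16 * dev$E * dev$h^3 * V / (pi * dev$R0^6 * (1 - dev$v^2))
}

#' Initial nondimensional membrane stiffness derivative
#'
#' `G'(0) = 16 h^2 / (pi R0^2 (1 - v^2))`; for an incompressible membrane
#' (`v = 0.5`) this reduces to `(64 / 3 pi) (h / R0)^2`, the constant slope
#' of the bending-dominated regime.
#'
#' @param dev A [device_parameters()] object.
#' @return Dimensionless `G'(0)`.
#' @export
gprime0 <- function(dev) {
  stopifnot(inherits(dev, "device_parameters"))
  16 * dev$h^2 / (pi * dev$R0^2 * (1 - dev$v^2))
}

#' Bending-plate PV model
#'
#' The linear constitutive model `G(V*) = G'(0) V*` with `G'' = 0`,
#' obtained by nondimensionalizing [bending_f()].
#'
#' @param dev A [device_parameters()] object.
#' @return A [pv_model()].
#' @export
bending_plate_model <- function(dev) {
  k <- gprime0(dev)
  pv_model(G = function(V) k * V,
           Gprime = function(V) rep_len(k, length(V)),
           Gdprime = function(V) rep_len(0, length(V)),
           label = sprintf("bending plate (G'(0) = %.5g)", k))
}

#' Monotone interpolating PV model from tabulated data
#'
#' Builds a shape-preserving (Hyman-filtered) cubic-spline model through
#' tabulated `(V*, G)` pairs, e.g. exported from a finite-element inflation
#' analysis. Monotone interpolation guarantees `G' > 0` between the knots;
#' `G''` is the analytic second derivative of the interpolant (piecewise
#' continuous). Beyond the last knot the curve is continued linearly with
#' the end slope and a warning is raised once per model.
#'
#' @param Vstar Strictly increasing nondimensional volumes. A leading
#'   `(0, 0)` point is inserted if absent.
#' @param G Strictly increasing nondimensional pressures, `G(0) = 0`.
#' @return A [pv_model()] with the tabulated points attached as attribute
#'   `"knots"`.
#' @export
tabulated_curve <- function(Vstar, G) {
  if (length(Vstar) != length(G)) stop_invalid("G", "column lengths differ")
  ord_bad_v <- which(diff(Vstar) <= 0)
  ord_bad_g <- which(diff(G) <= 0)
  if (length(ord_bad_v) || length(ord_bad_g))
    stop(sprintf(
      "tabulated curve must be strictly increasing in both columns; offending rows: %s",
      paste(sort(unique(c(ord_bad_v + 1L, ord_bad_g + 1L))), collapse = ", ")),
      call. = FALSE)
  if (Vstar[1] < 0 || G[1] < 0) stop_invalid("Vstar", "curve must start at or above (0, 0)")
  if (Vstar[1] > 0) { Vstar <- c(0, Vstar); G <- c(0, G) }
  if (G[1] != 0) stop_invalid("G", "G(0) must be 0")
  if (length(Vstar) < 4L) stop_invalid("Vstar", "at least 4 points are required")

  sf <- stats::splinefun(Vstar, G, method = "hyman")
  vmax <- Vstar[length(Vstar)]
  gmax <- G[length(G)]
  slope_end <- sf(vmax, deriv = 1)
  warned <- new.env(parent = emptyenv()); warned$done <- FALSE
  warn_extrap <- function() {
    if (!warned$done) {
      warned$done <- TRUE
      warning(sprintf("evaluating tabulated PV curve beyond V* = %g: linear continuation", vmax),
              call. = FALSE)
    }
  }
  eval_k <- function(V, k) {
    out <- numeric(length(V))
    inside <- V <= vmax
    if (any(inside)) out[inside] <- sf(V[inside], deriv = k)
    if (any(!inside)) {
      warn_extrap()
      out[!inside] <- switch(as.character(k),
        "0" = gmax + slope_end * (V[!inside] - vmax),
        "1" = slope_end,
        "2" = 0)
    }
    out
  }
  m <- pv_model(G = function(V) eval_k(V, 0L),
                Gprime = function(V) eval_k(V, 1L),
                Gdprime = function(V) eval_k(V, 2L),
                label = sprintf("tabulated curve (%d points)", length(Vstar)),
                Vstar_max = vmax)
  attr(m, "knots") <- data.frame(Vstar = Vstar, G = G)
  m
}

#' Read a tabulated pressure-volume curve from delimited text
#'
#' Accepts two-column whitespace-, comma- or tab-delimited text (header
#' optional, `#` comments ignored). Columns may already be nondimensional
#' `(V*, G)` or dimensional, in which case a [device_parameters()] object
#' is required to nondimensionalize them.
#'
#' @param path File path.
#' @param dev Device parameters; required unless `units = "nondim"`.
#' @param units Units of the two columns: `"nondim"` (`V*`, `G`), `"SI"`
#'   (m^3, Pa) or `"ul_kPa"` (microlitre, kPa).
#' @return A [tabulated_curve()] model.
#' @export
load_curve <- function(path, dev = NULL, units = c("nondim", "SI", "ul_kPa")) {
  units <- match.arg(units)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*(#|$)", first)]
  if (!length(first)) stop("empty pressure-volume curve file", call. = FALSE)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first[1]), "[,\t ]+")[[1]][1])))
  tab <- utils::read.table(path, header = has_header, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) == 1L)  # comma-delimited fallback
    tab <- utils::read.table(path, header = has_header, sep = ",",
                             comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("pressure-volume curve needs two columns", call. = FALSE)
  V <- as.numeric(tab[[1]]); P <- as.numeric(tab[[2]])
  if (anyNA(V) || anyNA(P)) stop("non-numeric entries in pressure-volume curve", call. = FALSE)
  if (units != "nondim") {
    if (is.null(dev)) stop_invalid("dev", "device parameters required for dimensional curves")
    if (units == "ul_kPa") { V <- V * 1e-9; P <- P * 1e3 }
    V <- V / dev$R0^3
    P <- P / (dev$E * dev$h / dev$R0)
  }
  tabulated_curve(V, P)
}

#' Write a tabulated curve (or its knots) to delimited text
#'
#' @param model A [tabulated_curve()] model.
#' @param path Output path. Written as nondimensional tab-separated
#'   `Vstar`, `G` with full double precision.
#' @export
write_curve <- function(model, path) {
  kn <- attr(model, "knots")
  if (is.null(kn)) stop("model has no tabulated knots to write", call. = FALSE)
  utils::write.table(format(kn, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Synthesize a stiffening pressure-volume curve
#'
#' Generates a tabulated curve emulating the qualitative shape of a
#' finite-element membrane-inflation analysis: it matches the bending-plate
#' slope at small inflation and stiffens cubically as stretching becomes
#' relevant, `G(V*) = G'(0) V* + stiffening V*^3`. With `stiffening = 0`
#' the samples reduce exactly to the bending-plate line.
#'
#' @param dev A [device_parameters()] object (sets `G'(0)`).
#' @param stiffening Cubic stiffening coefficient, `>= 0`.
#' @param Vstar_max Upper end of the sampled grid (default 1.5).
#' @param n Number of sample points (default 200).
#' @return A [tabulated_curve()] model; the generating closed form is kept
#'   in attribute `"generator"` for verification.
#' @export
synthesize_fea_like_curve <- function(dev, stiffening, Vstar_max = 1.5, n = 200L) {
  check_positive(stiffening, "stiffening", strict = FALSE)
  k <- gprime0(dev)
  grid <- seq(0, Vstar_max, length.out = n)
  m <- tabulated_curve(grid, k * grid + stiffening * grid^3)
  attr(m, "generator") <- list(Gprime0 = k, stiffening = stiffening,
                               G = function(V) k * V + stiffening * V^3,
                               Gprime = function(V) k + 3 * stiffening * V^2,
                               Gdprime = function(V) 6 * stiffening * V)
  m$label <- sprintf("synthetic stiffening curve (G'(0) = %.4g, c3 = %.4g)", k, stiffening)
  m
}
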
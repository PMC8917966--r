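#' Run a single delivery simulation with all three solution routes
#'
#' Computes the numerical solution of the governing ODE together with the
#' analytical slow and slow+fast solutions on the numerical grid, the
#' explicit maximum-flowrate formula and the refined numerical peak, and a
#' run manifest recording all resolved parameters.
#'
#' @param dev A [device_parameters()] object (or `NULL` when `groups` is
#'   given directly).
#' @param op An [operating_conditions()] object (ignored when `groups`
#'   is given).
#' @param model A [pv_model()]; default the bending-plate model of `dev`.
#' @param settings A [solver_settings()] object.
#' @param groups Optional precomputed [nondimensional_groups()]; when
#'   supplied, `dev`/`op` are only used for the membrane model default.
#' @param t_end_star Optional nondimensional end time.
#' @param out_dir Optional directory: profiles are written as delimited
#'   text and the manifest as JSON.
#' @return A list of class `delivery_run` with elements `numerical`,
#'   `slow`, `slow_fast` (profiles), `peak_explicit`, `peak_numeric`,
#'   `groups` and `manifest`.
#' @export
run_single <- function(dev = NULL, op = NULL, model = NULL,
                       settings = solver_settings(), groups = NULL,
                       t_end_star = NULL, out_dir = NULL) {
  if (is.null(groups)) {
    stopifnot(!is.null(dev), !is.null(op))
    groups <- compute_groups(dev, op)
  }
  if (is.null(model)) {
    if (is.null(dev)) stop_invalid("model", "a pv_model is required when dev is absent")
    model <- bending_plate_model(dev)
  }
  num <- solve_governing_ode(groups, model, settings, t_end_star = t_end_star)
  slow <- analytic_profile(groups, model, num$t_star, kind = "slow")
  sf <- analytic_profile(groups, model, num$t_star, kind = "slow+fast")
  pk_exp <- max_flowrate_explicit(groups)
  pk_num <- max_flowrate_numeric(num)

  manifest <- list(
    package = "ecpump",
    version = as.character(utils::packageVersion("ecpump")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    groups = groups[c("P0star", "V0star", "Mstar", "time_scale",
                      "flow_scale", "Gprime0")],
    model = model$label,
    solver = unclass(settings),
    t_end_star = max(num$t_star),
    peak_explicit = pk_exp,
    peak_numeric = pk_num[c("q_star", "t_star", "at_end")]
  )
  run <- structure(list(numerical = num, slow = slow, slow_fast = sf,
                        peak_explicit = pk_exp, peak_numeric = pk_num,
                        groups = groups, manifest = manifest),
                   class = "delivery_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile(num, file.path(out_dir, "profile_numerical.tsv"))
    write_profile(slow, file.path(out_dir, "profile_slow.tsv"))
    write_profile(sf, file.path(out_dir, "profile_slow_fast.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.delivery_run <- function(x, ...) {
  g <- x$groups
  cat("Electrochemical pump delivery run\n")
  cat(sprintf("  P0* = %.4f, V0* = %.4f, M* = %.4f\n",
              g$P0star, g$V0star, g$Mstar))
  cat(sprintf("  peak flowrate  explicit formula: %.4g", x$peak_explicit$q_star))
  if (!is.null(x$peak_explicit$q_ul_min))
    cat(sprintf(" (%.2f ul/min)", x$peak_explicit$q_ul_min))
  cat(sprintf("\n                 numerical ODE:    %.4g", x$peak_numeric$q_star))
  if (!is.null(x$peak_numeric$q_ul_min))
    cat(sprintf(" (%.2f ul/min)", x$peak_numeric$q_ul_min))
  cat("\n")
  invisible(x)
}

#' Parametric sweep of the maximum flowrate
#'
#' Sweeps one quantity — the electrical current, the channel width, or one
#' of the three nondimensional groups directly — and records the explicit-
#' formula and numerical-ODE peak flowrates at each grid value. Failures
#' at individual grid points are caught and reported per row.
#'
#' @param quantity One of `"current"`, `"channel_width"`, `"Mstar"`,
#'   `"V0star"`, `"P0star"`.
#' @param values Strictly increasing, nonempty grid of swept values
#'   (SI units for current/width).
#' @param dev,op Base device and operating conditions (required for the
#'   dimensional sweeps; for group sweeps they seed the fixed groups).
#' @param groups Base groups for the nondimensional sweeps; default
#'   derived from `dev`/`op`.
#' @param model A [pv_model()] or `NULL` for bending-plate.
#' @param settings A [solver_settings()] object.
#' @return A data frame with one row per grid value: the swept value, the
#'   three groups, `q_star_explicit`, `q_star_numeric`,
#'   `q_ul_min_explicit`, `q_ul_min_numeric` (NA when no flow scale),
#'   `t_star_max` and `error` (NA or the failure message).
#' @export
sweep_max_flowrate <- function(quantity = c("current", "channel_width",
                                            "Mstar", "V0star", "P0star"),
                               values, dev = NULL, op = NULL, groups = NULL,
                               model = NULL, settings = solver_settings()) {
  quantity <- match.arg(quantity)
  if (!length(values) || is.unsorted(values, strictly = TRUE))
    stop_invalid("values", "sweep grid must be nonempty and strictly increasing")
  if (quantity %in% c("current", "channel_width") && (is.null(dev) || is.null(op)))
    stop_invalid("dev", "dimensional sweeps need device and operating parameters")
  if (is.null(groups) && !is.null(dev) && !is.null(op))
    groups <- compute_groups(dev, op)

  one <- function(val) {
    g <- groups
    dv <- dev
    if (quantity == "current") {
      opx <- op; opx$i <- val
      g <- compute_groups(dev, opx)
    } else if (quantity == "channel_width") {
      dv <- device_parameters(R0 = dev$R0, h = dev$h, E = dev$E, v = dev$v,
                              a = val, b = val, L = dev$L, mu = dev$mu)
      g <- compute_groups(dv, op)
    } else {
      g[[quantity]] <- val
    }
    mdl <- model
    if (is.null(mdl)) {
      mdl <- if (!is.null(dv)) bending_plate_model(dv) else
        pv_model(G = function(V) g$Gprime0 * V,
                 Gprime = function(V) rep_len(g$Gprime0, length(V)),
                 Gdprime = function(V) rep_len(0, length(V)),
                 label = "bending plate")
    }
    pk_exp <- suppressWarnings(max_flowrate_explicit(g))
    prof <- solve_governing_ode(g, mdl, settings)
    pk_num <- max_flowrate_numeric(prof)
    data.frame(value = val, P0star = g$P0star, V0star = g$V0star, Mstar = g$Mstar,
               q_star_explicit = pk_exp$q_star, q_star_numeric = pk_num$q_star,
               q_ul_min_explicit = if (is.finite(g$flow_scale))
                 m3s_to_ulmin(pk_exp$q_star * g$flow_scale) else NA_real_,
               q_ul_min_numeric = if (is.finite(g$flow_scale))
                 m3s_to_ulmin(pk_num$q_star * g$flow_scale) else NA_real_,
               t_star_max = pk_num$t_star, error = NA_character_)
  }
  rows <- lapply(values, function(v) {
    tryCatch(one(v), error = function(e)
      data.frame(value = v, P0star = NA_real_, V0star = NA_real_, Mstar = NA_real_,
                 q_star_explicit = NA_real_, q_star_numeric = NA_real_,
                 q_ul_min_explicit = NA_real_, q_ul_min_numeric = NA_real_,
                 t_star_max = NA_real_, error = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  attr(out, "quantity") <- quantity
  out
}

#' Compare two delivery profiles
#'
#' Deviation metrics between two profiles of the same run: sup-norm
#' absolute and relative flowrate deviation, relative peak difference,
#' and the same statistics restricted to the start-up boundary-layer
#' window `t* < 10 M*/lambda` and to its complement.
#'
#' @param pA,pB `delivery_profile` objects; `pB` is interpolated onto
#'   `pA`'s grid where the grids differ. Their time ranges must overlap.
#' @param lambda Boundary-layer decay rate; default from `pA`'s groups
#'   with the bending slope `Gprime0`.
#' @return A list of metrics (`sup_abs`, `sup_rel`, `peak_rel`,
#'   `layer_sup_abs`, `post_layer_sup_rel`, `t_split`).
#' @export
compare_profiles <- function(pA, pB, lambda = NULL) {
  g <- attr(pA, "groups")
  lo <- max(min(pA$t_star), min(pB$t_star))
  hi <- min(max(pA$t_star), max(pB$t_star))
  if (lo >= hi) stop("profiles cover disjoint time ranges", call. = FALSE)
  keep <- pA$t_star >= lo & pA$t_star <= hi
  tt <- pA$t_star[keep]
  qa <- pA$q_star[keep]
  qb <- if (identical(pB$t_star, pA$t_star)) pB$q_star[keep] else
    stats::approx(pB$t_star, pB$q_star, xout = tt, rule = 2)$y
  scale <- max(abs(qa))
  if (is.null(lambda)) {
    lambda <- if (!is.null(g) && g$V0star > 0) g$P0star / g$V0star + g$Gprime0 else Inf
  }
  t_split <- if (is.finite(lambda)) 10 * g$Mstar / lambda else 0
  dv <- abs(qa - qb)
  inlayer <- tt < t_split
  list(
    sup_abs = max(dv),
    sup_rel = max(dv) / scale,
    peak_rel = abs(max(qa) - max(qb)) / max(qa),
    layer_sup_abs = if (any(inlayer)) max(dv[inlayer]) else 0,
    post_layer_sup_rel = if (any(!inlayer)) max(dv[!inlayer]) / scale else 0,
    t_split = t_split
  )
}

#' Write a delivery profile to delimited text
#'
#' Tab-separated values at 17 significant digits, preceded by `#`-comment
#' header lines carrying the provenance, membrane model and the three
#' nondimensional groups, so a profile file is self-describing and
#' round-trips through [read_profile()].
#'
#' @param profile A `delivery_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  g <- attr(profile, "groups")
  hdr <- c(
    sprintf("# provenance: %s", attr(profile, "provenance")),
    sprintf("# model: %s", attr(profile, "model_label")),
    sprintf("# P0star: %.17g", g$P0star),
    sprintf("# V0star: %.17g", g$V0star),
    sprintf("# Mstar: %.17g", g$Mstar),
    sprintf("# Gprime0: %.17g", g$Gprime0),
    sprintf("# time_scale: %.17g", g$time_scale),
    sprintf("# flow_scale: %.17g", g$flow_scale),
    sprintf("# pressure_scale: %.17g", g$pressure_scale),
    sprintf("# volume_scale: %.17g", g$volume_scale)
  )
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(lapply(profile, function(col) sprintf("%.17g", col)),
                      stringsAsFactors = FALSE)
  names(df) <- names(profile)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a delivery profile written by [write_profile()]
#'
#' @param path File path.
#' @return A `delivery_profile` with groups and provenance restored.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", hdr)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  named <- stats::setNames(as.list(vals), keys)
  num <- function(k) as.numeric(named[[k]])
  g <- nondimensional_groups(
    P0star = num("P0star"), V0star = num("V0star"), Mstar = num("Mstar"),
    Gprime0 = num("Gprime0"), time_scale = num("time_scale"),
    flow_scale = num("flow_scale"), pressure_scale = num("pressure_scale"),
    volume_scale = num("volume_scale"))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  structure(tab, groups = g, provenance = named[["provenance"]],
            model_label = named[["model"]],
            class = c("delivery_profile", "data.frame"))
}
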
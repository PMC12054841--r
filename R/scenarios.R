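#' @title Scenarios: fully parameterized plant + wound + environment
#' @description A `scenario` bundles every physical parameter needed by the
#'   simulators, in strict SI. Presets reproduce the published configurations:
#'   a small herbaceous (Arabidopsis-scale) transpiring plant, wheat-scale
#'   seedlings, and the local (nonvascular) wounding geometry. Two fields,
#'   `c_xyl` and `a_xyl`, are calibrated rather than measured (see the methods
#'   vignette): they set only the tracer-displacement magnitudes, never the
#'   pressure dynamics.
#' @name scenarios
NULL

#' Wound specification
#'
#' @param position coordinate of the wound along the plant axis \[m\]
#'   (0 = tip of the wounded leaf, the package origin).
#' @param mode `"sustained_reservoir"` (water-immersed wound: released water
#'   never runs out), `"depleting_reservoir"` (air-exposed wound: the wound
#'   seals once `reservoir_moles` have been drawn), or `"none"`.
#' @param reservoir_moles available released water \[mol\]
#'   (depleting mode only).
#' @param wound_pressure pressure imposed at the wound while water remains
#'   \[Pa gauge\]; default 0 (atmospheric).
#' @export
wound_spec <- function(position = 0,
                       mode = c("sustained_reservoir", "depleting_reservoir",
                                "none"),
                       reservoir_moles = NULL, wound_pressure = 0) {
  mode <- match.arg(mode)
  if (mode == "depleting_reservoir") {
    if (is.null(reservoir_moles) || !is.finite(reservoir_moles) ||
        reservoir_moles <= 0) {
      stop("depleting_reservoir wounds need reservoir_moles > 0")
    }
  }
  structure(list(position = as.numeric(position), mode = mode,
                 reservoir_moles = if (is.null(reservoir_moles)) NULL
                                   else as.numeric(reservoir_moles),
                 wound_pressure = as.numeric(wound_pressure)),
            class = "wound_spec")
}

# Preset parameter tables. Units here are SI already (converted by hand once
# from the published mixed units). a_stem is the effective stem-node coupling
# area making the pre-wound steady mean xylem pressure equal P0 (see
# vignette); c_xyl and a_xyl are calibrated (vignette, "Calibrated inputs").
.presets <- function() {
  base <- list(
    L = 0.01, vein_spacing = 4e-4, d_th = 2e-4,
    kappa_xyl = 1, kappa_t = 1e-10,
    c_t = 1e-2, c_xyl = 5.6e-4, a_xyl = 1e-8,
    P0 = -0.2e6, pi_t = 0.75e6, pi_xyl = 0,
    E = 1e-3, h_stem = 1e-8, a_stem = 4e-6,
    D = 1e-10, Vw = VW_WATER)
  wheat <- utils::modifyList(base, list(
    L = 0.2, vein_spacing = 3e-4, E = 0, a_stem = 4e-6))
  list(
    arabidopsis_fig2 = base,
    arabidopsis_fig4b = base,
    wheat_fig3 = wheat,
    wheat_fig4c = utils::modifyList(wheat, list(E = 1.2e-3, a_stem = 7.2e-5)),
    local_fig5 = utils::modifyList(base, list(E = 0, vein_spacing = 1e-3)))
}

#' Names of the built-in scenario presets
#' @export
scenario_presets <- function() names(.presets())

.scenario_fields <- c("L", "vein_spacing", "d_th", "kappa_xyl", "kappa_t",
                      "c_t", "c_xyl", "a_xyl", "P0", "pi_t", "pi_xyl", "E",
                      "h_stem", "a_stem", "D", "Vw")

#' Build a validated scenario from a preset plus overrides
#'
#' Overrides are applied after the preset and may be bare SI numerics or
#' `{value, unit}` pairs (see [si_value()]). The wound defaults to a sustained
#' reservoir at the leaf tip (`x = 0`) held at atmospheric pressure.
#'
#' @param preset one of [scenario_presets()].
#' @param overrides named list of field overrides; may include `wound`
#'   (a [wound_spec()] or a list of its arguments).
#' @return object of class `scenario`.
#' @export
#' @examples
#' s <- make_scenario("arabidopsis_fig2")
#' s$L                                    # 0.01 m
#' make_scenario("arabidopsis_fig2", list(E = 0))$E
#' make_scenario("wheat_fig3", list(vein_spacing = list(value = 0.3, unit = "mm")))
make_scenario <- function(preset, overrides = list()) {
  tab <- .presets()
  if (!preset %in% names(tab)) {
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(names(tab), collapse = ", ")))
  }
  s <- tab[[preset]]
  s$wound <- wound_spec()
  bad <- setdiff(names(overrides), c(.scenario_fields, "wound"))
  if (length(bad)) {
    stop(sprintf("unknown scenario field(s) in overrides: %s",
                 paste(bad, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    if (nm == "wound") {
      w <- overrides$wound
      s$wound <- if (inherits(w, "wound_spec")) w else do.call(wound_spec, w)
    } else {
      s[[nm]] <- si_value(overrides[[nm]], nm)
    }
  }
  s$preset <- preset
  class(s) <- "scenario"
  validate_scenario(s)
}

#' Validate a scenario's physical invariants
#'
#' Fails on sign/positivity violations; warns (does not fail) when the
#' xylem/tissue scale separation `kappa_xyl / kappa_t >= 1e6` assumed by the
#' quasi-steady machinery is violated.
#' @param s a `scenario`.
#' @return `s`, invisibly classed, on success.
#' @export
validate_scenario <- function(s) {
  pos <- c("L", "vein_spacing", "d_th", "kappa_xyl", "kappa_t", "c_t",
           "c_xyl", "a_xyl", "Vw")
  for (nm in pos) {
    if (!is.finite(s[[nm]]) || s[[nm]] <= 0) {
      stop(sprintf("scenario field '%s' must be strictly positive", nm))
    }
  }
  nonneg <- c("pi_t", "E", "h_stem", "a_stem", "D")
  for (nm in nonneg) {
    if (!is.finite(s[[nm]]) || s[[nm]] < 0) {
      stop(sprintf("scenario field '%s' must be >= 0", nm))
    }
  }
  if (!is.finite(s$P0) || s$P0 > 0) {
    stop("P0 is a xylem tension: P0 <= 0 (gauge) required")
  }
  if (s$pi_xyl != 0) stop("pi_xyl is fixed at 0 in this model")
  if (s$kappa_xyl / s$kappa_t < 1e6) {
    warning(sprintf(
      "scale separation kappa_xyl/kappa_t = %.3g < 1e6; quasi-steady xylem mode is questionable",
      s$kappa_xyl / s$kappa_t))
  }
  if (!inherits(s$wound, "wound_spec")) stop("scenario needs a wound_spec")
  s
}

#' Tissue half-spacing W = vein_spacing / 2
#' @param s a `scenario`.
#' @export
half_spacing <- function(s) s$vein_spacing / 2

#' Equilibrium tissue turgor pressures before and after wounding
#'
#' Before wounding the tissue sits in water-potential equilibrium with the
#' tensioned xylem: `P_t,init = P0 + pi_t`. A wound held at `wound_pressure`
#' relaxes the xylem, so the tissue equilibrates to
#' `P_t,final = wound_pressure + pi_t` (0.75 MPa for the default presets).
#'
#' @param s a `scenario`.
#' @return named numeric `c(P_t_initial, P_t_final)` \[Pa\].
#' @export
equilibrium_pressures <- function(s) {
  c(P_t_initial = s$P0 + s$pi_t,
    P_t_final = s$wound$wound_pressure + s$pi_t)
}

#' Characteristic poroelastic relaxation timescales
#'
#' `tau_xyl = L^2 / kappa_xyl` (whole-plant xylem equilibration) and
#' `tau_t = W^2 / kappa_t` with `W = vein_spacing / 2` (transverse tissue
#' relaxation). For the Arabidopsis-scale preset these evaluate to 1e-4 s
#' (100 microseconds) and 400 s.
#'
#' @param s a `scenario`.
#' @return named numeric `c(tau_xyl, tau_t)` \[s\].
#' @export
characteristic_timescales <- function(s) {
  c(tau_xyl = s$L^2 / s$kappa_xyl,
    tau_t = half_spacing(s)^2 / s$kappa_t)
}

#' @export
print.scenario <- function(x, ...) {
  ts <- characteristic_timescales(x)
  cat(sprintf("<scenario:%s> L = %.3g m, 2W = %.3g m, wound = %s\n",
              x$preset, x$L, x$vein_spacing, x$wound$mode))
  cat(sprintf("  tau_xyl = %.3g s, tau_t = %.3g s, E = %.3g mol m-2 s-1\n",
              ts[["tau_xyl"]], ts[["tau_t"]], x$E))
  invisible(x)
}

#' Serialize / parse scenarios (round-trip safe)
#'
#' @param s a `scenario`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
scenario_to_json <- function(s, path = NULL) {
  obj <- unclass(s)
  obj$wound <- unclass(obj$wound)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(path)
  } else txt
}

#' @rdname scenario_to_json
#' @param x JSON string or file path.
#' @export
scenario_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  w <- obj$wound
  obj$wound <- wound_spec(position = w$position, mode = w$mode,
                          reservoir_moles = w$reservoir_moles,
                          wound_pressure = w$wound_pressure)
  preset <- obj$preset
  obj$preset <- NULL
  flds <- obj[names(obj) %in% c(.scenario_fields, "wound")]
  make_scenario(preset, flds)
}

#' Stable content hash of a scenario
#'
#' Field order does not affect the hash (names are sorted recursively).
#' @param s a `scenario` (or any list-like object).
#' @export
scenario_hash <- function(s) {
  canon <- function(x) {
    x <- unclass(x)
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  rlang::hash(canon(s))
}

#' Solver configuration
#'
#' Plumbing for the coupled simulators: mesh resolutions, horizon, output
#' count and the theta scheme parameter. `random_seed` is accepted for
#' interface completeness; every solver in the package is deterministic.
#'
#' @param n_cells_x axial cells (>= 8).
#' @param n_cells_y transverse tissue cells across W (>= 8).
#' @param t_end simulation horizon \[s\]; `NULL` = 3 tau_t of the scenario.
#' @param n_times number of output times (geometric grid over the two
#'   timescales).
#' @param theta time scheme parameter in \[0.5, 1\].
#' @param tol linear-solve / conservation tolerance.
#' @param n_sub substeps per output interval.
#' @param random_seed unused by the core solvers; reserved.
#' @export
solver_config <- function(n_cells_x = 200, n_cells_y = 64, t_end = NULL,
                          n_times = 240, theta = 1, tol = 1e-10, n_sub = 2,
                          random_seed = NULL) {
  n_cells_x <- as.integer(n_cells_x)
  n_cells_y <- as.integer(n_cells_y)
  if (n_cells_x < 8L || n_cells_y < 8L) stop("solver_config: n_cells >= 8")
  if (!is.null(t_end) && t_end <= 0) stop("solver_config: t_end > 0")
  if (theta < 0.5 || theta > 1) stop("solver_config: theta in [0.5, 1]")
  structure(list(n_cells_x = n_cells_x, n_cells_y = n_cells_y, t_end = t_end,
                 n_times = as.integer(n_times), theta = theta, tol = tol,
                 n_sub = as.integer(n_sub), random_seed = random_seed),
            class = "solver_config")
}
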
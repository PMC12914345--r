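#' Uncertainty scenarios
#'
#' A scenario is either the nominal (unperturbed) geometry, a rigid patient
#' setup shift along exactly one axis, or a proton range over/undershoot
#' realized as a multiplicative factor on radiological depth. The sign
#' convention is fixed once: a "patient shift +s" is implemented as a beam
#' (isocenter) shift of -s; only the symmetry of the +/- scenario pairs is
#' relied on downstream.
#'
#' @param kind `"nominal"`, `"setup"` or `"range"`.
#' @param shift length-3 setup shift in mm (setup scenarios only).
#' @param range_scale multiplicative range factor (range scenarios only).
#' @param id character label.
#' @return object of class `scenario`.
#' @export
scenario <- function(kind = c("nominal", "setup", "range"),
                     shift = c(0, 0, 0), range_scale = 1, id = NULL) {
  kind <- match.arg(kind)
  s <- structure(
    list(kind = kind, shift = shift, range_scale = range_scale,
         id = id %||% kind),
    class = "scenario"
  )
  validate_scenario(s)
  s
}

#' @rdname scenario
#' @export
scenario_nominal <- function() scenario("nominal")

validate_scenario <- function(s) {
  if (!inherits(s, "scenario"))
    stop_letplan("not a scenario object", class = "letplan_domain_error")
  nz <- sum(abs(s$shift) > 0)
  ok <- switch(s$kind,
    nominal = nz == 0 && s$range_scale == 1,
    setup = nz == 1 && s$range_scale == 1,
    range = nz == 0 && s$range_scale != 1 && s$range_scale > 0
  )
  if (!ok)
    stop_letplan("invalid ", s$kind, " scenario: shift = (",
                 paste(s$shift, collapse = ", "), "), range_scale = ",
                 s$range_scale, class = "letplan_domain_error")
  invisible(s)
}

#' Generate the standard nine-scenario uncertainty set
#'
#' One nominal scenario, six single-axis setup shifts of `+/- setup_mm`
#' along the left-right, anterior-posterior, and superior-inferior axes,
#' and two range scenarios scaling radiological depth by
#' `1 -/+ range_fraction`. Deterministic order with nominal first.
#'
#' @param setup_mm setup shift magnitude (mm), default 2.25.
#' @param range_fraction relative range uncertainty, default 0.035.
#' @return object of class `scenario_set`: a list of [scenario()]s with the
#'   magnitudes stored as attributes.
#' @examples
#' length(generate_scenarios())  # 9
#' @export
generate_scenarios <- function(setup_mm = 2.25, range_fraction = 0.035) {
  if (setup_mm < 0 || range_fraction < 0 || range_fraction >= 1)
    stop_letplan("setup_mm must be >= 0 and range_fraction in [0, 1)",
                 class = "letplan_domain_error")
  axes <- c("x", "y", "z")
  sc <- list(scenario_nominal())
  for (a in 1:3) for (sgn in c(1, -1)) {
    shift <- c(0, 0, 0); shift[a] <- sgn * setup_mm
    sc[[length(sc) + 1]] <- scenario(
      "setup", shift = shift,
      id = sprintf("setup_%s%s", axes[a], if (sgn > 0) "+" else "-"))
  }
  sc[[length(sc) + 1]] <- scenario("range", range_scale = 1 - range_fraction,
                                   id = "range-")
  sc[[length(sc) + 1]] <- scenario("range", range_scale = 1 + range_fraction,
                                   id = "range+")
  structure(sc, setup_mm = setup_mm, range_fraction = range_fraction,
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("scenario_set:", length(x), "scenarios (",
      paste(vapply(x, function(s) s$id, ""), collapse = ", "), ")\n")
  invisible(x)
}

#' Apply a scenario to a phantom/beam geometry
#'
#' Returns the perturbation handle consumed by [compute_influence()]: for a
#' setup scenario the patient is displaced by `+shift` (equivalently the
#' isocenter by `-shift`); a range scenario forwards its `range_scale` into
#' [radiological_depth()]; the nominal scenario is the identity.
#'
#' @param grid a `phantom_grid` (used for bounds checking).
#' @param beams beam list (unused by the parallel-beam model, kept for
#'   interface stability).
#' @param scenario a [scenario()].
#' @return the validated scenario, ready to pass to [compute_influence()].
#' @export
apply_scenario <- function(grid, beams, scenario) {
  validate_scenario(scenario)
  extent <- dim(grid$density) * grid$voxel_size
  if (any(abs(scenario$shift) > extent))
    stop_letplan("setup shift exceeds the grid extent",
                 class = "letplan_bounds_error")
  scenario
}

#' Influence matrices for every scenario in a set
#'
#' Radiological depth depends only on the scenario's range scaling, so the
#' expensive ray traces are shared across the six setup scenarios.
#'
#' @param grid a `phantom_grid`.
#' @param spots a `spot_grid`.
#' @param scenarios a `scenario_set`.
#' @param ... forwarded to [compute_influence()].
#' @return list of `influence` objects, one per scenario, named by id.
#' @export
influence_set <- function(grid, spots, scenarios, ...) {
  cache <- new.env(parent = emptyenv())
  out <- lapply(scenarios, function(s) {
    compute_influence(grid, spots, apply_scenario(grid, NULL, s),
                      wepl_cache = cache, ...)
  })
  names(out) <- vapply(scenarios, function(s) s$id, "")
  out
}
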
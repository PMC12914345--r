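#' Dose and LET objective specification
#'
#' Prescription, penalty weights, organ-at-risk (OAR) dose levels and LET
#' priorities for spot-weight optimization. All doses in the objective are
#' constant-RBE-weighted (1.1 x physical) Gy(RBE). OAR limits follow
#' pediatric brain practice: brainstem max 60 Gy(RBE), spinal cord max
#' 57 Gy(RBE), target prescription 54 Gy(RBE) in 30 fractions with a D95
#' acceptability floor of 51 Gy(RBE).
#'
#' @param prescription target dose, Gy(RBE).
#' @param d95_floor acceptability floor for CTV D95, Gy(RBE).
#' @param target_weights named numeric, penalties `under` and `over` for the
#'   target.
#' @param oar_limits named numeric, max-dose levels per OAR, Gy(RBE).
#' @param oar_weights named numeric, overdose penalties per OAR.
#' @param phi_t,phi_o LET priorities for target and OARs (>= 0); both zero
#'   reduces the LET objective to the plain dose objective.
#' @param mu_weight weight of the linear total-fluence term
#'   `mu_weight * sum(w)`, a surrogate for integral dose to normal tissue
#'   and delivery efficiency. It breaks the large degeneracy of the
#'   quadratic dose objective toward fluence-efficient plans (Bragg peaks
#'   placed where dose is needed), as clinical optimizers do.
#' @param rbe constant RBE factor used inside the objective.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(prescription = 54, d95_floor = 51,
                           target_weights = c(under = 800, over = 120),
                           oar_limits = c(brainstem = 60, spinal_cord = 57),
                           oar_weights = c(brainstem = 300,
                                           spinal_cord = 300),
                           phi_t = 0, phi_o = 0, mu_weight = 0,
                           rbe = 1.1) {
  if (prescription <= 0)
    stop_letplan("prescription must be > 0", class = "letplan_domain_error")
  if (any(c(target_weights, oar_weights, phi_t, phi_o, mu_weight) < 0))
    stop_letplan("penalties must be >= 0", class = "letplan_domain_error")
  structure(
    list(prescription = prescription, d95_floor = d95_floor,
         target_weights = target_weights, oar_limits = oar_limits,
         oar_weights = oar_weights, phi_t = phi_t, phi_o = phi_o,
         mu_weight = mu_weight, rbe = rbe),
    class = "objective_spec"
  )
}

#' Resolve an objective spec against a phantom's structures
#'
#' Attaches voxel index sets (target, each OAR, and the OAR union used by
#' the LET terms) so the objective functions can be evaluated.
#'
#' @param spec an [objective_spec()].
#' @param grid a `phantom_grid` whose masks contain `ctv` and every OAR
#'   named in `oar_limits`.
#' @return the spec with `target_idx`, `oars`, and `oar_union_idx` fields.
#' @export
resolve_objective <- function(spec, grid) {
  target_idx <- which(grid$masks$ctv)
  if (length(target_idx) == 0)
    stop_letplan("CTV mask is empty", class = "letplan_domain_error")
  oars <- lapply(names(spec$oar_limits), function(nm) {
    if (is.null(grid$masks[[nm]]))
      stop_letplan("phantom has no structure mask '", nm, "'",
                   class = "letplan_domain_error")
    list(name = nm, idx = which(grid$masks[[nm]]),
         level = spec$oar_limits[[nm]], weight = spec$oar_weights[[nm]])
  })
  spec$target_idx <- target_idx
  spec$oars <- oars
  spec$oar_union_idx <- sort(unique(unlist(lapply(oars, `[[`, "idx"))))
  spec
}

check_w <- function(w, influence) {
  if (length(w) != ncol(influence$D))
    stop_letplan("intensity vector length ", length(w),
                 " does not match ", ncol(influence$D), " beamlets",
                 class = "letplan_shape_error")
  if (any(w < -1e-9 * max(abs(w), 1)))
    stop_letplan("beamlet intensities must be nonnegative",
                 class = "letplan_domain_error")
  # clamp sub-epsilon bound violations from the box-constrained solver
  if (any(w < 0)) w[w < 0] <- 0
  w
}

#' Quadratic penalty dose objective and its gradient
#'
#' `FD(w) = (pu/NT) sum max(0, p - d)^2 + (po/NT) sum max(0, d - p)^2 +
#' sum_OAR (pk/Nk) sum max(0, d - level_k)^2` with `d` the
#' constant-RBE-weighted dose `rbe * D w`. The gradient is analytic.
#'
#' @param w nonnegative beamlet intensity vector.
#' @param influence an `influence` object (one scenario).
#' @param spec a [resolve_objective()]-ed [objective_spec()].
#' @return list with `value` and `gradient` (length of `w`).
#' @export
dose_objective <- function(w, influence, spec) {
  w <- check_w(w, influence)
  d <- spec$rbe * as.numeric(influence$D %*% w)
  p <- spec$prescription
  ti <- spec$target_idx
  nt <- length(ti)
  under <- pmax(p - d[ti], 0)
  over <- pmax(d[ti] - p, 0)
  value <- spec$target_weights[["under"]] / nt * sum(under^2) +
    spec$target_weights[["over"]] / nt * sum(over^2)
  r <- numeric(length(d))
  r[ti] <- 2 / nt * (spec$target_weights[["over"]] * over -
                     spec$target_weights[["under"]] * under)
  for (o in spec$oars) {
    odev <- pmax(d[o$idx] - o$level, 0)
    value <- value + o$weight / length(o$idx) * sum(odev^2)
    r[o$idx] <- r[o$idx] + 2 * o$weight / length(o$idx) * odev
  }
  grad <- spec$rbe * as.numeric(Matrix::crossprod(influence$D, r))
  mu <- spec$mu_weight %||% 0
  if (mu > 0) {
    value <- value + mu * sum(w)
    grad <- grad + mu
  }
  list(value = value, gradient = grad)
}

#' Dose-averaged LET map of a plan
#'
#' For voxel i, `Li = sum_j Dij Lij wj / sum_j Dij wj` wherever the
#' denominator (physical dose) is positive, and 0 elsewhere. The map is
#' homogeneous of degree zero in `w`: rescaling a plan leaves LETd
#' unchanged.
#'
#' @param w nonnegative beamlet intensity vector.
#' @param influence an `influence` object.
#' @param DL optional precomputed elementwise product `D * L`.
#' @return list with `letd` (keV/um per voxel), `dose` (physical Gy per
#'   voxel), and the influence's `scenario` id.
#' @export
letd_map <- function(w, influence, DL = NULL) {
  w <- check_w(w, influence)
  if (is.null(DL)) DL <- influence$D * influence$L
  denom <- as.numeric(influence$D %*% w)
  numer <- as.numeric(DL %*% w)
  letd <- numeric(length(denom))
  pos <- denom > 0
  letd[pos] <- numer[pos] / denom[pos]
  list(letd = letd, dose = denom, scenario_id = influence$scenario$id)
}

#' LET-aware objective and its gradient
#'
#' Extends the dose objective with dose-averaged-LET terms that reward high
#' LETd in the target and penalize it in the OAR union:
#' `FL(w) = FD(w) - (phi_t/NT) sum_target Li^2 +
#' (phi_o/NO) sum_OAR Li^2`. The gradient uses the quotient rule
#' `dLi/dwj = Dij (Lij - Li) / sum_k Dik wk`; zero-dose voxels contribute
#' neither value nor gradient.
#'
#' @inheritParams dose_objective
#' @param DL optional precomputed elementwise product `D * L`.
#' @return list with `value` and `gradient`.
#' @export
let_objective <- function(w, influence, spec, DL = NULL) {
  if (is.null(DL)) DL <- influence$D * influence$L
  base <- dose_objective(w, influence, spec)
  if (spec$phi_t == 0 && spec$phi_o == 0) return(base)
  denom <- as.numeric(influence$D %*% w)
  numer <- as.numeric(DL %*% w)
  li <- numeric(length(denom))
  pos <- denom > 0
  li[pos] <- numer[pos] / denom[pos]
  ti <- spec$target_idx
  oi <- spec$oar_union_idx
  nt <- length(ti); no <- length(oi)
  value <- base$value - spec$phi_t / nt * sum(li[ti]^2) +
    spec$phi_o / no * sum(li[oi]^2)
  # d(sum coef Li^2)/dwj = sum_i 2 coef_i Li Dij (Lij - Li) / denom_i
  coef <- numeric(length(denom))
  coef[ti] <- coef[ti] - spec$phi_t / nt
  coef[oi] <- coef[oi] + spec$phi_o / no
  a <- numeric(length(denom))
  a[pos] <- 2 * coef[pos] * li[pos] / denom[pos]
  grad <- base$gradient +
    as.numeric(Matrix::crossprod(DL, a)) -
    as.numeric(Matrix::crossprod(influence$D, a * li))
  list(value = value, gradient = grad)
}

#' Objective-wise worst-case robust composite
#'
#' Each objective term (target underdose, target overdose, and each OAR
#' overdose) is evaluated in every uncertainty scenario and its worst
#' (largest) value kept; the composite is the sum of the per-term maxima and
#' the gradient sums the active worst scenario's term gradients. Ties are
#' broken toward the lowest scenario index, so a singleton nominal set
#' reproduces the nominal objective exactly.
#'
#' @param w nonnegative beamlet intensity vector.
#' @param influences list of `influence` objects, one per scenario.
#' @param spec a [resolve_objective()]-ed [objective_spec()].
#' @return list with `value`, `gradient`, and `active` (worst scenario
#'   index per term).
#' @export
robust_objective <- function(w, influences, spec) {
  ns <- length(influences)
  if (ns == 0)
    stop_letplan("robust objective needs at least one scenario",
                 class = "letplan_config_error")
  p <- spec$prescription
  ti <- spec$target_idx
  nt <- length(ti)
  n_oar <- length(spec$oars)
  doses <- vector("list", ns)
  terms <- matrix(0, nrow = 2 + n_oar, ncol = ns)
  for (s in seq_len(ns)) {
    d <- spec$rbe * as.numeric(influences[[s]]$D %*% w)
    doses[[s]] <- d
    terms[1, s] <- spec$target_weights[["under"]] / nt *
      sum(pmax(p - d[ti], 0)^2)
    terms[2, s] <- spec$target_weights[["over"]] / nt *
      sum(pmax(d[ti] - p, 0)^2)
    for (k in seq_len(n_oar)) {
      o <- spec$oars[[k]]
      terms[2 + k, s] <- o$weight / length(o$idx) *
        sum(pmax(d[o$idx] - o$level, 0)^2)
    }
  }
  active <- apply(terms, 1, which.max)
  value <- sum(terms[cbind(seq_len(nrow(terms)), active)])
  mu <- spec$mu_weight %||% 0
  value <- value + mu * sum(w)
  grad <- numeric(length(w))
  for (s in unique(active)) {
    d <- doses[[s]]
    r <- numeric(length(d))
    if (active[1] == s)
      r[ti] <- r[ti] - 2 * spec$target_weights[["under"]] / nt *
        pmax(p - d[ti], 0)
    if (active[2] == s)
      r[ti] <- r[ti] + 2 * spec$target_weights[["over"]] / nt *
        pmax(d[ti] - p, 0)
    for (k in seq_len(n_oar)) {
      if (active[2 + k] == s) {
        o <- spec$oars[[k]]
        r[o$idx] <- r[o$idx] + 2 * o$weight / length(o$idx) *
          pmax(d[o$idx] - o$level, 0)
      }
    }
    grad <- grad + spec$rbe *
      as.numeric(Matrix::crossprod(influences[[s]]$D, r))
  }
  grad <- grad + mu
  list(value = value, gradient = grad, active = active)
}

#' Bound-constrained spot-weight solve
#'
#' Minimizes an objective callable over nonnegative beamlet intensities with
#' L-BFGS-B. The callable must return `list(value, gradient)`. The solve is
#' deterministic given identical inputs; the returned intensities are never
#' worse than the start.
#'
#' @param objective function of `w` returning `list(value, gradient)`.
#' @param w0 nonnegative start vector.
#' @param options list; `maxit` iterations per round (default 400), `factr`
#'   L-BFGS-B tolerance (default 100), `restarts` maximum solve rounds
#'   (default 4) — restarting from the incumbent helps on the piecewise-
#'   smooth worst-case composite, where a single L-BFGS-B run can stall at
#'   a kink.
#' @return object of class `impt_plan`: list with `w`, `value`,
#'   `history` (objective value at every evaluation), `convergence`, and
#'   `strategy` (filled by [plan_strategy()]).
#' @export
solve_plan <- function(objective, w0, options = list()) {
  if (any(w0 < 0))
    stop_letplan("w0 must be nonnegative", class = "letplan_domain_error")
  f0 <- objective(w0)
  if (!is.finite(f0$value))
    stop_letplan("objective is not finite at w0 (initialization error)",
                 class = "letplan_init_error")
  cache <- new.env(parent = emptyenv())
  cache$w <- w0; cache$res <- f0; cache$history <- f0$value
  eval_at <- function(w) {
    if (!identical(w, cache$w)) {
      cache$w <- w
      cache$res <- objective(w)
      cache$history <- c(cache$history, cache$res$value)
    }
    cache$res
  }
  w <- w0
  value <- f0$value
  convergence <- NA_integer_
  for (round in seq_len(options$restarts %||% 4)) {
    fit <- stats::optim(
      par = w,
      fn = function(w) eval_at(w)$value,
      gr = function(w) eval_at(w)$gradient,
      method = "L-BFGS-B", lower = 0,
      control = list(maxit = options$maxit %||% 400,
                     factr = options$factr %||% 100)
    )
    convergence <- fit$convergence
    new_w <- pmax(fit$par, 0)
    new_value <- objective(new_w)$value
    improved <- new_value < value - 1e-8 * (abs(value) + 1)
    if (new_value <= value) {
      w <- new_w
      value <- new_value
    }
    if (!improved) break
  }
  structure(
    list(w = w, value = value, history = cache$history,
         convergence = fit$convergence, strategy = NA_character_,
         normalization = 1),
    class = "impt_plan"
  )
}

#' @export
print.impt_plan <- function(x, ...) {
  cat("impt_plan (", x$strategy, "): ", length(x$w), " beamlets, objective ",
      format(x$value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Run one planning strategy end to end
#'
#' Builds (or reuses) influence matrices, initializes spot weights uniformly
#' so the mean CTV dose matches the prescription in the nominal scenario,
#' and solves the strategy's objective: `"nominal"` and `"let"` use the
#' nominal scenario only (the LET strategy adds the LETd terms); `"robust"`
#' composes the objective-wise worst case over the full scenario set.
#'
#' @param strategy `"nominal"`, `"robust"` or `"let"`.
#' @param grid a `phantom_grid`.
#' @param beams list of [beam_config()].
#' @param spec an [objective_spec()]; for `"let"` its `phi_t`/`phi_o` are
#'   used as given, for the other strategies they are ignored.
#' @param scenarios a `scenario_set` (required for `"robust"`).
#' @param options solver options, see [solve_plan()].
#' @param spots optional precomputed `spot_grid`.
#' @param influences optional precomputed list of `influence` objects named
#'   by scenario id (must include `"nominal"`).
#' @return an `impt_plan` with `strategy`, `spots`, and solve metadata.
#' @export
plan_strategy <- function(strategy = c("nominal", "robust", "let"),
                          grid, beams, spec, scenarios = NULL,
                          options = list(), spots = NULL,
                          influences = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(spots)) spots <- place_spots(grid, beams)
  if (is.null(influences)) {
    if (strategy == "robust") {
      if (is.null(scenarios))
        stop_letplan("robust strategy needs a scenario set",
                     class = "letplan_config_error")
      influences <- influence_set(grid, spots, scenarios)
    } else {
      influences <- list(nominal = compute_influence(grid, spots))
    }
  }
  nominal <- influences[["nominal"]]
  if (is.null(nominal))
    stop_letplan("influences must include the nominal scenario",
                 class = "letplan_config_error")
  rspec <- resolve_objective(spec, grid)
  n <- ncol(nominal$D)
  mean_dose_unit <- mean(as.numeric(
    nominal$D[rspec$target_idx, , drop = FALSE] %*% rep(1, n)))
  w0 <- rep(rspec$prescription / (rspec$rbe * mean_dose_unit), n)
  objective <- switch(strategy,
    nominal = {
      sp <- rspec; sp$phi_t <- 0; sp$phi_o <- 0
      function(w) dose_objective(w, nominal, sp)
    },
    let = {
      DL <- nominal$D * nominal$L
      function(w) let_objective(w, nominal, rspec, DL = DL)
    },
    robust = {
      sp <- rspec; sp$phi_t <- 0; sp$phi_o <- 0
      function(w) robust_objective(w, influences, sp)
    }
  )
  if (strategy == "robust") {
    # continuation: the worst-case composite is only piecewise smooth, so
    # quasi-Newton solves stall when started far from the solution. A
    # smooth surrogate — the same objective on the scenario-averaged
    # influence — is solved first (from the uniform start) and its
    # solution seeds the worst-case solve.
    sp <- rspec; sp$phi_t <- 0; sp$phi_o <- 0
    Dbar <- Reduce(`+`, lapply(influences, `[[`, "D")) / length(influences)
    avg_inf <- list(D = Dbar, L = Dbar, scenario = scenario_nominal(),
                    spots = spots)
    seed_plan <- solve_plan(function(w) dose_objective(w, avg_inf, sp),
                            w0, options)
    plan <- solve_plan(objective, seed_plan$w, options)
    plan$history <- c(seed_plan$history, plan$history)
  } else {
    plan <- solve_plan(objective, w0, options)
  }
  plan$strategy <- strategy
  plan$spots <- spots
  plan
}
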
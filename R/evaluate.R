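#' Cumulative volume histogram and Dq quantile
#'
#' Builds the cumulative histogram (fraction of the structure receiving at
#' least each abscissa value) over the masked voxels and reports `Dq`, the
#' largest value received by at least a fraction `q` of the structure.
#'
#' @param values per-voxel field (Gy or keV/um), full grid or pre-masked.
#' @param mask logical array/vector or integer indices selecting the
#'   structure; `NULL` if `values` is already restricted.
#' @param q volume fraction in (0, 1); default 0.95 gives D95.
#' @param n_bins number of histogram bins.
#' @param structure,quantity labels carried into the result.
#' @return list with `abscissa`, `fraction` (nonincreasing), `dq`,
#'   `structure`, `quantity`.
#' @export
dvh_and_quantile <- function(values, mask = NULL, q = 0.95, n_bins = 200,
                             structure = NA_character_,
                             quantity = "dose") {
  v <- if (is.null(mask)) values else values[mask]
  if (length(v) == 0)
    stop_letplan("empty mask for structure '", structure, "'",
                 class = "letplan_structure_error")
  if (q <= 0 || q >= 1)
    stop_letplan("q must be in (0, 1)", class = "letplan_domain_error")
  n <- length(v)
  vmax <- max(v, 0)
  edges <- seq(0, vmax * 1.001 + 1e-12, length.out = n_bins)
  frac <- vapply(edges, function(e) sum(v >= e) / n, numeric(1))
  # Dq: largest value received by >= q of the volume
  s <- sort(v, decreasing = TRUE)
  dq <- s[ceiling(q * n)]
  list(abscissa = edges, fraction = frac, dq = dq, structure = structure,
       quantity = quantity)
}

#' Normalize a plan so CTV D95 hits a reference dose
#'
#' Dose is linear in the spot weights, so scaling `w` by
#' `reference / D95_current` makes the nominal-scenario constant-RBE CTV D95
#' equal the reference exactly; the LETd map is homogeneous of degree zero
#' in `w` and is untouched.
#'
#' @param plan an `impt_plan`.
#' @param influence nominal-scenario `influence`.
#' @param target_idx CTV voxel indices.
#' @param reference Gy(RBE), default 54.
#' @param rbe constant RBE factor.
#' @return the plan with scaled `w` and the `normalization` factor recorded.
#' @export
normalize_to_d95 <- function(plan, influence, target_idx, reference = 54,
                             rbe = 1.1) {
  d <- rbe * as.numeric(influence$D[target_idx, , drop = FALSE] %*% plan$w)
  d95 <- dvh_and_quantile(d, q = 0.95, structure = "ctv")$dq
  if (d95 <= 0)
    stop_letplan("normalization error: CTV D95 is zero",
                 class = "letplan_normalization_error")
  scale <- reference / d95
  plan$w <- plan$w * scale
  plan$normalization <- plan$normalization * scale
  plan
}

#' Dose-thresholded LETd statistics
#'
#' LETd is set to zero wherever the paired dose is at or below `threshold`
#' (default 1 Gy, applied to the constant-RBE-weighted dose), then the mean
#' (over all structure voxels, zeros included) and maximum are reported.
#' This suppresses clinically irrelevant high-LET values in nearly
#' unirradiated tissue.
#'
#' @param letd per-voxel LETd (keV/um), full grid.
#' @param dose per-voxel dose used for the threshold (Gy), full grid.
#' @param mask logical array/vector or integer indices for the structure.
#' @param threshold Gy; LETd below-or-at this dose is zeroed.
#' @return list with `mean` and `max` (keV/um).
#' @export
masked_letd_stats <- function(letd, dose, mask, threshold = 1) {
  idx <- if (is.logical(mask)) which(mask) else mask
  if (length(idx) == 0)
    stop_letplan("empty structure mask", class = "letplan_structure_error")
  l <- letd[idx]
  l[dose[idx] <= threshold] <- 0
  list(mean = mean(l), max = max(l))
}

#' Worst-case spread of a metric across scenarios
#'
#' @param values numeric vector of one metric evaluated in each scenario.
#' @return list with `min`, `max`, `bandwidth` (`max - min`).
#' @export
robustness_bandwidth <- function(values) {
  if (length(values) == 0)
    stop_letplan("no scenario values given", class = "letplan_domain_error")
  list(min = min(values), max = max(values),
       bandwidth = max(values) - min(values))
}

#' Per-beam dose and LETd decomposition
#'
#' Splits a plan's dose into additive per-beam maps (their sum is the total
#' dose exactly) and evaluates the dose-averaged LET of each beam's
#' contribution alone.
#'
#' @param w beamlet intensities.
#' @param influence an `influence` object.
#' @return list per beam: `dose` (physical Gy, full grid vector), `letd`.
#' @export
per_beam_decomposition <- function(w, influence) {
  w <- check_w(w, influence)
  beams <- influence$spots$beam
  parts <- sort(unique(beams))
  if (!setequal(seq_along(w), unlist(lapply(parts, function(b)
    which(beams == b)))))
    stop_letplan("beam partition does not cover all beamlet columns",
                 class = "letplan_partition_error")
  DL <- influence$D * influence$L
  out <- lapply(parts, function(b) {
    cols <- which(beams == b)
    Db <- influence$D[, cols, drop = FALSE]
    denom <- as.numeric(Db %*% w[cols])
    numer <- as.numeric(DL[, cols, drop = FALSE] %*% w[cols])
    letd <- numeric(length(denom))
    pos <- denom > 0
    letd[pos] <- numer[pos] / denom[pos]
    list(dose = denom, letd = letd)
  })
  names(out) <- paste0("beam", parts)
  out
}

#' Compare normalized plans across scenarios and structures
#'
#' Produces the full evaluation report: per plan x scenario x structure
#' dose and (1-Gy-masked) LETd statistics with CTV D95; per plan x
#' structure worst-case min/max and bandwidths; and nominal-scenario
#' biological-effect summaries (variable-RBE-weighted dose and the linear
#' LET-weighted dose surrogate — mean for the target, max for OARs).
#'
#' @param plans named list of normalized `impt_plan`s (names are the
#'   strategies).
#' @param grid the `phantom_grid`.
#' @param influences list of `influence` objects named by scenario id,
#'   containing `"nominal"`.
#' @param biology named list of [rbe_parameters()]: `tumor` and `oar`.
#' @param let_threshold Gy; dose threshold for LETd masking.
#' @return object of class `evaluation_report`: list of data frames
#'   `scenario_metrics`, `bandwidths`, `biology`.
#' @export
compare_plans <- function(plans, grid, influences,
                          biology = list(tumor = rbe_parameters(10),
                                         oar = rbe_parameters(2)),
                          let_threshold = 1) {
  if (is.null(influences[["nominal"]]))
    stop_letplan("influences must include the nominal scenario",
                 class = "letplan_completeness_error")
  structures <- c("ctv", "brainstem", "spinal_cord")
  rows <- list()
  for (pn in names(plans)) {
    w <- plans[[pn]]$w
    for (sn in names(influences)) {
      inf <- influences[[sn]]
      lm <- letd_map(w, inf)
      drbe <- constant_rbe_dose(lm$dose)
      for (st in structures) {
        idx <- which(grid$masks[[st]])
        ls <- masked_letd_stats(lm$letd, drbe, idx,
                                threshold = let_threshold)
        rows[[length(rows) + 1]] <- data.frame(
          plan = pn, scenario = sn, structure = st,
          mean_dose = mean(drbe[idx]), max_dose = max(drbe[idx]),
          d95 = if (st == "ctv")
            dvh_and_quantile(drbe, idx, structure = st)$dq else NA_real_,
          mean_letd = ls$mean, max_letd = ls$max
        )
      }
    }
  }
  scen <- do.call(rbind, rows)

  band_rows <- list()
  for (pn in names(plans)) for (st in structures)
    for (metric in c("mean_dose", "max_dose", "mean_letd", "max_letd")) {
      v <- scen[[metric]][scen$plan == pn & scen$structure == st]
      bw <- robustness_bandwidth(v)
      band_rows[[length(band_rows) + 1]] <- data.frame(
        plan = pn, structure = st, metric = metric,
        wc_min = bw$min, wc_max = bw$max, bandwidth = bw$bandwidth)
    }
  bands <- do.call(rbind, band_rows)

  bio_rows <- list()
  nominal <- influences[["nominal"]]
  for (pn in names(plans)) {
    lm <- letd_map(plans[[pn]]$w, nominal)
    for (st in structures) {
      idx <- which(grid$masks[[st]])
      pars <- if (st == "ctv") biology$tumor else biology$oar
      vrbe <- variable_rbe_dose(lm$dose[idx], lm$letd[idx], pars)
      lwd <- let_weighted_dose(lm$dose[idx], lm$letd[idx], c = pars$c)
      bio_rows[[length(bio_rows) + 1]] <- data.frame(
        plan = pn, structure = st,
        stat = if (st == "ctv") "mean" else "max",
        variable_rbe_dose = if (st == "ctv") mean(vrbe) else max(vrbe),
        clet_x_d_total = if (st == "ctv") mean(lwd$total)
                         else max(lwd$total),
        clet_x_d_component = if (st == "ctv") mean(lwd$component)
                             else max(lwd$component))
    }
  }
  bio <- do.call(rbind, bio_rows)

  structure(list(scenario_metrics = scen, bandwidths = bands,
                 biology = bio),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", length(unique(x$scenario_metrics$plan)),
      "plans x", length(unique(x$scenario_metrics$scenario)),
      "scenarios x", length(unique(x$scenario_metrics$structure)),
      "structures\n")
  nom <- x$scenario_metrics[x$scenario_metrics$scenario == "nominal", ]
  print(nom[, c("plan", "structure", "mean_dose", "max_dose", "d95",
                "mean_letd", "max_letd")], row.names = FALSE, digits = 4)
  invisible(x)
}
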
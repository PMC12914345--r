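#' Beam configuration
#'
#' A treatment beam defined by gantry and couch angles (degrees, folded to
#' \[0, 360)) and an isocenter in world coordinates (mm). The beam is modeled
#' as parallel pencil beams: at gantry 0 / couch 0 it travels from anterior
#' to posterior (+y); the gantry rotates the direction in the axial (x-y)
#' plane and the couch rotates it about the anterior-posterior axis, so
#' couch 90 yields a vertex (superior-inferior) beam.
#'
#' @param gantry_angle,couch_angle degrees.
#' @param isocenter world coordinates (mm); if `NULL`, filled in later with
#'   the CTV centroid by [place_spots()].
#' @return object of class `beam_config`.
#' @export
beam_config <- function(gantry_angle, couch_angle = 0, isocenter = NULL) {
  structure(
    list(gantry_angle = gantry_angle %% 360,
         couch_angle = couch_angle %% 360,
         isocenter = isocenter),
    class = "beam_config"
  )
}

#' Beam-fixed orthonormal basis
#'
#' @param beam a [beam_config()].
#' @return list with unit vectors `u` (beam travel direction) and lateral
#'   axes `e1`, `e2` spanning the beam's-eye-view plane.
#' @keywords internal
beam_basis <- function(beam) {
  gr <- beam$gantry_angle * pi / 180
  cr <- beam$couch_angle * pi / 180
  u0 <- c(sin(gr), cos(gr), 0)
  # couch rotation about the +y (anterior-posterior) axis
  u <- c(u0[1] * cos(cr) + u0[3] * sin(cr), u0[2],
         -u0[1] * sin(cr) + u0[3] * cos(cr))
  u <- u / sqrt(sum(u^2))
  # e1: horizontal-ish lateral axis; fall back if u is near the z axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Analytical central-axis depth-dose and LET curves
#'
#' Parametric stand-in for a generic proton beam line: the depth-dose is a
#' power-law-free plateau rising gently toward a Gaussian-smeared Bragg peak
#' at `range_water` (peak width grows with range to mimic range straggling,
#' with a sharper distal than proximal shoulder); the LET curve rises
#' monotonically from an entrance value below 2 keV/um to a peak-region
#' value near 11 keV/um at and just beyond the Bragg peak.
#'
#' @param range_water nominal range in water (mm), > 0.
#' @param depth_water water-equivalent depth(s) (mm), >= 0.
#' @return list with numeric vectors `dose` (relative, peak about 1.2) and
#'   `let` (keV/um).
#' @examples
#' z <- seq(0, 120, by = 0.5)
#' dl <- depth_dose_let(100, z)
#' z[which.max(dl$dose)]  # close to 100 mm
#' @export
depth_dose_let <- function(range_water, depth_water) {
  if (length(range_water) != 1 || !is.finite(range_water) ||
      range_water <= 0)
    stop_letplan("range_water must be a single positive number",
                 class = "letplan_domain_error")
  z <- depth_water
  R <- range_water
  sigma <- 0.015 * R + 1            # range straggling, mm
  dz <- z - R
  peak <- exp(-dz^2 / (2 * sigma^2))
  distal <- dz > 0
  peak[distal] <- exp(-dz[distal]^2 / (2 * (0.8 * sigma)^2))
  # plateau with smooth distal cutoff at the peak
  cutoff <- 0.5 * (1 - erf(dz / (0.7 * sigma * sqrt(2))))
  plateau <- 0.28 * (1 + 0.45 * pmin(z / R, 1)) * cutoff
  dose <- plateau + peak
  residual <- pmax(R - z, 0)
  let <- 0.9 + (11 - 0.9) / (1 + (residual / 4)^2)
  list(dose = dose, let = let)
}

# erf via pnorm; avoids a dependency for one special function
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Per-voxel radiological (water-equivalent) depth
#'
#' Traces parallel rays opposite to the beam direction from each requested
#' voxel center to the grid boundary, accumulating relative stopping power
#' with a midpoint rule (1 mm steps, nearest-voxel density sampling — the
#' phantoms are piecewise constant, so this matches interpolation to
#' within the voxelization; density outside the grid is zero).
#' `range_scale` multiplies the accumulated line integral and is how range
#' uncertainty scenarios enter.
#'
#' @param grid a `phantom_grid`.
#' @param beam a [beam_config()].
#' @param range_scale multiplicative factor on the line integral (> 0).
#' @param voxels integer indices (into the flattened grid) to evaluate;
#'   default all body voxels.
#' @param step ray sampling step (mm).
#' @return numeric vector of WEPL (mm), aligned with `voxels`.
#' @export
radiological_depth <- function(grid, beam, range_scale = 1, voxels = NULL,
                               step = 1) {
  if (range_scale <= 0)
    stop_letplan("range_scale must be > 0", class = "letplan_domain_error")
  if (is.null(voxels)) voxels <- which(grid$masks$body)
  if (length(voxels) == 0)
    stop_letplan("empty trace: no voxels intersect the beam",
                 class = "letplan_trace_error")
  bb <- beam_basis(beam)
  u <- bb$u
  co <- voxel_coordinates(dim(grid$density), grid$origin, grid$voxel_size)
  px <- co$x[voxels]; py <- co$y[voxels]; pz <- co$z[voxels]
  lo <- grid$origin
  hi <- grid$origin + dim(grid$density) * grid$voxel_size
  # distance backwards along -u to the grid bounding box
  t_back <- rep(Inf, length(voxels))
  p <- list(px, py, pz)
  for (a in 1:3) {
    if (u[a] > 1e-12) t_back <- pmin(t_back, (p[[a]] - lo[a]) / u[a])
    else if (u[a] < -1e-12) t_back <- pmin(t_back, (p[[a]] - hi[a]) / u[a])
  }
  kmax <- ceiling(max(t_back) / step)
  wepl <- numeric(length(voxels))
  dm <- dim(grid$density)
  vs <- rep(grid$voxel_size, length.out = 3)
  n1 <- dm[1]; n12 <- dm[1] * dm[2]
  # nearest-neighbor density sampling: the phantom is piecewise constant,
  # so this matches trilinear to within the voxelization itself
  for (k in seq_len(kmax)) {
    t <- (k - 0.5) * step
    act <- which(t <= t_back)
    if (length(act) == 0) break
    i <- round((px[act] - t * u[1] - lo[1]) / vs[1] + 0.5)
    j <- round((py[act] - t * u[2] - lo[2]) / vs[2] + 0.5)
    kk <- round((pz[act] - t * u[3] - lo[3]) / vs[3] + 0.5)
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & kk >= 1 & kk <= dm[3]
    if (any(ok)) {
      sel <- act[ok]
      wepl[sel] <- wepl[sel] +
        grid$density[i[ok] + (j[ok] - 1) * n1 + (kk[ok] - 1) * n12] * step
    }
  }
  range_scale * wepl
}

#' Place scanning spots to cover the CTV
#'
#' For each beam, CTV voxels are projected onto the beam's-eye-view plane.
#' Lateral spot positions form a regular grid at `spacing` covering the
#' projection plus one spacing of margin; at each lateral position spot
#' ranges (energies) are chosen so Bragg peaks sample the radiological-depth
#' values of the nearby CTV voxels at `layer_step` resolution.
#'
#' @param grid a `phantom_grid`.
#' @param beams list of [beam_config()].
#' @param spacing lateral spot spacing (mm), default 5.
#' @param layer_step energy-layer step in water-equivalent depth (mm),
#'   default 5.
#' @return object of class `spot_grid`: data frame with columns `beam`,
#'   `range` (mm WEPL), `a`, `b` (lateral offsets, mm), plus the resolved
#'   beam list and placement parameters as attributes.
#' @export
place_spots <- function(grid, beams, spacing = 5, layer_step = 5) {
  ctv_idx <- which(grid$masks$ctv)
  if (length(ctv_idx) == 0)
    stop_letplan("spot placement error: CTV mask is empty",
                 class = "letplan_placement_error")
  co <- voxel_coordinates(dim(grid$density), grid$origin, grid$voxel_size)
  centroid <- c(mean(co$x[ctv_idx]), mean(co$y[ctv_idx]),
                mean(co$z[ctv_idx]))
  beams <- lapply(beams, function(b) {
    if (is.null(b$isocenter)) b$isocenter <- centroid
    b
  })
  rows <- list()
  for (bi in seq_along(beams)) {
    beam <- beams[[bi]]
    bb <- beam_basis(beam)
    px <- co$x[ctv_idx] - beam$isocenter[1]
    py <- co$y[ctv_idx] - beam$isocenter[2]
    pz <- co$z[ctv_idx] - beam$isocenter[3]
    la <- px * bb$e1[1] + py * bb$e1[2] + pz * bb$e1[3]
    lb <- px * bb$e2[1] + py * bb$e2[2] + pz * bb$e2[3]
    wepl <- radiological_depth(grid, beam, voxels = ctv_idx)
    a_grid <- seq(floor(min(la) / spacing) * spacing - spacing,
                  ceiling(max(la) / spacing) * spacing + spacing,
                  by = spacing)
    b_grid <- seq(floor(min(lb) / spacing) * spacing - spacing,
                  ceiling(max(lb) / spacing) * spacing + spacing,
                  by = spacing)
    for (a in a_grid) for (b in b_grid) {
      near <- abs(la - a) <= spacing & abs(lb - b) <= spacing
      if (!any(near)) next
      d <- wepl[near]
      # energy layers on a global layer_step lattice, only where CTV
      # voxels actually sit (skips gaps, e.g. inside a C-shaped target),
      # plus one distal margin layer so range-overshoot scenarios remain
      # coverable; the proximal edge is coverable by the plateau of
      # deeper layers, so no proximal margin layer is added
      layers <- sort(unique(round(d / layer_step) * layer_step))
      layers <- unique(c(layers, max(layers) + layer_step))
      layers <- layers[layers > 0]
      if (length(layers) == 0) next
      rows[[length(rows) + 1]] <-
        data.frame(beam = bi, range = layers, a = a, b = b)
    }
  }
  spots <- do.call(rbind, rows)
  rownames(spots) <- NULL
  structure(spots, beams = beams, spacing = spacing,
            layer_step = layer_step,
            class = c("spot_grid", "data.frame"))
}

#' Sparse dose and LET influence matrices for one scenario
#'
#' For each spot the dose per unit intensity at voxel i is the central-axis
#' depth-dose at the voxel's water-equivalent depth (under the scenario's
#' range scaling) times a single-Gaussian lateral factor whose width grows
#' linearly with depth, normalized as a 2-d density so the integrated
#' depth-dose is preserved. The LET entry is the central-axis LET at that
#' depth, defined wherever the dose entry is kept. Entries below
#' `cutoff` times the spot's peak dose are dropped. Setup-shift scenarios
#' displace the patient relative to the beam axes; with parallel beams this
#' changes lateral positions but not intrinsic radiological depth.
#'
#' @param grid a `phantom_grid`.
#' @param spots a `spot_grid` from [place_spots()].
#' @param scenario a [scenario()]; default nominal.
#' @param sigma0 lateral Gaussian sigma at the surface (mm).
#' @param sigma_growth sigma growth per mm of depth.
#' @param cutoff sparsity cutoff relative to each spot's peak dose.
#' @param wepl_cache optional environment memoizing ray traces across
#'   scenarios that share a range scaling (used by [influence_set()]).
#' @return object of class `influence`: list with sparse matrices `D`
#'   (Gy per unit intensity) and `L` (keV/um) of dimension voxels x spots,
#'   the `scenario`, and the `spots` reference.
#' @export
compute_influence <- function(grid, spots, scenario = scenario_nominal(),
                              sigma0 = 3, sigma_growth = 0.03,
                              cutoff = 1e-4, wepl_cache = NULL) {
  if (!inherits(spots, "spot_grid"))
    stop_letplan("spots must be a spot_grid", class = "letplan_shape_error")
  validate_scenario(scenario)
  beams <- attr(spots, "beams")
  if (any(spots$beam > length(beams)))
    stop_letplan("scenario/spot grid mismatch: spot refers to unknown beam",
                 class = "letplan_consistency_error")
  nvox <- length(grid$density)
  body_idx <- which(grid$masks$body)
  co <- voxel_coordinates(dim(grid$density), grid$origin, grid$voxel_size)
  shift <- scenario$shift
  ii <- list(); jj <- list(); dd <- list(); ll <- list()
  for (bi in seq_along(beams)) {
    cols <- which(spots$beam == bi)
    if (length(cols) == 0) next
    beam <- beams[[bi]]
    bb <- beam_basis(beam)
    # patient shifted by +shift == beam axes shifted by -shift
    px <- co$x[body_idx] + shift[1] - beam$isocenter[1]
    py <- co$y[body_idx] + shift[2] - beam$isocenter[2]
    pz <- co$z[body_idx] + shift[3] - beam$isocenter[3]
    la <- px * bb$e1[1] + py * bb$e1[2] + pz * bb$e1[3]
    lb <- px * bb$e2[1] + py * bb$e2[2] + pz * bb$e2[3]
    key <- sprintf("beam%d_rs%.6f", bi, scenario$range_scale)
    if (!is.null(wepl_cache) && !is.null(wepl_cache[[key]])) {
      wepl <- wepl_cache[[key]]
    } else {
      wepl <- radiological_depth(grid, beam,
                                 range_scale = scenario$range_scale,
                                 voxels = body_idx)
      if (!is.null(wepl_cache)) wepl_cache[[key]] <- wepl
    }
    sigma <- sigma0 + sigma_growth * wepl
    halo <- 3.2 * max(sigma)
    # 2-d lateral binning so each spot only scans nearby voxels
    bw <- 8
    nb <- ceiling(halo / bw) + 1
    ka <- floor(la / bw); kb <- floor(lb / bw)
    ka0 <- min(ka); kb0 <- min(kb)
    na_bins <- max(ka) - ka0 + 1
    nb_bins <- max(kb) - kb0 + 1
    key <- factor((ka - ka0) + na_bins * (kb - kb0),
                  levels = 0:(na_bins * nb_bins - 1))
    bins <- split(seq_along(la), key)
    for (ci in cols) {
      a <- spots$a[ci]; b <- spots$b[ci]; R <- spots$range[ci]
      sa <- floor(a / bw) - ka0; sb <- floor(b / bw) - kb0
      ia <- sa + (-nb:nb); ia <- ia[ia >= 0 & ia < na_bins]
      ib <- sb + (-nb:nb); ib <- ib[ib >= 0 & ib < nb_bins]
      if (length(ia) == 0 || length(ib) == 0) next
      keys <- as.vector(outer(ia, na_bins * ib, "+")) + 1L
      cand <- unlist(bins[keys], use.names = FALSE)
      if (length(cand) == 0) next
      cand <- cand[abs(la[cand] - a) < halo & abs(lb[cand] - b) < halo]
      if (length(cand) == 0) next
      r2 <- (la[cand] - a)^2 + (lb[cand] - b)^2
      sg <- sigma[cand]
      keep <- r2 < (3.2 * sg)^2
      if (!any(keep)) next
      cand <- cand[keep]; r2 <- r2[keep]; sg <- sg[keep]
      dl <- depth_dose_let(R, wepl[cand])
      dose <- dl$dose * exp(-r2 / (2 * sg^2)) / (2 * pi * sg^2) * 25
      peak <- max(dose)
      keep <- dose > cutoff * peak
      if (!any(keep)) next
      ii[[length(ii) + 1]] <- body_idx[cand[keep]]
      jj[[length(jj) + 1]] <- rep.int(ci, sum(keep))
      dd[[length(dd) + 1]] <- dose[keep]
      ll[[length(ll) + 1]] <- dl$let[keep]
    }
  }
  i <- unlist(ii); j <- unlist(jj)
  D <- Matrix::sparseMatrix(i = i, j = j, x = unlist(dd),
                            dims = c(nvox, nrow(spots)))
  L <- Matrix::sparseMatrix(i = i, j = j, x = unlist(ll),
                            dims = c(nvox, nrow(spots)))
  structure(list(D = D, L = L, scenario = scenario, spots = spots),
            class = "influence")
}
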
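#' Specification of a synthetic voxel phantom
#'
#' Describes one of three pediatric-brain-like anatomical archetypes used to
#' exercise the planning pipeline without patient CT data:
#' \describe{
#'   \item{`wraparound`}{a C-shaped clinical target volume (CTV) wrapping
#'     around the brainstem, sharing roughly 22\% of the brainstem voxels;}
#'   \item{`abutting`}{a roughly spherical CTV abutting the brainstem
#'     posteriorly;}
#'   \item{`inferior_extension`}{an elongated CTV extending inferiorly beyond
#'     the brainstem and overlapping the spinal cord.}
#' }
#' Anatomy is piecewise geometric: a spherical head with a bone (skull)
#' shell, a neck cylinder, a brainstem cylinder, and a spinal-cord column,
#' all on a regular grid of relative-stopping-power densities
#' (air 0.001, soft tissue 1.0, bone 1.5 by default).
#'
#' @param archetype one of `"wraparound"`, `"abutting"`,
#'   `"inferior_extension"`.
#' @param grid_shape integer length 3, voxels per axis
#'   (left-right, anterior-posterior, superior-inferior).
#' @param voxel_size mm per axis (scalar or length 3); default 3 mm.
#' @param origin world position of the grid corner, mm.
#' @param target_ctv_volume requested CTV volume in cc. Defaults per
#'   archetype: 55.27 (wraparound), 56.67 (abutting),
#'   40.88 (inferior_extension).
#' @param densities named list with relative stopping powers `air`,
#'   `tissue`, `bone`.
#' @param geometry named list of geometric parameters (mm); see Details.
#'   Only entries being overridden need to be supplied.
#' @details `geometry` understands: `head_center`, `head_radius`,
#'   `skull_thickness`, `neck_radius`, `brainstem_center_xy`,
#'   `brainstem_radius`, `brainstem_z`, `cord_center_xy`, `cord_radius`,
#'   `cord_z`, `ctv_z` (axial extent of the C-shaped CTV), `ctv_open_angle`
#'   (angular opening of the C, degrees), `wrap_overlap_target` (fraction of
#'   brainstem voxels the wraparound CTV should share), plus archetype
#'   centers `abut_center` and `inferior_center_xy`/`inferior_z`.
#' @return object of class `phantom_spec`.
#' @seealso [build_phantom()]
#' @export
phantom_spec <- function(archetype = c("wraparound", "abutting",
                                       "inferior_extension"),
                         grid_shape = c(44L, 44L, 56L),
                         voxel_size = 3,
                         origin = c(0, 0, 0),
                         target_ctv_volume = NULL,
                         densities = list(air = 0.001, tissue = 1.0,
                                          bone = 1.5),
                         geometry = list()) {
  archetype <- match.arg(archetype)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape <= 0))
    stop_letplan("grid_shape must be 3 positive voxel counts",
                 class = "letplan_spec_error")
  vs <- rep(voxel_size, length.out = 3)
  if (any(vs <= 0))
    stop_letplan("voxel_size must be > 0", class = "letplan_spec_error")
  if (is.null(target_ctv_volume))
    target_ctv_volume <- switch(archetype,
      wraparound = 55.27, abutting = 56.67, inferior_extension = 40.88)
  if (target_ctv_volume <= 0)
    stop_letplan("target_ctv_volume must be > 0 (zero-volume structure)",
                 class = "letplan_spec_error")
  extent <- grid_shape * vs
  cx <- origin[1] + extent[1] / 2
  cy <- origin[2] + extent[2] / 2
  g <- list(
    head_center = c(cx, cy, origin[3] + 54),
    head_radius = 52,
    skull_thickness = 4,
    neck_radius = 30,
    brainstem_center_xy = c(cx, cy + 6),
    brainstem_radius = 9,
    brainstem_z = origin[3] + c(44, 80),
    cord_center_xy = c(cx, cy + 8),
    cord_radius = 4.5,
    cord_z = origin[3] + c(80, 150),
    ctv_z = origin[3] + c(46, 76),
    ctv_open_angle = NULL,
    wrap_overlap_target = 0.22,
    abut_center = c(cx, cy + 30, origin[3] + 62),
    inferior_center_xy = c(cx, cy + 8),
    inferior_z = origin[3] + c(70, 128)
  )
  g[names(geometry)] <- geometry
  for (nm in c("air", "tissue", "bone"))
    if (is.null(densities[[nm]]) || densities[[nm]] < 0)
      stop_letplan("densities must provide nonnegative '", nm, "'",
                   class = "letplan_spec_error")
  structure(
    list(archetype = archetype, grid_shape = grid_shape, voxel_size = vs,
         origin = origin, target_ctv_volume = target_ctv_volume,
         densities = densities, geometry = g),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$archetype, "\n",
      " grid ", paste(x$grid_shape, collapse = "x"),
      " @ ", paste(x$voxel_size, collapse = "x"), " mm\n",
      " target CTV volume ", x$target_ctv_volume, " cc\n", sep = "")
  invisible(x)
}

# voxelized cylinder along z
cyl_mask <- function(co, center_xy, radius, z_range) {
  (co$x - center_xy[1])^2 + (co$y - center_xy[2])^2 <= radius^2 &
    co$z >= z_range[1] & co$z <= z_range[2]
}

sphere_mask <- function(co, center, radius) {
  (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2 <=
    radius^2
}

# C-shaped annulus around the brainstem axis, opening toward anterior (-y)
wrap_ctv_mask <- function(co, g, r_in, r_out, open_angle) {
  dx <- co$x - g$brainstem_center_xy[1]
  dy <- co$y - g$brainstem_center_xy[2]
  r2 <- dx^2 + dy^2
  # angle about the axis, 0 pointing anterior (-y)
  ang <- atan2(dx, -dy) * 180 / pi
  r2 >= r_in^2 & r2 <= r_out^2 &
    abs(ang) >= open_angle / 2 &
    co$z >= g$ctv_z[1] & co$z <= g$ctv_z[2]
}

#' Build a synthetic voxel phantom
#'
#' Deterministically voxelizes the anatomy described by a [phantom_spec()].
#' The free size parameter of each archetype's CTV is tuned by bisection so
#' the achieved CTV volume lands within 5\% of `target_ctv_volume`; for the
#' `wraparound` archetype the inner radius of the C is additionally tuned so
#' the CTV overlaps close to 22\% of the brainstem voxels.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_grid`: a list with the `density` array
#'   (relative stopping power, water = 1), logical structure `masks`
#'   (`body`, `ctv`, `brainstem`, `spinal_cord`), `origin`, `voxel_size`,
#'   the `spec`, and an `achieved` summary (CTV cc, brainstem overlap
#'   fraction, structure voxel counts).
#' @examples
#' ph <- build_phantom(phantom_spec("wraparound"))
#' ph$achieved$ctv_cc
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop_letplan("spec must be a phantom_spec", class = "letplan_spec_error")
  g <- spec$geometry
  vs <- spec$voxel_size
  extent <- spec$grid_shape * vs
  lo <- spec$origin
  hi <- spec$origin + extent
  if (any(g$head_center - g$head_radius < lo[1:3] - 1e-9) ||
      any(g$head_center + g$head_radius > hi[1:3] + 1e-9))
    stop_letplan("grid too small: head sphere does not fit inside the grid",
                 class = "letplan_sizing_error")

  co <- voxel_coordinates(spec$grid_shape, spec$origin, vs)
  vox_cc <- prod(vs) / 1000

  head <- sphere_mask(co, g$head_center, g$head_radius)
  brain <- sphere_mask(co, g$head_center, g$head_radius - g$skull_thickness)
  neck <- cyl_mask(co, g$head_center[1:2], g$neck_radius,
                   c(g$head_center[3], hi[3]))
  body <- head | neck
  skull <- head & !brain & !neck

  brainstem <- cyl_mask(co, g$brainstem_center_xy, g$brainstem_radius,
                        g$brainstem_z) & body
  cord <- cyl_mask(co, g$cord_center_xy, g$cord_radius, g$cord_z) & body
  if (!any(brainstem) || !any(cord))
    stop_letplan("zero-volume structure: brainstem or spinal cord empty ",
                 "on this grid", class = "letplan_spec_error")

  target_vox <- spec$target_ctv_volume / vox_cc

  make_ctv <- switch(spec$archetype,
    wraparound = {
      # the brainstem-overlap fraction is a step function of the C's inner
      # radius and opening angle on a voxel grid, so a plain bisection can
      # land between steps; a small deterministic grid search picks the
      # (r_in, opening) pair closest to the requested overlap fraction
      nbs <- sum(brainstem)
      overlap_frac <- function(r_in, open_angle) {
        m <- wrap_ctv_mask(co, g, r_in, g$brainstem_radius + 60, open_angle)
        sum(m & brainstem) / nbs
      }
      if (is.null(g$ctv_open_angle)) {
        combos <- expand.grid(
          frac = seq(0.95, 0.55, by = -0.05),
          open = seq(150, 30, by = -15))
        err <- mapply(function(f, o)
          abs(overlap_frac(f * g$brainstem_radius, o) -
                g$wrap_overlap_target),
          combos$frac, combos$open)
        best <- combos[which.min(err), ]
        r_in <- best$frac * g$brainstem_radius
        open_angle <- best$open
      } else {
        open_angle <- g$ctv_open_angle
        lo_r <- 0; hi_r <- g$brainstem_radius
        for (it in 1:40) {
          mid <- (lo_r + hi_r) / 2
          if (overlap_frac(mid, open_angle) > g$wrap_overlap_target)
            lo_r <- mid else hi_r <- mid
        }
        r_in <- (lo_r + hi_r) / 2
      }
      function(size) wrap_ctv_mask(co, g, r_in, size, open_angle) & body
    },
    abutting = function(size) sphere_mask(co, g$abut_center, size) & body,
    inferior_extension = function(size)
      cyl_mask(co, g$inferior_center_xy, size, g$inferior_z) & body
  )

  # bisection on the archetype's size parameter to match the CTV volume
  lo_s <- 0.5; hi_s <- min(extent) / 2
  if (sum(make_ctv(hi_s)) < target_vox)
    stop_letplan("grid too small: requested CTV volume not realizable",
                 class = "letplan_sizing_error")
  for (it in 1:48) {
    mid <- (lo_s + hi_s) / 2
    if (sum(make_ctv(mid)) < target_vox) lo_s <- mid else hi_s <- mid
  }
  ctv <- make_ctv(hi_s)
  if (!any(ctv))
    stop_letplan("zero-volume structure: CTV empty",
                 class = "letplan_spec_error")
  achieved_cc <- sum(ctv) * vox_cc
  if (abs(achieved_cc - spec$target_ctv_volume) / spec$target_ctv_volume >
      0.05)
    stop_letplan(sprintf(
      "grid too coarse: achieved CTV volume %.2f cc misses target %.2f cc",
      achieved_cc, spec$target_ctv_volume), class = "letplan_sizing_error")

  density <- array(spec$densities$air, dim = spec$grid_shape)
  density[body] <- spec$densities$tissue
  density[skull] <- spec$densities$bone

  masks <- list(body = body, ctv = ctv, brainstem = brainstem,
                spinal_cord = cord)
  achieved <- list(
    ctv_cc = achieved_cc,
    overlap_brainstem_frac = sum(ctv & brainstem) / sum(brainstem),
    overlap_cord_frac = sum(ctv & cord) / sum(cord),
    voxel_counts = vapply(masks[c("ctv", "brainstem", "spinal_cord")], sum,
                          integer(1))
  )
  structure(
    list(density = density, masks = masks, origin = spec$origin,
         voxel_size = vs, spec = spec, achieved = achieved),
    class = "phantom_grid"
  )
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat("phantom_grid (", x$spec$archetype, "): ",
      paste(dim(x$density), collapse = "x"), " voxels @ ",
      paste(x$voxel_size, collapse = "x"), " mm\n", sep = "")
  cat(sprintf("  CTV %.2f cc (%d voxels), brainstem %d, spinal cord %d\n",
              x$achieved$ctv_cc, x$achieved$voxel_counts[1],
              x$achieved$voxel_counts[2], x$achieved$voxel_counts[3]))
  cat(sprintf("  CTV/brainstem overlap: %.1f%% of brainstem voxels\n",
              100 * x$achieved$overlap_brainstem_frac))
  invisible(x)
}
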
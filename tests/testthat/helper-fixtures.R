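# Small deterministic fixtures shared across test files.

# a compact phantom (fast to build and trace) for unit tests
tiny_spec <- function(archetype = "wraparound", target_ctv_volume = 12,
                      ...) {
  phantom_spec(
    archetype = archetype,
    grid_shape = c(30L, 30L, 36L),
    voxel_size = 3,
    target_ctv_volume = target_ctv_volume,
    geometry = list(
      head_center = c(45, 45, 40), head_radius = 36, skull_thickness = 3,
      neck_radius = 20,
      brainstem_center_xy = c(45, 49), brainstem_radius = 7,
      brainstem_z = c(26, 56),
      cord_center_xy = c(45, 50), cord_radius = 4, cord_z = c(56, 100),
      ctv_z = c(32, 50),
      abut_center = c(45, 66, 42),
      inferior_center_xy = c(45, 50), inferior_z = c(44, 80)
    ),
    ...
  )
}

tiny_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(archetype = "wraparound", ...) {
    key <- paste(archetype, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_phantom(tiny_spec(archetype, ...))
    cache[[key]]
  }
})

tiny_beams <- function() list(beam_config(180, 0), beam_config(90, 0))

# random sparse influence-like object with consistent D/L pattern
random_influence <- function(n_vox, n_spot, density = 0.15, seed = 1) {
  set.seed(seed)
  nnz <- max(1, round(n_vox * n_spot * density))
  i <- sample(n_vox, nnz, replace = TRUE)
  j <- sample(n_spot, nnz, replace = TRUE)
  dup <- duplicated(cbind(i, j))
  i <- i[!dup]; j <- j[!dup]
  x <- runif(length(i), 0.01, 1)
  l <- runif(length(i), 0.5, 12)
  D <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_vox, n_spot))
  L <- Matrix::sparseMatrix(i = i, j = j, x = l, dims = c(n_vox, n_spot))
  structure(list(D = D, L = L, scenario = scenario_nominal(),
                 spots = data.frame(beam = rep(1L, n_spot))),
            class = "influence")
}

# dense double-loop LETd oracle, independent of the sparse implementation
letd_dense_oracle <- function(w, influence) {
  D <- as.matrix(influence$D)
  L <- as.matrix(influence$L)
  n <- nrow(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_along(w)) {
      num <- num + D[i, j] * L[i, j] * w[j]
      den <- den + D[i, j] * w[j]
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# random resolved objective spec over an influence instance
random_objective_setup <- function(n_vox, n_spot, seed = 1, phi_t = 0,
                                   phi_o = 0, density = 0.15) {
  inf <- random_influence(n_vox, n_spot, seed = seed, density = density)
  set.seed(seed + 1000)
  idx <- sample(n_vox)
  n_t <- max(2, round(n_vox * 0.3))
  n_o <- max(2, round(n_vox * 0.2))
  masks <- list(
    ctv = seq_len(n_vox) %in% idx[seq_len(n_t)],
    brainstem = seq_len(n_vox) %in% idx[n_t + seq_len(n_o)],
    spinal_cord = seq_len(n_vox) %in% idx[n_t + n_o + seq_len(n_o)]
  )
  grid <- list(masks = masks)
  spec <- objective_spec(prescription = 5,
                         oar_limits = c(brainstem = 4, spinal_cord = 3.5),
                         target_weights = c(under = 10, over = 4),
                         oar_weights = c(brainstem = 6, spinal_cord = 6),
                         phi_t = phi_t, phi_o = phi_o)
  list(influence = inf, spec = resolve_objective(spec, grid), grid = grid)
}

# central finite-difference gradient oracle
fd_gradient <- function(f, w, idx = seq_along(w), h = NULL) {
  if (is.null(h)) h <- 1e-6 * max(sqrt(sum(w^2)), 1)
  vapply(idx, function(j) {
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (f(wp) - f(wm)) / (2 * h)
  }, numeric(1))
}
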
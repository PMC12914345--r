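test_that("DVH quantiles match a counting oracle", {
  # uniform field: D95 is the field value and the curve is a unit step
  u <- rep(7.5, 40)
  r <- dvh_and_quantile(u, q = 0.95)
  expect_equal(r$dq, 7.5)
  expect_true(all(r$fraction[r$abscissa <= 7.5] == 1))
  # sort-based oracle on random fields: largest v with >= q receiving >= v
  set.seed(14)
  for (i in 1:10) {
    v <- runif(200, 0, 60)
    r <- dvh_and_quantile(v, q = 0.95)
    oracle <- max(Filter(function(x) mean(v >= x) >= 0.95, v))
    expect_equal(r$dq, oracle)
    expect_true(all(diff(r$fraction) <= 0))
  }
  expect_error(dvh_and_quantile(numeric(0)),
               class = "letplan_structure_error")
})

test_that("histogram mean equals the survival-curve integral", {
  set.seed(15)
  v <- runif(500, 0, 40)
  r <- dvh_and_quantile(v, n_bins = 2000)
  integral <- sum(diff(r$abscissa) *
                    (head(r$fraction, -1) + tail(r$fraction, -1)) / 2)
  expect_lt(abs(integral - mean(v)) / mean(v), 0.01)
})

test_that("D95 normalization is exact, linear, and LETd neutral", {
  setup <- random_objective_setup(60, 25, seed = 30, density = 0.6)
  inf <- setup$influence
  ti <- setup$spec$target_idx
  set.seed(31)
  plan <- structure(list(w = runif(25, 0.5, 2), value = 0, history = 0,
                         convergence = 0, strategy = "nominal",
                         normalization = 1), class = "impt_plan")
  before <- letd_map(plan$w, inf)
  d_before <- 1.1 * as.numeric(inf$D[ti, ] %*% plan$w)
  d95_before <- dvh_and_quantile(d_before)$dq
  norm <- normalize_to_d95(plan, inf, ti, reference = 54)
  expect_equal(norm$normalization, 54 / d95_before)
  d_after <- 1.1 * as.numeric(inf$D[ti, ] %*% norm$w)
  expect_lt(abs(dvh_and_quantile(d_after)$dq - 54) / 54, 1e-9)
  # dose scales linearly, LETd not at all
  expect_equal(d_after, d_before * norm$normalization)
  expect_equal(letd_map(norm$w, inf)$letd, before$letd,
               tolerance = 1e-12)
  # zero plan cannot be normalized
  zp <- plan; zp$w[] <- 0
  expect_error(normalize_to_d95(zp, inf, ti),
               class = "letplan_normalization_error")
})

test_that("LETd statistics honor the 1 Gy dose mask", {
  # two voxels, doses (0.5, 10), LETd (9, 4) -> mean 2, max 4
  letd <- c(9, 4); dose <- c(0.5, 10)
  s <- masked_letd_stats(letd, dose, c(1, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$max, 4)
  # fully below threshold: everything zero
  s0 <- masked_letd_stats(c(3, 5), c(0.2, 1), c(1, 2))
  expect_equal(s0$mean, 0); expect_equal(s0$max, 0)
  # brute-force loop oracle on random instances
  set.seed(16)
  for (i in 1:8) {
    n <- 50
    letd <- runif(n, 0, 12); dose <- runif(n, 0, 5)
    mask <- sample(n, 20)
    s <- masked_letd_stats(letd, dose, mask)
    vals <- vapply(mask, function(i)
      if (dose[i] <= 1) 0 else letd[i], numeric(1))
    expect_equal(s$mean, mean(vals))
    expect_equal(s$max, max(vals))
  }
  expect_error(masked_letd_stats(1, 1, integer(0)),
               class = "letplan_structure_error")
})

test_that("bandwidth summarizes worst-case spread", {
  expect_equal(robustness_bandwidth(rep(4.2, 9))$bandwidth, 0)
  r <- robustness_bandwidth(c(50, 52, 55))
  expect_equal(r$min, 50); expect_equal(r$max, 55)
  expect_equal(r$bandwidth, 5)
  # a member value always lies inside [min, max]
  set.seed(17)
  v <- runif(9, 40, 60)
  r <- robustness_bandwidth(v)
  expect_true(all(v >= r$min & v <= r$max))
  expect_error(robustness_bandwidth(numeric(0)),
               class = "letplan_domain_error")
})

test_that("per-beam decomposition is additive and matches the restricted map", {
  ph <- tiny_phantom()
  spots <- place_spots(ph, tiny_beams())
  inf <- compute_influence(ph, spots)
  set.seed(18)
  w <- runif(ncol(inf$D), 0, 2)
  dec <- per_beam_decomposition(w, inf)
  expect_length(dec, 2)
  total <- as.numeric(inf$D %*% w)
  expect_lt(max(abs(dec$beam1$dose + dec$beam2$dose - total)), 1e-10)
  # restricted-columns oracle for beam LETd
  cols <- which(inf$spots$beam == 1)
  sub <- structure(list(D = inf$D[, cols], L = inf$L[, cols],
                        scenario = inf$scenario,
                        spots = inf$spots[cols, ]), class = "influence")
  expect_equal(dec$beam1$letd, letd_map(w[cols], sub)$letd,
               tolerance = 1e-12)
  # single-beam plan: decomposition equals the total map
  w1 <- w; w1[inf$spots$beam != 1] <- 0
  dec1 <- per_beam_decomposition(w1, inf)
  expect_equal(dec1$beam1$dose, as.numeric(inf$D %*% w1))
})
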
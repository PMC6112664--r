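test_that("default phantom carries the documented compartment T1 values", {
  ph <- tiny_phantom(nz = 1, n = 48)
  expect_setequal(unique(ph$t1[ph$labels == 1]), 289)
  sub_t1 <- vapply(2:6, function(l) unique(ph$t1[ph$labels == l]), numeric(1))
  expect_equal(sub_t1, c(211, 434, 556, 953, 1257))
  # physical invariants
  expect_true(all(ph$t2s[ph$labels > 0] <= ph$t1[ph$labels > 0]))
  expect_true(all(ph$pd[ph$labels == 0] == 0))
})

test_that("zero sub-volumes gives a uniform phantom with labels {0, 1}", {
  ph <- uniform_phantom(n = 24)
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L))
  expect_true(all(ph$t1[ph$labels == 1] == 289))
})

test_that("voxelization matches a brute-force point-in-shape oracle", {
  spec <- phantom_spec(grid_shape = c(2, 40, 40))
  ph <- build_phantom(spec)
  n <- 40
  for (z in 1:2) {
    th <- (z - 1) * spec$slice_rotation
    expected <- matrix(0L, n, n)
    for (iy in 1:n) {
      for (ix in 1:n) {
        y <- (iy - 0.5) / n; x <- (ix - 0.5) / n
        if (((y - 0.5) / 0.42)^2 + ((x - 0.5) / 0.42)^2 > 1) next
        expected[iy, ix] <- 1L
        for (k in seq_len(nrow(spec$subvols))) {
          s <- spec$subvols[k, ]
          v <- c(s$cy, s$cx) - 0.5
          cy <- 0.5 + cos(th) * v[1] - sin(th) * v[2]
          cx <- 0.5 + sin(th) * v[1] + cos(th) * v[2]
          if ((y - cy)^2 + (x - cx)^2 <= s$r^2) expected[iy, ix] <- s$label
        }
        v <- spec$vessel
        if ((y - v$cy)^2 + (x - v$cx)^2 <= v$r^2) {
          expected[iy, ix] <- max(spec$subvols$label) + 1L
        }
      }
    }
    expect_identical(ph$labels[z, , ], expected)
  }
  expect_identical(sum(ph$pd > 0), sum(ph$labels > 0))
})

test_that("overlapping sub-volumes with conflicting values name the labels", {
  bad <- phantom_spec(
    grid_shape = c(1, 32, 32),
    subvols = data.frame(label = c(2L, 3L), t1 = c(211, 434),
                         t2s = c(20, 35), pd = 100,
                         cy = c(0.5, 0.52), cx = c(0.5, 0.5), r = 0.2),
    vessel = NULL)
  expect_error(build_phantom(bad), "labels 2 and 3")
  # identical values may overlap freely
  ok <- phantom_spec(
    grid_shape = c(1, 32, 32),
    subvols = data.frame(label = c(2L, 3L), t1 = 211, t2s = 20, pd = 100,
                         cy = c(0.5, 0.52), cx = c(0.5, 0.5), r = 0.2),
    vessel = NULL)
  expect_s3_class(build_phantom(ok), "phantom_volume")
})

test_that("build_phantom is deterministic", {
  expect_identical(build_phantom(phantom_spec(grid_shape = c(2, 24, 24))),
                   build_phantom(phantom_spec(grid_shape = c(2, 24, 24))))
})

test_that("coil maps: identity, determinism, distinctness, normalization", {
  one <- build_coil_maps(1, c(16, 16))
  expect_true(all(one$maps == 1 + 0i))

  a <- build_coil_maps(8, c(32, 32), n_slices = 2, seed = 7)
  b <- build_coil_maps(8, c(32, 32), n_slices = 2, seed = 7)
  expect_identical(a$maps, b$maps)
  expect_false(identical(a$maps,
                         build_coil_maps(8, c(32, 32), 2, seed = 8)$maps))

  # pairwise correlation magnitudes below 0.999: maps are distinct
  m <- matrix(a$maps[, , , 1], nrow = 32 * 32)
  gram <- abs(Conj(t(m)) %*% m)
  norms <- sqrt(diag(gram))
  corr <- gram / outer(norms, norms)
  expect_true(all(corr[upper.tri(corr)] < 0.999))

  # sum-of-squares magnitude ~ 1 inside a central disc
  sos <- sqrt(apply(abs(a$maps[, , , 1])^2, c(1, 2), sum))
  yy <- matrix(1:32 - 16.5, 32, 32); xx <- t(yy)
  disc <- yy^2 + xx^2 < 10^2
  expect_true(all(abs(sos[disc] - 1) < 0.05))
  expect_error(build_coil_maps(0, c(16, 16)), "n_coils")
})

test_that("spgr_signal limits and Ernst-angle maximum", {
  expect_equal(spgr_signal(42, t1 = 100, t2s = 50, fa = 90, tr = 1e6, te = 0),
               42)
  s0 <- spgr_signal(100, 289, 30, 90, 261, te = 0)
  expect_equal(spgr_signal(100, 289, 30, 90, 261, te = 30), s0 * exp(-1))
  # at tr/t1 = 0.3 the signal is maximal at the Ernst angle (grid search)
  fa_grid <- seq(0.01, 90, by = 0.01)
  s <- spgr_signal(1, t1 = 100, t2s = 50, fa = fa_grid, tr = 30, te = 0)
  expect_equal(fa_grid[which.max(s)], ernst_angle(30, 100), tolerance = 0.01)
})

test_that("ernst_angle closed form", {
  expect_equal(round(ernst_angle(30, 100)), 42)
  expect_equal(ernst_angle(30, 100), acos(exp(-0.3)) * 180 / pi)
  expect_lt(ernst_angle(1, 1e9), 0.01)           # tr/t1 -> 0 limit
  expect_equal(ernst_angle(100, 100), 68.43, tolerance = 1e-3)
})

test_that("gamma variate: causality, zero bolus, closed-form integral", {
  m <- bolus_model(t0 = 10)
  t <- seq(0, 120, by = 0.02)
  cc <- concentration_curve(m, t)
  expect_true(all(cc$vascular[t < 10] == 0))
  expect_true(all(cc$tissue[t < 10] == 0))
  expect_true(all(cc$vascular >= 0) && all(cc$tissue >= 0))

  z <- concentration_curve(bolus_model(peak_conc = 0), t)
  expect_true(all(z$vascular == 0) && all(z$tissue == 0))

  g <- gamma_variate(t, t0 = 10, alpha = 3, beta = 1.5, amplitude = 2)
  quad <- sum(diff(t) * (g[-1] + g[-length(g)]) / 2)
  expect_equal(quad, gamma_variate_integral(3, 1.5, 2), tolerance = 0.01)
})

test_that("bolus approaches the steady level and the tissue curve lags", {
  m <- bolus_model(t0 = 5, steady_level = 0.5)
  t <- seq(0, 400, by = 0.5)
  cc <- concentration_curve(m, t)
  expect_equal(tail(cc$vascular, 1), 0.5, tolerance = 0.02)
  expect_gt(which.max(cc$tissue), which.max(cc$vascular))
})

test_that("apply_contrast_agent follows the relaxivity rate equation", {
  ph <- uniform_phantom(n = 16)
  ph$t1[] <- 1000; ph$t2s[] <- 100
  # inject a known concentration via a degenerate curve table
  m <- bolus_model(r1 = 4, r2s = 5)
  curves <- data.frame(t = 1, vascular = 1, tissue = 1)
  out <- apply_contrast_agent(ph, m, t = 1, curves = curves)
  # 1/T1' = 1/1000 + 4/1000 -> 200 ms
  expect_equal(unique(out$t1[ph$labels == 1]), 200)
  expect_equal(unique(out$t2s[ph$labels == 1]), 1 / (1 / 100 + 5 / 1000))

  # C = 0 leaves the volume unchanged
  same <- apply_contrast_agent(ph, m, t = 1,
                               curves = data.frame(t = 1, vascular = 0,
                                                   tissue = 0))
  expect_identical(same$t1, ph$t1)
  # doubling C never increases T2*
  out2 <- apply_contrast_agent(ph, m, t = 1,
                               curves = data.frame(t = 1, vascular = 2,
                                                   tissue = 2))
  expect_true(all(out2$t2s <= out$t2s))
  expect_error(apply_contrast_agent(ph, m, t = 1,
                                    curves = data.frame(t = 1, vascular = -1,
                                                        tissue = 0)),
               "negative")
})
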
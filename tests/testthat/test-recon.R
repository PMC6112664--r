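test_that("downsample_acs crops the central block and preserves DC", {
  k64 <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  expect_identical(downsample_acs(k64, c(64, 64)), k64)

  k <- matrix(complex(real = rnorm(128 * 68), imaginary = rnorm(128 * 68)),
              128, 68)
  out <- downsample_acs(k, c(64, 64))
  expect_identical(dim(out), c(64L, 64L))
  # brute-force crop oracle (0-based DC at floor(N/2))
  brute <- k[(64 - 32 + 1):(64 + 32), (34 - 32 + 1):(34 + 32)]
  expect_identical(out, brute)
  expect_identical(out[33, 33], k[65, 35])   # DC bin preserved exactly

  imp <- matrix(0i, 16, 16); imp[9, 9] <- 1 + 0i
  expect_identical(downsample_acs(imp, c(8, 8))[5, 5], 1 + 0i)
  expect_lte(sum(abs(downsample_acs(k, c(32, 32)))^2), sum(abs(k)^2))
  expect_error(downsample_acs(k64, c(128, 64)), "larger than source")
})

test_that("ACS preparation contracts (both methods)", {
  ph <- tiny_phantom(nz = 2, n = 24)
  coils <- build_coil_maps(3, c(24, 24), 2)
  enc <- encode_pair(ph, coils, mb = 2, f = 2)

  # method 1: noiseless measured SMS source equals collapse of the targets
  acs1 <- prepare_acs_method1(enc$sms, enc$sb, enc$plan_sms)
  acs2 <- prepare_acs_method2(enc$sb, enc$plan_sms)
  expect_lt(max(abs(acs1$source - acs2$source)), 1e-10)
  expect_identical(acs1$method, 1L)
  expect_identical(acs2$method, 2L)

  # mb = 1: target and source both equal the single-band data
  pl1 <- enc$plan_sb
  a1 <- prepare_acs_method2(enc$sb, pl1)
  expect_equal(a1$source[, , , 1, 1], enc$sb$kspace[, , , 1, 1, 1],
               tolerance = 1e-14)

  # contrast mismatch is an error
  par_other <- acquisition_params(fa = 30, mb = 2, fov_shift_factor = 2,
                                  noise_sd = 0)
  pl_sms <- enc$plan_sms
  sms_other <- encode_acquisition(ph, coils, pl_sms, par_other)
  expect_error(prepare_acs_method1(sms_other, enc$sb, pl_sms),
               "contrast mismatch")

  # missing slices
  pl4 <- plan(24, 4, 4, mb = 2, f = 2, te_list = TE3, tr = 261)
  expect_error(prepare_acs_method2(enc$sb, pl4), "missing slices|slices")
})

test_that("slice-GRAPPA identity unfolding at mb = 1", {
  ph <- tiny_phantom(nz = 1, n = 24)
  coils <- build_coil_maps(3, c(24, 24), 1)
  enc <- encode_pair(ph, coils, mb = 1, f = 1)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sb)
  # noiseless identity problem: no ridge needed (the default ridge trades
  # ~1% shrinkage for noise robustness and would dominate this check)
  k <- fit_slice_grappa(acs, lambda = 0)
  expect_lt(max(k$residual), 1e-12)
  r <- unfold(enc$sb, k)
  ref <- sb_reference_images(enc$sb)
  expect_lt(nrmse(r$slice_images[, , 1, 1], ref[, , 1, 1]), 1e-6)
})

test_that("mb = 2 noiseless unfolding reaches NRMSE < 0.02", {
  ph <- tiny_phantom(nz = 2, n = 48)
  coils <- build_coil_maps(8, c(48, 48), 2, seed = 2)
  enc <- encode_pair(ph, coils, mb = 2, f = 2)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sms)
  k <- fit_slice_grappa(acs, lambda = 1e-6)   # noiseless: minimal ridge
  r <- unfold(enc$sms, k)
  ref <- sb_reference_images(enc$sb)
  for (z in 1:2) {
    expect_lt(nrmse(r$slice_images[, , z, 1], ref[, , z, 1]), 0.02)
  }
})

test_that("ridge residual is non-decreasing in lambda", {
  ph <- tiny_phantom(nz = 2, n = 24)
  coils <- build_coil_maps(4, c(24, 24), 2, seed = 3)
  enc <- encode_pair(ph, coils, mb = 2, f = 2, noise_sd = 0.01)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sms)
  res <- vapply(c(0, 1e-6, 1e-3),
                function(l) mean(fit_slice_grappa(acs, lambda = l)$residual),
                numeric(1))
  expect_true(all(diff(res) >= -1e-12))
})

test_that("singular normal equations with lambda = 0 advise lambda > 0", {
  ph <- tiny_phantom(nz = 2, n = 16)
  maps <- array(0i, c(16, 16, 2, 2))
  maps[, , 1, ] <- 1      # coil 2 identically zero: singular design
  coils <- manual_coils(maps)
  enc <- encode_pair(ph, coils, mb = 2, f = 2, te_list = 9)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sms)
  expect_error(fit_slice_grappa(acs, lambda = 0), "lambda > 0")
})

test_that("split slice-GRAPPA equals SG for a single slice", {
  ph <- tiny_phantom(nz = 1, n = 24)
  coils <- build_coil_maps(3, c(24, 24), 1, seed = 5)
  enc <- encode_pair(ph, coils, mb = 1, f = 1)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sb)
  k_sg <- fit_slice_grappa(acs)
  k_ssg <- fit_split_slice_grappa(acs)
  expect_lt(max(abs(k_sg$kernels[[1]] - k_ssg$kernels[[1]])), 1e-8)
})

test_that("SSG rejects method-1 ACS", {
  ph <- tiny_phantom(nz = 2, n = 16)
  coils <- build_coil_maps(2, c(16, 16), 2)
  enc <- encode_pair(ph, coils, mb = 2, f = 2, te_list = 9)
  acs1 <- prepare_acs_method1(enc$sms, enc$sb, enc$plan_sms)
  expect_error(fit_split_slice_grappa(acs1), "method 2")
})

test_that("SSG leaks less energy between slices than SG", {
  ph <- tiny_phantom(nz = 4, n = 48)
  coils <- build_coil_maps(8, c(48, 48), 4, seed = 2)
  enc <- encode_pair(ph, coils, mb = 4, f = 4)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sms)
  k_sg <- fit_slice_grappa(acs)
  k_ssg <- fit_split_slice_grappa(acs)
  for (slice in c(1, 3)) {
    l_sg <- leak_fraction(k_sg, enc$sb, slice, f = 4, mb = 4)
    l_ssg <- leak_fraction(k_ssg, enc$sb, slice, f = 4, mb = 4)
    expect_lt(l_ssg, l_sg)
  }
  # and SSG still reconstructs accurately: per-slice NRMSE < 0.05
  r <- unfold(enc$sms, k_ssg)
  ref <- sb_reference_images(enc$sb)
  for (z in 1:4) {
    expect_lt(nrmse(r$slice_images[, , z, 1], ref[, , z, 1]), 0.05)
  }
})

test_that("method 1 and method 2 give identical kernels on exact collapse", {
  ph <- tiny_phantom(nz = 2, n = 24)
  coils <- build_coil_maps(4, c(24, 24), 2, seed = 6)
  enc <- encode_pair(ph, coils, mb = 2, f = 2)
  k1 <- fit_slice_grappa(prepare_acs_method1(enc$sms, enc$sb, enc$plan_sms))
  k2 <- fit_slice_grappa(prepare_acs_method2(enc$sb, enc$plan_sms))
  expect_lt(max(abs(k1$kernels[[1]] - k2$kernels[[1]])), 1e-8)
})

test_that("unfold: training-data round trip, linearity and alignment", {
  ph <- tiny_phantom(nz = 2, n = 32)
  coils <- build_coil_maps(6, c(32, 32), 2, seed = 2)
  enc <- encode_pair(ph, coils, mb = 2, f = 2)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sms)
  k <- fit_slice_grappa(acs)
  r <- unfold(enc$sms, k)
  ref <- sb_reference_images(enc$sb)

  # round trip: reconstruction error comparable to the ACS fit residual
  rel <- nrmse(r$slice_images[, , 1, 1], ref[, , 1, 1])
  expect_lt(rel, 10 * sqrt(max(k$residual)))

  # kernel linearity: unfold(a * frame) = |a| * unfold(frame)
  a <- 0.7 - 1.1i
  scaled <- enc$sms
  scaled$kspace <- scaled$kspace * a
  r2 <- unfold(scaled, k)
  expect_equal(r2$slice_images, Mod(a) * r$slice_images, tolerance = 1e-10)

  # shift removal: cross-correlation peak with the reference at lag 0
  for (z in 1:2) {
    xc <- vapply(0:31, function(lag) {
      sum(circshift_rows(r$slice_images[, , z, 1], lag) * ref[, , z, 1])
    }, numeric(1))
    expect_identical(which.max(xc), 1L)
  }
})

test_that("ACS111 and ACS123 agree on matched-contrast noiseless data", {
  ph <- tiny_phantom(nz = 2, n = 32)
  coils <- build_coil_maps(6, c(32, 32), 2, seed = 2)
  enc <- encode_pair(ph, coils, mb = 2, f = 2, ets = 0)
  acs <- prepare_acs_method2(enc$sb, enc$plan_sms)
  k111 <- train_kernel(acs, "sg", "acs111")
  k123 <- train_kernel(acs, "sg", "acs123")
  r111 <- unfold(enc$sms, k111)
  r123 <- unfold(enc$sms, k123)
  ref <- sb_reference_images(enc$sb)
  for (z in 1:2) {
    for (e in 1:3) {
      d <- abs(nrmse(r111$slice_images[, , z, e], ref[, , z, e]) -
                 nrmse(r123$slice_images[, , z, e], ref[, , z, e]))
      expect_lt(d, 0.01)
    }
  }
})

test_that("navigator phase correction: identity, constant, linear", {
  ph <- tiny_phantom(nz = 2, n = 32)
  coils <- build_coil_maps(4, c(32, 32), 2, seed = 3)
  pl <- plan(32, 4, 2, mb = 1, f = 1, te_list = TE3, tr = 261)

  par0 <- acquisition_params(mb = 1, fov_shift_factor = 1, noise_sd = 0)
  ks0 <- encode_acquisition(ph, coils, pl, par0)
  plane0 <- ks0$kspace[, , , 1, 1, 1]
  # ghost_phase = (0, 0): data unchanged within 1e-12
  corr0 <- navigator_phase_correct(plane0, ks0$navigators[, , , 1, 1], 4)
  expect_lt(max(abs(corr0 - plane0)), 1e-12)

  img_of <- function(pl3) {
    sos_combine(array(apply(pl3, 3, ift2), dim(pl3)))
  }
  ref_img <- img_of(plane0)

  # constant phase pi/8 on odd lines: ghost energy reduced by > 90%
  par_c <- acquisition_params(mb = 1, fov_shift_factor = 1, noise_sd = 0,
                              ghost_phase = c(pi / 8, 0))
  ks_c <- encode_acquisition(ph, coils, pl, par_c)
  plane_c <- ks_c$kspace[, , , 1, 1, 1]
  e_before <- sum((img_of(plane_c) - ref_img)^2)
  corr_c <- navigator_phase_correct(plane_c, ks_c$navigators[, , , 1, 1], 4)
  e_after <- sum((img_of(corr_c) - ref_img)^2)
  expect_lt(e_after, 0.1 * e_before)

  # linear phase 0.01 rad/sample: slope estimate within 5%
  par_l <- acquisition_params(mb = 1, fov_shift_factor = 1, noise_sd = 0,
                              ghost_phase = c(0, 0.01))
  ks_l <- encode_acquisition(ph, coils, pl, par_l)
  est <- estimate_nav_phase(ks_l$navigators[, , , 1, 1])
  expect_lt(abs(est["slope"] - 0.01) / 0.01, 0.05)

  # missing navigators: warning, data unchanged
  expect_warning(out <- navigator_phase_correct(plane_c, NULL, 4), "skipped")
  expect_identical(out, plane_c)
})

test_that("sum-of-squares combination", {
  img <- matrix(runif(64), 8, 8)
  expect_equal(sos_combine(img * (0.6 + 0.8i)), img)
  two <- array(0i, c(8, 8, 2))
  two[, , 1] <- 3 * img; two[, , 2] <- 4i * img
  expect_equal(sos_combine(two), 5 * img)
  # SoS-normalized simulated maps: combined image ~ |object| in support
  ph <- tiny_phantom(nz = 1, n = 32)
  coils <- build_coil_maps(5, c(32, 32), 1, seed = 4)
  obj <- phantom_echo_image(ph, 90, 261, 9)[1, , ]
  ci <- array(0i, c(32, 32, 5))
  for (cc in 1:5) ci[, , cc] <- obj * coils$maps[, , cc, 1]
  comb <- sos_combine(ci)
  sup <- obj > 0
  expect_true(all(abs(comb[sup] - obj[sup]) / obj[sup] < 0.05))
})

test_that("reconstruct_series: static frames, determinism, dynamics", {
  ph <- tiny_phantom(nz = 2, n = 24)
  coils <- build_coil_maps(4, c(24, 24), 2, seed = 5)
  pl_sms <- plan(24, 4, 2, mb = 2, f = 2, te_list = TE3, tr = 261,
                 n_frames = 3, dead_time = 261)
  pl_sb <- plan(24, 4, 2, mb = 1, f = 1, te_list = TE3, tr = 261)
  par_sb <- acquisition_params(mb = 1, fov_shift_factor = 1, noise_sd = 0)
  sb <- encode_acquisition(ph, coils, pl_sb, par_sb)
  kern <- train_kernel(prepare_acs_method2(sb, pl_sms), "sg")

  par_dyn <- acquisition_params(mb = 2, fov_shift_factor = 2,
                                noise_sd = 0.01, seed = 9)
  dyn <- encode_acquisition(rep(list(ph), 3), coils, pl_sms, par_dyn)
  r1 <- reconstruct_series(dyn, kern)
  r2 <- reconstruct_series(dyn, kern)
  expect_identical(r1$slice_images, r2$slice_images)   # deterministic

  # static series: frames identical within noise
  m <- apply(r1$slice_images[, , 1, 1, ], 3, mean)
  expect_lt(max(abs(m - mean(m))) / mean(m), 0.05)

  # dynamic series with bolus: error never exceeds 2x pre-bolus error
  model <- bolus_model(t0 = 1.5, peak_conc = 3)
  times <- (0:2) * pl_sms$dt
  vols <- lapply(times, function(t) apply_contrast_agent(ph, model, t))
  dynb <- encode_acquisition(vols, coils, pl_sms, par_dyn)
  rb <- reconstruct_series(dynb, kern)
  err <- matrix(0, 3, 2)
  for (fr in 1:3) {
    pv <- plan(24, 4, 2, mb = 1, f = 1, te_list = TE3, tr = 261)
    sbv <- encode_acquisition(vols[[fr]], coils, pv, par_sb)
    refv <- sb_reference_images(sbv)
    for (z in 1:2) err[fr, z] <- nrmse(rb$slice_images[, , z, 1, fr],
                                       refv[, , z, 1])
  }
  expect_true(all(err <= 2 * max(err[1, ]) + 0.02))
})
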
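test_that("Huang threshold: two-valued image and constant volume", {
  img <- array(0, c(10, 10)); img[3:6, 3:6] <- 100
  m <- huang_mask(img)
  expect_identical(m, img == 100)
  expect_warning(thr <- huang_threshold(array(5, c(4, 4))), "constant")
  expect_true(is.na(thr))
  expect_warning(m0 <- huang_mask(array(5, c(4, 4))), "constant")
  expect_false(any(m0))
})

test_that("Huang threshold separates a two-Gaussian mixture", {
  set.seed(11)
  truth <- rep(c(FALSE, TRUE), each = 4000)
  v <- c(rnorm(4000, 10, 5), rnorm(4000, 100, 5))
  m <- huang_mask(v)
  expect_lt(mean(m != truth), 0.01)
  # inverted image: complementary mask up to the threshold bin
  m_inv <- huang_mask(-v)
  expect_lt(mean(m_inv == m), 0.01)
})

test_that("Huang threshold equals the brute-force entropy sweep", {
  set.seed(12)
  v <- c(rgamma(3000, 2, 1), rnorm(1500, 30, 4))
  thr <- huang_threshold(v)
  # independent oracle: naive per-threshold loop over the same histogram
  nb <- 256L
  rng <- range(v); width <- diff(rng) / nb
  bin <- pmin(floor((v - rng[1]) / width), nb - 1L)
  h <- tabulate(bin + 1L, nbins = nb)
  g <- 0:(nb - 1L); C <- nb - 1L
  ent <- numeric(nb - 1L)
  for (t in 0:(nb - 2L)) {
    lo <- g <= t
    n0 <- sum(h[lo]); n1 <- sum(h[!lo])
    u <- numeric(nb)
    mu0 <- if (n0 > 0) sum(h[lo] * g[lo]) / n0 else sum(h * g) / sum(h)
    mu1 <- if (n1 > 0) sum(h[!lo] * g[!lo]) / n1 else sum(h * g) / sum(h)
    u[lo] <- 1 / (1 + abs(g[lo] - mu0) / C)
    u[!lo] <- 1 / (1 + abs(g[!lo] - mu1) / C)
    s <- ifelse(u > 0 & u < 1, -u * log(u) - (1 - u) * log(1 - u), 0)
    ent[t + 1L] <- sum(h * s) / sum(h)
  }
  t_star <- which.min(ent) - 1L
  expect_equal(thr, rng[1] + (t_star + 1L) * width)
})

test_that("ediff: exact values, scale invariance, zero-reference handling", {
  sb <- array(runif(64, 1, 2), c(8, 8))
  mask <- array(TRUE, c(8, 8))
  expect_equal(ediff(sb, sb, mask)$mean, 0)
  e <- ediff(1.1 * sb, sb, mask)
  expect_equal(e$mean, 0.1, tolerance = 1e-12)
  # scale invariance
  e2 <- ediff(1.1 * sb * 37, sb * 37, mask)
  expect_equal(e2$map, e$map, tolerance = 1e-12)
  # zero reference voxels inside the mask are excluded and counted
  sb0 <- sb; sb0[1, 1] <- 0
  e3 <- ediff(1.1 * sb0, sb0, mask)
  expect_identical(e3$n_excluded, 1L)
  expect_equal(e3$map[1, 1], 0)
})

test_that("delta_s algebra", {
  a <- array(runif(32, 1, 2), c(4, 8))
  expect_true(all(delta_s(a, a)$map == 0))
  expect_equal(delta_s(a, 0.9 * a)$map, array(0.1, dim(a)),
               tolerance = 1e-12)
  b <- array(runif(32, 0.5, 1.5), c(4, 8))
  expect_equal(delta_s(a, b)$map, 1 - b / a, tolerance = 1e-12)
  a0 <- a; a0[2, 2] <- 0
  d <- delta_s(a0, b)
  expect_identical(d$n_excluded, 1L)
  expect_true(is.na(d$map[2, 2]))
})

test_that("binned linear fit recovers known lines", {
  x <- runif(500, 0, 50)
  cfit <- binned_linear_fit(x, rep(3.5, 500))
  expect_equal(cfit$b0, 0, tolerance = 1e-12)
  expect_equal(cfit$b1, 3.5, tolerance = 1e-12)

  lfit <- binned_linear_fit(x, 2 * x)
  expect_equal(lfit$b0, 2, tolerance = 0.05)  # bin means vs centers

  set.seed(13)
  y <- 0.5 * x + rnorm(500, sd = 0.1)
  nfit <- binned_linear_fit(x, y)
  # closed-form OLS slope variance on the bin means; per-bin variance has a
  # noise term and a within-bin x-spread term (x uniform over width 5)
  bins <- nfit$bins
  var_bin <- (0.1^2 + 0.5^2 * 5^2 / 12) / bins$n
  wts <- (bins$center - mean(bins$center)) /
    sum((bins$center - mean(bins$center))^2)
  se <- sqrt(sum(wts^2 * var_bin))
  expect_lt(abs(nfit$b0 - 0.5), 3 * se)
  expect_error(binned_linear_fit(rep(1, 10), rnorm(10)), "2 non-empty bins")
})

test_that("pseudo-replica g-factor: identity and disjoint-support coils", {
  ph <- tiny_phantom(nz = 2, n = 24)
  # identity: unaccelerated recon as 'accelerated' gives g = 1
  coils <- build_coil_maps(3, c(24, 24), 2, seed = 5)
  enc <- encode_pair(ph, coils, mb = 2, f = 2, te_list = 9)
  ref_clean <- enc$sb$kspace[, , , 1, , 1, drop = FALSE]
  dim(ref_clean) <- c(24, 24, 3, 2)
  recon_ref <- function(ks) {
    out <- array(0, c(24, 24, 2))
    for (z in 1:2) {
      out[, , z] <- sos_combine(array(apply(ks[, , , z], 3, ift2),
                                      c(24, 24, 3)))
    }
    out
  }
  g_id <- gfactor_pmr(ref_clean, ref_clean, recon_ref, recon_ref,
                      noise_sd = 0.05, n_replicas = 100, seed = 3)
  expect_lt(abs(g_id$median - 1), 0.1)

  # disjoint-support coils at mb = 2: perfectly conditioned, median g < 1.1
  maps <- array(0i, c(24, 24, 2, 2))
  maps[, , 1, 1] <- 1; maps[, , 2, 2] <- 1
  cdis <- manual_coils(maps)
  encd <- encode_pair(ph, cdis, mb = 2, f = 2, te_list = 9)
  kern <- fit_slice_grappa(prepare_acs_method2(encd$sb, encd$plan_sms))
  accel_clean <- encd$sms$kspace[, , , 1, , 1, drop = FALSE]
  dim(accel_clean) <- c(24, 24, 2, 1)
  refd_clean <- encd$sb$kspace[, , , 1, , 1, drop = FALSE]
  dim(refd_clean) <- c(24, 24, 2, 2)
  recon_a <- function(ks) {
    unfold(array(ks, c(24, 24, 2, 1, 1)), kern)$slice_images[, , , 1]
  }
  recon_r <- function(ks) {
    out <- array(0, c(24, 24, 2))
    for (z in 1:2) {
      out[, , z] <- sos_combine(array(apply(ks[, , , z], 3, ift2),
                                      c(24, 24, 2)))
    }
    out
  }
  mask <- array(aperm(ph$labels, c(2, 3, 1)) > 0, c(24, 24, 2))
  g_dis <- gfactor_pmr(accel_clean, refd_clean, recon_a, recon_r,
                       noise_sd = 0.05, n_replicas = 100, seed = 4,
                       mask = mask)
  expect_lt(g_dis$median, 1.1)
})

test_that("identical coil maps make the unfolding ill-conditioned (g > 5)", {
  ph <- tiny_phantom(nz = 2, n = 24)
  cm <- build_coil_maps(2, c(24, 24), 1, seed = 4)
  maps <- array(0i, c(24, 24, 2, 2))
  maps[, , , 1] <- cm$maps[, , , 1]
  maps[, , , 2] <- cm$maps[, , , 1]     # same sensitivities for both slices
  cid <- manual_coils(maps)
  enc <- encode_pair(ph, cid, mb = 2, f = 1, te_list = 9, n_segments = 4)
  # near-zero ridge: the claim reasons from the unregularized unfolding,
  # whose closed-form g diverges for identical sensitivities
  kern <- fit_slice_grappa(prepare_acs_method2(enc$sb, enc$plan_sms),
                           lambda = 1e-8)
  accel_clean <- enc$sms$kspace[, , , 1, , 1, drop = FALSE]
  dim(accel_clean) <- c(24, 24, 2, 1)
  ref_clean <- enc$sb$kspace[, , , 1, , 1, drop = FALSE]
  dim(ref_clean) <- c(24, 24, 2, 2)
  recon_a <- function(ks) {
    unfold(array(ks, c(24, 24, 2, 1, 1)), kern)$slice_images[, , , 1]
  }
  recon_r <- function(ks) {
    out <- array(0, c(24, 24, 2))
    for (z in 1:2) {
      out[, , z] <- sos_combine(array(apply(ks[, , , z], 3, ift2),
                                      c(24, 24, 2)))
    }
    out
  }
  # overlap region: object voxels of both slices
  overlap <- array(aperm(ph$labels, c(2, 3, 1)) > 0, c(24, 24, 2))
  g <- gfactor_pmr(accel_clean, ref_clean, recon_a, recon_r,
                   noise_sd = 0.05, n_replicas = 100, seed = 7,
                   mask = overlap)
  expect_gt(g$median, 5)
})

test_that("g-map converges: doubling replicas changes the median < 5%", {
  ph <- tiny_phantom(nz = 2, n = 16)
  coils <- build_coil_maps(3, c(16, 16), 2, seed = 6)
  enc <- encode_pair(ph, coils, mb = 2, f = 2, te_list = 9)
  kern <- fit_slice_grappa(prepare_acs_method2(enc$sb, enc$plan_sms))
  accel_clean <- enc$sms$kspace[, , , 1, , 1, drop = FALSE]
  dim(accel_clean) <- c(16, 16, 3, 1)
  ref_clean <- enc$sb$kspace[, , , 1, , 1, drop = FALSE]
  dim(ref_clean) <- c(16, 16, 3, 2)
  recon_a <- function(ks) {
    unfold(array(ks, c(16, 16, 3, 1, 1)), kern)$slice_images[, , , 1]
  }
  recon_r <- function(ks) {
    out <- array(0, c(16, 16, 2))
    for (z in 1:2) {
      out[, , z] <- sos_combine(array(apply(ks[, , , z], 3, ift2),
                                      c(16, 16, 3)))
    }
    out
  }
  mask <- array(aperm(ph$labels, c(2, 3, 1)) > 0, c(16, 16, 2))
  g1 <- gfactor_pmr(accel_clean, ref_clean, recon_a, recon_r, 0.05,
                    n_replicas = 200, seed = 5, mask = mask)
  g2 <- gfactor_pmr(accel_clean, ref_clean, recon_a, recon_r, 0.05,
                    n_replicas = 400, seed = 5, mask = mask)
  expect_lt(abs(g2$median - g1$median) / g1$median, 0.05)

  # paired (shared-noise) variant is computable and biased low on average
  sms_from_sb <- function(sb_noisy) {
    out <- array(0i, c(16, 16, 3, 1))
    for (n in 0:1) {
      ph_line <- caipi_line_phase(n, 2, 16)
      out[, , , 1] <- out[, , , 1] + sb_noisy[, , , n + 1] * ph_line
    }
    out
  }
  # the shared-noise pairing couples the two variances and biases the
  # ratio away from the independent-noise estimate
  gp <- gfactor_pmr(accel_clean, ref_clean, recon_a, recon_r, 0.05,
                    n_replicas = 200, seed = 5, paired = TRUE,
                    accel_from_ref = sms_from_sb, mask = mask)
  expect_true(is.finite(gp$median))
  expect_gt(abs(gp$median - g1$median), 0.02)
})

test_that("delta_s pipeline is exactly zero for identical ACS arms", {
  cd <- contrast_dependency_experiment(
    phantom = build_phantom(phantom_spec(grid_shape = c(2, 32, 32))),
    coils = build_coil_maps(4, c(32, 32), 2, seed = 2),
    averages = 1, algorithms = "sg", mb = 2L, f = 2L,
    fa_mismatch = 5,                 # same contrast as the data
    mismatch_seed_offset = 0L,       # and the same noise stream
    seed = 3)
  expect_true(all(abs(cd$results$b0) < 1e-12))
  expect_true(all(abs(cd$results$b1) < 1e-12))
  expect_true(all(cd$results$mean_abs_ds < 1e-12))
})
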
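#' Slice-GRAPPA and split-slice-GRAPPA kernel calibration
#'
#' `fit_slice_grappa()` trains, for every multiband group, target slice and
#' target coil, a small k-space convolution kernel mapping the collapsed
#' multi-coil source data to the (CAIPIRINHA-shifted) individual-slice
#' target data, by ridge-regularized least squares over all fully interior
#' ACS positions:
#' \deqn{\min_K \|T_{s,c} - K_{s,c} \ast S\|^2 + \lambda \|K\|^2 .}
#'
#' `fit_split_slice_grappa()` instead minimizes the leak-block objective
#' \deqn{\min_K \sum_{s'} \|K_{s} \ast S_{s'} - \delta_{s s'} T_s\|^2
#'       + \lambda \|K\|^2 ,}
#' driving signal originating from the other slices of the group to zero.
#' It requires per-slice sources and therefore a method-2 ACS pair.
#'
#' The regularization is trace-scaled: the ridge added to the normal matrix
#' is `lambda * mean(diag(A^H A))`. With `lambda = 0` a singular system is
#' an error advising `lambda > 0`. The solver is deterministic
#' (regularized normal equations).
#'
#' @param acs an `acs_pair` (see [prepare_acs_method1()] /
#'   [prepare_acs_method2()]).
#' @param kernel_size odd integer pair `(ky, kx)`; default `c(5, 5)`.
#' @param lambda relative ridge parameter, >= 0; default `1e-4`.
#' @param echo which ACS echo to calibrate on.
#' @return object of class `slice_kernel`; fields `kernels` (list indexed
#'   by echo slot, each `[n_features, target_coil, slice-in-group, group]`),
#'   `residual` (`[slice, coil, group]` relative fit residuals), kernel
#'   geometry and algorithm tags.
#' @export
fit_slice_grappa <- function(acs, kernel_size = c(5L, 5L), lambda = 1e-4,
                             echo = 1L) {
  fit_kernel_impl(acs, kernel_size, lambda, echo, algorithm = "sg")
}

#' @rdname fit_slice_grappa
#' @export
fit_split_slice_grappa <- function(acs, kernel_size = c(5L, 5L),
                                   lambda = 1e-4, echo = 1L) {
  if (acs$method != 2L) {
    stop(paste("split slice-GRAPPA cannot use unseparated, measured ACS",
               "source data: per-slice sources are required (method 2)"))
  }
  fit_kernel_impl(acs, kernel_size, lambda, echo, algorithm = "ssg")
}

# design matrix of all interior kernel positions; column order must match
# apply_kernel_weights(): dky fastest, then dkx, then source coil
build_source_matrix <- function(S, kh, kw) {
  ny <- dim(S)[1]; nx <- dim(S)[2]; nc <- dim(S)[3]
  hh <- (kh - 1L) %/% 2L; hw <- (kw - 1L) %/% 2L
  ry <- (hh + 1L):(ny - hh); rx <- (hw + 1L):(nx - hw)
  A <- matrix(0i, nrow = length(ry) * length(rx), ncol = kh * kw * nc)
  col <- 0L
  for (cc in seq_len(nc)) {
    for (dx in -hw:hw) {
      for (dy in -hh:hh) {
        col <- col + 1L
        A[, col] <- as.vector(S[ry + dy, rx + dx, cc])
      }
    }
  }
  list(A = A, ry = ry, rx = rx)
}

solve_reg <- function(M, rhs, lambda_eff, lambda) {
  Mreg <- M + diag(lambda_eff, nrow(M))
  out <- tryCatch(solve(Mreg, rhs), error = function(e) NULL)
  if (is.null(out)) {
    if (lambda == 0) stop("singular normal equations; use lambda > 0")
    stop("kernel normal equations could not be solved")
  }
  out
}

fit_kernel_impl <- function(acs, kernel_size, lambda, echo, algorithm) {
  stopifnot(inherits(acs, "acs_pair"), length(kernel_size) == 2,
            all(kernel_size %% 2 == 1), lambda >= 0)
  kh <- as.integer(kernel_size[1]); kw <- as.integer(kernel_size[2])
  ds <- dim(acs$source)
  if (ds[1] < kh || ds[2] < kw) stop("ACS grid smaller than the kernel")
  nc <- ds[3]; ng <- acs$n_groups; mb <- acs$mb
  nfeat <- kh * kw * nc

  weights <- array(0i, dim = c(nfeat, nc, mb, ng))
  residual <- array(NA_real_, dim = c(mb, nc, ng))

  for (g in seq_len(ng)) {
    if (algorithm == "sg") {
      src <- acs$source[, , , echo, g]
      dim(src) <- ds[1:3]
      bm <- build_source_matrix(src, kh, kw)
      A <- bm$A
      AH <- Conj(t(A))
      M <- AH %*% A
      lam <- lambda * Re(mean(diag(M)))
      for (n in seq_len(mb)) {
        Tn <- acs$target[, , , n, echo, g]
        dim(Tn) <- ds[1:3]
        for (ct in seq_len(nc)) {
          b <- as.vector(Tn[bm$ry, bm$rx, ct])
          w <- solve_reg(M, AH %*% b, lam, lambda)
          weights[, ct, n, g] <- w
          residual[n, ct, g] <- sum(Mod(A %*% w - b)^2) / sum(Mod(b)^2)
        }
      }
    } else {
      # leak-block: stack per-slice sources (the phased targets themselves)
      As <- vector("list", mb)
      for (sp in seq_len(mb)) {
        Ssp <- acs$target[, , , sp, echo, g]
        dim(Ssp) <- ds[1:3]
        As[[sp]] <- build_source_matrix(Ssp, kh, kw)
      }
      M <- matrix(0i, nfeat, nfeat)
      for (sp in seq_len(mb)) {
        M <- M + Conj(t(As[[sp]]$A)) %*% As[[sp]]$A
      }
      lam <- lambda * Re(mean(diag(M)))
      for (n in seq_len(mb)) {
        Tn <- acs$target[, , , n, echo, g]
        dim(Tn) <- ds[1:3]
        for (ct in seq_len(nc)) {
          b <- as.vector(Tn[As[[n]]$ry, As[[n]]$rx, ct])
          rhs <- Conj(t(As[[n]]$A)) %*% b
          w <- solve_reg(M, rhs, lam, lambda)
          weights[, ct, n, g] <- w
          res <- sum(Mod(As[[n]]$A %*% w - b)^2)
          for (sp in seq_len(mb)[-n]) {
            res <- res + sum(Mod(As[[sp]]$A %*% w)^2)
          }
          residual[n, ct, g] <- res / sum(Mod(b)^2)
        }
      }
    }
  }

  structure(list(kernels = stats::setNames(list(weights), as.character(echo)),
                 kernel_size = c(kh, kw), lambda = lambda,
                 algorithm = algorithm, acs_policy = "acs111",
                 mb = mb, f = acs$f, n_groups = ng, n_coils = nc,
                 residual = residual, method = acs$method),
            class = "slice_kernel")
}

#' Train a reconstruction kernel with an ACS echo policy
#'
#' `acs111` calibrates a single kernel from the first ACS echo and applies
#' it to every echo of the data (the policy used for the dynamic
#' reconstruction); `acs123` calibrates one kernel per echo.
#'
#' @inheritParams fit_slice_grappa
#' @param algorithm `"sg"` (slice-GRAPPA) or `"ssg"` (split slice-GRAPPA).
#' @param policy `"acs111"` or `"acs123"`.
#' @return a `slice_kernel`.
#' @export
train_kernel <- function(acs, algorithm = c("sg", "ssg"),
                         policy = c("acs111", "acs123"),
                         kernel_size = c(5L, 5L), lambda = 1e-4) {
  algorithm <- match.arg(algorithm)
  policy <- match.arg(policy)
  fitter <- if (algorithm == "sg") fit_slice_grappa else fit_split_slice_grappa
  ne <- dim(acs$source)[4]
  echoes <- if (policy == "acs111") 1L else seq_len(ne)
  fits <- lapply(echoes, function(e) fitter(acs, kernel_size, lambda, echo = e))
  k <- fits[[1]]
  k$kernels <- stats::setNames(lapply(fits, function(f) f$kernels[[1]]),
                               as.character(echoes))
  k$acs_policy <- policy
  k
}

#' @export
print.slice_kernel <- function(x, ...) {
  cat(sprintf(
    "<slice_kernel> %s / %s: %d x %d kernel, %d coils, mb = %d, %d group(s), lambda = %g\n",
    toupper(x$algorithm), toupper(x$acs_policy),
    x$kernel_size[1], x$kernel_size[2], x$n_coils, x$mb, x$n_groups, x$lambda))
  cat(sprintf("  mean relative ACS residual: %.3g\n", mean(x$residual)))
  invisible(x)
}

# convolve one collapsed [ky, kx, coil] k-space plane with the weight
# vector of a single (slice, target-coil); zero padding at the boundary
apply_kernel_weights <- function(S, w, kh, kw) {
  ny <- dim(S)[1]; nx <- dim(S)[2]; nc <- dim(S)[3]
  hh <- (kh - 1L) %/% 2L; hw <- (kw - 1L) %/% 2L
  pad <- array(0i, dim = c(ny + 2 * hh, nx + 2 * hw, nc))
  pad[(hh + 1):(hh + ny), (hw + 1):(hw + nx), ] <- S
  out <- matrix(0i, ny, nx)
  col <- 0L
  for (cc in seq_len(nc)) {
    for (dx in -hw:hw) {
      for (dy in -hh:hh) {
        col <- col + 1L
        if (w[col] != 0i) {
          out <- out + w[col] *
            pad[(hh + 1 + dy):(hh + ny + dy), (hw + 1 + dx):(hw + nx + dx), cc]
        }
      }
    }
  }
  out
}

kernel_for_echo <- function(kernel, e) {
  if (kernel$acs_policy == "acs111" || length(kernel$kernels) == 1) {
    kernel$kernels[[1]]
  } else {
    kernel$kernels[[min(e, length(kernel$kernels))]]
  }
}

#' Unfold collapsed SMS k-space into slice images
#'
#' Applies the calibrated kernel to every group, echo and target coil of
#' one frame, producing per-slice multi-coil k-space; the CAIPIRINHA shift
#' is then removed by exact k-space demodulation (conjugate of the collapse
#' phase, equivalent to the image-domain circular back-shift by
#' `-n N_PE / f` plus removal of the constant per-slice phase), and coil
#' images are combined by sum of squares.
#'
#' @param frame an SMS `kspace_set`, or a plain `[ky, kx, coil, echo]`
#'   complex array holding one group of one frame (then `group_plan` /
#'   geometry are taken from the kernel).
#' @param kernel a `slice_kernel`.
#' @param frame_index which frame of a `kspace_set` to unfold.
#' @param keep_coil_images return the complex per-coil images as well.
#' @return object of class `recon_result`: `slice_images` magnitude array
#'   `[ny, nx, slice, echo]` (slices ordered `1..n_slices` of the volume),
#'   optional `coil_images` `[ny, nx, coil, slice, echo]`, `residual` from
#'   the kernel fit.
#' @export
unfold <- function(frame, kernel, frame_index = 1L, keep_coil_images = FALSE) {
  stopifnot(inherits(kernel, "slice_kernel"))
  if (inherits(frame, "kspace_set")) {
    ks <- frame$kspace[, , , , , frame_index, drop = FALSE]
    dim(ks) <- dim(frame$kspace)[1:5]
  } else {
    ks <- frame
    if (length(dim(ks)) == 3) dim(ks) <- c(dim(ks), 1L)
    dim(ks) <- c(dim(ks), 1L)[1:5]
  }
  d <- dim(ks)
  ny <- d[1]; nx <- d[2]; nc <- d[3]; ne <- d[4]; ng <- d[5]
  if (nc != kernel$n_coils) stop("coil count does not match the kernel")
  if (ng != kernel$n_groups) stop("group count does not match the kernel")
  mb <- kernel$mb
  n_slices <- mb * ng
  kh <- kernel$kernel_size[1]; kw <- kernel$kernel_size[2]

  slice_map <- outer(seq_len(ng), 0:(mb - 1), function(g, n) g + n * ng)
  slice_images <- array(0, dim = c(ny, nx, n_slices, ne))
  coil_images <- if (keep_coil_images) {
    array(0i, dim = c(ny, nx, nc, n_slices, ne))
  } else NULL

  for (g in seq_len(ng)) {
    for (e in seq_len(ne)) {
      w_e <- kernel_for_echo(kernel, e)
      S <- ks[, , , e, g]
      dim(S) <- c(ny, nx, nc)
      for (n in seq_len(mb)) {
        z <- slice_map[g, n]
        demod <- Conj(caipi_line_phase(n - 1L, kernel$f, ny))
        ci <- array(0i, dim = c(ny, nx, nc))
        for (ct in seq_len(nc)) {
          Kslice <- apply_kernel_weights(S, w_e[, ct, n, g], kh, kw)
          ci[, , ct] <- ift2(Kslice * demod)
        }
        slice_images[, , z, e] <- sos_combine(ci)
        if (keep_coil_images) coil_images[, , , z, e] <- ci
      }
    }
  }

  structure(list(slice_images = slice_images, coil_images = coil_images,
                 residual = kernel$residual, mb = mb, n_groups = ng),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  d <- dim(x$slice_images)
  cat(sprintf("<recon_result> %d x %d, %d slice(s), %d echo(es)",
              d[1], d[2], d[3], d[4]))
  if (length(d) > 4) cat(sprintf(", %d frame(s)", d[5]))
  cat("\n")
  invisible(x)
}

#' Reconstruct a dynamic series with a fixed kernel
#'
#' Frame-wise navigator phase correction (optional), unfolding and
#' sum-of-squares combination, with the kernel held fixed across frames
#' (the kernel is calibrated once, before contrast arrival, and reused for
#' the whole dynamic run). Per-frame failures are reported with the frame
#' index.
#'
#' @param dynamic an SMS `kspace_set` with one or more frames.
#' @param kernel a `slice_kernel`.
#' @param nav_correct apply [navigator_phase_correct()] per group before
#'   unfolding (skipped with a warning if the set has no navigators).
#' @param correction_order `"nav_first"` (default, vendor order) or
#'   `"unfold_first"` (slice separation before phase correction).
#' @return `recon_result` whose `slice_images` has a fifth frame dimension.
#' @export
reconstruct_series <- function(dynamic, kernel, nav_correct = TRUE,
                               correction_order = c("nav_first",
                                                    "unfold_first")) {
  correction_order <- match.arg(correction_order)
  stopifnot(inherits(dynamic, "kspace_set"))
  d <- dim(dynamic$kspace)
  nf <- d[6]
  out <- NULL
  for (fr in seq_len(nf)) {
    res <- tryCatch({
      ks <- dynamic$kspace[, , , , , fr, drop = FALSE]
      dim(ks) <- d[1:5]
      if (nav_correct && correction_order == "nav_first") {
        ks <- correct_frame(ks, dynamic, fr)
      }
      r <- unfold(ks, kernel)
      if (nav_correct && correction_order == "unfold_first") {
        # correction on unfolded per-slice data is not supported for
        # magnitude output; re-run with correction first instead
        ks2 <- correct_frame(dynamic$kspace[, , , , , fr, drop = FALSE],
                             dynamic, fr)
        dim(ks2) <- d[1:5]
        r <- unfold(ks2, kernel)
      }
      r
    }, error = function(e) {
      stop(sprintf("frame %d: %s", fr, conditionMessage(e)), call. = FALSE)
    })
    if (is.null(out)) {
      out <- array(0, dim = c(dim(res$slice_images), nf))
    }
    out[, , , , fr] <- res$slice_images
  }
  structure(list(slice_images = out, coil_images = NULL,
                 residual = kernel$residual, mb = kernel$mb,
                 n_groups = kernel$n_groups),
            class = "recon_result")
}

correct_frame <- function(ks, set, fr) {
  if (is.null(set$navigators)) {
    warning("no navigators in the k-space set; phase correction skipped")
    return(ks)
  }
  d <- dim(set$kspace)[1:5]
  dim(ks) <- d
  ns <- set$plan$n_segments
  for (g in seq_len(d[5])) {
    navs <- set$navigators[, , , g, fr]
    dim(navs) <- dim(set$navigators)[1:3]
    for (e in seq_len(d[4])) {
      plane <- ks[, , , e, g]
      dim(plane) <- d[1:3]
      ks[, , , e, g] <- navigator_phase_correct(plane, navs, ns)
    }
  }
  ks
}
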
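#' Huang fuzzy-entropy threshold and mask
#'
#' Computes the Huang & Wang fuzzy-threshold of an image: over a 256-bin
#' histogram of `[min, max]`, each candidate threshold `t` splits the gray
#' levels into two classes with mean levels `mu0`, `mu1`; the membership of
#' level `g` to its class is `1 / (1 + |g - mu_class| / C)` with `C` the
#' gray-level range, and the threshold minimizing the total Shannon fuzzy
#' entropy `sum_g h(g) S(mu(g))` is selected (ties broken toward the lowest
#' threshold). `huang_mask()` returns the voxels strictly above the
#' threshold (the upper edge of the selected bin).
#'
#' @param volume numeric array or vector (magnitude image volume).
#' @param n_bins histogram bins (256).
#' @return `huang_threshold()`: the threshold value (`NA` with a warning for
#'   a constant volume); `huang_mask()`: a logical array shaped like
#'   `volume` (all `FALSE` for a constant volume).
#' @export
huang_threshold <- function(volume, n_bins = 256L) {
  v <- as.vector(volume)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant volume: no threshold, empty mask")
    return(NA_real_)
  }
  width <- diff(rng) / n_bins
  bin <- pmin(floor((v - rng[1]) / width), n_bins - 1L)  # 0-based bins
  h <- tabulate(bin + 1L, nbins = n_bins)
  g <- 0:(n_bins - 1L)
  C <- n_bins - 1L

  cs_h <- cumsum(h)
  cs_hg <- cumsum(h * g)
  tot_h <- cs_h[n_bins]
  tot_hg <- cs_hg[n_bins]

  ent <- rep(Inf, n_bins - 1L)
  shannon <- function(u) {
    s <- numeric(length(u))
    i <- u > 0 & u < 1
    s[i] <- -u[i] * log(u[i]) - (1 - u[i]) * log(1 - u[i])
    s
  }
  for (t in 0:(n_bins - 2L)) {
    n0 <- cs_h[t + 1L]; n1 <- tot_h - n0
    if (n0 == 0 || n1 == 0) {
      # one empty class: all memberships in the other class
      mu <- if (n0 == 0) tot_hg / tot_h else cs_hg[t + 1L] / n0
      u <- 1 / (1 + abs(g - mu) / C)
      ent[t + 1L] <- sum(h * shannon(u)) / tot_h
      next
    }
    mu0 <- cs_hg[t + 1L] / n0
    mu1 <- (tot_hg - cs_hg[t + 1L]) / n1
    u <- ifelse(g <= t, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    ent[t + 1L] <- sum(h * shannon(u)) / tot_h
  }
  t_star <- which.min(ent) - 1L  # ties: which.min takes the first = lowest t
  rng[1] + (t_star + 1L) * width
}

#' @rdname huang_threshold
#' @export
huang_mask <- function(volume, n_bins = 256L) {
  thr <- huang_threshold(volume, n_bins)
  if (is.na(thr)) {
    return(array(FALSE, dim = if (is.null(dim(volume))) length(volume)
                 else dim(volume)))
  }
  volume > thr
}

#' Normalized subtraction error
#'
#' Voxel-wise `|(I_SMS - I_SB) / I_SB|` inside a binary mask, 0 outside;
#' the mean over the mask quantifies the exactness of the SMS
#' reconstruction. Masked voxels where the reference is 0 are excluded and
#' counted. The metric is invariant under joint rescaling of both images.
#'
#' @param i_sms,i_sb magnitude arrays of identical shape.
#' @param mask logical array of the same shape (e.g. from [huang_mask()]).
#' @return list with `map`, `mean`, `n_excluded`.
#' @export
ediff <- function(i_sms, i_sb, mask) {
  stopifnot(all(dim(i_sms) == dim(i_sb)), all(dim(mask) == dim(i_sb)))
  map <- array(0, dim = dim(i_sb))
  valid <- mask & (i_sb != 0)
  n_excluded <- sum(mask & (i_sb == 0))
  map[valid] <- abs((i_sms[valid] - i_sb[valid]) / i_sb[valid])
  list(map = map, mean = mean(map[valid]), n_excluded = n_excluded)
}

#' Normalized signal difference between two reconstructions
#'
#' `(s_a - s_b) / s_a` voxel-wise, where A is the reference arm (matched
#' ACS contrast) and B the comparison arm. Voxels with `s_a = 0` are set to
#' `NA` and counted.
#'
#' @param s_a,s_b signal arrays of identical shape.
#' @return list with `map` and `n_excluded`.
#' @export
delta_s <- function(s_a, s_b) {
  stopifnot(all(dim(s_a) == dim(s_b)))
  map <- array(NA_real_, dim = if (is.null(dim(s_a))) length(s_a)
               else dim(s_a))
  ok <- s_a != 0
  map[ok] <- (s_a[ok] - s_b[ok]) / s_a[ok]
  list(map = map, n_excluded = sum(!ok))
}

#' Binned linear model of a voxel-wise quantity
#'
#' Bins `x` into fixed-width bins anchored at 0 (`[0, w), [w, 2w), ...`),
#' computes the mean and standard deviation of `y` per non-empty bin, and
#' fits an ordinary least-squares line to the bin means versus the bin
#' centers. Following the field's reporting convention, `b0` is the slope
#' and `b1` the offset.
#'
#' @param x binning variable (e.g. S0 in signal units, or T2* in ms).
#' @param y response (e.g. the normalized signal difference).
#' @param bin_width bin width in the units of `x` (5 by default).
#' @return list with `b0` (slope), `b1` (offset) and `bins`
#'   (data.frame: center, n, mean, sd).
#' @export
binned_linear_fit <- function(x, y, bin_width = 5) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  idx <- floor(x / bin_width)
  centers <- (sort(unique(idx)) + 0.5) * bin_width
  tab <- data.frame(
    center = centers,
    n = as.vector(table(factor(idx, levels = sort(unique(idx))))),
    mean = tapply(y, factor(idx, levels = sort(unique(idx))), mean),
    sd = tapply(y, factor(idx, levels = sort(unique(idx))), stats::sd)
  )
  rownames(tab) <- NULL
  if (nrow(tab) < 2) stop("need at least 2 non-empty bins for a linear fit")
  fit <- stats::lm(mean ~ center, data = tab)
  list(b0 = unname(stats::coef(fit)[2]), b1 = unname(stats::coef(fit)[1]),
       bins = tab)
}
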
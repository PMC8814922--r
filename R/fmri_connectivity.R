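# Effective-connectivity target identification: nuisance regression,
# high-pass filtering, ICA-component selection, seed extraction, first-order
# Granger causality mapping, and peak-cluster target extraction.

#' Binarize and erode a tissue-probability map
#'
#' Thresholds a probability map (values in \[0, 1\]) at `threshold` and
#' erodes the result with a discrete spherical structuring element. This is
#' the standard construction of conservative white-matter and CSF nuisance
#' masks (probability >= 0.98, erosion radius 2 voxels).
#'
#' @param prob_map `spatial_map` or 3D array with values in \[0, 1\].
#' @param threshold probability threshold (default 0.98).
#' @param radius_voxels erosion radius in voxels (default 2); 0 skips erosion.
#' @param label optional label for the returned mask.
#' @return A `voxel_mask`. If the eroded mask is empty a warning is issued
#'   and the empty mask is returned for the caller to handle.
#' @export
binarize_and_erode_mask <- function(prob_map, threshold = 0.98,
                                    radius_voxels = 2, label = NULL) {
  v <- .map_values(prob_map)
  if (min(v) < 0 || max(v) > 1)
    stop("probability map values must lie in [0, 1]")
  vs <- if (inherits(prob_map, "spatial_map")) prob_map$voxel_size else c(1, 1, 1)
  bin <- v >= threshold
  out <- erode_mask(bin, radius_voxels)
  if (!any(out))
    warning("mask is empty after thresholding and erosion")
  voxel_mask(out, label = label, voxel_size = vs)
}

#' Erode a binary mask with a discrete spherical kernel
#'
#' A voxel survives iff every voxel within Euclidean distance
#' `radius_voxels` (in voxel units) is inside the mask; voxels outside the
#' grid count as background, so the border is always eroded.
#'
#' @param mask 3D logical array or `voxel_mask`.
#' @param radius_voxels integer radius in voxels.
#' @return 3D logical array.
#' @export
erode_mask <- function(mask, radius_voxels = 2) {
  m <- .mask_values(mask)
  if (radius_voxels <= 0) return(m)
  r <- radius_voxels
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= r^2, , drop = FALSE]
  d <- dim(m)
  out <- m
  for (i in seq_len(nrow(offs))) {
    sh <- .shift3d(m, offs$dx[i], offs$dy[i], offs$dz[i], fill = FALSE)
    out <- out & sh
  }
  out
}

# Shift a 3D array by integer offsets, padding with `fill`. The value at
# out[x] is m[x + (dx,dy,dz)], i.e. erosion probes the neighbourhood.
.shift3d <- function(m, dx, dy, dz, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, dim = d)
  src <- function(n, o) {
    i <- seq_len(n) + o
    ok <- i >= 1 & i <= n
    list(dst = seq_len(n)[ok], src = i[ok])
  }
  sx <- src(d[1], dx); sy <- src(d[2], dy); sz <- src(d[3], dz)
  if (length(sx$dst) && length(sy$dst) && length(sz$dst))
    out[sx$dst, sy$dst, sz$dst] <- m[sx$src, sy$src, sz$src]
  out
}

#' Regress WM and CSF nuisance series out of a BOLD series
#'
#' Replaces every voxel time series with the residual of an ordinary
#' least-squares regression on an intercept plus the mean white-matter and
#' mean CSF series. If the two nuisance series are collinear one is dropped
#' with a message.
#'
#' @param bold a `bold_series`.
#' @param wm,csf `voxel_mask` objects (nonempty, same grid as `bold`).
#' @return A `bold_series` of residuals.
#' @export
regress_nuisance <- function(bold, wm, csf) {
  stopifnot(inherits(bold, "bold_series"))
  wm_ts <- seed_series(bold, wm)
  csf_ts <- seed_series(bold, csf)
  X <- cbind(intercept = 1, wm = wm_ts, csf = csf_ts)
  # drop a collinear regressor (keeps the design full rank)
  if (qr(X)$rank < ncol(X)) {
    message("WM and CSF series are collinear; dropping the CSF regressor")
    X <- X[, 1:2, drop = FALSE]
    if (qr(X)$rank < ncol(X)) X <- X[, 1, drop = FALSE]
  }
  d <- dim(bold$data)
  Y <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  # residual maker applied to all voxels at once: R = Y - Y X (X'X)^-1 X'
  beta <- solve(crossprod(X), crossprod(X, t(Y)))
  res <- t(t(Y) - X %*% beta)
  bold_series(array(res, dim = d), voxel_size = bold$voxel_size, tr = bold$tr)
}

#' High-pass filter a BOLD series
#'
#' Hard frequency-domain filter: the DC component and all frequencies
#' strictly below `cutoff_hz` are zeroed; everything at or above the cutoff
#' is preserved exactly. Output length equals input length.
#'
#' @param bold a `bold_series`.
#' @param cutoff_hz cutoff frequency in Hz (default 0.01); must be positive
#'   and below the Nyquist frequency `1 / (2 * tr)`.
#' @return A filtered `bold_series`.
#' @export
highpass <- function(bold, cutoff_hz = 0.01) {
  stopifnot(inherits(bold, "bold_series"))
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0)
    stop("`cutoff_hz` must be a positive scalar")
  nyq <- 1 / (2 * bold$tr)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.4g Hz is not below the Nyquist frequency %.4g Hz",
                 cutoff_hz, nyq))
  d <- dim(bold$data)
  n <- d[4]
  freqs <- (seq_len(n) - 1) / (n * bold$tr)
  freqs <- pmin(freqs, 1 / bold$tr - freqs)     # two-sided frequency axis
  keep <- freqs >= cutoff_hz
  keep[1] <- FALSE                               # remove DC
  Y <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = n))
  F <- mvfft(Y)
  F[!keep, ] <- 0
  out <- Re(mvfft(F, inverse = TRUE)) / n
  bold_series(array(t(out), dim = d), voxel_size = bold$voxel_size, tr = bold$tr)
}

#' Select the component best matching a network template
#'
#' Each candidate z-scored component is filtered by zeroing values below
#' `z_threshold`; the component whose filtered map has the highest Pearson
#' correlation with the template is returned. Degenerate (zero-variance)
#' filtered components rank below every valid one.
#'
#' @param components list of `spatial_map`s (or 3D arrays) on the template
#'   grid.
#' @param template `spatial_map` or 3D array (e.g. an lCEN z-score map).
#' @param z_threshold filtering threshold (default 1.96).
#' @return A list with `index` (1-based), `map` (the filtered winning
#'   component as a `spatial_map`), and `correlations` (per candidate, with
#'   `-Inf` for degenerate ones).
#' @export
select_component <- function(components, template, z_threshold = 1.96) {
  if (length(components) < 1L) stop("at least one component is required")
  tv <- as.numeric(.map_values(template))
  cors <- vapply(components, function(cmp) {
    v <- .map_values(cmp)
    if (!identical(dim(v), dim(.map_values(template))))
      stop("component grid does not match the template grid")
    v[v < z_threshold] <- 0
    if (sd(v) == 0 || sd(tv) == 0) return(-Inf)
    cor(as.numeric(v), tv)
  }, numeric(1))
  if (all(!is.finite(cors)))
    stop("all filtered components are degenerate (zero variance)")
  idx <- which.max(cors)
  win <- .map_values(components[[idx]])
  win[win < z_threshold] <- 0
  vs <- if (inherits(components[[idx]], "spatial_map"))
    components[[idx]]$voxel_size else c(3, 3, 3)
  list(index = idx, map = spatial_map(win, voxel_size = vs),
       correlations = cors)
}

#' Mean time series over a region of interest
#'
#' @param bold a `bold_series`.
#' @param roi nonempty `voxel_mask` on the same grid.
#' @return Numeric vector of per-frame means.
#' @export
seed_series <- function(bold, roi) {
  stopifnot(inherits(bold, "bold_series"))
  m <- .mask_values(roi)
  if (!identical(dim(m), dim(bold$data)[1:3]))
    stop("ROI grid does not match the BOLD grid")
  if (!any(m)) stop("ROI mask is empty")
  d <- dim(bold$data)
  Y <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(Y[as.vector(m), , drop = FALSE])
}

#' First-order bivariate Granger path coefficient
#'
#' Standardizes `x` and `y` to zero mean and unit variance, then fits the
#' restricted first-order model
#' \deqn{y_t = c + a\,y_{t-1} + b\,x_{t-1} + e_t}
#' by ordinary least squares over frames 2..T and returns the signed
#' coefficient `b`, the directed (effective-connectivity) influence of `x`
#' on `y`.
#'
#' @param x,y numeric time series of equal length (>= 10 frames).
#' @return Signed scalar coefficient `b`.
#' @export
granger_first_order <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 10L) stop("at least 10 frames are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input series")
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  X <- cbind(1, ys[-n], xs[-n])
  if (qr(X)$rank < 3L)
    stop("rank-deficient Granger design (x and y lags are collinear)")
  beta <- solve(crossprod(X), crossprod(X, ys[-1]))
  as.numeric(beta[3])
}

#' Voxelwise Granger-causality z-map
#'
#' Computes the first-order Granger path coefficient from the seed series to
#' every voxel inside `search_mask`, then z-standardizes the coefficients
#' across in-mask voxels: `z_v = (b_v - mean(b)) / sd(b)`. Out-of-mask
#' voxels are 0.
#'
#' @param bold a `bold_series`.
#' @param seed numeric seed time series (frame count of `bold`).
#' @param search_mask nonempty `voxel_mask`.
#' @return A `spatial_map` of z values (in-mask mean 0, sd 1).
#' @export
gca_zmap <- function(bold, seed, search_mask) {
  stopifnot(inherits(bold, "bold_series"))
  m <- .mask_values(search_mask)
  if (!any(m)) stop("search mask is empty")
  d <- dim(bold$data)
  if (length(seed) != d[4]) stop("seed length does not match frame count")
  Y <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  idx <- which(as.vector(m))
  b <- vapply(idx, function(v) granger_first_order(seed, Y[v, ]), numeric(1))
  sb <- sd(b)
  if (sb == 0) stop("zero variance of Granger coefficients across the mask")
  z <- (b - mean(b)) / sb
  out <- array(0, dim = d[1:3])
  out[idx] <- z
  spatial_map(out, voxel_size = bold$voxel_size)
}

#' Peak of the most significant suprathreshold cluster
#'
#' Forms 26-connected clusters of voxels with `z > z_threshold` inside the
#' mask and returns the voxel of the global maximum z, which by construction
#' lies in the most significant cluster. Ties are broken by lexicographic
#' voxel order (x, then y, then z).
#'
#' @param zmap `spatial_map` (or 3D array) of z values.
#' @param mask `voxel_mask` restricting the search.
#' @param z_threshold cluster-forming threshold (default 1.96).
#' @return A `brain_target` list: `voxel_index` (1-based triple), `world_mm`,
#'   `kind = "cgiTBS"`, `peak_z`, and `cluster_size`.
#' @export
peak_cluster_target <- function(zmap, mask, z_threshold = 1.96) {
  z <- .map_values(zmap)
  m <- .mask_values(mask)
  supra <- (z > z_threshold) & m
  if (!any(supra))
    stop("no significant target: no in-mask voxel exceeds the z threshold")
  vs <- if (inherits(zmap, "spatial_map")) zmap$voxel_size else c(3, 3, 3)
  d <- dim(z)
  idx <- which(supra)
  # lexicographic (x, y, z) tie-break: order candidates, take first max
  ai <- arrayInd(idx, d)
  ord <- order(ai[, 1], ai[, 2], ai[, 3])
  idx <- idx[ord]; ai <- ai[ord, , drop = FALSE]
  best <- idx[which.max(z[idx])]
  peak <- as.integer(arrayInd(best, d))
  structure(list(voxel_index = peak,
                 world_mm = voxel_to_mm(peak, vs),
                 kind = "cgiTBS",
                 peak_z = z[best],
                 cluster_size = .cluster_size_at(supra, peak)),
            class = "brain_target")
}

# size of the 26-connected suprathreshold cluster containing `start`
.cluster_size_at <- function(supra, start) {
  d <- dim(supra)
  seen <- array(FALSE, dim = d)
  queue <- matrix(start, nrow = 1)
  seen[start[1], start[2], start[3]] <- TRUE
  count <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    count <- count + 1L
    nb <- sweep(offs, 2, p, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    for (j in seq_len(nrow(nb))) {
      q <- nb[j, ]
      if (supra[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
        seen[q[1], q[2], q[3]] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  count
}

#' Project a world-space point onto the nearest in-mask voxel
#'
#' Returns the mask voxel minimizing Euclidean distance in mm to the point,
#' e.g. projecting the F3 scalp coordinate onto the brain parenchyma. Ties
#' are broken lexicographically.
#'
#' @param point_mm numeric length-3 point in mm.
#' @param mask nonempty `voxel_mask`.
#' @param voxel_size mm spacing; defaults to the mask's.
#' @return A `brain_target` with `kind = "rTMS"` and `distance_mm`.
#' @export
project_point_to_mask <- function(point_mm, mask,
                                  voxel_size = NULL) {
  m <- .mask_values(mask)
  if (!any(m)) stop("mask is empty")
  if (is.null(voxel_size))
    voxel_size <- if (inherits(mask, "voxel_mask")) mask$voxel_size else c(1, 1, 1)
  idx <- which(m)
  ai <- arrayInd(idx, dim(m))
  ord <- order(ai[, 1], ai[, 2], ai[, 3])
  ai <- ai[ord, , drop = FALSE]
  mm <- sweep(sweep(ai - 1, 2, voxel_size, "*"), 2, as.numeric(point_mm), "-")
  d2 <- rowSums(mm^2)
  k <- which.min(d2)
  peak <- as.integer(ai[k, ])
  structure(list(voxel_index = peak,
                 world_mm = voxel_to_mm(peak, voxel_size),
                 kind = "rTMS",
                 distance_mm = sqrt(d2[k])),
            class = "brain_target")
}

#' @export
print.brain_target <- function(x, ...) {
  cat(sprintf("<brain_target %s> voxel (%s), world (%s) mm%s\n",
              x$kind, paste(x$voxel_index, collapse = ", "),
              paste(format(x$world_mm, digits = 4), collapse = ", "),
              if (!is.null(x$peak_z)) sprintf(", peak z = %.3f", x$peak_z) else ""))
  invisible(x)
}
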
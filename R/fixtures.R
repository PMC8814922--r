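# Synthetic fixtures with known ground truth: a VAR-coupled BOLD phantom,
# sphere/ellipsoid head meshes with analytic normals and fiducials, motion
# traces, and MEGA-PRESS edited spectrum sets. Every generator is
# deterministic under a fixed seed.

#' Synthetic BOLD series with a planted causal voxel
#'
#' Builds a 4D noise volume in which a seed region (a 6 mm sphere standing
#' in for the right anterior insula) carries a white-noise driver `x_t`,
#' and one voxel inside the search region (standing in for the left middle
#' frontal gyrus) follows the first-order coupling
#' `y_t = b * x_{t-1} + noise`. All other voxels are independent noise.
#' Also returns matching template/component maps so the full
#' component-selection and Granger pipeline can run end to end.
#'
#' @param seed integer random seed.
#' @param dims grid dimensions (default `c(24, 24, 18)`).
#' @param n_frames number of frames (default 240).
#' @param tr repetition time in seconds (default 2).
#' @param voxel_size mm spacing (default 3 mm isotropic).
#' @param coupling causal coefficient `b` (default 0.5).
#' @param noise_sd noise standard deviation (default 1).
#' @param seed_noise_sd within-seed-region voxel noise (default 0.1).
#' @return List: `bold` (`bold_series`), masks `rai`, `lmfg`, `brain`,
#'   `wm`, `csf` (`voxel_mask`), `components` (list of 3 `spatial_map`s),
#'   `template` (`spatial_map`), `truth_voxel` (1-based index triple of the
#'   planted voxel), and `driver` (the seed series used).
#' @export
make_var_bold <- function(seed = 1, dims = c(24, 24, 18), n_frames = 240,
                          tr = 2, voxel_size = c(3, 3, 3), coupling = 0.5,
                          noise_sd = 1, seed_noise_sd = 0.1) {
  set.seed(seed)
  stopifnot(length(dims) == 3L, n_frames >= 10)
  nvox <- prod(dims)
  Y <- matrix(rnorm(nvox * n_frames, sd = noise_sd), nvox, n_frames)

  rai_center <- c(18, 8, 6)
  rai <- sphere_mask(dims, rai_center, radius_mm = 6, voxel_size = voxel_size,
                     label = "rAI_sphere")
  lmfg_arr <- array(FALSE, dims)
  lmfg_arr[5:9, 14:18, 10:13] <- TRUE
  lmfg <- voxel_mask(lmfg_arr, label = "lMFG", voxel_size = voxel_size)

  x <- rnorm(n_frames)
  rai_idx <- which(as.vector(rai$values))
  for (v in rai_idx)
    Y[v, ] <- x + rnorm(n_frames, sd = seed_noise_sd)

  truth <- c(7, 16, 11)                        # inside the lMFG box
  tv <- truth[1] + (truth[2] - 1) * dims[1] + (truth[3] - 1) * dims[1] * dims[2]
  y <- c(rnorm(1, sd = noise_sd),
         coupling * x[-n_frames] + rnorm(n_frames - 1, sd = noise_sd))
  Y[tv, ] <- y

  bold <- bold_series(array(Y, dim = c(dims, n_frames)),
                      voxel_size = voxel_size, tr = tr)

  brain <- voxel_mask(array(TRUE, dims), label = "brain",
                      voxel_size = voxel_size)
  wm_arr <- array(FALSE, dims); wm_arr[1:3, 1:3, 1:3] <- TRUE
  csf_arr <- array(FALSE, dims); csf_arr[1:3, 1:3, (dims[3] - 2):dims[3]] <- TRUE
  wm <- voxel_mask(wm_arr, label = "WM", voxel_size = voxel_size)
  csf <- voxel_mask(csf_arr, label = "CSF", voxel_size = voxel_size)

  # z-scored component maps: a blob over the search region (the lCEN-like
  # winner), a blob elsewhere, and pure noise
  blob <- function(center, peak = 6, width = 4) {
    ix <- seq_len(dims[1]); iy <- seq_len(dims[2]); iz <- seq_len(dims[3])
    d2 <- outer(outer((ix - center[1])^2, (iy - center[2])^2, "+"),
                (iz - center[3])^2, "+")
    peak * exp(-d2 / (2 * width^2))
  }
  lmfg_center <- c(7, 16, 11.5)
  template <- spatial_map(blob(lmfg_center), voxel_size = voxel_size)
  components <- list(
    spatial_map(blob(lmfg_center) + array(rnorm(nvox, sd = 0.2), dims),
                voxel_size = voxel_size),
    spatial_map(blob(c(18, 18, 6)) + array(rnorm(nvox, sd = 0.2), dims),
                voxel_size = voxel_size),
    spatial_map(array(rnorm(nvox, sd = 1), dims), voxel_size = voxel_size))

  list(bold = bold, rai = rai, lmfg = lmfg, brain = brain, wm = wm,
       csf = csf, components = components, template = template,
       truth_voxel = truth, driver = x)
}

#' Synthetic head fixture with analytic normals and fiducials
#'
#' A subdivided-icosahedron sphere or ellipsoid mesh with fiducial
#' landmarks at the analytic nasion (+x pole), left preauricular (+y pole)
#' and right preauricular (-y pole) positions, optionally rigidly moved.
#'
#' @param kind "sphere" or "ellipsoid".
#' @param radius sphere radius in mm (default 80), or ignored for
#'   ellipsoids.
#' @param semiaxes length-3 ellipsoid semi-axes in mm (default
#'   `c(80, 70, 90)`).
#' @param subdivisions icosphere subdivision level (default 3, 642
#'   vertices).
#' @param center mm triple added to all coordinates (default origin).
#' @return List: `mesh` (`head_model` with landmarks), `landmarks`,
#'   `normal_at` (function mm point -> analytic unit outward normal),
#'   `center`, and `edge_length` (median mesh edge, mm).
#' @export
make_head_fixture <- function(kind = c("sphere", "ellipsoid"), radius = 80,
                              semiaxes = c(80, 70, 90), subdivisions = 3,
                              center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  ico <- .icosphere(subdivisions)
  ax <- if (kind == "sphere") rep(radius, 3) else as.numeric(semiaxes)
  V <- sweep(sweep(ico$vertices, 2, ax, "*"), 2, center, "+")
  lm <- landmark_set(center + c(ax[1], 0, 0),
                     center + c(0, ax[2], 0),
                     center + c(0, -ax[2], 0))
  mesh <- head_model(V, ico$faces, lm)
  normal_at <- function(p) .unit((as.numeric(p) - center) / ax^2)
  e <- mesh$vertices[mesh$faces[, 1], ] - mesh$vertices[mesh$faces[, 2], ]
  list(mesh = mesh, landmarks = lm, normal_at = normal_at, center = center,
       edge_length = stats::median(sqrt(rowSums(e^2))))
}

# unit icosphere: icosahedron subdivided `k` times, vertices on the sphere
.icosphere <- function(k = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Fm <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
              c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
              c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(k)) {
    mid_env <- new.env(hash = TRUE, parent = emptyenv())
    newV <- V
    midpoint <- function(i, j) {
      key <- paste(sort(c(i, j)), collapse = "-")
      id <- mid_env[[key]]
      if (is.null(id)) {
        p <- .unit(V[i, ] + V[j, ])
        newV <<- rbind(newV, p)
        id <- nrow(newV)
        mid_env[[key]] <- id
      }
      id
    }
    newF <- matrix(0L, nrow = 4 * nrow(Fm), ncol = 3)
    for (f in seq_len(nrow(Fm))) {
      a <- Fm[f, 1]; b <- Fm[f, 2]; c3 <- Fm[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c3, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- newV; Fm <- newF
  }
  list(vertices = V, faces = Fm)
}

#' Synthetic rigid motion trace
#'
#' Baseline Gaussian jitter with optional translation spikes at chosen
#' frames.
#'
#' @param n_frames number of frames.
#' @param spike_frames integer frame indices receiving a translation jump.
#' @param spike_sizes_mm jump sizes in mm (recycled against
#'   `spike_frames`); the jump is applied to the x-translation from that
#'   frame onward.
#' @param jitter_sd baseline jitter sd in mm / radians (default 0.01).
#' @param seed integer random seed.
#' @return n x 6 numeric matrix (translations mm, rotations radians).
#' @export
make_motion_trace <- function(n_frames = 240, spike_frames = integer(0),
                              spike_sizes_mm = numeric(0), jitter_sd = 0.01,
                              seed = 1) {
  set.seed(seed)
  tr <- matrix(rnorm(n_frames * 6, sd = jitter_sd), n_frames, 6)
  tr <- apply(tr, 2, cumsum) * 0.1   # slow random walk, small amplitude
  if (length(spike_frames)) {
    sizes <- rep_len(spike_sizes_mm, length(spike_frames))
    for (i in seq_along(spike_frames)) {
      f <- spike_frames[i]
      stopifnot(f >= 2, f <= n_frames)
      tr[f:n_frames, 1] <- tr[f:n_frames, 1] + sizes[i]
    }
  }
  tr
}

#' Synthetic MEGA-PRESS edited spectrum set
#'
#' Interleaved ON/OFF FIDs built from Lorentzian resonances (default:
#' choline 3.2 ppm, creatine 3.0 ppm, NAA 2.0 ppm) plus edited resonances
#' present only in ON acquisitions (default: GABA 3.0 ppm), with optional
#' per-FID frequency/phase jitter and complex white noise. The water
#' reference is a single Lorentzian at the carrier.
#'
#' @param peaks data frame with columns `ppm`, `amplitude`, `lw_hz`
#'   (Lorentzian FWHM) for resonances present in both ON and OFF.
#' @param edited_on_only data frame in the same format for ON-only
#'   resonances.
#' @param n_on,n_off acquisition counts (defaults 160/160).
#' @param n_points FID length (default 2048).
#' @param dwell_time seconds (default 1/2000, i.e. 2 kHz spectral width).
#' @param spectrometer_frequency MHz (default 127.7).
#' @param freq_jitter_sd per-FID frequency offset sd in Hz (default 0).
#' @param phase_jitter_sd per-FID phase offset sd in degrees (default 0).
#' @param snr time-domain signal-to-noise (first FID point magnitude over
#'   noise sd); `Inf` for noiseless (default `Inf`).
#' @param water_lw_hz water linewidth (FWHM) in Hz (default 8).
#' @param water_amplitude water amplitude (default 50).
#' @param seed integer random seed.
#' @return List: `set` (`edited_spectrum_set`, ON/OFF interleaved starting
#'   with OFF) and `truth` (data frame of the planted per-FID frequency and
#'   phase offsets).
#' @export
make_megapress <- function(peaks = data.frame(ppm = c(3.2, 3.0, 2.0),
                                              amplitude = c(2, 3, 4),
                                              lw_hz = c(5, 5, 5)),
                           edited_on_only = data.frame(ppm = 3.0,
                                                       amplitude = 1,
                                                       lw_hz = 8),
                           n_on = 160, n_off = 160, n_points = 2048,
                           dwell_time = 1 / 2000,
                           spectrometer_frequency = 127.7,
                           freq_jitter_sd = 0, phase_jitter_sd = 0,
                           snr = Inf, water_lw_hz = 8, water_amplitude = 50,
                           seed = 1, water_ppm = 4.7) {
  set.seed(seed)
  tt <- (seq_len(n_points) - 1) * dwell_time
  lorentz_fid <- function(tbl) {
    out <- rep(0 + 0i, n_points)
    for (i in seq_len(nrow(tbl))) {
      f <- (tbl$ppm[i] - water_ppm) * spectrometer_frequency
      out <- out + tbl$amplitude[i] *
        exp(1i * 2 * pi * f * tt) * exp(-pi * tbl$lw_hz[i] * tt)
    }
    out
  }
  base_off <- lorentz_fid(peaks)
  base_on <- base_off + lorentz_fid(edited_on_only)
  n_total <- n_on + n_off
  labels <- rep(c("OFF", "ON"), length.out = n_total)
  if (n_on != n_off)
    labels <- c(rep("OFF", n_off), rep("ON", n_on))
  f_off <- rnorm(n_total, sd = freq_jitter_sd)
  p_off <- rnorm(n_total, sd = phase_jitter_sd)
  amp0 <- max(Mod(base_on))
  noise_sd <- if (is.finite(snr)) amp0 / snr else 0
  fids <- lapply(seq_len(n_total), function(i) {
    base <- if (labels[i] == "ON") base_on else base_off
    out <- base * exp(1i * (2 * pi * f_off[i] * tt + p_off[i] * pi / 180))
    if (noise_sd > 0)
      out <- out + complex(real = rnorm(n_points, sd = noise_sd),
                           imaginary = rnorm(n_points, sd = noise_sd))
    out
  })
  water <- water_amplitude * exp(-pi * water_lw_hz * tt)
  set <- edited_spectrum_set(fids, labels, water, dwell_time,
                             spectrometer_frequency, water_ppm)
  list(set = set,
       truth = data.frame(index = seq_len(n_total), label = labels,
                          frequency_offset_hz = f_off,
                          phase_offset_deg = p_off))
}
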
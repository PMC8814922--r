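# MEGA-PRESS edited-spectroscopy preprocessing: ON/OFF splitting, water-
# reference eddy-current correction, time-domain spectral registration,
# choline-window outlier rejection, averaging/differencing, and the
# linewidth and SNR quality gates.

#' Construct an edited spectrum set
#'
#' Interleaved editing-ON / editing-OFF complex FIDs with an unsuppressed
#' water reference.
#'
#' @param fids list of complex vectors, all the same length.
#' @param labels character vector of "ON"/"OFF", one per FID.
#' @param water_reference complex vector (same length as the FIDs).
#' @param dwell_time sampling interval in seconds.
#' @param spectrometer_frequency transmitter frequency in MHz (default
#'   127.7, a 3 T proton system).
#' @param water_ppm chemical shift of the carrier/water in ppm (default 4.7).
#' @return An object of class `edited_spectrum_set`.
#' @export
edited_spectrum_set <- function(fids, labels, water_reference, dwell_time,
                                spectrometer_frequency = 127.7,
                                water_ppm = 4.7) {
  if (length(fids) == 0L) stop("empty spectrum set")
  lens <- vapply(fids, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all FIDs must have equal length")
  labels <- toupper(as.character(labels))
  if (length(labels) != length(fids) || !all(labels %in% c("ON", "OFF")))
    stop("`labels` must be one of ON/OFF per FID")
  if (!is.numeric(dwell_time) || dwell_time <= 0)
    stop("`dwell_time` must be positive (seconds)")
  if (length(water_reference) != lens[1])
    stop("water reference length must match the FIDs")
  structure(list(fids = lapply(fids, as.complex),
                 labels = labels,
                 water_reference = as.complex(water_reference),
                 dwell_time = dwell_time,
                 spectrometer_frequency = spectrometer_frequency,
                 water_ppm = water_ppm),
            class = "edited_spectrum_set")
}

#' @export
print.edited_spectrum_set <- function(x, ...) {
  cat(sprintf("<edited_spectrum_set> %d FIDs (%d ON / %d OFF), %d points, dwell %.3g ms\n",
              length(x$fids), sum(x$labels == "ON"), sum(x$labels == "OFF"),
              length(x$fids[[1]]), 1000 * x$dwell_time))
  invisible(x)
}

#' Split an edited set into ON and OFF sub-lists
#'
#' Partitions the FIDs by editing label, preserving acquisition order
#' within each label.
#'
#' @param set an `edited_spectrum_set`.
#' @return list with elements `on` and `off` (lists of complex vectors).
#' @export
split_on_off <- function(set) {
  stopifnot(inherits(set, "edited_spectrum_set"))
  list(on = set$fids[set$labels == "ON"],
       off = set$fids[set$labels == "OFF"])
}

#' Eddy-current correction from the water reference
#'
#' Klose-style pointwise phase correction: each FID sample is rotated by the
#' negative instantaneous phase of the water reference,
#' `out_t = fid_t * exp(-i * Arg(water_t))`. Magnitudes are unchanged.
#' Where the water magnitude is (near) zero the phase of the last valid
#' sample is carried forward.
#'
#' @param fid complex vector.
#' @param water_reference complex vector of the same length.
#' @param min_magnitude samples with water magnitude below this fraction of
#'   the water maximum are treated as invalid (default 1e-8).
#' @return Corrected complex FID.
#' @export
eddy_correct <- function(fid, water_reference, min_magnitude = 1e-8) {
  fid <- as.complex(fid); w <- as.complex(water_reference)
  if (length(fid) != length(w)) stop("FID and water reference lengths differ")
  mag <- Mod(w)
  valid <- mag > min_magnitude * max(mag)
  if (!any(valid)) stop("water reference is entirely (near) zero")
  ph <- Arg(w)
  if (!all(valid)) {          # carry the last valid phase forward
    message(sum(!valid), " near-zero water sample(s); carrying phase forward")
    last <- ph[which(valid)[1]]
    for (t in seq_along(ph)) {
      if (valid[t]) last <- ph[t] else ph[t] <- last
    }
  }
  fid * exp(-1i * ph)
}

#' Align a FID to a reference by spectral registration
#'
#' Estimates the frequency and phase offset of `fid` relative to
#' `reference_fid` by nonlinear least squares in the time domain: the
#' estimate minimizes `sum_t |fid_t e^{-i(2 pi f t + phi)} - ref_t|^2` over
#' real and imaginary parts. For fixed f the optimal phase has a closed
#' form, so the fit profiles the objective down to a 1-D search over f
#' (coarse grid plus golden-section refinement).
#'
#' @param fid,reference_fid complex vectors of equal length.
#' @param dwell_time sampling interval in seconds.
#' @param max_shift_hz half-width of the frequency search window
#'   (default 20 Hz).
#' @return An `alignment_result`: `frequency_shift` (Hz), `phase_shift`
#'   (degrees) of the FID relative to the reference, and `aligned_fid`
#'   (the input with those shifts removed).
#' @export
spectral_register <- function(fid, reference_fid, dwell_time,
                              max_shift_hz = 20) {
  fid <- as.complex(fid); ref <- as.complex(reference_fid)
  if (length(fid) != length(ref)) stop("FID and reference lengths differ")
  n <- length(fid)
  tt <- (seq_len(n) - 1) * dwell_time
  # profiled objective: maximize |S(f)|, S(f) = sum fid e^{-i 2 pi f t} conj(ref)
  S <- function(f) sum(fid * exp(-1i * 2 * pi * f * tt) * Conj(ref))
  obj <- function(f) Mod(S(f))
  total_t <- n * dwell_time
  step <- min(0.25, 1 / (4 * total_t))
  grid <- seq(-max_shift_hz, max_shift_hz, by = step)
  vals <- vapply(grid, obj, numeric(1))
  f0 <- grid[which.max(vals)]
  opt <- optimize(obj, interval = c(f0 - step, f0 + step), maximum = TRUE,
                  tol = 1e-10)
  f_hat <- opt$maximum
  if (!is.finite(f_hat) || !is.finite(opt$objective))
    stop("spectral registration failed to converge (non-finite objective)")
  phi_hat <- Arg(S(f_hat))
  aligned <- fid * exp(-1i * (2 * pi * f_hat * tt + phi_hat))
  structure(list(frequency_shift = f_hat,
                 phase_shift = phi_hat * 180 / pi,
                 aligned_fid = aligned),
            class = "alignment_result")
}

# fftshifted complex spectrum and its ppm axis
.spectrum_ppm <- function(fid, dwell_time, spectrometer_frequency,
                          water_ppm = 4.7, pad = 1) {
  n0 <- length(fid)
  n <- n0 * pad
  sp <- fft(c(as.complex(fid), rep(0 + 0i, n - n0)))
  k <- seq_len(n) - 1
  f_hz <- k / (n * dwell_time)
  sw <- 1 / dwell_time
  f_hz[f_hz >= sw / 2] <- f_hz[f_hz >= sw / 2] - sw   # wrap to [-SW/2, SW/2)
  ord <- order(f_hz)
  f_hz <- f_hz[ord]
  sp <- sp[ord]
  ppm <- water_ppm + f_hz / spectrometer_frequency
  list(spectrum = sp, ppm = ppm, f_hz = f_hz)
}

#' Reject outlier spectra over the choline window
#'
#' Computes, for every FID, the mean squared error between its
#' frequency-domain spectrum and the mean spectrum, restricted to the
#' choline window (default 3.1-3.3 ppm), and rejects FIDs whose MSE exceeds
#' the across-spectra mean by more than 3 standard deviations. Single pass:
#' the threshold is not re-estimated after rejection.
#'
#' @param fids list of complex FIDs (>= 3).
#' @param dwell_time sampling interval in seconds.
#' @param spectrometer_frequency MHz.
#' @param choline_window_ppm length-2 ppm window (default `c(3.1, 3.3)`).
#' @param n_sd rejection threshold in standard deviations (default 3).
#' @param water_ppm carrier ppm (default 4.7).
#' @return List with `kept` (indices), `rejected` (indices), `mse` (per
#'   FID), and `threshold`.
#' @export
reject_outliers <- function(fids, dwell_time, spectrometer_frequency = 127.7,
                            choline_window_ppm = c(3.1, 3.3), n_sd = 3,
                            water_ppm = 4.7) {
  if (length(fids) < 3L) stop("outlier rejection needs at least 3 spectra")
  specs <- lapply(fids, function(f)
    .spectrum_ppm(f, dwell_time, spectrometer_frequency, water_ppm))
  ppm <- specs[[1]]$ppm
  win <- ppm >= min(choline_window_ppm) & ppm <= max(choline_window_ppm)
  if (!any(win)) stop("choline window contains no spectral points")
  M <- vapply(specs, function(s) s$spectrum[win],
              complex(sum(win)))
  M <- matrix(M, nrow = sum(win))
  mean_spec <- rowMeans(M)
  mse <- colMeans(Mod(M - mean_spec)^2)
  thr <- mean(mse) + n_sd * sd(mse)
  rejected <- which(mse > thr)
  list(kept = setdiff(seq_along(fids), rejected),
       rejected = rejected, mse = mse, threshold = thr)
}

#' Average aligned spectra and form the edited difference
#'
#' @param on,off nonempty lists of complex FIDs.
#' @return List with `mean_on`, `mean_off` and `difference`
#'   (`mean_on - mean_off`), all complex vectors.
#' @export
average_and_difference <- function(on, off) {
  if (length(on) == 0L || length(off) == 0L)
    stop("both ON and OFF lists must be nonempty")
  mean_fid <- function(l) Reduce(`+`, l) / length(l)
  mean_on <- mean_fid(on); mean_off <- mean_fid(off)
  list(mean_on = mean_on, mean_off = mean_off,
       difference = mean_on - mean_off)
}

#' Water linewidth (FWHM) in Hz
#'
#' Full width at half maximum of the absorption-mode water peak: the
#' spectrum is zero-order phased so the peak is purely absorptive (real),
#' and the half-height crossings of the real part are located by linear
#' interpolation. For a Lorentzian FID with decay `exp(-pi * lambda * t)`
#' this returns `lambda` Hz (the conventional linewidth; the magnitude-mode
#' width would be `sqrt(3)` times larger). The FID is zero-padded for
#' sub-bin resolution.
#'
#' @param water_reference complex FID.
#' @param dwell_time sampling interval in seconds.
#' @param pad zero-padding factor (default 8).
#' @return FWHM in Hz.
#' @export
water_linewidth <- function(water_reference, dwell_time, pad = 8) {
  if (length(water_reference) == 0L) stop("empty water reference")
  sp <- .spectrum_ppm(water_reference, dwell_time, 1, water_ppm = 0, pad = pad)
  ipk0 <- which.max(Mod(sp$spectrum))
  phased <- sp$spectrum * exp(-1i * Arg(sp$spectrum[ipk0]))
  mag <- Re(phased)
  f <- sp$f_hz
  ipk <- which.max(mag)
  half <- mag[ipk] / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(ipk - 1)) else (ipk + 1):length(mag)
    for (i in idx) {
      if (mag[i] <= half) {
        j <- if (side == "left") i + 1L else i - 1L   # last point above half
        return(f[i] + (f[j] - f[i]) * (half - mag[i]) / (mag[j] - mag[i]))
      }
    }
    stop("water peak does not fall to half height inside the spectral window")
  }
  abs(cross("right") - cross("left"))
}

#' Spectral signal-to-noise ratio of an OFF spectrum
#'
#' Peak magnitude inside the NAA window (default 1.8-2.2 ppm) divided by
#' the standard deviation of the spectrum's real part over the noise-only
#' edges of the spectral window (outermost `noise_fraction` of points on
#' each side).
#'
#' @param fid complex FID.
#' @param dwell_time seconds.
#' @param spectrometer_frequency MHz.
#' @param naa_window_ppm length-2 ppm window (default `c(1.8, 2.2)`).
#' @param noise_fraction fraction of spectral points per edge used as the
#'   noise region (default 0.1).
#' @param water_ppm carrier ppm (default 4.7).
#' @return SNR (dimensionless).
#' @export
spectrum_snr <- function(fid, dwell_time, spectrometer_frequency = 127.7,
                         naa_window_ppm = c(1.8, 2.2), noise_fraction = 0.1,
                         water_ppm = 4.7) {
  sp <- .spectrum_ppm(fid, dwell_time, spectrometer_frequency, water_ppm)
  win <- sp$ppm >= min(naa_window_ppm) & sp$ppm <= max(naa_window_ppm)
  if (!any(win)) stop("NAA window contains no spectral points")
  n <- length(sp$spectrum)
  k <- max(2L, floor(noise_fraction * n))
  noise <- c(Re(sp$spectrum[seq_len(k)]), Re(sp$spectrum[(n - k + 1):n]))
  max(Mod(sp$spectrum[win])) / sd(noise)
}

#' SNR gate over OFF spectra
#'
#' Rejects spectra whose SNR falls more than `n_sd` standard deviations
#' below the across-spectra mean.
#'
#' @param snr numeric vector of SNR values (>= 3).
#' @param n_sd threshold in standard deviations (default 3).
#' @return Integer vector of kept indices.
#' @export
snr_gate <- function(snr, n_sd = 3) {
  if (length(snr) < 3L) stop("SNR gate needs at least 3 values")
  which(snr >= mean(snr) - n_sd * sd(snr))
}

#' Full MEGA-PRESS preprocessing pipeline
#'
#' Splits into ON/OFF, eddy-corrects every FID against the water reference,
#' aligns each FID to the mean OFF spectrum by spectral registration,
#' rejects choline-window outliers within each label group, averages, and
#' forms the ON-OFF difference. QC gates (water linewidth < `max_linewidth_hz`,
#' OFF-spectrum SNR within 3 SD of the mean) annotate the result.
#'
#' @param set an `edited_spectrum_set`.
#' @param choline_window_ppm outlier-rejection window (default `c(3.1, 3.3)`).
#' @param max_linewidth_hz water-linewidth pass threshold (default 13).
#' @return List with `mean_on`, `mean_off`, `difference`, `alignment`
#'   (per-FID shifts), `rejected_on`, `rejected_off`, `water_fwhm_hz`,
#'   `linewidth_pass`, `snr_off` and `snr_kept`.
#' @export
mrs_preprocess <- function(set, choline_window_ppm = c(3.1, 3.3),
                           max_linewidth_hz = 13) {
  stopifnot(inherits(set, "edited_spectrum_set"))
  corrected <- lapply(set$fids, eddy_correct,
                      water_reference = set$water_reference)
  labels <- set$labels
  off_idx <- which(labels == "OFF"); on_idx <- which(labels == "ON")
  if (length(off_idx) == 0L || length(on_idx) == 0L)
    stop("need both ON and OFF spectra")
  ref <- Reduce(`+`, corrected[off_idx]) / length(off_idx)
  aligned <- lapply(corrected, function(f)
    spectral_register(f, ref, set$dwell_time))
  fids_al <- lapply(aligned, `[[`, "aligned_fid")
  maybe_reject <- function(idx) {
    if (length(idx) < 3L)   # too few spectra for a spread estimate
      return(list(kept = seq_along(idx), rejected = integer(0)))
    reject_outliers(fids_al[idx], set$dwell_time,
                    set$spectrometer_frequency, choline_window_ppm,
                    water_ppm = set$water_ppm)
  }
  rej_on <- maybe_reject(on_idx)
  rej_off <- maybe_reject(off_idx)
  on_kept <- fids_al[on_idx][rej_on$kept]
  off_kept <- fids_al[off_idx][rej_off$kept]
  avg <- average_and_difference(on_kept, off_kept)
  fwhm <- water_linewidth(set$water_reference, set$dwell_time)
  snr_off <- vapply(off_kept, spectrum_snr, numeric(1),
                    dwell_time = set$dwell_time,
                    spectrometer_frequency = set$spectrometer_frequency,
                    water_ppm = set$water_ppm)
  snr_kept <- if (length(snr_off) < 3L) seq_along(snr_off) else snr_gate(snr_off)
  c(avg,
    list(alignment = data.frame(
           index = seq_along(aligned), label = labels,
           frequency_shift_hz = vapply(aligned, `[[`, numeric(1), "frequency_shift"),
           phase_shift_deg = vapply(aligned, `[[`, numeric(1), "phase_shift")),
         rejected_on = on_idx[rej_on$rejected],
         rejected_off = off_idx[rej_off$rejected],
         water_fwhm_hz = fwhm,
         linewidth_pass = fwhm < max_linewidth_hz,
         snr_off = snr_off,
         snr_kept = snr_kept))
}

#' Write an edited spectrum set to CSV + JSON sidecar
#'
#' Plain-text dialect: `<path>.csv` holds one row per (FID, sample) with
#' columns `fid`, `sample`, `re`, `im`, where `fid` 0 is the water
#' reference; `<path>.json` holds the dwell time, spectrometer frequency,
#' water ppm, and labels.
#'
#' @param set an `edited_spectrum_set`.
#' @param path output basename (without extension).
#' @return The basename, invisibly.
#' @export
write_spectrum_set <- function(set, path) {
  all_fids <- c(list(set$water_reference), set$fids)
  n <- length(all_fids[[1]])
  df <- data.frame(
    fid = rep(seq_along(all_fids) - 1L, each = n),
    sample = rep(seq_len(n) - 1L, times = length(all_fids)),
    re = unlist(lapply(all_fids, Re)),
    im = unlist(lapply(all_fids, Im)))
  write.table(df, paste0(path, ".csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(dwell_time = set$dwell_time,
                            spectrometer_frequency = set$spectrometer_frequency,
                            water_ppm = set$water_ppm,
                            labels = set$labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an edited spectrum set written by [write_spectrum_set()]
#'
#' @param path basename (without extension).
#' @return An `edited_spectrum_set`.
#' @export
read_spectrum_set <- function(path) {
  df <- read.table(paste0(path, ".csv"), sep = ",", header = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  ids <- sort(unique(df$fid))
  fids <- lapply(ids, function(i) {
    sub <- df[df$fid == i, ]
    sub <- sub[order(sub$sample), ]
    complex(real = sub$re, imaginary = sub$im)
  })
  edited_spectrum_set(fids[-1], meta$labels, fids[[1]], meta$dwell_time,
                      meta$spectrometer_frequency, meta$water_ppm)
}
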
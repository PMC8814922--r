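nt_fid <- 1024
dwell <- 1 / 2000

test_that("splitting preserves acquisition order within labels", {
  fids <- lapply(1:4, function(i) complex(real = rep(i, 8), imaginary = 0))
  set <- edited_spectrum_set(fids, c("ON", "OFF", "ON", "OFF"),
                             rep(1 + 0i, 8), dwell)
  sp <- split_on_off(set)
  expect_equal(sp$on, fids[c(1, 3)])
  expect_equal(sp$off, fids[c(2, 4)])

  expect_error(edited_spectrum_set(list(), character(0), complex(0), dwell),
               "empty")
})

test_that("eddy-current correction removes the water phase and preserves magnitude", {
  set.seed(401)
  tt <- (seq_len(nt_fid) - 1) * dwell
  water <- 50 * exp(-pi * 8 * tt) * exp(1i * (2 * pi * 1.5 * tt + 0.4))

  # fid equal to the water reference comes out purely real, non-negative
  out <- eddy_correct(water, water)
  expect_lt(max(abs(Im(out))), 1e-9)
  expect_true(all(Re(out) >= 0))

  # zero-phase water: identity
  fid <- complex(real = rnorm(nt_fid), imaginary = rnorm(nt_fid))
  expect_equal(eddy_correct(fid, complex(real = abs(rnorm(nt_fid)) + 1)), fid)

  # planted time-varying phase equal to the water phase is removed
  phase <- 0.5 * sin(2 * pi * 3 * tt)
  w2 <- (1 + 0i) * exp(1i * phase)
  f2 <- exp(-pi * 5 * tt) * exp(1i * phase)
  corr <- eddy_correct(f2, w2)
  expect_lt(max(abs(Arg(corr[Mod(corr) > 1e-6]))), 1e-9)

  # pointwise magnitude preserved
  expect_equal(Mod(eddy_correct(fid, water)), Mod(fid), tolerance = 1e-12)
})

test_that("spectral registration recovers planted frequency and phase shifts", {
  mp <- make_megapress(n_on = 1, n_off = 1, n_points = nt_fid, seed = 6)
  base <- mp$set$fids[[1]]
  tt <- (seq_len(nt_fid) - 1) * dwell

  r0 <- spectral_register(base, base, dwell)
  expect_lt(abs(r0$frequency_shift), 1e-6)
  expect_lt(abs(r0$phase_shift), 1e-6)

  # noiseless planted shift: exact recovery and inverse consistency
  sh <- base * exp(1i * (2 * pi * 3 * tt + 20 * pi / 180))
  r <- spectral_register(sh, base, dwell)
  expect_equal(r$frequency_shift, 3, tolerance = 1e-6)
  expect_equal(r$phase_shift, 20, tolerance = 1e-6)
  expect_equal(r$aligned_fid, base, tolerance = 1e-6)
  undone <- r$aligned_fid * exp(1i * (2 * pi * r$frequency_shift * tt +
                                        r$phase_shift * pi / 180))
  expect_equal(undone, sh, tolerance = 1e-9)

  # graceful degradation: median error under heavy noise stays bounded
  set.seed(402)
  errs <- replicate(40, {
    ns <- max(Mod(base)) / 5
    noisy <- sh + complex(real = rnorm(nt_fid, sd = ns),
                          imaginary = rnorm(nt_fid, sd = ns))
    spectral_register(noisy, base, dwell)$frequency_shift - 3
  })
  expect_lt(median(abs(errs)), 0.5)
})

test_that("spectral registration is unbiased over repeated planted-shift draws", {
  mp <- make_megapress(n_on = 1, n_off = 1, n_points = nt_fid, seed = 7)
  base <- mp$set$fids[[1]]
  tt <- (seq_len(nt_fid) - 1) * dwell
  set.seed(403)
  n_draws <- 300
  errs <- t(replicate(n_draws, {
    f_true <- runif(1, -4, 4); p_true <- runif(1, -60, 60)
    ns <- max(Mod(base)) / 50
    sh <- base * exp(1i * (2 * pi * f_true * tt + p_true * pi / 180)) +
      complex(real = rnorm(nt_fid, sd = ns),
              imaginary = rnorm(nt_fid, sd = ns))
    r <- spectral_register(sh, base, dwell)
    c(r$frequency_shift - f_true, r$phase_shift - p_true)
  }))
  expect_lt(abs(mean(errs[, 1])), 0.02)
  expect_lt(abs(mean(errs[, 2])), 0.2)
})

test_that("outlier rejection flags only the corrupted spectrum", {
  mp <- make_megapress(n_on = 16, n_off = 16, n_points = nt_fid,
                       snr = 200, seed = 8)
  fids <- mp$set$fids
  expect_equal(length(fids), 32)

  # identical spectra: nothing rejected
  same <- rep(fids[1], 8)
  r_same <- reject_outliers(same, dwell)
  expect_length(r_same$rejected, 0)

  # double the choline peak in one spectrum
  tt <- (seq_len(nt_fid) - 1) * dwell
  cho_extra <- 2 * exp(1i * 2 * pi * ((3.2 - 4.7) * 127.7) * tt) *
    exp(-pi * 5 * tt)
  fids[[13]] <- fids[[13]] + cho_extra
  rr <- reject_outliers(fids, dwell)
  expect_identical(rr$rejected, 13L)
  expect_identical(rr$kept, setdiff(1:32, 13L))

  # report schema: per-fid MSE and a single threshold
  expect_length(rr$mse, 32)
  expect_true(is.numeric(rr$threshold) && length(rr$threshold) == 1)
  expect_error(reject_outliers(fids[1:2], dwell), "at least 3")
})

test_that("averaging and differencing are linear and recover the edited peak", {
  mp <- make_megapress(n_on = 8, n_off = 8, n_points = nt_fid, seed = 9)
  sp <- split_on_off(mp$set)

  # ON = OFF gives a zero difference
  z <- average_and_difference(sp$off, sp$off)
  expect_lt(max(Mod(z$difference)), 1e-12)

  one <- average_and_difference(sp$on[1], sp$off[1])
  expect_equal(one$difference, sp$on[[1]] - sp$off[[1]])

  # edited resonance present only in ON survives in the difference spectrum
  avg <- average_and_difference(sp$on, sp$off)
  spec <- fft(avg$difference)
  tt <- (seq_len(nt_fid) - 1) * dwell
  planted <- fft(1 * exp(1i * 2 * pi * ((3.0 - 4.7) * 127.7) * tt) *
                   exp(-pi * 8 * tt))
  expect_equal(max(Mod(spec)), max(Mod(planted)), tolerance = 0.02)

  # linearity under global scaling
  k <- 2.5
  sc <- average_and_difference(lapply(sp$on, `*`, k), lapply(sp$off, `*`, k))
  expect_equal(sc$difference, k * avg$difference, tolerance = 1e-12)

  expect_error(average_and_difference(list(), sp$off), "nonempty")
})

test_that("water linewidth matches the analytic Lorentzian width", {
  tt <- (seq_len(2048) - 1) * dwell
  # decay time constant 1/(pi*10): linewidth 10 Hz
  fid10 <- exp(-tt * pi * 10)
  expect_equal(water_linewidth(fid10, dwell), 10, tolerance = 0.02)

  # identical acquisitions give identical linewidths
  expect_identical(water_linewidth(fid10, dwell), water_linewidth(fid10, dwell))

  # off-carrier, phase-shifted water: width unchanged
  fid_off <- exp(1i * (2 * pi * 12 * tt + 0.7)) * exp(-tt * pi * 10)
  expect_equal(water_linewidth(fid_off, dwell), 10, tolerance = 0.02)

  # gate verdicts on either side of the 13 Hz limit
  mk <- function(lw) make_megapress(n_on = 2, n_off = 2, n_points = nt_fid,
                                    water_lw_hz = lw, seed = 10)$set
  expect_true(mrs_preprocess(mk(11))$linewidth_pass)
  expect_false(mrs_preprocess(mk(15))$linewidth_pass)
})

test_that("the SNR gate rejects spectra far below the group mean", {
  expect_identical(snr_gate(rep(40, 6)), 1:6)

  set.seed(411)
  snr <- rnorm(50, 40, 2)
  snr[7] <- mean(snr[-7]) - 4 * sd(snr[-7])
  kept <- snr_gate(snr)
  expect_false(7 %in% kept)

  expect_error(snr_gate(numeric(0)), "at least 3")
})

test_that("the full preprocessing pipeline aligns, rejects, and reports QC", {
  mp <- make_megapress(n_on = 8, n_off = 8, n_points = nt_fid,
                       freq_jitter_sd = 1, phase_jitter_sd = 10, snr = 100,
                       seed = 12)
  out <- mrs_preprocess(mp$set)
  expect_named(out, c("mean_on", "mean_off", "difference", "alignment",
                      "rejected_on", "rejected_off", "water_fwhm_hz",
                      "linewidth_pass", "snr_off", "snr_kept"),
               ignore.order = TRUE)
  expect_equal(nrow(out$alignment), 16)
  # estimated shifts track the planted jitter up to the group mean offset
  est <- out$alignment$frequency_shift_hz
  tru <- mp$truth$frequency_offset_hz
  expect_gt(cor(est, tru), 0.95)
  expect_true(out$linewidth_pass)
  # the aligned difference recovers the planted edited resonance, which the
  # unaligned (jittered) difference would smear
  tt <- (seq_len(nt_fid) - 1) * dwell
  planted <- fft(1 * exp(1i * 2 * pi * ((3.0 - 4.7) * 127.7) * tt) *
                   exp(-pi * 8 * tt))
  expect_equal(max(Mod(fft(out$difference))), max(Mod(planted)),
               tolerance = 0.1)
})

test_that("spectrum sets round trip through the CSV + JSON dialect", {
  mp <- make_megapress(n_on = 2, n_off = 2, n_points = 64,
                       freq_jitter_sd = 0.5, snr = 50, seed = 13)
  base <- file.path(tempdir(), "mrs_set")
  write_spectrum_set(mp$set, base)
  back <- read_spectrum_set(base)
  expect_equal(back$fids, mp$set$fids, tolerance = 1e-12)
  expect_identical(back$labels, mp$set$labels)
  expect_equal(back$water_reference, mp$set$water_reference, tolerance = 1e-12)
  expect_equal(back$dwell_time, mp$set$dwell_time)
})
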
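test_that("mask binarization and spherical erosion match the neighborhood-scan oracle", {
  # full grid: erosion removes a 2-voxel boundary shell
  full <- spatial_map(array(1, c(9, 9, 9)))
  m <- binarize_and_erode_mask(full, 0.98, 2)
  expected <- array(FALSE, c(9, 9, 9))
  expected[3:7, 3:7, 3:7] <- TRUE
  expect_identical(m$values, expected)

  # subthreshold map: empty with a warning
  expect_warning(
    m0 <- binarize_and_erode_mask(spatial_map(array(0.5, c(5, 5, 5))), 0.98, 2),
    "empty")
  expect_false(any(m0$values))

  # random blobs against the brute-force oracle, two radii
  set.seed(11)
  for (radius in 1:2) {
    p <- array(runif(8 * 8 * 6), c(8, 8, 6))
    p[2:6, 2:7, 2:5] <- pmin(1, p[2:6, 2:7, 2:5] + 0.6)
    got <- binarize_and_erode_mask(spatial_map(p), 0.6, radius)
    expect_identical(got$values, oracle_erode(p >= 0.6, radius))
  }
})

test_that("nuisance regression produces residuals orthogonal to WM/CSF regressors", {
  set.seed(21)
  dims <- c(4, 4, 3); nt <- 60
  arr <- array(rnorm(prod(dims) * nt), c(dims, nt))
  wm <- voxel_mask(array(c(TRUE, rep(FALSE, prod(dims) - 1)), dims), "WM")
  csf_arr <- array(FALSE, dims); csf_arr[2, 1, 1] <- TRUE
  csf <- voxel_mask(csf_arr, "CSF")

  # a voxel set exactly to the WM series comes back as zeros
  arr[3, 3, 2, ] <- arr[1, 1, 1, ]
  bold <- bold_series(arr, tr = 2)
  res <- regress_nuisance(bold, wm, csf)
  expect_lt(max(abs(res$data[3, 3, 2, ])), 1e-10)

  # residuals orthogonal to both nuisance series
  wm_ts <- seed_series(bold, wm); csf_ts <- seed_series(bold, csf)
  for (v in list(c(2, 3, 1), c(4, 4, 3))) {
    r <- res$data[v[1], v[2], v[3], ]
    expect_lt(abs(sum(r * wm_ts)) / (sqrt(sum(r^2)) * sqrt(sum(wm_ts^2))), 1e-8)
    expect_lt(abs(sum(r * csf_ts)) / (sqrt(sum(r^2)) * sqrt(sum(csf_ts^2))), 1e-8)
  }

  # per-voxel normal-equations oracle
  X <- cbind(1, wm_ts, csf_ts)
  for (v in list(c(1, 2, 3), c(4, 1, 2))) {
    y <- arr[v[1], v[2], v[3], ]
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(res$data[v[1], v[2], v[3], ], as.numeric(y - X %*% beta),
                 tolerance = 1e-10)
  }

  # all-zero nuisance voxels: output equals the demeaned input
  arr0 <- arr
  arr0[1, 1, 1, ] <- 0
  arr0[2, 1, 1, ] <- 0
  res0 <- suppressMessages(regress_nuisance(bold_series(arr0, tr = 2), wm, csf))
  y <- arr0[3, 2, 1, ]
  expect_equal(res0$data[3, 2, 1, ], y - mean(y), tolerance = 1e-10)
})

test_that("high-pass filter removes slow drift and DC but preserves passband sinusoids", {
  nt <- 240; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  mk <- function(ts) bold_series(array(rep(ts, each = 1), c(1, 1, 1, nt)), tr = tr)

  s05 <- sin(2 * pi * 0.05 * tt)
  out <- highpass(mk(s05), 0.01)
  amp_ratio <- sqrt(sum(out$data^2) / sum(s05^2))
  expect_gt(amp_ratio, 0.95); expect_lt(amp_ratio, 1.05)

  expect_lt(max(abs(highpass(mk(rep(5, nt)), 0.01)$data)), 1e-10)

  drift <- sin(2 * pi * 0.002 * tt)
  out_d <- highpass(mk(drift), 0.01)
  expect_lt(sqrt(sum(out_d$data^2) / sum(drift^2)), 0.1)

  expect_error(highpass(mk(s05), -1), "positive")
  expect_error(highpass(mk(s05), 0.5), "Nyquist")
})

test_that("component selection picks the template-matched map and ignores positive rescaling", {
  set.seed(31)
  dims <- c(10, 10, 8)
  blob <- function(center) {
    d2 <- outer(outer((1:dims[1] - center[1])^2, (1:dims[2] - center[2])^2, "+"),
                (1:dims[3] - center[3])^2, "+")
    5 * exp(-d2 / 8)
  }
  template <- blob(c(3, 3, 4))
  cands <- list(template, -template, array(rnorm(prod(dims)), dims))
  sel <- select_component(cands, template, 1.96)
  expect_identical(sel$index, 1L)

  expect_identical(select_component(list(template), template)$index, 1L)

  # brute-force correlation scan over blob candidates
  cands2 <- lapply(list(c(3, 3, 4), c(7, 7, 2), c(5, 8, 6)), function(ctr)
    blob(ctr) + array(rnorm(prod(dims), sd = 0.1), dims))
  sel2 <- select_component(cands2, template, 1.96)
  scan <- vapply(cands2, function(v) {
    v[v < 1.96] <- 0
    cor(as.numeric(v), as.numeric(template))
  }, numeric(1))
  expect_identical(sel2$index, which.max(scan))

  # winner is stable under positive rescaling of the candidate maps
  for (k in c(0.8, 3)) {
    sel3 <- select_component(lapply(cands2, function(v) k * v), template, 1.96)
    expect_identical(sel3$index, sel2$index)
  }
})

test_that("seed series equals the explicit ROI mean", {
  set.seed(41)
  dims <- c(4, 4, 3); nt <- 30
  arr <- array(rnorm(prod(dims) * nt), c(dims, nt))
  bold <- bold_series(arr, tr = 2)

  one <- array(FALSE, dims); one[2, 3, 1] <- TRUE
  expect_equal(seed_series(bold, voxel_mask(one)), arr[2, 3, 1, ])

  # two voxels with opposite series cancel
  arr2 <- arr; arr2[1, 1, 1, ] <- arr2[2, 1, 1, ] * -1
  two <- array(FALSE, dims); two[1:2, 1, 1] <- TRUE
  expect_lt(max(abs(seed_series(bold_series(arr2, tr = 2), voxel_mask(two)))), 1e-12)

  # random ROI against explicit summation
  set.seed(42)
  roi <- array(runif(prod(dims)) < 0.3, dims)
  roi[1, 1, 1] <- TRUE
  got <- seed_series(bold, voxel_mask(roi))
  manual <- sapply(seq_len(nt), function(t) mean(arr[, , , t][roi]))
  expect_equal(got, manual, tolerance = 1e-12)

  expect_error(seed_series(bold, voxel_mask(array(FALSE, dims))), "empty")
})

test_that("first-order Granger coefficient matches the lm oracle and detects direction", {
  set.seed(51)
  nt <- 240
  x <- rnorm(nt)
  y <- c(rnorm(1), 0.8 * x[-nt] + rnorm(nt - 1))
  expect_equal(granger_first_order(x, y), oracle_granger(x, y),
               tolerance = 1e-10)

  # no causal structure: mean coefficient near zero over many realizations
  set.seed(52)
  bs <- replicate(1000, granger_first_order(rnorm(60), rnorm(60)))
  expect_lt(abs(mean(bs)), 0.01)

  # pure autoregression in y: no spurious x coefficient at large T
  set.seed(53)
  nT <- 10000
  ya <- as.numeric(stats::filter(rnorm(nT), 0.6, method = "recursive"))
  expect_lt(abs(granger_first_order(rnorm(nT), ya)), 0.05)

  # asymmetry: planted x -> y coupling dwarfs the reverse coefficient
  set.seed(54)
  ratios <- replicate(100, {
    x <- rnorm(nt)
    y <- c(rnorm(1), 0.5 * x[-nt] + rnorm(nt - 1))
    abs(granger_first_order(x, y)) / abs(granger_first_order(y, x))
  })
  expect_gt(median(ratios), 3)

  expect_error(granger_first_order(rep(1, 50), rnorm(50)), "zero-variance")
  z <- rnorm(50)
  expect_error(granger_first_order(z, z), "rank")
})

test_that("GCA z-map is standardized over the mask and recovers a planted causal voxel", {
  set.seed(61)
  dims <- c(5, 5, 4); nt <- 240
  arr <- array(rnorm(prod(dims) * nt), c(dims, nt))
  x <- rnorm(nt)
  arr[2, 3, 2, ] <- c(rnorm(1), 0.6 * x[-nt] + rnorm(nt - 1))
  bold <- bold_series(arr, tr = 2)
  mask <- voxel_mask(array(TRUE, dims))
  z <- gca_zmap(bold, x, mask)
  vals <- z$values[mask$values]
  expect_lt(abs(mean(vals)), 1e-12)
  expect_equal(sd(vals), 1, tolerance = 1e-12)

  # identical in-mask series: zero coefficient spread
  same <- array(rep(sin(1:nt), each = prod(dims)), c(dims, nt))
  expect_error(gca_zmap(bold_series(same + 0, tr = 2), x, mask), "variance")

  # planted voxel is the z-map maximum in >= 19/20 seeded simulations
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    a <- array(rnorm(prod(dims) * nt), c(dims, nt))
    xs <- rnorm(nt)
    a[4, 2, 3, ] <- c(rnorm(1), 0.5 * xs[-nt] + rnorm(nt - 1))
    zm <- gca_zmap(bold_series(a, tr = 2), xs, mask)
    hits <- hits + all(arrayInd(which.max(zm$values), dims) == c(4, 2, 3))
  }
  expect_gte(hits, 19)
})

test_that("peak-cluster target is the suprathreshold in-mask argmax", {
  dims <- c(6, 6, 4)
  mask <- voxel_mask(array(TRUE, dims))

  z1 <- array(0, dims); z1[3, 4, 2] <- 2.5
  t1 <- peak_cluster_target(spatial_map(z1), mask, 1.96)
  expect_identical(t1$voxel_index, c(3L, 4L, 2L))
  expect_identical(t1$cluster_size, 1L)

  # two clusters: the 4.0 peak wins and its cluster is reported
  z2 <- array(0, dims)
  z2[1:2, 1, 1] <- c(4.0, 3.2); z2[5:6, 5, 3] <- c(3.0, 2.1)
  t2 <- peak_cluster_target(spatial_map(z2), mask, 1.96)
  expect_identical(t2$voxel_index, c(1L, 1L, 1L))
  expect_identical(t2$cluster_size, 2L)

  # random maps against the brute-force argmax oracle
  set.seed(71)
  for (i in 1:5) {
    z <- array(rnorm(prod(dims)), dims)
    m <- array(runif(prod(dims)) < 0.7, dims)
    supra <- which((z > 1.0) & m)
    if (length(supra) == 0) next
    got <- peak_cluster_target(spatial_map(z), voxel_mask(m), 1.0)
    expect_identical(got$voxel_index,
                     as.integer(arrayInd(supra[which.max(z[supra])], dims)))
  }

  expect_error(peak_cluster_target(spatial_map(array(0, dims)), mask, 1.96),
               "no significant target")
})

test_that("point-to-mask projection minimizes mm distance with lexicographic ties", {
  dims <- c(6, 6, 6)
  m <- array(FALSE, dims); m[4, 5, 2] <- TRUE
  got <- project_point_to_mask(c(50, 50, 50), voxel_mask(m), c(3, 3, 3))
  expect_identical(got$voxel_index, c(4L, 5L, 2L))

  # point already inside the mask: that voxel, distance 0
  full <- voxel_mask(array(TRUE, dims))
  got2 <- project_point_to_mask(c(6, 9, 3), full, c(3, 3, 3))
  expect_identical(got2$voxel_index, c(3L, 4L, 2L))
  expect_equal(got2$distance_mm, 0)

  # random instances against the exhaustive scan oracle
  set.seed(81)
  for (i in 1:10) {
    mk <- array(runif(prod(dims)) < 0.4, dims)
    mk[1, 1, 1] <- TRUE
    pt <- runif(3, -5, 20)
    got <- project_point_to_mask(pt, voxel_mask(mk), c(3, 3, 3))
    idx <- which(mk)
    ai <- arrayInd(idx, dims)
    d2 <- rowSums(sweep(sweep(ai - 1, 2, c(3, 3, 3), "*"), 2, pt)^2)
    expect_equal(sqrt(min(d2)), got$distance_mm, tolerance = 1e-12)
  }

  expect_error(project_point_to_mask(c(0, 0, 0), voxel_mask(array(FALSE, dims))),
               "empty")
})
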
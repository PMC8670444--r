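test_that("illumination correction removes shading ramps, keeps flats", {
  flat <- matrix(0.4, 64, 64)
  expect_equal(correct_illumination(flat), flat, tolerance = 1e-12)

  # fine texture (no large-scale content, no clipping) plus a linear ramp
  n <- 96
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  base <- 0.5 + 0.18 * sin(2 * pi * xs / 9) * cos(2 * pi * ys / 11)
  ramp <- outer(seq(-0.1, 0.1, length.out = n), rep(1, n))
  corr <- correct_illumination(base + ramp, sigma = 6)
  base_corr <- correct_illumination(base, sigma = 6)
  # compare away from the border where the background estimate is clean
  i <- 20:77
  expect_lt(max(abs(corr[i, i] - base_corr[i, i])), 0.02)

  # impulse noise stays bounded, no NaN
  spiky <- matrix(0.2, 32, 32); spiky[c(5, 200, 800)] <- 1
  out <- correct_illumination(spiky)
  expect_true(all(is.finite(out)) && all(out >= 0) && all(out <= 1))
})

test_that("otsu matches the brute-force between-class maximizer", {
  brute_force_otsu <- function(counts, mids) {
    n <- sum(counts)
    best <- -Inf; kbest <- 1L
    for (k in seq_len(length(counts) - 1)) {
      w0 <- sum(counts[1:k]); w1 <- n - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(counts[1:k] * mids[1:k]) / w0
      m1 <- sum(counts[(k + 1):length(counts)] *
                  mids[(k + 1):length(counts)]) / w1
      bcv <- (w0 / n) * (w1 / n) * (m0 - m1)^2
      if (bcv > best) { best <- bcv; kbest <- k }
    }
    (mids[kbest] + mids[kbest + 1]) / 2
  }
  set.seed(10)
  for (rep in 1:100) {
    nbin <- sample(4:40, 1)
    counts <- rpois(nbin, lambda = sample(c(2, 10, 50), 1)) + 1L
    mids <- sort(runif(nbin))
    vals <- rep(mids, counts)
    expect_identical(otsu_threshold(vals, levels = 1e6),
                     brute_force_otsu(counts, mids))
  }
})

test_that("otsu separates a bimodal image and rejects constants", {
  img <- matrix(c(rep(50, 40), rep(200, 60)), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 50); expect_lt(thr, 200)
  expect_identical(sum(img > thr), 60L)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("otsu agrees with an independent reference implementation", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  img <- matrix(pmin(pmax(c(rnorm(2000, 0.3, 0.05),
                            rnorm(2096, 0.7, 0.05)), 0), 1), 64, 64)
  ours <- otsu_threshold(img, levels = 256)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  # binning conventions differ slightly; both must land between the modes
  expect_equal(ours, ref, tolerance = 0.1)
  expect_gt(ours, 0.35); expect_lt(ours, 0.65)
})

test_that("real contact area recovers analytic disk areas", {
  n <- 200; res <- 0.01
  xm <- matrix(rep(1:n, each = n), n, n)
  ym <- matrix(rep(1:n, times = n), n, n)
  disk <- (xm - 60)^2 + (ym - 60)^2 <= 50^2
  img <- matrix(0.1, n, n); img[disk] <- 0.9
  expect_equal(real_contact_area(img, res), pi * 0.5^2, tolerance = 0.02)

  disk2 <- (xm - 150)^2 + (ym - 150)^2 <= 30^2
  img2 <- img; img2[disk2] <- 0.9
  expect_equal(real_contact_area(img2, res), pi * (0.5^2 + 0.3^2),
               tolerance = 0.02)

  # forcing the threshold to the max yields zero area
  expect_identical(real_contact_area(img, res, threshold = 1), 0)
})

test_that("contact area is robust to illumination gradients after correction", {
  # asperity-scale bright speckle (as in the contact channel) under a ramp
  set.seed(6)
  n <- 128; res <- 0.02
  xm <- matrix(rep(1:n, each = n), n, n)
  ym <- matrix(rep(1:n, times = n), n, n)
  inside <- (xm - 64)^2 + (ym - 64)^2 <= 50^2
  spots <- matrix(runif(n * n) < 0.25, n, n) & inside
  img <- matrix(0.15, n, n); img[spots] <- 0.85
  a0 <- real_contact_area(img, res)
  ramp <- outer(seq(-0.12, 0.12, length.out = n), rep(1, n))
  a1 <- real_contact_area(
    correct_illumination(pmin(pmax(img + ramp, 0), 1), sigma = 12), res)
  expect_equal(a1, a0, tolerance = 0.03)
})

test_that("local brightness averages the discrete disk", {
  img <- matrix(0.37, 50, 50)
  expect_equal(local_brightness(img, 25, 25), 0.37, tolerance = 1e-12)

  # point centred in a wide bright disk reads the disk intensity
  n <- 60
  xm <- matrix(rep(1:n, each = n), n, n)
  ym <- matrix(rep(1:n, times = n), n, n)
  img2 <- matrix(0.1, n, n)
  img2[(xm - 30)^2 + (ym - 30)^2 <= 20^2] <- 0.8
  expect_equal(local_brightness(img2, 30, 30), 0.8, tolerance = 1e-12)

  # half-bright boundary point: mean of the two sides up to discretisation
  img3 <- matrix(0.2, n, n); img3[, 31:n] <- 0.8
  b <- local_brightness(img3, 30.5, 30, radius_px = 10)
  # pixel-counting oracle over the same discrete disk
  off <- expand.grid(dx = -10:10, dy = -10:10)
  off <- off[off$dx^2 + off$dy^2 <= 100, ]
  oracle <- mean(ifelse(round(30.5) + off$dx >= 31, 0.8, 0.2))
  expect_equal(b, oracle, tolerance = 1e-12)

  expect_error(local_brightness(img, 3, 3), "border")
})

test_that("force filtering is zero-lag with unit DC gain", {
  fs <- 1000
  const <- rep(2.5, 500)
  expect_lt(max(abs(filter_force(const, fs) - 2.5)), 1e-9)

  t <- seq(0, 1, by = 1 / fs)
  low <- sin(2 * pi * 5 * t)
  lowf <- filter_force(low, fs)
  i <- 100:900
  expect_equal(max(abs(lowf[i])), 1, tolerance = 0.01)
  # zero phase: cross-correlation peaks at lag 0
  cc <- ccf(lowf[i], low[i], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 200 Hz tone attenuated by the squared second-order response; the
  # digital design warps frequencies by the bilinear transform, so the
  # analytic oracle uses Omega = tan(pi f / fs)
  hi <- sin(2 * pi * 200 * t)
  hif <- filter_force(hi, fs)
  warp <- tan(pi * 200 / fs) / tan(pi * 50 / fs)
  h2 <- 1 / (1 + warp^(2 * 2))        # |H|^2 of the forward+backward pass
  expect_equal(max(abs(hif[i])), h2, tolerance = 0.15)

  expect_error(filter_force(rep(1, 10), fs), "short")
  expect_error(filter_force(const, 80), "sample_rate")
})

test_that("filtering twice behaves like a tightened cutoff, no blowup", {
  fs <- 1000
  set.seed(3)
  x <- cumsum(rnorm(1000)) / 10
  once <- filter_force(x, fs)
  twice <- filter_force(once, fs)
  expect_true(all(is.finite(twice)))
  # twice-filtered signal has no more high-frequency energy than once
  hf <- function(v) mean(diff(v, differences = 2)^2)
  expect_lte(hf(twice), hf(once) * (1 + 1e-9))
})

test_that("spearman correlation matches a hand-ranked table", {
  tracked <- tibble::tibble(
    displacement_mm = c(0.1, 0.3, 0.2, 0.5, 0.4,
                        0.15, 0.35, 0.25, 0.55, 0.45),
    brightness = c(0.2, 0.5, 0.3, 0.9, 0.6,
                   0.25, 0.55, 0.35, 0.95, 0.65))
  out <- displacement_brightness_correlation(tracked)
  expect_equal(out$rho, 1, tolerance = 1e-12)   # monotone relation

  hand <- tibble::tibble(
    displacement_mm = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    brightness = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  expect_equal(displacement_brightness_correlation(hand)$rho,
               cor(hand$displacement_mm, hand$brightness,
                   method = "spearman"),
               tolerance = 1e-12)

  expect_error(displacement_brightness_correlation(tracked[1:4, ]), "10")
})
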
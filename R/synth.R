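#' Map ultrasonic vibration amplitude to friction coefficient
#'
#' Ultrasonic lubrication reduces fingertip friction monotonically with the
#' flexural-wave amplitude. The map is an exponential decay pinned to the
#' two calibration anchors measured during steady sliding: \eqn{\mu = 0.81}
#' at the reference amplitude (\eqn{10^{-3}} micrometres, effectively no
#' lubrication) and \eqn{\mu = 0.18} at the maximal amplitude of 3
#' micrometres — a 78% relative reduction in friction.
#'
#' @param alpha_um Vibration amplitude(s), micrometres, non-negative.
#' @param mu_ref Friction coefficient at `alpha_ref` (default 0.81).
#' @param mu_max_alpha Friction coefficient at `alpha_max` (default 0.18).
#' @param alpha_ref,alpha_max Anchor amplitudes (micrometres).
#' @return Friction coefficient(s), same length as `alpha_um`.
#' @examples
#' alpha_to_mu(c(1e-3, 3))
#' @export
alpha_to_mu <- function(alpha_um, mu_ref = 0.81, mu_max_alpha = 0.18,
                        alpha_ref = 1e-3, alpha_max = 3) {
  if (any(!is.finite(alpha_um)) || any(alpha_um < 0)) {
    stop("`alpha_um` must be finite and non-negative", call. = FALSE)
  }
  lam <- log(mu_ref / mu_max_alpha) / (alpha_max - alpha_ref)
  mu_ref * exp(-lam * (alpha_um - alpha_ref))
}

#' Synthetic-trial generator configuration
#'
#' Bundles every knob of the synthetic press-trial generator with defaults
#' matching the statistics of the human experiment: peak normal force
#' 5.5 +/- 3.5 N, press duration 1.47 +/- 0.39 s, force rate 3.6 +/- 3 N/s
#' (each truncated to stay positive), 2AFC amplitudes 0.5–3 micrometres.
#'
#' @param seed Master seed; every trial derives an independent substream.
#' @param alpha_um Vibration amplitude of the trial (micrometres); sets the
#'   friction coefficient through [alpha_to_mu()].
#' @param size_px Side of the square image frames (pixels).
#' @param pixel_resolution_mm mm per pixel.
#' @param ridge_wavelength_mm Fingerprint ridge period (mm).
#' @param frame_rate_hz Camera frame rate.
#' @param force_rate_hz Force-channel sample rate.
#' @param divergence_gain True radial-expansion gain per newton at zero
#'   friction modulation: the generated in-contact displacement is
#'   \eqn{u_r = g_{\mathrm{eff}} F r} with
#'   \eqn{g_{\mathrm{eff}} = g/(1 + c_\mu \mu)}, so the true field
#'   divergence is \eqn{2 g_{\mathrm{eff}} F}.
#' @param mu_sensitivity \eqn{c_\mu}: how strongly friction suppresses the
#'   radial expansion.
#' @param peak_force_N,duration_s,force_rate_N_s Trial kinematics; `NA`
#'   (default) samples them from the experimental distributions, a number
#'   fixes them.
#' @param contact_radius_mm Apparent contact radius once the contact is
#'   fully established (mm). The default exceeds the camera field of view
#'   (as in a close-up view of the contact interior), so no tracked feature
#'   sits on the contact boundary; shrink it to study boundary effects.
#' @param contact_full_force_N Normal force at which the apparent contact
#'   has grown to its full radius; the gross footprint is established very
#'   early in a press (about 1 mm of indentation suffices), so this is a
#'   small fraction of the peak force.
#' @param trigger_force_N Normal force that triggers frame acquisition.
#'   Defaulting above `contact_full_force_N`, it makes every tracked
#'   feature's contact onset fall on the first frame, giving the generated
#'   displacement field a spatially constant true divergence
#'   \eqn{2(s(F) - s(F_{\mathrm{trig}}))/(1 + s(F_{\mathrm{trig}}))}.
#' @param real_contact_reduction Fractional reduction of the real contact
#'   area at the maximal amplitude (default 0.38).
#' @param image_noise_sd,force_noise_sd_N Additive Gaussian noise levels.
#' @param illumination_ramp Amplitude of the per-frame linear shading ramp
#'   (fraction of full scale).
#' @param brightness_sign +1 couples higher local brightness with larger
#'   displacement, -1 reverses the coupling (the brightness-convention
#'   ambiguity is left as a parameter).
#' @param n_features Feature budget the ridge texture is designed to
#'   support.
#' @param motion `"press"` (radial expansion driven by the force),
#'   `"translation"` (rigid motion by `translation_mm_per_frame`), or
#'   `"static"`.
#' @param translation_mm_per_frame Length-2 vector for `motion =
#'   "translation"`.
#' @param saturating If `TRUE`, the radial expansion saturates above 2 N
#'   (compression of the pulp flattens the divergence-force curve).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, alpha_um = 1e-3, size_px = 200,
                         pixel_resolution_mm = 0.05,
                         ridge_wavelength_mm = 0.5,
                         frame_rate_hz = 20, force_rate_hz = 1000,
                         divergence_gain = 0.012, mu_sensitivity = 1.2,
                         peak_force_N = NA_real_, duration_s = NA_real_,
                         force_rate_N_s = NA_real_,
                         contact_radius_mm = 7,
                         contact_full_force_N = 0.25,
                         trigger_force_N = 0.3,
                         real_contact_reduction = 0.38,
                         image_noise_sd = 0.02, force_noise_sd_N = 0.01,
                         illumination_ramp = 0.08, brightness_sign = 1,
                         n_features = 700, motion = "press",
                         translation_mm_per_frame = c(0.1, 0),
                         saturating = FALSE) {
  cfg <- as.list(environment())
  stopifnot(size_px >= 32, pixel_resolution_mm > 0,
            ridge_wavelength_mm > 0, frame_rate_hz > 0,
            image_noise_sd >= 0, force_noise_sd_N >= 0,
            motion %in% c("press", "translation", "static"))
  cfg$mu <- alpha_to_mu(alpha_um)
  class(cfg) <- "synth_config"
  cfg
}

# deterministic substream seed from a master seed and an index (kept below
# 2^31); splitting rule: multiplicative hash of (seed, index)
split_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 +
                12345) %% 2147483647)
}

#' Generate a synthetic fingerprint-ridge image
#'
#' A quasi-concentric ridge texture: a radial carrier at the configured
#' ridge wavelength, phase-modulated along the azimuth and overlaid with
#' band-passed speckle so that ridge intersections provide well-conditioned
#' corners for feature tracking (at the default settings at least 700
#' detectable features). Deterministic under the configuration seed.
#'
#' @param config A [synth_config()].
#' @param ridge_amplitude Contrast of the ridge carrier (0 gives a constant
#'   image).
#' @return A `size_px` x `size_px` numeric matrix in `[0, 1]`, quantised to
#'   8 bits (rows = image y, columns = image x).
#' @export
gen_ridge_image <- function(config, ridge_amplitude = 0.25) {
  n <- config$size_px
  set.seed(split_seed(config$seed, 1L))
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n, n)    # column index
  y <- matrix(rep(seq_len(n), times = n), n, n)   # row index
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  th <- atan2(y - cy, x - cx)
  lam_px <- config$ridge_wavelength_mm / config$pixel_resolution_mm
  phase <- 1.5 * sin(3 * th) + 0.8 * sin(7 * th + 1)
  ridges <- ridge_amplitude * cos(2 * pi * r / lam_px + phase)
  speckle <- matrix(rnorm(n * n), n, n)
  speckle <- blur_separable(speckle, sigma = lam_px / 6)
  speckle <- speckle / max(sd(speckle), 1e-12)
  pores <- matrix(rnorm(n * n), n, n)        # sweat-pore-scale detail
  pores <- blur_separable(pores, sigma = max(lam_px / 16, 0.6))
  pores <- pores / max(sd(pores), 1e-12)
  img <- 0.55 + ridges +
    if (ridge_amplitude > 0) 0.13 * speckle + 0.10 * pores else 0
  quantize8(img)
}

quantize8 <- function(img) round(pmin(pmax(img, 0), 1) * 255) / 255

# separable Gaussian blur with renormalised edges
blur_separable <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  kk <- exp(-0.5 * ((-half):half / sigma)^2)
  kk <- kk / sum(kk)
  pad_conv <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    out <- matrix(0, n1, n2)
    wsum <- matrix(0, n1, n2)
    for (o in (-half):half) {
      w <- kk[o + half + 1]
      src <- pmin(pmax(seq_len(n1) + o, 1L), n1)  # replicate edges
      out <- out + w * m[src, , drop = FALSE]
      wsum <- wsum + w
    }
    out / wsum
  }
  t(pad_conv(t(pad_conv(img))))
}

# smooth ramp-plateau force profile: initial slope = rate, plateau = peak
force_profile <- function(t, peak, rate) peak * tanh(rate * t / peak)

#' Generate a complete synthetic press trial with ground truth
#'
#' Emits a synchronized dual-channel image sequence (ridge channel for
#' feature tracking, contact channel for real-contact measurement), a
#' force trace, and a `truth` record holding everything the generator knows:
#' the per-frame true mean divergence (2 g_eff F), the warp parameters, the
#' true real-contact area, and the trial kinematics.
#'
#' The press kinematics emulate the experiment: the apparent contact grows
#' radially from the centre with the normal force; the in-contact skin
#' expands radially as \eqn{u_r = g_{\mathrm{eff}}\,F\,r}, with the gain
#' suppressed at higher friction; the real-contact intensity/density is
#' reduced with the vibration amplitude so that the peak real-contact area
#' at the maximal amplitude is `real_contact_reduction` (38%) below the
#' reference-amplitude trial by construction.
#'
#' @param config A [synth_config()].
#' @return A list of class `press_trial`: `frames` (list of
#'   `list(ridge, contact, t_s, fz_N)`), `force` (tibble `t_s`, `fx_N`,
#'   `fy_N`, `fz_N` at the force sample rate), `meta`, and `truth`.
#' @export
gen_press_trial <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(split_seed(config$seed, 2L))
  peak <- config$peak_force_N
  if (is.na(peak)) peak <- truncpos(rnorm(1, 5.5, 3.5), 0.5)
  dur <- config$duration_s
  if (is.na(dur)) dur <- truncpos(rnorm(1, 1.47, 0.39), 0.4)
  rate <- config$force_rate_N_s
  if (is.na(rate)) rate <- truncpos(rnorm(1, 3.6, 3), 0.8)

  n <- config$size_px
  res <- config$pixel_resolution_mm
  mu <- config$mu
  g_eff <- config$divergence_gain / (1 + config$mu_sensitivity * mu)

  # frame acquisition is triggered once the contact force passes the
  # trigger level; the force channel records the whole press from t = 0
  f_trig <- min(config$trigger_force_N, 0.9 * peak)
  t_trig <- if (f_trig > 0) (peak / rate) * atanh(f_trig / peak) else 0
  t_frames <- seq(t_trig, dur, by = 1 / config$frame_rate_hz)
  f_frames <- force_profile(t_frames, peak, rate)
  t_force <- seq(0, dur, by = 1 / config$force_rate_hz)
  f_force <- force_profile(t_force, peak, rate) +
    rnorm(length(t_force), 0, config$force_noise_sd_N)

  # the gross footprint is established early: the apparent contact radius
  # grows from the centre and saturates at contact_full_force_N
  a_mm <- config$contact_radius_mm *
    pmin(1, sqrt(pmax(f_frames, 0) / config$contact_full_force_N))
  a_px <- a_mm / res

  # real-contact speckle: blurred noise thresholded at a force- and
  # alpha-dependent fraction; reduction anchored at the max amplitude
  red <- config$real_contact_reduction *
    (alpha_to_mu(1e-3) - mu) / (alpha_to_mu(1e-3) - alpha_to_mu(3))
  base_frac <- 0.45
  spot <- blur_separable(matrix(rnorm(n * n), n, n), sigma = 0.8)
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xm <- matrix(rep(seq_len(n), each = n), n, n)
  ym <- matrix(rep(seq_len(n), times = n), n, n)
  rm2 <- (xm - cx)^2 + (ym - cy)^2

  ridge0 <- gen_ridge_image(config)
  warp_of_force <- function(f) {
    if (config$saturating) f <- 2 * tanh(f / 2)  # pulp saturates above ~2 N
    g_eff * f
  }
  frames <- vector("list", length(t_frames))
  true_div <- numeric(length(t_frames))
  true_area <- numeric(length(t_frames))
  s1 <- if (config$motion == "press") warp_of_force(f_frames[1]) else 0
  for (i in seq_along(t_frames)) {
    s <- warp_of_force(f_frames[i])
    # true divergence of the onset-referenced field, in frame-1 coordinates
    true_div[i] <- if (config$motion == "press") 2 * (s - s1) / (1 + s1)
                   else 0
    if (config$motion == "press") {
      # point at reference p maps to c + (1+s)(p-c); sample inverse map
      ridge <- warp_scale(ridge0, 1 / (1 + s), cx, cy)
    } else if (config$motion == "translation") {
      sh <- config$translation_mm_per_frame / res * (i - 1)
      ridge <- warp_shift(ridge0, sh[1], sh[2])
    } else {
      ridge <- ridge0
    }
    # radial density gradient carries the brightness/displacement coupling;
    # asperity density also grows mildly with the normal force
    dens_mod <- 1 + config$brightness_sign * 1.2 *
      (sqrt(rm2) / max(a_px[i], 1) - 0.5)
    grow <- 0.6 + 0.4 * f_frames[i] / peak
    frac <- base_frac * (1 - red) * grow * pmin(pmax(dens_mod, 0.05), 2)
    thr_map <- qnorm(1 - pmin(frac, 0.95), 0, max(sd(spot), 1e-12))
    inside <- rm2 <= a_px[i]^2
    bright <- inside & (spot > thr_map)
    true_area[i] <- sum(bright) * res^2
    contact <- matrix(0.05, n, n)
    contact[inside] <- 0.25
    contact[bright] <- 0.85
    # shared nuisances: illumination ramp + sensor noise, then 8-bit
    ang <- runif(1, 0, 2 * pi)
    ramp <- config$illumination_ramp *
      ((xm - cx) * cos(ang) + (ym - cy) * sin(ang)) / n
    noise1 <- matrix(rnorm(n * n, 0, config$image_noise_sd), n, n)
    noise2 <- matrix(rnorm(n * n, 0, config$image_noise_sd), n, n)
    frames[[i]] <- list(ridge = quantize8(ridge + ramp + noise1),
                        contact = quantize8(contact + ramp + noise2),
                        t_s = t_frames[i], fz_N = f_frames[i])
  }
  meta <- list(alpha_um = config$alpha_um, mu = mu,
               pixel_resolution_mm = res, frame_rate_hz = config$frame_rate_hz,
               size_px = n, seed = config$seed)
  truth <- list(divergence = tibble::tibble(t_s = t_frames, fz_N = f_frames,
                                            true_divergence = true_div,
                                            true_area_mm2 = true_area,
                                            contact_radius_mm = a_mm),
                g_eff = g_eff, warp_of_force = warp_of_force,
                center_px = c(cx, cy), peak_force_N = peak,
                duration_s = dur, force_rate_N_s = rate, mu = mu,
                s_first_frame = s1, trigger_force_N = f_trig)
  structure(list(frames = frames,
                 force = tibble::tibble(t_s = t_force,
                                        fx_N = 0, fy_N = 0, fz_N = f_force),
                 meta = meta, truth = truth),
            class = "press_trial")
}

truncpos <- function(x, lo) max(x, lo)

# rescale image about (cx, cy): output pixel p sampled at c + s*(p - c)
warp_scale <- function(img, s, cx, cy) {
  n1 <- nrow(img); n2 <- ncol(img)
  xm <- matrix(rep(seq_len(n2), each = n1), n1, n2)
  ym <- matrix(rep(seq_len(n1), times = n2), n1, n2)
  sample_bilinear(img, cx + s * (xm - cx), cy + s * (ym - cy))
}

warp_shift <- function(img, dx_px, dy_px) {
  n1 <- nrow(img); n2 <- ncol(img)
  xm <- matrix(rep(seq_len(n2), each = n1), n1, n2)
  ym <- matrix(rep(seq_len(n1), times = n2), n1, n2)
  sample_bilinear(img, xm - dx_px, ym - dy_px)
}

# bilinear sampling with edge clamping; x = column coord, y = row coord
sample_bilinear <- function(img, x, y) {
  n1 <- nrow(img); n2 <- ncol(img)
  x <- pmin(pmax(x, 1), n2); y <- pmin(pmax(y, 1), n1)
  x0 <- pmin(floor(x), n2 - 1); y0 <- pmin(floor(y), n1 - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * n1 + y0
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i00 + n1] +
    (1 - fx) * fy * img[i00 + 1] + fx * fy * img[i00 + n1 + 1]
  out <- x * 0 + v
  dim(out) <- dim(x)
  out
}

#' Simulate 2AFC responses from a known psychometric curve
#'
#' Bernoulli responses with success probability given by the configured
#' cumulative-Gaussian sigmoid (chance floor `guess`), for parameter-recovery
#' testing of [fit_psychometric()]. The generating curve is parameterised by
#' its threshold (the `threshold_p` point of the lapse-corrected curve) and
#' spread.
#'
#' @param threshold_um True discrimination threshold (micrometres).
#' @param spread_um True sigmoid spread (micrometres).
#' @param levels_um Comparison levels; default 0.5–3 in 0.5 steps.
#' @param reps Trials per level (default 10).
#' @param seed RNG seed.
#' @param guess,lapse,threshold_p Sigmoid floor/ceiling conventions, as in
#'   [fit_psychometric()].
#' @return A list: `responses` (tibble `level_um`, `chose_comparison`),
#'   `truth` (tibble of generating parameters and per-level true
#'   probabilities).
#' @export
gen_2afc_responses <- function(threshold_um = 1.13, spread_um = 1.0,
                               levels_um = seq(0.5, 3, by = 0.5),
                               reps = 10, seed = 1, guess = 0.5,
                               lapse = 0.02, threshold_p = 0.75) {
  stopifnot(reps >= 1, length(levels_um) >= 1)
  set.seed(seed)
  span <- 1 - guess - lapse
  m <- threshold_um - spread_um * qnorm((threshold_p - guess) / span)
  p <- guess + span * pnorm((levels_um - m) / spread_um)
  lev <- rep(levels_um, each = reps)
  pr <- rep(p, each = reps)
  resp <- rbinom(length(lev), 1, pr) == 1
  # presentation order was randomised in the experiment; shuffle rows
  ord <- sample.int(length(lev))
  list(responses = tibble::tibble(level_um = lev[ord],
                                  chose_comparison = resp[ord]),
       truth = tibble::tibble(level_um = levels_um, p_true = p,
                              threshold_um = threshold_um,
                              spread_um = spread_um, midpoint_um = m))
}
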
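#' Remove large-scale illumination gradients from a contact image
#'
#' Estimates the illumination background as a heavily smoothed copy of the
#' image (separable Gaussian, standard deviation `sigma` pixels) and
#' subtracts it, restoring the original mean level. A flat image is
#' returned unchanged; ridge-scale structure (much finer than `sigma`)
#' passes through while shading ramps are removed.
#'
#' @param image Numeric matrix in `[0, 1]` (rows = image y).
#' @param sigma Background smoothing scale in pixels; defaults to 1/16 of
#'   the larger image dimension.
#' @return Corrected image, clipped to `[0, 1]`.
#' @export
correct_illumination <- function(image, sigma = max(dim(image)) / 16) {
  stopifnot(is.matrix(image), length(image) > 0)
  bg <- blur_separable(image, sigma)
  pmin(pmax(image - bg + mean(image), 0), 1)
}

#' Otsu's threshold of an image or intensity sample
#'
#' The threshold maximising the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0 - \mu_1)^2} of the intensity histogram,
#' used to segment the asperities in intimate contact from the background.
#' When the data take few distinct values (for example 8-bit images) the
#' exact histogram over those values is used; otherwise intensities are
#' binned into `levels` equal-width bins. Deterministic: ties are broken
#' toward the lowest threshold.
#'
#' @param image Numeric matrix or vector of intensities with at least two
#'   distinct values.
#' @param levels Maximum number of histogram bins.
#' @return The threshold intensity; pixels strictly above it are classed
#'   as being in contact.
#' @export
otsu_threshold <- function(image, levels = 256) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  uv <- sort(unique(v))
  if (length(uv) < 2) {
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  }
  if (length(uv) <= levels) {
    mids <- uv
    counts <- tabulate(match(v, uv), nbins = length(uv))
  } else {
    br <- seq(min(uv), max(uv), length.out = levels + 1)
    idx <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1),
                levels)
    counts <- tabulate(idx, nbins = levels)
    mids <- (br[-1] + br[-length(br)]) / 2
  }
  k <- otsu_split(counts, mids)
  (mids[k] + mids[k + 1]) / 2
}

# index k maximising between-class variance when splitting after bin k
otsu_split <- function(counts, mids) {
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[length(w)]
  mt <- m[length(m)]
  kk <- seq_len(length(counts) - 1)
  w0 <- w[kk]; w1 <- n - w0
  bcv <- ifelse(w0 == 0 | w1 == 0, -Inf,
                (n * m[kk] - mt * w0)^2 / (w0 * w1))
  which.max(bcv)
}

#' Real area of contact from the coaxial-illumination channel
#'
#' Thresholds the contact image (Otsu by default) and sums the bright
#' pixels — the asperities in intimate contact — scaled by the pixel
#' resolution: area = count × resolution².
#'
#' @param contact_image Numeric matrix, contact = bright.
#' @param pixel_resolution_mm mm per pixel.
#' @param threshold Optional fixed threshold; default [otsu_threshold()].
#' @return Contact area in mm².
#' @export
real_contact_area <- function(contact_image, pixel_resolution_mm,
                              threshold = NULL) {
  stopifnot(pixel_resolution_mm > 0)
  if (is.null(threshold)) threshold <- otsu_threshold(contact_image)
  sum(contact_image > threshold) * pixel_resolution_mm^2
}

#' Mean local brightness around a point
#'
#' Mean intensity over the discrete disk of radius `radius_px` centred on
#' each `(x_px, y_px)` point — the per-feature measure of the local density
#' of asperities in intimate contact, also used for contact-onset
#' detection.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param x_px,y_px Point coordinates in pixels (may be vectors).
#' @param radius_px Disk radius in pixels.
#' @param clip If `TRUE`, points whose disk overhangs the image border use
#'   the in-bounds part of the disk; if `FALSE` (default) such points are
#'   an error.
#' @return Vector of mean intensities.
#' @export
local_brightness <- function(image, x_px, y_px, radius_px = 10,
                             clip = FALSE) {
  stopifnot(is.matrix(image), length(x_px) == length(y_px))
  n1 <- nrow(image); n2 <- ncol(image)
  r <- floor(radius_px)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius_px^2, ]
  out <- numeric(length(x_px))
  for (i in seq_along(x_px)) {
    xs <- round(x_px[i]) + off$dx
    ys <- round(y_px[i]) + off$dy
    inb <- xs >= 1 & xs <= n2 & ys >= 1 & ys <= n1
    if (!all(inb) && !clip) {
      stop("point ", i, " closer than radius_px to the image border",
           call. = FALSE)
    }
    if (!any(inb)) stop("point ", i, " outside the image", call. = FALSE)
    out[i] <- mean(image[cbind(ys[inb], xs[inb])])
  }
  out
}

#' Zero-lag second-order low-pass filtering of a force signal
#'
#' Butterworth low-pass of the given order and cutoff applied forward and
#' backward ([signal::filtfilt()]), so the passband is preserved with zero
#' phase lag and the effective magnitude response is squared. DC gain is 1.
#'
#' @param force Numeric vector, or a data frame whose `fx_N`, `fy_N`,
#'   `fz_N` columns are each filtered.
#' @param sample_rate_hz Uniform sampling rate, must exceed 100 Hz.
#' @param cutoff_hz Cutoff frequency (default 50 Hz).
#' @param order Filter order (default 2).
#' @return Same shape as the input, filtered.
#' @export
filter_force <- function(force, sample_rate_hz, cutoff_hz = 50, order = 2) {
  stopifnot(sample_rate_hz > 100, cutoff_hz > 0,
            cutoff_hz < sample_rate_hz / 2)
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), "low")
  apply1 <- function(x) {
    n <- length(x)
    if (n < 24) {
      stop("force series too short for zero-lag filtering", call. = FALSE)
    }
    # detrend through the end points (restored afterwards: exact DC gain)
    # and mirror-pad so the forward/backward start-up transients decay
    # outside the retained window
    trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
    r <- x - trend
    npad <- min(n - 1, as.integer(ceiling(6 * sample_rate_hz / cutoff_hz)))
    head_pad <- 2 * r[1] - r[(npad + 1):2]
    tail_pad <- 2 * r[n] - r[(n - 1):(n - npad)]
    y <- as.numeric(signal::filtfilt(bf, c(head_pad, r, tail_pad)))
    y[(npad + 1):(npad + n)] + trend
  }
  if (is.data.frame(force)) {
    for (cl in intersect(c("fx_N", "fy_N", "fz_N"), names(force))) {
      force[[cl]] <- apply1(force[[cl]])
    }
    tibble::as_tibble(force)
  } else {
    apply1(force)
  }
}

#' Detect salient fingerprint features (minimum-eigenvalue corners)
#'
#' Shi–Tomasi-style corner detection: image gradients are accumulated into
#' the local structure tensor and the smaller tensor eigenvalue scores each
#' pixel; local maxima are thinned to at most one feature per
#' `min_distance` cell and the strongest `n_features` are kept.
#'
#' @param image Numeric matrix.
#' @param n_features Maximum number of features (default 700, the tracking
#'   budget of the analysis).
#' @param min_distance Minimum spacing between features, px.
#' @param margin Border margin excluded from detection, px.
#' @param smooth_sigma Pre-smoothing of the image before gradients, px.
#' @param tensor_sigma Structure-tensor integration scale, px.
#' @return Tibble `x_px`, `y_px`, `score`, strongest first.
#' @export
detect_features <- function(image, n_features = 700, min_distance = 3,
                            margin = 12, smooth_sigma = 1,
                            tensor_sigma = 1.2) {
  stopifnot(is.matrix(image))
  sm <- blur_separable(image, smooth_sigma)
  gi <- grad_xy(sm)
  sxx <- blur_separable(gi$gx^2, tensor_sigma)
  syy <- blur_separable(gi$gy^2, tensor_sigma)
  sxy <- blur_separable(gi$gx * gi$gy, tensor_sigma)
  tr2 <- (sxx + syy) / 2
  det2 <- sqrt(pmax(((sxx - syy) / 2)^2 + sxy^2, 0))
  lmin <- tr2 - det2
  n1 <- nrow(image); n2 <- ncol(image)
  lmin[seq_len(min(margin, n1)), ] <- -Inf
  lmin[seq(max(n1 - margin + 1, 1), n1), ] <- -Inf
  lmin[, seq_len(min(margin, n2))] <- -Inf
  lmin[, seq(max(n2 - margin + 1, 1), n2)] <- -Inf
  # 3x3 non-maximum suppression
  mx <- lmin
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- shift2(lmin, dx, dy, fill = -Inf)
    mx <- pmax(mx, sh)
  }
  peak <- which(lmin >= mx & is.finite(lmin) & lmin > 0)
  if (length(peak) == 0) {
    stop("feature-poor input: no corners detected", call. = FALSE)
  }
  ys <- (peak - 1) %% n1 + 1
  xs <- (peak - 1) %/% n1 + 1
  sc <- lmin[peak]
  ord <- order(-sc)
  ys <- ys[ord]; xs <- xs[ord]; sc <- sc[ord]
  # one feature per min_distance cell, strongest kept
  cell <- paste(xs %/% min_distance, ys %/% min_distance)
  keep <- !duplicated(cell)
  ys <- ys[keep]; xs <- xs[keep]; sc <- sc[keep]
  nkeep <- min(n_features, length(xs))
  tibble::tibble(x_px = as.numeric(xs[seq_len(nkeep)]),
                 y_px = as.numeric(ys[seq_len(nkeep)]),
                 score = sc[seq_len(nkeep)])
}

grad_xy <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  gx <- (shift2(img, -1, 0, edge = TRUE) - shift2(img, 1, 0, edge = TRUE)) / 2
  gy <- (shift2(img, 0, -1, edge = TRUE) - shift2(img, 0, 1, edge = TRUE)) / 2
  list(gx = gx, gy = gy)
}

# shift image by (dx, dy) pixels: out(x) = img(x - dx); edge replicate or fill
shift2 <- function(img, dx, dy, fill = 0, edge = FALSE) {
  n1 <- nrow(img); n2 <- ncol(img)
  rows <- seq_len(n1) - dy
  cols <- seq_len(n2) - dx
  if (edge) {
    rows <- pmin(pmax(rows, 1), n1)
    cols <- pmin(pmax(cols, 1), n2)
    img[rows, cols, drop = FALSE]
  } else {
    out <- matrix(fill, n1, n2)
    rok <- rows >= 1 & rows <= n1
    cok <- cols >= 1 & cols <= n2
    out[rok, cok] <- img[rows[rok], cols[cok], drop = FALSE]
    out
  }
}

#' Track fingerprint features through a press trial
#'
#' Detects up to `n_features` corners on the first ridge frame and follows
#' them frame to frame with an iterative, two-level pyramidal local
#' optical-flow (Lucas–Kanade) tracker. Tracking runs from the first frame
#' until the normal force reaches `stop_force_N` (or the force peak for
#' trials that never get there). Each point's displacement is referenced to
#' its contact onset: the first frame at which the local brightness of the
#' contact channel around the point exceeds `onset_fraction` of that
#' point's maximum over the trial. Lost tracks (ill-conditioned texture,
#' divergence, or drifting off the image) are dropped and counted.
#'
#' @param trial A `press_trial` from [gen_press_trial()] or [read_trial()].
#' @param n_features Feature budget (default 700).
#' @param window_half Half-width of the tracking window, px.
#' @param n_levels Pyramid levels (1 or 2).
#' @param max_iter Optical-flow iterations per level.
#' @param onset_fraction Contact-onset brightness fraction.
#' @param min_brightness Absolute brightness floor: points whose peak local
#'   contact brightness never exceeds this never made contact and are
#'   dropped from the displacement analysis.
#' @param stop_force_N Tracking stops once the normal force reaches this
#'   value (default 3 N).
#' @param brightness_radius_px Radius of the local-brightness disk.
#' @return A tibble, one row per surviving feature: reference and final
#'   positions (px), onset frame and position, displacement in mm (`ux_mm`,
#'   `uy_mm`, `displacement_mm`), onset-position coordinates in mm (`x_mm`,
#'   `y_mm`) ready for [grid_interpolate()], and `brightness` (local
#'   contact brightness at the final frame). Attributes: `n_lost`,
#'   `stop_frame`, `stop_force_N`.
#' @export
track_features <- function(trial, n_features = 700, window_half = 7,
                           n_levels = 2, max_iter = 12,
                           onset_fraction = 0.5, min_brightness = 0.15,
                           stop_force_N = 3,
                           brightness_radius_px = 10) {
  frames <- trial$frames
  if (length(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  fz <- vapply(frames, function(f) f$fz_N, numeric(1))
  stop_i <- which(fz >= stop_force_N)[1]
  if (is.na(stop_i)) stop_i <- which.max(fz)
  stop_i <- max(stop_i, 2L)
  res <- trial$meta$pixel_resolution_mm

  ridge <- lapply(frames[seq_len(stop_i)], function(f) f$ridge)
  feats <- detect_features(ridge[[1]], n_features = n_features)
  n <- nrow(feats)
  pos <- array(NA_real_, c(n, 2, stop_i))
  pos[, , 1] <- cbind(feats$x_px, feats$y_px)
  alive <- rep(TRUE, n)
  for (t in 2:stop_i) {
    prev <- pos[, , t - 1]
    cur <- lk_track(ridge[[t - 1]], ridge[[t]], prev, alive,
                    window_half = window_half, n_levels = n_levels,
                    max_iter = max_iter)
    alive <- alive & cur$ok
    pos[, , t] <- cur$pos
  }
  # onset from the contact-channel brightness history of each point; a
  # tight (2 px) probe decides whether the point itself ever lies inside
  # the apparent contact, the 10 px disk gives the reported brightness
  bright <- matrix(NA_real_, n, stop_i)
  probe <- matrix(NA_real_, n, stop_i)
  for (t in seq_len(stop_i)) {
    p <- pos[, , t]
    idx <- which(alive)
    bright[idx, t] <- local_brightness(frames[[t]]$contact,
                                       p[idx, 1], p[idx, 2],
                                       radius_px = brightness_radius_px,
                                       clip = TRUE)
    probe[idx, t] <- local_brightness(frames[[t]]$contact,
                                      p[idx, 1], p[idx, 2],
                                      radius_px = 2, clip = TRUE)
  }
  onset <- rep(NA_integer_, n)
  for (i in which(alive)) {
    if (max(probe[i, ]) < min_brightness) next   # never made contact
    bmax <- max(bright[i, ])
    onset[i] <- which(bright[i, ] > onset_fraction * bmax)[1]
  }
  ok <- alive & !is.na(onset)
  n_lost <- n - sum(ok)
  idx <- which(ok)
  ux <- (pos[idx, 1, stop_i] - pos[cbind(idx, 1, onset[idx])]) * res
  uy <- (pos[idx, 2, stop_i] - pos[cbind(idx, 2, onset[idx])]) * res
  out <- tibble::tibble(
    feature = idx,
    x0_px = pos[idx, 1, 1], y0_px = pos[idx, 2, 1],
    onset_frame = onset[idx],
    x_onset_px = pos[cbind(idx, 1, onset[idx])],
    y_onset_px = pos[cbind(idx, 2, onset[idx])],
    x_final_px = pos[idx, 1, stop_i], y_final_px = pos[idx, 2, stop_i],
    ux_mm = ux, uy_mm = uy,
    displacement_mm = sqrt(ux^2 + uy^2),
    x_mm = pos[cbind(idx, 1, onset[idx])] * res,
    y_mm = pos[cbind(idx, 2, onset[idx])] * res,
    brightness = bright[idx, stop_i])
  attr(out, "n_lost") <- n_lost
  attr(out, "stop_frame") <- stop_i
  attr(out, "stop_force_N") <- fz[stop_i]
  attr(out, "pixel_resolution_mm") <- res
  out
}

# iterative Lucas-Kanade step for all alive features, with optional
# coarse-to-fine pyramid; returns updated positions and validity
lk_track <- function(img0, img1, pos, alive, window_half = 7,
                     n_levels = 2, max_iter = 12) {
  n1 <- nrow(img0); n2 <- ncol(img0)
  pyr0 <- list(img0); pyr1 <- list(img1)
  if (n_levels >= 2 && min(n1, n2) >= 64) {
    down <- function(m) {
      b <- blur_separable(m, 1)
      b[seq(1, nrow(b), 2), seq(1, ncol(b), 2)]
    }
    pyr0[[2]] <- down(img0); pyr1[[2]] <- down(img1)
  }
  nlev <- length(pyr0)
  np <- nrow(pos)
  d <- matrix(0, np, 2)          # displacement estimate
  idx <- which(alive)
  if (length(idx) == 0) {
    return(list(pos = pos, ok = rep(FALSE, np)))
  }
  off <- expand.grid(ox = -window_half:window_half,
                     oy = -window_half:window_half)
  ok <- alive
  for (lev in nlev:1) {
    sc <- 2^(lev - 1)
    a0 <- pyr0[[lev]]; a1 <- pyr1[[lev]]
    g <- grad_xy(a0)
    p <- pos[idx, , drop = FALSE] / sc
    dd <- d[idx, , drop = FALSE] / sc
    # template and its gradients at the level-scaled positions
    X0 <- outer(p[, 1], rep(1, nrow(off))) +
      outer(rep(1, length(idx)), off$ox)
    Y0 <- outer(p[, 2], rep(1, nrow(off))) +
      outer(rep(1, length(idx)), off$oy)
    Tm <- sample_bilinear(a0, X0, Y0)
    Gx <- sample_bilinear(g$gx, X0, Y0)
    Gy <- sample_bilinear(g$gy, X0, Y0)
    gxx <- rowSums(Gx * Gx); gyy <- rowSums(Gy * Gy)
    gxy <- rowSums(Gx * Gy)
    det <- gxx * gyy - gxy^2
    good <- det > 1e-12 & (gxx + gyy) / 2 -
      sqrt(pmax(((gxx - gyy) / 2)^2 + gxy^2, 0)) > 1e-6
    for (it in seq_len(max_iter)) {
      I1 <- sample_bilinear(a1, X0 + dd[, 1], Y0 + dd[, 2])
      er <- Tm - I1
      bx <- rowSums(Gx * er); by <- rowSums(Gy * er)
      sx <- (gyy * bx - gxy * by) / pmax(det, 1e-12)
      sy <- (gxx * by - gxy * bx) / pmax(det, 1e-12)
      sx[!good] <- 0; sy[!good] <- 0
      dd[, 1] <- dd[, 1] + sx
      dd[, 2] <- dd[, 2] + sy
      if (max(abs(c(sx, sy))) < 0.005) break
    }
    ok_lev <- rep(TRUE, length(idx))
    ok_lev[!good] <- FALSE
    maxd <- 3 * (window_half + 2)
    ok_lev[abs(dd[, 1]) > maxd | abs(dd[, 2]) > maxd] <- FALSE
    ok[idx[!ok_lev]] <- FALSE
    d[idx, ] <- dd * sc
  }
  newpos <- pos + d
  m <- window_half + 2
  inb <- newpos[, 1] >= m & newpos[, 1] <= n2 - m + 1 &
    newpos[, 2] >= m & newpos[, 2] <= n1 - m + 1
  ok <- ok & inb & alive
  list(pos = newpos, ok = ok)
}

#' Correlation between feature displacement and local contact brightness
#'
#' Spearman rank correlation (ties mid-ranked) between each tracked
#' point's displacement magnitude and the local brightness of the contact
#' channel around it — the microscale link between asperity contact
#' density and lateral skin mobility.
#'
#' @param tracked A tibble from [track_features()] (columns
#'   `displacement_mm`, `brightness`), with at least 10 rows.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
displacement_brightness_correlation <- function(tracked) {
  stopifnot(is.data.frame(tracked),
            all(c("displacement_mm", "brightness") %in% names(tracked)))
  d <- tracked$displacement_mm; b <- tracked$brightness
  keep <- is.finite(d) & is.finite(b)
  d <- d[keep]; b <- b[keep]
  if (length(d) < 10) stop("need at least 10 tracked points", call. = FALSE)
  if (sd(d) == 0 || sd(b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(d, b, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(d))
}
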
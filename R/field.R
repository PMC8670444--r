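#' Construct a gridded displacement field
#'
#' A displacement field is the central container of the analysis: the two
#' in-plane components of skin displacement sampled on a uniform rectangular
#' grid, together with a boolean mask `mask` marking the apparent contact
#' area over which every summary (mean divergence, strain, energy) is taken.
#'
#' @param df Data frame with columns `x_mm`, `y_mm`, `ux_mm`, `uy_mm`,
#'   `mask`. Rows must cover a complete regular grid (every combination of
#'   the unique x and y coordinates present exactly once). Displacements may
#'   be `NA` outside the mask but must be finite inside it.
#' @param pixel_resolution Provenance tag, mm per pixel of the source images
#'   (optional).
#' @param timestamp Frame time in seconds (optional).
#' @return A tibble of class `displacement_field` with grid metadata stored
#'   in attributes (`nx`, `ny`, `dx`, `dy`).
#' @export
displacement_field <- function(df, pixel_resolution = NA_real_,
                               timestamp = NA_real_) {
  stopifnot(is.data.frame(df),
            all(c("x_mm", "y_mm", "ux_mm", "uy_mm", "mask") %in% names(df)))
  xs <- sort(unique(df$x_mm))
  ys <- sort(unique(df$y_mm))
  nx <- length(xs); ny <- length(ys)
  if (nrow(df) != nx * ny) {
    stop("grid is incomplete: expected ", nx * ny, " cells, got ", nrow(df),
         call. = FALSE)
  }
  dx <- if (nx > 1) diff(xs) else 1
  dy <- if (ny > 1) diff(ys) else 1
  if (nx > 1 && max(abs(dx - dx[1])) > 1e-8 * abs(dx[1])) {
    stop("x grid is not uniform", call. = FALSE)
  }
  if (ny > 1 && max(abs(dy - dy[1])) > 1e-8 * abs(dy[1])) {
    stop("y grid is not uniform", call. = FALSE)
  }
  if (!any(df$mask)) stop("mask is empty", call. = FALSE)
  bad <- df$mask & (!is.finite(df$ux_mm) | !is.finite(df$uy_mm))
  if (any(bad)) {
    stop("non-finite displacements inside the contact mask", call. = FALSE)
  }
  out <- tibble::as_tibble(df[order(df$y_mm, df$x_mm),
                              c("x_mm", "y_mm", "ux_mm", "uy_mm", "mask")])
  structure(out,
            class = c("displacement_field", class(out)),
            nx = nx, ny = ny, dx = dx[1], dy = dy[1],
            pixel_resolution = pixel_resolution,
            timestamp = timestamp)
}

# reshape a displacement_field into nx-by-ny matrices (rows index x)
field_mats <- function(field) {
  nx <- attr(field, "nx"); ny <- attr(field, "ny")
  list(ux = matrix(field$ux_mm, nx, ny),
       uy = matrix(field$uy_mm, nx, ny),
       mask = matrix(field$mask, nx, ny),
       x = matrix(field$x_mm, nx, ny),
       y = matrix(field$y_mm, nx, ny),
       dx = attr(field, "dx"), dy = attr(field, "dy"),
       nx = nx, ny = ny)
}

# masked finite difference along dimension 1 (x) or 2 (y): central where
# both neighbours are masked, one-sided where only one is, invalid where
# neither is. Values outside the mask never enter the stencil.
masked_gradient <- function(v, mask, h, dim) {
  n1 <- nrow(v); n2 <- ncol(v)
  shift <- function(m, by) {
    out <- matrix(NA_real_, n1, n2)
    if (dim == 1) {
      if (by > 0) out[(1 + by):n1, ] <- m[1:(n1 - by), ]
      else out[1:(n1 + by), ] <- m[(1 - by):n1, ]
    } else {
      if (by > 0) out[, (1 + by):n2] <- m[, 1:(n2 - by)]
      else out[, 1:(n2 + by)] <- m[, (1 - by):n2]
    }
    out
  }
  mnum <- mask * 1
  vp <- shift(v, -1); mp <- shift(mnum, -1); mp[is.na(mp)] <- 0
  vm <- shift(v, 1);  mm <- shift(mnum, 1);  mm[is.na(mm)] <- 0
  g <- matrix(NA_real_, n1, n2)
  both <- mask & mp == 1 & mm == 1
  fwd <- mask & mp == 1 & mm == 0
  bwd <- mask & mp == 0 & mm == 1
  g[both] <- (vp[both] - vm[both]) / (2 * h)
  g[fwd] <- (vp[fwd] - v[fwd]) / h
  g[bwd] <- (v[bwd] - vm[bwd]) / h
  list(g = g, valid = both | fwd | bwd)
}

#' Mean divergence of a displacement field
#'
#' Computes \eqn{\nabla\cdot u = \partial u_x/\partial x +
#' \partial u_y/\partial y} by finite differences on the masked grid
#' (central differences in the interior, one-sided at mask boundaries) and
#' averages it over the apparent contact area. A positive value means the
#' skin expands radially outward; the divergence is invariant to adding any
#' rigid translation and vanishes for rigid rotations.
#'
#' @param field A [displacement_field()].
#' @param total If `TRUE`, return the raw area integral
#'   \eqn{\int_S \nabla\cdot u\, dS} (mm^2) instead of the area-normalised
#'   mean (dimensionless, the default).
#' @return A single number.
#' @export
mean_divergence <- function(field, total = FALSE) {
  m <- field_mats(field)
  gx <- masked_gradient(m$ux, m$mask, m$dx, 1)
  gy <- masked_gradient(m$uy, m$mask, m$dy, 2)
  valid <- gx$valid & gy$valid
  if (!any(valid)) {
    stop("contact mask has no cell with enough neighbours to difference",
         call. = FALSE)
  }
  div <- gx$g[valid] + gy$g[valid]
  if (total) sum(div) * m$dx * m$dy else mean(div)
}

#' Per-cell divergence map
#'
#' @inheritParams mean_divergence
#' @return A tibble `x_mm`, `y_mm`, `divergence` restricted to masked cells
#'   where a finite-difference stencil exists.
#' @export
divergence_map <- function(field) {
  m <- field_mats(field)
  gx <- masked_gradient(m$ux, m$mask, m$dx, 1)
  gy <- masked_gradient(m$uy, m$mask, m$dy, 2)
  valid <- gx$valid & gy$valid
  tibble::tibble(x_mm = m$x[valid], y_mm = m$y[valid],
                 divergence = gx$g[valid] + gy$g[valid])
}

#' Grid scattered tracked-feature displacements
#'
#' Interpolates per-feature displacements, measured at scattered image
#' locations, onto a uniform rectangular grid. Each grid node inside the
#' convex hull of the features receives the value of a local least-squares
#' plane fitted through its `k` nearest features (a moving-least-squares
#' scheme): affine displacement fields are therefore reproduced exactly, and
#' smooth fields converge at second order in the feature spacing. Nodes
#' outside the convex hull are masked out, never extrapolated.
#'
#' @param points Data frame with columns `x_mm`, `y_mm`, `ux_mm`, `uy_mm`;
#'   at least 3 non-collinear rows.
#' @param nx,ny Grid resolution (number of nodes along x and y).
#' @param k Number of nearest neighbours used in each local plane fit.
#' @param pixel_resolution,timestamp Passed through to the field's metadata.
#' @return A [displacement_field()] whose mask is the convex hull of the
#'   input features.
#' @export
grid_interpolate <- function(points, nx = 64, ny = 64, k = 12,
                             pixel_resolution = NA_real_,
                             timestamp = NA_real_) {
  stopifnot(is.data.frame(points),
            all(c("x_mm", "y_mm", "ux_mm", "uy_mm") %in% names(points)))
  pts <- points[is.finite(points$x_mm) & is.finite(points$y_mm), ]
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 tracked points", call. = FALSE)
  P <- cbind(pts$x_mm, pts$y_mm)
  # collinearity check via the smaller singular value of the centred cloud
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1)) {
    stop("tracked points are collinear; cannot triangulate a field",
         call. = FALSE)
  }
  hull <- chull(P)
  hx <- P[hull, 1]; hy <- P[hull, 2]
  xs <- seq(min(P[, 1]), max(P[, 1]), length.out = nx)
  ys <- seq(min(P[, 2]), max(P[, 2]), length.out = ny)
  grid <- expand.grid(x_mm = xs, y_mm = ys, KEEP.OUT.ATTRS = FALSE)
  inside <- in_convex_hull(grid$x_mm, grid$y_mm, hx, hy)
  k <- min(k, n)
  ux <- rep(NA_real_, nrow(grid)); uy <- rep(NA_real_, nrow(grid))
  idx_in <- which(inside)
  for (ii in idx_in) {
    gx <- grid$x_mm[ii]; gy <- grid$y_mm[ii]
    d2 <- (P[, 1] - gx)^2 + (P[, 2] - gy)^2
    nb <- order(d2)[seq_len(k)]
    A <- cbind(1, P[nb, 1] - gx, P[nb, 2] - gy)
    fit <- tryCatch(qr.coef(qr(A), cbind(pts$ux_mm[nb], pts$uy_mm[nb])),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit[1, ])) {
      # degenerate neighbourhood: fall back to inverse-distance weights
      w <- 1 / pmax(d2[nb], 1e-12)
      ux[ii] <- sum(w * pts$ux_mm[nb]) / sum(w)
      uy[ii] <- sum(w * pts$uy_mm[nb]) / sum(w)
    } else {
      ux[ii] <- fit[1, 1]
      uy[ii] <- fit[1, 2]
    }
  }
  displacement_field(
    tibble::tibble(x_mm = grid$x_mm, y_mm = grid$y_mm,
                   ux_mm = ux, uy_mm = uy, mask = inside),
    pixel_resolution = pixel_resolution, timestamp = timestamp)
}

# point-in-convex-polygon (vertices in chull order) with boundary included
in_convex_hull <- function(px, py, hx, hy) {
  nh <- length(hx)
  j <- c(2:nh, 1)
  sgn <- sign(sum(hx * hy[j] - hx[j] * hy))  # shoelace orientation
  if (sgn == 0) return(rep(FALSE, length(px)))
  res <- rep(TRUE, length(px))
  for (i in seq_len(nh)) {
    jj <- j[i]
    cr <- (hx[jj] - hx[i]) * (py - hy[i]) - (hy[jj] - hy[i]) * (px - hx[i])
    tol <- 1e-9 * (abs(hx[jj] - hx[i]) + abs(hy[jj] - hy[i]) + 1)
    res <- res & (sgn * cr >= -tol)
  }
  res
}

#' Global (rigid) displacement of the contact and trial-exclusion flag
#'
#' The rigid component of the skin motion is summarised by the median
#' displacement vector over the apparent contact area. Trials in which its
#' magnitude exceeds `threshold_mm` (default 0.3 mm) are flagged for
#' exclusion from the divergence analysis, so that gross lateral sliding of
#' the whole contact cannot masquerade as a radial-expansion cue.
#'
#' @inheritParams mean_divergence
#' @param threshold_mm Exclusion threshold on the median-displacement
#'   magnitude (mm).
#' @return One-row tibble: `gx_mm`, `gy_mm` (median vector),
#'   `magnitude_mm`, `excluded` (logical).
#' @export
global_displacement <- function(field, threshold_mm = 0.3) {
  gx <- median(field$ux_mm[field$mask])
  gy <- median(field$uy_mm[field$mask])
  mag <- sqrt(gx^2 + gy^2)
  tibble::tibble(gx_mm = gx, gy_mm = gy, magnitude_mm = mag,
                 excluded = mag > threshold_mm)
}

#' Infinitesimal strain components of a displacement field
#'
#' Strain tensor components from the displacement gradients on the masked
#' grid: \eqn{\epsilon_{xx} = \partial u_x/\partial x},
#' \eqn{\epsilon_{yy} = \partial u_y/\partial y},
#' \eqn{\epsilon_{xy} = (\partial u_x/\partial y +
#' \partial u_y/\partial x)/2}, plus the principal strains. To first order
#' the strains are invariant under rigid translations and small rotations.
#'
#' @inheritParams mean_divergence
#' @return A tibble with one row per masked grid cell where gradients exist:
#'   `x_mm`, `y_mm`, `eps_xx`, `eps_yy`, `eps_xy`, `principal_max`,
#'   `principal_min` (all dimensionless).
#' @export
strain_components <- function(field) {
  m <- field_mats(field)
  dux_dx <- masked_gradient(m$ux, m$mask, m$dx, 1)
  dux_dy <- masked_gradient(m$ux, m$mask, m$dy, 2)
  duy_dx <- masked_gradient(m$uy, m$mask, m$dx, 1)
  duy_dy <- masked_gradient(m$uy, m$mask, m$dy, 2)
  valid <- dux_dx$valid & dux_dy$valid & duy_dx$valid & duy_dy$valid
  if (!any(valid)) stop("mask too small to form strain gradients",
                        call. = FALSE)
  exx <- dux_dx$g[valid]
  eyy <- duy_dy$g[valid]
  exy <- 0.5 * (dux_dy$g[valid] + duy_dx$g[valid])
  ctr <- (exx + eyy) / 2
  rad <- sqrt(((exx - eyy) / 2)^2 + exy^2)
  tibble::tibble(x_mm = m$x[valid], y_mm = m$y[valid],
                 eps_xx = exx, eps_yy = eyy, eps_xy = exy,
                 principal_max = ctr + rad, principal_min = ctr - rad)
}

#' Longitudinal strain of a frame, in percent
#'
#' The longitudinal strain reported for a frame is the largest principal
#' strain magnitude over the apparent contact area, expressed in percent —
#' the quantity compared against mechanoreceptor activation thresholds
#' (roughly 2–4% strain).
#'
#' @inheritParams mean_divergence
#' @return Scalar strain in percent.
#' @export
longitudinal_strain <- function(field) {
  sc <- strain_components(field)
  100 * max(pmax(abs(sc$principal_max), abs(sc$principal_min)))
}

#' Strain-rate series of a press trial
#'
#' Longitudinal strain per frame, its time derivative by central
#' differences, the peak strain rate, and the normal force interpolated at
#' the instant of the peak. A strain rate above roughly 8%/s is the
#' literature threshold for driving every tactile afferent type.
#'
#' @param fields A list of [displacement_field()]s with `timestamp`
#'   attributes in strictly increasing order.
#' @param force Optional data frame `t_s`, `fz_N` used to read off the force
#'   at the strain-rate peak.
#' @return A list with `series` (tibble `t_s`, `strain_pct`,
#'   `strain_rate_pct_s`), `peak_rate_pct_s`, `t_peak_s`, `force_at_peak_N`.
#' @export
strain_rate_series <- function(fields, force = NULL) {
  if (length(fields) < 2) {
    stop("need at least 2 frames to form a strain rate", call. = FALSE)
  }
  ts <- vapply(fields, function(f) attr(f, "timestamp"), numeric(1))
  if (anyNA(ts) || any(diff(ts) <= 0)) {
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  }
  s <- vapply(fields, longitudinal_strain, numeric(1))
  n <- length(s)
  rate <- numeric(n)
  rate[1] <- (s[2] - s[1]) / (ts[2] - ts[1])
  rate[n] <- (s[n] - s[n - 1]) / (ts[n] - ts[n - 1])
  if (n > 2) {
    rate[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (ts[3:n] - ts[1:(n - 2)])
  }
  ipk <- which.max(rate)
  f_at <- NA_real_
  if (!is.null(force)) {
    f_at <- approx(force$t_s, force$fz_N, xout = ts[ipk], rule = 2)$y
  }
  list(series = tibble::tibble(t_s = ts, strain_pct = s,
                               strain_rate_pct_s = rate),
       peak_rate_pct_s = rate[ipk], t_peak_s = ts[ipk],
       force_at_peak_N = f_at)
}

#' Elastic strain energy stored in the skin layer
#'
#' Plane-stress linear-elastic energy of the masked displacement field,
#' integrated over the contact area and a nominal skin thickness:
#' \deqn{U = \frac{t}{2}\int_S \sigma : \epsilon \; dS}
#' with \eqn{\sigma} from the plane-stress Hooke law. With the modulus in
#' MPa (N/mm^2), lengths in mm and strains dimensionless the result is in
#' N·mm, i.e. millijoules. Defaults (E = 0.1 MPa, \eqn{\nu} = 0.4,
#' t = 1.5 mm) are typical of fingertip skin in compression.
#'
#' @inheritParams mean_divergence
#' @param modulus_mpa Elastic modulus of skin (MPa).
#' @param thickness_mm Effective skin-layer thickness (mm).
#' @param poisson Poisson ratio, in `[0, 0.5)`.
#' @return Strain energy in mJ (non-negative).
#' @export
strain_energy <- function(field, modulus_mpa = 0.1, thickness_mm = 1.5,
                          poisson = 0.4) {
  if (!is.finite(modulus_mpa) || modulus_mpa <= 0 ||
      !is.finite(thickness_mm) || thickness_mm <= 0 ||
      !is.finite(poisson) || poisson < 0 || poisson >= 0.5) {
    stop("non-physical elastic parameters", call. = FALSE)
  }
  sc <- strain_components(field)
  E <- modulus_mpa; nu <- poisson
  sxx <- E / (1 - nu^2) * (sc$eps_xx + nu * sc$eps_yy)
  syy <- E / (1 - nu^2) * (sc$eps_yy + nu * sc$eps_xx)
  sxy <- E / (1 + nu) * sc$eps_xy
  dens <- 0.5 * (sxx * sc$eps_xx + syy * sc$eps_yy + 2 * sxy * sc$eps_xy)
  dA <- attr(field, "dx") * attr(field, "dy")
  sum(dens) * dA * thickness_mm
}
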
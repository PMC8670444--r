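# analytic displacement fields on a grid, used across the field tests

make_grid <- function(n = 48, half = 1) {
  expand.grid(x_mm = seq(-half, half, length.out = n),
              y_mm = seq(-half, half, length.out = n),
              KEEP.OUT.ATTRS = FALSE)
}

disk_mask <- function(g, radius = 0.95) g$x_mm^2 + g$y_mm^2 <= radius^2

# u = constant + k (x, y) + omega (-y, x)
make_field <- function(n = 48, k = 0, omega = 0, const = c(0, 0),
                       mask_radius = 0.95, timestamp = NA_real_) {
  g <- make_grid(n)
  displacement_field(
    data.frame(g,
               ux_mm = const[1] + k * g$x_mm - omega * g$y_mm,
               uy_mm = const[2] + k * g$y_mm + omega * g$x_mm,
               mask = disk_mask(g, mask_radius)),
    timestamp = timestamp)
}

field_rms <- function(f) {
  sqrt(mean(f$ux_mm[f$mask]^2 + f$uy_mm[f$mask]^2))
}

# rms difference between two fields on their common mask
field_rms_diff <- function(f1, f2) {
  m <- f1$mask & f2$mask
  sqrt(mean((f1$ux_mm[m] - f2$ux_mm[m])^2 +
              (f1$uy_mm[m] - f2$uy_mm[m])^2))
}

scatter_from_function <- function(n_pts, fun, seed = 1, half = 1) {
  set.seed(seed)
  x <- runif(n_pts, -half, half)
  y <- runif(n_pts, -half, half)
  u <- fun(x, y)
  tibble::tibble(x_mm = x, y_mm = y, ux_mm = u[[1]], uy_mm = u[[2]])
}
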
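#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("midpoint_um", "spread_um", "threshold_um", "slope_per_um",
             "guess", "lapse"),
    estimate = c(x$midpoint_um, x$spread_um, x$threshold_um,
                 x$slope_per_um, x$guess, x$lapse))
}

#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(threshold_um = x$threshold_um,
                 slope_per_um = x$slope_per_um,
                 logLik = x$logLik,
                 n_levels = nrow(x$table),
                 n_trials = sum(x$table$n_trials),
                 converged = x$converged,
                 extrapolated = x$extrapolated)
}

#' @method tidy press_sim
#' @export
tidy.press_sim <- function(x, ...) {
  x$profile
}

#' @method glance press_sim
#' @export
glance.press_sim <- function(x, ...) {
  tibble::tibble(mu = x$params$mu,
                 target_force_N = x$params$target_force,
                 contact_force_N = sum(x$state$fn),
                 n_contact = sum(x$state$contact),
                 divergence = x$divergence,
                 peak_normal_N_mm = max(c(x$profile$p_normal, 0)),
                 peak_tangential_N_mm = max(c(abs(x$profile$p_tangential), 0)),
                 tangential_energy_mJ = x$tangential_energy_mJ,
                 membrane_energy_mJ = x$membrane_energy_mJ,
                 skin_energy_mJ = x$skin_energy_mJ,
                 converged = x$converged,
                 iterations = x$iterations)
}

#' @method tidy field_decomposition
#' @export
tidy.field_decomposition <- function(x, ...) {
  nrm <- function(f) sqrt(mean(f$ux_mm[f$mask]^2 + f$uy_mm[f$mask]^2))
  tibble::tibble(
    component = c("constant", "divergent", "rotational", "residual"),
    rms_mm = c(sqrt(sum(x$constant^2)), nrm(x$divergent),
               nrm(x$rotational), nrm(x$residual)))
}
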
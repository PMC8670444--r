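#' Hemisphere-flattening model of fingertip compression
#'
#' A purely kinematic model of the strain the fingertip skin undergoes when
#' pressed on a flat plate. The distal pulp is idealised as a quasihemisphere
#' of radius `radius_mm`; indenting it by `indentation_mm` flattens the
#' spherical cap into a disk. Material that originally lay along the meridian
#' arc of the cap must now fit on the (shorter) flat chord, so the skin is
#' compressed by
#' \deqn{\epsilon = 1 - \frac{R\sin\theta}{R\theta}, \qquad
#'       \theta = \arccos\!\left(1 - \delta/R\right),}
#' where \eqn{R} is the fingertip radius and \eqn{\delta} the indentation
#' depth. For a typical adult index fingertip (\eqn{R} = 10 mm) indented by
#' 3 mm this predicts roughly 10% compressive strain. An azimuthal (hoop)
#' strain of the flattened cap is reported alongside: rings of material at
#' colatitude \eqn{\phi} with circumference \eqn{2\pi R\sin\phi} are pressed
#' to radius \eqn{R\phi}; its cap-average is returned as `hoop_strain`
#' (negative values mean circumferential stretch).
#'
#' @param geometry A data frame with columns `radius_mm` and `indentation_mm`
#'   (one row per configuration), or nothing if the two scalar arguments are
#'   given instead.
#' @param radius_mm,indentation_mm Scalar shortcut for a single geometry.
#' @return A tibble with one row per input geometry and columns `radius_mm`,
#'   `indentation_mm`, `contact_angle_rad`, `compressive_strain` (meridional,
#'   dimensionless, in `[0, 1)`), `hoop_strain`, and `contact_radius_mm`.
#' @examples
#' hemisphere_strain(radius_mm = 10, indentation_mm = 3)
#' @export
hemisphere_strain <- function(geometry = NULL, radius_mm = NULL,
                              indentation_mm = NULL) {
  if (is.null(geometry)) {
    geometry <- tibble::tibble(radius_mm = radius_mm,
                               indentation_mm = indentation_mm)
  }
  stopifnot(is.data.frame(geometry),
            all(c("radius_mm", "indentation_mm") %in% names(geometry)))
  R <- geometry$radius_mm
  d <- geometry$indentation_mm
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("`radius_mm` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0) || any(d >= R)) {
    stop("`indentation_mm` must satisfy 0 <= indentation < radius",
         call. = FALSE)
  }
  theta <- acos(1 - d / R)
  # meridional strain: arc R*theta flattened onto chord R*sin(theta)
  strain <- ifelse(theta == 0, 0, 1 - sin(theta) / theta)
  tibble::tibble(
    radius_mm = R,
    indentation_mm = d,
    contact_angle_rad = theta,
    compressive_strain = strain,
    hoop_strain = hoop_strain_cap(theta),
    contact_radius_mm = contact_radius(R, d)
  )
}

#' Gross contact radius of an indented hemisphere
#'
#' Radius of the circular footprint left when a rigid sphere of radius
#' `radius_mm` is truncated by a plane at depth `indentation_mm`:
#' \eqn{a = \sqrt{R^2 - (R-\delta)^2}}. Monotone increasing in the
#' indentation; useful for contact-area-versus-indentation reporting.
#'
#' @param radius_mm Fingertip radius (mm), positive.
#' @param indentation_mm Indentation depth (mm), in `[0, radius_mm)`.
#' @return Contact radius in mm (vectorised).
#' @examples
#' contact_radius(5, 3) # sqrt(21)
#' @export
contact_radius <- function(radius_mm, indentation_mm) {
  if (any(!is.finite(radius_mm)) || any(radius_mm <= 0)) {
    stop("`radius_mm` must be finite and positive", call. = FALSE)
  }
  if (any(indentation_mm < 0) || any(indentation_mm >= radius_mm)) {
    stop("`indentation_mm` must satisfy 0 <= indentation < radius",
         call. = FALSE)
  }
  sqrt(radius_mm^2 - (radius_mm - indentation_mm)^2)
}

# average azimuthal compression of the flattened cap: a ring at colatitude
# phi (circumference ~ sin phi) lands at planar radius R*phi after
# flattening; strain 1 - phi/sin(phi) <= 0 (hoop stretch), averaged over
# the cap weighted by ring circumference
hoop_strain_cap <- function(theta) {
  vapply(theta, function(th) {
    if (th == 0) return(0)
    f <- function(phi) (1 - phi / sin(phi)) * sin(phi)
    w <- function(phi) sin(phi)
    num <- stats::integrate(function(p) ifelse(p == 0, 0, f(p)), 0, th)$value
    den <- stats::integrate(w, 0, th)$value
    num / den
  }, numeric(1))
}
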
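#' Decompose a displacement field into constant, divergent and rotational parts
#'
#' Splits the masked displacement field as
#' \deqn{u = c + \nabla\phi + \nabla^\perp\psi + r:}
#' a constant (rigid-translation) part, a curl-free divergent part, a
#' divergence-free rotational part, and a residual. The constant part is the
#' median vector over the contact mask. The two potentials \eqn{\phi} and
#' \eqn{\psi} are represented as polynomials of total degree `degree` in the
#' (centred, scaled) grid coordinates and fitted jointly to the remaining
#' field by least squares, taking the minimum-norm solution (via SVD) to fix
#' the harmonic gauge. With quadratic potentials representable exactly, a
#' pure radial field \eqn{u = k(x, y)} is captured entirely by the divergent
#' part and a pure rotation \eqn{u = \omega(-y, x)} entirely by the
#' rotational part. The residual is defined as the remainder, so
#' constant + divergent + rotational + residual reconstructs the input
#' exactly on the mask.
#'
#' @param field A [displacement_field()].
#' @param degree Total polynomial degree of the potential expansion.
#' @return An object of class `field_decomposition`: a list with
#'   `constant` (length-2 vector, mm), `divergent`, `rotational`, `residual`
#'   (each a [displacement_field()] on the same grid and mask), and the
#'   input `field`.
#' @export
decompose_field <- function(field, degree = 8) {
  m <- field_mats(field)
  sel <- which(m$mask)
  cN <- c(median(m$ux[sel]), median(m$uy[sel]))
  ux <- m$ux[sel] - cN[1]
  uy <- m$uy[sel] - cN[2]
  x <- m$x[sel]; y <- m$y[sel]
  cx <- mean(range(x)); cy <- mean(range(y))
  L <- max(max(abs(x - cx)), max(abs(y - cy)), .Machine$double.eps)
  X <- (x - cx) / L; Y <- (y - cy) / L

  # monomial exponents, excluding the constant (a gradient's null mode)
  ex <- expand.grid(a = 0:degree, b = 0:degree)
  ex <- ex[ex$a + ex$b >= 1 & ex$a + ex$b <= degree, ]
  nb <- nrow(ex)
  M <- length(sel)
  dPdx <- matrix(0, M, nb); dPdy <- matrix(0, M, nb)
  for (q in seq_len(nb)) {
    a <- ex$a[q]; b <- ex$b[q]
    if (a > 0) dPdx[, q] <- a * X^(a - 1) * Y^b / L
    if (b > 0) dPdy[, q] <- b * X^a * Y^(b - 1) / L
  }
  # unknowns: [phi coeffs | psi coeffs]; grad(phi) + perp-grad(psi)
  A <- rbind(cbind(dPdx, dPdy), cbind(dPdy, -dPdx))
  b <- c(ux, uy)
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  cph <- coef[seq_len(nb)]
  cps <- coef[nb + seq_len(nb)]

  div_ux <- dPdx %*% cph; div_uy <- dPdy %*% cph
  rot_ux <- dPdy %*% cps; rot_uy <- -dPdx %*% cps

  mk_field <- function(vux, vuy) {
    fux <- matrix(NA_real_, m$nx, m$ny); fuy <- matrix(NA_real_, m$nx, m$ny)
    fux[sel] <- vux; fuy[sel] <- vuy
    displacement_field(tibble::tibble(
      x_mm = as.vector(m$x), y_mm = as.vector(m$y),
      ux_mm = as.vector(fux), uy_mm = as.vector(fuy),
      mask = as.vector(m$mask)),
      pixel_resolution = attr(field, "pixel_resolution"),
      timestamp = attr(field, "timestamp"))
  }
  structure(list(constant = cN,
                 divergent = mk_field(div_ux, div_uy),
                 rotational = mk_field(rot_ux, rot_uy),
                 residual = mk_field(ux - div_ux - rot_ux,
                                     uy - div_uy - rot_uy),
                 field = field),
            class = "field_decomposition")
}

#' @export
print.field_decomposition <- function(x, ...) {
  nrm <- function(f) sqrt(mean(f$ux_mm[f$mask]^2 + f$uy_mm[f$mask]^2))
  cat("Field decomposition over", sum(x$field$mask), "masked cells\n")
  cat(sprintf("  constant   : (%.4g, %.4g) mm\n",
              x$constant[1], x$constant[2]))
  cat(sprintf("  divergent  : rms %.4g mm\n", nrm(x$divergent)))
  cat(sprintf("  rotational : rms %.4g mm\n", nrm(x$rotational)))
  cat(sprintf("  residual   : rms %.4g mm\n", nrm(x$residual)))
  invisible(x)
}
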
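#' Homogeneous optical background of the medium
#'
#' Bulk optical properties of the semi-infinite scattering medium (e.g. a 1%
#' intralipid phantom, or breast/brain tissue).  Derived quantities follow
#' standard diffusion theory: diffusion coefficient D = 1/(3(mua + musp)) and
#' effective attenuation mu_eff = sqrt(mua / D).
#'
#' @param mua background absorption coefficient (cm^-1).
#' @param musp reduced scattering coefficient (cm^-1).
#' @param refractive_index refractive index of the medium (dimensionless).
#' @param A_bnd boundary-mismatch factor entering the extrapolated boundary
#'   distance z_b = 2 * A_bnd * D.
#' @return Object of class `optical_background` with fields `mua`, `musp`,
#'   `refractive_index`, `A_bnd`, `D`, `mu_eff`, `z_b` and the effective
#'   source depth `z0 = 1/(mua + musp)`.
#' @export
optical_background <- function(mua = 0.03, musp = 10, refractive_index = 1.33,
                               A_bnd = 2.0) {
  if (mua <= 0 || musp <= 0)
    stop("'mua' and 'musp' must be positive (cm^-1)", call. = FALSE)
  D <- 1 / (3 * (mua + musp))
  structure(
    list(mua = mua, musp = musp, refractive_index = refractive_index,
         A_bnd = A_bnd, D = D, mu_eff = sqrt(mua / D),
         z_b = 2 * A_bnd * D, z0 = 1 / (mua + musp)),
    class = "optical_background")
}

#' @export
print.optical_background <- function(x, ...) {
  cat(sprintf(
    "Optical background: mua = %g, musp = %g cm^-1  (D = %.5g cm, mu_eff = %.4g cm^-1)\n",
    x$mua, x$musp, x$D, x$mu_eff))
  invisible(x)
}

# infinite-medium CW Green's function, r in cm (vectorized over r)
greens_inf <- function(r, bg) {
  exp(-bg$mu_eff * r) / (4 * pi * bg$D * r)
}

#' Continuous-wave Green's function for a semi-infinite medium
#'
#' Photon-fluence Green's function of CW diffusion theory in a homogeneous
#' half-space z >= 0, using the image-source construction about the
#' extrapolated boundary z = -z_b: G(r1, r2) = Ginf(|r1 - r2|) -
#' Ginf(|r1 - r2*|), where r2* mirrors r2 across z = -z_b and
#' Ginf(r) = exp(-mu_eff r) / (4 pi D r).  Symmetric in its arguments.
#'
#' @param r1,r2 positions (cm), length-3 vectors or n x 3 matrices.
#' @param bg an [optical_background()].
#' @return fluence weight(s) in cm^-2.
#' @export
greens_fn <- function(r1, r2, bg) {
  if (is.null(dim(r1))) r1 <- matrix(r1, ncol = 3)
  if (is.null(dim(r2))) r2 <- matrix(r2, ncol = 3)
  d <- sqrt(rowSums((r1[, , drop = FALSE] - r2)^2))
  if (any(d == 0))
    stop("coincident points: the Green's function is singular", call. = FALSE)
  r2m <- r2
  r2m[, 3] <- -r2[, 3] - 2 * bg$z_b
  dm <- sqrt(rowSums((r1 - r2m)^2))
  greens_inf(d, bg) - greens_inf(dm, bg)
}

# pairwise Green's function between every row of P (k x 3) and Q (l x 3);
# distances clamped below at dmin to regularize the near-field singularity
greens_pairs <- function(P, Q, bg, dmin = 0) {
  dx <- outer(P[, 1], Q[, 1], "-")
  dy <- outer(P[, 2], Q[, 2], "-")
  dz <- outer(P[, 3], Q[, 3], "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  d <- pmax(d, dmin)
  dzm <- outer(P[, 3], -Q[, 3] - 2 * bg$z_b, "-")
  dm <- sqrt(dx^2 + dy^2 + dzm^2)
  dm <- pmax(dm, dmin)
  greens_inf(d, bg) - greens_inf(dm, bg)
}
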
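# DKL opponent-colour decomposition for display-referred sRGB images.
#
# Pipeline: sRGB -> linear RGB (IEC 61966-2-1 transfer) -> CIE XYZ (sRGB/D65
# primaries) -> LMS cone responses (Hunt-Pointer-Estevez, D65-normalised).
# Cone responses are then divided by the white point's cone responses and
# combined into opponent axes
#
#   Ach = (l + m) / 2,  RG = l - m,  YV = s - (l + m) / 2
#
# so that any grey pixel maps to RG = YV = 0 and the white point itself to
# (1, 0, 0). The matrices are package constants and may be swapped via the
# `rgb_to_lms` argument.

.M_SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.M_XYZ_TO_LMS <- matrix(c(
  0.4002, 0.7076, -0.0808,
  -0.2263, 1.1653, 0.0457,
  0.0000, 0.0000, 0.9182), nrow = 3, byrow = TRUE)

#' Default linear-RGB to LMS matrix
#'
#' Product of the sRGB(D65) RGB-to-XYZ matrix and the
#' Hunt-Pointer-Estevez XYZ-to-LMS matrix.
#'
#' @return 3x3 matrix.
#' @export
default_rgb_to_lms <- function() .M_XYZ_TO_LMS %*% .M_SRGB_TO_XYZ

srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * pmax(x, 0)^(1 / 2.4) - 0.055)
}

srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

# opponent recombination matrices for normalised cone responses (l, m, s)
.M_LMS_TO_DKL <- matrix(c(
  0.5, 0.5, 0,
  1, -1, 0,
  -0.5, -0.5, 1), nrow = 3, byrow = TRUE)

#' Convert a display-referred sRGB image to DKL opponent planes
#'
#' @param image Numeric array `height x width x 3` with values in [0, 1]
#'   (sRGB-encoded).
#' @param white Linear-RGB white point the opponent axes are normalised to
#'   (default display white `c(1, 1, 1)`).
#' @param rgb_to_lms 3x3 linear-RGB-to-LMS matrix.
#' @return Object of class `dkl_image`: list of matrices `Ach`, `RG`, `YV`
#'   plus the transform constants needed for the inverse.
#' @export
srgb_to_dkl <- function(image, white = c(1, 1, 1),
                        rgb_to_lms = default_rgb_to_lms()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            min(image) >= -1e-9, max(image) <= 1 + 1e-9)
  d <- dim(image)[1:2]
  lin <- srgb_decode(pmin(pmax(image, 0), 1))
  px <- matrix(lin, ncol = 3)  # n x 3 linear RGB
  lms_w <- as.numeric(rgb_to_lms %*% white)
  if (any(lms_w <= 0)) stop("white point has non-positive cone response")
  lms <- px %*% t(rgb_to_lms)
  lms <- sweep(lms, 2, lms_w, "/")          # normalised cone responses
  dkl <- lms %*% t(.M_LMS_TO_DKL)
  structure(list(
    Ach = matrix(dkl[, 1], d[1], d[2]),
    RG = matrix(dkl[, 2], d[1], d[2]),
    YV = matrix(dkl[, 3], d[1], d[2]),
    white = white, rgb_to_lms = rgb_to_lms),
    class = "dkl_image")
}

#' Convert DKL opponent planes back to sRGB
#'
#' Exact matrix inverse of [srgb_to_dkl()] followed by sRGB re-encoding.
#' Out-of-gamut pixels are clipped to [0, 1] and counted in the `clipped`
#' attribute.
#'
#' @param dkl A `dkl_image`.
#' @return Numeric array `height x width x 3` in [0, 1].
#' @export
dkl_to_srgb <- function(dkl) {
  stopifnot(inherits(dkl, "dkl_image"))
  d <- dim(dkl$Ach)
  planes <- cbind(as.numeric(dkl$Ach), as.numeric(dkl$RG), as.numeric(dkl$YV))
  lms <- planes %*% t(solve(.M_LMS_TO_DKL))
  lms_w <- as.numeric(dkl$rgb_to_lms %*% dkl$white)
  lms <- sweep(lms, 2, lms_w, "*")
  lin <- lms %*% t(solve(dkl$rgb_to_lms))
  n_clip <- sum(lin < -1e-9 | lin > 1 + 1e-9)
  lin <- pmin(pmax(lin, 0), 1)
  out <- array(srgb_encode(lin), dim = c(d, 3))
  attr(out, "clipped") <- n_clip
  out
}
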
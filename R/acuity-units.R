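# Visual-acuity and display-geometry unit conversions.
#
# All geometry uses the exact arctangent of the pixel pitch at the display
# centre, along the display normal. ppd (pixels per degree) and cpd (cycles
# per degree) are Nyquist-paired: cpd = ppd / 2 exactly.

DEG_PER_RAD <- 180 / pi

tan_deg <- function(x) tan(x * pi / 180)
atan_deg <- function(x) atan(x) * DEG_PER_RAD

#' Convert pixels per degree to cycles per degree
#'
#' The finest grating a display can show has a period of two pixels, so the
#' maximum representable spatial frequency in cycles per degree is exactly
#' half the pixels-per-degree value.
#'
#' @param ppd Pixels per visual degree (> 0).
#' @return Cycles per visual degree.
#' @export
ppd_to_cpd <- function(ppd) {
  stopifnot(is.numeric(ppd), all(ppd > 0))
  ppd / 2
}

#' @rdname ppd_to_cpd
#' @param cpd Cycles per visual degree (> 0).
#' @export
cpd_to_ppd <- function(cpd) {
  stopifnot(is.numeric(cpd), all(cpd > 0))
  cpd * 2
}

#' Convert minimum angle of resolution to pixels per degree
#'
#' One resolvable feature of `mar` arcminutes corresponds to one pixel, so a
#' MAR of 1 arcmin equals 60 pixels per degree.
#'
#' @param mar Minimum angle of resolution in arcminutes (> 0).
#' @return Pixels per degree.
#' @examples
#' mar_to_ppd(1)   # 60
#' mar_to_ppd(2)   # 30
#' @export
mar_to_ppd <- function(mar) {
  if (!is.numeric(mar) || any(!is.finite(mar)) || any(mar <= 0)) {
    stop("`mar` must be a positive number of arcminutes")
  }
  60 / mar
}

#' Convert a Snellen fraction to pixels per degree
#'
#' Snellen acuity N/D corresponds to a minimum angle of resolution of D/N
#' arcminutes; 20/20 (or 6/6) is MAR 1 arcmin, i.e. 60 ppd.
#'
#' @param numerator Testing distance (e.g. 20 ft or 6 m), or a string
#'   `"N/D"` in which case `denominator` must be missing.
#' @param denominator Distance at which a standard eye resolves the optotype,
#'   in the same unit as `numerator`.
#' @return Pixels per degree.
#' @examples
#' snellen_to_ppd(20, 20)   # 60
#' snellen_to_ppd("20/40")  # 30
#' @export
snellen_to_ppd <- function(numerator, denominator) {
  if (is.character(numerator)) {
    if (!missing(denominator)) {
      stop("give either a \"N/D\" string or a numeric pair, not both")
    }
    parts <- strsplit(numerator, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("Snellen string must have the form \"N/D\"")
    numerator <- suppressWarnings(as.numeric(parts[1]))
    denominator <- suppressWarnings(as.numeric(parts[2]))
    if (anyNA(c(numerator, denominator))) {
      stop("Snellen string must contain two numbers, e.g. \"20/20\"")
    }
  }
  if (!is.numeric(numerator) || !is.numeric(denominator) ||
      numerator <= 0 || denominator <= 0) {
    stop("Snellen distances must both be positive")
  }
  mar_to_ppd(denominator / numerator)
}

#' Pixels per degree of a display at a given viewing distance
#'
#' Computes the angular resolution at the centre of a flat display viewed
#' along its normal, from the vertical line count and the viewing distance in
#' display heights. One pixel subtends `atan((1/lines)/distance)` degrees.
#'
#' @param lines Vertical resolution in lines (integer >= 1).
#' @param distance_heights Viewing distance in display heights (> 0).
#' @return Pixels per degree at the display centre.
#' @examples
#' display_ppd(1080, 3.2)  # about 60.3 ppd
#' display_ppd(1080, 6)    # about 113 ppd
#' @export
display_ppd <- function(lines, distance_heights) {
  stopifnot(is.numeric(lines), all(lines >= 1),
            is.numeric(distance_heights), all(distance_heights > 0))
  1 / atan_deg((1 / lines) / distance_heights)
}

#' Minimum viewing distance for a target angular resolution
#'
#' Exact inverse of [display_ppd()] in its distance argument: the distance in
#' display heights at which a display with `lines` vertical lines reaches
#' `target_ppd` pixels per degree at its centre.
#'
#' @param lines Vertical resolution in lines (integer >= 1).
#' @param target_ppd Desired pixels per degree (> 0).
#' @return Viewing distance in display heights.
#' @export
min_viewing_distance <- function(lines, target_ppd) {
  stopifnot(is.numeric(lines), all(lines >= 1),
            is.numeric(target_ppd), all(target_ppd > 0))
  (1 / lines) / tan_deg(1 / target_ppd)
}

#' Pixels per degree from pixel density and viewing distance
#'
#' @param ppi Pixel density in pixels per inch (> 0).
#' @param distance_m Viewing distance in metres (> 0).
#' @return Pixels per degree at the display centre.
#' @examples
#' ppi_distance_to_ppd(100, 1)  # about 68.7 ppd
#' @export
ppi_distance_to_ppd <- function(ppi, distance_m) {
  stopifnot(is.numeric(ppi), all(ppi > 0),
            is.numeric(distance_m), all(distance_m > 0))
  pitch_m <- 0.0254 / ppi
  1 / atan_deg(pitch_m / distance_m)
}

#' Pixel density needed for a target resolution at a distance
#'
#' Inverse of [ppi_distance_to_ppd()] in its first argument.
#'
#' @param target_ppd Desired pixels per degree (> 0).
#' @param distance_m Viewing distance in metres (> 0).
#' @return Required pixels per inch.
#' @export
required_ppi <- function(target_ppd, distance_m) {
  stopifnot(is.numeric(target_ppd), all(target_ppd > 0),
            is.numeric(distance_m), all(distance_m > 0))
  0.0254 / (distance_m * tan_deg(1 / target_ppd))
}

#' Convert a visual angle to a typographic size
#'
#' Physical size is `distance * tan(angle)`; the result is expressed in
#' typographic points. The default point is the PostScript/DTP point
#' (1/72 inch = 0.3528 mm); the traditional TeX point (1/72.27 inch) can be
#' selected via `point_mm = 25.4 / 72.27`.
#'
#' @param angle_deg Visual angle in degrees (>= 0).
#' @param distance_cm Viewing distance in centimetres (> 0).
#' @param point_mm Size of one typographic point in millimetres.
#' @return Size in points.
#' @examples
#' visual_angle_to_points(0.5, 40)   # about 9.9 pt (a 10 pt font body)
#' visual_angle_to_points(0.28, 40)  # about 5.5 pt (capital height)
#' @export
visual_angle_to_points <- function(angle_deg, distance_cm,
                                   point_mm = 25.4 / 72) {
  if (!is.numeric(angle_deg) || any(angle_deg < 0)) {
    stop("`angle_deg` must be non-negative")
  }
  stopifnot(is.numeric(distance_cm), all(distance_cm > 0), point_mm > 0)
  size_mm <- distance_cm * 10 * tan_deg(angle_deg)
  size_mm / point_mm
}

#' Small-angle approximation of display ppd
#'
#' Documented helper: `ppd ~= lines * distance * pi / 180`. The exact
#' arctangent path ([display_ppd()]) is canonical; the approximation agrees
#' within 0.1 percent for ppd >= 20.
#'
#' @inheritParams display_ppd
#' @return Approximate pixels per degree.
#' @export
display_ppd_small_angle <- function(lines, distance_heights) {
  lines * distance_heights * pi / 180
}
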
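#' Wrap angles to the device convention
#'
#' `wrapAngle180()` maps angles (degrees) to the half-open interval
#' (-180, 180]; `foldAngle90()` folds pitch-style angles into [-90, 90]
#' by reflection about +/-90 (the physical behaviour of a pitch angle,
#' which cannot exceed the vertical).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length.
#' @examples
#' wrapAngle180(c(-180, 181, 360))   # 180, -179, 0
#' foldAngle90(c(100, -100, 45))     # 80, -80, 45
#' @export
wrapAngle180 <- function(x) {
  180 - ((180 - x) %% 360)
}

#' @rdname wrapAngle180
#' @export
foldAngle90 <- function(x) {
  x <- wrapAngle180(x)
  over <- !is.na(x) & abs(x) > 90
  x[over] <- sign(x[over]) * 180 - x[over]
  x
}

# circular mean of angles in degrees, result in (-180, 180]
circularMeanDeg <- function(x) {
  r <- x * pi / 180
  wrapAngle180(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}
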
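#' Square open-field arena
#'
#' Describes the test arena geometry. Coordinates throughout the package are
#' in centimetres with the origin at the lower-left corner of the arena and
#' the y axis pointing up. The center zone is the axis-aligned square of side
#' \code{center_fraction * side_cm} centered at the arena midpoint.
#'
#' @param side_cm Side length of the square arena in cm (default 50).
#' @param center_fraction Linear fraction of the side defining the center
#'   zone, in (0, 1] (default 0.5, i.e. a 25 x 25 cm center in a 50 cm arena).
#' @return An object of class \code{"arena"}.
#' @examples
#' a <- arena()
#' center_bounds(a)
#' @export
arena <- function(side_cm = 50, center_fraction = 0.5) {
  stopifnot(is.numeric(side_cm), length(side_cm) == 1L, is.finite(side_cm),
            side_cm > 0)
  stopifnot(is.numeric(center_fraction), length(center_fraction) == 1L,
            center_fraction > 0, center_fraction <= 1)
  structure(list(side_cm = as.numeric(side_cm),
                 center_fraction = as.numeric(center_fraction)),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cb <- center_bounds(x)
  cat(sprintf("Square arena %g x %g cm; center zone [%g, %g] x [%g, %g] cm\n",
              x$side_cm, x$side_cm, cb[1], cb[2], cb[1], cb[2]))
  invisible(x)
}

#' Bounds of the arena center zone
#'
#' @param arena An \code{\link{arena}} object.
#' @return Numeric vector \code{c(lo, hi)}: the center zone occupies
#'   \code{[lo, hi]} on both axes.
#' @export
center_bounds <- function(arena) {
  stopifnot(inherits(arena, "arena"))
  half <- arena$side_cm * arena$center_fraction / 2
  mid <- arena$side_cm / 2
  c(mid - half, mid + half)
}

#' Test points for center-zone membership
#'
#' @param x,y Coordinates in cm.
#' @param arena An \code{\link{arena}} object.
#' @return Logical vector; \code{NA} where coordinates are missing.
#' @export
in_center <- function(x, y, arena) {
  cb <- center_bounds(arena)
  x >= cb[1] & x <= cb[2] & y >= cb[1] & y <= cb[2]
}
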
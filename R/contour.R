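#' Construct a cell contour
#'
#' A contour is the ordered, implicitly closed pixel polygon traced around a
#' single cell. Coordinates follow the camera convention: origin at the top
#' left, `x` along the flow direction, `y` downward, vertices at pixel
#' centers. All downstream shape features (area, volume, deformation,
#' inertia ratio, ...) are computed from this polygon.
#'
#' @param x,y Numeric vertex coordinates in pixels (equal length, >= 3
#'   vertices, finite). The polygon is closed implicitly; do not repeat the
#'   first vertex.
#' @param pixel_size Physical pixel size in micrometers per pixel.
#' @param id Optional event identifier (kept through feature extraction).
#' @return An object of class `rtdc_contour`: a tibble with columns `x`, `y`
#'   and attributes `pixel_size` and `id`.
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1), pixel_size = 1)
#' contour_area(sq)
#' @export
contour <- function(x, y, pixel_size = 1, id = NA_character_) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) stop("a contour needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("contour coordinates must be finite", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  # drop a duplicated closing vertex if the caller supplied one
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n] && n > 3L) {
    x <- x[-n]; y <- y[-n]
  }
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "pixel_size") <- as.numeric(pixel_size)
  attr(out, "id") <- as.character(id)
  class(out) <- c("rtdc_contour", class(out))
  out
}

#' @export
print.rtdc_contour <- function(x, ...) {
  cat(sprintf("<rtdc_contour> %d vertices, pixel_size = %g um/px, id = %s\n",
              nrow(x), attr(x, "pixel_size"), attr(x, "id")))
  NextMethod()
}

is_contour <- function(x) inherits(x, "rtdc_contour")

contour_matrix <- function(ct) cbind(x = ct$x, y = ct$y)

contour_pixel_size <- function(ct) attr(ct, "pixel_size")

assert_contour <- function(ct) {
  if (!is_contour(ct)) stop("expected an `rtdc_contour` object", call. = FALSE)
  invisible(ct)
}

assert_nondegenerate <- function(xy, what = "contour") {
  if (polygon_area(xy) <= .Machine$double.eps * max(1, sum(abs(xy)))) {
    stop(sprintf("degenerate %s: enclosed area is zero", what), call. = FALSE)
  }
  invisible(xy)
}
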
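#' Plate specification
#'
#' Defines the square (or rectangular) tissue sample in which the incision is
#' embedded. The default 60 mm x 60 mm plate is large relative to a ~2 mm
#' incision so that the infinite-plate fracture-mechanics limit applies.
#'
#' @param width,height Plate dimensions in metres (default 0.060 x 0.060).
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(width = 0.060, height = 0.060) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (width <= 0 || height <= 0) stop("plate dimensions must be positive")
  structure(list(width = width, height = height), class = "plate_spec")
}

#' Incision shape
#'
#' Parametric description of the three incision families used in
#' small-incision cataract surgery:
#' \describe{
#'   \item{straight}{a straight cut of total length `2a`.}
#'   \item{chevron}{two straight arms of length `a` meeting at an apex with
#'     included angle `alpha` (degrees, 120--180). `alpha = 180` degenerates
#'     to the straight incision.}
#'   \item{frown}{a circular arc of arclength `2a` subtending central angle
#'     `beta` (degrees, 0 < beta <= 50). `beta -> 0` degenerates to straight.}
#' }
#'
#' @param family `"straight"`, `"chevron"` or `"frown"`.
#' @param length Total incision length `2a` in metres (default 2.2e-3).
#' @param angle Shape angle in degrees: the arm angle `alpha` for a chevron,
#'   the central angle `beta` for a frown. Ignored for straight.
#' @return An object of class `incision_shape` with fields `family`, `a`
#'   (half length, metres) and `angle` (degrees; `NA` for straight).
#' @examples
#' incision_shape("chevron", length = 2.2e-3, angle = 150)
#' @export
incision_shape <- function(family = c("straight", "chevron", "frown"),
                           length = 2.2e-3, angle = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(length), length(length) == 1L, is.finite(length))
  if (length <= 0) stop("incision length 2a must be positive")
  a <- length / 2
  if (family == "straight") {
    angle <- NA_real_
  } else {
    if (is.null(angle) || !is.numeric(angle) || length(angle) != 1L || !is.finite(angle))
      stop(sprintf("a %s incision requires a finite numeric 'angle' in degrees", family))
    if (family == "chevron" && (angle < 120 || angle > 180))
      stop("chevron arm angle alpha must lie in [120, 180] degrees")
    if (family == "frown" && (angle <= 0 || angle > 50))
      stop("frown central angle beta must lie in (0, 50] degrees")
  }
  structure(list(family = family, a = a, angle = angle),
            class = "incision_shape")
}

#' @export
print.incision_shape <- function(x, ...) {
  ang <- if (is.na(x$angle)) "" else sprintf(", angle %.4g deg", x$angle)
  cat(sprintf("<incision_shape> %s, 2a = %.4g mm%s\n",
              x$family, 2 * x$a * 1e3, ang))
  invisible(x)
}

# Point on the incision at arclength s from the midpoint, s in [-a, a].
# Conventions: midpoint (chevron apex / arc midpoint / centre) at the origin,
# incision nominally horizontal, chevron apex pointing +y, frown bowing +y.
# Vectorised in s.
path_point <- function(shape, s) {
  a <- shape$a
  p <- switch(shape$family,
    straight = cbind(s, 0 * s),
    chevron = {
      th <- (180 - shape$angle) * pi / 360  # half-kink from horizontal
      cbind(s * cos(th), -abs(s) * sin(th))
    },
    frown = {
      R <- 2 * a / (shape$angle * pi / 180)
      cbind(R * sin(s / R), R * (cos(s / R) - 1))
    })
  dimnames(p) <- NULL
  p
}

# Unit tangent dP/ds at arclength s (vectorised). At the chevron apex (s = 0)
# the tangent is discontinuous; the value for s = 0 is the +s side limit.
path_tangent <- function(shape, s) {
  p <- switch(shape$family,
    straight = cbind(1 + 0 * s, 0 * s),
    chevron = {
      th <- (180 - shape$angle) * pi / 360
      sg <- ifelse(s < 0, -1, 1)
      cbind(1 + 0 * s, 0 * s) * cos(th) + cbind(0 * s, -sg * sin(th))
    },
    frown = {
      R <- 2 * shape$a / (shape$angle * pi / 180)
      cbind(cos(s / R), -sin(s / R))
    })
  dimnames(p) <- NULL
  p
}

# Unit normal (tangent rotated +90 deg: the "upper" crack face side for the
# conventions above). At the chevron apex the kink bisector normal (0, 1) is
# returned.
path_normal <- function(shape, s) {
  if (shape$family == "chevron") {
    t <- path_tangent(shape, s)
    n <- cbind(-t[, 2], t[, 1])
    n[s == 0, ] <- rep(c(0, 1), each = sum(s == 0))
    n
  } else {
    t <- path_tangent(shape, s)
    cbind(-t[, 2], t[, 1])
  }
}

# Path extended straight along the tip tangents beyond |s| > a; used by the
# mesh shape map.
path_point_ext <- function(shape, s) {
  a <- shape$a
  p <- path_point(shape, pmin(pmax(s, -a), a))
  over <- abs(s) > a
  if (any(over)) {
    sc <- pmin(pmax(s[over], -a), a)
    t <- path_tangent(shape, sc)
    p[over, ] <- p[over, , drop = FALSE] + (s[over] - sc) * t
  }
  p
}

#' Discretize an incision as a planar crack path
#'
#' Produces the polyline representation of the incision together with tip
#' locations and tip tangents (the crack-extension directions used by the
#' contour integral).
#'
#' @param shape An [incision_shape()].
#' @param n_segments Even number of polyline segments (>= 2) so that the
#'   midpoint (chevron apex) is a vertex.
#' @return An object of class `crack_path`: `vertices` (matrix, metres),
#'   `s` (arclength stations of the vertices), `tip_left`, `tip_right`,
#'   `tip_tangents` (outward unit extension directions, rows left/right),
#'   `midpoint`, and the generating `shape`.
#' @export
make_crack_path <- function(shape, n_segments = 64L) {
  stopifnot(inherits(shape, "incision_shape"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L || n_segments %% 2L != 0L)
    stop("n_segments must be an even integer >= 2")
  a <- shape$a
  s <- seq(-a, a, length.out = n_segments + 1L)
  v <- path_point(shape, s)
  tl <- as.vector(path_tangent(shape, -a))
  tr <- as.vector(path_tangent(shape, a))
  structure(list(
    vertices = v,
    s = s,
    tip_left = v[1L, ],
    tip_right = v[n_segments + 1L, ],
    tip_tangents = rbind(left = -tl, right = tr),
    midpoint = v[n_segments / 2L + 1L, ],
    shape = shape
  ), class = "crack_path")
}

#' @export
print.crack_path <- function(x, ...) {
  cat(sprintf("<crack_path> %s, %d vertices, tips (%.5g, %.5g) / (%.5g, %.5g) mm\n",
              x$shape$family, nrow(x$vertices),
              x$tip_left[1] * 1e3, x$tip_left[2] * 1e3,
              x$tip_right[1] * 1e3, x$tip_right[2] * 1e3))
  invisible(x)
}

#' Tip-to-tip chord of an incision
#'
#' Straight-line distance between the two incision tips; used for
#' plate-size sanity checks (the infinite-plate comparison assumes the chord
#' is small relative to the plate).
#'
#' @param shape An [incision_shape()].
#' @return Chord length in metres.
#' @export
chord_span <- function(shape) {
  stopifnot(inherits(shape, "incision_shape"))
  p <- path_point(shape, c(-shape$a, shape$a))
  sqrt(sum((p[2, ] - p[1, ])^2))
}

#' Export a crack path as CSV
#'
#' Writes the polyline vertices as a two-column CSV (`x`, `y`, metres).
#'
#' @param path A [make_crack_path()] result.
#' @param file Output file path.
#' @return `file`, invisibly.
#' @export
write_crack_path_csv <- function(path, file) {
  stopifnot(inherits(path, "crack_path"))
  df <- data.frame(x = path$vertices[, 1], y = path$vertices[, 2])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
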
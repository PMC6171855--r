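#' @keywords internal
#' @useDynLib carilow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Canonical viewpoint labels and their yaw (degrees, positive = turned to the
## sitter's right; the two left views have negative yaw).
VIEWPOINTS <- c(front = 0, right10 = 10, left10 = -10, left30 = -30)

#' Landmark annotation schemes
#'
#' Three schemes are supported:
#' \describe{
#'   \item{S147}{147 points per face, hand-annotation style, frontal views.
#'     Traces every feature in detail: face outline/jaw, forehead hairline,
#'     both ears, both eyebrows as closed contours (so eyebrow *width* is
#'     coded), eyes, nose including the width of its middle section, and
#'     inner + outer lip contours.}
#'   \item{S136}{The same scheme for non-frontal views, where only one ear is
#'     visible: the 11 points of the occluded ear are dropped.}
#'   \item{S68}{The widely used 68-point automatic annotation convention
#'     (jawline 17, brows 5+5, nose 9, eyes 6+6, mouth 20). It carries no
#'     points on the forehead, the ears, the lower eyebrow contour or the
#'     mid-nose width, so those regions are uncovered.}
#' }
#'
#' @param name one of `"S147"`, `"S136"`, `"S68"`.
#' @return an object of class `landmark_scheme` with elements `name`,
#'   `point_count`, `region_labels` (one semantic tag per point, in point
#'   order) and `covered_regions` (the coarse facial regions the scheme
#'   codes).
#' @examples
#' landmark_scheme("S68")$point_count
#' setdiff(landmark_scheme("S147")$covered_regions,
#'         landmark_scheme("S68")$covered_regions)
#' @export
landmark_scheme <- function(name = c("S147", "S136", "S68")) {
  name <- match.arg(name)
  blocks147 <- c(
    jaw = 27L, forehead = 17L, ear_left = 11L, ear_right = 11L,
    brow_left_top = 5L, brow_left_bot = 5L,
    brow_right_top = 5L, brow_right_bot = 5L,
    eye_left = 8L, eye_right = 8L,
    nose_bridge = 4L, nose_mid_left = 3L, nose_mid_right = 3L,
    nose_base = 9L, mouth_outer = 16L, mouth_inner = 10L
  )
  blocks68 <- c(
    jaw = 17L,
    brow_left_top = 5L, brow_right_top = 5L,
    nose_bridge = 4L, nose_base = 5L,
    eye_left = 6L, eye_right = 6L,
    mouth_outer = 12L, mouth_inner = 8L
  )
  covered147 <- c("jaw", "forehead", "ears", "brows", "brow_width",
                  "eyes", "nose_bridge", "nose_mid_width", "nose_base",
                  "mouth")
  blocks <- switch(name,
    S147 = blocks147,
    S136 = {
      b <- blocks147[names(blocks147) != "ear_left"]
      names(b)[names(b) == "ear_right"] <- "ear"
      b
    },
    S68 = blocks68
  )
  covered <- switch(name,
    S147 = covered147,
    S136 = covered147,
    S68 = setdiff(covered147,
                  c("forehead", "ears", "brow_width", "nose_mid_width"))
  )
  structure(
    list(
      name = name,
      point_count = sum(blocks),
      blocks = blocks,
      region_labels = rep(names(blocks), blocks),
      covered_regions = covered
    ),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme", x$name, "-", x$point_count, "points\n")
  cat("Regions:", paste(names(x$blocks), collapse = ", "), "\n")
  invisible(x)
}

resolve_scheme <- function(scheme, viewpoint) {
  if (inherits(scheme, "landmark_scheme")) return(scheme)
  if (!is.character(scheme) || length(scheme) != 1L)
    stop("`scheme` must be a scheme name or a landmark_scheme object",
         call. = FALSE)
  if (scheme == "hand")
    scheme <- if (viewpoint == "front") "S147" else "S136"
  if (scheme == "auto") scheme <- "S68"
  landmark_scheme(scheme)
}

#' Number of landmark points a scheme assigns for a viewpoint
#'
#' The hand-annotation scheme uses the full 147 points for frontal views but
#' 136 for non-frontal views (only one ear is visible); the automatic 68-point
#' scheme has no ear points, so its count is viewpoint-independent.
#'
#' @param scheme_name `"hand"`, `"auto"`, or an explicit scheme name
#'   (`"S147"`, `"S136"`, `"S68"`).
#' @param viewpoint one of `"front"`, `"right10"`, `"left10"`, `"left30"`.
#' @return integer point count.
#' @examples
#' scheme_point_count("hand", "front")   # 147
#' scheme_point_count("hand", "left30")  # 136
#' scheme_point_count("auto", "front")   # 68
#' @export
scheme_point_count <- function(scheme_name, viewpoint) {
  if (!is.character(viewpoint) || length(viewpoint) != 1L ||
      !viewpoint %in% names(VIEWPOINTS))
    stop("unknown viewpoint: ", deparse(viewpoint), call. = FALSE)
  if (!is.character(scheme_name) || length(scheme_name) != 1L ||
      !scheme_name %in% c("hand", "auto", "S147", "S136", "S68"))
    stop("unknown scheme: ", deparse(scheme_name), call. = FALSE)
  resolve_scheme(scheme_name, viewpoint)$point_count
}

#' Construct a validated landmark set
#'
#' A landmark set binds an ordered list of (x, y) points to a scheme, a
#' viewpoint and an image frame. The coordinate convention is origin at the
#' top-left corner, x rightward, y downward, 0-based pixel units, floating
#' point; all points must lie within `[0, width) x [0, height)`.
#'
#' @param points numeric n x 2 matrix (columns x, y).
#' @param scheme scheme name (`"hand"`/`"auto"`/`"S147"`/`"S136"`/`"S68"`) or
#'   a [landmark_scheme()] object.
#' @param viewpoint one of `"front"`, `"right10"`, `"left10"`, `"left30"`.
#' @param image_size integer c(width, height) of the image frame, pixels.
#' @param check validate point count and bounds (default `TRUE`).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, scheme, viewpoint, image_size, check = TRUE) {
  if (!viewpoint %in% names(VIEWPOINTS))
    stop("unknown viewpoint: ", deparse(viewpoint), call. = FALSE)
  scheme <- resolve_scheme(scheme, viewpoint)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a numeric n x 2 matrix", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  image_size <- as.numeric(image_size)
  if (length(image_size) != 2L || any(image_size <= 0))
    stop("`image_size` must be c(width, height) > 0", call. = FALSE)
  x <- structure(
    list(scheme = scheme, viewpoint = viewpoint, points = points,
         image_size = image_size),
    class = "landmark_set"
  )
  if (check) validate_landmarks(x)
  x
}

#' Validate a landmark set against its scheme
#'
#' Checks that the number of points equals the scheme's count for the set's
#' viewpoint and that every point lies inside the image frame.
#'
#' @param x a `landmark_set`.
#' @return `x`, invisibly; errors describe the violation.
#' @export
validate_landmarks <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  expected <- x$scheme$point_count
  found <- nrow(x$points)
  if (found != expected)
    stop(sprintf("landmark count mismatch for scheme %s: expected %d, found %d",
                 x$scheme$name, expected, found), call. = FALSE)
  w <- x$image_size[1]; h <- x$image_size[2]
  bad <- which(x$points[, 1] < 0 | x$points[, 1] >= w |
               x$points[, 2] < 0 | x$points[, 2] >= h)
  if (length(bad))
    stop(sprintf("landmark(s) outside image frame [0,%g) x [0,%g): point %d at (%g, %g)",
                 w, h, bad[1], x$points[bad[1], 1], x$points[bad[1], 2]),
         call. = FALSE)
  if (anyNA(x$points))
    stop("landmark coordinates contain NA", call. = FALSE)
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %d points (%s), viewpoint %s, frame %g x %g\n",
              nrow(x$points), x$scheme$name, x$viewpoint,
              x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Point indices of a named region block
#'
#' @param set a `landmark_set` (or `landmark_scheme`).
#' @param region a region label present in the scheme's `region_labels`.
#' @return integer vector of point indices, in point order.
#' @export
region_index <- function(set, region) {
  scheme <- if (inherits(set, "landmark_scheme")) set else set$scheme
  idx <- which(scheme$region_labels %in% region)
  if (!length(idx))
    stop("region not present in scheme ", scheme$name, ": ",
         paste(region, collapse = ", "), call. = FALSE)
  idx
}
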
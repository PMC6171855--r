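## Piecewise-affine image warping on a Delaunay triangulation of control
## points. This is the standard, reproducible realisation of shape-only
## ("warp not fade") face morphing: the triangulation is computed once on the
## source control points and re-used for the destination, pixels are filled
## by backward mapping with bilinear interpolation, and pixels outside every
## destination triangle pass through unchanged.

#' Delaunay triangulation of a 2-D point set
#'
#' Incremental Bowyer--Watson construction. Deterministic for a given point
#' order; ties between co-circular configurations are resolved by insertion
#' order.
#'
#' @param pts numeric n x 2 matrix of distinct points, n >= 3.
#' @return integer m x 3 matrix of point indices, one triangle per row,
#'   oriented counter-clockwise in a y-down coordinate frame.
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to triangulate", call. = FALSE)
  if (anyDuplicated(paste(pts[, 1], pts[, 2])))
    stop("duplicate control points are not allowed", call. = FALSE)

  # circumcentres + squared radii of triangle rows; collinear -> infinite
  circum_rows <- function(P, T) {
    a <- P[T[, 1], , drop = FALSE]; b <- P[T[, 2], , drop = FALSE]
    c <- P[T[, 3], , drop = FALSE]
    d <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
              c[, 1] * (a[, 2] - b[, 2]))
    a2 <- rowSums(a^2); b2 <- rowSums(b^2); c2 <- rowSums(c^2)
    ux <- (a2 * (b[, 2] - c[, 2]) + b2 * (c[, 2] - a[, 2]) +
           c2 * (a[, 2] - b[, 2])) / d
    uy <- (a2 * (c[, 1] - b[, 1]) + b2 * (a[, 1] - c[, 1]) +
           c2 * (b[, 1] - a[, 1])) / d
    r2 <- (a[, 1] - ux)^2 + (a[, 2] - uy)^2
    r2[abs(d) < 1e-12] <- Inf
    cbind(ux, uy, r2)
  }

  # super-triangle comfortably containing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  d <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1) * 64
  P <- rbind(pts, c(cx - d, cy - d), c(cx + d, cy - d), c(cx, cy + d))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  ccs <- circum_rows(P, tris)

  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- (p[1] - ccs[, 1])^2 + (p[2] - ccs[, 2])^2 < ccs[, 3] * (1 + 1e-12)
    bt <- tris[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1, 2), drop = FALSE],
                   bt[, c(2, 3), drop = FALSE],
                   bt[, c(3, 1), drop = FALSE])
    key <- pmin(edges[, 1], edges[, 2]) * (n + 4) +
           pmax(edges[, 1], edges[, 2])
    boundary <- edges[!(key %in% key[duplicated(key)]), , drop = FALSE]
    newt <- cbind(boundary, i)
    tris <- rbind(tris[!bad, , drop = FALSE], newt)
    ccs <- rbind(ccs[!bad, , drop = FALSE], circum_rows(P, newt))
  }
  tri <- tris[tris[, 1] <= n & tris[, 2] <= n & tris[, 3] <= n, ,
              drop = FALSE]
  # orient counter-clockwise (y-down frame: signed area >= 0)
  for (r in seq_len(nrow(tri))) {
    if (signed_area(pts[tri[r, 1], ], pts[tri[r, 2], ], pts[tri[r, 3], ]) < 0)
      tri[r, 2:3] <- tri[r, 3:2]
  }
  tri
}

signed_area <- function(a, b, c) {
  0.5 * ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
}

## Fixed frame anchors: 4 corners + 4 edge midpoints of the pixel frame,
## identical in source and destination, so the image border stays put.
frame_anchors <- function(width, height) {
  w <- width - 1; h <- height - 1
  cbind(
    x = c(0, w / 2, w, 0, w, 0, w / 2, w),
    y = c(0, 0, 0, h / 2, h / 2, h, h, h)
  )
}

as_points <- function(x) {
  if (inherits(x, "landmark_set")) return(unname(x$points))
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) != 2L)
    stop("control points must be a landmark_set or an n x 2 matrix",
         call. = FALSE)
  unname(m)
}

#' Warp an image by moving landmarks
#'
#' Piecewise-affine backward warp taking image content at the source
#' landmarks to the destination landmarks. Control points are the landmarks
#' plus (by default) fixed frame anchors (4 corners + 4 edge midpoints,
#' identical in source and destination). The Delaunay triangulation is
#' computed once on the source control points and re-used for the
#' destination; destination triangles whose orientation flips are reported
#' with a warning, and zero-area destination triangles are an error. Pixels
#' outside every destination triangle pass through unchanged, and an
#' identity warp (dst == src) returns the input bit-exactly.
#'
#' @param image a [face_image()] (or plain matrix).
#' @param src,dst source and destination landmarks: `landmark_set`s of the
#'   same scheme and viewpoint, or plain n x 2 matrices of equal size.
#' @param add_anchors add the fixed frame anchors to the control set
#'   (default `TRUE`; disable only if `src`/`dst` already span the frame).
#' @return a `face_image` of the same size and angular metadata.
#' @export
warp_image <- function(image, src, dst, add_anchors = TRUE) {
  if (inherits(src, "landmark_set") && inherits(dst, "landmark_set")) {
    if (src$scheme$name != dst$scheme$name ||
        src$viewpoint != dst$viewpoint)
      stop(sprintf("scheme/viewpoint mismatch between src (%s/%s) and dst (%s/%s)",
                   src$scheme$name, src$viewpoint,
                   dst$scheme$name, dst$viewpoint), call. = FALSE)
  }
  img <- if (inherits(image, "face_image")) image$pixels else as.matrix(image)
  wd <- if (inherits(image, "face_image")) image$width_deg else NA_real_
  S <- as_points(src); D <- as_points(dst)
  if (nrow(S) != nrow(D))
    stop("src and dst must have the same number of points", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (inherits(src, "landmark_set") &&
      any(src$image_size != c(w, h)))
    stop(sprintf("image size %d x %d does not match landmark frame %g x %g",
                 w, h, src$image_size[1], src$image_size[2]), call. = FALSE)

  if (isTRUE(all.equal(S, D, tolerance = 0)) || identical(S, D))
    return(face_image(img, width_deg = wd))

  if (add_anchors) {
    A <- frame_anchors(w, h)
    S <- rbind(S, A); D <- rbind(D, A)
  }
  tri <- delaunay_triangulation(S)

  res <- warp_fill_cpp(img, S, D, matrix(as.integer(tri), ncol = 3))
  if (res$flips > 0L)
    warning(sprintf("%d destination triangle(s) flipped orientation; the warp folds there",
                    res$flips), call. = FALSE)
  face_image(res$out, width_deg = wd)
}
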
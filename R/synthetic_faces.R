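## Parametric synthetic faces with ground-truth landmarks in both annotation
## schemes. Faces are schematic, not photorealistic: the pipeline's contracts
## are geometric and photometric, and every downstream stage (caricaturing,
## warping, blur, phosphenisation, rating simulation) only needs smooth,
## deterministic images with exactly known landmarks.

## Canonical 147-point template geometry in a unit frame (x right, y down).
## Every region of the hand-annotation scheme is traced: jaw outline,
## forehead/hairline, both ears, both eyebrows as closed contours (width),
## eyes, nose bridge + mid-nose width + base, and outer + inner lips.
template_points_unit <- function(jaw_width = 1) {
  cx <- 0.5
  arc <- function(n) seq(0, 1, length.out = n)

  t <- arc(27)  # jaw: left temple -> chin -> right temple
  al <- pi * (1 + t)
  a_j <- 0.30 * (1 - (1 - jaw_width) * sin(pi * t))
  jaw <- cbind(cx + a_j * cos(al), 0.46 - 0.42 * sin(al))

  t <- arc(17)  # forehead/hairline: left temple -> crown -> right temple
  al <- pi * (1 + t)
  forehead <- cbind(cx + 0.285 * cos(al), 0.46 + 0.33 * sin(al))

  ear <- function(side) {  # outer arc of the pinna
    b <- pi / 2 + side * pi * arc(11)
    cbind(cx - side * 0.335 + 0.025 * cos(b), 0.48 + 0.075 * sin(b))
  }

  brow <- function(side) {  # closed contour: 5 on top, 5 underneath
    xs <- side * seq(0.20, 0.065, length.out = 5)
    top <- cbind(cx - xs, 0.355 - 0.025 * sin(pi * arc(5)))
    bot <- cbind(cx - xs, 0.385 - 0.018 * sin(pi * arc(5)))
    list(top = top, bot = bot)
  }
  bl <- brow(1); br <- brow(-1)

  eye <- function(side) {
    th <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(cx - side * 0.13 + 0.055 * cos(side * th),
          0.46 + 0.028 * sin(th))
  }

  nose_bridge <- cbind(rep(cx, 4), seq(0.45, 0.575, length.out = 4))
  nmid <- function(side)
    cbind(cx - side * c(0.028, 0.034, 0.040), c(0.515, 0.548, 0.580))
  t <- arc(9)
  nose_base <- cbind(cx + 0.055 * cos(pi * (1 + t)),
                     0.612 + 0.018 * sin(pi * t))

  th <- seq(0, 2 * pi, length.out = 17)[-17]
  mouth_outer <- cbind(cx + 0.100 * cos(th), 0.73 + 0.038 * sin(th))
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  mouth_inner <- cbind(cx + 0.065 * cos(th), 0.73 + 0.015 * sin(th))

  rbind(jaw, forehead, ear(1), ear(-1),
        bl$top, bl$bot, br$top, br$bot,
        eye(1), eye(-1),
        nose_bridge, nmid(1), nmid(-1), nose_base,
        mouth_outer, mouth_inner)
}

#' Sex-specific 147-point face template
#'
#' Deterministic, bilaterally symmetric template landmark set covering every
#' region of the hand-annotation scheme. The male and female templates
#' differ in the jaw-width parameter.
#'
#' @param sex `"M"` or `"F"`.
#' @param image_size c(width, height) of the target frame, pixels.
#' @return a frontal `landmark_set` (S147 scheme).
#' @export
make_template <- function(sex = c("M", "F"), image_size = c(128, 128)) {
  sex <- match.arg(sex)
  jw <- if (sex == "M") 1.00 else 0.86
  pts <- template_points_unit(jaw_width = jw)
  pts <- cbind(pts[, 1] * image_size[1], pts[, 2] * image_size[2])
  landmark_set(pts, "S147", "front", image_size)
}

#' Sample a synthetic identity
#'
#' An identity is a smooth displacement field away from its sex's template:
#' a low-dimensional part (per-feature random shift and scaling, so whole
#' features move and resize coherently) plus small per-point jitter. The
#' field is zero-mean across identities by construction, and the
#' `distinctiveness` scalar multiplies the whole field when it is applied.
#'
#' @param template the sex template from [make_template()].
#' @param sex identity sex label.
#' @param id identity label.
#' @param distinctiveness scalar multiplier on the displacement field
#'   (0 reproduces the template exactly).
#' @param seed integer seed; the same seed reproduces the same identity.
#' @return an object of class `identity_params` with the (unscaled)
#'   `displacement` field in pixels.
#' @export
sample_identity <- function(template, sex, id, distinctiveness = 1, seed) {
  stopifnot(inherits(template, "landmark_set"),
            template$scheme$name == "S147")
  w <- template$image_size[1]
  # ears ride with the head outline so exaggeration cannot fold the thin
  # gap between pinna and jawline; features vary as coherent units
  groups <- list(
    outline = c("jaw", "forehead", "ear_left", "ear_right"),
    brow_left = c("brow_left_top", "brow_left_bot"),
    brow_right = c("brow_right_top", "brow_right_bot"),
    eye_left = "eye_left", eye_right = "eye_right",
    nose = c("nose_bridge", "nose_mid_left", "nose_mid_right", "nose_base"),
    mouth = c("mouth_outer", "mouth_inner")
  )
  disp <- with_seed(seed, {
    d <- matrix(0, nrow = nrow(template$points), ncol = 2)
    for (g in groups) {
      idx <- region_index(template, g)
      ctr <- colMeans(template$points[idx, , drop = FALSE])
      shift <- stats::rnorm(2, sd = 0.008 * w)
      scale <- stats::rnorm(2, sd = 0.04)
      rel <- sweep(template$points[idx, , drop = FALSE], 2, ctr)
      d[idx, ] <- sweep(rel %*% diag(scale), 2, shift, `+`)
    }
    # jitter kept small relative to contour spacing so identity fields stay
    # smooth (close parallel contours must not cross once exaggerated)
    d + matrix(stats::rnorm(2 * nrow(d), sd = 0.0015 * w), ncol = 2)
  })
  structure(list(id = id, sex = sex, displacement = disp,
                 distinctiveness = distinctiveness, seed = seed),
            class = "identity_params")
}

#' Frontal landmarks of a sampled identity
#'
#' @param template the sex template.
#' @param params an `identity_params`.
#' @return a frontal S147 `landmark_set`:
#'   template + distinctiveness * displacement.
#' @export
identity_landmarks <- function(template, params) {
  stopifnot(inherits(params, "identity_params"))
  pts <- template$points + params$distinctiveness * params$displacement
  landmark_set(pts, "S147", "front", template$image_size)
}

#' Rotate landmarks to a non-frontal viewpoint
#'
#' Applies horizontal foreshortening about the frame's vertical midline,
#' `x' = x_c + (x - x_c) cos(yaw)`, and removes the occluded ear's 11 points
#' for non-zero yaw (S147 becomes S136; the 68-point scheme has no ear
#' points and keeps its count). Positive yaw turns the face to the sitter's
#' right and occludes the right ear.
#'
#' @param landmarks a frontal `landmark_set` (S147 or S68).
#' @param viewpoint target viewpoint name (`"front"`, `"right10"`,
#'   `"left10"`, `"left30"`) or a yaw angle in degrees (0, 10, -10, -30).
#' @return the projected `landmark_set` with its viewpoint updated.
#' @export
project_viewpoint <- function(landmarks, viewpoint) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.numeric(viewpoint)) {
    m <- match(viewpoint, VIEWPOINTS)
    if (is.na(m)) stop("unsupported yaw: ", viewpoint, call. = FALSE)
    viewpoint <- names(VIEWPOINTS)[m]
  }
  if (!viewpoint %in% names(VIEWPOINTS))
    stop("unknown viewpoint: ", deparse(viewpoint), call. = FALSE)
  yaw <- VIEWPOINTS[[viewpoint]]
  if (yaw == 0 && landmarks$viewpoint == "front") return(landmarks)
  if (landmarks$viewpoint != "front")
    stop("projection starts from frontal landmarks", call. = FALSE)
  pts <- landmarks$points
  scheme <- landmarks$scheme$name
  if (yaw != 0 && scheme == "S147") {
    occluded <- if (yaw > 0) "ear_right" else "ear_left"
    pts <- pts[-region_index(landmarks, occluded), , drop = FALSE]
    scheme <- "S136"
  }
  xc <- landmarks$image_size[1] / 2
  pts[, 1] <- xc + (pts[, 1] - xc) * cos(yaw * pi / 180)
  landmark_set(pts, scheme, viewpoint, landmarks$image_size)
}

## Fill a polygon (n x 2 pixel vertices) on the canvas. `value` is either a
## constant or a function(px, py) returning per-pixel intensities.
fill_polygon <- function(canvas, poly, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  x0 <- max(0L, floor(min(poly[, 1]))); x1 <- min(w - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2]))); y1 <- min(h - 1L, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  bnd <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  if (!any(inside)) return(canvas)
  v <- if (is.function(value)) value(px[inside], py[inside]) else value
  canvas[cbind(py[inside] + 1L, px[inside] + 1L)] <- v
  canvas
}

circle_poly <- function(cx, cy, r, n = 12) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Render a synthetic face image from its landmarks
#'
#' Deterministic schematic rendering: the head (jaw + forehead outline) is
#' filled with a mild vertical shading gradient, and ears, brows, eyes with
#' pupils, nose and lips are filled from their landmark contours, so that
#' landmark warps produce visible, testable pixel changes. The background
#' is uniform.
#'
#' @param landmarks an S147 or S136 `landmark_set`.
#' @param width_deg angular-size metadata for the returned image.
#' @return a `face_image` of the landmark frame's size.
#' @export
render_face <- function(landmarks, width_deg = 18.11) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!landmarks$scheme$name %in% c("S147", "S136"))
    stop("rendering needs the hand-annotation scheme (S147/S136)",
         call. = FALSE)
  w <- landmarks$image_size[1]; h <- landmarks$image_size[2]
  p <- landmarks$points
  ri <- function(region) region_index(landmarks, region)
  canvas <- matrix(0.15, nrow = h, ncol = w)

  # ears behind the head outline
  has_left <- any(landmarks$scheme$region_labels %in% c("ear_left", "ear"))
  for (er in intersect(c("ear_left", "ear_right", "ear"),
                       unique(landmarks$scheme$region_labels)))
    canvas <- fill_polygon(canvas, p[ri(er), ], 0.70)

  head <- rbind(p[ri("jaw"), ], p[rev(ri("forehead")), ])
  ymin <- min(head[, 2]); ymax <- max(head[, 2])
  canvas <- fill_polygon(canvas, head, function(px, py)
    0.72 + 0.12 * (py - ymin) / (ymax - ymin))

  for (side in c("left", "right")) {
    b <- rbind(p[ri(paste0("brow_", side, "_top")), ],
               p[rev(ri(paste0("brow_", side, "_bot"))), ])
    canvas <- fill_polygon(canvas, b, 0.25)
    e <- p[ri(paste0("eye_", side)), ]
    canvas <- fill_polygon(canvas, e, 0.93)
    ctr <- colMeans(e)
    canvas <- fill_polygon(canvas, circle_poly(ctr[1], ctr[2], 0.012 * w), 0.08)
  }

  nose <- rbind(p[ri("nose_mid_left"), ], p[ri("nose_base"), ],
                p[rev(ri("nose_mid_right")), ], p[rev(ri("nose_bridge")), ])
  canvas <- fill_polygon(canvas, nose, 0.62)
  canvas <- fill_polygon(canvas, p[ri("mouth_outer"), ], 0.45)
  canvas <- fill_polygon(canvas, p[ri("mouth_inner"), ], 0.22)

  face_image(canvas, width_deg = width_deg)
}

#' Derive the 68-point annotation from the 147-point set
#'
#' Deterministic selection of the automatic-detector landmark layout from
#' the hand-annotated points: 17 jawline points subsampled from the 27-point
#' outline, the 5 upper points of each brow (the lower contour, i.e. brow
#' width, is not represented), the 4 bridge and 5 of the 9 base points of
#' the nose (the mid-nose width points are not represented), 6 of the 8
#' points of each eye, and 12 outer + 8 inner lip points. Forehead and ear
#' points have no counterpart and are dropped entirely.
#'
#' @param landmarks an S147 or S136 `landmark_set`.
#' @return an S68 `landmark_set` at the same viewpoint.
#' @export
derive_68 <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!landmarks$scheme$name %in% c("S147", "S136"))
    stop("derive_68 expects the hand-annotation scheme (S147/S136)",
         call. = FALSE)
  p <- landmarks$points
  ri <- function(region) region_index(landmarks, region)
  sel <- function(idx, take) idx[take]
  pts <- rbind(
    p[sel(ri("jaw"), round(seq(1, 27, length.out = 17))), ],
    p[ri("brow_left_top"), ],
    p[ri("brow_right_top"), ],
    p[ri("nose_bridge"), ],
    p[sel(ri("nose_base"), c(1, 3, 5, 7, 9)), ],
    p[sel(ri("eye_left"), c(1, 2, 4, 5, 6, 8)), ],
    p[sel(ri("eye_right"), c(1, 2, 4, 5, 6, 8)), ],
    p[sel(ri("mouth_outer"), round(seq(1, 16, length.out = 12))), ],
    p[sel(ri("mouth_inner"), round(seq(1, 10, length.out = 8))), ]
  )
  landmark_set(pts, "S68", landmarks$viewpoint, landmarks$image_size)
}

#' Generate the full synthetic study cohort
#'
#' Emulates the stimulus set of the behavioural experiments: `n_male` +
#' `n_female` test identities, each at the four viewpoints, with
#' sex-by-viewpoint average faces built from a larger seeded pool of
#' identities disjoint from the test cohort (mirroring averages taken over
#' "a large number of individuals" of the category).
#'
#' @param n_male,n_female test identities per sex (defaults 13 + 13).
#' @param seed master integer seed; everything (identities, pool) derives
#'   from it deterministically.
#' @param image_size c(width, height) pixels for all rendered faces.
#' @param avg_pool pool size per sex for the average faces (default 50).
#' @param distinctiveness identity distinctiveness multiplier.
#' @param render render veridical and average images (default `TRUE`;
#'   `FALSE` gives a landmarks-only cohort for fast simulation work).
#' @return an object of class `cohort`: `landmarks[[id]][[viewpoint]]`,
#'   `images[[id]][[viewpoint]]`, `averages[[sex]][[viewpoint]]`
#'   ([average_face()] objects), `identities`, and a `manifest` data frame
#'   of the veridical stimuli (one row per identity x viewpoint).
#' @export
make_cohort <- function(n_male = 13, n_female = 13, seed = 1L,
                        image_size = c(128, 128), avg_pool = 50,
                        distinctiveness = 1, render = TRUE) {
  templates <- list(M = make_template("M", image_size),
                    F = make_template("F", image_size))
  n_ids <- c(M = n_male, F = n_female)
  sub <- with_seed(seed, sample.int(2^30, n_male + n_female + 2 * avg_pool))
  k <- 0L

  identities <- list()
  for (sex in c("M", "F")) {
    for (i in seq_len(n_ids[[sex]])) {
      id <- sprintf("%s%02d", sex, i)
      k <- k + 1L
      identities[[id]] <- sample_identity(templates[[sex]], sex, id,
                                          distinctiveness, seed = sub[k])
    }
  }
  pools <- list()
  for (sex in c("M", "F")) {
    pools[[sex]] <- lapply(seq_len(avg_pool), function(i) {
      k <<- k + 1L
      sample_identity(templates[[sex]], sex, sprintf("pool_%s%02d", sex, i),
                      distinctiveness, seed = sub[k])
    })
  }

  vps <- names(VIEWPOINTS)
  landmarks <- list(); images <- list()
  for (id in names(identities)) {
    sex <- identities[[id]]$sex
    front <- identity_landmarks(templates[[sex]], identities[[id]])
    landmarks[[id]] <- lapply(vps, function(v) project_viewpoint(front, v))
    names(landmarks[[id]]) <- vps
    if (render) {
      images[[id]] <- lapply(landmarks[[id]], render_face)
    }
  }

  averages <- list()
  for (sex in c("M", "F")) {
    front_sets <- lapply(pools[[sex]], function(p)
      identity_landmarks(templates[[sex]], p))
    avg_front <- build_average_landmarks(front_sets)
    averages[[sex]] <- lapply(vps, function(v) {
      lm <- project_viewpoint(avg_front, v)
      average_face(lm, sex, image = if (render) render_face(lm) else NULL)
    })
    names(averages[[sex]]) <- vps
  }

  manifest <- do.call(rbind, lapply(names(identities), function(id)
    data.frame(identity = id, sex = identities[[id]]$sex, viewpoint = vps,
               caricature = "V", resolution = "HR",
               stringsAsFactors = FALSE)))

  structure(list(templates = templates, identities = identities,
                 landmarks = landmarks, images = images,
                 averages = averages, manifest = manifest,
                 image_size = image_size, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  sexes <- vapply(x$identities, function(i) i$sex, character(1))
  cat(sprintf("Synthetic cohort: %d identities (%d M, %d F) x %d viewpoints, frame %g x %g (seed %d)\n",
              length(x$identities), sum(sexes == "M"), sum(sexes == "F"),
              length(VIEWPOINTS), x$image_size[1], x$image_size[2], x$seed))
  invisible(x)
}

#' Build the full caricature stimulus inventory
#'
#' For every identity x viewpoint of the cohort, produces the veridical
#' stimulus plus shape-only caricatures from the 68-point and the
#' 147/136-point landmark sets (both at the same strength, both away from
#' the same sex-and-viewpoint-matched average), mirroring the 312-image
#' inventory of the behavioural studies (104 veridical, 104 C-68p,
#' 104 C-147p at the default cohort size).
#'
#' @param cohort a rendered [make_cohort()] result.
#' @param strength caricature strength (default 0.6).
#' @return an object of class `stimulus_set`: list `stimuli` and a
#'   `manifest` data frame keyed by (identity, viewpoint, caricature).
#' @export
make_stimulus_set <- function(cohort, strength = 0.6) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$images) || !length(cohort$images))
    stop("cohort was built with render = FALSE; no images to caricature",
         call. = FALSE)
  spec <- caricature_spec(strength)
  stimuli <- list(); rows <- list()
  for (id in names(cohort$landmarks)) {
    sex <- cohort$identities[[id]]$sex
    for (vp in names(cohort$landmarks[[id]])) {
      img <- cohort$images[[id]][[vp]]
      lms <- cohort$landmarks[[id]][[vp]]
      avg <- cohort$averages[[sex]][[vp]]
      avg68 <- average_face(derive_68(avg$landmarks), sex)
      trio <- list(
        V = stimulus(img, id, sex, vp, scheme = NA, strength = 0),
        `C-68p` = make_caricature(img, derive_68(lms), avg68, spec,
                                  identity = id, sex = sex),
        `C-147p` = make_caricature(img, lms, avg, spec,
                                   identity = id, sex = sex)
      )
      for (lev in names(trio)) {
        key <- paste(id, vp, lev, sep = "_")
        stimuli[[key]] <- trio[[lev]]
        rows[[key]] <- data.frame(identity = id, sex = sex, viewpoint = vp,
                                  caricature = lev, resolution = "HR",
                                  key = key, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (anyDuplicated(manifest$key))
    stop("duplicate stimulus keys in manifest", call. = FALSE)
  structure(list(stimuli = stimuli, manifest = manifest,
                 strength = strength),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d stimuli (%s)\n", length(x$stimuli),
              paste(sprintf("%s: %d", names(table(x$manifest$caricature)),
                            table(x$manifest$caricature)), collapse = ", ")))
  invisible(x)
}
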
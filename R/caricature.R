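#' Caricature strength specification
#'
#' Strength `s` scales every landmark's displacement away from the
#' category-matched average face: `s = 0` is the veridical face, `s = 1`
#' doubles the distance between each landmark and its average position, and
#' the behavioural work this package supports uses `s = 0.6`. Strengths
#' above 1 fall outside the regime validated for artefact-free morphs and
#' are rejected unless `allow_extreme = TRUE`. Only shape is caricatured
#' ("warp not fade"): texture is never blended.
#'
#' @param strength dimensionless fraction `s >= 0` (0.6 = 60%).
#' @param allow_extreme permit `s > 1`.
#' @return an object of class `caricature_spec`.
#' @export
caricature_spec <- function(strength = 0.6, allow_extreme = FALSE) {
  if (!is.numeric(strength) || length(strength) != 1L || is.na(strength))
    stop("`strength` must be a single number", call. = FALSE)
  if (strength < 0)
    stop("negative strength (anti-caricature) is out of scope", call. = FALSE)
  if (strength > 1 && !allow_extreme)
    stop("strength > 1 exceeds the validated regime; pass allow_extreme = TRUE to override",
         call. = FALSE)
  structure(list(strength = strength, shape_only = TRUE),
            class = "caricature_spec")
}

#' Average face for a (sex, viewpoint) category
#'
#' Caricaturing must push a face away from an average matched on category, so
#' that only identity information is exaggerated: a female face at 30 degrees
#' left is caricatured away from the average 30-degrees-left female.
#'
#' @param landmarks average-face `landmark_set`.
#' @param sex `"M"` or `"F"`.
#' @param image optional rendered average `face_image`.
#' @return an object of class `average_face` with fields `sex`, `viewpoint`,
#'   `landmarks`, `image`.
#' @export
average_face <- function(landmarks, sex, image = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'", call. = FALSE)
  structure(list(sex = sex, viewpoint = landmarks$viewpoint,
                 landmarks = landmarks, image = image),
            class = "average_face")
}

#' Caricature landmark positions
#'
#' For every landmark `i`, the caricatured position is
#' `p'_i = v_i + s * (v_i - a_i)`, where `v` is the veridical landmark, `a`
#' the corresponding average-face landmark, and `s` the strength: at
#' `s = 1` the distance of every landmark from its average position exactly
#' doubles. The caricatured point stays on the ray from the average through
#' the veridical point.
#'
#' @param veridical,average `landmark_set`s of the same scheme, viewpoint
#'   and point order.
#' @param s caricature strength (`s >= 0`), or a [caricature_spec()].
#' @return the caricatured `landmark_set` (same scheme and viewpoint).
#' @examples
#' # a landmark 10 px right of its average position moves 10 px further out
#' # at s = 1: (110, 100) -> (120, 100)
#' @export
caricature_landmarks <- function(veridical, average, s) {
  stopifnot(inherits(veridical, "landmark_set"),
            inherits(average, "landmark_set"))
  if (inherits(s, "caricature_spec")) s <- s$strength
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
    stop("caricature strength must be a single number >= 0", call. = FALSE)
  if (veridical$scheme$name != average$scheme$name)
    stop(sprintf("scheme mismatch: veridical is %s, average is %s",
                 veridical$scheme$name, average$scheme$name), call. = FALSE)
  if (veridical$viewpoint != average$viewpoint)
    stop(sprintf("viewpoint mismatch: veridical is %s, average is %s",
                 veridical$viewpoint, average$viewpoint), call. = FALSE)
  pts <- veridical$points + s * (veridical$points - average$points)
  landmark_set(pts, veridical$scheme, veridical$viewpoint,
               veridical$image_size, check = FALSE)
}

#' Componentwise mean of landmark sets
#'
#' Builds an average-face landmark set as the arithmetic mean of
#' corresponding points over many individuals of the same category.
#'
#' @param sets non-empty list of `landmark_set`s, all of the same scheme and
#'   viewpoint.
#' @return the mean `landmark_set`.
#' @export
build_average_landmarks <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("`sets` must be a non-empty list of landmark sets", call. = FALSE)
  schemes <- vapply(sets, function(s) s$scheme$name, character(1))
  views <- vapply(sets, function(s) s$viewpoint, character(1))
  if (length(unique(schemes)) != 1L)
    stop("mixed schemes in average: ", paste(unique(schemes), collapse = ", "),
         call. = FALSE)
  if (length(unique(views)) != 1L)
    stop("mixed viewpoints in average", call. = FALSE)
  acc <- Reduce(`+`, lapply(sets, function(s) s$points)) / length(sets)
  landmark_set(acc, sets[[1]]$scheme, sets[[1]]$viewpoint,
               sets[[1]]$image_size)
}

#' Stimulus container
#'
#' An image together with its provenance: identity, sex, viewpoint, landmark
#' scheme used for caricaturing, caricature strength, resolution condition,
#' and the seed of any stochastic rendering step.
#'
#' @param image a `face_image`.
#' @param identity identity label.
#' @param sex `"M"`/`"F"` or `NA`.
#' @param viewpoint viewpoint label.
#' @param scheme landmark scheme name used (or `NA` for veridical).
#' @param strength caricature strength (0 for veridical).
#' @param resolution resolution condition label (default `"HR"`).
#' @param seed seed of any stochastic rendering, or `NA`.
#' @return an object of class `stimulus`.
#' @export
stimulus <- function(image, identity, sex = NA, viewpoint, scheme = NA,
                     strength = 0, resolution = "HR", seed = NA) {
  stopifnot(inherits(image, "face_image"))
  structure(list(image = image, identity = identity, sex = sex,
                 viewpoint = viewpoint, scheme = scheme,
                 strength = strength, resolution = resolution, seed = seed),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus %s (%s, %s): s = %g (%s), resolution %s\n",
              x$identity, ifelse(is.na(x$sex), "?", x$sex), x$viewpoint,
              x$strength, ifelse(is.na(x$scheme), "-", x$scheme),
              x$resolution))
  invisible(x)
}

#' Make a shape-only caricatured stimulus
#'
#' Computes the caricatured landmark positions away from the
#' category-matched average and warps the image from the veridical to the
#' caricatured landmarks (piecewise-affine, texture untouched). At `s = 0`
#' the image passes through unchanged.
#'
#' @param image veridical `face_image`.
#' @param veridical_lms veridical `landmark_set` (147/136-point hand scheme
#'   or 68-point automatic scheme).
#' @param avg an [average_face()] whose category matches `sex` and the
#'   landmark viewpoint.
#' @param spec a [caricature_spec()] (or a bare strength).
#' @param identity identity label recorded in the stimulus.
#' @param sex sex of the face, checked against the average's category.
#' @return a [stimulus()] with provenance filled in.
#' @export
make_caricature <- function(image, veridical_lms, avg, spec = caricature_spec(0.6),
                            identity = "face", sex = avg$sex) {
  stopifnot(inherits(avg, "average_face"),
            inherits(veridical_lms, "landmark_set"))
  if (inherits(spec, "caricature_spec")) s <- spec$strength
  else s <- caricature_spec(spec)$strength
  if (!is.na(sex) && sex != avg$sex)
    stop(sprintf("category mismatch: %s face caricatured against %s average",
                 sex, avg$sex), call. = FALSE)
  if (veridical_lms$viewpoint != avg$viewpoint)
    stop(sprintf("category mismatch: %s face against %s average",
                 veridical_lms$viewpoint, avg$viewpoint), call. = FALSE)
  if (s == 0) {
    return(stimulus(image, identity, sex, veridical_lms$viewpoint,
                    scheme = NA, strength = 0))
  }
  cari <- caricature_landmarks(veridical_lms, avg$landmarks, s)
  warped <- warp_image(image, veridical_lms, cari)
  stimulus(warped, identity, sex, veridical_lms$viewpoint,
           scheme = veridical_lms$scheme$name, strength = s)
}
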
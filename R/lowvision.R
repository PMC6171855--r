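## Low-vision rendering: (1) spatially uniform Gaussian blur whose cutoff
## frequency falls with simulated eccentricity, as in peripheral /
## macular-degeneration viewing; (2) phosphenised prosthetic-vision rendering
## (grid of circular Gaussian phosphenes, 8-level quantisation, optional
## random electrode dropout).

#' Blur viewing condition
#'
#' @param eccentricity_deg simulated eccentricity E in degrees; 0 is the
#'   high-resolution passthrough, 20 and 30 are the moderate and severe blur
#'   conditions.
#' @param f0 foveal cutoff frequency, cycles/degree (default 30).
#' @param E2 eccentricity at which the cutoff halves, degrees (default 2.5).
#' @return an object of class `blur_condition`.
#' @export
blur_condition <- function(eccentricity_deg, f0 = 30, E2 = 2.5) {
  if (!is.numeric(eccentricity_deg) || eccentricity_deg < 0)
    stop("eccentricity must be >= 0 degrees", call. = FALSE)
  structure(list(eccentricity_deg = eccentricity_deg, f0 = f0, E2 = E2,
                 label = if (eccentricity_deg == 0) "HR"
                         else paste0("Blur", eccentricity_deg)),
            class = "blur_condition")
}

#' Cutoff spatial frequency at a given eccentricity
#'
#' The acuity cutoff declines with eccentricity following the standard
#' inverse-linear law `f_c(E) = f0 * E2 / (E2 + E)`: `f_c(0) = f0` at the
#' fovea, and `f_c(E2) = f0 / 2`.
#'
#' @param E eccentricity in degrees (`E >= 0`).
#' @param f0 foveal cutoff, cycles/degree.
#' @param E2 halving eccentricity, degrees.
#' @return cutoff frequency in cycles/degree, strictly decreasing in `E`.
#' @export
cutoff_frequency <- function(E, f0 = 30, E2 = 2.5) {
  if (any(E < 0)) stop("eccentricity must be >= 0", call. = FALSE)
  f0 * E2 / (E2 + E)
}

## Gaussian blur sd (degrees) whose modulation transfer is 0.5 at f_c:
## MTF(f) = exp(-2 pi^2 sigma^2 f^2)  =>  sigma = sqrt(ln 2 / 2) / (pi f_c)
sigma_for_cutoff <- function(f_c) sqrt(log(2) / 2) / (pi * f_c)

#' Apply eccentricity-dependent uniform Gaussian blur
#'
#' Low-pass filters the image with a Gaussian whose modulation transfer
#' function equals 0.5 at the cutoff frequency `f_c(E)`; the attenuation at
#' frequency `f` (cycles/degree) is `exp(-2 pi^2 sigma^2 f^2)`. The filter
#' is applied exactly in the frequency domain (periodic boundary), so it is
#' linear, shift-invariant, and preserves the image mean. At `E = 0` the
#' input is returned unchanged.
#'
#' @param image a [face_image()] carrying angular-size metadata.
#' @param cond a [blur_condition()], or a bare eccentricity in degrees.
#' @return the blurred `face_image`.
#' @export
blur_image <- function(image, cond) {
  stopifnot(inherits(image, "face_image"))
  if (!inherits(cond, "blur_condition")) cond <- blur_condition(cond)
  if (cond$eccentricity_deg == 0) return(image)
  ppd <- pixels_per_degree(image)  # errors if width_deg missing
  f_c <- cutoff_frequency(cond$eccentricity_deg, cond$f0, cond$E2)
  sigma <- sigma_for_cutoff(f_c)   # degrees
  img <- image$pixels
  h <- nrow(img); w <- ncol(img)
  # frequency of FFT bin k along an axis of length n: k/n cycles/pixel
  # (wrapped to the negative half), times ppd pixels/degree -> cycles/degree
  fx <- (seq_len(w) - 1) / w; fx <- ifelse(fx > 0.5, fx - 1, fx)
  fy <- (seq_len(h) - 1) / h; fy <- ifelse(fy > 0.5, fy - 1, fy)
  f2 <- outer(fy^2, fx^2, `+`) * ppd^2           # |f|^2 in (cycles/deg)^2
  H <- exp(-2 * pi^2 * sigma^2 * f2)
  out <- Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (w * h)
  face_image(pmin(pmax(out, 0), 1), width_deg = image$width_deg)
}

#' Phosphene viewing condition
#'
#' @param grid c(rows, cols) of the simulated electrode array; 40 x 40 and
#'   32 x 32 are the conditions studied.
#' @param dropout fraction of phosphenes rendered inactive (failed
#'   electrodes); 0 (ND) or 0.30 (DO).
#' @param seed integer seed for the dropout mask (one mask per condition,
#'   held fixed across trials, emulating a fixed broken-electrode array).
#' @param levels number of quantisation levels L (default 8).
#' @return an object of class `phosphene_condition` with a conventional
#'   label such as `"40x40ND"` or `"32x32DO"`.
#' @export
phosphene_condition <- function(grid = c(40, 40), dropout = 0.30, seed = 1L,
                                levels = 8L) {
  if (length(grid) != 2L || any(grid < 1)) stop("bad grid", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout fraction must be in [0, 1)", call. = FALSE)
  structure(list(grid = as.integer(grid), dropout = dropout,
                 seed = as.integer(seed), levels = as.integer(levels),
                 label = paste0(grid[1], "x", grid[2],
                                if (dropout > 0) "DO" else "ND")),
            class = "phosphene_condition")
}

#' Place a regular phosphene lattice over the face
#'
#' Sites are cell-centred on a rows x cols lattice spanning the face
#' bounding box: along each axis the first and last sites sit half a cell
#' spacing inside the box edges.
#'
#' @param face_box numeric c(x0, y0, x1, y1), pixel coordinates of the box
#'   the grid tiles (typically hairline to just below the chin).
#' @param grid c(rows, cols).
#' @return data frame with columns `row`, `col`, `x`, `y` and attributes
#'   `spacing` (c(dx, dy), pixels).
#' @export
place_phosphene_grid <- function(face_box, grid) {
  stopifnot(length(face_box) == 4L, length(grid) == 2L)
  wbox <- face_box[3] - face_box[1]; hbox <- face_box[4] - face_box[2]
  dx <- wbox / grid[2]; dy <- hbox / grid[1]
  if (dx < 1 || dy < 1)
    stop(sprintf("face box too small for a %d x %d grid (spacing %.2f x %.2f px < 1)",
                 grid[1], grid[2], dx, dy), call. = FALSE)
  g <- expand.grid(col = seq_len(grid[2]), row = seq_len(grid[1]))
  sites <- data.frame(
    row = g$row, col = g$col,
    x = face_box[1] + (g$col - 0.5) * dx,
    y = face_box[2] + (g$row - 0.5) * dy
  )
  attr(sites, "spacing") <- c(dx = dx, dy = dy)
  sites
}

#' Random electrode dropout
#'
#' Removes `round(d * N)` sites, sampled uniformly without replacement.
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param sites site table from [place_phosphene_grid()].
#' @param d dropout fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return the surviving subset of `sites` (spacing attribute preserved).
#' @export
apply_dropout <- function(sites, d, seed) {
  if (d < 0 || d >= 1) stop("dropout fraction must be in [0, 1)", call. = FALSE)
  n <- nrow(sites)
  n_drop <- round(d * n)
  if (n_drop == 0L) return(sites)
  drop <- with_seed(seed, sample.int(n, n_drop))
  out <- sites[-drop, , drop = FALSE]
  attr(out, "spacing") <- attr(sites, "spacing")
  out
}

#' Sample image brightness at phosphene sites and quantise
#'
#' Each site reads the intensity of the nearest-neighbour image pixel and
#' maps it to a discrete level in `0 .. L-1` by uniform binning of `[0, 1]`
#' (intensity 1 maps to the top level).
#'
#' @param image a `face_image` (or matrix).
#' @param sites site table.
#' @param L number of quantisation levels (default 8).
#' @return integer vector of levels, one per site.
#' @export
sample_and_quantize <- function(image, sites, L = 8L) {
  img <- if (inherits(image, "face_image")) image$pixels else as.matrix(image)
  h <- nrow(img); w <- ncol(img)
  ix <- pmin(pmax(round(sites$x), 0), w - 1) + 1L
  iy <- pmin(pmax(round(sites$y), 0), h - 1) + 1L
  val <- img[cbind(iy, ix)]
  as.integer(pmin(floor(val * L), L - 1))
}

#' Render quantised phosphenes
#'
#' Each surviving site becomes an isotropic circular Gaussian patch on a
#' black background. Brightness is conveyed jointly by peak amplitude
#' `a = level / (L - 1)` and by size, `sigma_p = spacing * (0.30 + 0.10 a)`,
#' so brighter phosphenes are both brighter and slightly larger. Overlapping
#' patches are summed (additive light) and the result clipped to `[0, 1]`.
#'
#' @param levels integer levels from [sample_and_quantize()], one per site.
#' @param sites site table (must carry the `spacing` attribute).
#' @param image_size c(width, height) of the output, pixels.
#' @param L number of quantisation levels.
#' @return a `face_image` (angular metadata unset).
#' @export
render_phosphenes <- function(levels, sites, image_size, L = 8L) {
  stopifnot(length(levels) == nrow(sites))
  spacing <- attr(sites, "spacing")
  if (is.null(spacing)) stop("sites table lacks its spacing attribute",
                             call. = FALSE)
  delta <- mean(spacing)
  w <- image_size[1]; h <- image_size[2]
  out <- matrix(0, nrow = h, ncol = w)
  for (i in seq_len(nrow(sites))) {
    a <- levels[i] / (L - 1)
    if (a == 0) next
    sg <- delta * (0.30 + 0.10 * a)
    rad <- ceiling(4 * sg)
    xs <- max(0, floor(sites$x[i]) - rad):min(w - 1, ceiling(sites$x[i]) + rad)
    ys <- max(0, floor(sites$y[i]) - rad):min(h - 1, ceiling(sites$y[i]) + rad)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - sites$x[i])^2 / (2 * sg^2))
    gy <- exp(-(ys - sites$y[i])^2 / (2 * sg^2))
    out[ys + 1L, xs + 1L] <- out[ys + 1L, xs + 1L] + a * outer(gy, gx)
  }
  face_image(pmin(out, 1), width_deg = NA_real_)
}

#' Phosphenise an image
#'
#' Full prosthetic-vision rendering: place the phosphene lattice over the
#' face box, apply the condition's electrode dropout, sample and quantise
#' brightness at each surviving site, and render the Gaussian phosphenes.
#' Deterministic (byte-identical) for a fixed condition seed.
#'
#' @param image a `face_image`.
#' @param cond a [phosphene_condition()].
#' @param landmarks optional `landmark_set`; its bounding box (hairline to
#'   chin for the schemes here) defines the area the grid tiles. Without
#'   landmarks the full image frame is used.
#' @param identity,sex provenance labels for the returned stimulus.
#' @return a [stimulus()] whose `resolution` is the condition label and
#'   whose `seed` records the dropout seed.
#' @export
phosphenise <- function(image, cond, landmarks = NULL,
                        identity = "face", sex = NA) {
  stopifnot(inherits(image, "face_image"),
            inherits(cond, "phosphene_condition"))
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  box <- if (is.null(landmarks)) c(0, 0, w - 1, h - 1) else {
    p <- landmarks$points
    c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  }
  sites <- place_phosphene_grid(box, cond$grid)
  sites <- apply_dropout(sites, cond$dropout, cond$seed)
  lv <- sample_and_quantize(image, sites, cond$levels)
  img <- render_phosphenes(lv, sites, c(w, h), cond$levels)
  img$width_deg <- image$width_deg
  stimulus(img, identity, sex,
           viewpoint = if (is.null(landmarks)) NA else landmarks$viewpoint,
           scheme = NA, strength = 0,
           resolution = cond$label, seed = cond$seed)
}
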
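test_that("cutoff frequency follows the inverse-linear eccentricity law", {
  expect_equal(cutoff_frequency(0), 30)
  expect_equal(cutoff_frequency(2.5), 15)     # halves at E2
  f <- cutoff_frequency(c(0, 20, 30))
  expect_true(f[3] < f[2] && f[2] < f[1])     # monotone decrease
  expect_error(cutoff_frequency(-1), ">= 0")
  expect_equal(cutoff_frequency(10, f0 = 40, E2 = 5), 40 * 5 / 15)
})

test_that("blur attenuates a grating at the cutoff to half amplitude", {
  w <- 128; k <- 16
  for (E in c(20, 30)) {
    fc <- cutoff_frequency(E)
    # k integer cycles across the frame; width chosen so the grating
    # frequency in cycles/degree equals f_c exactly
    grating <- 0.5 + 0.4 * sin(2 * pi * k * (0:(w - 1)) / w)
    img <- face_image(matrix(rep(grating, each = w), nrow = w),
                      width_deg = k / fc)
    out <- blur_image(img, blur_condition(E))
    amp <- function(m) (max(m) - min(m)) / 2
    # oracle: Gaussian MTF exp(-2 pi^2 sigma^2 f^2) = 0.5 at f_c
    expect_equal(amp(out$pixels) / amp(img$pixels), 0.5, tolerance = 0.02)
  }
})

test_that("blur is linear, mean-preserving, and a passthrough at E = 0", {
  set.seed(11)
  i1 <- matrix(runif(48 * 48), 48); i2 <- matrix(runif(48 * 48), 48)
  f1 <- face_image(i1); f2 <- face_image(i2)
  cond <- blur_condition(20)
  mix <- blur_image(face_image(0.3 * i1 + 0.6 * i2), cond)
  lin <- 0.3 * blur_image(f1, cond)$pixels + 0.6 * blur_image(f2, cond)$pixels
  expect_equal(mix$pixels, lin, tolerance = 1e-6)
  expect_equal(mean(blur_image(f1, cond)$pixels), mean(i1), tolerance = 1e-3)
  expect_identical(blur_image(f1, blur_condition(0))$pixels, i1)
  expect_error(blur_image(face_image(i1, width_deg = NA), cond),
               "angular-size")
})

test_that("stronger blur removes more fine structure", {
  co <- small_cohort(render = TRUE)
  img <- co$images$M01$front
  lap_var <- function(m) {
    h <- nrow(m); w <- ncol(m); c <- m[2:(h - 1), 2:(w - 1)]
    stats::var(as.vector(4 * c - m[1:(h - 2), 2:(w - 1)] - m[3:h, 2:(w - 1)] -
                           m[2:(h - 1), 1:(w - 2)] - m[2:(h - 1), 3:w]))
  }
  v0 <- lap_var(img$pixels)
  v20 <- lap_var(blur_image(img, blur_condition(20))$pixels)
  v30 <- lap_var(blur_image(img, blur_condition(30))$pixels)
  expect_true(v30 < v20 && v20 < v0)
})

test_that("phosphene lattice is cell-centred with the right site count", {
  box <- c(10, 20, 90, 120)
  s40 <- place_phosphene_grid(box, c(40, 40))
  expect_identical(nrow(s40), 1600L)
  expect_identical(nrow(place_phosphene_grid(box, c(32, 32))), 1024L)
  # oracle: explicit lattice enumeration; corners offset half a spacing
  dx <- (90 - 10) / 40; dy <- (120 - 20) / 40
  expect_equal(unname(attr(s40, "spacing")), c(dx, dy))
  expect_equal(min(s40$x), 10 + dx / 2)
  expect_equal(max(s40$x), 90 - dx / 2)
  expect_equal(min(s40$y), 20 + dy / 2)
  expect_equal(max(s40$y), 120 - dy / 2)
  expect_equal(sort(unique(s40$x)), 10 + (seq_len(40) - 0.5) * dx)
  expect_error(place_phosphene_grid(c(0, 0, 20, 20), c(40, 40)),
               "too small")
})

test_that("dropout removes exactly round(d*N) sites, reproducibly", {
  sites <- place_phosphene_grid(c(0, 0, 100, 100), c(40, 40))
  surv <- apply_dropout(sites, 0.30, seed = 7)
  expect_identical(nrow(surv), 1120L)   # oracle: 1600 - round(0.3 * 1600)
  expect_identical(nrow(apply_dropout(sites, 0, seed = 7)), 1600L)
  again <- apply_dropout(sites, 0.30, seed = 7)
  expect_identical(surv$row, again$row)
  expect_identical(surv$col, again$col)
  other <- apply_dropout(sites, 0.30, seed = 8)
  expect_false(identical(surv$row, other$row) && identical(surv$col, other$col))
  expect_error(apply_dropout(sites, 1, seed = 1), "\\[0, 1\\)")
})

test_that("brightness sampling quantises by uniform binning", {
  w <- 64
  sites <- place_phosphene_grid(c(0, 0, w - 1, w - 1), c(8, 8))
  expect_true(all(sample_and_quantize(face_image(matrix(0, w, w)), sites) == 0))
  expect_true(all(sample_and_quantize(face_image(matrix(1, w, w)), sites) == 7))
  expect_identical(length(unique(
    sample_and_quantize(face_image(matrix(0.5, w, w)), sites))), 1L)
  # linear horizontal ramp: one row of sites spans exactly 8 distinct levels
  ramp <- face_image(matrix(rep((0:(w - 1)) / (w - 1), each = w), nrow = w))
  lv <- sample_and_quantize(ramp, sites, L = 8)
  expect_identical(sort(unique(lv)), 0:7)
  # oracle: direct binning of the nearest-neighbour ramp values
  oracle <- pmin(floor(ramp$pixels[cbind(round(sites$y) + 1,
                                         round(sites$x) + 1)] * 8), 7)
  expect_identical(lv, as.integer(oracle))
})

test_that("phosphene rendering composes Gaussian patches correctly", {
  sites <- place_phosphene_grid(c(0, 0, 63, 63), c(8, 8))
  black <- render_phosphenes(rep(0L, 64), sites, c(64, 64))
  expect_true(all(black$pixels == 0))
  # a single bright site: maximum at its centre, radially monotone decreasing
  lv <- rep(0L, 64); lv[28] <- 7L
  one <- render_phosphenes(lv, sites, c(64, 64))
  cx <- round(sites$x[28]); cy <- round(sites$y[28])
  expect_identical(which.max(one$pixels),
                   which(row(one$pixels) == cy + 1 & col(one$pixels) == cx + 1))
  ray <- one$pixels[cy + 1, (cx + 1):64]
  expect_true(all(diff(ray) <= 1e-12))
  # quantisation: an isolated phosphene's peak brightness takes one of at
  # most 8 distinct values (level / (L - 1)); integer site centres so the
  # Gaussian maximum falls on a pixel
  sites2 <- place_phosphene_grid(c(0, 0, 64, 64), c(8, 8))
  peaks <- vapply(0:7, function(level) {
    lv <- rep(0L, 64); lv[28] <- level
    max(render_phosphenes(lv, sites2, c(64, 64))$pixels)
  }, numeric(1))
  expect_equal(peaks, 0:7 / 7, tolerance = 1e-12)
  expect_identical(length(unique(peaks)), 8L)
})

test_that("phosphenisation is deterministic and depends only on sampled pixels", {
  co <- small_cohort(render = TRUE)
  img <- co$images$M02$front
  cond <- phosphene_condition(c(40, 40), 0.30, seed = 13)
  a <- phosphenise(img, cond)
  b <- phosphenise(img, cond)
  expect_identical(a$image$pixels, b$image$pixels)   # byte-identical
  expect_identical(a$resolution, "40x40DO")
  expect_identical(phosphenise(img, phosphene_condition(c(40, 40), 0))$resolution,
                   "40x40ND")
  expect_identical(phosphenise(img, phosphene_condition(c(32, 32), 0.3))$resolution,
                   "32x32DO")
  # perturb a pixel no surviving site samples: output must be unchanged
  sites <- apply_dropout(place_phosphene_grid(c(0, 0, 127, 127), c(40, 40)),
                         0.30, seed = 13)
  sampled <- cbind(round(sites$y) + 1, round(sites$x) + 1)
  m <- img$pixels
  free <- setdiff(seq_along(m), sampled[, 1] + (sampled[, 2] - 1) * nrow(m))
  m[free[1]] <- 1 - m[free[1]]
  pert <- phosphenise(face_image(m, img$width_deg), cond)
  expect_identical(pert$image$pixels, a$image$pixels)
})
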
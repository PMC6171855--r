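test_that("templates cover all regions, are symmetric, and differ by sex", {
  tM <- make_template("M"); tF <- make_template("F")
  expect_identical(nrow(tM$points), 147L)
  expect_setequal(unique(tM$scheme$region_labels),
                  names(landmark_scheme("S147")$blocks))
  # bilateral symmetry: the reflected point set equals the original
  refl <- cbind(tM$image_size[1] - tM$points[, 1], tM$points[, 2])
  nn <- apply(refl, 1, function(p)
    min(sqrt(rowSums(sweep(tM$points, 2, p)^2))))
  expect_lt(max(nn), 1e-9)
  # sexes differ in the jaw, share the eyes
  jaw <- region_index(tM, "jaw"); eyes <- region_index(tM, c("eye_left", "eye_right"))
  expect_gt(max(abs(tM$points[jaw, ] - tF$points[jaw, ])), 0.5)
  expect_identical(tM$points[eyes, ], tF$points[eyes, ])
})

test_that("identity sampling is seeded, centred, and scales with distinctiveness", {
  t <- make_template("M")
  p1 <- sample_identity(t, "M", "a", 1, seed = 33)
  p2 <- sample_identity(t, "M", "a", 1, seed = 33)
  expect_identical(p1$displacement, p2$displacement)
  p3 <- sample_identity(t, "M", "b", 1, seed = 34)
  expect_false(identical(p1$displacement, p3$displacement))
  # distinctiveness 0 reproduces the template
  p0 <- sample_identity(t, "M", "z", 0, seed = 35)
  expect_identical(identity_landmarks(t, p0)$points, t$points)
  # a cohort's mean landmarks stay near the template (zero-mean field)
  cohort <- lapply(1:26, function(i)
    identity_landmarks(t, sample_identity(t, "M", paste(i), 1, seed = 400 + i)))
  avg <- build_average_landmarks(cohort)
  expect_lt(mean(abs(avg$points - t$points)), 0.5)
  expect_gt(mean(abs(identity_landmarks(t, p1)$points - t$points)), 0.5)
})

test_that("viewpoint projection foreshortens and drops the occluded ear", {
  t <- make_template("F")
  expect_identical(project_viewpoint(t, "front"), t)
  l30 <- project_viewpoint(t, "left30")
  expect_identical(nrow(l30$points), 136L)
  expect_identical(l30$scheme$name, "S136")
  expect_identical(l30$viewpoint, "left30")
  # x compresses toward the midline by cos(yaw); y untouched
  xc <- t$image_size[1] / 2
  kept <- setdiff(seq_len(147), region_index(t, "ear_left"))
  expect_equal(l30$points[, 1], xc + (t$points[kept, 1] - xc) * cos(30 * pi / 180))
  expect_identical(l30$points[, 2], t$points[kept, 2])
  # the 68-point scheme has no ears: count survives rotation
  s68 <- derive_68(t)
  expect_identical(nrow(project_viewpoint(s68, "left30")$points), 68L)
  # mirror symmetry of the two 10-degree views for a symmetric template
  r10 <- project_viewpoint(t, "right10")$points
  l10 <- project_viewpoint(t, "left10")$points
  refl <- cbind(t$image_size[1] - l10[, 1], l10[, 2])
  nn <- apply(refl, 1, function(p) min(sqrt(rowSums(sweep(r10, 2, p)^2))))
  expect_lt(max(nn), 1e-9)
  expect_error(project_viewpoint(l30, "right10"), "frontal")
})

test_that("derive_68 excludes the uncovered regions deterministically", {
  t <- make_template("M")
  d1 <- derive_68(t)
  expect_identical(nrow(d1$points), 68L)
  expect_identical(d1$points, derive_68(t)$points)  # deterministic
  # every derived point is one of the hand-annotated points (selection)
  keys147 <- paste(t$points[, 1], t$points[, 2])
  expect_true(all(paste(d1$points[, 1], d1$points[, 2]) %in% keys147))
  # none of the derived points comes from forehead or ears
  excl <- region_index(t, c("forehead", "ear_left", "ear_right",
                            "brow_left_bot", "brow_right_bot",
                            "nose_mid_left", "nose_mid_right"))
  expect_false(any(paste(d1$points[, 1], d1$points[, 2]) %in% keys147[excl]))
  expect_error(derive_68(d1), "S147/S136")
})

test_that("rendering is deterministic with a uniform background", {
  t <- make_template("M")
  a <- render_face(t); b <- render_face(t)
  expect_identical(a$pixels, b$pixels)
  # frame corners lie outside the head: uniform background value
  corners <- c(a$pixels[1:4, 1:4], a$pixels[1:4, 125:128])
  expect_identical(length(unique(corners)), 1L)
})

test_that("rendering caricatured landmarks approximates warping the render", {
  co <- small_cohort(render = TRUE)
  v <- co$landmarks$M01$front
  avg <- co$averages$M$front
  cl <- caricature_landmarks(v, avg$landmarks, 0.6)
  direct <- render_face(cl)
  warped <- warp_image(co$images$M01$front, v, cl)
  frac_off <- mean(abs(direct$pixels - warped$pixels) > 0.05)
  expect_lt(frac_off, 0.10)  # disagreement confined to contour bands
})

test_that("cohorts have the advertised composition and reproduce under seed", {
  co <- small_cohort(seed = 9, render = FALSE)
  expect_identical(length(co$landmarks), 8L)
  expect_identical(nrow(co$manifest), 32L)          # ids x 4 viewpoints
  expect_identical(sum(lengths(co$averages)), 8L)   # 2 sexes x 4 viewpoints
  expect_false(anyDuplicated(co$manifest[c("identity", "viewpoint")]) > 0)
  co2 <- small_cohort(seed = 9, render = FALSE)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$landmarks$F02$left10$points, co2$landmarks$F02$left10$points)
  # averages come from a pool disjoint from the cohort: names never collide
  expect_false(any(grepl("^pool", names(co$landmarks))))
})

test_that("caricaturing pushes every face away from every other cohort face", {
  co <- small_cohort(seed = 2, render = FALSE)
  for (sex in c("M", "F")) {
    ids <- names(Filter(function(i) i$sex == sex, co$identities))
    avg <- co$averages[[sex]]$front$landmarks
    cl <- lapply(ids, function(id)
      caricature_landmarks(co$landmarks[[id]]$front, avg, 0.6))
    names(cl) <- ids
    for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
      d_v <- latent_dissimilarity(co$landmarks[[ids[i]]]$front,
                                  co$landmarks[[ids[j]]]$front)
      d_c <- latent_dissimilarity(cl[[ids[i]]], cl[[ids[j]]])
      expect_gt(d_c, d_v)
      expect_equal(d_c / d_v, 1.6, tolerance = 1e-9)  # shared-average geometry
    }
  }
})

test_that("the full stimulus inventory has consistent provenance", {
  co <- small_cohort(seed = 4, render = TRUE)
  ss <- make_stimulus_set(co)
  expect_identical(length(ss$stimuli), 8L * 4L * 3L)
  expect_identical(as.vector(table(ss$manifest$caricature)[c("V", "C-68p", "C-147p")]),
                   rep(32L, 3))
  expect_false(anyDuplicated(ss$manifest$key) > 0)
  s <- ss$stimuli[["M01_front_C-68p"]]
  expect_identical(s$scheme, "S68")
  expect_identical(s$strength, 0.6)
  expect_identical(ss$stimuli[["M01_front_V"]]$strength, 0)
})
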
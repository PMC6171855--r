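test_that("condition means reproduce hand-computed values", {
  # constant table
  const <- data.frame(participant = rep(1:2, each = 9),
                      resolution = rep(rep(c("R1", "R2", "R3"), each = 3), 2),
                      caricature = rep(c("V", "C-68p", "C-147p"), 6),
                      sex = "M", rating = 5)
  cm <- condition_means(const)
  expect_true(all(cm$mean_rating == 5))
  expect_identical(attr(cm, "n_participants"), 2L)
  # two-participant toy table, means computed by hand
  toy <- data.frame(
    participant = c(1, 1, 1, 1, 2, 2),
    resolution = "R1",
    caricature = c("V", "V", "C-68p", "C-68p", "V", "C-68p"),
    sex = c("M", "F", "M", "F", "M", "M"),
    rating = c(2, 4, 6, 7, 5, 9))
  cm <- condition_means(toy)
  expect_equal(cm$mean_rating[cm$participant == 1 & cm$caricature == "V"], 3)
  expect_equal(cm$mean_rating[cm$participant == 1 & cm$caricature == "C-68p"], 6.5)
  expect_equal(cm$mean_rating[cm$participant == 2 & cm$caricature == "V"], 5)
  # collapsed mean equals the trial-weighted mean of sex-split cells
  cs <- condition_means(toy, collapse_sex = FALSE)
  p1v <- cs[cs$participant == 1 & cs$caricature == "V", ]
  expect_equal(stats::weighted.mean(p1v$mean_rating, c(1, 1)), 3)
})

test_that("paired t matches the closed formula and t.test", {
  a <- c(5, 6, 7); b <- c(4, 4, 6)
  r <- paired_t(a, b)
  expect_equal(r$statistic, 4)        # (4/3) / (sqrt(1/3)/sqrt(3)), by hand
  expect_identical(r$df, 2L)
  expect_equal(r$p.value, 2 * pt(-4, 2))
  # degenerate case: identical samples give t = 0
  expect_identical(paired_t(a, a)$statistic, 0)
  # cross-check against the standard implementation on non-degenerate data
  set.seed(20); x <- rnorm(15, 1); y <- rnorm(15)
  tt <- t.test(x, y, paired = TRUE)
  r2 <- paired_t(x, y)
  expect_equal(r2$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p.value, tt$p.value, tolerance = 1e-12)
  # equals the one-sample t of differences; shift-invariant
  expect_equal(paired_t(x + 3, y + 3)$statistic, r2$statistic,
               tolerance = 1e-12)
  expect_error(paired_t(a, b[1:2]), "equal length")
})

test_that("two-way RM-ANOVA matches the brute-force SS decomposition", {
  g <- toy_means_grid(5, function(p, r, c, s)
    4 + 0.2 * p + 0.5 * (c == "C-147p") + 0.3 * (r == "R3") +
      0.4 * (c == "C-147p" & r == "R1"), noise_sd = 0.3, seed = 6)
  cm <- condition_means(transform(g, rating = mean_rating, sex = "M"))
  out <- rm_anova_2way(cm)
  oracle <- brute_rm_anova(cm, "resolution", "caricature")
  expect_equal(out$interaction$statistic, unname(oracle$F_ab), tolerance = 1e-9)
  expect_equal(out$resolution$statistic, unname(oracle$F_a), tolerance = 1e-9)
  expect_equal(out$caricature$statistic, unname(oracle$F_b), tolerance = 1e-9)
  expect_equal(out$interaction$df, as.numeric(oracle$df_ab))
  # design algebra at N = 20: interaction df = (4, 76)
  g20 <- toy_means_grid(20, function(p, r, c, s) 5, noise_sd = 0.4, seed = 7)
  out20 <- rm_anova_2way(structure(g20, class = c("condition_means", "data.frame")))
  expect_equal(out20$interaction$df, c(4, 76))
})

test_that("additive data give interaction F near 1 on average", {
  fs <- vapply(1:150, function(i) {
    g <- toy_means_grid(8, function(p, r, c, s)
      4 + 0.3 * p + 0.6 * (c == "C-147p") + 0.2 * (r == "R2"),
      noise_sd = 0.4, seed = 900 + i)
    rm_anova_2way(structure(g, class = c("condition_means", "data.frame")))$
      interaction$statistic
  }, numeric(1))
  expect_equal(mean(fs), 28 / 26, tolerance = 0.25)  # E[F] = df2/(df2-2)
})

test_that("within-subject SEM derives from the one-way RM-ANOVA MSE", {
  # participant offsets only: zero MSE after centring, zero error bar
  g <- toy_means_grid(4, function(p, r, c, s) 2 + p + (c == "C-147p"))
  cm <- structure(g, class = c("condition_means", "data.frame"))
  expect_equal(within_subject_sem(cm, "R1"), 0, tolerance = 1e-12)
  # brute-force SS oracle on a noisy 4-participant grid
  g2 <- toy_means_grid(4, function(p, r, c, s) 3 + 0.5 * p +
                         0.8 * (c == "C-68p"), noise_sd = 0.5, seed = 12)
  cm2 <- structure(g2, class = c("condition_means", "data.frame"))
  sub <- cm2[cm2$resolution == "R2", ]
  expect_equal(within_subject_sem(cm2, "R2"),
               sqrt(brute_oneway_mse(sub, "caricature") / 4),
               tolerance = 1e-9)
  # error bar shrinks as 1/sqrt(N): replicating the participant sample
  # 5-fold vs 10-fold shrinks it by ~1/sqrt(2) (exact only as N grows,
  # because the error df is (N-1)(a-1), not N(a-1))
  rep_k <- function(k) {
    d <- do.call(rbind, lapply(seq_len(k), function(i)
      transform(sub, participant = participant + 10 * i)))
    within_subject_sem(structure(d, class = c("condition_means", "data.frame")),
                       "R2")
  }
  expect_equal(rep_k(10) / rep_k(5), 1 / sqrt(2), tolerance = 0.05)
  expect_error(within_subject_sem(cm2, "R9"), "no such resolution")
})

test_that("sex-check ANOVA has the right design algebra and calibration", {
  # balanced design: df (1, 19) for the sex main effect at N = 20
  g <- toy_means_grid(20, function(p, r, c, s) 5, noise_sd = 0.3, seed = 1,
                      sexes = c("M", "F"))
  out <- sex_check_anova(g)
  expect_equal(out$sex$df, c(1, 19))
  expect_equal(out$`resolution:caricature:sex`$df, c(4, 76))
  # sex-symmetric data: sex effects rarely significant
  ps <- vapply(1:40, function(i) {
    g <- toy_means_grid(10, function(p, r, c, s)
      4 + 0.2 * p + 0.5 * (c == "C-147p"), noise_sd = 0.4, seed = 100 + i,
      sexes = c("M", "F"))
    sex_check_anova(g)$sex$p.value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  # an injected sex main effect is detected with high power
  hits <- vapply(1:40, function(i) {
    g <- toy_means_grid(10, function(p, r, c, s)
      4 + 0.2 * p + 0.6 * (s == "F"), noise_sd = 0.4, seed = 200 + i,
      sexes = c("M", "F"))
    sex_check_anova(g)$sex$p.value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("relative effectiveness has the documented fixed points", {
  expect_equal(relative_effectiveness(4, 5, 5)$re, 100)   # equal caricatures
  expect_equal(relative_effectiveness(4, 4, 5)$re, 0)     # C68 no better than V
  expect_equal(relative_effectiveness(4.0, 4.52, 5.0)$re, 52)
  expect_equal(relative_effectiveness(4.0, 4.52, 5.0, "printed")$re,
               100 / 0.52, tolerance = 1e-9)
  expect_error(relative_effectiveness(4, 4.5, 4 + 1e-9), "undefined")
  # affine invariance: shift and positive scale leave RE unchanged
  set.seed(9)
  for (i in 1:10) {
    v <- runif(1, 3, 5); c68 <- v + runif(1, 0.2, 1); c147 <- c68 + runif(1, 0.2, 1)
    a <- runif(1, 0.2, 3); b <- runif(1, -2, 2)
    expect_equal(relative_effectiveness(a * v + b, a * c68 + b, a * c147 + b)$re,
                 relative_effectiveness(v, c68, c147)$re, tolerance = 1e-9)
  }
})

test_that("full analysis report is coherent on simulated data", {
  co <- small_cohort()
  dis <- pair_dissimilarities(co)
  sch <- build_schedule("E1", n_participants = 8, seed = 15,
                        ids_male = small_ids("M"), ids_female = small_ids("F"))
  rt <- simulate_ratings(sch, dis, rater_model(seed = 16))
  rep <- analyze_ratings(rt)
  expect_identical(rep$n, 8L)
  expect_setequal(names(rep$per_resolution), c("HR", "Blur20", "Blur30"))
  hr <- rep$per_resolution$HR
  # caricatures beat veridical in the simulated world
  expect_gt(hr$t_c147_v$statistic, 0)
  expect_gt(hr$means["C-147p"], hr$means["V"])
  expect_identical(hr$t_c147_v$df, 7L)
  expect_true(is.finite(rep$anova$interaction$statistic))
  expect_false(is.null(rep$sex_check))
  expect_equal(rep$sex_check$sex$df, c(1, 7))
})

test_that("published-workbook reanalysis works on the documented schema", {
  co <- small_cohort()
  dis <- pair_dissimilarities(co)
  s1 <- build_schedule("E1", n_participants = 6, seed = 61,
                       ids_male = small_ids("M"), ids_female = small_ids("F"))
  s2 <- build_schedule("E2", n_participants = 6, seed = 62,
                       ids_male = small_ids("M"), ids_female = small_ids("F"))
  r1 <- simulate_ratings(s1, dis, rater_model(seed = 63))
  r2 <- simulate_ratings(s2, dis, rater_model(seed = 64))
  p <- file.path(withr::local_tempdir(), "ratings.csv")
  both <- rbind(r1, r2)
  utils::write.csv(both[c("participant", "experiment", "resolution",
                          "caricature", "sex", "rating")], p, row.names = FALSE)
  out <- reproduce_published(p)
  direct <- relative_effectiveness_summary(analyze_ratings(r1),
                                           analyze_ratings(r2))
  expect_equal(out$re$overall, direct$overall, tolerance = 1e-9)
  expect_equal(out$e2$anova$interaction$df, c(4, 20))
  # schema escape hatch: non-standard column and level names
  odd <- both[c("participant", "experiment", "resolution", "caricature", "rating")]
  names(odd) <- c("Subj", "experiment", "Format", "CaricLevel", "Score")
  odd$CaricLevel <- c(V = "verid", `C-68p` = "auto68",
                      `C-147p` = "hand147")[odd$CaricLevel]
  p2 <- file.path(withr::local_tempdir(), "odd.csv")
  utils::write.csv(odd, p2, row.names = FALSE)
  out2 <- reproduce_published(p2, mapping = list(
    columns = list(participant = "Subj", resolution = "Format",
                   caricature = "CaricLevel", rating = "Score"),
    caricature_levels = c(verid = "V", auto68 = "C-68p", hand147 = "C-147p")))
  expect_equal(out2$re$overall, direct$overall, tolerance = 1e-9)
  # missing workbook and unmappable schema fail with clear messages
  expect_error(reproduce_published("no-such-file.xlsx"), "not found")
  bad <- both[c("participant", "rating")]
  p3 <- file.path(withr::local_tempdir(), "bad.csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  expect_error(reproduce_published(p3), "resolution")
})
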
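# Shared fixtures and independent oracles, all built in code.

# A valid S68 landmark set in a frame, with controllable first point.
toy_set68 <- function(p1 = c(64, 64), fill = c(10, 10), frame = c(200, 200),
                      viewpoint = "front") {
  pts <- matrix(rep(fill, each = 68), ncol = 2)
  pts[1, ] <- p1
  landmark_set(pts, "S68", viewpoint, frame)
}

# Small random landmark sets for property loops.
random_set68 <- function(seed, frame = c(200, 200)) {
  set.seed(seed)
  pts <- cbind(runif(68, 10, 190), runif(68, 10, 190))
  landmark_set(pts, "S68", "front", frame)
}

# Brute-force sums-of-squares decomposition for a fully within-subjects
# two-factor design (long data frame: participant, f1, f2, y). Independent of
# stats::aov: explicit marginal means and explicit SS loops.
brute_rm_anova <- function(df, f1, f2, y = "mean_rating") {
  p <- factor(df$participant); a <- factor(df[[f1]]); b <- factor(df[[f2]])
  v <- df[[y]]
  gm <- mean(v)
  m_p <- tapply(v, p, mean); m_a <- tapply(v, a, mean); m_b <- tapply(v, b, mean)
  m_pa <- tapply(v, interaction(p, a), mean)
  m_pb <- tapply(v, interaction(p, b), mean)
  m_ab <- tapply(v, interaction(a, b), mean)
  nP <- nlevels(p); nA <- nlevels(a); nB <- nlevels(b)
  ss_a <- nP * nB * sum((m_a - gm)^2)
  ss_b <- nP * nA * sum((m_b - gm)^2)
  ss_ab <- 0
  for (i in levels(a)) for (j in levels(b))
    ss_ab <- ss_ab + nP * (m_ab[paste(i, j, sep = ".")] - m_a[i] - m_b[j] + gm)^2
  ss_pa <- 0   # error term for the A effect
  for (k in levels(p)) for (i in levels(a))
    ss_pa <- ss_pa + nB * (m_pa[paste(k, i, sep = ".")] - m_p[k] - m_a[i] + gm)^2
  ss_pb <- 0
  for (k in levels(p)) for (j in levels(b))
    ss_pb <- ss_pb + nA * (m_pb[paste(k, j, sep = ".")] - m_p[k] - m_b[j] + gm)^2
  ss_tot <- sum((v - gm)^2)
  ss_p <- nA * nB * sum((m_p - gm)^2)
  ss_pab <- ss_tot - ss_p - ss_a - ss_b - ss_ab - ss_pa - ss_pb
  df_a <- nA - 1; df_b <- nB - 1; df_ab <- df_a * df_b
  df_pa <- (nP - 1) * df_a; df_pb <- (nP - 1) * df_b
  df_pab <- (nP - 1) * df_ab
  list(
    F_a = (ss_a / df_a) / (ss_pa / df_pa), df_a = c(df_a, df_pa),
    F_b = (ss_b / df_b) / (ss_pb / df_pb), df_b = c(df_b, df_pb),
    F_ab = (ss_ab / df_ab) / (ss_pab / df_pab), df_ab = c(df_ab, df_pab),
    mse_ab = ss_pab / df_pab
  )
}

# One-way within-subjects brute-force SS (participant x factor grid).
brute_oneway_mse <- function(df, f, y = "mean_rating") {
  p <- factor(df$participant); a <- factor(df[[f]]); v <- df[[y]]
  gm <- mean(v)
  m_p <- tapply(v, p, mean); m_a <- tapply(v, a, mean)
  ss_tot <- sum((v - gm)^2)
  ss_p <- nlevels(a) * sum((m_p - gm)^2)
  ss_a <- nlevels(p) * sum((m_a - gm)^2)
  ss_err <- ss_tot - ss_p - ss_a
  ss_err / ((nlevels(p) - 1) * (nlevels(a) - 1))
}

# Condition-means grid for analysis tests: base + participant offset +
# cell effects (+ optional noise), as a long data frame.
toy_means_grid <- function(n_participants, cell_fun, noise_sd = 0, seed = 1,
                           resolutions = c("R1", "R2", "R3"),
                           caricatures = c("V", "C-68p", "C-147p"),
                           sexes = NULL) {
  set.seed(seed)
  g <- expand.grid(participant = seq_len(n_participants),
                   resolution = resolutions, caricature = caricatures,
                   stringsAsFactors = FALSE)
  if (!is.null(sexes))
    g <- merge(g, data.frame(sex = sexes), by = NULL)
  g$mean_rating <- mapply(cell_fun, g$participant, g$resolution,
                          g$caricature,
                          if (is.null(sexes)) NA else g$sex) +
    rnorm(nrow(g), sd = noise_sd)
  g
}

# Lean relative-effectiveness estimator used in recovery loops (grand means
# per plot, no ANOVA machinery).
quick_overall_re <- function(...) {
  res <- unlist(lapply(list(...), function(r) {
    cm <- condition_means(r)
    sapply(split(cm, cm$resolution), function(d) {
      m <- tapply(d$mean_rating, d$caricature, mean)
      100 * (m[["C-68p"]] - m[["V"]]) / (m[["C-147p"]] - m[["V"]])
    })
  }))
  mean(res)
}

# Small cohort shared by several test files (4 + 4 identities so that the
# subset split 2/2 still yields pairs; landmarks only unless rendered).
small_cohort <- function(seed = 5, render = FALSE)
  make_cohort(n_male = 4, n_female = 4, seed = seed, avg_pool = 10,
              render = render)
small_ids <- function(sex) sprintf("%s%02d", sex, 1:4)
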
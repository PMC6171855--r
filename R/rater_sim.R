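## Simulated raters. Each participant produces a 1-9 dissimilarity rating
## per trial from a latent geometric dissimilarity between the two faces,
## multiplied by a caricature-level gain, scaled by a per-resolution
## caricature-effect attenuation, perturbed by rater noise, and mapped onto
## the rating scale by an affine rescaling within each rescaling block
## (emulating the instruction to re-anchor the scale per resolution block).

#' Rater model parameters
#'
#' The caricature gains express how much more dissimilar a caricatured pair
#' looks than the veridical pair. The full-precision gain default is 1.6:
#' caricaturing both members of a same-category pair at strength 0.6 scales
#' their landmark distance by exactly 1 + s. The 68-point caricature
#' realises only a fraction of that gain (its *effectiveness*); the
#' effectiveness defaults encode the effect structure observed behaviourally
#' (0.68 for high-resolution, 0.65 for blurred, 0.39 for phosphenised
#' viewing). `attenuation` scales the whole caricature effect per resolution
#' condition (default: reduced to 0.6 at the two degraded phosphene
#' resolutions, reproducing the reduced overall caricature effect there).
#'
#' @param g_veridical gain of the veridical condition (1 by definition).
#' @param g_c147 gain of the 147-point caricature (default 1.6).
#' @param effectiveness named vector (by resolution condition) or scalar:
#'   fraction of the 147-point gain realised by the 68-point caricature,
#'   so `g_c68 = 1 + effectiveness * (g_c147 - 1)`.
#' @param attenuation named vector or scalar: per-resolution multiplier on
#'   the caricature effect `(g - 1)`.
#' @param sigma_r rater noise, expressed relative to the within-block
#'   standard deviation of the latent dissimilarities (default 1.5,
#'   calibrated once so that simulated condition means concentrate in the
#'   central band of the scale and simulated test statistics have
#'   realistic magnitudes).
#' @param rescale honour the schedule's rescaling blocks (default `TRUE`).
#' @param seed integer seed for noise.
#' @return an object of class `rater_model`.
#' @export
rater_model <- function(g_veridical = 1,
                        g_c147 = 1.6,
                        effectiveness = c(HR = 0.68, Blur20 = 0.65,
                                          Blur30 = 0.65, "40x40ND" = 0.39,
                                          "40x40DO" = 0.39, "32x32DO" = 0.39),
                        attenuation = c(HR = 1, Blur20 = 1, Blur30 = 1,
                                        "40x40ND" = 1, "40x40DO" = 0.6,
                                        "32x32DO" = 0.6),
                        sigma_r = 1.5, rescale = TRUE, seed = 1L) {
  if (sigma_r < 0) stop("sigma_r must be >= 0", call. = FALSE)
  if (g_c147 < g_veridical)
    stop("g_c147 must be >= the veridical gain", call. = FALSE)
  structure(list(g_veridical = g_veridical, g_c147 = g_c147,
                 effectiveness = effectiveness, attenuation = attenuation,
                 sigma_r = sigma_r, rescale = rescale,
                 seed = as.integer(seed)),
            class = "rater_model")
}

lookup_par <- function(par, keys) {
  if (length(par) == 1L && is.null(names(par))) return(rep(par, length(keys)))
  out <- par[keys]
  if (anyNA(out))
    stop("rater model parameter missing for condition(s): ",
         paste(unique(keys[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Latent geometric dissimilarity of two faces
#'
#' Mean Euclidean distance between corresponding ground-truth landmarks of
#' the two faces (same scheme and viewpoint). This is the inter-face
#' distance that caricaturing stretches: caricaturing both members of a
#' same-category pair at strength `s` scales it by exactly `1 + s`.
#'
#' @param a,b `landmark_set`s of the same scheme and viewpoint.
#' @return non-negative scalar; 0 iff the sets coincide; symmetric.
#' @export
latent_dissimilarity <- function(a, b) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  if (a$scheme$name != b$scheme$name || a$viewpoint != b$viewpoint)
    stop("latent dissimilarity needs matching scheme and viewpoint",
         call. = FALSE)
  mean(sqrt(rowSums((a$points - b$points)^2)))
}

#' Latent dissimilarities of all same-sex pairs of a cohort
#'
#' @param cohort a [make_cohort()] result (images not required).
#' @return data frame (idA, idB, viewpoint, d) for every unordered same-sex
#'   pair at every viewpoint, keyed for fast lookup during simulation.
#' @export
pair_dissimilarities <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- names(cohort$landmarks)
  sexes <- vapply(cohort$identities, function(i) i$sex, character(1))
  rows <- list()
  for (sex in c("M", "F")) {
    sid <- ids[sexes == sex]
    cmb <- utils::combn(sid, 2)
    for (vp in names(VIEWPOINTS)) {
      d <- vapply(seq_len(ncol(cmb)), function(j)
        latent_dissimilarity(cohort$landmarks[[cmb[1, j]]][[vp]],
                             cohort$landmarks[[cmb[2, j]]][[vp]]),
        numeric(1))
      rows[[paste(sex, vp)]] <- data.frame(
        idA = cmb[1, ], idB = cmb[2, ], viewpoint = vp, d = d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-participant dissimilarity ratings
#'
#' For each trial the latent dissimilarity of the pair (at the trial's
#' viewpoint, i.e. face A's viewpoint) is multiplied by the caricature gain
#' and resolution attenuation of the trial's condition, Gaussian rater noise
#' is added, and within each rescaling block the latent values are affinely
#' mapped to span the 1-9 scale, rounded, and clipped.
#'
#' @param schedule a [build_schedule()] trial schedule (any number of
#'   participants).
#' @param dissim pair dissimilarity table from [pair_dissimilarities()], or
#'   a `cohort` (the table is computed on the fly).
#' @param model a [rater_model()].
#' @param seed optional seed overriding `model$seed`.
#' @return a `rating_table`: the schedule plus a `rating` column (integers
#'   in 1..9).
#' @export
simulate_ratings <- function(schedule, dissim, model = rater_model(),
                             seed = NULL) {
  stopifnot(inherits(model, "rater_model"))
  if (inherits(dissim, "cohort")) dissim <- pair_dissimilarities(dissim)
  if (is.null(seed)) seed <- model$seed

  key <- function(a, b, vp)
    ifelse(a < b, paste(a, b, vp), paste(b, a, vp))
  lut <- stats::setNames(dissim$d, key(dissim$idA, dissim$idB, dissim$viewpoint))
  d <- lut[key(schedule$idA, schedule$idB, schedule$viewA)]
  if (anyNA(d))
    stop("schedule contains pairs or viewpoints absent from the dissimilarity table",
         call. = FALSE)

  g147 <- model$g_c147 - model$g_veridical
  eff <- lookup_par(model$effectiveness, schedule$resolution)
  att <- lookup_par(model$attenuation, schedule$resolution)
  gain <- ifelse(schedule$caricature == "V", 0,
          ifelse(schedule$caricature == "C-147p", g147, eff * g147))
  latent <- unname(d * (model$g_veridical + att * gain))

  blk <- if (isTRUE(model$rescale))
    interaction(schedule$participant, schedule$rescale_block, drop = TRUE)
  else factor(schedule$participant)

  noisy <- with_seed(seed, {
    s <- stats::ave(latent, blk, FUN = stats::sd)
    s[is.na(s)] <- 0
    latent + stats::rnorm(length(latent), sd = model$sigma_r * s)
  })
  lo <- stats::ave(noisy, blk, FUN = min)
  hi <- stats::ave(noisy, blk, FUN = max)
  cont <- ifelse(hi > lo, 1 + 8 * (noisy - lo) / (hi - lo), 5)
  out <- schedule
  out$rating <- pmin(9L, pmax(1L, as.integer(round(cont))))
  class(out) <- c("rating_table", "data.frame")
  out
}
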
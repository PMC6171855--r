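## Trial schedules for the two dissimilarity-rating experiments.
##
## Both experiments cross 3 resolution levels with 3 caricature levels and
## show same-sex, same-subset face pairs, both members of a pair always in
## the same (resolution, caricature) condition. Each sex's 13 identities are
## split once into subsets of 7 and 6 and every within-subset pair is rated
## once per condition: (21 + 15) pairs x 2 sexes = 72 trials per condition,
## 648 trials per participant.

E1_RESOLUTIONS <- c("HR", "Blur20", "Blur30")
E2_RESOLUTIONS <- c("40x40ND", "40x40DO", "32x32DO")
CARICATURE_LEVELS <- c("V", "C-68p", "C-147p")

#' Split a sex's identities into the two rating subsets
#'
#' 13 identities are split into one subset of 7 and one of 6 (rating all 13
#' against each other would take too many trials). The split is a seeded
#' random partition, fixed across participants.
#'
#' @param ids character vector of identity labels (or a count).
#' @param seed integer seed.
#' @return list with elements `s1` (size `ceiling(n/2)`) and `s2`
#'   (size `floor(n/2)`); disjoint, union = input.
#' @export
split_subsets <- function(ids, seed = 1L) {
  if (is.numeric(ids) && length(ids) == 1L) ids <- sprintf("id%02d", seq_len(ids))
  n <- length(ids)
  perm <- with_seed(seed, sample(ids))
  n1 <- ceiling(n / 2)
  list(s1 = sort(perm[seq_len(n1)]), s2 = sort(perm[(n1 + 1):n]))
}

#' All unordered face pairs within a subset
#'
#' @param subset character vector of identity labels (length >= 2).
#' @return data frame with columns `idA`, `idB`, one row per unordered pair:
#'   `choose(n, 2)` rows (21 for 7 faces, 15 for 6).
#' @export
pairs_within <- function(subset) {
  if (length(subset) < 2L)
    stop("a subset needs at least 2 faces to form a pair", call. = FALSE)
  cmb <- utils::combn(subset, 2)
  data.frame(idA = cmb[1, ], idB = cmb[2, ], stringsAsFactors = FALSE)
}

#' Build the trial schedule of an experiment
#'
#' Experiment 1 (blur): trials are blocked by face sex (block order
#' counterbalanced across participants: odd-numbered participants see male
#' faces first); within a sex block, all 9 conditions are intermixed in
#' seeded random order, and the rating scale is calibrated once for the
#' whole session. Experiment 2 (phosphenes): trials are additionally
#' blocked by resolution in the fixed order 40x40ND, 40x40DO, 32x32DO for
#' every participant, and a rescale marker is emitted at the start of each
#' resolution block (participants are told to discard their previous
#' criteria and re-anchor the 1-9 scale).
#'
#' Presentation metadata the design does not constrain is drawn under the
#' seed: each face's viewpoint (4 options) and size (uniform in 4.3-9.1
#' degrees), and the pair's left/right placement.
#'
#' @param experiment `"E1"` or `"E2"`.
#' @param n_participants number of participants (default 20).
#' @param seed master integer seed; subsets and every participant's ordering
#'   derive from it.
#' @param ids_male,ids_female identity labels (defaults `M01..M13`,
#'   `F01..F13`, matching [make_cohort()]).
#' @param resolutions,caricatures condition grids; must be 3 x 3.
#' @return a `trial_schedule`: a data frame with one row per trial and
#'   columns participant, experiment, block, trial, sex, subset, idA, idB,
#'   resolution, caricature, viewA, viewB, sizeA, sizeB, swap_lr,
#'   rescale_block, rescale_marker.
#' @export
build_schedule <- function(experiment = c("E1", "E2"), n_participants = 20,
                           seed = 1L,
                           ids_male = sprintf("M%02d", 1:13),
                           ids_female = sprintf("F%02d", 1:13),
                           resolutions = NULL,
                           caricatures = CARICATURE_LEVELS) {
  experiment <- match.arg(experiment)
  if (is.null(resolutions))
    resolutions <- if (experiment == "E1") E1_RESOLUTIONS else E2_RESOLUTIONS
  if (length(resolutions) != 3L || length(caricatures) != 3L)
    stop("the condition grid must be 3 resolutions x 3 caricature levels",
         call. = FALSE)

  sub_seeds <- with_seed(seed, sample.int(2^30, n_participants + 2L))
  subsets <- list(
    M = split_subsets(ids_male, seed = sub_seeds[1]),
    F = split_subsets(ids_female, seed = sub_seeds[2])
  )
  pairs_by_sex <- lapply(subsets, function(s) {
    rbind(cbind(pairs_within(s$s1), subset = "s1"),
          cbind(pairs_within(s$s2), subset = "s2"))
  })
  conds <- expand.grid(resolution = resolutions, caricature = caricatures,
                       stringsAsFactors = FALSE)

  one_participant <- function(p) {
    pseed <- sub_seeds[p + 2L]
    sex_order <- if (p %% 2L == 1L) c("M", "F") else c("F", "M")
    with_seed(pseed, {
      sex_chunk <- function(sex, res_set) {
        # all pairs of this sex crossed with the given conditions, shuffled
        cs <- conds[conds$resolution %in% res_set, , drop = FALSE]
        grid <- merge(pairs_by_sex[[sex]], cs, by = NULL)
        grid$sex <- sex
        grid[sample.int(nrow(grid)), , drop = FALSE]
      }
      blocks <- if (experiment == "E1") {
        lapply(sex_order, function(sx) {
          b <- sex_chunk(sx, resolutions)
          b$block <- paste0("sex_", sx)
          b$rescale_block <- "session"
          b
        })
      } else {
        out <- list()
        for (res in resolutions) {      # fixed order for all participants
          for (sx in sex_order) {
            b <- sex_chunk(sx, res)
            b$block <- paste(res, sx, sep = "_")
            b$rescale_block <- res
            out[[length(out) + 1L]] <- b
          }
        }
        out
      }
      df <- do.call(rbind, blocks)
      n <- nrow(df)
      df$participant <- p
      df$experiment <- experiment
      df$trial <- seq_len(n)
      df$viewA <- sample(names(VIEWPOINTS), n, replace = TRUE)
      df$viewB <- sample(names(VIEWPOINTS), n, replace = TRUE)
      df$sizeA <- stats::runif(n, 4.3, 9.1)
      df$sizeB <- stats::runif(n, 4.3, 9.1)
      df$swap_lr <- sample(c(TRUE, FALSE), n, replace = TRUE)
      df$rescale_marker <- !duplicated(df$rescale_block)
      df[, c("participant", "experiment", "block", "trial", "sex", "subset",
             "idA", "idB", "resolution", "caricature", "viewA", "viewB",
             "sizeA", "sizeB", "swap_lr", "rescale_block", "rescale_marker")]
    })
  }

  sched <- do.call(rbind, lapply(seq_len(n_participants), one_participant))
  rownames(sched) <- NULL
  class(sched) <- c("trial_schedule", "data.frame")
  attr(sched, "experiment") <- experiment
  attr(sched, "seed") <- seed
  attr(sched, "subsets") <- subsets
  sched
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule %s: %d participants x %d trials\n",
              attr(x, "experiment"),
              length(unique(x$participant)),
              nrow(x) / length(unique(x$participant))))
  NextMethod()
}

#' Write / read a trial schedule as delimited text
#'
#' @param schedule a `trial_schedule`.
#' @param path a `.csv` path.
#' @return `path` (write) or the schedule data frame (read).
#' @export
save_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_schedule
#' @export
load_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("trial_schedule", "data.frame")
  df
}
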
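## Scoring and statistics for the dissimilarity-rating experiments:
## per-participant condition means, the preliminary sex-of-face check,
## paired contrasts, one- and two-way repeated-measures ANOVAs with
## within-subject error bars, and the relative-effectiveness statistic.

#' Per-participant condition means
#'
#' Averages ratings over trials for each participant x resolution x
#' caricature cell; optionally keeps the sex of the faces as a further
#' factor (for the preliminary sex check). Collapsing over sex equals the
#' trial-count-weighted mean of the sex-split cells.
#'
#' @param ratings a `rating_table` from [simulate_ratings()] (or any data
#'   frame with participant, resolution, caricature, sex, rating columns).
#' @param collapse_sex average over male and female faces (default `TRUE`).
#' @return a `condition_means` data frame (participant, resolution,
#'   caricature, \[sex,\] mean_rating) with attribute `n_participants`.
#' @export
condition_means <- function(ratings, collapse_sex = TRUE) {
  needed <- c("participant", "resolution", "caricature", "rating")
  if (!all(needed %in% names(ratings)))
    stop("ratings table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  by <- list(participant = ratings$participant,
             resolution = ratings$resolution,
             caricature = ratings$caricature)
  if (!collapse_sex) {
    if (!"sex" %in% names(ratings))
      stop("sex-split means need a 'sex' column", call. = FALSE)
    by$sex <- ratings$sex
  }
  cm <- stats::aggregate(list(mean_rating = ratings$rating), by, mean)
  cm <- cm[do.call(order, cm[setdiff(names(cm), "mean_rating")]), ]
  rownames(cm) <- NULL
  if (any(cm$mean_rating < 1 | cm$mean_rating > 9))
    stop("condition means outside the 1-9 scale", call. = FALSE)
  structure(cm, class = c("condition_means", "data.frame"),
            n_participants = length(unique(cm$participant)))
}

stat_result <- function(statistic, df, p.value, label,
                        effect = NA_character_) {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 label = label, effect = effect),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: %s(%s) = %.2f, p = %.4g\n", x$effect %||% "", x$label,
              dfs, x$statistic, x$p.value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Paired-samples t test (two-tailed)
#'
#' `t = mean(a - b) / (sd(a - b) / sqrt(N))`, `df = N - 1`; identical to the
#' one-sample t of the differences. Invariant to adding any per-participant
#' constant to both members of a pair.
#'
#' @param a,b per-participant values, same participant order.
#' @param effect description recorded in the result.
#' @return a `stat_result` with fields statistic, df, p.value.
#' @export
paired_t <- function(a, b, effect = "paired contrast") {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  stat_result(t, n - 1L, p, "t", effect)
}

## Extract one effect row from a summary.aov of an Error()-stratified fit.
aov_effect <- function(fit, term) {
  sm <- summary(fit)
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    if (!is.na(i) && !is.na(tab[i, "F value"])) {
      j <- match("Residuals", rn)
      return(stat_result(tab[i, "F value"],
                         c(tab[i, "Df"], tab[j, "Df"]),
                         tab[i, "Pr(>F)"], "F", term))
    }
  }
  stop("effect not found in ANOVA table: ", term, call. = FALSE)
}

rm_factors <- function(cm, cols) {
  for (cl in cols) cm[[cl]] <- factor(cm[[cl]])
  cm$participant <- factor(cm$participant)
  cm
}

#' Two-way repeated-measures ANOVA (resolution x caricature)
#'
#' Full within-subjects 3 x 3 ANOVA on the condition means; degrees of
#' freedom are uncorrected (no sphericity correction), so the interaction
#' has df (4, 76) at N = 20.
#'
#' @param cm a [condition_means()] table (sex collapsed).
#' @return list with `resolution`, `caricature`, `interaction`
#'   (`stat_result`s) and the full `aov` fit.
#' @export
rm_anova_2way <- function(cm) {
  cm <- rm_factors(as.data.frame(cm), c("resolution", "caricature"))
  fit <- stats::aov(
    mean_rating ~ resolution * caricature +
      Error(participant / (resolution * caricature)), data = cm)
  list(resolution = aov_effect(fit, "resolution"),
       caricature = aov_effect(fit, "caricature"),
       interaction = aov_effect(fit, "resolution:caricature"),
       fit = fit)
}

#' Preliminary sex-of-face check: 3 x 3 x 2 repeated-measures ANOVA
#'
#' Full within-subjects resolution x caricature x sex ANOVA on sex-split
#' condition means, used to justify collapsing over the sex of the faces
#' when none of the sex effects is significant.
#'
#' @param cm_sex sex-split means from `condition_means(..., collapse_sex = FALSE)`.
#' @return list of `stat_result`s for all seven effects plus the fit; the
#'   `sex_effects` element collects the four involving sex.
#' @export
sex_check_anova <- function(cm_sex) {
  if (!"sex" %in% names(cm_sex))
    stop("needs sex-split condition means", call. = FALSE)
  cm <- rm_factors(as.data.frame(cm_sex), c("resolution", "caricature", "sex"))
  fit <- stats::aov(
    mean_rating ~ resolution * caricature * sex +
      Error(participant / (resolution * caricature * sex)), data = cm)
  terms <- c("resolution", "caricature", "sex",
             "resolution:caricature", "resolution:sex", "caricature:sex",
             "resolution:caricature:sex")
  res <- lapply(terms, function(t) aov_effect(fit, t))
  names(res) <- terms
  res$sex_effects <- res[grep("sex", terms, value = TRUE)]
  res$fit <- fit
  res
}

#' Within-subject SEM for caricature-level error bars
#'
#' One-way repeated-measures ANOVA on the three caricature levels at a fixed
#' resolution; the error bar half-width is `sqrt(MSE / N)`, the standard
#' within-subject SEM appropriate for comparing the within-participant
#' caricature conditions.
#'
#' @param cm a [condition_means()] table.
#' @param resolution the resolution condition to evaluate.
#' @return numeric half-width.
#' @export
within_subject_sem <- function(cm, resolution) {
  sub <- cm[cm$resolution == resolution, , drop = FALSE]
  if (!nrow(sub)) stop("no such resolution: ", resolution, call. = FALSE)
  sub <- rm_factors(as.data.frame(sub), "caricature")
  fit <- stats::aov(mean_rating ~ caricature + Error(participant / caricature),
                    data = sub)
  sm <- summary(fit)
  tab <- sm[["Error: participant:caricature"]][[1]]
  mse <- tab[trimws(rownames(tab)) == "Residuals", "Mean Sq"]
  n <- length(unique(sub$participant))
  sqrt(mse / n)
}

#' Relative effectiveness of the reduced-precision caricature
#'
#' `RE = 100 * (C68 - V) / (C147 - V)`: the 68-point caricature's mean
#' rating gain over veridical as a percentage of the 147-point caricature's
#' gain. 100 when the two caricatures are equally effective, 0 when the
#' 68-point caricature is no better than veridical. Invariant to any affine
#' rescaling (shift and positive scale) applied to all three means, which
#' is what makes it comparable across rescaled blocks. `orientation =
#' "printed"` computes the reciprocal form `100 * (C147 - V) / (C68 - V)`
#' instead.
#'
#' @param v,c68,c147 condition mean ratings.
#' @param orientation `"effectiveness"` (default) or `"printed"`.
#' @param tol the denominator gap must exceed this (default 1e-6);
#'   otherwise RE is undefined and an error is raised.
#' @return an object of class `relative_effectiveness` (field `re`,
#'   percent, plus the three components).
#' @export
relative_effectiveness <- function(v, c68, c147,
                                   orientation = c("effectiveness", "printed"),
                                   tol = 1e-6) {
  orientation <- match.arg(orientation)
  den <- if (orientation == "effectiveness") c147 - v else c68 - v
  num <- if (orientation == "effectiveness") c68 - v else c147 - v
  if (abs(den) < tol)
    stop("relative effectiveness undefined: caricature-vs-veridical gap ",
         "smaller than tolerance (", tol, ")", call. = FALSE)
  structure(list(re = 100 * num / den, orientation = orientation,
                 components = c(V = v, C68 = c68, C147 = c147)),
            class = "relative_effectiveness")
}

#' @export
print.relative_effectiveness <- function(x, ...) {
  cat(sprintf("Relative effectiveness (%s): %.1f%%  [V = %.3f, C68 = %.3f, C147 = %.3f]\n",
              x$orientation, x$re, x$components[1], x$components[2],
              x$components[3]))
  invisible(x)
}

grand_means <- function(cm, resolution) {
  sub <- cm[cm$resolution == resolution, ]
  vapply(c("V", "C-68p", "C-147p"), function(lv)
    mean(sub$mean_rating[sub$caricature == lv]), numeric(1))
}

#' Analyse a rating table
#'
#' Full analysis of one experiment's ratings: condition means, the
#' preliminary sex check, per-resolution paired contrasts (C-147p vs V,
#' C-68p vs V, C-147p vs C-68p), per-resolution relative effectiveness and
#' within-subject SEMs, and the two-way resolution x caricature
#' repeated-measures ANOVA.
#'
#' @param ratings a `rating_table`.
#' @return an `analysis_report` list.
#' @export
analyze_ratings <- function(ratings) {
  cm <- condition_means(ratings)
  cm_sex <- if ("sex" %in% names(ratings))
    condition_means(ratings, collapse_sex = FALSE) else NULL
  resolutions <- unique(as.character(cm$resolution))

  per_res <- lapply(resolutions, function(res) {
    sub <- cm[cm$resolution == res, ]
    wide <- do.call(cbind, lapply(c("V", "C-68p", "C-147p"), function(lv)
      sub$mean_rating[sub$caricature == lv][order(sub$participant[sub$caricature == lv])]))
    colnames(wide) <- c("V", "C68", "C147")
    gm <- grand_means(cm, res)
    list(
      means = gm,
      t_c147_v = paired_t(wide[, "C147"], wide[, "V"],
                          paste0(res, ": C-147p vs V")),
      t_c68_v = paired_t(wide[, "C68"], wide[, "V"],
                         paste0(res, ": C-68p vs V")),
      t_c147_c68 = paired_t(wide[, "C147"], wide[, "C68"],
                            paste0(res, ": C-147p vs C-68p")),
      re = relative_effectiveness(gm["V"], gm["C-68p"], gm["C-147p"]),
      sem = within_subject_sem(cm, res)
    )
  })
  names(per_res) <- resolutions

  structure(list(
    condition_means = cm,
    sex_check = if (!is.null(cm_sex)) sex_check_anova(cm_sex) else NULL,
    per_resolution = per_res,
    anova = rm_anova_2way(cm),
    n = attr(cm, "n_participants")
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis of %d participants\n", x$n))
  for (res in names(x$per_resolution)) {
    p <- x$per_resolution[[res]]
    cat(sprintf("  %-8s means V/C68/C147 = %.2f/%.2f/%.2f, RE = %.1f%%, SEM = %.3f\n",
                res, p$means[1], p$means[2], p$means[3], p$re$re, p$sem))
  }
  i <- x$anova$interaction
  cat(sprintf("  interaction F(%g, %g) = %.2f, p = %.4g\n",
              i$df[1], i$df[2], i$statistic, i$p.value))
  invisible(x)
}

#' Relative effectiveness summarised across both experiments
#'
#' The overall figure is the mean of the per-plot (per-resolution) RE values
#' across the two experiments' six plots; per-format figures average the
#' high-resolution plot, the two blur plots, and the three phosphene plots
#' respectively.
#'
#' @param report_e1,report_e2 [analyze_ratings()] reports for the blur and
#'   phosphene experiments.
#' @return named list: `overall`, `high_resolution`, `blur`, `phosphene`
#'   (percentages), plus `per_plot`.
#' @export
relative_effectiveness_summary <- function(report_e1, report_e2) {
  res <- function(rep) vapply(rep$per_resolution, function(p) p$re$re,
                              numeric(1))
  re1 <- res(report_e1); re2 <- res(report_e2)
  per_plot <- c(re1, re2)
  blur_plots <- setdiff(names(re1), "HR")
  list(
    overall = mean(per_plot),
    high_resolution = unname(re1["HR"]),
    blur = mean(re1[blur_plots]),
    phosphene = mean(re2),
    per_plot = per_plot
  )
}

#' Compare the caricature benefit between the two experiments
#'
#' Two-sample comparison of the per-participant relative caricature benefit
#' between the (independent) participant groups of the two experiments.
#' Reported descriptively only: with two groups of 20 the nominal df is 38.
#'
#' @param report_e1,report_e2 analysis reports.
#' @return a `stat_result` (Welch t).
#' @export
compare_experiments <- function(report_e1, report_e2) {
  per_participant_benefit <- function(rep) {
    cm <- rep$condition_means
    sapply(split(cm, cm$participant), function(d) {
      mean(d$mean_rating[d$caricature == "C-68p"] -
             d$mean_rating[d$caricature == "V"]) /
        max(mean(d$mean_rating[d$caricature == "C-147p"] -
                   d$mean_rating[d$caricature == "V"]), 1e-9)
    })
  }
  a <- per_participant_benefit(report_e1)
  b <- per_participant_benefit(report_e2)
  tt <- stats::t.test(a, b)
  stat_result(unname(tt$statistic), unname(tt$parameter), tt$p.value, "t",
              "between-experiment caricature benefit")
}
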
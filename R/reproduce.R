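## Re-analysis of a deposited ratings workbook. The expected layout is one
## long-format table per experiment: one row per participant x trial (or per
## participant x condition mean) with columns identifying the participant,
## the resolution condition, the caricature condition and the rating. XLSX
## input needs the 'readxl' package; delimited text (.csv/.tsv) is read with
## base R. A mapping list renames non-standard column or level names.

standard_cols <- c(participant = "participant", resolution = "resolution",
                   caricature = "caricature", rating = "rating")

apply_mapping <- function(df, mapping) {
  cols <- standard_cols
  if (!is.null(mapping$columns)) {
    for (k in names(mapping$columns)) cols[[k]] <- mapping$columns[[k]]
  }
  # case-insensitive matching of column names
  take <- function(want) {
    i <- match(tolower(want), tolower(names(df)))
    if (is.na(i)) stop("cannot find a '", want, "' column; supply ",
                       "mapping$columns$", names(which(cols == want))[1],
                       call. = FALSE)
    df[[i]]
  }
  out <- data.frame(
    participant = take(cols[["participant"]]),
    resolution = as.character(take(cols[["resolution"]])),
    caricature = as.character(take(cols[["caricature"]])),
    rating = as.numeric(take(cols[["rating"]])),
    stringsAsFactors = FALSE
  )
  if (!is.null(mapping$caricature_levels)) {
    lv <- mapping$caricature_levels  # named: file level -> standard level
    out$caricature <- ifelse(out$caricature %in% names(lv),
                             unlist(lv)[out$caricature], out$caricature)
  }
  if (!all(c("V", "C-68p", "C-147p") %in% unique(out$caricature)))
    stop("caricature levels not recognised (need V, C-68p, C-147p after ",
         "mapping); found: ", paste(unique(out$caricature), collapse = ", "),
         call. = FALSE)
  if ("sex" %in% tolower(names(df)))
    out$sex <- df[[match("sex", tolower(names(df)))]]
  out
}

read_ratings_source <- function(path, sheet = NULL) {
  if (!file.exists(path))
    stop("ratings workbook not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package; export the sheet ",
           "to CSV instead", call. = FALSE)
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  }
}

#' Re-analyse a deposited ratings workbook
#'
#' Recomputes, from per-trial (or per-condition) ratings, everything the
#' rating analysis reports: the condition means, the paired C-147p-vs-V and
#' C-68p-vs-V contrasts at every resolution, the two-way repeated-measures
#' ANOVA, and relative effectiveness overall and per stimulus format.
#'
#' @param path workbook file: `.xlsx` (one sheet per experiment, needs
#'   `readxl`), or `.csv`/`.tsv` with an `experiment` column (or a single
#'   experiment's data).
#' @param mapping optional schema mapping when the file does not use the
#'   standard column/level names: a list with elements `columns` (named
#'   character: standard name -> file column name) and `caricature_levels`
#'   (named character: file level -> standard level).
#' @param sheets for XLSX input, the sheet names/indices of the two
#'   experiments (default the first two sheets).
#' @return list with `e1`, `e2` ([analyze_ratings()] reports; one may be
#'   `NULL` if only one experiment is present) and `re` (the
#'   [relative_effectiveness_summary()] when both are present).
#' @export
reproduce_published <- function(path, mapping = NULL, sheets = c(1, 2)) {
  is_xl <- grepl("\\.xlsx?$", path, ignore.case = TRUE)
  if (is_xl) {
    tables <- lapply(sheets, function(s) read_ratings_source(path, sheet = s))
  } else {
    df <- read_ratings_source(path)
    exp_col <- match("experiment", tolower(names(df)))
    tables <- if (!is.na(exp_col)) split(df, df[[exp_col]]) else list(df)
  }
  tables <- lapply(tables, apply_mapping, mapping = mapping)

  reports <- lapply(tables, function(tb) {
    class(tb) <- c("rating_table", "data.frame")
    analyze_ratings(tb)
  })
  e1 <- reports[[1]]
  e2 <- if (length(reports) >= 2L) reports[[2]] else NULL
  list(
    e1 = e1, e2 = e2,
    re = if (!is.null(e2)) relative_effectiveness_summary(e1, e2) else NULL
  )
}

#' Write / read a rating table as delimited text
#'
#' One row per participant x trial, the schedule columns plus `rating`.
#'
#' @param ratings a `rating_table`.
#' @param path a `.csv` path.
#' @return `path` (write) or the rating table (read).
#' @export
save_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_ratings
#' @export
load_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("rating_table", "data.frame")
  df
}
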
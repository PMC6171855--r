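## Landmark file I/O.
##
## Two dialects, chosen by file extension:
##   *.pts / *.txt  plain text:
##       carilow-landmarks 1
##       scheme S147
##       viewpoint front
##       image_size 128 128
##       <x> <y>            (one pair per line, full double precision)
##   *.json         the same fields as a JSON object with a `points` array.
## Coordinates are written with "%.17g" so a save/load round trip is exact
## for every IEEE double (well beyond the documented 6 significant digits).

#' Write a landmark set to disk
#'
#' @param set a `landmark_set`.
#' @param path output file; extension selects the dialect (`.pts`/`.txt`
#'   plain text, `.json` JSON). Parent directory must exist.
#' @return `path`, invisibly.
#' @seealso [load_landmarks()]
#' @export
save_landmarks <- function(set, path) {
  stopifnot(inherits(set, "landmark_set"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write landmarks: directory does not exist: ", dir,
         call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(
      format = "carilow-landmarks", version = 1L,
      scheme = set$scheme$name, viewpoint = set$viewpoint,
      image_size = set$image_size,
      points = unname(set$points)
    )
    # I(17) = 17 *significant* digits: exact round trip for IEEE doubles
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  } else {
    lines <- c(
      "carilow-landmarks 1",
      paste("scheme", set$scheme$name),
      paste("viewpoint", set$viewpoint),
      paste("image_size", sprintf("%.17g", set$image_size[1]),
            sprintf("%.17g", set$image_size[2])),
      sprintf("%.17g %.17g", set$points[, 1], set$points[, 2])
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a landmark set from disk
#'
#' Reads either dialect written by [save_landmarks()] and returns a validated
#' [landmark_set()]. The point count must match the scheme declared in the
#' file (or the `scheme` override) for its viewpoint.
#'
#' @param path file to read.
#' @param scheme optional scheme override (`"hand"`, `"auto"`, or an explicit
#'   scheme name); by default the scheme recorded in the file is used.
#' @return a `landmark_set`.
#' @export
load_landmarks <- function(path, scheme = NULL) {
  if (!file.exists(path))
    stop("landmark file does not exist: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$points) || is.null(obj$viewpoint))
      stop("not a carilow landmark JSON file: ", path, call. = FALSE)
    pts <- matrix(as.numeric(as.matrix(obj$points)), ncol = 2)
    sch <- if (is.null(scheme)) obj$scheme else scheme
    return(landmark_set(pts, sch, obj$viewpoint, as.numeric(obj$image_size)))
  }
  lines <- readLines(path)
  if (length(lines) < 5L || !startsWith(lines[1], "carilow-landmarks"))
    stop("not a carilow landmark file: ", path, call. = FALSE)
  hdr <- function(i, key) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (parts[1] != key)
      stop(sprintf("parse error in %s line %d: expected '%s', found '%s'",
                   path, i, key, parts[1]), call. = FALSE)
    parts[-1]
  }
  file_scheme <- hdr(2, "scheme")
  viewpoint <- hdr(3, "viewpoint")
  image_size <- as.numeric(hdr(4, "image_size"))
  body <- lines[-(1:4)]
  body <- body[nzchar(trimws(body))]
  pts <- matrix(NA_real_, nrow = length(body), ncol = 2)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                              "[[:space:]]+")[[1]]))
    if (length(v) != 2L || anyNA(v))
      stop(sprintf("parse error in %s line %d: expected 'x y', found '%s'",
                   path, i + 4L, body[i]), call. = FALSE)
    pts[i, ] <- v
  }
  sch <- if (is.null(scheme)) file_scheme else scheme
  landmark_set(pts, sch, viewpoint, image_size)
}
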
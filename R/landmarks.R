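# Named anatomical landmarks. A landmark set is a tibble with columns
# name, x, y, z (mm); order is meaningful and two sets correspond iff their
# name sequences are identical.

#' Canonical 16-landmark foot schema
#'
#' The ordered names of the sixteen anatomical landmarks used to drive the
#' affine and point-based RBF registration, from the posterior calcaneus to
#' the fifth toe tip.
#'
#' @format Character vector of length 16.
#' @export
FOOT_LANDMARKS_16 <- c(
  "posterior calcaneus", "central plantar heel", "heel medial", "heel lateral",
  "achilles tendon between malleoli", "malleolus medial", "malleolus lateral",
  "navicular tuberosity", "navicular dorsal", "fifth metatarsal basis",
  "first metatarsal head", "second tarsometatarsal dorsal",
  "third metatarsophalangeal plantar", "hallux tip", "second toe tip",
  "fifth toe tip"
)

#' Create a landmark set
#'
#' @param name character vector of unique landmark names (order matters).
#' @param x,y,z numeric coordinates in mm, or `points` as an n-by-3 matrix.
#' @param points optional n-by-3 coordinate matrix used instead of `x,y,z`.
#' @return A tibble of class `landmark_set` with columns `name, x, y, z`.
#' @export
landmark_set <- function(name, x = NULL, y = NULL, z = NULL, points = NULL) {
  if (!is.null(points)) {
    points <- as.matrix(points)
    x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  }
  out <- tibble::tibble(name = as.character(name),
                        x = as.double(x), y = as.double(y), z = as.double(z))
  validate_landmark_set(out)
  class(out) <- c("landmark_set", class(out))
  out
}

validate_landmark_set <- function(lms) {
  if (anyDuplicated(lms$name)) {
    dup <- unique(lms$name[duplicated(lms$name)])
    abort(sprintf("Duplicate landmark name(s): %s.", paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(c(lms$x, lms$y, lms$z)))) {
    abort("Landmark coordinates must all be finite.")
  }
  invisible(lms)
}

#' Landmark coordinates as a matrix
#' @param lms a `landmark_set`.
#' @return An n-by-3 numeric matrix (mm), rows in landmark order.
#' @export
landmark_points <- function(lms) {
  unname(cbind(lms$x, lms$y, lms$z))
}

#' Check that two landmark sets correspond
#'
#' Two sets correspond iff their name sequences are identical (same names,
#' same order).
#'
#' @param a,b landmark sets.
#' @return `TRUE`/`FALSE`.
#' @export
landmarks_correspond <- function(a, b) {
  identical(as.character(a$name), as.character(b$name))
}

#' Read / write landmark files
#'
#' The on-disk dialect is a plain CSV `name,x,y,z` with a one-line header and
#' mm units; a JSON alternate (array of `{name, x, y, z}` objects) is accepted
#' by extension.
#'
#' @param path file path (`.csv` or `.json`).
#' @return [read_landmarks()] returns a `landmark_set`; [write_landmarks()]
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read landmarks: '%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(sprintf("Landmark file '%s' must have columns name,x,y,z.", path))
  }
  landmark_set(df$name, df$x, df$y, df$z)
}

#' @rdname read_landmarks
#' @param lms a `landmark_set`.
#' @export
write_landmarks <- function(lms, path) {
  validate_landmark_set(lms)
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(lms[, c("name", "x", "y", "z")])
  if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  } else {
    write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
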
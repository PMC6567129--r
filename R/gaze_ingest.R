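#' @useDynLib gazealign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 76 printable symbols used to serialize AOI-coded scanpaths.
AOI_ALPHABET <- c(letters, LETTERS, as.character(0:9),
                  strsplit("!#$%&*+-/<=>?@", "")[[1]])

FIXATION_COLUMNS <- c("subject_id", "group", "trial_id", "image_id", "eye",
                      "start_ms", "duration_ms", "x", "y")
LANDMARK_COLUMNS <- c("image_id", "point_id", "group", "x", "y")

#' The 76-symbol AOI alphabet
#'
#' One printable character per AOI point; `point_id` k (0-based) maps to
#' `aoi_alphabet()[k + 1]`.
#'
#' @return Character vector of length 76, all distinct.
#' @export
aoi_alphabet <- function() AOI_ALPHABET

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

check_numeric_column <- function(df, col, what) {
  v <- df[[col]]
  if (is.character(v)) {
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad) > 0)
      stop(what, ": non-numeric value in column '", col, "' at data row ",
           bad[1], " ('", v[bad[1]], "')", call. = FALSE)
    v <- num
  }
  if (!is.numeric(v))
    stop(what, ": column '", col, "' is not numeric", call. = FALSE)
  if (anyNA(v))
    stop(what, ": missing value in column '", col, "' at data row ",
         which(is.na(v))[1], call. = FALSE)
  v
}

#' Read a fixation-event table
#'
#' Parses a delimited table of fixation events (one row per fixation) with
#' columns `subject_id, group, trial_id, image_id, eye, start_ms,
#' duration_ms, x, y`. The delimiter is chosen from the file extension
#' (`.csv` comma, `.tsv`/`.txt` tab). Rows are validated (positive
#' durations, eyes in `left`/`right`, finite coordinates, no temporal
#' overlap within a subject/trial/eye stream) and sorted by `start_ms`
#' within each stream.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @return A `data.frame` of validated fixations.
#' @seealso [assign_fixations()], [simulate_study()]
#' @export
read_fixations <- function(path) {
  df <- read_delim_auto(path)
  check_columns(df, FIXATION_COLUMNS, "fixation")
  validate_fixations(df[FIXATION_COLUMNS], what = basename(path))
}

#' @rdname read_fixations
#' @param fixations A data.frame shaped like the fixation table (used when
#'   fixations are already in memory, e.g. from [simulate_study()]).
#' @export
validate_fixations <- function(fixations, what = "fixations") {
  check_columns(fixations, FIXATION_COLUMNS, "fixation")
  df <- fixations
  for (col in c("start_ms", "duration_ms", "x", "y"))
    df[[col]] <- check_numeric_column(df, col, what)
  for (col in c("subject_id", "group", "trial_id", "image_id", "eye"))
    df[[col]] <- as.character(df[[col]])
  if (!all(df$eye %in% c("left", "right")))
    stop(what, ": eye must be 'left' or 'right'", call. = FALSE)
  if (any(df$duration_ms <= 0))
    stop(what, ": duration_ms must be positive (row ",
         which(df$duration_ms <= 0)[1], ")", call. = FALSE)
  if (any(df$start_ms < 0))
    stop(what, ": start_ms must be non-negative", call. = FALSE)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop(what, ": non-finite fixation coordinates", call. = FALSE)
  key <- interaction(df$subject_id, df$trial_id, df$eye, drop = TRUE)
  df <- df[order(key, df$start_ms), , drop = FALSE]
  rownames(df) <- NULL
  # non-overlap within each stream
  for (k in split(seq_len(nrow(df)), interaction(
         df$subject_id, df$trial_id, df$eye, drop = TRUE))) {
    if (length(k) < 2) next
    ends <- df$start_ms[k] + df$duration_ms[k]
    if (any(df$start_ms[k][-1] < ends[-length(k)] - 1e-9))
      stop(what, ": overlapping fixations within subject ",
           df$subject_id[k[1]], ", trial ", df$trial_id[k[1]], ", ",
           df$eye[k[1]], " eye", call. = FALSE)
  }
  df
}

#' Read an AOI landmark table
#'
#' Parses a delimited table of facial-landmark AOI points with columns
#' `image_id, point_id, group, x, y`. Landmark detection itself is
#' upstream; this table is its output. Semantic group labels (e.g.
#' `outline`, `mouth`, `nose`, `eyes`, `eyebrows`) come from the file, so
#' non-face layouts are supported.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @return A `data.frame` of landmark points.
#' @export
read_landmarks <- function(path) {
  df <- read_delim_auto(path)
  check_columns(df, LANDMARK_COLUMNS, "landmark")
  df <- df[LANDMARK_COLUMNS]
  for (col in c("x", "y")) df[[col]] <- check_numeric_column(df, col, basename(path))
  df$point_id <- as.integer(df$point_id)
  df$image_id <- as.character(df$image_id)
  df$group <- as.character(df$group)
  df
}

#' Frame points enclosing a landmark set
#'
#' Computes the 8 exterior frame AOIs: the 4 corners and 4 edge midpoints
#' of the landmark bounding box expanded by `margin` pixels on every side.
#' These capture stray fixations that land far from the face.
#'
#' @param landmarks A data.frame with numeric `x` and `y` columns (the 68
#'   facial landmarks, or any non-degenerate point set).
#' @param margin Expansion in pixels on each side; default 5% of the
#'   bounding-box diagonal.
#' @return A data.frame of 8 rows (`point_id` continuing after the
#'   landmarks, `group = "frame"`, `x`, `y`), ordered clockwise from the
#'   top-left corner.
#' @export
build_frame_points <- function(landmarks, margin = NULL) {
  x <- landmarks$x; y <- landmarks$y
  if (length(x) < 3) stop("need at least 3 landmark points", call. = FALSE)
  xr <- range(x); yr <- range(y)
  if (diff(xr) <= 0 || diff(yr) <= 0)
    stop("degenerate landmark bounding box (zero area)", call. = FALSE)
  if (is.null(margin)) margin <- 0.05 * sqrt(diff(xr)^2 + diff(yr)^2)
  x0 <- xr[1] - margin; x1 <- xr[2] + margin
  y0 <- yr[1] - margin; y1 <- yr[2] + margin
  xm <- (x0 + x1) / 2; ym <- (y0 + y1) / 2
  data.frame(
    point_id = length(x) + 0:7,
    group = "frame",
    x = c(x0, xm, x1, x1, x1, xm, x0, x0),
    y = c(y0, y0, y0, ym, y1, y1, y1, ym),
    stringsAsFactors = FALSE
  )
}

#' Build an AOI layout for one image
#'
#' Combines the 68 facial landmarks of one image with the 8 frame points
#' from [build_frame_points()] into a 76-point AOI layout whose points are
#' identified by `point_id` 0..75 and by one character each of
#' [aoi_alphabet()].
#'
#' @param landmarks Landmark rows for a single image (columns `point_id`,
#'   `group`, `x`, `y`; `point_id` 0-based and contiguous).
#' @param image_id Image identifier; defaults to the table's `image_id`.
#' @param frame_margin Passed to [build_frame_points()].
#' @return An object of class `aoi_layout`: a list with `image_id`,
#'   `points` (76-row data.frame) and `alphabet`.
#' @export
build_layout <- function(landmarks, image_id = NULL, frame_margin = NULL) {
  if (is.null(image_id)) {
    image_id <- unique(as.character(landmarks$image_id))
    if (length(image_id) != 1)
      stop("landmarks must belong to a single image", call. = FALSE)
  }
  lm <- landmarks[order(landmarks$point_id), , drop = FALSE]
  if (!all(lm$point_id == seq_len(nrow(lm)) - 1L))
    stop("landmark point_id must be 0-based and contiguous", call. = FALSE)
  if (any(!is.finite(lm$x)) || any(!is.finite(lm$y)))
    stop("non-finite landmark coordinates", call. = FALSE)
  frame <- build_frame_points(lm, margin = frame_margin)
  pts <- rbind(
    data.frame(point_id = lm$point_id, group = as.character(lm$group),
               x = lm$x, y = lm$y, stringsAsFactors = FALSE),
    frame
  )
  if (nrow(pts) != 76)
    stop("an AOI layout requires 68 landmarks + 8 frame points (got ",
         nrow(pts), ")", call. = FALSE)
  structure(list(image_id = image_id, points = pts, alphabet = AOI_ALPHABET),
            class = "aoi_layout")
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat("AOI layout for image '", x$image_id, "': ", nrow(x$points),
      " points in groups ", paste(unique(x$points$group), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Build AOI layouts for every image in a landmark table
#'
#' @param landmark_table Output of [read_landmarks()] (all images).
#' @param frame_margin Passed to [build_frame_points()].
#' @return Named list of `aoi_layout` objects, one per `image_id`. All
#'   layouts must share point ids and group labels.
#' @export
build_layouts <- function(landmark_table, frame_margin = NULL) {
  layouts <- lapply(split(landmark_table, landmark_table$image_id),
                    build_layout, frame_margin = frame_margin)
  ref <- layouts[[1]]$points$group
  for (ly in layouts)
    if (!identical(ly$points$group, ref))
      stop("inconsistent point groups across image layouts", call. = FALSE)
  layouts
}

#' Assign fixations to their nearest AOI
#'
#' For each fixation, finds the AOI point of its image's layout with the
#' smallest Euclidean distance to the fixation position. Ties are broken
#' towards the lowest `point_id`.
#'
#' @param fixations Validated fixation data.frame (see [read_fixations()]).
#' @param layouts A single `aoi_layout` or a named list from
#'   [build_layouts()] covering every `image_id` present.
#' @return The fixation data.frame with an integer `point_id` column added.
#' @export
assign_fixations <- function(fixations, layouts) {
  if (inherits(layouts, "aoi_layout")) {
    layouts <- stats::setNames(list(layouts), layouts$image_id)
  }
  if (any(!is.finite(fixations$x)) || any(!is.finite(fixations$y)))
    stop("non-finite fixation coordinates", call. = FALSE)
  out <- fixations
  out$point_id <- NA_integer_
  for (img in unique(fixations$image_id)) {
    ly <- layouts[[img]]
    if (is.null(ly)) stop("no AOI layout for image '", img, "'", call. = FALSE)
    rows <- which(fixations$image_id == img)
    # N x 76 squared distances; which.min takes the first (lowest point_id)
    dx <- outer(fixations$x[rows], ly$points$x, "-")
    dy <- outer(fixations$y[rows], ly$points$y, "-")
    nearest <- apply(dx * dx + dy * dy, 1, which.min)
    out$point_id[rows] <- ly$points$point_id[nearest]
  }
  out
}
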
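#' Average pairwise AOI distances across image layouts
#'
#' Entry (i, j) is the mean over images of the Euclidean distance between
#' AOI points i and j of that image's layout. Averaging is done per pair
#' across images (not on averaged point positions), so layouts with
#' varying facial geometry are handled correctly.
#'
#' @param layouts A single `aoi_layout` or list of layouts sharing point
#'   ids and groups (see [build_layouts()]).
#' @return A 76 x 76 symmetric matrix with zero diagonal; attribute
#'   `groups` holds the per-point semantic group labels.
#' @export
average_pair_distances <- function(layouts) {
  if (inherits(layouts, "aoi_layout")) layouts <- list(layouts)
  if (length(layouts) == 0) stop("need at least one layout", call. = FALSE)
  ref <- layouts[[1]]$points
  acc <- matrix(0, nrow(ref), nrow(ref))
  for (ly in layouts) {
    pts <- ly$points
    if (!identical(pts$point_id, ref$point_id) ||
        !identical(pts$group, ref$group))
      stop("layouts have inconsistent point sets", call. = FALSE)
    acc <- acc + as.matrix(stats::dist(cbind(pts$x, pts$y)))
  }
  d <- acc / length(layouts)
  dimnames(d) <- list(ref$point_id, ref$point_id)
  attr(d, "groups") <- ref$group
  d
}

#' Build the alignment substitution matrix
#'
#' Scores substitutions between AOI symbols from their spatial and
#' semantic relationship. For distinct points i, j in the same semantic
#' group the score is positive and inversely proportional to their average
#' distance, `+ d_min_same / d(i, j)`, where `d_min_same` is the smallest
#' distance over distinct same-group pairs — so the closest same-group
#' pair scores exactly +1. For points in different groups the score is
#' negative and directly proportional to distance, `- d(i, j) /
#' d_max_diff`, where `d_max_diff` is the largest cross-group distance —
#' so the most distant cross-group pair scores exactly -1. The diagonal
#' (identity substitution) is +1 and all entries lie in \[-1, +1\].
#'
#' With `form = "linear"` the same-group score decreases linearly from +1
#' at `d_min_same` to 0 at the largest same-group distance instead of
#' reciprocally (the cross-group branch is already linear); the +/-1
#' anchors are unchanged.
#'
#' @param distances 76 x 76 average distance matrix from
#'   [average_pair_distances()].
#' @param groups Character vector of per-point group labels; defaults to
#'   the `groups` attribute of `distances`.
#' @param gap_penalty Score contributed by each gap in the alignment
#'   (default 0, the ScanMatch toolbox default).
#' @param form `"reciprocal"` (default) or `"linear"` same-group score.
#' @return A `substitution_matrix`: a 76 x 76 symmetric numeric matrix
#'   with attributes `gap_penalty`, `groups` and `form`.
#' @export
build_substitution_matrix <- function(distances, groups = NULL,
                                      gap_penalty = 0,
                                      form = c("reciprocal", "linear")) {
  form <- match.arg(form)
  if (is.null(groups)) groups <- attr(distances, "groups")
  if (is.null(groups) || length(groups) != nrow(distances))
    stop("need one group label per AOI point", call. = FALSE)
  d <- unclass(distances)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  same <- outer(groups, groups, "==")
  off <- !diag(nrow(d))
  same_off <- same & off
  cross <- !same
  if (!any(same_off) || !any(cross))
    stop("need at least one same-group pair and one cross-group pair",
         call. = FALSE)
  if (any(d[same_off] == 0))
    stop("coincident distinct points within a group (zero distance)",
         call. = FALSE)
  d_min_same <- min(d[same_off])
  d_max_diff <- max(d[cross])
  s <- matrix(0, nrow(d), ncol(d))
  if (form == "reciprocal") {
    s[same_off] <- d_min_same / d[same_off]
  } else {
    d_max_same <- max(d[same_off])
    if (d_max_same > d_min_same) {
      s[same_off] <- (d_max_same - d[same_off]) / (d_max_same - d_min_same)
    } else {
      s[same_off] <- 1
    }
  }
  s[cross] <- -d[cross] / d_max_diff
  diag(s) <- 1
  s <- pmin(pmax(s, -1), 1)
  dimnames(s) <- dimnames(d)
  structure(s, gap_penalty = gap_penalty, groups = groups, form = form,
            class = c("substitution_matrix", "matrix"))
}

as_codes <- function(x) {
  if (is.list(x) && !is.null(x$codes)) x <- x$codes
  if (is.list(x) && length(x) == 1) x <- x[[1]]
  cd <- as.integer(x)
  if (length(cd) == 0) stop("empty scanpath string", call. = FALSE)
  cd
}

check_alphabet <- function(codes, sub) {
  if (any(codes < 1L) || any(codes > nrow(sub)))
    stop("scanpath symbol outside the substitution-matrix alphabet",
         call. = FALSE)
}

#' Needleman-Wunsch global alignment score
#'
#' Score of the optimal global alignment of two AOI-coded scanpath
#' strings: aligned symbol pairs contribute their substitution score, each
#' gap contributes `gap_penalty`. Score-only dynamic program, O(|s1| |s2|).
#'
#' @param s1,s2 Integer code vectors (or single scanpath rows).
#' @param sub A `substitution_matrix`.
#' @return The optimal total alignment score (scalar).
#' @export
nw_score <- function(s1, s2, sub) {
  a <- as_codes(s1); b <- as_codes(s2)
  check_alphabet(c(a, b), sub)
  .nw_score_cpp(a, b, unclass(sub), attr(sub, "gap_penalty"))
}

#' Length-normalized alignment similarity
#'
#' [nw_score()] divided by the length of the longer of the two strings,
#' guarding against longer scanpaths accumulating larger raw scores (with
#' a +1 diagonal, a string's normalized self-similarity is 1).
#'
#' @inheritParams nw_score
#' @return Normalized similarity (scalar).
#' @export
normalized_similarity <- function(s1, s2, sub) {
  a <- as_codes(s1); b <- as_codes(s2)
  nw_score(a, b, sub) / max(length(a), length(b))
}

#' All-pairs scanpath similarity matrix
#'
#' Computes [normalized_similarity()] for every unordered pair of
#' scanpaths (diagonal included).
#'
#' @param scanpaths Scanpath data.frame (see [encode_scanpaths()]); all
#'   strings must be non-empty.
#' @param sub A `substitution_matrix`.
#' @return A `similarity_matrix`: N x N symmetric numeric matrix with a
#'   `keys` attribute (data.frame subject_id/group/trial_id/eye/kind).
#' @export
similarity_matrix <- function(scanpaths, sub) {
  lens <- vapply(scanpaths$codes, length, integer(1))
  if (any(lens == 0))
    stop("similarity_matrix requires non-empty scanpath strings", call. = FALSE)
  check_alphabet(unlist(scanpaths$codes), sub)
  v <- .similarity_matrix_cpp(scanpaths$codes, unclass(sub),
                              attr(sub, "gap_penalty"))
  keys <- scanpaths[c("subject_id", "group", "trial_id", "eye", "kind")]
  key_str <- do.call(paste, c(keys, sep = "/"))
  if (anyDuplicated(key_str))
    stop("duplicate scanpath keys", call. = FALSE)
  dimnames(v) <- list(key_str, key_str)
  structure(v, keys = keys, class = c("similarity_matrix", "matrix"))
}

#' Levenshtein edit distance
#'
#' Minimum number of insertions, deletions and substitutions (unit costs)
#' between two symbol sequences; delegates to [utils::adist()]. Used by
#' the benchmark pathway in place of the alignment similarity.
#'
#' @param s1,s2 Integer code vectors, or character scalars.
#' @return Non-negative integer edit distance.
#' @export
levenshtein <- function(s1, s2) {
  to_str <- function(s) {
    if (is.character(s) && length(s) == 1) return(s)
    if (is.list(s) && !is.null(s$codes)) s <- s$codes
    if (is.list(s) && length(s) == 1) s <- s[[1]]
    paste(AOI_ALPHABET[as.integer(s)], collapse = "")
  }
  as.integer(utils::adist(to_str(s1), to_str(s2)))
}

#' All-pairs Levenshtein distance matrix
#'
#' @param scanpaths Scanpath data.frame.
#' @return N x N integer matrix of edit distances with a `keys` attribute.
#' @export
levenshtein_matrix <- function(scanpaths) {
  strs <- scanpath_strings(scanpaths)
  d <- utils::adist(strs)
  keys <- scanpaths[c("subject_id", "group", "trial_id", "eye", "kind")]
  key_str <- do.call(paste, c(keys, sep = "/"))
  dimnames(d) <- list(key_str, key_str)
  structure(d, keys = keys)
}

#' Write a similarity or substitution matrix to CSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
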
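#' Round half away from zero
#'
#' Binning uses round-half-up (2.5 bins -> 3), not banker's rounding.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Encode AOI-assigned fixations as temporally binned scanpath strings
#'
#' For each subject/trial/eye stream, every fixation contributes its AOI
#' symbol repeated `round(duration_ms / bin_ms)` times (round-half-up);
#' the per-fixation runs are concatenated in temporal order. Fixations
#' shorter than half a bin contribute nothing; a stream whose string comes
#' out empty is kept with a zero-length code so that the trial-exclusion
#' rule can act on it.
#'
#' @param fixations Fixation data.frame with a `point_id` column (see
#'   [assign_fixations()]).
#' @param bin_ms Temporal bin width in milliseconds (default 50).
#' @return A scanpath data.frame with one row per subject/trial/eye:
#'   columns `subject_id, group, trial_id, image_id, eye, kind` and a
#'   list-column `codes` of integer vectors (1-based AOI indices, i.e.
#'   `point_id + 1`). `kind` is `"original"`.
#' @export
encode_scanpaths <- function(fixations, bin_ms = 50) {
  if (nrow(fixations) == 0) stop("no fixations to encode", call. = FALSE)
  if (!"point_id" %in% names(fixations))
    stop("fixations must carry AOI assignments; run assign_fixations() first",
         call. = FALSE)
  stopifnot(bin_ms > 0)
  key <- interaction(fixations$subject_id, fixations$trial_id,
                     fixations$eye, drop = TRUE)
  idx <- split(seq_len(nrow(fixations)), key)
  rows <- lapply(idx, function(k) {
    k <- k[order(fixations$start_ms[k])]
    reps <- round_half_up(fixations$duration_ms[k] / bin_ms)
    codes <- rep(fixations$point_id[k] + 1L, pmax(reps, 0))
    f1 <- k[1]
    list(subject_id = fixations$subject_id[f1],
         group = fixations$group[f1],
         trial_id = fixations$trial_id[f1],
         image_id = fixations$image_id[f1],
         eye = fixations$eye[f1],
         codes = as.integer(codes))
  })
  out <- data.frame(
    subject_id = vapply(rows, `[[`, "", "subject_id"),
    group = vapply(rows, `[[`, "", "group"),
    trial_id = vapply(rows, `[[`, "", "trial_id"),
    image_id = vapply(rows, `[[`, "", "image_id"),
    eye = vapply(rows, `[[`, "", "eye"),
    kind = "original",
    stringsAsFactors = FALSE
  )
  out$codes <- lapply(rows, `[[`, "codes")
  out <- out[order(out$subject_id, out$trial_id, out$eye), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop trials without AOI transitions
#'
#' A trial is excluded when, for each eye, the scanpath string contains at
#' most one distinct symbol (an empty string counts as transition-free):
#' such trials carry no sequence information. A trial is kept as soon as
#' any eye shows a transition.
#'
#' @param scanpaths Scanpath data.frame from [encode_scanpaths()].
#' @param drop_empty_eyes Also drop kept trials in which some eye's string
#'   is empty (those cannot enter pairwise alignment); default TRUE.
#' @return The filtered scanpath data.frame. The number of dropped trials
#'   is reported via `message()` and attached as attribute `n_dropped`.
#' @export
exclude_transition_free <- function(scanpaths, drop_empty_eyes = TRUE) {
  key <- interaction(scanpaths$subject_id, scanpaths$trial_id, drop = TRUE)
  keep_trial <- vapply(split(seq_len(nrow(scanpaths)), key), function(k) {
    has_transition <- vapply(scanpaths$codes[k],
                             function(cd) length(unique(cd)) > 1, logical(1))
    if (!any(has_transition)) return(FALSE)
    if (drop_empty_eyes &&
        any(vapply(scanpaths$codes[k], length, integer(1)) == 0))
      return(FALSE)
    TRUE
  }, logical(1))
  keep <- keep_trial[as.character(key)]
  n_dropped <- length(unique(key[!keep])) # trials, not rows
  if (n_dropped > 0)
    message("excluding ", n_dropped, " transition-free trial(s)")
  out <- scanpaths[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Character-permuted spatial-only control scanpaths
#'
#' Destroys the temporal order of each scanpath string by a uniform random
#' permutation of its symbols, preserving the symbol multiset (AOI visit
#' frequencies). The permuted strings carry only spatial information and
#' serve as the spatial-only control in the classifier comparison.
#'
#' @param scanpaths Scanpath data.frame with `kind == "original"`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A scanpath data.frame of the same shape with `kind = "permuted"`.
#' @export
permute_scanpaths <- function(scanpaths, seed) {
  if (!all(scanpaths$kind == "original"))
    stop("can only permute original scanpaths", call. = FALSE)
  out <- scanpaths
  set.seed(seed)
  out$codes <- lapply(scanpaths$codes, function(cd) {
    if (length(cd) <= 1) cd else sample(cd)
  })
  out$kind <- "permuted"
  out
}

#' Render scanpath codes as character strings
#'
#' @param scanpaths Scanpath data.frame.
#' @return Character vector; symbol k of a string is
#'   `aoi_alphabet()[code_k]`.
#' @export
scanpath_strings <- function(scanpaths) {
  vapply(scanpaths$codes,
         function(cd) paste(AOI_ALPHABET[cd], collapse = ""), "")
}

#' Write scanpaths to a delimited file
#'
#' Serializes a scanpath table (codes rendered via [scanpath_strings()])
#' to CSV.
#'
#' @param scanpaths Scanpath data.frame.
#' @param path Output file path.
#' @export
write_scanpaths <- function(scanpaths, path) {
  df <- scanpaths[c("subject_id", "group", "trial_id", "image_id", "eye",
                    "kind")]
  df$symbols <- scanpath_strings(scanpaths)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
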
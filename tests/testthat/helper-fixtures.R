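# Shared fixtures and independent oracles, built in code at test time.

# Substitution-matrix object over a small alphabet, bypassing layout
# construction (the aligner itself is size-agnostic).
make_sub <- function(scores, gap = 0) {
  structure(scores, gap_penalty = gap,
            groups = rep("g", nrow(scores)),
            class = c("substitution_matrix", "matrix"))
}

# Scanpath table from a named list of integer code vectors.
make_scanpaths <- function(codes, eye = "left", group = "A",
                           kind = "original") {
  n <- length(codes)
  out <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep_len(group, n),
    trial_id = "t001",
    image_id = "img01",
    eye = rep_len(eye, n),
    kind = rep_len(kind, n),
    stringsAsFactors = FALSE)
  out$codes <- lapply(codes, as.integer)
  out
}

# Exhaustive global-alignment oracle: plain recursion over the three
# moves (substitute, gap in a, gap in b), maximizing the total score.
# Independent of the dynamic program under test; fine for lengths <= 6.
align_enumerate <- function(a, b, scores, gap) {
  if (length(a) == 0 && length(b) == 0) return(0)
  best <- -Inf
  if (length(a) > 0 && length(b) > 0)
    best <- max(best, scores[a[1], b[1]] +
                        align_enumerate(a[-1], b[-1], scores, gap))
  if (length(a) > 0)
    best <- max(best, gap + align_enumerate(a[-1], b, scores, gap))
  if (length(b) > 0)
    best <- max(best, gap + align_enumerate(a, b[-1], scores, gap))
  best
}

# All strings of the given lengths over symbols 1..k, as a list.
all_strings <- function(lengths, k) {
  out <- list()
  for (L in lengths) {
    g <- do.call(expand.grid, rep(list(seq_len(k)), L))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ])))
  }
  out
}

# Random symmetric substitution scores with +1 diagonal.
random_scores <- function(k) {
  m <- matrix(stats::runif(k * k, -1, 1), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Temporary CSV writer for ingest tests.
write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

valid_fixation_row <- function(...) {
  defaults <- list(subject_id = "s1", group = "A", trial_id = "t1",
                   image_id = "img01", eye = "left", start_ms = 0,
                   duration_ms = 200, x = 100, y = 100)
  args <- utils::modifyList(defaults, list(...))
  do.call(data.frame, c(args, stringsAsFactors = FALSE))
}

# Small complete study fast enough for pipeline tests.
tiny_study <- function(seed = 1, effect = "null", nsub = 5, ntrials = 4) {
  simulate_study(sim_scenario(
    n_subjects_per_group = nsub, trials_per_subject = ntrials,
    effect = effect, n_images = 2, seed = seed))
}
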
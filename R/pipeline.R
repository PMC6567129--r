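#' Pipeline configuration
#'
#' Collects every tunable of the group-comparison pipeline with its
#' default: 50 ms temporal bins, zero gap penalty, reciprocal
#' substitution scores, t-SNE at perplexity 30 for 1000 iterations, a
#' 1000-replicate Cramér permutation null at alpha 0.05, 5x2
#' cross-validation, and 1000 label permutations. A single master seed
#' fans out to per-stage seeds (see [derive_stage_seeds()]) so any stage
#' can be reproduced in isolation.
#'
#' @param bin_ms Temporal bin width (ms).
#' @param frame_margin Frame-point margin in px (`NULL` = 5% of the
#'   landmark bounding-box diagonal).
#' @param gap_penalty Alignment gap score.
#' @param sub_form Substitution-matrix form, `"reciprocal"` or
#'   `"linear"`.
#' @param perplexity,tsne_iterations t-SNE settings.
#' @param cramer_replicates,alpha Cramér-test settings.
#' @param cv_numerator 5x2cv t numerator, `"first"` or `"mean"`.
#' @param nrounds,max_depth Boosted-tree settings.
#' @param perm_k Label permutations for the chance-level test.
#' @param run_permutation_test Whether [compare_groups()] runs the
#'   (costly) label-permutation tests.
#' @param benchmark Use the Levenshtein + non-metric MDS pathway instead
#'   of alignment similarity + t-SNE.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(bin_ms = 50, frame_margin = NULL, gap_penalty = 0,
                       sub_form = "reciprocal", perplexity = 30,
                       tsne_iterations = 1000, cramer_replicates = 1000,
                       alpha = 0.05, cv_numerator = "first", nrounds = 50,
                       max_depth = 6, perm_k = 1000,
                       run_permutation_test = TRUE, benchmark = FALSE,
                       seed = 1) {
  stopifnot(bin_ms > 0, perplexity > 0, tsne_iterations > 0,
            cramer_replicates > 0, alpha > 0, alpha < 1, nrounds > 0,
            max_depth > 0, perm_k > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Derive per-stage seeds from the master seed
#'
#' Stage seeds are the first draws of `sample.int(2^31 - 1)` under the
#' master seed, assigned in a fixed documented order, so that any stage
#' can be re-run independently and reproducibly.
#'
#' @param seed Master seed.
#' @return Named integer vector with elements `permute`, `tsne_left`,
#'   `tsne_right`, `tsne_left_perm`, `tsne_right_perm`, `cramer_left`,
#'   `cramer_right`, `cv`, `perm_spatial`, `perm_full`.
#' @export
derive_stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 1, 10),
                  c("permute", "tsne_left", "tsne_right", "tsne_left_perm",
                    "tsne_right_perm", "cramer_left", "cramer_right", "cv",
                    "perm_spatial", "perm_full"))
}

log_stage <- function(verbose, ...) if (verbose) message("[gazealign] ", ...)

#' Full group-comparison pipeline
#'
#' Runs the complete analysis on a fixation table and landmark table:
#' AOI assignment, temporal binning into scanpath strings, exclusion of
#' transition-free trials, character-permuted spatial controls, pairwise
#' alignment similarity under the geometry-derived substitution matrix
#' (one similarity matrix per eye and per kind), 2-D embedding, the
#' per-eye permutation Cramér test of group difference (on the original,
#' i.e. spatio-temporal embeddings), per-trial feature assembly, the 5x2
#' cross-validated comparison of the spatial-only vs spatial + temporal
#' classifier, and (optionally) label-permutation chance-level tests for
#' both models. With `config$benchmark = TRUE` the Levenshtein distance
#' and non-metric MDS replace alignment similarity and t-SNE.
#'
#' @param fixations Fixation data.frame (see [read_fixations()];
#'   revalidated here).
#' @param landmarks Landmark data.frame (see [read_landmarks()]).
#' @param config A [run_config()].
#' @param verbose Log per-stage progress via `message()`.
#' @return List of class `gaze_report`: counts per stage, the per-eye
#'   Cramér results, embeddings, features, `cv` (the 5x2cv comparison),
#'   permutation tests, and the configuration with derived stage seeds.
#' @export
compare_groups <- function(fixations, landmarks, config = run_config(),
                           verbose = TRUE) {
  seeds <- derive_stage_seeds(config$seed)
  method <- if (config$benchmark) "levenshtein+nmds" else "scanmatch+tsne"
  fixations <- validate_fixations(fixations)
  layouts <- build_layouts(landmarks, frame_margin = config$frame_margin)
  log_stage(verbose, "layouts: ", length(layouts), " image(s), ",
            nrow(layouts[[1]]$points), " AOI points each")
  fx <- assign_fixations(fixations, layouts)
  sp <- encode_scanpaths(fx, bin_ms = config$bin_ms)
  log_stage(verbose, "encoded ", nrow(sp), " scanpath strings from ",
            nrow(fx), " fixations")
  sp <- suppressMessages(exclude_transition_free(sp))
  n_excluded <- attr(sp, "n_dropped")
  log_stage(verbose, "excluded ", n_excluded, " transition-free trial(s); ",
            nrow(sp), " strings retained")
  perm <- permute_scanpaths(sp, seed = seeds[["permute"]])
  sub <- NULL
  if (!config$benchmark) {
    sub <- build_substitution_matrix(
      average_pair_distances(layouts), gap_penalty = config$gap_penalty,
      form = config$sub_form)
  }
  embed_one <- function(strings, eye, kind) {
    seed_key <- paste0("tsne_", eye, if (kind == "permuted") "_perm" else "")
    subset <- strings[strings$eye == eye, , drop = FALSE]
    if (config$benchmark) {
      D <- levenshtein_matrix(subset)
      E <- nmds_embed(D, seed = seeds[[seed_key]])
    } else {
      S <- similarity_matrix(subset, sub)
      E <- tsne_embed(to_dissimilarity(S), perplexity = config$perplexity,
                      iterations = config$tsne_iterations,
                      seed = seeds[[seed_key]])
    }
    log_stage(verbose, "embedded ", nrow(E), " ", kind, " ", eye,
              "-eye scanpaths (", method, ")")
    E
  }
  embeddings <- list(
    original_left = embed_one(sp, "left", "original"),
    original_right = embed_one(sp, "right", "original"),
    permuted_left = embed_one(perm, "left", "permuted"),
    permuted_right = embed_one(perm, "right", "permuted"))
  groups <- sort(unique(sp$group))
  cramer <- lapply(c(left = "left", right = "right"), function(eye) {
    E <- embeddings[[paste0("original_", eye)]]
    res <- cramer_test(
      as.matrix(E[E$group == groups[1], c("dim1", "dim2")]),
      as.matrix(E[E$group == groups[2], c("dim1", "dim2")]),
      replicates = config$cramer_replicates, alpha = config$alpha,
      seed = seeds[[paste0("cramer_", eye)]])
    log_stage(verbose, eye, "-eye Cramer test: statistic = ",
              signif(res$statistic, 4), ", p = ", signif(res$p_value, 4))
    res
  })
  features <- suppressMessages(assemble_features(embeddings))
  log_stage(verbose, "assembled ", nrow(features), " trial feature rows (",
            attr(features, "n_dropped"), " dropped)")
  cv <- five_by_two_cv(features, seed = seeds[["cv"]],
                       numerator = config$cv_numerator,
                       nrounds = config$nrounds,
                       max_depth = config$max_depth)
  log_stage(verbose, "5x2cv: spatial = ", signif(100 * cv$acc_spatial, 3),
            "%, spatial+temporal = ", signif(100 * cv$acc_full, 3),
            "%, t(5) = ", signif(cv$t_stat, 3), ", p = ",
            signif(cv$p_value, 3))
  perm_tests <- NULL
  if (config$run_permutation_test) {
    perm_tests <- list(
      spatial = label_permutation_test(features, "spatial", k = config$perm_k,
                                       seed = seeds[["perm_spatial"]],
                                       nrounds = config$nrounds,
                                       max_depth = config$max_depth),
      full = label_permutation_test(features, "full", k = config$perm_k,
                                    seed = seeds[["perm_full"]],
                                    nrounds = config$nrounds,
                                    max_depth = config$max_depth))
    log_stage(verbose, "chance-level permutation tests: p_spatial = ",
              signif(perm_tests$spatial$p_value, 4), ", p_full = ",
              signif(perm_tests$full$p_value, 4))
  }
  structure(list(
    method = method,
    counts = list(fixations = nrow(fixations), scanpaths = nrow(sp),
                  trials_excluded = n_excluded,
                  feature_rows = nrow(features),
                  features_dropped = attr(features, "n_dropped")),
    groups = groups,
    substitution = sub,
    embeddings = embeddings,
    cramer = cramer,
    features = features,
    cv = cv,
    permutation_tests = perm_tests,
    config = config,
    stage_seeds = seeds
  ), class = "gaze_report")
}

#' @export
print.gaze_report <- function(x, ...) {
  cat("gazealign group comparison (", x$method, ")\n", sep = "")
  cat("  groups: ", paste(x$groups, collapse = " vs "), "; ",
      x$counts$scanpaths, " scanpaths from ", x$counts$fixations,
      " fixations (", x$counts$trials_excluded, " trials excluded)\n",
      sep = "")
  for (eye in names(x$cramer))
    cat(sprintf("  %s eye Cramer: statistic = %.4g, critical = %.4g, p = %.4g\n",
                eye, x$cramer[[eye]]$statistic,
                x$cramer[[eye]]$critical_value, x$cramer[[eye]]$p_value))
  print(x$cv)
  if (!is.null(x$permutation_tests))
    cat(sprintf("  chance-level tests: p_spatial = %.4g, p_full = %.4g\n",
                x$permutation_tests$spatial$p_value,
                x$permutation_tests$full$p_value))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (counts, Cramér results, 5x2cv comparison,
#' permutation tests, config) plus CSV intermediates (embeddings,
#' features, fold log) into `dir`.
#'
#' @param report A `gaze_report` from [compare_groups()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$embeddings))
    utils::write.csv(report$embeddings[[nm]],
                     file.path(dir, paste0("embedding_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cv$fold_log, file.path(dir, "fold_log.csv"),
                   row.names = FALSE)
  json <- list(
    method = report$method,
    groups = report$groups,
    counts = report$counts,
    cramer = lapply(report$cramer, function(r)
      r[c("statistic", "critical_value", "p_value", "replicates", "alpha",
          "seed")]),
    cv = report$cv[c("acc_spatial", "acc_full", "t_stat", "df", "p_value",
                     "numerator", "seed")],
    confusion = lapply(report$cv$confusion, function(m)
      list(labels = rownames(m), counts = unclass(m))),
    permutation_tests = lapply(report$permutation_tests, function(r)
      r[c("observed", "p_value", "k", "feature_set", "seed")]),
    config = unclass(report$config)[!vapply(unclass(report$config), is.null,
                                            logical(1))],
    stage_seeds = as.list(report$stage_seeds))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
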
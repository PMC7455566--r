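#' Sample a random feature subset for one trial
#'
#' Uniform sample without replacement of `k` feature ids from a bank; each
#' presented stimulus is the sum of such a subset (default 90 of 1000).
#'
#' @param bank A [feature_bank()].
#' @param k Subset size (default 90).
#' @return Integer vector of `k` feature ids.
#' @export
sample_subset <- function(bank, k = 90L) {
  if (k > bank$n_features)
    stopf("subset size k = %d exceeds bank size %d", k, bank$n_features)
  sample(bank$wavelets$feature_id, k)
}

#' Build a trial list for one participant
#'
#' Sessions each contain `trials_per_image` trials of every image (default
#' 50), with an independent random 90-feature subset per trial and a uniform
#' shuffle of trial order within each session.
#'
#' @param banks Named list of [feature_bank()]s (names = image ids).
#' @param n_sessions Number of sessions (>= 1).
#' @param participant_id Identifier recorded on every trial.
#' @param true_categories Named character vector mapping image id to its
#'   category label (e.g. "cat"/"dog"); defaults to the leading alphabetic
#'   prefix of each image id.
#' @param trials_per_image Trials per image per session (default 50).
#' @param subset_size Features per trial (default 90).
#' @return A data.frame (one row per trial) with columns `trial_id`,
#'   `participant_id`, `session`, `image_id`, `true_category`,
#'   `feature_ids` (semicolon-joined integers).
#' @export
build_experiment <- function(banks, n_sessions, participant_id = "p01",
                             true_categories = NULL,
                             trials_per_image = 50L, subset_size = 90L) {
  if (length(banks) == 0L) stopf("at least one feature bank is required")
  if (n_sessions < 1L) stopf("`n_sessions` must be >= 1")
  image_ids <- vapply(banks, `[[`, character(1), "image_id")
  names(banks) <- image_ids
  if (is.null(true_categories))
    true_categories <- stats::setNames(sub("[^a-zA-Z].*$", "", image_ids),
                                       image_ids)
  rows <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    imgs <- rep(image_ids, each = trials_per_image)
    imgs <- imgs[sample.int(length(imgs))]
    subsets <- vapply(imgs, function(id)
      paste(sample_subset(banks[[id]], subset_size), collapse = ";"),
      character(1), USE.NAMES = FALSE)
    rows[[s]] <- data.frame(
      participant_id = participant_id, session = s, image_id = imgs,
      true_category = unname(true_categories[imgs]), feature_ids = subsets)
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial_id = sprintf("%s_t%05d", participant_id,
                                  seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Render the stimulus image of one trial
#'
#' Sums the trial's feature subset and rescales to the full 0-255 display
#' range.
#'
#' @param trial One row of a trial table (list or one-row data.frame).
#' @param banks Named list of [feature_bank()]s.
#' @return Integer matrix in 0..255.
#' @export
render_trial <- function(trial, banks) {
  trial <- as.list(trial[1, , drop = FALSE])
  bank <- banks[[trial$image_id]]
  if (is.null(bank)) stopf("no feature bank for image '%s'", trial$image_id)
  ids <- parse_feature_ids(trial$feature_ids)[[1]]
  rescale_to_display(sum_features(bank, ids))
}

# "1;5;9" -> list(c(1L, 5L, 9L)); vectorized over rows.
parse_feature_ids <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), as.integer)
}

#' Write / read a trial table CSV
#'
#' Long-format trial manifest: `trial_id, participant_id, session, image_id,
#' true_category, feature_ids` plus, when responses have been collected or
#' simulated, `response` (reported category or "unsure") and `rt_ms`.
#'
#' @param trials Trial table data.frame.
#' @param path CSV path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, colClasses = c(feature_ids = "character"))
}
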
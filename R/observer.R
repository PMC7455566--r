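#' Cohort configuration for the simulated-observer generator
#'
#' Defines the study conditions the generator emulates: cohort size and AQ
#' score distribution, the empirical distribution of completed sessions, and
#' the planted effect sizes that downstream analyses are expected to
#' recover. AQ totals are drawn from a normal distribution truncated to
#' `aq_range` and rounded; participants with AQ above the cohort median form
#' the high-AQ group. The planted structure enters through
#' [ground_truth_weights()]: high-AQ participants up-weight high-spatial-
#' frequency features by `sf_coupling["high"]`, and every endorsed AQ item
#' adds `item_coupling` times its (centered) clinical log-diagnosticity, so
#' that trait-level analyses see reliance-on-detail scale with
#' diagnosticity.
#'
#' @param n_participants Cohort size (default 52, >= 4).
#' @param aq_range Inclusive AQ total range (default 5-30).
#' @param aq_mean,aq_sd Location/spread of the (truncated) AQ sampler
#'   (defaults 14.3 and 5.9).
#' @param sessions_tab Named integer vector: completed-session counts and
#'   how many participants completed each; the default matches 6, 5, 4, 3
#'   and 2 sessions completed by 2, 14, 25, 10 and 1 of 52 participants.
#'   Used as an empirical sampling distribution for other cohort sizes.
#' @param trials_per_image Trials per image per session (default 50).
#' @param subset_size Features shown per trial (default 90).
#' @param sf_coupling Named numeric, planted spatial-frequency coupling per
#'   AQ group (weight added per SD of feature spatial frequency).
#' @param item_coupling Planted per-endorsed-item coupling, scaled by the
#'   item's centered log-diagnosticity.
#' @param base_weight_scale Scale of the shared base diagnosticity structure
#'   (1 = rank-normalized covariance weights spanning (0, 1]; 0 = flat
#'   weights, making responses pure noise — the fully uninformative
#'   null observer).
#' @param trait_table Trait table (see [synthetic_trait_table()]).
#' @param rt_base_ms,rt_base_sd_ms,rt_sd_ms Reaction-time parameters:
#'   cohort-level mean and SD of per-participant baseline, and trial-level
#'   SD (defaults echo a ~895 +/- 313 ms empirical RT distribution).
#' @param rt_coupling_ms RT decrease (ms) per unit of trial evidence above
#'   baseline; 0 (the default) makes RT carry no feature information.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 52L,
                          aq_range = c(5L, 30L),
                          aq_mean = 14.3, aq_sd = 5.9,
                          sessions_tab = c(`2` = 1, `3` = 10, `4` = 25,
                                           `5` = 14, `6` = 2),
                          trials_per_image = 50L,
                          subset_size = 90L,
                          sf_coupling = c(low = 0, high = 0.05),
                          item_coupling = 0.01,
                          base_weight_scale = 1,
                          trait_table = synthetic_trait_table(),
                          rt_base_ms = 895, rt_base_sd_ms = 100,
                          rt_sd_ms = 313,
                          rt_coupling_ms = 0) {
  if (n_participants < 4L) stopf("`n_participants` must be >= 4")
  if (length(aq_range) != 2L || aq_range[1] > aq_range[2])
    stopf("`aq_range` must be c(min, max)")
  if (!all(c("low", "high") %in% names(sf_coupling)))
    stopf("`sf_coupling` must have elements named 'low' and 'high'")
  if (!all(is.finite(c(sf_coupling, item_coupling, rt_coupling_ms))))
    stopf("planted effect sizes must be finite")
  structure(
    list(n_participants = as.integer(n_participants),
         aq_range = as.integer(aq_range), aq_mean = aq_mean, aq_sd = aq_sd,
         sessions_tab = sessions_tab,
         trials_per_image = as.integer(trials_per_image),
         subset_size = as.integer(subset_size),
         sf_coupling = sf_coupling, item_coupling = item_coupling,
         base_weight_scale = base_weight_scale,
         trait_table = trait_table,
         rt_base_ms = rt_base_ms, rt_base_sd_ms = rt_base_sd_ms,
         rt_sd_ms = rt_sd_ms, rt_coupling_ms = rt_coupling_ms),
    class = "cohort_config"
  )
}

#' Simulated-observer decision model
#'
#' Trial evidence is the mean ground-truth weight of the presented features
#' plus Gaussian noise; the response is the correct category above
#' `theta_correct`, the wrong category below `theta_wrong`, and "unsure" in
#' between. With the default weight scale (rank-normalized base weights in
#' (0, 1]) the defaults put cohort marginals near 50% correct, 21% wrong and
#' 29% unsure.
#'
#' @param theta_correct,theta_wrong Decision thresholds
#'   (`theta_wrong < theta_correct`).
#' @param noise_sd Evidence noise SD (>= 0).
#' @param rt_min_ms Lower truncation of simulated reaction times.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(theta_correct = 0.5, theta_wrong = 0.46,
                           noise_sd = 0.04, rt_min_ms = 150) {
  if (!(theta_wrong < theta_correct))
    stopf("`theta_wrong` must be below `theta_correct`")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(list(theta_correct = theta_correct, theta_wrong = theta_wrong,
                 noise_sd = noise_sd, rt_min_ms = rt_min_ms),
            class = "observer_model")
}

#' Simulate a participant cohort with AQ profiles
#'
#' Draws AQ totals from the truncated normal sampler, endorses that many of
#' the 50 items uniformly at random, scores the five 10-item subscales,
#' assigns high/low group by the "AQ above the cohort median" rule, and
#' draws per-participant session counts and RT baselines.
#'
#' @param cfg A [cohort_config()].
#' @param seed Optional integer seed.
#' @return An object of class `cohort`: `profiles` (data.frame with
#'   `participant_id`, `aq_total`, `group`, `n_sessions`, `rt_base_ms`,
#'   `rt_sd_ms` and the five subscale scores), `items` (n x 50 binary
#'   matrix), `trait_table`, `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = NULL) {
  with_seed(seed, {
    n <- cfg$n_participants
    draw_aq <- function() {
      repeat {
        x <- round(stats::rnorm(1, cfg$aq_mean, cfg$aq_sd))
        if (x >= cfg$aq_range[1] && x <= cfg$aq_range[2]) return(x)
      }
    }
    aq <- vapply(seq_len(n), function(i) draw_aq(), numeric(1))
    med <- stats::median(aq)
    if (all(aq == aq[1])) {
      warnf("degenerate cohort: all AQ totals identical; everyone assigned to the low group")
      group <- rep("low", n)
    } else {
      group <- ifelse(aq > med, "high", "low")
    }
    items <- t(vapply(seq_len(n), function(i) {
      x <- integer(50)
      x[sample.int(50, aq[i])] <- 1L
      x
    }, integer(50)))
    colnames(items) <- sprintf("item_%02d", 1:50)
    sub <- cfg$trait_table$subscale[order(cfg$trait_table$item_id)]
    sub_scores <- t(apply(items, 1, function(x) tapply(x, sub, sum)))
    sessions <- sample(as.integer(names(cfg$sessions_tab)), n, replace = TRUE,
                       prob = cfg$sessions_tab)
    profiles <- data.frame(
      participant_id = sprintf("p%02d", seq_len(n)),
      aq_total = as.integer(aq), group = group, n_sessions = sessions,
      rt_base_ms = stats::rnorm(n, cfg$rt_base_ms, cfg$rt_base_sd_ms),
      rt_sd_ms = cfg$rt_sd_ms)
    profiles <- cbind(profiles, as.data.frame(sub_scores))
    rownames(items) <- profiles$participant_id
    structure(list(profiles = profiles, items = items,
                   trait_table = cfg$trait_table, config = cfg),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, AQ %d-%d (median %.1f), %d high / %d low\n",
              nrow(x$profiles), min(x$profiles$aq_total),
              max(x$profiles$aq_total), stats::median(x$profiles$aq_total),
              sum(x$profiles$group == "high"),
              sum(x$profiles$group == "low")))
  invisible(x)
}

#' Extract one participant's profile (with item endorsements)
#'
#' @param cohort A [simulate_cohort()] result.
#' @param participant_id Participant identifier.
#' @return A list with the profile fields plus `items` (length-50 binary
#'   vector).
#' @export
participant_profile <- function(cohort, participant_id) {
  i <- match(participant_id, cohort$profiles$participant_id)
  if (is.na(i)) stopf("unknown participant '%s'", participant_id)
  out <- as.list(cohort$profiles[i, ])
  out$items <- cohort$items[i, ]
  out
}

#' Planted ground-truth feature weights for one participant and image
#'
#' The generative diagnosticity of feature f is
#' `base_f + coupling * zscore(sf_f)`, where `base_f` is the feature's
#' normalized covariance rank within the bank (in (0, 1], highest covariance
#' -> 1; shrunk toward a flat 0.5 by `base_weight_scale < 1`) and the
#' participant's coupling is the group spatial-frequency coupling plus
#' `item_coupling` times the sum of centered log-diagnosticities of the
#' items they endorse.
#'
#' @param bank A [feature_bank()] with a `covariance` column.
#' @param profile A [participant_profile()] (needs `group` and `items`).
#' @param cfg A [cohort_config()].
#' @return Numeric vector of weights, ordered by `feature_id`.
#' @export
ground_truth_weights <- function(bank, profile, cfg = cohort_config()) {
  w <- bank$wavelets[order(bank$wavelets$feature_id), ]
  if (is.null(w$covariance))
    stopf("bank has no `covariance` column; use decompose() or synthetic_feature_bank()")
  base <- 0.5 +
    cfg$base_weight_scale * (rank(w$covariance, ties.method = "average") /
                               nrow(w) - 0.5)
  zsf <- as.vector(scale(w$sf_cpd))
  if (anyNA(zsf)) zsf <- rep(0, nrow(w)) # single-frequency bank
  coupling <- participant_coupling(profile, cfg)
  base + coupling * zsf
}

# Planted spatial-frequency coupling of one participant.
participant_coupling <- function(profile, cfg) {
  d <- cfg$trait_table$log_diagnosticity[order(cfg$trait_table$item_id)]
  unname(cfg$sf_coupling[profile$group]) +
    cfg$item_coupling * sum(profile$items * (d - mean(d)))
}

#' Simulate the response and reaction time of one trial
#'
#' Evidence is the mean planted weight of the presented features plus
#' `N(0, noise_sd)` noise; the outcome is "correct" above `theta_correct`,
#' "wrong" below `theta_wrong`, otherwise "unsure". The reaction time is
#' `max(rt_min_ms, N(rt_base, rt_sd))`; with a nonzero `rt_coupling_ms` the
#' RT mean decreases with the (noiseless) evidence, planting feature
#' information into RTs.
#'
#' @param trial One trial row (needs `feature_ids`).
#' @param weights Planted weight vector of the trial's image (by
#'   feature_id).
#' @param model An [observer_model()].
#' @param rt_base_ms,rt_sd_ms,rt_coupling_ms RT parameters.
#' @return A list with `response` ("correct"/"wrong"/"unsure") and `rt_ms`.
#' @export
simulate_response <- function(trial, weights, model = observer_model(),
                              rt_base_ms = 895, rt_sd_ms = 313,
                              rt_coupling_ms = 0) {
  ids <- parse_feature_ids(trial$feature_ids)[[1]]
  ev <- mean(weights[ids + 1L])
  r <- simulate_responses_core(ev, model, rt_base_ms, rt_sd_ms,
                               rt_coupling_ms)
  list(response = r$response, rt_ms = r$rt_ms)
}

# Vectorized decision + RT core over noiseless evidence values.
simulate_responses_core <- function(ev, model, rt_base_ms, rt_sd_ms,
                                    rt_coupling_ms) {
  n <- length(ev)
  e <- ev + stats::rnorm(n, 0, model$noise_sd)
  response <- ifelse(e > model$theta_correct, "correct",
                     ifelse(e < model$theta_wrong, "wrong", "unsure"))
  rt <- pmax(model$rt_min_ms,
             stats::rnorm(n, rt_base_ms - rt_coupling_ms * (ev - 0.5),
                          rt_sd_ms))
  list(response = response, rt_ms = rt)
}

#' Simulate a full behavioral experiment
#'
#' Composes [simulate_cohort()], per-participant [build_experiment()] and
#' the observer decision model into a complete trial table. The `response`
#' column records the reported category ("unsure" when neither threshold is
#' crossed), so correctness can be recomputed as
#' `response == true_category`; a logical `correct` column is included.
#'
#' @param cfg A [cohort_config()].
#' @param banks Named list of [feature_bank()]s (with `covariance` columns).
#' @param seed Optional integer seed (drives cohort, trial structure and
#'   responses).
#' @param model An [observer_model()].
#' @param n_sessions Optional fixed session count overriding the cohort's
#'   sampled session numbers (e.g. 4 for 200 trials/image).
#' @param cohort Optional pre-built [simulate_cohort()] result to reuse.
#' @return An object of class `fdi_simulation`: `trials` (trial table with
#'   `response`, `correct`, `rt_ms`), `cohort`, `weights` (participant ->
#'   image -> weight vector), `model`.
#' @export
simulate_experiment <- function(cfg = cohort_config(), banks, seed = NULL,
                                model = observer_model(),
                                n_sessions = NULL, cohort = NULL) {
  if (length(banks) == 0L) stopf("at least one feature bank is required")
  image_ids <- vapply(banks, `[[`, character(1), "image_id")
  names(banks) <- image_ids
  cats <- stats::setNames(sub("[^a-zA-Z].*$", "", image_ids), image_ids)
  if (length(unique(cats)) < 2L) {
    # need a distractor label for wrong responses
    cats <- stats::setNames(rep(c("a", "b"), length.out = length(image_ids)),
                            image_ids)
  }
  run <- function() {
    if (is.null(cohort))
      cohort <- simulate_cohort(cfg)
    prof <- cohort$profiles
    all_cats <- unique(unname(cats))
    out <- vector("list", nrow(prof))
    weights <- vector("list", nrow(prof))
    names(weights) <- prof$participant_id
    for (i in seq_len(nrow(prof))) {
      p <- participant_profile(cohort, prof$participant_id[i])
      ns <- if (is.null(n_sessions)) p$n_sessions else n_sessions
      tr <- build_experiment(banks, ns, participant_id = p$participant_id,
                             true_categories = cats,
                             trials_per_image = cfg$trials_per_image,
                             subset_size = cfg$subset_size)
      w <- lapply(banks, ground_truth_weights, profile = p, cfg = cfg)
      ids <- parse_feature_ids(tr$feature_ids)
      ev <- vapply(seq_len(nrow(tr)), function(j)
        mean(w[[tr$image_id[j]]][ids[[j]] + 1L]), numeric(1))
      r <- simulate_responses_core(ev, model, p$rt_base_ms, p$rt_sd_ms,
                                   cfg$rt_coupling_ms)
      other <- vapply(tr$true_category, function(tc)
        if (length(all_cats) > 1L) sample(setdiff(all_cats, tc), 1L) else tc,
        character(1), USE.NAMES = FALSE)
      tr$response <- ifelse(r$response == "correct", tr$true_category,
                            ifelse(r$response == "wrong", other, "unsure"))
      tr$correct <- tr$response == tr$true_category
      tr$rt_ms <- round(r$rt_ms, 1)
      out[[i]] <- tr
      weights[[i]] <- w
    }
    structure(list(trials = do.call(rbind, out), cohort = cohort,
                   weights = weights, model = model),
              class = "fdi_simulation")
  }
  with_seed(seed, run())
}

#' @export
print.fdi_simulation <- function(x, ...) {
  cat(sprintf("<fdi_simulation> %d trials, %d participants, %d images; %.1f%% correct\n",
              nrow(x$trials), nrow(x$cohort$profiles),
              length(unique(x$trials$image_id)),
              100 * mean(x$trials$correct)))
  invisible(x)
}
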
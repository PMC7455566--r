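# Shared fixtures. Small geometries keep the default 250 px / 22.5 dva
# pixel pitch (11.11 px/dva) so the spatial-frequency ladder stays
# representable.

test_geom <- function(side = 64L) image_geometry(side, side / (250 / 22.5))

make_banks <- function(n_images = 2L, n_features = 200L, seed = 100L,
                       geom = image_geometry()) {
  ids <- sprintf("%s%02d", rep(c("cat", "dog"), length.out = n_images),
                 seq_len(n_images))
  lapply(stats::setNames(ids, ids), function(id)
    synthetic_feature_bank(id, n_features, geom,
                           seed = seed + match(id, ids)))
}

# A hand-sized trial table: 1 participant, 1 image, features 0..3,
# trials (0,1) correct, (0,2) correct, (0,3) wrong.
toy_trials <- function() {
  data.frame(
    trial_id = c("t1", "t2", "t3"),
    participant_id = "p01", session = 1L, image_id = "cat01",
    true_category = "cat",
    feature_ids = c("0;1", "0;2", "0;3"),
    response = c("cat", "cat", "dog"))
}

quick_sim <- function(n_participants = 8L, n_images = 2L, n_features = 100L,
                      n_sessions = 1L, seed = 42L,
                      subset_size = max(5L, round(0.09 * n_features)), ...) {
  banks <- make_banks(n_images, n_features, seed)
  cfg <- cohort_config(n_participants = n_participants,
                       subset_size = subset_size, ...)
  suppressMessages(
    simulate_experiment(cfg, banks, seed = seed, n_sessions = n_sessions))
}
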
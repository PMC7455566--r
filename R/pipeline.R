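#' Ingest and validate a trial table CSV
#'
#' Reads a long-format trial CSV (see [write_trials()]), checks the schema,
#' validates feature ids against the banks (or an explicit feature count),
#' and recomputes correctness as `response == true_category` — "unsure" and
#' wrong-animal responses both count as not recognized.
#'
#' @param path CSV path.
#' @param banks Optional named list of [feature_bank()]s for id validation.
#' @param n_features Optional feature count per image (used when `banks` is
#'   absent).
#' @return Validated trial table with a recomputed `correct` column.
#' @export
ingest_trials <- function(path, banks = NULL, n_features = NULL) {
  trials <- read_trials(path)
  req <- c("trial_id", "participant_id", "session", "image_id",
           "true_category", "feature_ids", "response")
  miss <- setdiff(req, names(trials))
  if (length(miss) > 0L)
    stopf("trial table misses column(s): %s", paste(miss, collapse = ", "))
  ids <- parse_feature_ids(trials$feature_ids)
  bad <- vapply(seq_along(ids), function(i) {
    nf <- if (!is.null(banks)) {
      b <- banks[[trials$image_id[i]]]
      if (is.null(b)) return(TRUE)
      b$n_features
    } else if (!is.null(n_features)) n_features else Inf
    anyNA(ids[[i]]) || any(ids[[i]] < 0L | ids[[i]] >= nf)
  }, logical(1))
  if (any(bad))
    stopf("invalid feature ids (or unknown image) in row(s): %s",
          paste(utils::head(which(bad), 10), collapse = ", "))
  trials$correct <- trials$response == trials$true_category
  trials
}

#' Default end-to-end run configuration
#'
#' When `images` is `NULL` the pipeline runs on synthetic feature banks and
#' a simulated cohort; when image PNG paths are given they are decomposed
#' first. When `trials_csv` is given, simulation is skipped and the CSV is
#' ingested instead (AQ groups then come from `aq_csv`, a table with
#' `participant_id` and either `group` or `aq_total`).
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Global integer seed.
#' @param images Optional named character vector of PNG paths.
#' @param landmarks Optional landmarks JSON path (enables the eye-distance
#'   analysis).
#' @param trials_csv Optional behavioral data CSV (skips simulation).
#' @param aq_csv Optional participant AQ table CSV.
#' @param trait_table Optional trait table CSV path (default: the bundled
#'   synthetic table).
#' @param n_images,n_features Synthetic bank shape when no images are given.
#' @param geom,decomposition,cohort,model Component configurations.
#' @param n_splits,n_perm Replicability parameters.
#' @param criteria Bin criteria to analyze (subset of `"sf"`,
#'   `"eye_distance"`, `"center_distance"`).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "fdimap_out", seed = 1L, images = NULL,
                       landmarks = NULL, trials_csv = NULL, aq_csv = NULL,
                       trait_table = NULL, n_images = 10L,
                       n_features = 1000L, geom = image_geometry(),
                       decomposition = decomposition_config(),
                       cohort = cohort_config(), model = observer_model(),
                       n_splits = 100L, n_perm = 1000L,
                       criteria = c("sf", "center_distance")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), images = images,
                 landmarks = landmarks, trials_csv = trials_csv,
                 aq_csv = aq_csv, trait_table = trait_table,
                 n_images = n_images, n_features = n_features, geom = geom,
                 decomposition = decomposition, cohort = cohort,
                 model = model, n_splits = n_splits, n_perm = n_perm,
                 criteria = criteria),
            class = "run_config")
}

#' Run the full feature-diagnosticity pipeline
#'
#' Executes decomposition (or synthetic bank generation), trial simulation
#' (or ingestion of a real trial CSV), FDi estimation, split-half
#' replicability with permutation null, the bin x group ANOVAs with the
#' highest-bin contrast, and the trait statistics; writes the FDi long CSV,
#' JSON reports and a plain-text summary into `cfg$out_dir`. Every JSON
#' report embeds the seed and a configuration hash. Deterministic given the
#' seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # fingerprint the scientific configuration, not the output location
  stamp <- list(seed = cfg$seed,
                config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]))
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[stage %s] %s", name, conditionMessage(e)))
  }

  # --- banks -------------------------------------------------------------
  banks <- stage("banks", {
    if (!is.null(cfg$images)) {
      say("decomposing %d image(s)", length(cfg$images))
      lapply(stats::setNames(names(cfg$images), names(cfg$images)),
             function(id) decompose(read_image_png(cfg$images[[id]]), id,
                                    cfg$geom, cfg$decomposition,
                                    seed = child_seed(cfg$seed, id)))
    } else {
      say("generating %d synthetic feature bank(s) of %d features",
          cfg$n_images, cfg$n_features)
      ids <- sprintf("%s%02d", rep(c("cat", "dog"), length.out = cfg$n_images),
                     seq_len(cfg$n_images))
      lapply(stats::setNames(ids, ids), function(id)
        synthetic_feature_bank(id, cfg$n_features, cfg$geom,
                               cfg$decomposition$ladder,
                               seed = child_seed(cfg$seed, id)))
    }
  })

  trait_table <- if (is.null(cfg$trait_table)) synthetic_trait_table()
                 else read_trait_table(cfg$trait_table)

  # --- trials ------------------------------------------------------------
  sim <- NULL
  if (is.null(cfg$trials_csv)) {
    sim <- stage("simulate", {
      say("simulating cohort of %d participants", cfg$cohort$n_participants)
      simulate_experiment(cfg$cohort, banks,
                          seed = child_seed(cfg$seed, "experiment"),
                          model = cfg$model)
    })
    trials <- sim$trials
    groups <- stats::setNames(sim$cohort$profiles$group,
                              sim$cohort$profiles$participant_id)
    items <- sim$cohort$items
    write_trials(trials, file.path(cfg$out_dir, "trials.csv"))
  } else {
    trials <- stage("ingest", ingest_trials(cfg$trials_csv, banks))
    groups <- items <- NULL
    if (!is.null(cfg$aq_csv)) {
      aq <- utils::read.csv(cfg$aq_csv)
      if (!"group" %in% names(aq))
        aq$group <- ifelse(aq$aq_total > stats::median(aq$aq_total),
                           "high", "low")
      groups <- stats::setNames(aq$group, aq$participant_id)
      icols <- grep("^item_", names(aq), value = TRUE)
      if (length(icols) == 50L)
        items <- as.matrix(aq[icols])
    }
  }
  say("%d trials from %d participants (%.1f%% correct)", nrow(trials),
      length(unique(trials$participant_id)), 100 * mean(trials$correct))

  # --- FDi ---------------------------------------------------------------
  nf <- banks[[1]]$n_features
  fdi <- stage("fdi", compute_fdi(trials, n_features = nf))
  write_fdi(fdi, file.path(cfg$out_dir, "fdi.csv"))
  rep_res <- stage("replicability",
                   permutation_p(fdi, cfg$n_splits, cfg$n_perm,
                                 seed = child_seed(cfg$seed, "replicability")))
  say("split-half replicability r = %.4f, p = %.4g", rep_res$observed_r,
      rep_res$p_value)
  jsonlite::write_json(c(stamp, unclass(rep_res)),
                       file.path(cfg$out_dir, "replicability.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- bin ANOVAs --------------------------------------------------------
  landmarks <- if (!is.null(cfg$landmarks)) read_landmarks(cfg$landmarks)
  if ("eye_distance" %in% cfg$criteria && is.null(landmarks))
    stopf("[stage bins] eye-distance analysis requested but no landmarks supplied")
  anovas <- list()
  bin_means_sf <- NULL
  for (crit in cfg$criteria) {
    fv <- stage("bins", feature_values(banks, crit, landmarks))
    spec <- assign_bins(fv$value, 5L, fv$image_id, fv$feature_id)
    bm <- participant_bin_means(fdi, spec)
    if (crit == "sf") bin_means_sf <- bm
    res <- list(boundaries = spec$boundaries)
    if (!is.null(groups)) {
      g <- unname(groups[rownames(bm)])
      an <- bin_group_anova(bm, g, error = "within")
      res$anova <- an$table
      res$contrast_highest_bin <- highest_bin_contrast(bm, g)
      say("%s x group interaction: F(%d, %d) = %.3f, p = %.4g", crit,
          an$table$df1[3], an$table$df2[3], an$table$F[3], an$table$p[3])
    }
    anovas[[crit]] <- res
  }
  if (!is.null(groups)) {
    rec <- recognition_anova(trials, groups, error = "within")
    anovas$recognition <- rec$table
  }
  jsonlite::write_json(c(stamp, anovas), file.path(cfg$out_dir, "anova.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- traits ------------------------------------------------------------
  traits <- NULL
  if (!is.null(items) && !is.null(bin_means_sf)) {
    traits <- stage("traits", {
      reliance <- reliance_on_detail(bin_means_sf)
      eff <- suppressWarnings(trait_effects(reliance, items))
      tt <- trait_table[order(trait_table$item_id), ]
      fit <- robust_regress(eff$effect, tt$log_diagnosticity)
      sa <- NULL
      if (!anyNA(eff$effect)) {
        sa <- subscale_anova(eff$effect, tt$subscale)
      } else {
        say("%d item(s) with all-or-none endorsement; subscale ANOVA skipped",
            sum(is.na(eff$effect)))
      }
      say("trait-effect ~ diagnosticity: slope = %.4g, t(%d) = %.3f, p = %.4g",
          fit$slope, fit$df, fit$t_stat, fit$p)
      list(effects = eff, robust_fit = unclass(fit), subscale_anova = sa)
    })
    jsonlite::write_json(c(stamp, traits),
                         file.path(cfg$out_dir, "traits.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  writeLines(c(sprintf("fdimap run (seed %d, config %s)", cfg$seed,
                       stamp$config_hash), log_lines),
             file.path(cfg$out_dir, "summary.txt"))
  invisible(list(banks = banks, trials = trials, simulation = sim, fdi = fdi,
                 replicability = rep_res, anovas = anovas, traits = traits,
                 stamp = stamp))
}
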
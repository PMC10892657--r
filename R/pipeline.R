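# Experiment orchestration: simulate a cohort, extract features, split,
# train the model variants and evaluate them, all derived from one master
# seed.

#' Configure an end-to-end experiment
#'
#' The default configuration is a smoke-scale multi-subject cohort suitable
#' for quick runs and continuous testing; the study-scale protocols are
#' available through [study_individual_config()] and [study_multi_config()].
#'
#' @param generator A [generator_config()] (counts, period, noise, coupling).
#' @param scope `"multi"` (6-input model, leave-subject-out split) or
#'   `"individual"` (3-input model, prefix/suffix set split; requires a
#'   single-subject generator).
#' @param variants Subset of `c("bp", "ga-bp", "ssa-bp")`.
#' @param smoothing_window Odd moving-average window applied to extracted
#'   angles (5 recommended for noisy data).
#' @param train_fraction Fraction of leading sets used for training in
#'   individual scope (0.8 reproduces the first-80/last-20 protocol).
#' @param test_subject Held-out subject id for multi scope (default: the
#'   last subject).
#' @param net A [train_config()] for the gradient refinement.
#' @param ga,ssa Metaheuristic configurations.
#' @param bounds Initial-weight search bounds.
#' @param max_train_frames Deterministic stride-subsampling cap on the number
#'   of training frames handed to the trainer and the fitness function (test
#'   frames are never subsampled).
#' @param mape_floor_deg Magnitude floor for the MAPE metric.
#' @param master_seed Master seed; every stage seed is derived from it with
#'   [derive_seed()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(n_subjects = 4L,
                                                           sets_per_subject = 6L,
                                                           keystrokes_per_set = 10L),
                              scope = c("multi", "individual"),
                              variants = c("bp", "ga-bp", "ssa-bp"),
                              smoothing_window = 5L,
                              train_fraction = 0.8,
                              test_subject = NULL,
                              net = train_config(max_epochs = 200L),
                              ga = ga_config(), ssa = ssa_config(),
                              bounds = c(-3, 3),
                              max_train_frames = 25000L,
                              mape_floor_deg = 1,
                              master_seed = 1L) {
  scope <- match.arg(scope)
  variants <- match.arg(variants, c("bp", "ga-bp", "ssa-bp"),
                        several.ok = TRUE)
  if (!length(variants)) arg_error("variants must be nonempty")
  if (scope == "individual" && generator$n_subjects != 1L) {
    arg_error("individual scope requires a single-subject generator")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    arg_error("train_fraction must lie in (0, 1)")
  }
  structure(
    list(generator = generator, scope = scope, variants = variants,
         smoothing_window = as.integer(smoothing_window),
         train_fraction = train_fraction, test_subject = test_subject,
         net = net, ga = ga, ssa = ssa, bounds = bounds,
         max_train_frames = as.integer(max_train_frames),
         mape_floor_deg = mape_floor_deg,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

#' Study-protocol experiment presets
#'
#' `study_individual_config()`: one subject, 100 sets of 25 keystrokes
#' (2500 cycles), 3-input model, first-80/last-20 set split, plain BP.
#' `study_multi_config()`: 12 subjects with 30 sets of 25 keystrokes each
#' (9000 cycles), 6-input model, leave-last-subject-out split.
#'
#' @param master_seed Master seed.
#' @param ... Overrides forwarded to [experiment_config()].
#' @return An `experiment_config`.
#' @export
study_individual_config <- function(master_seed = 1L, ...) {
  experiment_config(
    generator = generator_config(n_subjects = 1L, sets_per_subject = 100L,
                                 keystrokes_per_set = 25L),
    scope = "individual", variants = "bp", master_seed = master_seed, ...)
}

#' @rdname study_individual_config
#' @export
study_multi_config <- function(master_seed = 1L, ...) {
  experiment_config(
    generator = generator_config(),
    scope = "multi", master_seed = master_seed, ...)
}

#' Simulate a synthetic keystroke cohort
#'
#' Samples subject profiles from the study population and generates every
#' subject's keystroke sets. Per-subject generation seeds are derived from
#' `seed` and the subject id, so the cohort is reproducible and adding a
#' subject never perturbs the others.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param output_dir Optional directory: when given, writes one trajectory
#'   CSV per set plus a `cohort_manifest.json` with the profiles and the
#'   configuration.
#' @return A list with `subjects` (profile data.frame) and `sessions`
#'   (named list: per subject, a list of `hand_trajectory` sets).
#' @export
simulate_cohort <- function(config = generator_config(), seed = config$seed,
                            output_dir = NULL) {
  subjects <- sample_subjects(config$n_subjects,
                              seed = derive_seed(seed, "subjects"))
  sessions <- lapply(seq_len(nrow(subjects)), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(seed, paste0("session-", subjects$subject_id[i]))
    generate_session(subjects[i, , drop = FALSE], cfg_i)
  })
  names(sessions) <- subjects$subject_id
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir) &&
        !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)) {
      abort(paste0("cannot create output directory ", output_dir),
            "ringcast_io_error")
    }
    for (sid in names(sessions)) {
      for (traj in sessions[[sid]]) {
        write_trajectory(traj, file.path(output_dir,
                                         sprintf("%s_set%03d.csv", sid,
                                                 traj$set_index)))
      }
    }
    manifest <- list(subjects = subjects,
                     config = serializable_generator_config(config),
                     seed = seed)
    jsonlite::write_json(manifest,
                         file.path(output_dir, "cohort_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(subjects = subjects, sessions = sessions)
}

serializable_generator_config <- function(config) {
  out <- unclass(config)
  out$coupling <- unclass(out$coupling)
  out
}

# Extract + segment one subject's sets and build per-set feature tables.
subject_feature_sets <- function(sets, profile, scope, smoothing_window,
                                 cycle_period_s) {
  mode <- if (scope == "multi") "multi" else "individual"
  lapply(sets, function(traj) {
    series <- extract_angles(traj, smoothing_window)
    series <- segment_cycles(series, cycle_period_s)
    list(features = build_features(series, profile, mode),
         cycle_bounds = series$cycle_bounds)
  })
}

# rbind per-set feature tables, shifting cycle bounds to the concatenation.
bind_feature_sets <- function(set_list) {
  feats <- do.call(rbind, lapply(set_list, function(s) s$features))
  offset <- 0L
  bounds <- lapply(set_list, function(s) {
    b <- s$cycle_bounds + offset
    offset <<- offset + nrow(s$features)
    b
  })
  list(features = feats, cycle_bounds = do.call(rbind, bounds))
}

thin_rows <- function(df, max_rows) {
  n <- nrow(df)
  if (n <= max_rows) return(df)
  df[unique(round(seq(1L, n, length.out = max_rows))), , drop = FALSE]
}

#' Run a full simulated-keystroke modelling experiment
#'
#' Pipeline: simulate the cohort, extract and segment joint angles, build the
#' feature tables, split (per-set prefix/suffix for individual scope,
#' leave-subject-out for multi scope), fit every requested model variant with
#' [mcp_bpnn()], and evaluate predictions on the held-out frames. All stage
#' seeds derive from `config$master_seed`; passing several `fit_seeds`
#' re-fits each variant from different initialization seeds on the same
#' simulated cohort.
#'
#' @param config An [experiment_config()].
#' @param fit_seeds Optional integer vector of model-fitting seeds; default
#'   is the single master seed.
#' @return An object of class `keystroke_experiment`: list with `reports`
#'   (one `eval_report` per variant x seed), `table` (aggregate metrics
#'   data.frame with columns `model`, `seed`, `mae_deg`, `rmse_deg`,
#'   `mape_pct`), `fits` (fitted models), `n_cycles_total`, `n_train_frames`,
#'   `n_test_frames`, `subjects`, and `config`.
#' @export
run_experiment <- function(config = experiment_config(), fit_seeds = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  gen <- config$generator
  cohort <- simulate_cohort(gen, seed = derive_seed(config$master_seed,
                                                    "generate"))
  per_subject <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    subject_feature_sets(cohort$sessions[[i]],
                         cohort$subjects[i, , drop = FALSE],
                         config$scope, config$smoothing_window,
                         gen$cycle_period_s)
  })
  names(per_subject) <- cohort$subjects$subject_id
  n_cycles_total <- sum(vapply(per_subject, function(subj) {
    sum(vapply(subj, function(s) nrow(s$cycle_bounds), integer(1)))
  }, integer(1)))

  if (config$scope == "individual") {
    sets <- per_subject[[1L]]
    n_train <- floor(config$train_fraction * length(sets))
    sp <- split_per_set(sets, n_train)
    train_sets <- sp$train
    test_sets <- sp$test
    split_desc <- list(protocol = "per_set", n_train_sets = n_train,
                       n_test_sets = length(test_sets))
  } else {
    test_id <- if (is.null(config$test_subject)) {
      cohort$subjects$subject_id[nrow(cohort$subjects)]
    } else config$test_subject
    sp <- split_leave_subject_out(per_subject, test_id)
    train_sets <- do.call(c, unname(sp$train))
    test_sets <- do.call(c, unname(sp$test))
    split_desc <- list(protocol = "leave_subject_out", test_subject = test_id,
                       n_train_subjects = length(sp$train))
  }
  train_all <- bind_feature_sets(train_sets)
  test_all <- bind_feature_sets(test_sets)
  train_df <- thin_rows(train_all$features, config$max_train_frames)
  mode <- if (config$scope == "multi") "multi" else "individual"
  ff <- feature_formula(mode)

  seeds <- if (is.null(fit_seeds)) config$master_seed else fit_seeds
  fits <- list()
  reports <- list()
  rows <- list()
  for (s in seeds) {
    for (variant in config$variants) {
      fit_seed <- derive_seed(s, paste0("fit-", variant))
      fit <- mcp_bpnn(ff, train_df, variant = variant,
                      train = config$net, ga = config$ga, ssa = config$ssa,
                      bounds = config$bounds, seed = fit_seed)
      pred <- predict(fit, test_all$features)
      rep <- eval_report(pred, test_all$features$beta1_deg,
                         cycle_bounds = test_all$cycle_bounds,
                         model_variant = variant, scope = mode,
                         split_descriptor = split_desc, seed = fit_seed,
                         mape_floor_deg = config$mape_floor_deg)
      key <- if (length(seeds) > 1L) paste0(variant, "@", s) else variant
      fits[[key]] <- fit
      reports[[key]] <- rep
      rows[[key]] <- data.frame(model = variant, seed = s,
                                mae_deg = rep$mae_deg, rmse_deg = rep$rmse_deg,
                                mape_pct = rep$mape_pct,
                                stringsAsFactors = FALSE)
    }
  }
  structure(
    list(reports = reports,
         table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         fits = fits,
         n_cycles_total = n_cycles_total,
         n_train_frames = nrow(train_df),
         n_test_frames = nrow(test_all$features),
         subjects = cohort$subjects,
         config = config),
    class = "keystroke_experiment"
  )
}

#' @export
print.keystroke_experiment <- function(x, ...) {
  cat(sprintf("<keystroke_experiment> %s scope, %d cycles simulated, %d train / %d test frames\n",
              x$config$scope, x$n_cycles_total, x$n_train_frames,
              x$n_test_frames))
  print(x$table, row.names = FALSE)
  invisible(x)
}
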
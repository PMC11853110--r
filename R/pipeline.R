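#' Experiment configuration
#'
#' Collects every tunable of the pipeline in one serializable list with the
#' study defaults: a 60-subject cohort with the 2/15/19/24 shoe-size
#' histogram, three unloaded rounds plus one 500 g loaded round of 40 unit
#' steps each, Type I rounds 1-2 for training, the default unknown-subject
#' pattern for the open-set split, and the classifier/autoencoder training
#' schedule (learning rate 0.001, 50 epochs, batch 16, validation split
#' 0.1). Any field can be overridden by name.
#'
#' @param ... named overrides of the defaults.
#' @return object of class \code{gait_config}.
#' @export
gait_config <- function(...) {
  cfg <- list(
    n_subjects = 60,
    shoe_size_distribution = c("3" = 2, "4" = 15, "7" = 19, "10" = 24),
    identical_templates = FALSE,
    rounds_type1 = 3,
    rounds_type2 = 1,
    unit_steps_per_round = 40,
    load_g = 500,
    noise_sd = 2,
    anomaly_rate = 5e-5,
    z_threshold = 4,
    min_mass = 1000,
    roi_method = "components",
    train_rounds = c(1, 2),
    unknown_subjects = c(2, 4, 10, 11, 20, 24, 46, 50, 51, 55, 56, 57),
    augment = TRUE,
    conv_filters = c(32, 64, 128),
    learning_rate = 0.001,
    epochs = 50,
    batch_size = 16,
    validation_split = 0.1,
    ae_epochs = 30,
    ae_learning_rate = 0.001,
    ae_batch_size = 16,
    threshold = 0.85,
    seed = 1)
  mod <- list(...)
  bad <- setdiff(names(mod), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(mod)] <- mod
  structure(cfg, class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat(sprintf(
    "Experiment config [%s]: %d subjects, %d+%d rounds x %d unit steps, seed %d\n",
    config_hash(x), x$n_subjects, x$rounds_type1, x$rounds_type2,
    x$unit_steps_per_round, x$seed))
  invisible(x)
}

#' Short content hash of a configuration (polynomial rolling hash over its
#' serialization)
#' @param cfg a \code{gait_config}.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Subject attribute table
#' @param profiles list of \code{subject_profile}.
#' @return data.frame with subject_id, shoe_size_us, weight_kg, foot
#'   dimensions, step angle, stride and cadence.
#' @export
subjects_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    subject_id = p$subject_id, shoe_size_us = p$shoe_size_us,
    weight_kg = p$weight_kg, foot_len_cells = p$foot_len_cells,
    foot_width_cells = p$foot_width_cells,
    step_angle_deg = p$step_angle_deg, stride_cells = p$stride_cells,
    cadence_frames = p$cadence_frames)))
}

# Stream the whole cohort protocol walk-by-walk through preprocessing,
# keeping only the 32x32 maps (frames are discarded per walk). Seeds match
# schedule_cohort_trials(frames = TRUE) exactly.
simulate_cohort_maps <- function(cfg, profiles,
                                 geometry = mat_geometry(),
                                 progress = FALSE) {
  plan <- schedule_cohort_trials(
    profiles, cfg$rounds_type1, cfg$rounds_type2, cfg$unit_steps_per_round,
    geometry = geometry, seed = cfg$seed, frames = FALSE,
    load_g = cfg$load_g)
  by_id <- stats::setNames(profiles,
                           vapply(profiles, `[[`, 1, "subject_id"))
  maps <- vector("list", sum(plan$n_unit_steps))
  pos <- 0L
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    p <- by_id[[as.character(row$subject_id)]]
    cond <- walk_condition(if (row$condition == "II") cfg$load_g else 0)
    s <- simulate_walk(
      p, cond, n_steps = row$n_steps, geometry = geometry,
      noise_sd = cfg$noise_sd, anomaly_rate = cfg$anomaly_rate,
      seed = derive_seed(cfg$seed, row$subject_id, row$round_id, row$walk),
      trial_id = sprintf("S%03d_R%d_W%02d", row$subject_id, row$round_id,
                         row$walk),
      round_id = row$round_id)
    m <- preprocess_sequence(s, z_threshold = cfg$z_threshold,
                             min_mass = cfg$min_mass,
                             method = cfg$roi_method)
    if (length(m) != row$n_unit_steps)
      stop("preprocessing recovered ", length(m), " unit steps, expected ",
           row$n_unit_steps, " (", row$subject_id, "/", row$round_id, ")")
    maps[pos + seq_along(m)] <- m
    pos <- pos + length(m)
    if (progress && i %% 50 == 0)
      message("  simulated ", i, "/", nrow(plan), " walks")
  }
  # re-number cycles within (subject, round)
  tab <- map_table(maps)
  key <- paste(tab$subject_id, tab$round_id)
  cyc <- stats::ave(seq_along(maps), key, FUN = seq_along)
  for (i in seq_along(maps)) maps[[i]]$cycle_index <- cyc[i]
  maps
}

#' Run the closed-set identification experiment
#'
#' Simulates the cohort protocol, preprocesses every walk into average
#' bilateral pressure maps, trains the convolutional classifier on the
#' unloaded rounds 1-2 (with horizontal-flip augmentation), and evaluates
#' identification on the held-out unloaded round and on the loaded round
#' separately (macro-averaged precision/recall/F1, plus misclassification
#' attribution).
#'
#' @param config a \code{gait_config}.
#' @param progress print stage messages.
#' @return list with the config and its hash, the subject table, the
#'   fitted \code{gait_cnn}, per-condition metrics
#'   (\code{type1}, \code{type2}) and misclassification reports.
#' @export
run_closed_set <- function(config = gait_config(), progress = FALSE) {
  stopifnot(inherits(config, "gait_config"))
  profiles <- generate_cohort(config$n_subjects,
                              config$shoe_size_distribution,
                              seed = derive_seed(config$seed, 1L),
                              identical_templates = config$identical_templates)
  if (progress) message("simulating cohort ...")
  maps <- simulate_cohort_maps(config, profiles, progress = progress)
  ds <- build_datasets(maps, task = "closed",
                       train_rounds = config$train_rounds,
                       augment = config$augment)
  if (progress) message("training classifier on ", nrow(ds$train), " maps ...")
  model <- gait_cnn(ds$train$map, ds$train$subject_id,
                    conv_filters = config$conv_filters,
                    learning_rate = config$learning_rate,
                    epochs = config$epochs,
                    batch_size = config$batch_size,
                    validation_split = config$validation_split,
                    strata = ds$train$subject_id,
                    seed = derive_seed(config$seed, 2L))
  subj <- subjects_table(profiles)
  eval_cond <- function(te) {
    if (nrow(te) == 0) return(NULL)
    pred <- predict(model, te$map, type = "class")
    dec <- data.frame(true = te$subject_id, predicted = pred)
    c(macro_metrics(te$subject_id, pred)["accuracy"],
      macro_metrics(te$subject_id, pred)[c("precision", "recall", "f1")],
      list(decisions = dec,
           misclassification = misclassification_report(dec, subj)))
  }
  structure(list(
    task = "closed",
    config = config, config_hash = config_hash(config),
    subjects = subj,
    datasets = ds[c("counts", "train_rounds")],
    model = model,
    type1 = eval_cond(ds$test_type1),
    type2 = eval_cond(ds$test_type2)),
    class = "gait_run")
}

#' Run the open-set recognition experiment
#'
#' Splits the cohort into known (authorized) and unknown subjects, trains
#' the classifier on the knowns' unloaded rounds 1-2, compresses the
#' 256-dimensional embeddings to 64 dimensions with the autoencoder,
#' enrolls the knowns' training codes in the feature database, and scores
#' every test query (knowns' held-out rounds = genuine, unknowns =
#' impostor). Reports the full threshold sweep, EER, ROC AUC, and
#' accuracies at the EER threshold, separately for the unloaded and loaded
#' conditions.
#'
#' @inheritParams run_closed_set
#' @return list with config, subject table, models, enrollment database
#'   and per-condition results (\code{threshold_sweep}, \code{auc},
#'   \code{eer}, accuracies at the EER threshold and at the configured
#'   operating threshold).
#' @export
run_open_set <- function(config = gait_config(), progress = FALSE) {
  stopifnot(inherits(config, "gait_config"))
  profiles <- generate_cohort(config$n_subjects,
                              config$shoe_size_distribution,
                              seed = derive_seed(config$seed, 1L),
                              identical_templates = config$identical_templates)
  if (progress) message("simulating cohort ...")
  maps <- simulate_cohort_maps(config, profiles, progress = progress)
  ds <- build_datasets(maps, task = "open",
                       unknown_subjects = config$unknown_subjects,
                       train_rounds = config$train_rounds,
                       augment = config$augment)
  if (progress) message("training classifier on ", nrow(ds$train), " maps ...")
  model <- gait_cnn(ds$train$map, ds$train$subject_id,
                    conv_filters = config$conv_filters,
                    learning_rate = config$learning_rate,
                    epochs = config$epochs,
                    batch_size = config$batch_size,
                    validation_split = config$validation_split,
                    strata = ds$train$subject_id,
                    seed = derive_seed(config$seed, 2L))
  if (progress) message("training autoencoder ...")
  emb_train <- extract_embeddings(model, ds$train$map)
  ae <- gait_ae(emb_train, learning_rate = config$ae_learning_rate,
                epochs = config$ae_epochs,
                batch_size = config$ae_batch_size,
                seed = derive_seed(config$seed, 3L))

  enroll_rows <- ds$train[!ds$train$augmented, , drop = FALSE]
  codes_enroll <- encode(ae, extract_embeddings(model, enroll_rows$map))
  db <- enroll(feature_db(), codes_enroll, enroll_rows$subject_id)

  eval_cond <- function(te) {
    if (nrow(te) == 0) return(NULL)
    codes <- encode(ae, extract_embeddings(model, te$map))
    sq <- score_queries(db, codes)
    known <- !(te$subject_id %in% config$unknown_subjects)
    genuine <- sq$best_similarity[known]
    impostor <- sq$best_similarity[!known]
    correct <- (sq$best_subject == te$subject_id)[known]
    sw <- sweep_thresholds(genuine, impostor, genuine_correct = correct)
    list(sweep = sw, eer = sw$eer, eer_threshold = sw$eer_threshold,
         auc = roc_auc(genuine, impostor),
         at_eer = threshold_metrics(genuine, impostor, sw$eer_threshold,
                                    genuine_correct = correct),
         at_threshold = threshold_metrics(genuine, impostor,
                                          config$threshold,
                                          genuine_correct = correct),
         n_genuine = length(genuine), n_impostor = length(impostor))
  }
  structure(list(
    task = "open",
    config = config, config_hash = config_hash(config),
    subjects = subjects_table(profiles),
    datasets = ds[c("counts", "train_rounds")],
    unknown_subjects = config$unknown_subjects,
    model = model, autoencoder = ae, database = db,
    type1 = eval_cond(ds$test_type1),
    type2 = eval_cond(ds$test_type2)),
    class = "gait_run")
}

#' @export
print.gait_run <- function(x, ...) {
  cat(sprintf("Gait recognition run [%s]: %s-set, %d subjects\n",
              x$config_hash, x$task, x$config$n_subjects))
  fmt <- function(v) sprintf("%.3f%%", 100 * v)
  for (cond in c("type1", "type2")) {
    r <- x[[cond]]
    if (is.null(r)) next
    lab <- if (cond == "type1") "Type I (no load)" else "Type II (500 g)"
    if (x$task == "closed") {
      cat(sprintf("  %s: accuracy %s, precision %s, recall %s, F1 %s\n",
                  lab, fmt(r$accuracy), fmt(r$precision), fmt(r$recall),
                  fmt(r$f1)))
    } else {
      cat(sprintf(
        "  %s: EER %s at threshold %.4f, AUC %.4f, overall accuracy %s\n",
        lab, fmt(r$eer), r$eer_threshold, r$auc,
        fmt(r$at_eer$acc_overall)))
    }
  }
  invisible(x)
}
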
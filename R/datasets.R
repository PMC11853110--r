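#' Unit-step table from a schedule plan or preprocessed maps
#'
#' Normalizes either a schedule plan (from
#' \code{schedule_cohort_trials(frames = FALSE)}) or a list of
#' \code{pressure_map} into one row per unit step with columns
#' \code{subject_id}, \code{condition}, \code{round_id}, \code{cycle_index}
#' and, for maps, a \code{map} list-column.
#'
#' @param x schedule plan data.frame or list of \code{pressure_map}.
#' @return data.frame, one row per unit step.
#' @export
unit_step_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subject_id", "condition", "round_id",
                    "n_unit_steps") %in% names(x)))
    out <- x[rep(seq_len(nrow(x)), x$n_unit_steps),
             c("subject_id", "condition", "round_id")]
    rownames(out) <- NULL
    out$cycle_index <- stats::ave(out$subject_id,
                                  out$subject_id, out$round_id,
                                  FUN = seq_along)
    out$augmented <- FALSE
    out
  } else {
    tab <- map_table(x)
    tab$map <- x
    tab
  }
}

#' Partition unit steps into training and testing sets
#'
#' Implements the study's two protocols. Closed-set: unloaded (Type I)
#' rounds 1-2 of every subject train the classifier; Type I round 3 and the
#' loaded (Type II) round are held out for testing. Open-set: only the
#' known (authorized) subjects' Type I rounds 1-2 are used for training;
#' everything else -- known subjects' remaining rounds and all rounds of
#' the unknown subjects -- is test data.
#'
#' @param steps unit-step table (see \code{\link{unit_step_table}}), a
#'   schedule plan, or a list of \code{pressure_map}.
#' @param task \code{"closed"} or \code{"open"}.
#' @param unknown_subjects subject ids held out as unauthorized
#'   (open-set task only).
#' @param train_rounds Type I rounds used for training (default 1:2).
#' @param test_rounds_type1 optionally name the Type I rounds expected in
#'   the test partition; an overlap with \code{train_rounds} is rejected.
#' @param augment if \code{TRUE} and maps are present, append horizontally
#'   flipped copies of the training maps (training partition only).
#' @return object of class \code{gait_datasets}: list with \code{train} and
#'   \code{test} data.frames (test additionally split as \code{test_type1} /
#'   \code{test_type2}), the task, and unit-step counts (pre-augmentation).
#' @export
build_datasets <- function(steps, task = c("closed", "open"),
                           unknown_subjects = NULL, train_rounds = c(1, 2),
                           test_rounds_type1 = NULL, augment = FALSE) {
  task <- match.arg(task)
  if (!is.data.frame(steps)) steps <- unit_step_table(steps)
  else if ("n_unit_steps" %in% names(steps)) steps <- unit_step_table(steps)
  stopifnot(all(c("subject_id", "condition", "round_id") %in% names(steps)))
  if (!is.null(test_rounds_type1) &&
      length(intersect(test_rounds_type1, train_rounds)) > 0)
    stop("overlapping train/test assignment: round(s) ",
         paste(intersect(test_rounds_type1, train_rounds), collapse = ", "),
         " named for both roles")
  in_train_block <- steps$condition == "I" & steps$round_id %in% train_rounds

  if (task == "closed") {
    train <- in_train_block
  } else {
    if (is.null(unknown_subjects))
      stop("open-set task requires unknown_subjects")
    known <- !(steps$subject_id %in% unknown_subjects)
    train <- in_train_block & known
  }
  test <- !train
  if (any(train & test)) stop("overlapping train/test assignment")

  tr <- steps[train, , drop = FALSE]
  te <- steps[test, , drop = FALSE]
  counts <- list(train = nrow(tr), test = nrow(te), total = nrow(steps))

  if (augment && "map" %in% names(tr) && nrow(tr) > 0) {
    aug <- augment_flip(tr$map)[-seq_len(nrow(tr))]
    extra <- tr
    extra$map <- aug
    extra$augmented <- TRUE
    tr <- rbind(tr, extra)
  }
  structure(list(
    train = tr, test = te,
    test_type1 = te[te$condition == "I", , drop = FALSE],
    test_type2 = te[te$condition == "II", , drop = FALSE],
    task = task,
    unknown_subjects = unknown_subjects,
    train_rounds = train_rounds,
    counts = counts), class = "gait_datasets")
}

#' @export
print.gait_datasets <- function(x, ...) {
  cat(sprintf(
    "%s-set partition: %d training / %d testing unit steps (of %d)\n",
    x$task, x$counts$train, x$counts$test, x$counts$total))
  if (!is.null(x$unknown_subjects))
    cat("  unknown subjects:", paste(x$unknown_subjects, collapse = ", "),
        "\n")
  invisible(x)
}
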
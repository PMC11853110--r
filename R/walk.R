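#' Walking condition (carried load)
#'
#' Describes the carried-load condition of a trial. With no load the
#' footprint templates are used as-is; with a load the center of pressure is
#' shifted forward by a whole number of cells and pressure magnitude is
#' scaled up.
#'
#' @param load_g carried mass in grams (0 = unloaded "Type I" trials,
#'   500 = loaded "Type II" trials).
#' @param load_cop_shift_cells center-of-pressure shift along the walking
#'   direction, in cells; defaults to 0 without load, 2 with load.
#' @param load_scale pressure magnitude multiplier; defaults to 1 without
#'   load, 1.06 with load.
#' @return object of class \code{walk_condition}.
#' @export
walk_condition <- function(load_g = 0,
                           load_cop_shift_cells = NULL,
                           load_scale = NULL) {
  stopifnot(load_g >= 0)
  if (load_g == 0) {
    if (!is.null(load_cop_shift_cells) && load_cop_shift_cells != 0)
      stop("load_g = 0 implies zero center-of-pressure shift")
    if (!is.null(load_scale) && load_scale != 1)
      stop("load_g = 0 implies unit load scale")
    load_cop_shift_cells <- 0L
    load_scale <- 1
  } else {
    if (is.null(load_cop_shift_cells)) load_cop_shift_cells <- 2L
    if (is.null(load_scale)) load_scale <- 1.06
  }
  structure(list(load_g = load_g,
                 load_cop_shift_cells = as.integer(load_cop_shift_cells),
                 load_scale = load_scale,
                 type = if (load_g > 0) "II" else "I"),
            class = "walk_condition")
}

#' Simulate one walk across the pressure mat
#'
#' Renders a time-ordered stack of 8-bit pressure frames for one traversal:
#' alternating left/right foot contacts along the mat, each contact active
#' for ~60% of its gait cycle (stance) with a heel-to-forefoot intensity
#' crossfade, consecutive contacts overlapping in double support. Gaussian
#' sensor noise is added on active cells and isolated single-cell
#' full-scale spikes can be injected to exercise anomaly replacement.
#'
#' @param profile a \code{subject_profile}.
#' @param condition a \code{walk_condition}.
#' @param n_steps number of foot contacts (>= 1); all must fit on the mat.
#' @param geometry a \code{mat_geometry}.
#' @param noise_sd sd of additive integer-rounded Gaussian noise on active
#'   cells (8-bit units).
#' @param anomaly_rate per cell-frame probability of an isolated 255 spike.
#' @param seed integer seed; output is a deterministic function of it.
#' @param start_side side of the first contact, \code{"left"} or
#'   \code{"right"}.
#' @param trial_id,round_id metadata carried through to downstream tables.
#' @return object of class \code{pressure_seq}: a list with \code{frames}
#'   (integer array T x rows x cols, values 0..255), trial metadata, and a
#'   \code{truth} data.frame of scheduled contacts (step, side, onset frame,
#'   window position) usable as ground truth in tests.
#' @examples
#' p <- generate_cohort(1, c("7" = 1), seed = 2)[[1]]
#' s <- simulate_walk(p, walk_condition(0), n_steps = 3, seed = 5)
#' dim(s$frames)
#' @export
simulate_walk <- function(profile, condition = walk_condition(), n_steps,
                          geometry = mat_geometry(), noise_sd = 2,
                          anomaly_rate = 0, seed = 1,
                          start_side = "left",
                          trial_id = NA_character_, round_id = NA_integer_) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(condition, "walk_condition"),
            n_steps >= 1, noise_sd >= 0,
            anomaly_rate >= 0, anomaly_rate < 1)
  win_rows <- 32L; win_cols <- 16L
  row0 <- 5L                               # first window origin (margin)
  stride <- profile$stride_cells
  rows <- geometry$rows; cols <- geometry$cols

  win_r <- row0 + (seq_len(n_steps) - 1L) * stride
  if (any(win_r + win_rows - 1L > rows))
    stop("footprint exceeds mat bounds: ", n_steps, " steps of stride ",
         stride, " do not fit on ", rows, " rows")

  # lateral lanes: left foot on the left half-width, right on the right
  lane_left <- 3L; lane_right <- cols - win_cols - 2L  # window origin cols
  sides <- rep(if (start_side == "left") c("left", "right")
               else c("right", "left"), length.out = n_steps)

  half_cycle <- max(2L, as.integer(round(profile$cadence_frames / 2)))
  stance <- max(2L, as.integer(round(0.6 * profile$cadence_frames)))
  lead_in <- 8L                            # subject approaches off-mat
  onsets <- lead_in + 1L + (seq_len(n_steps) - 1L) * half_cycle
  n_frames <- onsets[n_steps] + stance + 7L

  sig <- array(0, dim = c(n_frames, rows, cols))
  cop_shift <- condition$load_cop_shift_cells
  for (k in seq_len(n_steps)) {
    lob <- if (sides[k] == "left") profile$lobes_left else profile$lobes_right
    heel <- lob$heel * condition$load_scale
    fore <- lob$fore * condition$load_scale
    r0 <- win_r[k] + cop_shift
    if (r0 + win_rows - 1L > rows || r0 < 1L)
      stop("footprint exceeds mat bounds under load shift")
    c0 <- if (sides[k] == "left") lane_left else lane_right
    rr <- r0:(r0 + win_rows - 1L)
    cc <- c0:(c0 + win_cols - 1L)
    for (t in 0:(stance - 1L)) {
      u <- t / (stance - 1)
      sig[onsets[k] + t, rr, cc] <- sig[onsets[k] + t, rr, cc] +
        (1 - u) * heel + u * fore
    }
  }

  with_local_seed(seed, {
    if (noise_sd > 0) {
      idx <- which(sig > 0)
      sig[idx] <- sig[idx] + round(rnorm(length(idx), 0, noise_sd))
    }
    frames <- round(sig)
    if (anomaly_rate > 0) {
      n_cells <- rows * cols
      # frame 1 stays silent: an all-zero frame precedes the first contact
      for (t in 2:n_frames) {
        n_sp <- rbinom(1, n_cells, anomaly_rate)
        if (n_sp == 0) next
        pos <- sample.int(n_cells, n_sp)
        pr <- ((pos - 1L) %% rows) + 1L
        pc <- ((pos - 1L) %/% rows) + 1L
        keep <- rep(TRUE, n_sp)            # enforce spatial isolation
        if (n_sp > 1) {
          for (i in 2:n_sp)
            if (any(abs(pr[i] - pr[1:(i - 1)]) <= 1 &
                    abs(pc[i] - pc[1:(i - 1)]) <= 1)) keep[i] <- FALSE
        }
        frames[cbind(t, pr[keep], pc[keep])] <- 255
      }
    }
    frames[frames < 0] <- 0
    frames[frames > 255] <- 255
    storage.mode(frames) <- "integer"

    truth <- data.frame(step = seq_len(n_steps), side = sides,
                        onset_frame = onsets,
                        window_row = win_r + cop_shift,
                        window_col = ifelse(sides == "left",
                                            lane_left, lane_right),
                        stance_frames = stance)
    structure(list(frames = frames,
                   subject_id = profile$subject_id,
                   trial_id = trial_id,
                   condition = condition$type,
                   load_g = condition$load_g,
                   round_id = round_id,
                   geometry = geometry,
                   truth = truth),
              class = "pressure_seq")
  })
}

#' @export
print.pressure_seq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Pressure sequence: subject %s, trial %s, Type %s round %s\n  %d frames of %d x %d, %d contact(s)\n",
    format(x$subject_id), format(x$trial_id), x$condition,
    format(x$round_id), d[1], d[2], d[3], nrow(x$truth)))
  invisible(x)
}

#' Schedule the full cohort trial protocol
#'
#' Emits, for every subject, \code{rounds_type1} unloaded rounds and
#' \code{rounds_type2} loaded rounds, each sized to yield exactly
#' \code{unit_steps_per_round} unit steps (average pressure maps) after
#' preprocessing. Since a walk of N contacts yields N-1 maps, each round is
#' assembled from several mat traversals whose (N-1)-counts sum to the
#' target.
#'
#' @param profiles list of \code{subject_profile}.
#' @param rounds_type1,rounds_type2 number of unloaded / loaded rounds.
#' @param unit_steps_per_round unit steps each round must yield.
#' @param geometry a \code{mat_geometry}.
#' @param noise_sd,anomaly_rate passed to \code{\link{simulate_walk}}.
#' @param seed master seed; per-walk seeds are derived deterministically.
#' @param frames if \code{TRUE} return the simulated \code{pressure_seq}
#'   list; if \code{FALSE} return only the schedule (one row per walk) with
#'   unit-step accounting, without rasterizing any frames.
#' @param load_g carried mass for the loaded rounds (grams).
#' @return list of \code{pressure_seq} (frames = TRUE) or a data.frame plan
#'   with columns subject_id, condition, round_id, walk, n_steps,
#'   n_unit_steps (frames = FALSE).
#' @export
schedule_cohort_trials <- function(profiles, rounds_type1 = 3,
                                   rounds_type2 = 1,
                                   unit_steps_per_round = 40,
                                   geometry = mat_geometry(),
                                   noise_sd = 2, anomaly_rate = 0,
                                   seed = 1, frames = TRUE, load_g = 500) {
  stopifnot(rounds_type1 >= 0, rounds_type2 >= 0, unit_steps_per_round >= 1)
  plan <- list(); seqs <- list()
  n_rounds <- rounds_type1 + rounds_type2
  # room for the loaded rounds' forward center-of-pressure shift
  shift_margin <- if (rounds_type2 > 0)
    walk_condition(load_g)$load_cop_shift_cells else 0L
  for (p in profiles) {
    max_steps <- (geometry$rows - 31L - 5L - shift_margin) %/%
      p$stride_cells + 1L
    if (max_steps < 2) stop("stride too long: no complete gait cycle fits")
    mpw <- max_steps - 1L                  # maps (unit steps) per full walk
    n_full <- unit_steps_per_round %/% mpw
    rem <- unit_steps_per_round %% mpw
    steps_per_walk <- c(rep(max_steps, n_full), if (rem > 0) rem + 1L)
    for (r in seq_len(n_rounds)) {
      type2 <- r > rounds_type1
      cond <- walk_condition(if (type2) load_g else 0)
      for (w in seq_along(steps_per_walk)) {
        plan[[length(plan) + 1L]] <- data.frame(
          subject_id = p$subject_id,
          condition = cond$type,
          round_id = r,
          walk = w,
          n_steps = steps_per_walk[w],
          n_unit_steps = steps_per_walk[w] - 1L)
        if (frames) {
          s <- simulate_walk(
            p, cond, n_steps = steps_per_walk[w], geometry = geometry,
            noise_sd = noise_sd, anomaly_rate = anomaly_rate,
            seed = derive_seed(seed, p$subject_id, r, w),
            trial_id = sprintf("S%03d_R%d_W%02d", p$subject_id, r, w),
            round_id = r)
          seqs[[length(seqs) + 1L]] <- s
        }
      }
    }
  }
  plan <- do.call(rbind, plan)
  if (frames) {
    attr(seqs, "plan") <- plan
    seqs
  } else plan
}
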
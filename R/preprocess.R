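#' Replace anomalous sensor readings
#'
#' Screens every frame for cells whose value sits far above the local
#' neighborhood distribution (isolated sensor spikes) and replaces them by
#' the mean of their unflagged 8-neighborhood. A cell is flagged when
#' \code{value > mean8 + z_threshold * max(sd8, 1)}, with mean/sd taken over
#' its available 8-neighborhood (population convention); the 1-count floor
#' on the sd keeps flat neighborhoods from flagging benign cells while still
#' catching full-scale spikes on a silent background.
#'
#' @param seq a \code{pressure_seq}.
#' @param z_threshold positive z-score cut-off (default 4).
#' @return the sequence with anomalous cells replaced (still 8-bit).
#' @export
replace_anomalies <- function(seq, z_threshold = 4) {
  stopifnot(inherits(seq, "pressure_seq"), z_threshold > 0)
  frames <- seq$frames
  for (t in seq_len(dim(frames)[1])) {
    m <- frames[t, , ]
    if (!any(m > 0)) next
    frames[t, , ] <- replace_anomalies_frame(m, z_threshold)
  }
  seq$frames <- frames
  seq
}

# 8-neighborhood sums via zero-padded shifts: list(s, s2, n) matrices.
neighbor_stats <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  padn <- pad
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  pad2 <- pad^2
  padn[2:(nr + 1), 2:(nc + 1)] <- 1
  s <- s2 <- n <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- (2 + dr):(nr + 1 + dr); cc <- (2 + dc):(nc + 1 + dc)
    s <- s + pad[rr, cc]
    s2 <- s2 + pad2[rr, cc]
    n <- n + padn[rr, cc]
  }
  list(s = s, s2 = s2, n = n)
}

replace_anomalies_frame <- function(m, z_threshold) {
  ns <- neighbor_stats(m)
  mu <- ns$s / ns$n
  v <- pmax(ns$s2 / ns$n - mu^2, 0)
  sd8 <- sqrt(v)
  flag <- m > mu + z_threshold * pmax(sd8, 1)
  if (!any(flag)) return(m)
  keep <- !flag
  nsk <- neighbor_stats(m * keep)
  nk <- neighbor_stats(keep + 0)$s  # count of unflagged neighbors
  repl <- ifelse(nk > 0, nsk$s / nk, mu)
  m[flag] <- as.integer(round(repl[flag]))
  m
}

#' Aggregate a traversal into a single pressure map
#'
#' Cellwise sum of all frames of one traversal, in double precision (no
#' 8-bit clipping), used to localize footprints.
#'
#' @param seq a \code{pressure_seq} with at least one frame.
#' @return rows x cols numeric matrix.
#' @export
accumulate_pressure <- function(seq) {
  stopifnot(inherits(seq, "pressure_seq"))
  if (dim(seq$frames)[1] < 1) stop("empty sequence")
  colSums(seq$frames * 1.0, dims = 1)
}

#' Extract footprint regions of interest
#'
#' Segments the summed pressure map into individual foot contacts and fits a
#' 32 x 16 window around each. Two localization strategies are available:
#' connected-component labeling on the active mask (default), or a
#' mask-correlation search that repeatedly takes the 32 x 16 window with the
#' largest summed pressure. Each ROI records its window position, the
#' active-cell coordinates, the foot side (by lateral position relative to
#' the mat midline), and the onset/offset frames (first/last frame with
#' nonzero pressure inside the window).
#'
#' @param summed map from \code{\link{accumulate_pressure}} of \code{seq}.
#' @param seq the matching \code{pressure_seq}.
#' @param min_mass minimum summed pressure for a region to count as a foot
#'   contact (filters residual specks).
#' @param method \code{"components"} or \code{"mask"}.
#' @param active_floor cells are considered active above this fraction of
#'   the summed map's maximum; suppresses faint single-frame residues left
#'   by anomaly replacement at footprint borders.
#' @return list of \code{footprint_roi}, sorted by onset frame.
#' @export
extract_rois <- function(summed, seq, min_mass = 1000,
                         method = c("components", "mask"),
                         active_floor = 0.02) {
  stopifnot(inherits(seq, "pressure_seq"))
  method <- match.arg(method)
  rows <- nrow(summed); cols <- ncol(summed)
  win_r <- 32L; win_c <- 16L
  if (max(summed) <= 0) return(list())
  active <- summed > active_floor * max(summed)

  windows <- list()
  if (method == "components") {
    lab <- EBImage::bwlabel(active)
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      mass <- sum(summed[idx])
      if (mass < min_mass) next
      rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
      cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
      if (rmax - rmin + 1 > win_r || cmax - cmin + 1 > win_c)
        stop("footprint larger than the 32 x 16 mask (",
             rmax - rmin + 1, " x ", cmax - cmin + 1, ")")
      w <- summed[idx]
      crm <- sum(idx[, 1] * w) / mass
      ccm <- sum(idx[, 2] * w) / mass
      # symmetric centering: mirroring the mat mirrors the window exactly
      wr <- clamp(round(crm - (win_r - 1) / 2), max(1, rmax - win_r + 1),
                  min(rmin, rows - win_r + 1))
      wc <- clamp(round(ccm - (win_c - 1) / 2), max(1, cmax - win_c + 1),
                  min(cmin, cols - win_c + 1))
      windows[[length(windows) + 1L]] <-
        list(row = wr, col = wc, cells = idx, mass = mass,
             centroid = c(crm, ccm))
    }
  } else {
    work <- summed
    repeat {
      ws <- window_sums(work, win_r, win_c)
      best <- which.max(ws)
      if (length(best) == 0 || ws[best] < min_mass) break
      wr <- ((best - 1) %% nrow(ws)) + 1
      wc <- ((best - 1) %/% nrow(ws)) + 1
      rr <- wr:(wr + win_r - 1); cc <- wc:(wc + win_c - 1)
      sub <- work[rr, cc]
      idx <- which(sub > active_floor * max(summed), arr.ind = TRUE)
      idx[, 1] <- idx[, 1] + wr - 1
      idx[, 2] <- idx[, 2] + wc - 1
      w <- summed[idx]
      mass <- sum(w)
      windows[[length(windows) + 1L]] <-
        list(row = wr, col = wc, cells = idx, mass = mass,
             centroid = c(sum(idx[, 1] * w) / mass,
                          sum(idx[, 2] * w) / mass))
      work[rr, cc] <- 0
      if (length(windows) > 64) break
    }
  }
  if (length(windows) == 0) return(list())

  nT <- dim(seq$frames)[1]
  fm <- matrix(seq$frames, nrow = nT)  # T x (rows*cols), cell-major cols
  rois <- lapply(windows, function(wn) {
    cellcol <- (wn$cells[, 2] - 1L) * rows + wn$cells[, 1]
    energy <- rowSums(fm[, cellcol, drop = FALSE])
    on <- which(energy > 0)
    structure(list(row = wn$row, col = wn$col,
                   side = if (wn$centroid[2] <= cols / 2) "left" else "right",
                   onset_frame = on[1], offset_frame = on[length(on)],
                   mass = wn$mass, centroid = wn$centroid,
                   cells = wn$cells),
              class = "footprint_roi")
  })
  rois[order(vapply(rois, `[[`, 1, "onset_frame"))]
}

clamp <- function(x, lo, hi) min(max(x, lo), hi)

# sliding window sums via an integral image (zero row/col prepended)
window_sums <- function(m, wr, wc) {
  I <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  I[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  nr <- nrow(m) - wr + 1; nc <- ncol(m) - wc + 1
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc))
    out[, j] <- I[(wr + 1):(nrow(m) + 1), j + wc] - I[1:nr, j + wc] -
      I[(wr + 1):(nrow(m) + 1), j] + I[1:nr, j]
  out
}

#' @export
print.footprint_roi <- function(x, ...) {
  cat(sprintf("Footprint ROI: %s foot, window (%d, %d), frames %d-%d, mass %.0f\n",
              x$side, x$row, x$col, x$onset_frame, x$offset_frame, x$mass))
  invisible(x)
}

#' Derive gait cycles from ordered foot contacts
#'
#' A gait cycle (stride) runs from one contact's onset to the next onset of
#' that same foot, i.e. two contacts later. N contacts yield N-1 cycles;
#' the last cycle, lacking a closing onset, is capped at the final frame
#' with nonzero pressure.
#'
#' @param rois list of \code{footprint_roi} sorted by onset frame.
#' @return list of \code{gait_cycle} (empty if fewer than 2 contacts).
#' @export
detect_gait_cycles <- function(rois) {
  n <- length(rois)
  if (n < 2) return(list())
  onsets <- vapply(rois, `[[`, 1, "onset_frame")
  if (is.unsorted(onsets)) stop("ROIs must be sorted by onset frame")
  last <- max(vapply(rois, `[[`, 1, "offset_frame"))
  lapply(seq_len(n - 1), function(i) {
    start <- onsets[i]
    end <- if (i + 2 <= n) onsets[i + 2] else last + 1  # exclusive
    dur <- end - start
    if (dur < 1) stop("zero-duration gait cycle at step ", i)
    structure(list(index = i, start_frame = start, end_frame = end,
                   duration_frames = dur,
                   rois = rois[c(i, i + 1)]),
              class = "gait_cycle")
  })
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("Gait cycle %d: frames [%d, %d), %d frames, feet %s+%s\n",
              x$index, x$start_frame, x$end_frame, x$duration_frames,
              x$rois[[1]]$side, x$rois[[2]]$side))
  invisible(x)
}

#' Average bilateral pressure map for one gait cycle
#'
#' Sums the pressure inside each participating foot's 32 x 16 window over
#' the cycle's frames, divides by the cycle duration, and places the left
#' foot in columns 1-16 and the right foot in columns 17-32 of a 32 x 32
#' image.
#'
#' @param seq the \code{pressure_seq}.
#' @param cycle a \code{gait_cycle} within the sequence.
#' @return object of class \code{pressure_map}: list with \code{grid}
#'   (32 x 32 non-negative matrix), subject/condition/round metadata,
#'   \code{cycle_index} and \code{augmented = FALSE}.
#' @export
compute_average_map <- function(seq, cycle) {
  stopifnot(inherits(seq, "pressure_seq"), inherits(cycle, "gait_cycle"))
  nT <- dim(seq$frames)[1]
  if (cycle$duration_frames < 1) stop("zero-duration cycle")
  tt <- cycle$start_frame:min(cycle$end_frame - 1, nT)
  grid <- matrix(0, 32, 32)
  sides <- vapply(cycle$rois, `[[`, "", "side")
  if (sides[1] == sides[2]) {
    warning("both cycle feet on the same side; placing by onset order")
    sides <- c("left", "right")
  }
  for (k in 1:2) {
    roi <- cycle$rois[[k]]
    rr <- roi$row:(roi$row + 31L)
    cc <- roi$col:(roi$col + 15L)
    win <- seq$frames[tt, rr, cc, drop = FALSE] * 1.0
    avg <- colSums(win, dims = 1) / cycle$duration_frames
    if (sides[k] == "left") grid[, 1:16] <- grid[, 1:16] + avg
    else grid[, 17:32] <- grid[, 17:32] + avg
  }
  structure(list(grid = grid,
                 subject_id = seq$subject_id,
                 condition = seq$condition,
                 round_id = seq$round_id,
                 trial_id = seq$trial_id,
                 cycle_index = cycle$index,
                 augmented = FALSE),
            class = "pressure_map")
}

#' @export
print.pressure_map <- function(x, ...) {
  cat(sprintf(
    "Average pressure map: subject %s, Type %s round %s, cycle %s%s; peak %.1f\n",
    format(x$subject_id), x$condition, format(x$round_id),
    format(x$cycle_index), if (x$augmented) " (flipped)" else "",
    max(x$grid)))
  invisible(x)
}

#' Full preprocessing of one frame sequence
#'
#' Anomaly replacement, traversal aggregation, ROI extraction, gait-cycle
#' detection and per-cycle averaging, in order. A walk of N contacts yields
#' N-1 average pressure maps.
#'
#' @inheritParams replace_anomalies
#' @inheritParams extract_rois
#' @return list of \code{pressure_map}.
#' @examples
#' p <- generate_cohort(1, c("7" = 1), seed = 2)[[1]]
#' s <- simulate_walk(p, n_steps = 3, seed = 5)
#' length(preprocess_sequence(s))  # 2
#' @export
preprocess_sequence <- function(seq, z_threshold = 4, min_mass = 1000,
                                method = c("components", "mask")) {
  seq <- replace_anomalies(seq, z_threshold)
  summed <- accumulate_pressure(seq)
  rois <- extract_rois(summed, seq, min_mass = min_mass, method = method)
  cycles <- detect_gait_cycles(rois)
  lapply(cycles, function(cy) compute_average_map(seq, cy))
}

#' Horizontal flip augmentation
#'
#' Returns the input maps followed by horizontally mirrored copies flagged
#' as augmented (left/right halves swap and each half mirrors). Intended
#' for training partitions only.
#'
#' @param maps list of \code{pressure_map}.
#' @return list of length \code{2 * length(maps)}.
#' @export
augment_flip <- function(maps) {
  flipped <- lapply(maps, function(m) {
    m$grid <- m$grid[, ncol(m$grid):1, drop = FALSE]
    m$augmented <- TRUE
    m
  })
  c(maps, flipped)
}

#' Stack pressure maps into an array
#' @param maps list of \code{pressure_map}.
#' @return numeric array n x 32 x 32.
#' @export
maps_to_array <- function(maps) {
  n <- length(maps)
  a <- array(0, dim = c(n, 32, 32))
  for (i in seq_len(n)) a[i, , ] <- maps[[i]]$grid
  a
}

#' Label table for a list of pressure maps
#' @param maps list of \code{pressure_map}.
#' @return data.frame with subject_id, condition, round_id, cycle_index,
#'   augmented, and the map index.
#' @export
map_table <- function(maps) {
  data.frame(
    idx = seq_along(maps),
    subject_id = vapply(maps, `[[`, 1, "subject_id"),
    condition = vapply(maps, `[[`, "", "condition"),
    round_id = vapply(maps, `[[`, 1, "round_id"),
    cycle_index = vapply(maps, `[[`, 1, "cycle_index"),
    augmented = vapply(maps, `[[`, TRUE, "augmented"))
}
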
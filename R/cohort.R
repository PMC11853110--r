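#' Generate a synthetic walking cohort
#'
#' Draws per-subject gait profiles with the statistical structure the
#' recognition pipeline assumes: footprint size tied to one of four discrete
#' shoe sizes, body weight scaling peak plantar pressure, a per-foot outward
#' step angle, stride length, cadence, and a bimodal (heel + forefoot)
#' pressure-intensity template per foot.
#'
#' Subjects are mutually distinct in their templates unless
#' \code{identical_templates = TRUE}, which clones one parameter set across
#' the whole cohort (a negative control: no identity signal beyond noise).
#'
#' @param n_subjects number of subjects.
#' @param shoe_size_distribution named integer vector mapping US shoe size to
#'   subject count; must sum to \code{n_subjects}. The default reproduces the
#'   study cohort histogram (2/15/19/24 across sizes 3/4/7/10) when
#'   \code{n_subjects = 60}.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @param identical_templates clone one template across all subjects.
#' @return list of \code{subject_profile} objects.
#' @examples
#' cohort <- generate_cohort(6, c("4" = 3, "7" = 3), seed = 1)
#' cohort[[1]]
#' @export
generate_cohort <- function(n_subjects,
                            shoe_size_distribution = c("3" = 2, "4" = 15,
                                                       "7" = 19, "10" = 24),
                            seed = 1,
                            identical_templates = FALSE) {
  if (n_subjects == 0) {
    if (length(shoe_size_distribution) && sum(shoe_size_distribution) != 0)
      stop("shoe_size_distribution must sum to n_subjects")
    return(list())
  }
  if (is.null(names(shoe_size_distribution)))
    stop("shoe_size_distribution must be a named vector (size -> count)")
  if (sum(shoe_size_distribution) != n_subjects)
    stop("shoe_size_distribution must sum to n_subjects (got ",
         sum(shoe_size_distribution), ", expected ", n_subjects, ")")

  with_local_seed(seed, {
    sizes <- rep(as.numeric(names(shoe_size_distribution)),
                 times = as.integer(shoe_size_distribution))
    sizes <- sizes[sample.int(length(sizes))]
    if (identical_templates) {
      proto <- draw_profile(1L, sizes[1])
      profiles <- lapply(seq_len(n_subjects), function(i) {
        p <- proto
        p$subject_id <- i
        p
      })
    } else {
      profiles <- lapply(seq_len(n_subjects),
                         function(i) draw_profile(i, sizes[i]))
    }
    profiles
  })
}

#' Shoe-size histogram scaled to a cohort size
#'
#' Distributes \code{n} subjects over the four cohort shoe sizes in
#' proportion to the study histogram (2/15/19/24 over US sizes 3/4/7/10),
#' using largest-remainder rounding so the counts sum exactly to \code{n}.
#'
#' @param n cohort size.
#' @return named integer vector (size -> count) summing to \code{n}.
#' @export
shoe_size_mix <- function(n) {
  ref <- c("3" = 2, "4" = 15, "7" = 19, "10" = 24)
  exact <- n * ref / sum(ref)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  out <- as.integer(base)
  names(out) <- names(ref)
  out[out > 0]
}

# Footprint extent (cells) per US shoe size; fits the 32x16 ROI window.
foot_dims_for_size <- function(shoe_size_us) {
  dims <- list("3" = c(22L, 8L), "4" = c(23L, 9L),
               "7" = c(25L, 10L), "10" = c(28L, 11L))
  d <- dims[[as.character(shoe_size_us)]]
  if (is.null(d)) stop("unsupported shoe size: ", shoe_size_us)
  d
}

# One subject's parameter draw; consumes the active RNG stream.
draw_profile <- function(subject_id, shoe_size_us) {
  d <- foot_dims_for_size(shoe_size_us)
  weight_kg <- round(min(max(rnorm(1, 66, 12), 42), 100), 1)
  # largest rotation keeping the rotated footprint inside the 32x16 mask
  fits <- function(theta) {
    th <- theta * pi / 180
    d[1] * sin(th) + d[2] * cos(th) <= 15.5 &&
      d[1] * cos(th) + d[2] * sin(th) <= 31.5
  }
  angle_cap <- 14
  while (angle_cap > 0 && !fits(angle_cap)) angle_cap <- angle_cap - 0.5
  step_angle_deg <- round(min(max(rnorm(1, 6, 3), 0), angle_cap), 1)
  stride_cells <- as.integer(round(min(max(rnorm(1, 45, 3), 38), 52)))
  cadence_frames <- as.integer(round(min(max(rnorm(1, 44, 3), 36), 52)))
  asymmetry <- min(max(rnorm(1, 1, 0.03), 0.9), 1.1)

  # per-subject template idiosyncrasies (identity signal)
  shape <- list(
    heel_u = -0.28 + runif(1, -0.03, 0.03),   # lobe centers, fractions of L
    fore_u =  0.22 + runif(1, -0.04, 0.04),
    heel_v = runif(1, -0.06, 0.06),           # lateral offsets, fractions of W
    fore_v = runif(1, -0.10, 0.10),
    heel_su = 0.11 * runif(1, 0.85, 1.15),    # Gaussian sds (fractions)
    heel_sv = 0.24 * runif(1, 0.85, 1.15),
    fore_su = 0.15 * runif(1, 0.85, 1.15),
    fore_sv = 0.30 * runif(1, 0.85, 1.15),
    amp_ratio = runif(1, 0.75, 1.25)          # forefoot / heel amplitude
  )
  frame_peak <- 40 + 1.6 * weight_kg  # 8-bit headroom up to ~200 at 100 kg

  tl <- footprint_lobes(d[1], d[2], -step_angle_deg, shape,
                        frame_peak * sqrt(asymmetry))
  tr <- footprint_lobes(d[1], d[2], +step_angle_deg, shape,
                        frame_peak / sqrt(asymmetry))

  structure(list(
    subject_id = subject_id,
    shoe_size_us = shoe_size_us,
    weight_kg = weight_kg,
    foot_len_cells = d[1],
    foot_width_cells = d[2],
    step_angle_deg = step_angle_deg,
    stride_cells = stride_cells,
    cadence_frames = cadence_frames,
    asymmetry = asymmetry,
    shape = shape,
    frame_peak = frame_peak,
    template_left = 0.5 * (tl$heel + tl$fore),
    template_right = 0.5 * (tr$heel + tr$fore),
    lobes_left = tl,
    lobes_right = tr
  ), class = "subject_profile")
}

# Rasterize heel and forefoot pressure lobes into a 32x16 window.
# Returns list(heel, fore): the stance crossfades heel -> fore, and their
# midpoint mean 0.5*(heel+fore) is the full-stance template. Peak cell value
# across both lobes equals `peak` so rendered frames stay within 8 bits.
footprint_lobes <- function(foot_len, foot_width, angle_deg, shape, peak,
                            win_rows = 32L, win_cols = 16L) {
  stopifnot(foot_len <= win_rows, foot_width <= win_cols)
  cr <- (win_rows + 1) / 2
  cc <- (win_cols + 1) / 2
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(win_rows), win_rows, win_cols) - cr
  c <- matrix(seq_len(win_cols), win_rows, win_cols, byrow = TRUE) - cc
  # rotate cell coordinates into the foot frame (u along foot, v across)
  u <- cos(th) * r + sin(th) * c
  v <- -sin(th) * r + cos(th) * c
  L <- foot_len; W <- foot_width
  lobe <- function(cu, cv, su, sv) {
    g <- exp(-0.5 * (((u - cu * L) / (su * L))^2 +
                     ((v - cv * W) / (sv * W))^2))
    g[g < 0.03] <- 0  # compact support
    g
  }
  heel <- lobe(shape$heel_u, shape$heel_v, shape$heel_su, shape$heel_sv)
  fore <- shape$amp_ratio *
    lobe(shape$fore_u, shape$fore_v, shape$fore_su, shape$fore_sv)
  s <- peak / max(pmax(heel, fore))
  list(heel = heel * s, fore = fore * s)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject %d: US size %s, %.1f kg, foot %dx%d cells, angle %.1f deg,\n  stride %d cells, cadence %d frames/cycle, L/R asymmetry %.3f\n",
    x$subject_id, format(x$shoe_size_us), x$weight_kg, x$foot_len_cells,
    x$foot_width_cells, x$step_angle_deg, x$stride_cells, x$cadence_frames,
    x$asymmetry))
  invisible(x)
}
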
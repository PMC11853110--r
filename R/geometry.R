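#' Pressure-mat geometry
#'
#' Describes the sensing mat: a chain of identical mat units laid end to end
#' along the walking direction, tiled with square piezoresistive sensors on a
#' fixed pitch. The default corresponds to three 64 cm x 40 cm units with a
#' 1 cm pitch, i.e. a 192 x 40 grid of 7680 sensors sampled at 40 Hz, each
#' sensor reporting an 8-bit value.
#'
#' @param n_units number of mat units along the walking direction.
#' @param unit_length_cm length of one unit (walking direction), cm.
#' @param unit_width_cm width of the mat, cm.
#' @param sensor_pitch_cm sensor pitch, cm (sensors are square).
#' @param sample_rate_hz frame rate of the mat, Hz.
#' @return An object of class \code{mat_geometry}: a list with \code{rows}
#'   (cells along the walking direction), \code{cols} (cells across the mat),
#'   \code{n_sensors}, \code{sample_rate_hz} and \code{value_max} (255).
#' @examples
#' g <- mat_geometry()
#' g$rows * g$cols  # 7680 sensors
#' @export
mat_geometry <- function(n_units = 3, unit_length_cm = 64, unit_width_cm = 40,
                         sensor_pitch_cm = 1, sample_rate_hz = 40) {
  stopifnot(n_units >= 1, unit_length_cm > 0, unit_width_cm > 0,
            sensor_pitch_cm > 0, sample_rate_hz > 0)
  rows <- as.integer(round(n_units * unit_length_cm / sensor_pitch_cm))
  cols <- as.integer(round(unit_width_cm / sensor_pitch_cm))
  structure(list(
    n_units = n_units,
    unit_length_cm = unit_length_cm,
    unit_width_cm = unit_width_cm,
    sensor_pitch_cm = sensor_pitch_cm,
    rows = rows,
    cols = cols,
    n_sensors = rows * cols,
    sample_rate_hz = sample_rate_hz,
    value_max = 255L
  ), class = "mat_geometry")
}

#' @export
print.mat_geometry <- function(x, ...) {
  cat("Pressure mat:", x$n_units, "unit(s),", x$rows, "x", x$cols,
      "cells (", x$n_sensors, "sensors ),", x$sample_rate_hz, "Hz, 8-bit\n")
  invisible(x)
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic per-walk seed fan-out from a master seed (kept < 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed %% 2147483647)
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(h)
}
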
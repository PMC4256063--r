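#' Random-dot kinematogram stimulus specification
#'
#' Describes the geometry and timing of the dot stimulus: 100 dots of 0.44
#' degree diameter drifting for 400 ms inside a 15 degree circular aperture at
#' 60 Hz, with positions updated every 3 frames. At the default timing this
#' gives 24 frames and 8 position updates after the initial frame. The two
#' standard speeds (1.5 and 6 degrees/s) correspond to per-update
#' displacements of 0.075 and 0.3 degrees.
#'
#' @param speed Dot speed in degrees of visual angle per second.
#' @param n_dots Number of dots.
#' @param dot_diameter Dot diameter in degrees.
#' @param aperture_diameter Aperture diameter in degrees.
#' @param duration_ms Stimulus duration in milliseconds.
#' @param frame_rate Monitor frame rate in Hz.
#' @param update_interval Frames between successive position updates.
#' @return An object of class `stimulus_spec`.
#' @examples
#' spec <- stimulus_spec(speed = 1.5)
#' displacement_per_update(spec$speed, spec$frame_rate, spec$update_interval)
#' @export
stimulus_spec <- function(speed = 1.5, n_dots = 100, dot_diameter = 0.44,
                          aperture_diameter = 15, duration_ms = 400,
                          frame_rate = 60, update_interval = 3) {
  check_number(speed, "speed", lower = 0)
  check_count(n_dots, "n_dots")
  check_number(dot_diameter, "dot_diameter", lower = 0, allow_equal = FALSE)
  check_number(aperture_diameter, "aperture_diameter", lower = 0,
               allow_equal = FALSE)
  check_number(duration_ms, "duration_ms", lower = 0, allow_equal = FALSE)
  check_number(frame_rate, "frame_rate", lower = 0, allow_equal = FALSE)
  check_count(update_interval, "update_interval")
  n_frames <- duration_ms * frame_rate / 1000
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop_invalid("duration_ms and frame_rate must yield an integer frame ",
                 "count (got ", format(n_frames), " frames)")
  }
  structure(
    list(speed = speed, n_dots = as.integer(n_dots),
         dot_diameter = dot_diameter, aperture_diameter = aperture_diameter,
         duration_ms = duration_ms, frame_rate = frame_rate,
         update_interval = as.integer(update_interval),
         n_frames = as.integer(round(n_frames))),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "RDK stimulus: %d dots (%.2f deg), aperture %.1f deg, %g ms at %g Hz\n",
    x$n_dots, x$dot_diameter, x$aperture_diameter, x$duration_ms,
    x$frame_rate
  ))
  cat(sprintf("  speed %g deg/s, update every %d frames (%.3f deg/update)\n",
              x$speed, x$update_interval,
              displacement_per_update(x$speed, x$frame_rate,
                                      x$update_interval)))
  invisible(x)
}

#' Per-update dot displacement
#'
#' Distance each dot travels between successive position updates:
#' `speed * update_interval / frame_rate`. At 60 Hz with updates every 3
#' frames this is 0.075 degrees for the slow (1.5 deg/s) condition and 0.3
#' degrees for the fast (6 deg/s) condition.
#'
#' @param speed Dot speed in degrees/s (may be 0).
#' @param frame_rate Frame rate in Hz (must be positive).
#' @param update_interval Frames between updates (must be positive).
#' @return Displacement in degrees per update.
#' @examples
#' displacement_per_update(1.5, 60, 3) # 0.075
#' displacement_per_update(6, 60, 3)   # 0.3
#' @export
displacement_per_update <- function(speed, frame_rate, update_interval) {
  check_number(speed, "speed", lower = 0)
  check_number(frame_rate, "frame_rate", lower = 0, allow_equal = FALSE)
  check_number(update_interval, "update_interval", lower = 0,
               allow_equal = FALSE)
  speed * update_interval / frame_rate
}

new_direction_field <- function(directions, mean_direction, direction_sd,
                                coherence) {
  structure(
    list(directions = wrap_angle(directions),
         mean_direction = wrap_angle(mean_direction),
         direction_sd = direction_sd, coherence = coherence),
    class = "direction_field"
  )
}

#' @export
print.direction_field <- function(x, ...) {
  dialect <- if (is.null(x$coherence)) "wrapped-normal" else "coherence"
  cat(sprintf("Direction field (%s): %d dots, mean %.1f deg", dialect,
              length(x$directions), x$mean_direction))
  if (is.null(x$coherence)) {
    cat(sprintf(", direction SD %.1f deg\n", x$direction_sd))
  } else {
    cat(sprintf(", coherence %.2f\n", x$coherence))
  }
  invisible(x)
}

#' Sample dot directions from a wrapped normal distribution
#'
#' Draws `n` directions from a normal distribution with the given mean and
#' standard deviation and wraps them onto the circle. This is the
#' equivalent-noise stimulus dialect: `sd` is the external direction noise.
#' For `sd > 180` degrees the wrapped normal is numerically indistinguishable
#' from the uniform distribution on the circle, and uniform samples are drawn
#' instead.
#'
#' @param mean Mean direction in degrees (0 = up, positive = rightward).
#' @param sd External noise: SD of the generating normal, in degrees
#'   (`sd >= 0`).
#' @param n Number of dots (`n >= 1`).
#' @return A `direction_field` with `direction_sd = sd` and no coherence.
#' @examples
#' set.seed(1)
#' f <- sample_wrapped_normal_directions(mean = 4, sd = 0, n = 100)
#' unique(f$directions)
#' @export
sample_wrapped_normal_directions <- function(mean, sd, n) {
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0)
  n <- check_count(n, "n")
  directions <- if (sd > 180) {
    runif(n, -180, 180)
  } else {
    rnorm(n, mean = mean, sd = sd)
  }
  new_direction_field(directions, mean, sd, coherence = NULL)
}

#' Build a coherence-mixture direction field
#'
#' Exactly `round(coherence * n)` signal dots move in `signal_direction`; the
#' remaining dots move in independent uniformly random directions. Signal-dot
#' identities are chosen at random each call, but the signal count is fixed
#' (not Bernoulli per dot), which reduces trial-to-trial threshold variance.
#'
#' @param coherence Proportion of signal dots in \[0, 1\].
#' @param signal_direction Signal direction in degrees (the standard task
#'   uses +90 or -90, i.e. horizontal).
#' @param n Number of dots.
#' @return A `direction_field` with `coherence` set and no `direction_sd`.
#' @examples
#' set.seed(1)
#' f <- make_coherence_directions(0.47, signal_direction = -90, n = 100)
#' sum(f$directions == -90)
#' @export
make_coherence_directions <- function(coherence, signal_direction, n) {
  check_number(coherence, "coherence", lower = 0, upper = 1)
  check_number(signal_direction, "signal_direction")
  n <- check_count(n, "n")
  n_signal <- round(coherence * n)
  directions <- runif(n, -180, 180)
  if (n_signal > 0) {
    idx <- sample.int(n, n_signal)
    directions[idx] <- signal_direction
  }
  new_direction_field(directions, signal_direction, NULL,
                      coherence = coherence)
}

#' Generate per-update dot positions for a trial
#'
#' Dots start at uniformly random positions inside the circular aperture and
#' move along their assigned directions by `displacement_per_update()` at each
#' update, with no lifetime limit. A dot whose centre leaves the aperture is
#' re-entered at a uniformly random position inside the aperture (the
#' re-entry rule is a package choice; see the methods vignette).
#'
#' @param spec A `stimulus_spec`.
#' @param field A `direction_field` with `spec$n_dots` directions.
#' @return A data frame with columns `update` (0 = initial placement),
#'   `dot`, `x_deg`, `y_deg`, `direction_deg`. Positive x is rightward,
#'   positive y upward; the aperture is centred on the origin.
#' @examples
#' set.seed(1)
#' spec <- stimulus_spec(speed = 1.5)
#' field <- sample_wrapped_normal_directions(0, 10, spec$n_dots)
#' traj <- generate_dot_trajectory(spec, field)
#' max(table(traj$dot)) # 9 records per dot: initial + 8 updates
#' @export
generate_dot_trajectory <- function(spec, field) {
  stopifnot(inherits(spec, "stimulus_spec"),
            inherits(field, "direction_field"))
  if (length(field$directions) != spec$n_dots) {
    stop_invalid("field has ", length(field$directions),
                 " directions but spec$n_dots = ", spec$n_dots)
  }
  n_updates <- spec$n_frames %/% spec$update_interval
  step <- displacement_per_update(spec$speed, spec$frame_rate,
                                  spec$update_interval)
  radius <- spec$aperture_diameter / 2
  n <- spec$n_dots

  random_position <- function(k) {
    r <- radius * sqrt(runif(k))
    a <- runif(k, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  }

  pos <- random_position(n)
  rad <- field$directions * pi / 180
  dx <- step * sin(rad)  # 0 deg = up, positive = rightward
  dy <- step * cos(rad)

  out_x <- matrix(NA_real_, nrow = n, ncol = n_updates + 1L)
  out_y <- matrix(NA_real_, nrow = n, ncol = n_updates + 1L)
  out_x[, 1L] <- pos[, 1L]
  out_y[, 1L] <- pos[, 2L]
  for (u in seq_len(n_updates)) {
    pos[, 1L] <- pos[, 1L] + dx
    pos[, 2L] <- pos[, 2L] + dy
    outside <- pos[, 1L]^2 + pos[, 2L]^2 > radius^2
    if (any(outside)) {
      pos[outside, ] <- random_position(sum(outside))
    }
    out_x[, u + 1L] <- pos[, 1L]
    out_y[, u + 1L] <- pos[, 2L]
  }

  data.frame(
    update = rep(0:n_updates, each = n),
    dot = rep(seq_len(n), n_updates + 1L),
    x_deg = as.vector(out_x),
    y_deg = as.vector(out_y),
    direction_deg = rep(field$directions, n_updates + 1L)
  )
}

#' Read and write stimulus specifications and trajectories
#'
#' `write_stimulus_spec()`/`read_stimulus_spec()` round-trip a
#' `stimulus_spec` through JSON; `write_trajectory()` stores a trajectory as
#' plain CSV.
#'
#' @param spec A `stimulus_spec`.
#' @param path File path.
#' @param trajectory Data frame from [generate_dot_trajectory()].
#' @return `read_stimulus_spec()` returns a `stimulus_spec`; the writers
#'   return `path` invisibly.
#' @export
write_stimulus_spec <- function(spec, path) {
  stopifnot(inherits(spec, "stimulus_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_spec
#' @export
read_stimulus_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_spec(speed = x$speed, n_dots = x$n_dots,
                dot_diameter = x$dot_diameter,
                aperture_diameter = x$aperture_diameter,
                duration_ms = x$duration_ms, frame_rate = x$frame_rate,
                update_interval = x$update_interval)
}

#' @rdname write_stimulus_spec
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
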
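#' Load a tracking export
#'
#' Reads a CSV of per-frame planar coordinates (columns `frame`,
#' `t_movie_s` and/or `t_min`, `x_mm`, `y_mm`, optional `interval`) as
#' exported from video tracking, and converts all units to millimetres and
#' real minutes at the boundary. The defaults encode time-lapse capture of
#' one frame every 2 s of real time compressed to a 30 fps movie, so 1 s of
#' movie equals 1 min of real time. Missing frame indices are flagged as
#' gaps; non-monotone or duplicated frames are an error. When no interval
#' column is present, frames are labelled `before` / `during` / `after` in
#' three equal segments (10 min each for a 30-min recording).
#'
#' @param path CSV file path.
#' @param time_scale Real minutes per second of movie (default 1).
#' @param capture_interval Real seconds per captured frame (default 2).
#' @param intervals Optional numeric vector of two real-time boundaries
#'   (minutes) splitting before/during/after; default splits the recording
#'   into three equal segments.
#' @return A `track_series` tibble: `frame`, `t_movie_s`, `t_min`, `x_mm`,
#'   `y_mm`, `interval`.
#' @export
load_track <- function(path, time_scale = 1, capture_interval = 2,
                       intervals = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "x_mm", "y_mm")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    abort(sprintf("Track file is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(d$frame)) {
    abort(sprintf(
      "Duplicated frame index: %s",
      paste(head(unique(d$frame[duplicated(d$frame)]), 5L), collapse = ", ")
    ))
  }
  if (is.unsorted(d$frame, strictly = TRUE)) {
    abort("Frame indices must be strictly increasing.")
  }
  gaps <- setdiff(seq(min(d$frame), max(d$frame)), d$frame)
  if (length(gaps) > 0L) {
    inform(sprintf("Track has %d missing frame(s); flagged in the `gaps` attribute.",
                   length(gaps)))
  }
  if (!"t_min" %in% names(d)) {
    d$t_min <- if ("t_movie_s" %in% names(d)) {
      d$t_movie_s * time_scale
    } else {
      d$frame * capture_interval / 60
    }
  }
  if (!"t_movie_s" %in% names(d)) d$t_movie_s <- d$t_min / time_scale
  if (!"interval" %in% names(d)) {
    bounds <- intervals %||% (max(d$t_min) * c(1, 2) / 3)
    d$interval <- cut(
      d$t_min, c(-Inf, bounds, Inf),
      labels = c("before", "during", "after"), right = FALSE
    )
    d$interval <- as.character(d$interval)
  }
  d <- dplyr::select(d, "frame", "t_movie_s", "t_min", "x_mm", "y_mm", "interval")
  new_track_series(tibble::as_tibble(d), time_scale, capture_interval,
                   gaps = gaps)
}

#' Write a track series to CSV
#'
#' @param x A `track_series`.
#' @param path CSV file path.
#' @export
write_track <- function(x, path) {
  readr::write_csv(
    tibble::as_tibble(x)[c("frame", "t_movie_s", "x_mm", "y_mm", "interval")],
    path, progress = FALSE
  )
  invisible(x)
}

#' Per-frame velocity series
#'
#' Frame-to-frame velocity in mm/min: the Euclidean displacement between
#' consecutive frames divided by the real-time step. The first frame has no
#' predecessor and is excluded. An optional centred rolling mean (default
#' window 5 frames, shrinking at the edges) smooths tracking noise;
#' `smooth_window = 1` keeps the raw series.
#'
#' @param track A `track_series`.
#' @param smooth_window Width (frames) of the centred rolling mean.
#' @return A tibble: `frame`, `t_min`, `interval`, `velocity`,
#'   `velocity_smooth`.
#' @export
velocity_series <- function(track, smooth_window = 5) {
  stopifnot(nrow(track) >= 2L)
  d <- tibble::as_tibble(track)
  dt <- diff(d$t_min)
  if (any(dt <= 0)) abort("Time must be strictly increasing.")
  disp <- sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2)
  v <- disp / dt
  out <- tibble::tibble(
    frame = d$frame[-1],
    t_min = d$t_min[-1],
    interval = d$interval[-1],
    velocity = v
  )
  out$velocity_smooth <- if (smooth_window > 1) {
    zoo::rollapply(v, smooth_window, mean, partial = TRUE, align = "center")
  } else {
    v
  }
  out
}

#' Per-interval kinematics summary
#'
#' Summarises motion within each stimulus interval: peak velocity (maximum
#' of the smoothed series), mean velocity, and path length, plus the
#' stimulus-response statistic `delta_peak = peak(during) - peak(before)`.
#'
#' @param velocities A tibble from [velocity_series()].
#' @return An object of class `kinematics_summary`: list with `intervals`
#'   (tibble: `interval`, `n_frames`, `peak_velocity`, `mean_velocity`,
#'   `path_length`) and `delta_peak` (mm/min).
#' @export
interval_summary <- function(velocities) {
  stopifnot(all(c("interval", "velocity", "velocity_smooth", "t_min")
                %in% names(velocities)))
  labs <- unique(velocities$interval)
  empty <- setdiff(c("before", "during", "after"), labs)
  if (length(empty) > 0L) {
    abort(sprintf("Empty interval(s): %s", paste(empty, collapse = ", ")))
  }
  d <- dplyr::group_by(tibble::as_tibble(velocities), .data$interval)
  d <- dplyr::summarise(
    d,
    n_frames = dplyr::n(),
    peak_velocity = max(.data$velocity_smooth),
    mean_velocity = mean(.data$velocity),
    .groups = "drop"
  )
  # path length = sum of frame displacements (v * dt); each velocity row
  # already corresponds to one frame-to-frame step, whose dt is the gap to
  # the previous frame, so reconstruct dt from the full series
  vv <- tibble::as_tibble(velocities)
  dt <- c(diff(vv$t_min)[1], diff(vv$t_min))
  pl <- vapply(split(vv$velocity * dt, vv$interval), sum, numeric(1))
  d$path_length <- unname(pl[d$interval])
  d <- d[match(c("before", "during", "after"), d$interval), , drop = FALSE]
  structure(
    list(
      intervals = d,
      delta_peak = d$peak_velocity[d$interval == "during"] -
        d$peak_velocity[d$interval == "before"]
    ),
    class = "kinematics_summary"
  )
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("<kinematics_summary> delta peak (during - before): %.4g mm/min\n",
              x$delta_peak))
  print(x$intervals)
  invisible(x)
}

#' Estimate total cells from an ellipsoid volume and a nuclear section
#'
#' Total-cell estimate for an ellipsoidal organism: nuclei are counted in
#' an optical section of known area and depth, giving a nuclear density
#' (`nuclei / (area * depth)`), which is multiplied by the ellipsoid
#' volume `(4/3) * pi * a * b * c`. By default pi is approximated as 22/7,
#' matching the original hand calculation; `exact_pi = TRUE` uses `pi`
#' (the two differ by the fixed factor 22/(7*pi), about 1.0004).
#'
#' @param radii Numeric vector of the three axial radii `a`, `b`, `c`
#'   (units consistent with `section_area` and `depth`).
#' @param nuclei_count Nuclei counted in the section.
#' @param section_area Area of the imaged section.
#' @param depth Imaged section depth (default 7, i.e. a 7 um optical
#'   section when working in um).
#' @param exact_pi Use `pi` instead of 22/7.
#' @return A one-row tibble: `radius_a`, `radius_b`, `radius_c`,
#'   `section_volume`, `nuclei_per_volume`, `total_volume`, `total_cells`.
#' @examples
#' # unit sphere with 22/7: volume = 88/21
#' estimate_total_cells(c(1, 1, 1), nuclei_count = 1, section_area = 1)
#' @export
estimate_total_cells <- function(radii, nuclei_count, section_area, depth = 7,
                                 exact_pi = FALSE) {
  stopifnot(length(radii) == 3L)
  if (any(radii <= 0)) abort("Radii must be positive.")
  check_scalar_number(nuclei_count, "nuclei_count", min = 0)
  check_scalar_number(section_area, "section_area", min = 0, strict_min = TRUE)
  check_scalar_number(depth, "depth", min = 0, strict_min = TRUE)
  pi_val <- if (exact_pi) pi else 22 / 7
  section_volume <- section_area * depth
  density <- nuclei_count / section_volume
  total_volume <- (4 / 3) * pi_val * radii[1] * radii[2] * radii[3]
  tibble::tibble(
    radius_a = radii[1], radius_b = radii[2], radius_c = radii[3],
    section_volume = section_volume,
    nuclei_per_volume = density,
    total_volume = total_volume,
    total_cells = density * total_volume
  )
}
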
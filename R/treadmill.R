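#' Define a fixed-paced treadmill exercise protocol
#'
#' A fixed-paced treadmill protocol is a sequence of stages, each with a
#' prescribed duration (minutes) and belt velocity (km/h). Walk time on such
#' a protocol converts deterministically into walk distance and average
#' velocity, which puts treadmill scores and six-minute walk test (6MWT)
#' scores on a common distance/velocity axis.
#'
#' @param name Protocol label.
#' @param stage_durations Numeric vector of per-stage durations in minutes;
#'   all positive.
#' @param stage_velocities Numeric vector of per-stage belt velocities in
#'   km/h; same length as `stage_durations`, all non-negative.
#' @param met_table Optional data frame with columns `time` (minutes) and
#'   `met`, tabulating device-reported MET scores for selected walk times.
#'   Protocol scoring devices map time to METs internally; the mapping is
#'   supplied as data, not a formula.
#' @return An object of class `treadmill_protocol`.
#' @seealso [mbruce()], [split_walk_time()], [walked_distance()]
#' @export
treadmill_protocol <- function(name, stage_durations, stage_velocities,
                               met_table = NULL) {
  stage_durations <- as.numeric(stage_durations)
  stage_velocities <- as.numeric(stage_velocities)
  if (length(stage_durations) < 1L ||
      length(stage_durations) != length(stage_velocities))
    stop("stage_durations and stage_velocities must have equal length >= 1")
  if (any(!is.finite(stage_durations)) || any(stage_durations <= 0))
    stop("all stage durations must be positive and finite")
  if (any(!is.finite(stage_velocities)) || any(stage_velocities < 0))
    stop("all stage velocities must be non-negative and finite")
  if (!is.null(met_table)) {
    met_table <- as.data.frame(met_table)
    if (!all(c("time", "met") %in% names(met_table)))
      stop("met_table must have columns 'time' and 'met'")
  }
  structure(
    list(name = as.character(name),
         stage_durations = stage_durations,
         stage_velocities = stage_velocities,
         met_table = met_table),
    class = "treadmill_protocol")
}

#' Modified Bruce protocol preset
#'
#' The modified Bruce (mBruce) submaximal treadmill protocol with 3-minute
#' stages. The preset ships the first four stage velocities (2.7, 2.7, 2.7
#' and 4.0 km/h); later stages of the published protocol can be appended via
#' `stage_velocities`. A single tabulated device score (walk time 10.5 min
#' corresponds to 5.95 MET) is included as the default `met_table`.
#'
#' @param stage_velocities Belt velocities in km/h, one per 3-minute stage.
#' @param met_table Optional time-to-MET score table; see
#'   [treadmill_protocol()].
#' @return A `treadmill_protocol` object.
#' @examples
#' p <- mbruce()
#' split_walk_time(p, 10.5)
#' walked_distance(p, 10.5)
#' @export
mbruce <- function(stage_velocities = c(2.7, 2.7, 2.7, 4.0),
                   met_table = data.frame(time = 10.5, met = 5.95)) {
  treadmill_protocol("mBruce",
                     stage_durations = rep(3, length(stage_velocities)),
                     stage_velocities = stage_velocities,
                     met_table = met_table)
}

#' @export
print.treadmill_protocol <- function(x, ...) {
  cat(sprintf("Treadmill protocol '%s': %d stages\n", x$name,
              length(x$stage_durations)))
  cat(sprintf("  durations [min]:  %s\n",
              paste(format(x$stage_durations), collapse = ", ")))
  cat(sprintf("  velocities [km/h]: %s\n",
              paste(format(x$stage_velocities), collapse = ", ")))
  invisible(x)
}

#' Split a walk time into completed stages and a partial-stage remainder
#'
#' Finds the number of fully completed stages `S` and the time `delta_t`
#' spent in the uncompleted stage `S + 1`. A walk time falling exactly on a
#' stage boundary is attributed to the completed stage (`delta_t = 0`), so
#' `delta_t` is always strictly less than the next stage's duration unless
#' the walk time exhausts the protocol.
#'
#' @param protocol A [treadmill_protocol()].
#' @param walk_time Total walk time in minutes; must lie in
#'   `[0, sum(stage_durations)]`.
#' @return A list with integer `completed_stages` and numeric
#'   `partial_stage_time` (minutes).
#' @examples
#' split_walk_time(mbruce(), 10.5)  # 3 completed stages, 1.5 min into stage 4
#' @export
split_walk_time <- function(protocol, walk_time) {
  stopifnot(inherits(protocol, "treadmill_protocol"))
  if (!is.numeric(walk_time) || length(walk_time) != 1L ||
      !is.finite(walk_time))
    stop("walk_time must be a single finite number")
  total <- sum(protocol$stage_durations)
  if (walk_time < 0 || walk_time > total)
    stop(sprintf("walk_time must lie in [0, %g] minutes for protocol '%s'",
                 total, protocol$name))
  ends <- cumsum(protocol$stage_durations)
  s <- sum(ends <= walk_time)
  dt <- walk_time - if (s > 0) ends[s] else 0
  # guard against floating-point residue at exact boundaries
  if (dt < 0) dt <- 0
  list(completed_stages = as.integer(s), partial_stage_time = dt)
}

#' Distance walked on a fixed-paced treadmill protocol
#'
#' Converts a walk time into the distance covered: the sum of full-stage
#' distances `(50/3) * T_s_i * v_i` over completed stages plus the
#' partial-stage distance `(50/3) * delta_t * v_(S+1)`, all in meters
#' (velocities in km/h equal 50/3 m/min; the rational factor is used
#' exactly).
#'
#' @inheritParams split_walk_time
#' @return Distance in meters.
#' @examples
#' walked_distance(mbruce(), 10.5)  # 505 m
#' @export
walked_distance <- function(protocol, walk_time) {
  sp <- split_walk_time(protocol, walk_time)
  s <- sp$completed_stages
  d_full <- if (s > 0) {
    (50 / 3) * sum(protocol$stage_durations[seq_len(s)] *
                     protocol$stage_velocities[seq_len(s)])
  } else 0
  d_part <- if (sp$partial_stage_time > 0) {
    (50 / 3) * sp$partial_stage_time * protocol$stage_velocities[s + 1L]
  } else 0
  d_full + d_part
}

#' Average walk velocity from distance and time
#'
#' `v = D / T` in m/min, i.e. `(3/50) * D / T` in km/h.
#'
#' @param distance Distance in meters, non-negative.
#' @param walk_time Walk time in minutes, strictly positive.
#' @return Average velocity in km/h.
#' @examples
#' average_velocity(505, 10.5)  # 2.886 km/h to 3 decimals
#' @export
average_velocity <- function(distance, walk_time) {
  if (!is.numeric(walk_time) || any(!is.finite(walk_time)) ||
      any(walk_time <= 0))
    stop("walk_time must be positive")
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be non-negative")
  (3 / 50) * distance / walk_time
}

#' Six-minute-walk equivalent velocity
#'
#' A 6MWT distance `D` meters corresponds to an average velocity
#' `v_6M = D / 6` m/min, i.e. `D / 100` km/h. This is the canonical
#' abscissa for all MET-velocity models in the package: the velocity axis in
#' km/h doubles as a distance axis in units of 100 m.
#'
#' @param distance Distance in meters, non-negative.
#' @return Velocity in km/h.
#' @examples
#' six_minute_velocity(505)  # 5.05 km/h
#' @export
six_minute_velocity <- function(distance) {
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be non-negative")
  distance / 100
}

#' Predicted heart-rate limit for submaximal testing
#'
#' Age-predicted maximal heart rate `HRmax = 208 - 0.7 * age` scaled by a
#' target fraction. Submaximal exercise testing in pulmonary rehabilitation
#' typically terminates at 70-80% of predicted HRmax.
#'
#' @param age Age in years, positive.
#' @param fraction Fraction of predicted maximal heart rate in `(0, 1]`;
#'   default 1 returns HRmax itself.
#' @return Heart rate in beats per minute.
#' @examples
#' predicted_hr_limit(40)        # 180 bpm
#' predicted_hr_limit(40, 0.75)  # 135 bpm
#' @export
predicted_hr_limit <- function(age, fraction = 1) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  fraction * (208 - 0.7 * age)
}

#' Full treadmill outcome for a walk time
#'
#' Convenience wrapper computing every derived quantity for one treadmill
#' walk: completed stages, partial-stage time, distance, average velocity,
#' the 6MWT-equivalent velocity of the same distance, and the tabulated MET
#' score when the protocol's `met_table` has an entry for this walk time.
#'
#' @inheritParams split_walk_time
#' @return A list of class `treadmill_outcome` with elements `walk_time`,
#'   `completed_stages`, `partial_stage_time`, `distance`,
#'   `average_velocity`, `six_minute_equivalent_velocity` and `met` (NA if
#'   not tabulated).
#' @examples
#' treadmill_outcome(mbruce(), 10.5)
#' @export
treadmill_outcome <- function(protocol, walk_time) {
  sp <- split_walk_time(protocol, walk_time)
  d <- walked_distance(protocol, walk_time)
  v <- if (walk_time > 0) average_velocity(d, walk_time) else 0
  met <- NA_real_
  if (!is.null(protocol$met_table)) {
    hit <- which(abs(protocol$met_table$time - walk_time) < 1e-9)
    if (length(hit) == 1L) met <- protocol$met_table$met[hit]
  }
  structure(
    list(walk_time = walk_time,
         completed_stages = sp$completed_stages,
         partial_stage_time = sp$partial_stage_time,
         distance = d,
         average_velocity = v,
         six_minute_equivalent_velocity = six_minute_velocity(d),
         met = met),
    class = "treadmill_outcome")
}

#' @export
print.treadmill_outcome <- function(x, ...) {
  cat(sprintf("Treadmill walk of %.3g min: S = %d stages completed, dT = %.3g min\n",
              x$walk_time, x$completed_stages, x$partial_stage_time))
  cat(sprintf("  distance D = %.5g m, average velocity v = %.3f km/h\n",
              x$distance, x$average_velocity))
  cat(sprintf("  6MWT-equivalent velocity v6M = %.3f km/h\n",
              x$six_minute_equivalent_velocity))
  if (!is.na(x$met)) cat(sprintf("  tabulated score: %.3g MET\n", x$met))
  invisible(x)
}
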
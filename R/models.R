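#' MET-velocity models
#'
#' The package models the MET score of a submaximal treadmill test as a
#' function of 6MWT average walk velocity `v` (km/h). Every model in the
#' family is anchored at the generalized resting MET: `M(0) = 1` exactly,
#' whatever the individual's resting oxygen uptake. Three model classes are
#' provided: the historical linear baseline `M = 0.5046 v + 1`, a
#' polynomial expansion `M = 1 + a1 v + ... + aK v^K`, and a continuous
#' piecewise-linear model with free change points.
#'
#' @name met_models
NULL

#' Linear baseline MET model
#'
#' The classical single-slope model `M = 0.5046 v + 1`, equivalent to
#' `(1.766 v + 3.5) / 3.5` with a resting uptake of 3.5 ml/kg/min. Kept as
#' the negative baseline: energy expenditure above the anaerobic threshold
#' is strongly nonlinear in velocity and the linear model underfits badly.
#'
#' @param slope Slope in MET per km/h; default the historical 0.5046.
#' @return A model object of class `c("met_linear", "met_model")`.
#' @examples
#' predict(met_linear(), c(0, 1, 3.5))
#' @export
met_linear <- function(slope = 0.5046) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  structure(list(slope = slope), class = c("met_linear", "met_model"))
}

#' Polynomial MET model with unit resting intercept
#'
#' `M(v) = 1 + a1 v + a2 v^2 + ... + aK v^K`. The intercept is structurally
#' fixed at 1 MET (the resting value) and is not a coefficient.
#'
#' @param coefficients Numeric vector `(a1, ..., aK)`; the order `K` is its
#'   length.
#' @param population Optional label for the population the model describes.
#' @return A model object of class `c("met_polynomial", "met_model")`.
#' @examples
#' m <- met_polynomial(c(0.51701, -0.029094, 0.027643), population = "men")
#' predict(m, c(0, 1, 5))
#' @export
met_polynomial <- function(coefficients, population = NULL) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || any(!is.finite(coefficients)))
    stop("coefficients must be a non-empty finite numeric vector")
  structure(
    list(order = length(coefficients), coefficients = coefficients,
         population = population),
    class = c("met_polynomial", "met_model"))
}

#' Derive continuity intercepts for a piecewise-linear MET model
#'
#' Given per-segment slopes `(a1, ..., an)` and strictly increasing change
#' points `(V1, ..., V_{n-1})`, the linear-spline property fixes every
#' intercept: `b1 = 1` (resting MET) and
#' `b_j = (a_{j-1} - a_j) V_{j-1} + b_{j-1}` for `j = 2, ..., n`, which
#' makes adjacent segments agree at each change point.
#'
#' @param slopes Numeric vector of segment slopes in MET per km/h.
#' @param change_points Numeric vector of change points in km/h, strictly
#'   increasing and positive; length `length(slopes) - 1`.
#' @return Numeric vector of intercepts `(b1, ..., bn)` in MET.
#' @examples
#' derive_intercepts(c(0.4866, 1.415, 1.99, 4.494), c(2.68, 3.945, 5.798))
#' @export
derive_intercepts <- function(slopes, change_points) {
  slopes <- as.numeric(slopes)
  change_points <- as.numeric(change_points)
  n <- length(slopes)
  if (n < 1L) stop("at least one slope is required")
  if (length(change_points) != n - 1L)
    stop("need exactly length(slopes) - 1 change points")
  if (n > 1L) {
    if (any(!is.finite(change_points)) || any(change_points <= 0))
      stop("change points must be positive and finite")
    if (any(diff(change_points) <= 0))
      stop("change points must be strictly increasing")
  }
  b <- numeric(n)
  b[1L] <- 1
  for (j in seq_len(n)[-1L])
    b[j] <- (slopes[j - 1L] - slopes[j]) * change_points[j - 1L] + b[j - 1L]
  b
}

#' Continuous piecewise-linear MET model
#'
#' An `n`-segment model `M(v) = a_j v + b_j` for
#' `V_{j-1} <= v < V_j` (with `V_0 = 0`, `V_n = +Inf`). Intercepts are not
#' free parameters: they follow from the slopes and change points via
#' [derive_intercepts()], so the curve is continuous and `M(0) = 1`.
#'
#' @inheritParams derive_intercepts
#' @param population Optional population label.
#' @return A model object of class `c("met_piecewise", "met_model")` with
#'   fields `n_segments`, `slopes`, `change_points`, `intercepts`,
#'   `population`.
#' @examples
#' w <- met_piecewise(c(0.4866, 1.415, 1.99, 4.494), c(2.68, 3.945, 5.798),
#'                    population = "women")
#' switch_points(w)
#' @export
met_piecewise <- function(slopes, change_points = numeric(0),
                          population = NULL) {
  slopes <- as.numeric(slopes)
  change_points <- as.numeric(change_points)
  intercepts <- derive_intercepts(slopes, change_points)
  structure(
    list(n_segments = length(slopes), slopes = slopes,
         change_points = change_points, intercepts = intercepts,
         population = population),
    class = c("met_piecewise", "met_model"))
}

#' Reference MET-velocity models for a COPD rehabilitation cohort
#'
#' Parameter estimates from a cohort of 299 COPD patients (159 men, 140
#' women) who underwent both a modified-Bruce submaximal treadmill test and
#' a 6MWT. Polynomial models are order-3; piecewise models have 4 segments.
#' These serve as generating truths for synthetic cohorts and as defaults
#' for model-derived rehabilitation schemes.
#'
#' @param population One of `"men"`, `"women"`, `"all"`.
#' @param kind `"piecewise"` (default) or `"polynomial"`.
#' @return A fitted `met_model` object.
#' @examples
#' copd_reference_model("women")
#' copd_reference_model("men", kind = "polynomial")
#' @export
copd_reference_model <- function(population = c("men", "women", "all"),
                                 kind = c("piecewise", "polynomial")) {
  population <- match.arg(population)
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    coefs <- switch(population,
      men   = c(0.51701, -0.029094, 0.027643),
      women = c(0.1822, 0.092524, 0.015432),
      all   = c(0.44886, -0.014615, 0.026691))
    met_polynomial(coefs, population = population)
  } else {
    est <- switch(population,
      men   = c(0.4877, 1.544, 2.106, 4.194, 2.50, 4.429, 5.879),
      women = c(0.4866, 1.415, 1.99, 4.494, 2.68, 3.945, 5.798),
      all   = c(0.494, 1.486, 2.081, 4.099, 2.602, 4.255, 5.814))
    piecewise_from_estimate(est, population = population)
  }
}

#' Build a piecewise model from a stacked estimate vector
#'
#' The combined estimate vector for an `n`-segment model stacks the `n`
#' slopes (segment order) followed by the `n - 1` change points (increasing
#' order): `c(a1, ..., an, V1, ..., V_{n-1})`.
#'
#' @param estimate Numeric vector of length `2n - 1`.
#' @param population Optional population label.
#' @return A `met_piecewise` model.
#' @export
piecewise_from_estimate <- function(estimate, population = NULL) {
  estimate <- as.numeric(estimate)
  len <- length(estimate)
  if (len %% 2L != 1L)
    stop("estimate vector must have odd length 2n - 1 (n slopes, n - 1 change points)")
  n <- (len + 1L) %/% 2L
  met_piecewise(estimate[seq_len(n)], estimate[seq_len(n - 1L) + n],
                population = population)
}

segment_index <- function(model, v) {
  # segment j covers V_{j-1} <= v < V_j; continuity makes boundaries safe
  findInterval(v, model$change_points) + 1L
}

#' Predict MET from velocity
#'
#' Evaluate a MET-velocity model at 6MWT average velocities (km/h). All
#' models return exactly 1 MET at `v = 0`.
#'
#' @param object A `met_model`.
#' @param velocity Numeric vector of velocities in km/h, non-negative.
#' @param ... Unused.
#' @return Numeric vector of MET values.
#' @export
predict.met_linear <- function(object, velocity, ...) {
  check_velocity(velocity)
  object$slope * velocity + 1
}

#' @rdname predict.met_linear
#' @export
predict.met_polynomial <- function(object, velocity, ...) {
  check_velocity(velocity)
  # Horner evaluation of 1 + a1 v + ... + aK v^K
  acc <- rep(0, length(velocity))
  for (a in rev(object$coefficients)) acc <- acc * velocity + a
  acc * velocity + 1
}

#' @rdname predict.met_linear
#' @export
predict.met_piecewise <- function(object, velocity, ...) {
  check_velocity(velocity)
  j <- segment_index(object, velocity)
  object$slopes[j] * velocity + object$intercepts[j]
}

check_velocity <- function(velocity) {
  if (!is.numeric(velocity) || any(!is.finite(velocity)) || any(velocity < 0))
    stop("velocity must be non-negative and finite (km/h)")
  invisible(velocity)
}

#' MET switch points of a piecewise model
#'
#' The model evaluated at its change points,
#' `M^(i) = M(V_i), i = 1, ..., n - 1`. With all slopes positive the switch
#' points are strictly increasing; they are the natural boundaries for a
#' model-derived rehabilitation group scheme.
#'
#' @param model A `met_piecewise` model.
#' @return Numeric vector of MET values (empty for a single-segment model).
#' @examples
#' switch_points(copd_reference_model("women"))  # 2.304 4.094 7.782
#' @export
switch_points <- function(model) {
  stopifnot(inherits(model, "met_piecewise"))
  if (model$n_segments == 1L) return(numeric(0))
  predict(model, model$change_points)
}

#' @export
print.met_linear <- function(x, ...) {
  cat(sprintf("Linear MET model: M(v) = %.4g v + 1\n", x$slope))
  invisible(x)
}

#' @export
print.met_polynomial <- function(x, ...) {
  terms <- paste(sprintf("%+.6g v^%d", x$coefficients, seq_len(x$order)),
                 collapse = " ")
  cat(sprintf("Polynomial MET model (K = %d%s): M(v) = 1 %s\n", x$order,
              if (is.null(x$population)) "" else paste0(", ", x$population),
              terms))
  invisible(x)
}

#' @export
print.met_piecewise <- function(x, ...) {
  cat(sprintf("Piecewise-linear MET model (%d segments%s)\n", x$n_segments,
              if (is.null(x$population)) "" else paste0(", ", x$population)))
  lo <- c(0, x$change_points)
  hi <- c(x$change_points, Inf)
  for (j in seq_len(x$n_segments))
    cat(sprintf("  [%.4g, %.4g): M(v) = %.4g v %+.4g\n",
                lo[j], hi[j], x$slopes[j], x$intercepts[j]))
  if (x$n_segments > 1L)
    cat("  switch points [MET]:",
        paste(format(round(switch_points(x), 3)), collapse = ", "), "\n")
  invisible(x)
}

# ---- reference VO2max model bank ------------------------------------------

vo2max_bank <- list(
  bruce_cubic = list(
    kind = "cubic-in-T",
    coefficients = c(14.76, -1.379, 0.451, -0.012),
    note = "general Bruce-protocol cubic; resting offset 14.76 ml/kg/min"),
  bruce_women_a = list(
    kind = "linear-in-T",
    coefficients = c(3.74, 2.94),
    note = "women; offset near resting uptake"),
  bruce_women_b = list(
    kind = "linear-in-T",
    coefficients = c(-3.9, 4.38),
    note = "women; negative offset (low-sick/low-medium population)"),
  bruce_men = list(
    kind = "linear-in-T",
    coefficients = c(7.65, 2.94),
    note = "men"),
  bruce_young_men = list(
    kind = "linear-in-T",
    coefficients = c(3.91, 3.62),
    note = "young men of low effort tolerance"))

#' Reference VO2max prediction formulas for treadmill walk time
#'
#' A small bank of published VO2max (ml/kg/min) prediction equations that
#' map Bruce-protocol walk time `T` (minutes) to aerobic capacity:
#' one cubic (`bruce_cubic`) and four linear population-specific formulas
#' (`bruce_women_a`, `bruce_women_b`, `bruce_men`, `bruce_young_men`).
#' Polynomial coefficients are stored in ascending order of `T`. Offsets
#' far from the resting uptake of ~3.5 ml/kg/min signal formulas tuned to
#' narrow populations — the motivation for population-specific model banks.
#'
#' @param name Formula name; `vo2max_reference_names()` lists them.
#' @param walk_time Walk time `T` in minutes, non-negative.
#' @return VO2max in ml/kg/min.
#' @examples
#' vo2max_reference("bruce_cubic", 0)     # 14.76
#' vo2max_reference("bruce_women_a", 0)   # 3.74
#' @export
vo2max_reference <- function(name, walk_time) {
  if (!name %in% names(vo2max_bank))
    stop(sprintf("unknown VO2max reference model '%s'; see vo2max_reference_names()",
                 name))
  if (!is.numeric(walk_time) || any(!is.finite(walk_time)) ||
      any(walk_time < 0))
    stop("walk_time must be non-negative")
  coefs <- vo2max_bank[[name]]$coefficients
  acc <- rep(0, length(walk_time))
  for (a in rev(coefs)) acc <- acc * walk_time + a
  acc
}

#' @rdname vo2max_reference
#' @export
vo2max_reference_names <- function() names(vo2max_bank)

# ---- JSON serialization ----------------------------------------------------

#' Serialize and restore MET models as JSON
#'
#' Models round-trip losslessly through a small JSON document holding the
#' model kind, parameters and population label. Numbers are written at full
#' precision.
#'
#' @param model A `met_model`.
#' @param path File path; for `write_met_model` the destination, for
#'   `read_met_model` the source.
#' @return `write_met_model` returns `path` invisibly; `read_met_model`
#'   returns the restored `met_model`.
#' @export
write_met_model <- function(model, path) {
  stopifnot(inherits(model, "met_model"))
  doc <- if (inherits(model, "met_linear")) {
    list(kind = "linear", slope = model$slope)
  } else if (inherits(model, "met_polynomial")) {
    list(kind = "polynomial", coefficients = as.list(model$coefficients),
         population = model$population)
  } else {
    list(kind = "piecewise", slopes = as.list(model$slopes),
         change_points = as.list(model$change_points),
         population = model$population)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_met_model
#' @export
read_met_model <- function(path) {
  doc <- jsonlite::read_json(path)
  pop <- doc$population
  switch(doc$kind,
    linear = met_linear(doc$slope),
    polynomial = met_polynomial(unlist(doc$coefficients), population = pop),
    piecewise = met_piecewise(unlist(doc$slopes),
                              unlist(doc$change_points), population = pop),
    stop(sprintf("unknown model kind '%s' in %s", doc$kind, path)))
}
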
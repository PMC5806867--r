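#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))` with denominator `N` (no
#' degrees-of-freedom correction), the convention used throughout for both
#' in-sample and cross-validated errors.
#'
#' @param observed,predicted Equal-length non-empty numeric vectors (MET).
#' @return RMSE in MET.
#' @examples
#' rmse(c(1, 2), c(2, 2))  # sqrt(0.5)
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted))
    stop("observed and predicted must be non-empty and of equal length")
  sqrt(mean((observed - predicted)^2))
}

new_met_fit <- function(model, cohort, meta = list()) {
  pred <- predict(model, cohort$velocity)
  res <- cohort$met - pred
  structure(
    list(model = model, rmse = sqrt(mean(res^2)), sse = sum(res^2),
         residuals = res, n = nrow(cohort), cohort_label = cohort_label(cohort),
         meta = meta),
    class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat(sprintf("MET model fit to cohort '%s' (N = %d): RMSE = %.4f MET\n",
              x$cohort_label, x$n, x$rmse))
  print(x$model)
  invisible(x)
}

#' Fit the polynomial MET model by analytic least squares
#'
#' With the resting intercept fixed at 1, the model is linear in its
#' coefficients: the shifted response `M - 1` is regressed on the monomial
#' basis `v, v^2, ..., v^K` with no intercept column, giving the exact
#' least-squares solution in closed form.
#'
#' @param cohort A [walk_cohort()] with more than `order` records at
#'   distinct velocities.
#' @param order Polynomial order `K >= 1`.
#' @return A `met_fit` with the fitted [met_polynomial()] model, residuals
#'   and RMSE (1/N normalization).
#' @examples
#' co <- walk_cohort(velocity = c(1, 2, 3), met = c(1.5, 2.0, 2.5))
#' fit_met_polynomial(co, order = 1)  # slope 0.5, RMSE 0
#' @export
fit_met_polynomial <- function(cohort, order = 3) {
  stopifnot(inherits(cohort, "walk_cohort"))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  n <- nrow(cohort)
  if (n <= order || length(unique(cohort$velocity)) <= order)
    stop(sprintf(
      "need more than K = %d records with distinct velocities (have N = %d, %d distinct)",
      order, n, length(unique(cohort$velocity))))
  X <- outer(cohort$velocity, seq_len(order), `^`)
  y <- cohort$met - 1
  ls <- stats::lm.fit(X, y)
  if (ls$rank < order)
    stop(sprintf("monomial basis is rank-deficient (rank %d < K = %d)",
                 ls$rank, order))
  model <- met_polynomial(unname(ls$coefficients),
                          population = cohort_label(cohort))
  new_met_fit(model, cohort, meta = list(method = "analytic LS", order = order))
}

#' Optimal segment slopes for fixed change points
#'
#' With the change points held fixed and `b1 = 1`, the continuous
#' piecewise-linear model is linear in its remaining parameters through the
#' hinge (linear-spline) representation
#' `M(v) = 1 + a1 v + sum_j (a_j - a_{j-1}) max(0, v - V_{j-1})`,
#' so the slope increments solve an ordinary least-squares problem. This is
#' the analytic inner step of the combined LS/GA fit: the genetic search
#' only has to explore change-point locations.
#'
#' @param cohort A [walk_cohort()].
#' @param change_points Strictly increasing positive change points (km/h)
#'   inside the data's velocity range.
#' @return A list with `slopes` (per-segment, MET per km/h), `sse` (sum of
#'   squared errors), and `rank_deficient` (TRUE when some segment holds no
#'   data and the minimum-norm pseudo-inverse solution was used).
#' @export
slopes_given_change_points <- function(cohort, change_points) {
  stopifnot(inherits(cohort, "walk_cohort"))
  change_points <- as.numeric(change_points)
  k <- length(change_points)
  if (k > 0L) {
    if (any(!is.finite(change_points)) || any(change_points <= 0))
      stop("change points must be positive and finite")
    if (k > 1L && any(diff(change_points) <= 0))
      stop("change points must be strictly increasing")
    rng <- range(cohort$velocity)
    if (any(change_points <= rng[1L]) || any(change_points >= rng[2L]))
      stop("change points must lie strictly inside the observed velocity range")
  }
  v <- cohort$velocity
  y <- cohort$met - 1
  X <- hinge_basis(v, change_points)
  qx <- qr(X)
  rank_deficient <- qx$rank < ncol(X)
  if (rank_deficient) {
    warning("a segment contains no data points; using minimum-norm solution")
    theta <- as.numeric(MASS::ginv(X) %*% y)
  } else {
    theta <- qr.coef(qx, y)
  }
  slopes <- cumsum(theta)
  sse <- sum((y - as.numeric(X %*% theta))^2)
  list(slopes = unname(slopes), sse = sse, rank_deficient = rank_deficient)
}

hinge_basis <- function(v, change_points) {
  k <- length(change_points)
  X <- matrix(0, nrow = length(v), ncol = k + 1L)
  X[, 1L] <- v
  for (j in seq_len(k)) X[, j + 1L] <- pmax(0, v - change_points[j])
  X
}

# SSE of the best continuous piecewise fit for a candidate change-point
# vector; +Inf when some segment holds no data (unidentifiable slopes).
piecewise_sse <- function(v, y, change_points) {
  counts <- tabulate(findInterval(v, change_points) + 1L,
                     nbins = length(change_points) + 1L)
  if (any(counts == 0L)) return(Inf)
  X <- hinge_basis(v, change_points)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) return(Inf)
  sum(fit$residuals^2)
}

#' Configuration of the genetic change-point search
#'
#' Parameters of the outer genetic algorithm (GA) used by
#' [fit_met_piecewise()]. The GA explores change-point vectors only; slopes
#' are always obtained analytically by least squares, so the search space
#' has just `n - 1` dimensions. Candidate vectors are repaired after every
#' operator by sorting, clipping to `bounds` and enforcing `min_gap`.
#'
#' @param population_size Number of candidate change-point vectors per
#'   generation.
#' @param generations Generations per restart.
#' @param mutation_sd Gaussian mutation scale in km/h.
#' @param mutation_prob Per-gene mutation probability.
#' @param crossover_rate Probability of blend crossover per offspring.
#' @param tournament_size Tournament selection size.
#' @param elitism Number of best candidates copied unchanged.
#' @param restarts Independent GA restarts; the best result over all
#'   restarts is kept.
#' @param min_gap Minimum spacing between consecutive change points (km/h).
#' @param bounds Length-2 numeric, allowed change-point interval (km/h);
#'   `NULL` (default) uses the 5th-95th percentile of observed velocities.
#' @param polish Apply coordinate-wise golden-section refinement of the
#'   change points around the GA optimum.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 60, generations = 300,
                      mutation_sd = 0.2, mutation_prob = 0.2,
                      crossover_rate = 0.7, tournament_size = 3,
                      elitism = 2, restarts = 3, min_gap = 0.3,
                      bounds = NULL, polish = TRUE) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              mutation_sd = mutation_sd, mutation_prob = mutation_prob,
              crossover_rate = crossover_rate,
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism), restarts = as.integer(restarts),
              min_gap = min_gap, bounds = bounds, polish = isTRUE(polish))
  with(cfg, stopifnot(population_size > 0, generations > 0, mutation_sd > 0,
                      mutation_prob >= 0, mutation_prob <= 1,
                      crossover_rate >= 0, crossover_rate <= 1,
                      tournament_size > 0, elitism >= 0, restarts > 0,
                      min_gap > 0))
  structure(cfg, class = "ga_config")
}

repair_candidate <- function(x, lo, hi, gap) {
  x <- sort(pmin(pmax(x, lo), hi))
  k <- length(x)
  if (k > 1L) {
    for (i in 2:k) x[i] <- max(x[i], x[i - 1L] + gap)
    if (x[k] > hi) {          # push back down from the top
      x[k] <- hi
      for (i in (k - 1L):1L) x[i] <- min(x[i], x[i + 1L] - gap)
    }
  }
  x
}

random_candidate <- function(k, lo, hi, gap) {
  repair_candidate(stats::runif(k, lo, hi), lo, hi, gap)
}

run_ga <- function(v, y, k, cfg, lo, hi) {
  score <- function(x) piecewise_sse(v, y, x)
  pop <- matrix(0, nrow = cfg$population_size, ncol = k)
  for (i in seq_len(cfg$population_size))
    pop[i, ] <- random_candidate(k, lo, hi, cfg$min_gap)
  fit <- apply(pop, 1L, score)
  best_trace <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    ord <- order(fit)
    elite_idx <- ord[seq_len(min(cfg$elitism, cfg$population_size))]
    n_off <- cfg$population_size - length(elite_idx)
    tournament <- function() {
      cand <- sample.int(cfg$population_size, cfg$tournament_size,
                         replace = TRUE)
      cand[which.min(fit[cand])]
    }
    off <- matrix(0, nrow = n_off, ncol = k)
    for (i in seq_len(n_off)) {
      p1 <- pop[tournament(), ]
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        p2 <- pop[tournament(), ]
        u <- stats::runif(k)
        u * p1 + (1 - u) * p2
      } else p1
      mut <- stats::runif(k) < cfg$mutation_prob
      if (any(mut))
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, cfg$mutation_sd)
      off[i, ] <- repair_candidate(child, lo, hi, cfg$min_gap)
    }
    pop <- rbind(pop[elite_idx, , drop = FALSE], off)
    fit <- c(fit[elite_idx], apply(off, 1L, score))
    best_trace[g] <- min(fit)
  }
  i <- which.min(fit)
  list(change_points = pop[i, ], sse = fit[i], trace = best_trace)
}

polish_change_points <- function(v, y, cps, lo, hi, gap, max_sweeps = 20L) {
  k <- length(cps)
  # finite penalty for empty segments keeps the line search well-defined
  penalty <- 2 * sum(y^2) + 1
  objective <- function(cand) {
    val <- piecewise_sse(v, y, cand)
    if (is.finite(val)) val else penalty
  }
  sse <- objective(cps)
  for (s in seq_len(max_sweeps)) {
    before <- sse
    for (i in seq_len(k)) {
      lwr <- if (i == 1L) lo else cps[i - 1L] + gap
      upr <- if (i == k) hi else cps[i + 1L] - gap
      if (lwr >= upr) next
      opt <- stats::optimize(function(x) {
        cand <- cps
        cand[i] <- x
        objective(cand)
      }, interval = c(lwr, upr), tol = .Machine$double.eps^0.5)
      if (opt$objective < sse) {
        cps[i] <- opt$minimum
        sse <- opt$objective
      }
    }
    if (before - sse <= 1e-12 * max(1, before)) break
  }
  list(change_points = cps, sse = sse)
}

#' Fit the piecewise-linear MET model by combined LS/GA search
#'
#' Locating the change points of a continuous piecewise-linear regression
#' is a non-convex problem: plain numerical least squares gets stuck in
#' local minima. The fit therefore splits the work: a genetic algorithm
#' searches over change-point vectors (sorted, bounded, gap-respecting),
#' and every candidate is scored by the exact analytic least-squares
#' solution for its slopes ([slopes_given_change_points()]). The best
#' candidate over all generations and restarts, optionally refined by
#' coordinate-wise golden-section polish, gives the returned model. With
#' `n_segments = 1` the fit reduces to the analytic order-1 polynomial fit.
#'
#' @param cohort A [walk_cohort()]; at least two records per expected
#'   segment.
#' @param n_segments Number of linear segments `n >= 1`; rehabilitation
#'   practice divides patients into four groups, hence the default 4.
#' @param config A [ga_config()].
#' @param seed Integer seed making the stochastic search reproducible.
#' @return A `met_fit` with the fitted [met_piecewise()] model; `meta`
#'   records the seed, config, best-SSE trace per restart and a
#'   convergence flag (best SSE unchanged over the final 10% of
#'   generations).
#' @examples
#' co <- simulate_cohort(120, copd_reference_model("women"), noise_sd = 0.3,
#'                       seed = 1)
#' fit_met_piecewise(co, 4, ga_config(population_size = 30, generations = 60,
#'                                    restarts = 1), seed = 1)
#' @export
fit_met_piecewise <- function(cohort, n_segments = 4, config = ga_config(),
                              seed = 20180209) {
  stopifnot(inherits(cohort, "walk_cohort"), inherits(config, "ga_config"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (nrow(cohort) < 2L * n_segments)
    stop(sprintf("need at least %d records for %d segments",
                 2L * n_segments, n_segments))
  v <- cohort$velocity
  y <- cohort$met - 1
  if (n_segments == 1L) {
    slope <- sum(v * y) / sum(v^2)
    model <- met_piecewise(slope, population = cohort_label(cohort))
    return(new_met_fit(model, cohort,
                       meta = list(method = "analytic LS (single segment)",
                                   seed = seed)))
  }
  k <- n_segments - 1L
  bounds <- config$bounds %||% unname(stats::quantile(v, c(0.05, 0.95)))
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L])
    stop("change-point bounds must be an increasing length-2 interval")
  lo <- bounds[1L]; hi <- bounds[2L]
  if (lo + (k - 1L) * config$min_gap > hi)
    stop(sprintf(
      "infeasible configuration: %d change points with gap %g do not fit in [%g, %g]",
      k, config$min_gap, lo, hi))
  best <- NULL
  traces <- vector("list", config$restarts)
  local_seed(seed, {
    for (r in seq_len(config$restarts)) {
      res <- run_ga(v, y, k, config, lo, hi)
      traces[[r]] <- res$trace
      if (is.null(best) || res$sse < best$sse) best <- res
    }
  })
  if (!is.finite(best$sse))
    stop("no feasible change-point vector found; widen bounds or reduce n_segments")
  if (config$polish) {
    pol <- polish_change_points(v, y, best$change_points, lo, hi,
                                config$min_gap)
    if (pol$sse <= best$sse) best[c("change_points", "sse")] <- pol
  }
  inner <- slopes_given_change_points(cohort, best$change_points)
  model <- met_piecewise(inner$slopes, best$change_points,
                         population = cohort_label(cohort))
  tail_len <- max(1L, config$generations %/% 10L)
  converged <- all(vapply(traces, function(tr) {
    diff(range(utils::tail(tr, tail_len))) < 1e-9
  }, logical(1)))
  new_met_fit(model, cohort,
              meta = list(method = "combined LS/GA", seed = seed,
                          config = config, bounds = c(lo, hi),
                          sse = best$sse, traces = traces,
                          converged = converged))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Serialize a fit report to JSON
#'
#' Writes the fitted model, RMSE, sample size and optimizer metadata
#' (method, seed, convergence flag) to a JSON document.
#'
#' @param fit A `met_fit`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "met_fit"))
  m <- fit$model
  model_doc <- if (inherits(m, "met_polynomial")) {
    list(kind = "polynomial", coefficients = as.list(m$coefficients))
  } else if (inherits(m, "met_piecewise")) {
    list(kind = "piecewise", slopes = as.list(m$slopes),
         change_points = as.list(m$change_points),
         intercepts = as.list(m$intercepts))
  } else list(kind = "linear", slope = m$slope)
  model_doc$population <- m$population
  doc <- list(model = model_doc, rmse = fit$rmse, n = fit$n,
              cohort = fit$cohort_label,
              method = fit$meta$method %||% NA,
              seed = fit$meta$seed %||% NA,
              converged = fit$meta$converged %||% NA)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
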
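#' Simulate a 6MWT cohort from a known MET-velocity model
#'
#' Draws 6MWT average velocities from a truncated normal distribution,
#' evaluates a generating ("true") MET-velocity model at each velocity, and
#' adds homoscedastic Gaussian noise to yield observed treadmill MET
#' scores. Defaults emulate a COPD pulmonary-rehabilitation cohort:
#' velocities around 5 km/h (roughly 500 m walked in 6 minutes) spanning
#' 2-8.5 km/h, MET noise SD 0.55 matching the residual scatter of fits to
#' such cohorts, and ages ~ N(56.43, 6.13) truncated to 40-65 years.
#' Observed METs are truncated below at 0.1 so that badly mis-specified
#' simulations can produce sub-resting observations (which exercise the
#' classifier's below-resting flag) without ever becoming non-positive.
#'
#' @param n Number of records.
#' @param model Generating `met_model`; default the women's reference
#'   piecewise model.
#' @param velocity_mean,velocity_sd Mean and SD of the velocity
#'   distribution (km/h) before truncation.
#' @param velocity_range Length-2 truncation bounds (km/h), positive and
#'   increasing, with positive probability mass between them.
#' @param noise_sd MET noise standard deviation, `>= 0`.
#' @param sex Optional single value `"male"`/`"female"` stored per record.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution
#'   (years).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   cohort exactly.
#' @param label Cohort label; default `"synthetic:<seed>"`.
#' @return A [walk_cohort()].
#' @examples
#' co <- simulate_cohort(100, seed = 7)
#' co
#' @export
simulate_cohort <- function(n, model = copd_reference_model("women"),
                            velocity_mean = 5.0, velocity_sd = 1.2,
                            velocity_range = c(2.0, 8.5), noise_sd = 0.55,
                            sex = NULL, age_mean = 56.43, age_sd = 6.13,
                            age_range = c(40, 65), seed = 20180209,
                            label = NULL) {
  stopifnot(inherits(model, "met_model"), n > 0, noise_sd >= 0)
  check_trunc <- function(rng, mean, sd, what) {
    if (length(rng) != 2L || rng[1L] >= rng[2L] || rng[1L] < 0)
      stop(sprintf("%s range must be an increasing non-negative interval",
                   what))
    if (stats::pnorm(rng[2L], mean, sd) - stats::pnorm(rng[1L], mean, sd)
        <= 0)
      stop(sprintf("infeasible truncation: no %s mass inside [%g, %g]",
                   what, rng[1L], rng[2L]))
  }
  check_trunc(velocity_range, velocity_mean, velocity_sd, "velocity")
  check_trunc(age_range, age_mean, age_sd, "age")
  if (is.null(label)) label <- paste0("synthetic:", seed)
  local_seed(seed, {
    v <- rtruncnorm(n, velocity_mean, velocity_sd, velocity_range)
    m <- predict(model, v) + stats::rnorm(n, 0, noise_sd)
    m <- pmax(m, 0.1)
    age <- rtruncnorm(n, age_mean, age_sd, age_range)
    walk_cohort(velocity = v, met = m, sex = sex, age = age, label = label)
  })
}

# Inverse-CDF sampler for the truncated normal.
rtruncnorm <- function(n, mean, sd, range) {
  p <- stats::runif(n, stats::pnorm(range[1L], mean, sd),
                    stats::pnorm(range[2L], mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a two-sex study cohort
#'
#' Generates sex-specific cohorts from sex-specific generating models and
#' pools them, mirroring a study sample of 159 men and 140 women (299 COPD
#' patients in total).
#'
#' @param n_male,n_female Records per sex.
#' @param model_male,model_female Generating models per sex; defaults are
#'   the sex-specific reference piecewise models.
#' @param seed Integer seed; the two sexes use `seed` and `seed + 1`.
#' @param ... Passed on to [simulate_cohort()] (noise, velocity and age
#'   distributions).
#' @return A list with `walk_cohort` elements `men`, `women`, `all`.
#' @export
simulate_study_cohort <- function(n_male = 159, n_female = 140,
                                  model_male = copd_reference_model("men"),
                                  model_female = copd_reference_model("women"),
                                  seed = 20180209, ...) {
  men <- simulate_cohort(n_male, model_male, sex = "male", seed = seed,
                         label = "men", ...)
  women <- simulate_cohort(n_female, model_female, sex = "female",
                           seed = seed + 1L, label = "women", ...)
  list(men = men, women = women, all = bind_cohorts(men, women))
}

#' Change-point parameter-recovery experiment
#'
#' Repeats simulate-then-fit: each replicate draws a fresh cohort from a
#' known piecewise generating model and refits it with the combined LS/GA
#' procedure. Summaries quantify how well the procedure recovers the
#' generating parameters at a given sample size and noise level — the
#' standard evidence that a change-point estimator works when the model
#' class contains the truth.
#'
#' @param truth Generating `met_piecewise` model.
#' @param n Records per replicate.
#' @param noise_sd MET noise SD.
#' @param replicates Number of replicates, `>= 1`.
#' @param config [ga_config()] for the fits.
#' @param seed Base seed; replicate `r` uses `seed + r` for data and
#'   `seed + 10000 + r` for the GA.
#' @param tolerance_kmh Change-point recovery tolerance (km/h) used for the
#'   coverage fraction; default 0.5.
#' @param ... Passed to [simulate_cohort()].
#' @return A list of class `recovery_report`: `estimates` (one row per
#'   replicate: slopes, change points, RMSE), `slope_bias` and
#'   `changepoint_bias` (mean estimate minus truth), `slope_mc_se`
#'   (Monte-Carlo standard errors of the slope means), and `coverage`
#'   (fraction of replicates with every change point within
#'   `tolerance_kmh` of truth).
#' @export
recovery_experiment <- function(truth, n = 300, noise_sd = 0.55,
                                replicates = 50, config = ga_config(),
                                seed = 20180209, tolerance_kmh = 0.5, ...) {
  stopifnot(inherits(truth, "met_piecewise"), replicates >= 1)
  ns <- truth$n_segments
  k <- ns - 1L
  est <- matrix(NA_real_, nrow = replicates, ncol = 2L * ns,
                dimnames = list(NULL, c(paste0("slope", seq_len(ns)),
                                        paste0("cp", seq_len(k)),
                                        "rmse")))
  failures <- character(0)
  for (r in seq_len(replicates)) {
    res <- tryCatch({
      co <- simulate_cohort(n, truth, noise_sd = noise_sd, seed = seed + r,
                            ...)
      fit_met_piecewise(co, ns, config, seed = seed + 10000L + r)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    est[r, ] <- c(res$model$slopes, res$model$change_points, res$rmse)
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop("all replicates failed:\n",
                     paste(failures, collapse = "\n"))
  slopes_hat <- est[ok, seq_len(ns), drop = FALSE]
  cps_hat <- est[ok, ns + seq_len(k), drop = FALSE]
  cp_err <- abs(sweep(cps_hat, 2L, truth$change_points))
  structure(
    list(estimates = as.data.frame(est),
         truth = truth,
         slope_bias = colMeans(slopes_hat) - truth$slopes,
         slope_mc_se = apply(slopes_hat, 2L, stats::sd) / sqrt(sum(ok)),
         changepoint_bias = if (k > 0)
           colMeans(cps_hat) - truth$change_points else numeric(0),
         coverage = if (k > 0)
           mean(apply(cp_err <= tolerance_kmh, 1L, all)) else NA_real_,
         tolerance_kmh = tolerance_kmh,
         n = n, noise_sd = noise_sd, replicates = replicates,
         failures = failures),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery: %d replicates, N = %d, noise SD = %.3g MET\n",
    x$replicates, x$n, x$noise_sd))
  cat(sprintf("  change points within %.2g km/h of truth in %.0f%% of replicates\n",
              x$tolerance_kmh, 100 * x$coverage))
  cat("  slope bias:", paste(sprintf("%+.4f", x$slope_bias), collapse = " "),
      "\n")
  if (length(x$failures))
    cat(sprintf("  %d replicate(s) failed\n", length(x$failures)))
  invisible(x)
}
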
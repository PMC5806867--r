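#' Run the full estimation pipeline on a study's populations
#'
#' For each named population (typically `men`, `women`, and the pooled
#' `all` built as their concatenation), fits the order-K polynomial and the
#' n-segment piecewise MET-velocity models, optionally leave-one-out
#' cross-validates both, and classifies every record under the conventional
#' scheme and the scheme derived from the population's piecewise fit. All
#' stochastic stages derive their seeds deterministically from one
#' top-level seed, so a single integer reproduces the whole run; any stage
#' failure aborts with the population and stage named.
#'
#' @param cohorts Named list of [walk_cohort()]s, e.g. the result of
#'   [simulate_study_cohort()] or
#'   `list(men = read_cohort("s1.txt"), women = read_cohort("s2.txt"))`.
#'   When exactly `men` and `women` are supplied, the pooled `all`
#'   population is added automatically.
#' @param order Polynomial order.
#' @param n_segments Piecewise segment count.
#' @param config [ga_config()] for piecewise fits.
#' @param seed Top-level seed; population `i` uses `seed + 100 * i` offsets
#'   per stage.
#' @param loo Run LOO cross-validation for both model classes (piecewise
#'   folds re-estimate change points; this dominates runtime).
#' @param out_dir Optional directory: per-population fit reports and a
#'   combined `summary.json` are written there.
#' @return A list of class `pipeline_result`, one element per population,
#'   each holding `polynomial` and `piecewise` fits, optional `cv`
#'   reports, and `classification` (conventional and model-derived).
#' @export
run_pipeline <- function(cohorts, order = 3, n_segments = 4,
                         config = ga_config(), seed = 20180209, loo = FALSE,
                         out_dir = NULL) {
  if (!is.list(cohorts) || is.null(names(cohorts)) ||
      any(names(cohorts) == ""))
    stop("configuration error: 'cohorts' must be a named list of walk_cohort objects")
  if (!all(vapply(cohorts, inherits, logical(1), "walk_cohort")))
    stop("configuration error: every input must be a walk_cohort")
  if (setequal(names(cohorts), c("men", "women")))
    cohorts$all <- bind_cohorts(cohorts$men, cohorts$women)
  stage <- function(pop, what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for population '%s': %s",
                   what, pop, conditionMessage(e))))
  }
  out <- vector("list", length(cohorts))
  names(out) <- names(cohorts)
  for (i in seq_along(cohorts)) {
    pop <- names(cohorts)[i]
    co <- cohorts[[i]]
    pop_seed <- seed + 100L * i
    pf <- stage(pop, "fit polynomial", fit_met_polynomial(co, order))
    wf <- stage(pop, "fit piecewise",
                fit_met_piecewise(co, n_segments, config, seed = pop_seed))
    cv <- NULL
    if (loo) {
      cv <- list(
        polynomial = stage(pop, "LOO polynomial",
                           loo_cv(co, "polynomial", order = order)),
        piecewise = stage(pop, "LOO piecewise",
                          loo_cv(co, "piecewise", n_segments = n_segments,
                                 config = config, seed = pop_seed + 1L)))
    }
    cls <- stage(pop, "classification", {
      conv <- assign_cohort(co, conventional_scheme())
      derived <- if (n_segments == 4L) {
        sch <- tryCatch(scheme_from_model(wf$model), error = function(e) {
          warning(sprintf(
            "population '%s': switch points are not increasing; %s",
            pop, "no model-derived scheme"), call. = FALSE)
          NULL
        })
        if (!is.null(sch))
          list(scheme = sch, assignment = assign_cohort(co, sch),
               disagreement = scheme_disagreement(co, conventional_scheme(),
                                                  sch))
      }
      list(conventional = conv, model_derived = derived)
    })
    out[[i]] <- list(cohort = co, polynomial = pf, piecewise = wf, cv = cv,
                     classification = cls)
  }
  res <- structure(out, seed = seed, class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = attr(res, "seed"), populations = list())
  for (pop in names(res)) {
    r <- res[[pop]]
    write_fit_report(r$polynomial,
                     file.path(out_dir, paste0(pop, "_polynomial.json")))
    write_fit_report(r$piecewise,
                     file.path(out_dir, paste0(pop, "_piecewise.json")))
    summary$populations[[pop]] <- list(
      n = r$polynomial$n,
      rmse_polynomial = r$polynomial$rmse,
      rmse_piecewise = r$piecewise$rmse,
      rmse_cv_polynomial = if (!is.null(r$cv)) r$cv$polynomial$rmse_cv,
      rmse_cv_piecewise = if (!is.null(r$cv)) r$cv$piecewise$rmse_cv,
      conventional_counts =
        as.list(as.integer(r$classification$conventional$counts)))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d), %d population(s)\n",
              attr(x, "seed"), length(x)))
  for (pop in names(x)) {
    r <- x[[pop]]
    cat(sprintf("  %-6s N = %3d  RMSE poly = %.4f  RMSE piecewise = %.4f",
                pop, r$polynomial$n, r$polynomial$rmse, r$piecewise$rmse))
    if (!is.null(r$cv))
      cat(sprintf("  RMSE_cv = %.4f / %.4f", r$cv$polynomial$rmse_cv,
                  r$cv$piecewise$rmse_cv))
    cat("\n")
  }
  invisible(x)
}
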
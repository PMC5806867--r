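#' Rehabilitation group schemes
#'
#' Cardiopulmonary rehabilitation practice divides patients into four
#' groups by submaximal effort tolerance in METs, from most severe (D) to
#' least (A). The conventional division is
#' `D: 1 < M < 3`, `C: 3 <= M < 5`, `B: 5 <= M < 7`, `A: M >= 7`.
#' A scheme generalizes this to any strictly increasing boundary vector:
#' with boundaries `(t1, t2, t3)` the groups are
#' `D: M < t1`, `C: t1 <= M < t2`, `B: t2 <= M < t3`, `A: M >= t3`
#' (lower boundaries closed, matching the conventional inequalities).
#'
#' @param boundaries Strictly increasing MET thresholds.
#' @param labels Group labels from most to least severe; one more than
#'   boundaries. Default `D, C, B, A` for three boundaries.
#' @param provenance `"conventional"` or `"model-derived"`.
#' @param model Optional `met_piecewise` recorded as the boundary source.
#' @return An object of class `rehab_scheme`.
#' @seealso [conventional_scheme()], [scheme_from_model()], [classify_met()]
#' @export
rehab_scheme <- function(boundaries, labels = NULL,
                         provenance = "conventional", model = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || any(!is.finite(boundaries)))
    stop("boundaries must be finite")
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  if (is.null(labels)) {
    if (length(boundaries) != 3L)
      stop("default labels D/C/B/A require exactly 3 boundaries")
    labels <- c("D", "C", "B", "A")
  }
  if (length(labels) != length(boundaries) + 1L)
    stop("need one more label than boundaries")
  structure(list(boundaries = boundaries, labels = as.character(labels),
                 provenance = provenance, model = model),
            class = "rehab_scheme")
}

#' @export
print.rehab_scheme <- function(x, ...) {
  cat(sprintf("Rehabilitation scheme (%s): boundaries %s MET -> groups %s\n",
              x$provenance,
              paste(format(round(x$boundaries, 3)), collapse = "/"),
              paste(x$labels, collapse = " < ")))
  invisible(x)
}

#' Conventional four-group rehabilitation scheme
#'
#' Boundaries 3, 5 and 7 MET, groups D (severe) through A (less sick).
#'
#' @return A `rehab_scheme`.
#' @export
conventional_scheme <- function() {
  rehab_scheme(c(3, 5, 7), provenance = "conventional")
}

#' Rehabilitation scheme from a fitted piecewise model
#'
#' The change points of a 4-segment MET-velocity model are optimized
#' against the cohort; their MET switch points `M(V_i)` are therefore
#' data-driven candidates for the group boundaries, replacing the
#' conventional 3/5/7 MET cuts. Requires exactly 4 segments (3 switch
#' points, 4 groups), the division used in rehabilitation practice.
#'
#' @param model A `met_piecewise` with 4 segments and increasing switch
#'   points.
#' @return A `rehab_scheme` with `provenance = "model-derived"`.
#' @examples
#' scheme_from_model(copd_reference_model("women"))
#' @export
scheme_from_model <- function(model) {
  stopifnot(inherits(model, "met_piecewise"))
  if (model$n_segments != 4L)
    stop("a model-derived scheme requires a 4-segment model (4 rehabilitation groups)")
  rehab_scheme(switch_points(model), provenance = "model-derived",
               model = model)
}

#' Assign a MET value to a rehabilitation group
#'
#' Boundary membership follows the conventional inequalities: each lower
#' boundary is closed, so a MET exactly on a boundary belongs to the less
#' severe group (e.g. 3.0 MET is group C, 7.0 MET is group A). The
#' conventional division leaves `M <= 1` (at or below resting) formally
#' unassigned; such values are placed in the most severe group and flagged,
#' since near-resting scores do occur in severe patients.
#'
#' @param met Positive MET value(s).
#' @param scheme A [rehab_scheme()]; default conventional.
#' @return Character vector of group labels, with attribute
#'   `below_resting` marking records at or below 1 MET.
#' @examples
#' classify_met(c(2, 3, 7))        # "D" "C" "A"
#' @export
classify_met <- function(met, scheme = conventional_scheme()) {
  stopifnot(inherits(scheme, "rehab_scheme"))
  if (!is.numeric(met) || any(!is.finite(met)) || any(met <= 0))
    stop("MET values must be positive and finite")
  idx <- findInterval(met, scheme$boundaries) + 1L
  out <- scheme$labels[idx]
  attr(out, "below_resting") <- met <= 1
  out
}

#' Label a whole cohort and tabulate group counts
#'
#' @param cohort A [walk_cohort()].
#' @param scheme A [rehab_scheme()].
#' @return A list with `labels` (per-record group, severity-ordered
#'   factor), `counts` (per-group table summing to `N`), and
#'   `below_resting` (indices of records at or below 1 MET).
#' @export
assign_cohort <- function(cohort, scheme = conventional_scheme()) {
  stopifnot(inherits(cohort, "walk_cohort"))
  lab <- classify_met(cohort$met, scheme)
  labels <- factor(as.character(lab), levels = scheme$labels)
  list(labels = labels, counts = table(labels),
       below_resting = which(attr(lab, "below_resting")))
}

#' Compare two rehabilitation schemes on a cohort
#'
#' Model-derived boundaries generally disagree with the conventional 3/5/7
#' MET cuts; this reports which records the two schemes place in different
#' groups.
#'
#' @param cohort A [walk_cohort()].
#' @param scheme_a,scheme_b Two [rehab_scheme()]s with identical labels.
#' @return A data frame of disagreeing records with columns `record`,
#'   `met`, `group_a`, `group_b` (zero rows when the schemes agree
#'   everywhere).
#' @export
scheme_disagreement <- function(cohort, scheme_a, scheme_b) {
  stopifnot(inherits(cohort, "walk_cohort"))
  if (!identical(scheme_a$labels, scheme_b$labels))
    stop("schemes must use identical group labels")
  a <- as.character(classify_met(cohort$met, scheme_a))
  b <- as.character(classify_met(cohort$met, scheme_b))
  diff_idx <- which(a != b)
  data.frame(record = diff_idx, met = cohort$met[diff_idx],
             group_a = a[diff_idx], group_b = b[diff_idx])
}
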
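#' Construct a walk-test cohort
#'
#' A cohort is a data frame of paired measurements: one 6MWT result per
#' patient, expressed as average velocity `v_6M` (km/h), together with the
#' MET score of the patient's submaximal treadmill test. Distance in meters
#' and velocity are interchangeable (`v_6M = distance / 100`); the cohort
#' stores both.
#'
#' @param velocity 6MWT average velocities in km/h (`v_6M`); non-negative.
#'   Give either `velocity` or `distance`, not both.
#' @param met Treadmill-test MET scores; positive, same length.
#' @param distance 6MWT distances in meters (alternative to `velocity`).
#' @param sex Optional character vector (`"male"`/`"female"`), recycled.
#' @param age Optional ages in years.
#' @param label Cohort label, e.g. `"men"`, `"women"`, `"all"`.
#' @return A data frame of class `walk_cohort` with columns `velocity`,
#'   `distance`, `met` and, when given, `sex` and `age`.
#' @examples
#' walk_cohort(distance = c(450, 610), met = c(4.2, 6.9), label = "demo")
#' @export
walk_cohort <- function(velocity = NULL, met, distance = NULL, sex = NULL,
                        age = NULL, label = "cohort") {
  if (is.null(velocity) == is.null(distance))
    stop("give exactly one of 'velocity' or 'distance'")
  if (is.null(velocity)) {
    if (any(!is.finite(distance)) || any(distance < 0))
      stop("distances must be non-negative and finite")
    velocity <- distance / 100
  } else {
    if (any(!is.finite(velocity)) || any(velocity < 0))
      stop("velocities must be non-negative and finite")
    distance <- velocity * 100
  }
  if (length(met) != length(velocity))
    stop("'met' must have the same length as the walk measurements")
  if (any(!is.finite(met)) || any(met <= 0))
    stop("MET scores must be positive and finite")
  df <- data.frame(velocity = as.numeric(velocity),
                   distance = as.numeric(distance),
                   met = as.numeric(met))
  if (!is.null(sex)) {
    sex <- rep_len(as.character(sex), nrow(df))
    if (!all(sex %in% c("male", "female")))
      stop("sex must be 'male' or 'female'")
    df$sex <- sex
  }
  if (!is.null(age)) {
    age <- rep_len(as.numeric(age), nrow(df))
    if (any(!is.finite(age)) || any(age <= 0)) stop("ages must be positive")
    df$age <- age
  }
  structure(df, label = as.character(label),
            class = c("walk_cohort", "data.frame"))
}

#' @export
print.walk_cohort <- function(x, ...) {
  cat(sprintf("6MWT cohort '%s': N = %d records\n", cohort_label(x), nrow(x)))
  cat(sprintf("  velocity [km/h]: %.2f-%.2f (mean %.2f)\n",
              min(x$velocity), max(x$velocity), mean(x$velocity)))
  cat(sprintf("  MET:             %.2f-%.2f (mean %.2f)\n",
              min(x$met), max(x$met), mean(x$met)))
  invisible(x)
}

#' @rdname walk_cohort
#' @param x A `walk_cohort`.
#' @export
cohort_label <- function(x) attr(x, "label", exact = TRUE) %||% "cohort"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate cohorts into a pooled population
#'
#' The pooled "all patients" population is always built by concatenating
#' the sex-specific cohorts, so `N_all = N_men + N_women` by construction.
#'
#' @param ... `walk_cohort` objects.
#' @param label Label for the pooled cohort.
#' @return A `walk_cohort`.
#' @export
bind_cohorts <- function(..., label = "all") {
  parts <- list(...)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "walk_cohort")))
  cols <- Reduce(intersect, lapply(parts, names))
  df <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)[cols]))
  rownames(df) <- NULL
  structure(df, label = label, class = c("walk_cohort", "data.frame"))
}

# ---- plain-text cohort files ----------------------------------------------

#' Read a two-column cohort table
#'
#' Reads plain-text cohort files: two numeric columns per line, the first a
#' 6MWT result (distance in meters or average velocity in km/h), the second
#' the treadmill MET score. The delimiter (whitespace or comma) and an
#' optional single header line are auto-detected. Column semantics are
#' detected by magnitude when `columns = "auto"`: first-column values above
#' 50 are read as meters. Every malformed line is reported with its line
#' number; nothing is silently dropped.
#'
#' @param path File to read.
#' @param columns `"auto"`, `"distance_met"` or `"velocity_met"`.
#' @param label Cohort label; defaults to the file name.
#' @return A [walk_cohort()].
#' @export
read_cohort <- function(path, columns = c("auto", "distance_met",
                                          "velocity_met"),
                        label = NULL) {
  columns <- match.arg(columns)
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) stop(sprintf("cohort file is empty: %s", path))
  delim_split <- function(s) {
    s <- trimws(s)
    if (grepl(",", s, fixed = TRUE)) {
      trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    } else strsplit(s, "[[:space:]]+")[[1L]]
  }
  tokens <- lapply(lines[keep], delim_split)
  is_num <- function(tok) !any(is.na(suppressWarnings(as.numeric(tok))))
  start <- 1L
  if (!is_num(tokens[[1L]])) start <- 2L  # single header line
  if (length(tokens) < start) stop(sprintf("no data lines in %s", path))
  vals <- matrix(NA_real_, nrow = length(tokens) - start + 1L, ncol = 2L)
  for (i in seq(start, length(tokens))) {
    lineno <- keep[i]
    tok <- tokens[[i]]
    if (length(tok) != 2L)
      stop(sprintf("%s line %d: expected 2 columns, found %d",
                   path, lineno, length(tok)))
    x <- suppressWarnings(as.numeric(tok))
    if (any(is.na(x)))
      stop(sprintf("%s line %d: non-numeric value '%s'", path, lineno,
                   tok[which(is.na(x))[1L]]))
    if (any(x < 0))
      stop(sprintf("%s line %d: negative value %g", path, lineno,
                   x[x < 0][1L]))
    vals[i - start + 1L, ] <- x
  }
  if (columns == "auto")
    columns <- if (any(vals[, 1L] > 50)) "distance_met" else "velocity_met"
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (columns == "distance_met") {
    walk_cohort(distance = vals[, 1L], met = vals[, 2L], label = label)
  } else {
    walk_cohort(velocity = vals[, 1L], met = vals[, 2L], label = label)
  }
}

#' Write a cohort table
#'
#' Writes the two-column plain-text dialect accepted by [read_cohort()]
#' (header line, then whitespace-separated values at full precision), so a
#' write/read round trip reproduces the cohort exactly.
#'
#' @param cohort A [walk_cohort()].
#' @param path Destination file.
#' @param columns Which first column to write: `"distance_met"` (meters,
#'   default) or `"velocity_met"` (km/h).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         columns = c("distance_met", "velocity_met")) {
  stopifnot(inherits(cohort, "walk_cohort"))
  columns <- match.arg(columns)
  if (columns == "distance_met") {
    header <- "distance met"
    col1 <- cohort$distance
  } else {
    header <- "velocity met"
    col1 <- cohort$velocity
  }
  lines <- c(header, paste(format(col1, digits = 17, trim = TRUE),
                           format(cohort$met, digits = 17, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}
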
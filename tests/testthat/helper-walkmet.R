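# Shared fixtures built in code.

# Reduced GA budget for test-scale fits; verified to reach the same optima
# as the default configuration on cohorts of the sizes used here.
light_ga <- function(bounds = NULL, ...) {
  ga_config(population_size = 30, generations = 80, restarts = 2,
            bounds = bounds, ...)
}

# Cohort lying exactly on a given model over a dense velocity grid.
noiseless_cohort <- function(model, v = seq(0.5, 8, length.out = 500),
                             label = "noiseless") {
  walk_cohort(velocity = v, met = predict(model, v), label = label)
}

# Collinear records through the resting anchor (0 km/h, 1 MET).
collinear_cohort <- function(slope = 0.5, v = c(1, 2, 3)) {
  walk_cohort(velocity = v, met = 1 + slope * v, label = "collinear")
}

# Independent least-squares oracle for a fixed change-point vector:
# explicit normal equations on the hinge basis, no package fitting code.
oracle_hinge_sse <- function(v, met, change_points) {
  X <- cbind(v, vapply(change_points, function(cp) pmax(0, v - cp),
                       numeric(length(v))))
  y <- met - 1
  theta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% theta)^2)
}
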
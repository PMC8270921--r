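# Shared fixtures, all built in code.

# the three reference norms used in recovery experiments
fig_norms <- function() recovery_norms()

# random slope set with non-negative entries, optionally constrained so the
# first-order (and finite-p) denominators stay strictly positive
random_slopes <- function(constrained = FALSE) {
  if (!constrained) {
    return(slope_set(runif(1), runif(1), runif(1), runif(1), runif(1)))
  }
  repeat {
    s <- slope_set(Ax = runif(1, 0, 0.3), Ay = runif(1, 0.2, 0.9),
                   Az = runif(1, 0, 0.3), Bx = runif(1, 0, 0.3),
                   By = runif(1, 0.2, 0.9))
    ok <- (s[["Ax"]] + s[["Az"]] < 0.95) &&
      (s[["Ax"]] + s[["Ay"]] * s[["Bx"]] < 0.95) &&
      (s[["Ax"]] + s[["Az"]] + s[["Ay"]] * (s[["Bx"]] + s[["By"]]) < 0.95)
    if (ok) return(s)
  }
}

random_norm_table <- function() {
  norm_table(runif(8), runif(4))
}

eps_vec <- function(x) {
  if (inherits(x, "reduced_state")) 1 - c(x$m00, x$m01, x$m10, x$m11)
  else c(x$eps00, x$eps01, x$eps10, x$eps11)
}
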
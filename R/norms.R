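# Norm construction and differentiation.
#
# Conventions (throughout the package): action C = 1, D = 0; reputation
# good = 1, bad = 0. An assessment corner a_uXv is the reputation assigned
# to a donor with reputation u who did X to a recipient with reputation v;
# a behaviour corner b_uv is the action prescribed to a donor with
# self-reputation u facing a co-player with reputation v.

# Canonical corner orderings. The "table order" used in user-facing vectors
# follows the usual presentation of the leading eight; the "binary order"
# (index 4u + 2X + v) is what the C++ kernel consumes.
ALPHA_KEYS <- c("a_1C1", "a_1D1", "a_1C0", "a_1D0",
                "a_0C1", "a_0D1", "a_0C0", "a_0D0")
BETA_KEYS <- c("b_11", "b_10", "b_01", "b_00")
ALPHA_BINARY_ORDER <- c("a_0D0", "a_0D1", "a_0C0", "a_0C1",
                        "a_1D0", "a_1D1", "a_1C0", "a_1C1")
BETA_BINARY_ORDER <- c("b_00", "b_01", "b_10", "b_11")

LEADING_EIGHT <- list(
  L1 = list(a = c(1, 0, 1, 1, 1, 0, 1, 0), b = c(1, 0, 1, 1)),
  L2 = list(a = c(1, 0, 0, 1, 1, 0, 1, 0), b = c(1, 0, 1, 1)),
  L3 = list(a = c(1, 0, 1, 1, 1, 0, 1, 1), b = c(1, 0, 1, 0)),
  L4 = list(a = c(1, 0, 1, 1, 1, 0, 0, 1), b = c(1, 0, 1, 0)),
  L5 = list(a = c(1, 0, 0, 1, 1, 0, 1, 1), b = c(1, 0, 1, 0)),
  L6 = list(a = c(1, 0, 0, 1, 1, 0, 0, 1), b = c(1, 0, 1, 0)),
  L7 = list(a = c(1, 0, 1, 1, 1, 0, 0, 0), b = c(1, 0, 1, 0)),
  L8 = list(a = c(1, 0, 0, 1, 1, 0, 0, 0), b = c(1, 0, 1, 0))
)

# dimension-preserving clamp to [0,1] (pmin/pmax would drop dim attributes)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Binary norm table
#'
#' A binary social norm is specified by eight assessment corner values
#' `a_uXv` (donor reputation u, action X in {C, D}, recipient reputation v)
#' and four behaviour corner values `b_uv`, all in \[0,1\]. Values of 1 and 0
#' encode good/cooperate and bad/defect; fractional values are allowed and
#' give stochastic (or graded) corner behaviour.
#'
#' @param assessment numeric vector of length 8. Either named with the keys
#'   `a_1C1, a_1D1, a_1C0, a_1D0, a_0C1, a_0D1, a_0C0, a_0D0`, or unnamed in
#'   exactly that order.
#' @param behaviour numeric vector of length 4, named `b_11, b_10, b_01,
#'   b_00` or unnamed in that order.
#' @param name optional label.
#' @return an object of class `norm_table`.
#' @seealso [leading_eight()], [interpolate_norm()]
#' @examples
#' norm_table(c(1, 0, 1, 1, 1, 0, 1, 1), c(1, 0, 1, 0), name = "L3")
#' @export
norm_table <- function(assessment, behaviour, name = NULL) {
  assessment <- resolve_corners(assessment, ALPHA_KEYS, "assessment")
  behaviour <- resolve_corners(behaviour, BETA_KEYS, "behaviour")
  structure(list(assessment = assessment, behaviour = behaviour,
                 name = name),
            class = "norm_table")
}

resolve_corners <- function(x, keys, what) {
  if (length(x) != length(keys)) {
    stop(sprintf("%s must have %d corner values, got %d",
                 what, length(keys), length(x)), call. = FALSE)
  }
  if (!is.numeric(x)) stop(what, " corners must be numeric", call. = FALSE)
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop(what, " corner values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(x))) {
    names(x) <- keys
  } else {
    if (!setequal(names(x), keys)) {
      stop(what, " corner names must be exactly {",
           paste(keys, collapse = ", "), "}", call. = FALSE)
    }
    x <- x[keys]
  }
  x
}

#' @export
print.norm_table <- function(x, ...) {
  cat("Binary norm table", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n  assessment:", paste(sprintf("%s=%g", names(x$assessment),
                                       x$assessment), collapse = " "),
      "\n  behaviour: ", paste(sprintf("%s=%g", names(x$behaviour),
                                       x$behaviour), collapse = " "), "\n")
  invisible(x)
}

#' Leading-eight norm presets
#'
#' Returns one of the eight binary norms that keep cooperation stable under
#' public assessment. Notable members: L3 "Simple Standing" (defection
#' against the ill-reputed is tolerated), L6 "Stern Judging", L8 "Judging".
#' `"SS"` is accepted as an alias of `"L3"`.
#'
#' @param name one of `"L1"` ... `"L8"` or `"SS"`.
#' @return a [norm_table()].
#' @examples
#' leading_eight("L3")
#' @export
leading_eight <- function(name) {
  if (!is.character(name) || length(name) != 1) {
    stop("name must be a single character string", call. = FALSE)
  }
  if (identical(name, "SS")) name <- "L3"
  row <- LEADING_EIGHT[[name]]
  if (is.null(row)) {
    stop(sprintf("unknown norm '%s'; valid names: %s, SS", name,
                 paste(names(LEADING_EIGHT), collapse = ", ")),
         call. = FALSE)
  }
  norm_table(row$a, row$b, name = name)
}

new_norm_pair <- function(alpha, beta, table = NULL, label = NULL,
                          alpha_raw = NULL, beta_raw = NULL) {
  cooperative <- isTRUE(all.equal(alpha(1, 1, 1), 1)) &&
    isTRUE(all.equal(beta(1, 1), 1))
  structure(list(alpha = alpha, beta = beta, table = table,
                 cooperative = cooperative, label = label,
                 alpha_raw = alpha_raw, beta_raw = beta_raw),
            class = "norm_pair")
}

#' @export
print.norm_pair <- function(x, ...) {
  cat("Continuous norm",
      if (!is.null(x$label)) paste0("'", x$label, "'"),
      if (!is.null(x$table)) "(interpolated)",
      sprintf("\n  cooperative fixed point: %s", x$cooperative),
      "\n")
  s <- norm_slopes(x)
  cat(sprintf("  slopes at (1,1,1)/(1,1): Ax=%.4g Ay=%.4g Az=%.4g Bx=%.4g By=%.4g\n",
              s[["Ax"]], s[["Ay"]], s[["Az"]], s[["Bx"]], s[["By"]]))
  invisible(x)
}

#' Interpolate a binary norm table to a continuous norm
#'
#' Extends a binary norm to continuous reputations and actions by trilinear
#' interpolation of the assessment corners and bilinear interpolation of the
#' behaviour corners. The resulting maps are multilinear, reproduce every
#' corner exactly, and automatically stay inside \[0,1\] (each value is a
#' convex combination of the corners). For Simple Standing (L3) the
#' interpolated assessment rule is `alpha(x, y, z) = y*z - z + 1` and the
#' behaviour rule is `beta(x, y) = y`.
#'
#' @param table a [norm_table()], or a preset name accepted by
#'   [leading_eight()].
#' @return a `norm_pair` with vectorized functions `alpha(x, y, z)` and
#'   `beta(x, y)`, carrying the corner table.
#' @examples
#' ss <- interpolate_norm("L3")
#' ss$alpha(0.5, 0.5, 0.5)  # 0.75
#' @export
interpolate_norm <- function(table) {
  table <- as_norm_table(table)
  a <- table$assessment
  b <- table$behaviour
  alpha <- function(x, y, z) {
    xm <- 1 - x; ym <- 1 - y; zm <- 1 - z
    a[["a_0D0"]] * xm * ym * zm + a[["a_0D1"]] * xm * ym * z +
      a[["a_0C0"]] * xm * y * zm + a[["a_0C1"]] * xm * y * z +
      a[["a_1D0"]] * x * ym * zm + a[["a_1D1"]] * x * ym * z +
      a[["a_1C0"]] * x * y * zm + a[["a_1C1"]] * x * y * z
  }
  beta <- function(x, y) {
    xm <- 1 - x; ym <- 1 - y
    b[["b_00"]] * xm * ym + b[["b_01"]] * xm * y +
      b[["b_10"]] * x * ym + b[["b_11"]] * x * y
  }
  new_norm_pair(alpha, beta, table = table, label = table$name)
}

#' Coerce to a binary norm table
#'
#' @param x a `norm_table`, a preset name (see [leading_eight()]), or a
#'   `norm_pair` produced by [interpolate_norm()].
#' @return a [norm_table()].
#' @export
as_norm_table <- function(x) {
  if (inherits(x, "norm_table")) return(x)
  if (is.character(x)) return(leading_eight(x))
  if (inherits(x, "norm_pair")) {
    if (is.null(x$table)) {
      stop("this norm_pair does not carry a corner table; ",
           "use as_corner_norm() to project it first", call. = FALSE)
    }
    return(x$table)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a norm table", call. = FALSE)
}

as_norm_pair <- function(x) {
  if (inherits(x, "norm_pair")) return(x)
  interpolate_norm(as_norm_table(x))
}

#' Build a norm with prescribed slopes at the cooperative point
#'
#' Constructs the planar norm `alpha = 1 - Ax*(1-x) - Ay*(1-y) - Az*(1-z)`
#' and `beta = 1 - Bx*(1-x) - By*(1-y)`, clamped to \[0,1\]. Near the
#' cooperative point (all arguments close to 1) the clamp is inactive, so
#' the partial derivatives there equal the requested slopes exactly. Useful
#' for probing the recovery criterion with slope combinations that no
#' corner table in \[0,1\] can realize.
#'
#' @param Ax,Ay,Az slopes of the assessment rule in the donor-reputation,
#'   action, and recipient-reputation directions.
#' @param Bx,By slopes of the behaviour rule in the self- and co-player
#'   reputation directions.
#' @return a `norm_pair` (not interpolated; carries no corner table).
#' @export
slope_norm <- function(Ax, Ay, Az, Bx, By) {
  force(Ax); force(Ay); force(Az); force(Bx); force(By)
  alpha <- function(x, y, z) clamp01(1 - Ax * (1 - x) - Ay * (1 - y) - Az * (1 - z))
  beta <- function(x, y) clamp01(1 - Bx * (1 - x) - By * (1 - y))
  new_norm_pair(alpha, beta,
                label = sprintf("slopes (%g,%g,%g)/(%g,%g)", Ax, Ay, Az, Bx, By))
}

#' Slope set at the cooperative point
#'
#' @param Ax,Ay,Az,Bx,By first partial derivatives of the assessment rule at
#'   (1,1,1) and of the behaviour rule at (1,1).
#' @return named numeric of class `slope_set` with an attribute
#'   `nonnegative` recording whether all five slopes are >= 0 (assumed by
#'   the ordering argument that makes the fourth eigenvalue family the
#'   largest).
#' @export
slope_set <- function(Ax, Ay, Az, Bx, By) {
  s <- c(Ax = Ax, Ay = Ay, Az = Az, Bx = Bx, By = By)
  if (!all(is.finite(s))) stop("slopes must be finite", call. = FALSE)
  structure(s, nonnegative = all(s >= 0), class = "slope_set")
}

#' @export
print.slope_set <- function(x, ...) {
  cat(sprintf("Slopes: Ax=%.6g Ay=%.6g Az=%.6g Bx=%.6g By=%.6g%s\n",
              x[["Ax"]], x[["Ay"]], x[["Az"]], x[["Bx"]], x[["By"]],
              if (isTRUE(attr(x, "nonnegative"))) "" else "  (not all >= 0)"))
  invisible(x)
}

as_slope_set <- function(x) {
  if (inherits(x, "slope_set")) return(x)
  if (inherits(x, c("norm_pair", "norm_table")) || is.character(x)) {
    return(norm_slopes(x))
  }
  if (is.numeric(x) && length(x) == 5) {
    if (is.null(names(x))) names(x) <- c("Ax", "Ay", "Az", "Bx", "By")
    return(slope_set(x[["Ax"]], x[["Ay"]], x[["Az"]], x[["Bx"]], x[["By"]]))
  }
  stop("cannot interpret object as a slope set", call. = FALSE)
}

#' First derivatives of a norm at the cooperative point
#'
#' For interpolated (multilinear) norms the partials are exact corner
#' differences, e.g. `Ax = a_1C1 - a_0C1` and `Az = a_1C1 - a_1C0`. For
#' general norms one-sided backward finite differences with step `h` are
#' used, because the cooperative point (1,1,1) sits on the boundary of the
#' domain; for a multilinear map these differences are exact for any h.
#'
#' @param norm a `norm_pair`, `norm_table`, or preset name.
#' @param h finite-difference step (default 1e-6).
#' @return a [slope_set()].
#' @examples
#' norm_slopes("L3")  # Ax=0 Ay=1 Az=0 Bx=0 By=1
#' @export
norm_slopes <- function(norm, h = 1e-6) {
  if (is.character(norm) || inherits(norm, "norm_table")) {
    norm <- interpolate_norm(as_norm_table(norm))
  }
  stopifnot(inherits(norm, "norm_pair"))
  if (!is.null(norm$table)) {
    a <- norm$table$assessment
    b <- norm$table$behaviour
    return(slope_set(Ax = a[["a_1C1"]] - a[["a_0C1"]],
                     Ay = a[["a_1C1"]] - a[["a_1D1"]],
                     Az = a[["a_1C1"]] - a[["a_1C0"]],
                     Bx = b[["b_11"]] - b[["b_01"]],
                     By = b[["b_11"]] - b[["b_10"]]))
  }
  al <- norm$alpha; be <- norm$beta
  vals <- c(al(1, 1, 1), al(1 - h, 1, 1), al(1, 1 - h, 1), al(1, 1, 1 - h),
            be(1, 1), be(1 - h, 1), be(1, 1 - h))
  if (!all(is.finite(vals))) {
    stop("norm evaluation returned non-finite values near the cooperative point",
         call. = FALSE)
  }
  slope_set(Ax = (vals[1] - vals[2]) / h,
            Ay = (vals[1] - vals[3]) / h,
            Az = (vals[1] - vals[4]) / h,
            Bx = (vals[5] - vals[6]) / h,
            By = (vals[5] - vals[7]) / h)
}

#' Second derivatives of a norm at the cooperative point
#'
#' Returns the nine second partials (Axx, Ayy, Azz, Axy, Ayz, Azx, Bxx,
#' Bxy, Byy) used by the second-order mutant expansion. For interpolated
#' norms the pure second partials vanish (multilinearity) and the mixed
#' ones are exact corner combinations, e.g.
#' `Axy = a_1C1 - a_1D1 - a_0C1 + a_0D1`. For general norms one-sided
#' backward differences with step `h` are used (accuracy O(h)).
#'
#' @inheritParams norm_slopes
#' @param h finite-difference step for non-interpolated norms.
#' @return named numeric of class `curvature_set`.
#' @export
norm_curvatures <- function(norm, h = 1e-4) {
  if (is.character(norm) || inherits(norm, "norm_table")) {
    norm <- interpolate_norm(as_norm_table(norm))
  }
  stopifnot(inherits(norm, "norm_pair"))
  if (!is.null(norm$table)) {
    a <- norm$table$assessment
    b <- norm$table$behaviour
    cs <- c(Axx = 0, Ayy = 0, Azz = 0,
            Axy = a[["a_1C1"]] - a[["a_1D1"]] - a[["a_0C1"]] + a[["a_0D1"]],
            Ayz = a[["a_1C1"]] - a[["a_1D1"]] - a[["a_1C0"]] + a[["a_1D0"]],
            Azx = a[["a_1C1"]] - a[["a_1C0"]] - a[["a_0C1"]] + a[["a_0C0"]],
            Bxx = 0, Byy = 0,
            Bxy = b[["b_11"]] - b[["b_10"]] - b[["b_01"]] + b[["b_00"]])
    return(structure(cs, class = "curvature_set"))
  }
  al <- norm$alpha; be <- norm$beta
  pure <- function(f) (f(0) - 2 * f(h) + f(2 * h)) / h^2
  mixed <- function(f) (f(0, 0) - f(h, 0) - f(0, h) + f(h, h)) / h^2
  cs <- c(
    Axx = pure(function(d) al(1 - d, 1, 1)),
    Ayy = pure(function(d) al(1, 1 - d, 1)),
    Azz = pure(function(d) al(1, 1, 1 - d)),
    Axy = mixed(function(dx, dy) al(1 - dx, 1 - dy, 1)),
    Ayz = mixed(function(dy, dz) al(1, 1 - dy, 1 - dz)),
    Azx = mixed(function(dz, dx) al(1 - dx, 1, 1 - dz)),
    Bxx = pure(function(d) be(1 - d, 1)),
    Byy = pure(function(d) be(1, 1 - d)),
    Bxy = mixed(function(dx, dy) be(1 - dx, 1 - dy))
  )
  structure(cs, class = "curvature_set")
}

curvature_set <- function(Axx = 0, Ayy = 0, Azz = 0, Axy = 0, Ayz = 0,
                          Azx = 0, Bxx = 0, Byy = 0, Bxy = 0) {
  structure(c(Axx = Axx, Ayy = Ayy, Azz = Azz, Axy = Axy, Ayz = Ayz,
              Azx = Azx, Bxx = Bxx, Byy = Byy, Bxy = Bxy),
            class = "curvature_set")
}

#' Mutant offset functions
#'
#' A mutant norm is written as the resident norm minus small offset
#' functions: `alpha_mut = alpha - delta`, `beta_mut = beta - eta`. The
#' scalars `delta1 = delta(1,1,1)` and `eta1 = eta(1,1)` must be
#' non-negative: starting from the fully cooperative state, only a mutant
#' that devalues cooperation (or cooperates less) at the cooperative point
#' produces a first-order payoff effect with a definite sign.
#'
#' The default `delta` is `delta1 * (2*y*z - 2*z + 1)`, the offset used in
#' the half-and-half mutant experiments; the default `eta` is the constant
#' `eta1`. First partial derivatives at the cooperative point are computed
#' by backward differences (they enter only the second-order expansion).
#'
#' @param delta1 offset of the assessment rule at (1,1,1), >= 0.
#' @param eta1 offset of the behaviour rule at (1,1), >= 0.
#' @param delta optional function of (x, y, z); must satisfy
#'   `delta(1,1,1) == delta1`.
#' @param eta optional function of (x, y); must satisfy `eta(1,1) == eta1`.
#' @param magnitude_warn warn if |delta1| or |eta1| exceeds this (the
#'   perturbation theory assumes small offsets).
#' @return an object of class `mutant_offset`.
#' @examples
#' off <- mutant_offset(delta1 = 0.02)
#' off$delta(1, 0, 1)  # -0.02
#' @export
mutant_offset <- function(delta1 = 0.02, eta1 = 0, delta = NULL, eta = NULL,
                          magnitude_warn = 0.2) {
  if (delta1 < 0 || eta1 < 0) {
    stop("delta1 and eta1 must be non-negative", call. = FALSE)
  }
  if (max(delta1, eta1) > magnitude_warn) {
    warning("offset magnitude exceeds ", magnitude_warn,
            "; the perturbative formulas assume small offsets")
  }
  if (is.null(delta)) {
    force(delta1)
    delta <- function(x, y, z) delta1 * (2 * y * z - 2 * z + 1)
  }
  if (is.null(eta)) {
    force(eta1)
    eta <- function(x, y) rep_len(eta1, length(x * y))
  }
  stopifnot(isTRUE(all.equal(delta(1, 1, 1), delta1)),
            isTRUE(all.equal(eta(1, 1), eta1)))
  h <- 1e-6
  d1 <- delta(1, 1, 1)
  e1 <- eta(1, 1)
  structure(list(
    delta = delta, eta = eta, delta1 = delta1, eta1 = eta1,
    dpart = c(x = (d1 - delta(1 - h, 1, 1)) / h,
              y = (d1 - delta(1, 1 - h, 1)) / h,
              z = (d1 - delta(1, 1, 1 - h)) / h),
    epart = c(x = (e1 - eta(1 - h, 1)) / h,
              y = (e1 - eta(1, 1 - h)) / h)
  ), class = "mutant_offset")
}

#' Subtract an offset from a norm
#'
#' Builds the mutant norm `(alpha - delta, beta - eta)`. Evaluation is
#' clamped to \[0,1\]; the unclamped functions are kept in the fields
#' `alpha_raw`/`beta_raw` for analytic use (the perturbative expansions
#' never leave \[0,1\] at first order, but arbitrary offsets can).
#'
#' @param base a `norm_pair` (or table/preset) for the resident norm.
#' @param offset a [mutant_offset()].
#' @return a `norm_pair`. If `base` is interpolated and the offset is
#'   multilinear, the result carries the exact mutant corner table.
#' @examples
#' mut <- offset_norm("L3", mutant_offset(delta1 = 0.02))
#' mut$alpha(1, 1, 1)  # 0.98
#' @export
offset_norm <- function(base, offset) {
  base <- as_norm_pair(base)
  stopifnot(inherits(offset, "mutant_offset"))
  ba <- base$alpha; bb <- base$beta
  de <- offset$delta; et <- offset$eta
  alpha_raw <- function(x, y, z) ba(x, y, z) - de(x, y, z)
  beta_raw <- function(x, y) bb(x, y) - et(x, y)
  alpha <- function(x, y, z) clamp01(alpha_raw(x, y, z))
  beta <- function(x, y) clamp01(beta_raw(x, y))
  out <- new_norm_pair(alpha, beta, label = paste0(
    if (is.null(base$label)) "norm" else base$label,
    sprintf(" - offset(d1=%g, e1=%g)", offset$delta1, offset$eta1)),
    alpha_raw = alpha_raw, beta_raw = beta_raw)
  out$offset <- offset
  # keep a corner table when the offset preserves multilinearity
  if (!is.null(base$table)) {
    projected <- try(as_corner_norm(out, tol = 1e-10), silent = TRUE)
    if (!inherits(projected, "try-error")) {
      out$table <- projected$table
    }
  }
  out
}

#' Project a norm onto its corner table
#'
#' Evaluates `alpha`/`beta` at the 12 corners of the unit cubes and builds
#' the interpolated norm with those corners, verifying on a grid that the
#' projection reproduces the original norm (i.e. that the norm is
#' multilinear up to `tol`). The stochastic simulator requires
#' corner-representable norms; this is the projection it applies.
#'
#' @param norm a `norm_pair`.
#' @param tol maximum absolute deviation allowed on the check grid.
#' @param grid_n points per axis for the check grid.
#' @return an interpolated `norm_pair`.
#' @export
as_corner_norm <- function(norm, tol = 1e-8, grid_n = 4) {
  norm <- as_norm_pair(norm)
  if (!is.null(norm$table)) return(norm)
  u <- c(0, 1)
  a <- numeric(8); names(a) <- ALPHA_KEYS
  for (du in u) for (dv in u) for (dX in u) {
    key <- sprintf("a_%d%s%d", du, if (dX == 1) "C" else "D", dv)
    a[[key]] <- norm$alpha(du, dX, dv)
  }
  b <- numeric(4); names(b) <- BETA_KEYS
  for (du in u) for (dv in u) b[[sprintf("b_%d%d", du, dv)]] <- norm$beta(du, dv)
  cand <- interpolate_norm(norm_table(a, b, name = norm$label))
  g <- seq(0, 1, length.out = grid_n)
  gr <- expand.grid(x = g, y = g, z = g)
  if (max(abs(cand$alpha(gr$x, gr$y, gr$z) - norm$alpha(gr$x, gr$y, gr$z))) > tol ||
      max(abs(cand$beta(gr$x[1:(grid_n^2)], gr$y[1:(grid_n^2)]) -
              norm$beta(gr$x[1:(grid_n^2)], gr$y[1:(grid_n^2)]))) > tol) {
    stop("norm is not corner-representable (not multilinear within tol = ",
         tol, ")", call. = FALSE)
  }
  cand
}

#' Random corner norm
#'
#' Draws the seven assessment corners other than `a_1C1` uniformly on
#' \[0,1\] (with `a_1C1` fixed to 1 when `fix_cooperative`, so the norm
#' keeps the cooperative fixed point) and interpolates. By default the
#' behaviour corners are Simple Standing's, so the mutant differs from L3
#' only in its assessment slopes.
#'
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   first (the global RNG stream is advanced either way).
#' @param fix_cooperative keep `a_1C1 = 1`.
#' @param random_beta also draw the four behaviour corners uniformly.
#' @return an interpolated `norm_pair`.
#' @export
random_corner_norm <- function(seed = NULL, fix_cooperative = TRUE,
                               random_beta = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  a <- runif(8)
  names(a) <- ALPHA_KEYS
  if (fix_cooperative) a[["a_1C1"]] <- 1
  b <- if (random_beta) setNames(runif(4), BETA_KEYS) else
    setNames(LEADING_EIGHT$L3$b, BETA_KEYS)
  interpolate_norm(norm_table(a, b, name = "random"))
}

# corner vectors in the binary order consumed by the C++ kernel
alpha_corners_binary <- function(norm) {
  unname(as_corner_norm(norm)$table$assessment[ALPHA_BINARY_ORDER])
}
beta_corners_binary <- function(norm) {
  unname(as_corner_norm(norm)$table$behaviour[BETA_BINARY_ORDER])
}
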
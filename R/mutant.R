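# Stationary-state mutant analysis.
#
# A mutant norm (alpha - delta, beta - eta) with delta1 = delta(1,1,1) >= 0
# and eta1 = eta(1,1) >= 0 is introduced into a resident population sitting
# at the fully cooperative state. The stationary image matrix then deviates
# from all-ones; the deviations eps_gh (g, h in {0 = mutant, 1 = resident})
# admit closed forms at first order, and the payoff difference between a
# mutant and a resident decides whether the norm punishes its local
# variants.

#' Donation-game parameters
#'
#' @param b benefit the recipient gains per unit cooperation.
#' @param c cost the donor pays per unit cooperation. The donation game is
#'   a dilemma for `0 < c < b`; the degenerate boundary `b = c` is allowed
#'   so that benefit-cost sweeps can start at b/c = 1.
#' @return an object of class `game_params`.
#' @export
game_params <- function(b = 2, c = 1) {
  if (!(is.numeric(b) && is.numeric(c) && c > 0 && b >= c)) {
    stop("game parameters must satisfy 0 < c <= b", call. = FALSE)
  }
  structure(list(b = b, c = c), class = "game_params")
}

singularity_stop <- function(which) {
  msg <- switch(which,
    resident_assessment = "singular denominator: 1 - Ax - Az must be > 0",
    behaviour_feedback = "singular denominator: 1 - Ax - Ay*Bx must be > 0",
    finite_p = paste0("singular denominator: Ax + Az + Ay*(Bx + By) < 1 is ",
                      "violated (as it is for all leading-eight norms); use ",
                      "the numeric oracle stationary_numeric() instead"))
  stop(structure(class = c("contrep_singularity", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_first_order_denominators <- function(s) {
  if (1 - s[["Ax"]] - s[["Az"]] <= 0) singularity_stop("resident_assessment")
  if (1 - s[["Ax"]] - s[["Ay"]] * s[["Bx"]] <= 0) {
    singularity_stop("behaviour_feedback")
  }
  invisible(TRUE)
}

new_perturbation_solution <- function(eps00, eps01, eps10, eps11, order,
                                      dpi0 = NA_real_) {
  structure(list(eps00 = eps00, eps01 = eps01, eps10 = eps10, eps11 = eps11,
                 dpi0 = dpi0, order = order),
            class = "perturbation_solution")
}

#' @export
print.perturbation_solution <- function(x, ...) {
  cat(sprintf(
    "Perturbation solution (%s):\n  eps00=%.6g eps01=%.6g eps10=%.6g eps11=%.6g\n",
    x$order, x$eps00, x$eps01, x$eps10, x$eps11))
  if (!is.na(x$dpi0)) cat(sprintf("  payoff difference dpi0 = %.6g\n", x$dpi0))
  invisible(x)
}

#' First-order stationary deviations for a rare mutant
#'
#' Closed forms for the stationary reputation deviations when a single
#' mutant (fraction p -> 0) with offsets (delta1, eta1) invades the
#' cooperative state:
#' \deqn{eps01 = delta1 / (1 - Ax - Az)}
#' \deqn{eps00 = [(1 - Ax + Ay By) delta1 + (1 - Ax - Az) Ay eta1] /
#'   [(1 - Ax - Az)(1 - Ax - Ay Bx)]}
#' \deqn{eps10 = Ay [(Bx + By) delta1 + (1 - Ax - Az) eta1] /
#'   [(1 - Ax - Az)(1 - Ax - Ay Bx)]}
#' and `eps11 = 0` (residents keep perfect opinions of each other). Valid
#' when both `1 - Ax - Az > 0` and `1 - Ax - Ay*Bx > 0`.
#'
#' @inheritParams compute_Q
#' @param delta1,eta1 non-negative offsets of the mutant's assessment and
#'   behaviour rules at the cooperative point.
#' @return a `perturbation_solution`.
#' @export
first_order_epsilons <- function(slopes, delta1, eta1 = 0) {
  s <- as_slope_set(slopes)
  stopifnot(delta1 >= 0, eta1 >= 0)
  check_first_order_denominators(s)
  Ax <- s[["Ax"]]; Ay <- s[["Ay"]]; Az <- s[["Az"]]
  Bx <- s[["Bx"]]; By <- s[["By"]]
  D1 <- 1 - Ax - Az
  D2 <- 1 - Ax - Ay * Bx
  new_perturbation_solution(
    eps00 = ((1 - Ax + Ay * By) * delta1 + D1 * Ay * eta1) / (D1 * D2),
    eps01 = delta1 / D1,
    eps10 = Ay * ((Bx + By) * delta1 + D1 * eta1) / (D1 * D2),
    eps11 = 0,
    order = "first_order")
}

#' Stationary deviations for a finite mutant fraction
#'
#' Linear-order closed forms when the mutant occupies a finite fraction p
#' of the population. The limit p -> 0 reproduces
#' [first_order_epsilons()]. Requires, in addition to the two rare-mutant
#' denominators, `Ax + Az + Ay*(Bx + By) < 1`, i.e. Q < 0 -- an inequality
#' every leading-eight norm violates, which is why the Q = 0 / Q > 0 norms
#' must be handled by the numeric oracle [stationary_numeric()].
#'
#' @inheritParams first_order_epsilons
#' @param p mutant fraction in \[0, 1\].
#' @return a `perturbation_solution`.
#' @export
finite_p_epsilons <- function(slopes, delta1, eta1 = 0, p = 0) {
  s <- as_slope_set(slopes)
  stopifnot(delta1 >= 0, eta1 >= 0, p >= 0, p <= 1)
  check_first_order_denominators(s)
  Ax <- s[["Ax"]]; Ay <- s[["Ay"]]; Az <- s[["Az"]]
  Bx <- s[["Bx"]]; By <- s[["By"]]
  if (Ax + Az + Ay * (Bx + By) >= 1) singularity_stop("finite_p")
  pb <- 1 - p
  D1 <- 1 - Ax - Az
  D2 <- 1 - Ax - Ay * Bx
  D3 <- 1 - Ax - Ay * Bx - Ay * By - Az
  den <- D1 * D2 * D3
  eps00 <- (delta1 * (Ax^2 + Ax * (Ay * Bx + Az - 2) -
                        pb * Ay^2 * Bx * By - pb * Ay^2 * By^2 +
                        Az * (Ay * (p * Bx - pb * By) - 1) - Ay * Bx + 1) +
              Ay * eta1 * D1 * (1 - Ax - Ay * Bx - pb * Ay * By - pb * Az)) / den
  eps01 <- (Ay * eta1 * p * D1 * (Ay * By + Az) +
              delta1 * (Ax^2 + Ax * (2 * Ay * Bx + Ay * By + Az - 2) +
                          Ay^2 * Bx^2 + Ay^2 * Bx * By * p + Ay^2 * Bx * By +
                          Ay^2 * By^2 * p) +
              delta1 * (Az * (Ay * (p * Bx + Bx + p * By) - 1) -
                          2 * Ay * Bx - Ay * By + 1)) / den
  common <- eta1 * D1 + (Bx + By) * delta1
  eps10 <- Ay * (1 - Ax - Ay * Bx - pb * Ay * By - pb * Az) * common / den
  eps11 <- Ay * p * (Ay * By + Az) * common / den
  new_perturbation_solution(eps00, eps01, eps10, eps11, order = "finite_p")
}

#' First-order payoff difference of a mutant
#'
#' \deqn{dpi0 = -\frac{b Ay By - c (1 - Ax)}{1 - Ax - Ay Bx}
#'   \left[\frac{Bx + By}{1 - Ax - Az}\, delta1 + eta1\right]}
#' The value is independent of the mutant fraction p (a cancellation that
#' holds exactly in the linearized algebra), and its sign flips at the
#' benefit-cost ratio [bc_threshold()].
#'
#' @inheritParams first_order_epsilons
#' @param game a [game_params()].
#' @return a single number (payoff units).
#' @export
payoff_difference_first_order <- function(slopes, delta1, eta1 = 0,
                                          game = game_params()) {
  s <- as_slope_set(slopes)
  stopifnot(delta1 >= 0, eta1 >= 0, inherits(game, "game_params"))
  check_first_order_denominators(s)
  Ax <- s[["Ax"]]; Ay <- s[["Ay"]]; Az <- s[["Az"]]
  Bx <- s[["Bx"]]; By <- s[["By"]]
  -(game$b * Ay * By - game$c * (1 - Ax)) / (1 - Ax - Ay * Bx) *
    ((Bx + By) / (1 - Ax - Az) * delta1 + eta1)
}

#' Benefit-cost threshold for punishing local mutants
#'
#' A norm penalizes every nearby mutant with `delta1 > 0` or `eta1 > 0`
#' (given the non-singularity conditions) if and only if
#' `b/c > (1 - Ax)/(Ay * By)`. If `Ay * By = 0` the threshold is infinite:
#' cooperation cannot be stabilized when reputation is insensitive to the
#' donor's action (Ay ~ 0) or behaviour is insensitive to the co-player's
#' reputation (By ~ 0).
#'
#' @inheritParams compute_Q
#' @return a single number, possibly `Inf`.
#' @examples
#' bc_threshold("L3")                         # 1
#' bc_threshold(slope_set(0, 0.9, 0, 0, 0.9)) # 1/0.81
#' @export
bc_threshold <- function(slopes) {
  s <- as_slope_set(slopes)
  denom <- s[["Ay"]] * s[["By"]]
  if (denom <= 0) return(Inf)
  unname((1 - s[["Ax"]]) / denom)
}

#' Two-type reduced state
#'
#' The four block reputations of the mutant/resident reduction: `m00`
#' (mutants' view of mutants), `m01` (mutants' view of residents), `m10`
#' (residents' view of mutants), `m11` (residents' view of residents),
#' plus the mutant fraction `p`.
#'
#' @param m00,m01,m10,m11 reputations in \[0,1\].
#' @param p mutant fraction in \[0,1\].
#' @return an object of class `reduced_state`.
#' @export
reduced_state <- function(m00, m01, m10, m11, p) {
  vals <- c(m00, m01, m10, m11, p)
  if (anyNA(vals) || any(vals < 0 | vals > 1)) {
    stop("reduced-state entries and p must lie in [0, 1]", call. = FALSE)
  }
  structure(list(m00 = m00, m01 = m01, m10 = m10, m11 = m11, p = p),
            class = "reduced_state")
}

#' Expected payoffs in the two-type reduction
#'
#' Exact (non-linearized) expected payoffs of a mutant (pi0) and a resident
#' (pi1) given the block reputations, using the norms' behaviour rules:
#' a mutant donates `beta0(m00, m00)` to fellow mutants and
#' `beta0(m00, m01)` to residents, receives from residents according to
#' `beta1(m11, m10)`, and so on. In a fully cooperative state with
#' identical norms both payoffs equal `b - c`.
#'
#' @param state a [reduced_state()].
#' @param resident,mutant `norm_pair` objects (only `beta` is used).
#' @param game a [game_params()].
#' @return named numeric `c(pi0 = ..., pi1 = ...)`.
#' @export
expected_payoffs <- function(state, resident, mutant, game = game_params()) {
  stopifnot(inherits(state, "reduced_state"))
  resident <- as_norm_pair(resident)
  mutant <- as_norm_pair(mutant)
  b0 <- mutant$beta; b1 <- resident$beta
  p <- state$p; pb <- 1 - p
  m00 <- state$m00; m01 <- state$m01; m10 <- state$m10; m11 <- state$m11
  pi0 <- game$b * (p * b0(m00, m00) + pb * b1(m11, m10)) -
    game$c * (p * b0(m00, m00) + pb * b0(m00, m01))
  pi1 <- game$b * (p * b0(m00, m01) + pb * b1(m11, m11)) -
    game$c * (p * b1(m11, m10) + pb * b1(m11, m11))
  c(pi0 = pi0, pi1 = pi1)
}

# Linearized payoffs assembled from a perturbation solution; used to verify
# the p-independence of the first-order payoff difference.
linearized_payoffs <- function(slopes, eps, eta1, game, p) {
  s <- as_slope_set(slopes)
  Bx <- s[["Bx"]]; By <- s[["By"]]
  pb <- 1 - p
  e00 <- eps$eps00; e01 <- eps$eps01; e10 <- eps$eps10; e11 <- eps$eps11
  pi0 <- game$b * (p * (1 - Bx * e00 - By * e00 - eta1) +
                     pb * (1 - Bx * e11 - By * e10)) -
    game$c * (p * (1 - Bx * e00 - By * e00 - eta1) +
                pb * (1 - Bx * e00 - By * e01 - eta1))
  pi1 <- game$b * (p * (1 - Bx * e00 - By * e01 - eta1) +
                     pb * (1 - Bx * e11 - By * e11)) -
    game$c * (p * (1 - Bx * e11 - By * e10) +
                pb * (1 - Bx * e11 - By * e11))
  c(pi0 = pi0, pi1 = pi1)
}

#' Numeric stationary state of the two-type reduction
#'
#' Damped fixed-point iteration of the four coupled stationarity equations
#' \deqn{m00 = p a0[m00, b0(m00, m00), m00] + (1-p) a0[m00, b0(m00, m01), m01]}
#' \deqn{m01 = p a0[m01, b1(m11, m10), m00] + (1-p) a0[m01, b1(m11, m11), m01]}
#' \deqn{m10 = p a1[m10, b0(m00, m00), m10] + (1-p) a1[m10, b0(m00, m01), m11]}
#' \deqn{m11 = p a1[m11, b1(m11, m10), m10] + (1-p) a1[m11, b1(m11, m11), m11]}
#' starting from the all-ones state. This is the full nonlinear problem,
#' so it captures every higher-order effect the perturbative closed forms
#' neglect; it serves as the oracle for them.
#'
#' @param resident,mutant `norm_pair` objects (alpha and beta are used).
#' @param p mutant fraction in \[0, 1\].
#' @param tol convergence tolerance on the max absolute update.
#' @param max_iter iteration cap.
#' @param damping damping factor lambda in (0, 1\]; the update is
#'   `new = (1 - lambda) * old + lambda * rhs`.
#' @return a [reduced_state()] with attribute `iterations`.
#' @export
stationary_numeric <- function(resident, mutant, p = 0, tol = 1e-12,
                               max_iter = 1e5, damping = 0.5) {
  resident <- as_norm_pair(resident)
  mutant <- as_norm_pair(mutant)
  stopifnot(p >= 0, p <= 1, damping > 0, damping <= 1)
  a0 <- mutant$alpha; b0 <- mutant$beta
  a1 <- resident$alpha; b1 <- resident$beta
  pb <- 1 - p
  st <- c(1, 1, 1, 1)  # (m00, m01, m10, m11)
  rhs <- function(v) {
    m00 <- v[1]; m01 <- v[2]; m10 <- v[3]; m11 <- v[4]
    c(p * a0(m00, b0(m00, m00), m00) + pb * a0(m00, b0(m00, m01), m01),
      p * a0(m01, b1(m11, m10), m00) + pb * a0(m01, b1(m11, m11), m01),
      p * a1(m10, b0(m00, m00), m10) + pb * a1(m10, b0(m00, m01), m11),
      p * a1(m11, b1(m11, m10), m10) + pb * a1(m11, b1(m11, m11), m11))
  }
  for (it in seq_len(max_iter)) {
    target <- rhs(st)
    new <- (1 - damping) * st + damping * target
    delta <- max(abs(new - st))
    st <- new
    if (delta < tol) {
      out <- reduced_state(st[1], st[2], st[3], st[4], p)
      attr(out, "iterations") <- it
      return(out)
    }
  }
  stop(sprintf(
    "fixed-point iteration did not converge in %d iterations (residual %.3g)",
    as.integer(max_iter), max(abs(rhs(st) - st))), call. = FALSE)
}

as_eps_vector <- function(x) {
  if (inherits(x, "perturbation_solution")) {
    c(x$eps00, x$eps01, x$eps10, x$eps11)
  } else if (inherits(x, "reduced_state")) {
    1 - c(x$m00, x$m01, x$m10, x$m11)
  } else {
    stopifnot(is.numeric(x), length(x) == 4)
    as.numeric(x)
  }
}

#' Second-order residual of the stationarity conditions
#'
#' Expands the four two-type stationarity equations to second order in the
#' deviations and offsets: the behaviour rules contribute
#' `kappa = Bx*eps_x + By*eps_y + eta1` at first order plus curvature and
#' offset-derivative corrections, and the assessment rules contribute the
#' analogous expansion with the curvatures Axx..Azx and the offset
#' derivatives (delta_x, delta_y, delta_z). The residual at a candidate
#' deviation vector `(eps00, eps01, eps10, eps11)` is RHS - LHS of the
#' four equations; at the first-order solution it is O(delta1^2), and a
#' root of the residual is the second-order solution (the closed-form
#' second-order coefficients are not tabulated anywhere, so the solve is
#' done numerically by [solve_second_order()]).
#'
#' @inheritParams first_order_epsilons
#' @param curv a `curvature_set` from [norm_curvatures()].
#' @param offset a [mutant_offset()].
#' @param eps candidate deviations: a `perturbation_solution`, a
#'   `reduced_state`, or a numeric 4-vector (eps00, eps01, eps10, eps11).
#' @param p mutant fraction.
#' @return numeric residual 4-vector.
#' @export
second_order_residual <- function(slopes, curv, offset, eps, p = 0) {
  s <- as_slope_set(slopes)
  stopifnot(inherits(curv, "curvature_set"), inherits(offset, "mutant_offset"))
  e <- as_eps_vector(eps)
  e00 <- e[1]; e01 <- e[2]; e10 <- e[3]; e11 <- e[4]
  Ax <- s[["Ax"]]; Ay <- s[["Ay"]]; Az <- s[["Az"]]
  Bx <- s[["Bx"]]; By <- s[["By"]]
  Axx <- curv[["Axx"]]; Ayy <- curv[["Ayy"]]; Azz <- curv[["Azz"]]
  Axy <- curv[["Axy"]]; Ayz <- curv[["Ayz"]]; Azx <- curv[["Azx"]]
  Bxx <- curv[["Bxx"]]; Byy <- curv[["Byy"]]; Bxy <- curv[["Bxy"]]
  d1 <- offset$delta1; dx <- offset$dpart[["x"]]
  dy <- offset$dpart[["y"]]; dz <- offset$dpart[["z"]]
  n1 <- offset$eta1; nx <- offset$epart[["x"]]; ny <- offset$epart[["y"]]
  # kappa: donor's deviation from full cooperation, split by order
  kappa <- function(mutant_donor, ex, ey) {
    k1 <- Bx * ex + By * ey + if (mutant_donor) n1 else 0
    k2 <- -(0.5 * Bxx * ex^2 + Bxy * ex * ey + 0.5 * Byy * ey^2)
    if (mutant_donor) k2 <- k2 - (nx * ex + ny * ey)
    list(k1 = k1, k2 = k2)
  }
  # alpha expanded to second order at (1 - er, 1 - kappa, 1 - es)
  alpha2 <- function(mutant_observer, er, kap, es) {
    k1 <- kap$k1
    val <- 1 - Ax * er - Ay * (kap$k1 + kap$k2) - Az * es +
      0.5 * Axx * er^2 + 0.5 * Ayy * k1^2 + 0.5 * Azz * es^2 +
      Axy * er * k1 + Ayz * k1 * es + Azx * er * es
    if (mutant_observer) val <- val - (d1 - dx * er - dy * k1 - dz * es)
    val
  }
  pb <- 1 - p
  r1 <- p * alpha2(TRUE, e00, kappa(TRUE, e00, e00), e00) +
    pb * alpha2(TRUE, e00, kappa(TRUE, e00, e01), e01) - (1 - e00)
  r2 <- p * alpha2(TRUE, e01, kappa(FALSE, e11, e10), e00) +
    pb * alpha2(TRUE, e01, kappa(FALSE, e11, e11), e01) - (1 - e01)
  r3 <- p * alpha2(FALSE, e10, kappa(TRUE, e00, e00), e10) +
    pb * alpha2(FALSE, e10, kappa(TRUE, e00, e01), e11) - (1 - e10)
  r4 <- p * alpha2(FALSE, e11, kappa(FALSE, e11, e10), e10) +
    pb * alpha2(FALSE, e11, kappa(FALSE, e11, e11), e11) - (1 - e11)
  c(r1, r2, r3, r4)
}

#' Solve the second-order stationarity conditions
#'
#' Newton iteration (finite-difference Jacobian) on
#' [second_order_residual()], started from the first-order solution when it
#' exists, otherwise from zero.
#'
#' @inheritParams second_order_residual
#' @param start optional starting 4-vector.
#' @param tol convergence tolerance on the residual norm.
#' @param max_iter Newton iteration cap.
#' @return a `perturbation_solution` with `order = "second_order"`.
#' @export
solve_second_order <- function(slopes, curv, offset, p = 0, start = NULL,
                               tol = 1e-13, max_iter = 100) {
  s <- as_slope_set(slopes)
  if (is.null(start)) {
    start <- tryCatch(
      as_eps_vector(first_order_epsilons(s, offset$delta1, offset$eta1)),
      contrep_singularity = function(e) rep(0, 4))
  }
  x <- as_eps_vector(start)
  f <- function(v) second_order_residual(s, curv, offset, v, p = p)
  h <- 1e-8
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) break
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - fx) / h
    }
    step <- tryCatch(solve(J, fx), error = function(e) {
      stop("singular Jacobian in second-order Newton solve", call. = FALSE)
    })
    x <- x - step
  }
  if (max(abs(f(x))) >= tol) {
    stop("second-order Newton solve did not converge", call. = FALSE)
  }
  new_perturbation_solution(x[1], x[2], x[3], x[4], order = "second_order")
}

#' Analytic report for a norm and mutant offset
#'
#' Convenience wrapper composing the stability and mutant toolkits: the
#' recovery criterion Q, the eigenvalue spectrum, the benefit-cost
#' threshold, the first-order (and, when non-singular, finite-p)
#' deviations, the numeric stationary state, and the payoff differences.
#'
#' @param norm resident norm (`norm_pair`, table, or preset name).
#' @param delta1,eta1 mutant offsets at the cooperative point.
#' @param p mutant fraction for the finite-p and numeric branches.
#' @param game a [game_params()].
#' @param q observation probability (spectrum only).
#' @param N population size (spectrum only).
#' @return a list of class `mutant_report`.
#' @export
mutant_report <- function(norm, delta1 = 0.02, eta1 = 0, p = 0.5,
                          game = game_params(), q = 0.4, N = 50) {
  norm <- as_norm_pair(norm)
  s <- norm_slopes(norm)
  offset <- mutant_offset(delta1 = delta1, eta1 = eta1)
  mutant <- offset_norm(norm, offset)
  first <- tryCatch(first_order_epsilons(s, delta1, eta1),
                    contrep_singularity = function(e) conditionMessage(e))
  finite <- tryCatch(finite_p_epsilons(s, delta1, eta1, p),
                     contrep_singularity = function(e) conditionMessage(e))
  dpi_first <- tryCatch(
    payoff_difference_first_order(s, delta1, eta1, game),
    contrep_singularity = function(e) NA_real_)
  numeric_state <- stationary_numeric(norm, mutant, p)
  pay <- expected_payoffs(numeric_state, norm, mutant, game)
  structure(list(
    norm = norm$label, slopes = s, Q = compute_Q(s),
    spectrum = eigen_spectrum(s, q, N),
    bc_threshold = bc_threshold(s),
    delta1 = delta1, eta1 = eta1, p = p, game = game,
    first_order = first, finite_p = finite,
    dpi0_first_order = dpi_first,
    numeric_state = numeric_state,
    payoffs_numeric = pay,
    dpi0_numeric = unname(pay["pi0"] - pay["pi1"])
  ), class = "mutant_report")
}

#' @export
print.mutant_report <- function(x, ...) {
  cat("Mutant analysis for", if (is.null(x$norm)) "norm" else x$norm, "\n")
  print(x$slopes)
  cat(sprintf("  Q = %.6g   b/c threshold = %.6g\n", x$Q, x$bc_threshold))
  cat(sprintf("  offsets: delta1 = %g, eta1 = %g, mutant fraction p = %g\n",
              x$delta1, x$eta1, x$p))
  if (inherits(x$first_order, "perturbation_solution")) {
    print(x$first_order)
  } else cat("  first-order: ", x$first_order, "\n")
  if (inherits(x$finite_p, "perturbation_solution")) {
    print(x$finite_p)
  } else cat("  finite-p: ", x$finite_p, "\n")
  cat(sprintf("  dpi0 (first order) = %.6g\n", x$dpi0_first_order))
  cat(sprintf("  numeric stationary state: m00=%.8g m01=%.8g m10=%.8g m11=%.8g\n",
              x$numeric_state$m00, x$numeric_state$m01,
              x$numeric_state$m10, x$numeric_state$m11))
  cat(sprintf("  dpi0 (numeric) = %.6g\n", x$dpi0_numeric))
  invisible(x)
}
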